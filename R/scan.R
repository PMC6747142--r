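# Mismatch- and bulge-tolerant guide-RNA site scanner.
#
# The scanner slides the protospacer along both strands and counts
# Hamming mismatches at every offset with a handful of vectorised
# cumulative-mismatch matrices; a single one-nucleotide bulge is handled
# by combining a prefix match with a shifted suffix match.  Coordinates
# are 0-based half-open on the forward reference strand.

hit_cols <- c("contig", "start", "end", "strand", "guide", "mismatches",
              "bulge", "bulge_offset", "pam_observed", "cut_position")

empty_hits <- function() {
  tibble(contig = character(), start = integer(), end = integer(),
         strand = character(), guide = character(), mismatches = integer(),
         bulge = character(), bulge_offset = integer(),
         pam_observed = character(), cut_position = integer())
}

# Cumulative mismatch matrix: M[o, j] = number of protospacer positions
# 1..j that mismatch the sequence when position j is compared to
# codes[o + j - 1 + shift].  Rows are offsets 1..n.
mismatch_cummat <- function(codep, proto, n, shift) {
  L <- length(proto)
  M <- matrix(0L, nrow = n, ncol = L)
  acc <- integer(n)
  jstart <- if (shift < 0) 2L else 1L
  for (j in jstart:L) {
    lo <- j + shift
    acc <- acc + as.integer(codep[lo:(lo + n - 1L)] != proto[j])
    M[, j] <- acc
  }
  M
}

# PAM evaluation at 1-based local start positions `p` (vectorised).
# Returns ok (pattern match, best across alternative patterns) and mm
# (minimum number of failing PAM positions across patterns).
pam_eval <- function(codep, p, patterns) {
  ok <- rep(FALSE, length(p))
  mm <- rep(3L, length(p))
  for (pat in patterns) {
    chars <- strsplit(pat, "", fixed = TRUE)[[1]]
    miss <- integer(length(p))
    for (k in 1:3) {
      allowed <- pam_allowed_codes(chars[k])
      miss <- miss + as.integer(!(codep[p + k - 1L] %in% allowed))
    }
    ok <- ok | (miss == 0L)
    mm <- pmin(mm, miss)
  }
  list(ok = ok, mm = mm)
}

# Scan one strand (local coordinates). Returns a data frame of candidate
# alignments before dedup: o (1-based local protospacer start), type,
# bulge_offset, mismatches, pam0 (0-based local PAM start), span.
scan_one_strand <- function(codes, proto, patterns, params) {
  S <- length(codes)
  L <- length(proto)
  n_none <- S - L - 2L
  n_dna  <- S - L - 3L
  n_rna  <- S - L - 1L
  n <- max(n_none, n_dna, if (params$allow_bulge) n_rna else 0L, 0L)
  if (n < 1L) return(NULL)
  codep <- c(codes, rep.int(0L, 8L))

  M0 <- mismatch_cummat(codep, proto, n, 0L)
  out <- list()

  # pam_pe: precomputed pam_eval at this alignment type's PAM positions
  take <- function(o, mm_proto, pam_p, pam_pe, type, b, span) {
    pe <- list(ok = pam_pe$ok[o], mm = pam_pe$mm[o])
    if (params$pam_mismatch_counted) {
      mm <- mm_proto + pe$mm
      ok <- rep(TRUE, length(o))
    } else {
      mm <- mm_proto
      ok <- pe$ok
    }
    cap <- if (type == "none") params$max_mismatches else
      min(params$bulge_mismatch_cap, params$max_mismatches)
    keep <- ok & mm <= cap
    if (!any(keep)) return(NULL)
    data.frame(o = o[keep], type = type, bulge_offset = b,
               mismatches = mm[keep], pam0 = pam_p[keep] - 1L, span = span)
  }

  if (n_none >= 1L) {
    o <- seq_len(n_none)
    pe0 <- pam_eval(codep, o + L, patterns)
    out[[length(out) + 1L]] <-
      take(o, M0[o, L], o + L, pe0, "none", NA_integer_, L + 3L)
  }

  if (params$allow_bulge) {
    if (n_dna >= 1L) {
      M1 <- mismatch_cummat(codep, proto, n, 1L)
      o <- seq_len(n_dna)
      pe_dna <- pam_eval(codep, o + L + 1L, patterns)
      for (b in 1:(L - 1L)) {
        mm <- M0[o, b] + (M1[o, L] - M1[o, b])
        out[[length(out) + 1L]] <-
          take(o, mm, o + L + 1L, pe_dna, "dna_bulge", b, L + 4L)
      }
    }
    if (n_rna >= 1L && L >= 3L) {
      Mm1 <- mismatch_cummat(codep, proto, n, -1L)
      o <- seq_len(n_rna)
      pe_rna <- pam_eval(codep, o + L - 1L, patterns)
      for (b in 2:(L - 1L)) {
        mm <- M0[o, b - 1L] + (Mm1[o, L] - Mm1[o, b])
        out[[length(out) + 1L]] <-
          take(o, mm, o + L - 1L, pe_rna, "rna_bulge", b, L + 2L)
      }
    }
  }

  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(NULL)
  cand <- do.call(rbind, out)

  # one alignment per (offset, type): fewest mismatches, then leftmost bulge
  cand <- cand[order(cand$o, cand$type, cand$mismatches, cand$bulge_offset), ]
  key <- paste(cand$o, cand$type)
  cand[!duplicated(key), ]
}

bulge_rank <- c(none = 0L, dna_bulge = 1L, rna_bulge = 2L)

# Suppress bulge alignments dominated by an overlapping bulge-free hit on
# the same strand with no more mismatches, then keep the single best hit
# per (contig, cut_position): fewest mismatches, bulge-free preferred,
# leftmost, then '+' strand.
dedup_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  free <- hits[hits$bulge == "none", ]
  if (nrow(free) > 0 && any(hits$bulge != "none")) {
    keep <- rep(TRUE, nrow(hits))
    bidx <- which(hits$bulge != "none")
    for (i in bidx) {
      dom <- free$contig == hits$contig[i] & free$strand == hits$strand[i] &
        free$start < hits$end[i] & free$end > hits$start[i] &
        free$mismatches <= hits$mismatches[i]
      if (any(dom)) keep[i] <- FALSE
    }
    hits <- hits[keep, ]
  }
  ord <- order(hits$contig, hits$cut_position, hits$mismatches,
               bulge_rank[hits$bulge], hits$start, hits$strand != "+",
               hits$bulge_offset)
  hits <- hits[ord, ]
  hits <- hits[!duplicated(paste(hits$contig, hits$cut_position)), ]
  hits[order(hits$start, hits$strand), ]
}

#' Scan a DNA sequence for guide-RNA target sites
#'
#' Finds every site on both strands matching the guide's protospacer
#' within the mismatch budget, optionally allowing a single
#' one-nucleotide DNA or RNA bulge (with at most `bulge_mismatch_cap`
#' mismatches), followed by a PAM matching one of the guide's IUPAC
#' patterns.  PAM mismatches are not counted against the mismatch budget
#' unless `params$pam_mismatch_counted` is set.  `N` (or any ambiguity
#' code) in the genome counts as a mismatch at protospacer positions.
#'
#' Overlapping alignments are reduced to one record per site: a bulge
#' alignment is reported only when no overlapping bulge-free alignment
#' on the same strand has as few mismatches, and alignments sharing a
#' cut position are reduced to the best one (fewest mismatches, then
#' bulge-free, then leftmost, then the `+` strand).
#'
#' @param seq DNA sequence (character string; IUPAC letters allowed).
#' @param guide A single guide, as returned by [guide_target()] (one row).
#' @param params A [match_params()] object.
#' @param contig Contig name recorded in the output.
#' @return A tibble of hits with 0-based half-open `start`/`end` covering
#'   protospacer + PAM, `strand`, `mismatches`, `bulge`
#'   (`none`/`dna_bulge`/`rna_bulge`), `bulge_offset` (position within
#'   the protospacer), `pam_observed` (as read on the hit strand) and
#'   `cut_position` (the blunt cut lies between `cut_position` and
#'   `cut_position + 1`, 3 nt 5' of the PAM).
#' @export
scan_sequence <- function(seq, guide, params = match_params(),
                          contig = "seq") {
  stopifnot(inherits(params, "match_params"))
  if (is.data.frame(guide)) {
    if (nrow(guide) != 1) abort("scan_sequence() takes a single guide")
    gname <- guide$name
    proto_str <- guide$protospacer
    patterns <- pam_patterns(guide$pam)
  } else {
    abort("guide must be a one-row guide_target() tibble")
  }
  check_protospacer(proto_str)
  codes <- seq_to_codes(seq)
  S <- length(codes)
  L <- nchar(proto_str)
  if (S < L + 2L) return(empty_hits())
  proto <- seq_to_codes(proto_str, "protospacer")

  seq_fwd <- toupper(seq)
  seq_rev <- revcomp(seq_fwd)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_fwd else seq_rev
    cand <- scan_one_strand(seq_to_codes(s), proto, patterns, params)
    if (is.null(cand)) next
    l_start0 <- cand$o - 1L
    l_end0 <- l_start0 + cand$span
    l_cut <- cand$pam0 - 4L
    if (strand == "+") {
      start0 <- l_start0; end0 <- l_end0; cut <- l_cut
    } else {
      start0 <- S - l_end0; end0 <- S - l_start0
      cut <- S - l_cut - 2L
    }
    res[[strand]] <- tibble(
      contig = contig, start = start0, end = end0, strand = strand,
      guide = gname, mismatches = cand$mismatches, bulge = cand$type,
      bulge_offset = cand$bulge_offset,
      pam_observed = substr(rep(s, nrow(cand)), cand$pam0 + 1L,
                            cand$pam0 + 3L),
      cut_position = cut
    )
  }
  hits <- bind_rows(res)
  if (nrow(hits) == 0) return(empty_hits())
  as_tibble(dedup_hits(as.data.frame(hits)))
}

#' Scan a genome for target sites of a set of guides
#'
#' Applies [scan_sequence()] to every contig and every guide.
#'
#' @param genome Named character vector of contig sequences, a
#'   `DNAStringSet`, or a FASTA file path.
#' @param guides An `editscan_guides` tibble ([guide_target()] /
#'   [read_guides()]).
#' @inheritParams scan_sequence
#' @return A tibble of hits (see [scan_sequence()]) over all guides and
#'   contigs, ordered by guide, contig, start.
#' @export
scan_genome <- function(genome, guides, params = match_params()) {
  genome <- as_genome(genome)
  if (nrow(guides) == 0) return(empty_hits())
  out <- purrr::map_dfr(seq_len(nrow(guides)), function(i) {
    g <- guides[i, ]
    purrr::map_dfr(names(genome), function(ctg) {
      scan_sequence(genome[[ctg]], g, params, contig = ctg)
    })
  })
  if (nrow(out) == 0) return(empty_hits())
  arrange(out, .data$guide, match(.data$contig, names(genome)),
          .data$start, .data$strand)
}

#' Write guide-site hits as BED6+ and TSV
#'
#' BED columns are contig, start, end, guide name, mismatches, strand,
#' plus bulge, pam_observed and cut_position; coordinates 0-based
#' half-open.
#'
#' @param hits Hit tibble from [scan_sequence()]/[scan_genome()].
#' @param bed,tsv Output paths (either may be `NULL` to skip).
#' @return `hits`, invisibly.
#' @export
write_hits <- function(hits, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) {
    bed_tbl <- hits[, c("contig", "start", "end", "guide", "mismatches",
                        "strand", "bulge", "pam_observed", "cut_position")]
    readr::write_tsv(bed_tbl, bed, col_names = FALSE)
  }
  if (!is.null(tsv)) readr::write_tsv(hits, tsv)
  invisible(hits)
}
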