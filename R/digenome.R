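# Digenome-style in vitro cleavage-site calling from read-start pileups.
# A blunt Cas9 cut between reference positions p and p+1 (0-based) shows
# up as forward-read 5' ends piling at p+1 and reverse-read 5' ends
# (rightmost aligned bases) piling at p.

#' Read an alignment table
#'
#' Dependency-free plain-text alignment format: a TSV with columns
#' `contig`, `strand` (`+`/`-`), `start`, `end` — 0-based half-open
#' reference span of the aligned bases (soft-clips excluded).
#'
#' @param path TSV path.
#' @return An alignment tibble.
#' @export
read_alignment_table <- function(path) {
  al <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          contig = readr::col_character(),
                          strand = readr::col_character(),
                          start = readr::col_integer(),
                          end = readr::col_integer()))
  al
}

# Reference span consumed by a CIGAR string (M/D/N/=/X).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- stringr::str_match_all(cg, "(\\d+)([MIDNSHP=X])")[[1]]
    sum(as.integer(ops[ops[, 3] %in% c("M", "D", "N", "=", "X"), 2]))
  }, integer(1), USE.NAMES = FALSE)
}

#' Read alignments from a coordinate-sorted SAM/BAM file
#'
#' Secondary, supplementary, duplicate and unmapped records are
#' excluded; the reference span is derived from POS and CIGAR, so
#' soft-clipped bases never contribute to read starts.
#'
#' @param path SAM or BAM file.
#' @return An alignment tibble (`contig`, `strand`, `start`, `end`,
#'   0-based half-open).
#' @export
read_alignments_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path,
                             destination = tempfile(fileext = ""),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isUnmappedQuery = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flags,
                               what = c("rname", "strand", "pos", "cigar"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  w <- cigar_ref_width(b$cigar)
  tibble(contig = as.character(b$rname),
         strand = as.character(b$strand),
         start = as.integer(b$pos) - 1L,
         end = as.integer(b$pos) - 1L + w)
}

#' Build a read-start profile from alignments
#'
#' Forward reads contribute their leftmost aligned base, reverse reads
#' their rightmost aligned base (the 5' end on each strand).  The
#' profile also keeps the alignment intervals for local-depth queries.
#'
#' @param alignments Alignment tibble (`contig`, `strand`, `start`,
#'   `end`, 0-based half-open), coordinate-sorted within contigs.
#' @return An object of class `readstart_profile`.
#' @export
build_read_start_profile <- function(alignments) {
  stopifnot(all(c("contig", "strand", "start", "end") %in%
                  names(alignments)))
  if (nrow(alignments) > 0) {
    unsorted <- alignments %>%
      group_by(.data$contig) %>%
      summarise(bad = is.unsorted(.data$start), .groups = "drop")
    if (any(unsorted$bad)) {
      abort("alignments must be coordinate-sorted within each contig")
    }
    if (!all(alignments$strand %in% c("+", "-"))) {
      abort("strand must be '+' or '-'")
    }
  }
  fwd <- alignments %>%
    filter(.data$strand == "+") %>%
    count(.data$contig, pos = .data$start, name = "n")
  rev <- alignments %>%
    filter(.data$strand == "-") %>%
    count(.data$contig, pos = .data$end - 1L, name = "n")
  structure(list(forward_start = fwd, reverse_end = rev,
                 alignments = alignments),
            class = "readstart_profile")
}

# Number of reads overlapping the two-base window [p, p+2) (0-based).
local_depth <- function(alignments, contig, p) {
  al <- alignments[alignments$contig == contig, ]
  vapply(p, function(pp) {
    sum(al$start < pp + 2L & al$end > pp)
  }, integer(1))
}

#' Call cleavage sites from a read-start profile
#'
#' A cut between positions `p` and `p+1` (0-based) is called when at
#' least `min_reads` forward starts cluster at `p+1` and at least
#' `min_reads` reverse ends cluster at `p` (each summed over a
#' `+/- window` stagger slack), and the clustered starts make up at
#' least `min_start_fraction` of the local depth (reads overlapping
#' `[p, p+2)`).  Nearby candidates are deduplicated to the local maximum
#' of the combined start count.
#'
#' @param profile A `readstart_profile`.
#' @param min_reads Minimum read starts per strand (default 5).
#' @param min_start_fraction Minimum fraction of local depth contributed
#'   by the clustered starts (default 0.2).
#' @param window Stagger slack in bp (default 1).
#' @return A tibble of cleavage sites: `contig`, `cut` (0-based; the cut
#'   lies between `cut` and `cut+1`), `f_count`, `r_count`, `depth`,
#'   `start_fraction`.
#' @export
call_cleavage_sites <- function(profile, min_reads = 5L,
                                min_start_fraction = 0.2, window = 1L) {
  stopifnot(inherits(profile, "readstart_profile"))
  window <- as.integer(window)
  empty <- tibble(contig = character(), cut = integer(),
                  f_count = integer(), r_count = integer(),
                  depth = integer(), start_fraction = double())
  fwd <- profile$forward_start
  rev <- profile$reverse_end
  if (nrow(fwd) == 0 || nrow(rev) == 0) return(empty)

  clustered <- function(tbl, contig, at) {
    t2 <- tbl[tbl$contig == contig, ]
    vapply(at, function(p) {
      sum(t2$n[t2$pos >= p - window & t2$pos <= p + window])
    }, integer(1))
  }

  out <- purrr::map_dfr(intersect(unique(fwd$contig), unique(rev$contig)),
                        function(ctg) {
    # candidate cuts: positions with enough raw signal on either strand
    cand <- sort(unique(c(fwd$pos[fwd$contig == ctg] - 1L,
                          rev$pos[rev$contig == ctg])))
    if (length(cand) == 0) return(NULL)
    f <- clustered(fwd, ctg, cand + 1L)
    r <- clustered(rev, ctg, cand)
    keep <- f >= min_reads & r >= min_reads
    if (!any(keep)) return(NULL)
    cand <- cand[keep]; f <- f[keep]; r <- r[keep]
    exact <- function(tbl, at) {
      t2 <- tbl[tbl$contig == ctg, ]
      out <- t2$n[match(at, t2$pos)]
      ifelse(is.na(out), 0L, out)
    }
    fx <- exact(fwd, cand + 1L)
    rx <- exact(rev, cand)
    depth <- local_depth(profile$alignments, ctg, cand)
    frac <- pmin((f + r) / pmax(depth, 1L), 1)
    keep2 <- frac >= min_start_fraction
    if (!any(keep2)) return(NULL)
    tibble(contig = ctg, cut = cand[keep2], f_count = f[keep2],
           r_count = r[keep2], f_exact = fx[keep2], r_exact = rx[keep2],
           depth = depth[keep2], start_fraction = frac[keep2])
  })
  if (nrow(out) == 0) return(empty)

  # deduplicate runs of nearby candidates to the local maximum; rank by
  # the un-slacked two-strand signal first so background starts cannot
  # displace the called cut from the true position
  out <- out %>%
    arrange(.data$contig, .data$cut) %>%
    group_by(.data$contig) %>%
    mutate(grp = cumsum(c(1L, diff(.data$cut) > 2L * window + 1L))) %>%
    group_by(.data$contig, .data$grp) %>%
    arrange(desc(.data$f_exact + .data$r_exact),
            desc(.data$f_count + .data$r_count), .data$cut,
            .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select(-"grp", -"f_exact", -"r_exact") %>%
    arrange(.data$contig, .data$cut)
  out
}

#' Filter cleavage sites against the guides
#'
#' Retains sites whose neighbourhood (protospacer + PAM length around the
#' cut, both strands) contains a guide match under `params` — by default
#' up to six mismatches or one bulge with no mismatch — and attaches the
#' best hit (fewest mismatches, then cut nearest the called cut).
#'
#' @param sites Tibble from [call_cleavage_sites()].
#' @param guides An `editscan_guides` tibble.
#' @param reference Genome.
#' @param params [match_params()].
#' @return The retained sites with `guide`, `mismatches`, `bulge`,
#'   `hit_strand`, `hit_start`, `hit_end`, `matched_cut` columns.
#' @export
filter_cleavage_candidates <- function(sites, guides, reference,
                                       params = match_params()) {
  reference <- as_genome(reference)
  empty_out <- mutate(sites[0, ], guide = character(0),
                      mismatches = integer(0), bulge = character(0),
                      hit_strand = character(0), hit_start = integer(0),
                      hit_end = integer(0), matched_cut = integer(0))
  if (nrow(sites) == 0) return(empty_out)
  span <- max(nchar(guides$protospacer)) + 6L  # protospacer+PAM+bulge slack
  out <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    clen <- nchar(reference[[s$contig]])
    w0 <- max(0L, s$cut - span)
    w1 <- min(clen, s$cut + 1L + span)
    nb <- substr(reference[[s$contig]], w0 + 1L, w1)
    best <- purrr::map_dfr(seq_len(nrow(guides)), function(gi) {
      h <- scan_sequence(nb, guides[gi, ], params, contig = s$contig)
      h
    })
    if (nrow(best) == 0) return(NULL)
    best <- best %>%
      mutate(cut_position = .data$cut_position + w0,
             start = .data$start + w0, end = .data$end + w0,
             cut_dist = abs(.data$cut_position - s$cut)) %>%
      arrange(.data$mismatches, .data$cut_dist) %>%
      dplyr::slice(1)
    bind_cols(s, tibble(guide = best$guide, mismatches = best$mismatches,
                        bulge = best$bulge, hit_strand = best$strand,
                        hit_start = best$start, hit_end = best$end,
                        matched_cut = best$cut_position))
  })
  if (nrow(out) == 0) empty_out else out
}

#' Mismatch-count histogram of retained cleavage sites
#'
#' @param filtered Output of [filter_cleavage_candidates()].
#' @return A tibble of site counts per guide and mismatch count.
#' @export
cleavage_mismatch_histogram <- function(filtered) {
  filtered %>% count(.data$guide, .data$mismatches, name = "n_sites")
}
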