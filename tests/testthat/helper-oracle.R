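# Independent brute-force oracle for the guide-site scanner.  Mismatch
# counting goes through Biostrings::neditStartingAt (fixed-start Hamming
# distances) rather than the package's cumulative-matrix scanner; bulges
# are enumerated as explicit prefix/suffix splits at every gap position.
# Enumeration is parameter-free; thresholds and reporting rules are
# applied afterwards, so one enumeration serves every parameter setting.

oracle_pam_mm <- function(s, p0, patterns) {
  # minimum number of failing PAM positions across patterns (0 = match)
  pam <- substr(rep(s, length(p0)), p0 + 1, p0 + 3)
  mm <- rep(3L, length(p0))
  for (pat in patterns) {
    chars <- strsplit(pat, "", fixed = TRUE)[[1]]
    miss <- integer(length(p0))
    for (k in 1:3) {
      set <- editscan:::IUPAC_SETS[[chars[k]]]
      if (chars[k] == "N") next
      miss <- miss + as.integer(!substr(pam, k, k) %in% set)
    }
    mm <- pmin(mm, miss)
  }
  mm
}

oracle_enumerate_strand <- function(s, proto, patterns) {
  S <- nchar(s)
  L <- nchar(proto)
  subj <- Biostrings::DNAString(s)
  nedit <- function(pat, at) {
    ok <- at >= 1 & at + nchar(pat) - 1 <= S
    out <- rep(NA_integer_, length(at))
    if (any(ok)) {
      out[ok] <- Biostrings::neditStartingAt(Biostrings::DNAString(pat),
                                             subj, starting.at = at[ok],
                                             with.indels = FALSE)
    }
    out
  }
  cand <- list()
  add <- function(o, mm, pam0, type, b, span) {
    keep <- !is.na(mm) & pam0 + 3 <= S
    if (!any(keep)) return()
    cand[[length(cand) + 1]] <<-
      data.frame(o = o[keep], mismatches = mm[keep], pam0 = pam0[keep],
                 type = type, bulge_offset = b, span = span)
  }
  n_none <- S - L - 2
  if (n_none >= 1) {
    o <- seq_len(n_none)
    add(o, nedit(proto, o), o + L - 1, "none", NA_integer_, L + 3)
  }
  n_dna <- S - L - 3
  if (n_dna >= 1) {
    o <- seq_len(n_dna)
    for (b in 1:(L - 1)) {
      mm <- nedit(substr(proto, 1, b), o) +
        nedit(substr(proto, b + 1, L), o + b + 1)
      add(o, mm, o + L, "dna_bulge", b, L + 4)
    }
  }
  n_rna <- S - L - 1
  if (n_rna >= 1 && L >= 3) {
    o <- seq_len(n_rna)
    for (b in 2:(L - 1)) {
      pre <- nedit(substr(proto, 1, b - 1), o)
      mm <- pre + nedit(substr(proto, b + 1, L), o + b - 1)
      add(o, mm, o + L - 2, "rna_bulge", b, L + 2)
    }
  }
  if (length(cand) == 0) return(NULL)
  out <- do.call(rbind, cand)
  out$pam_mm <- oracle_pam_mm(s, out$pam0, patterns)
  out$pam_obs <- substr(rep(s, nrow(out)), out$pam0 + 1, out$pam0 + 3)
  out
}

# parameter-free enumeration of every candidate alignment on both strands
oracle_enumerate <- function(seq, guide) {
  proto <- guide$protospacer
  patterns <- editscan:::pam_patterns(guide$pam)
  list(S = nchar(seq),
       name = guide$name,
       "+" = oracle_enumerate_strand(toupper(seq), proto, patterns),
       "-" = oracle_enumerate_strand(revcomp(seq), proto, patterns))
}

empty_oracle_hits <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             strand = character(), guide = character(),
             mismatches = integer(), bulge = character(),
             bulge_offset = integer(), pam_observed = character(),
             cut_position = integer())
}

# apply thresholds + the reporting rules to an enumeration
oracle_apply <- function(enum, params, contig = "seq") {
  S <- enum$S
  rows <- list()
  for (strand in c("+", "-")) {
    cc <- enum[[strand]]
    if (is.null(cc)) next
    mm <- cc$mismatches + if (params$pam_mismatch_counted) cc$pam_mm else 0L
    cap <- ifelse(cc$type == "none", params$max_mismatches,
                  min(params$bulge_mismatch_cap, params$max_mismatches))
    keep <- mm <= cap &
      (params$pam_mismatch_counted | cc$pam_mm == 0L) &
      (params$allow_bulge | cc$type == "none")
    cc <- cc[keep, ]
    if (nrow(cc) == 0) next
    cc$mismatches <- mm[keep]
    # one alignment per (offset, type): fewest mismatches, leftmost bulge
    cc <- cc[order(cc$o, cc$type, cc$mismatches, cc$bulge_offset), ]
    cc <- cc[!duplicated(paste(cc$o, cc$type)), ]
    l_start0 <- cc$o - 1
    l_end0 <- l_start0 + cc$span
    l_cut <- cc$pam0 - 4
    if (strand == "+") {
      start0 <- l_start0; end0 <- l_end0; cut <- l_cut
    } else {
      start0 <- S - l_end0; end0 <- S - l_start0; cut <- S - l_cut - 2
    }
    rows[[strand]] <- data.frame(
      contig = contig, start = start0, end = end0, strand = strand,
      guide = enum$name, mismatches = cc$mismatches, bulge = cc$type,
      bulge_offset = cc$bulge_offset, pam_observed = cc$pam_obs,
      cut_position = cut)
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits) || nrow(hits) == 0) return(empty_oracle_hits())
  # suppression of bulge alignments dominated by overlapping bulge-free
  # hits on the same strand, then one best record per cut position
  free <- hits[hits$bulge == "none", ]
  keep <- rep(TRUE, nrow(hits))
  for (i in which(hits$bulge != "none")) {
    dom <- free$strand == hits$strand[i] & free$start < hits$end[i] &
      free$end > hits$start[i] & free$mismatches <= hits$mismatches[i]
    if (any(dom)) keep[i] <- FALSE
  }
  hits <- hits[keep, ]
  brank <- c(none = 0, dna_bulge = 1, rna_bulge = 2)
  hits <- hits[order(hits$cut_position, hits$mismatches,
                     brank[hits$bulge], hits$start, hits$strand != "+",
                     hits$bulge_offset), ]
  hits <- hits[!duplicated(hits$cut_position), ]
  hits <- hits[order(hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

oracle_scan <- function(seq, guide, params = match_params(),
                        contig = "seq") {
  oracle_apply(oracle_enumerate(seq, guide), params, contig)
}

# comparable view of a hit table
hit_key <- function(h) {
  paste(h$start, h$end, h$strand, h$mismatches, h$bulge, sep = ":")
}
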