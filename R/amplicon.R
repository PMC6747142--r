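# Amplicon deep-sequencing editing quantification: align reads to the
# amplicon reference, classify reads as mutant when an indel overlaps
# the counting window around the cut, and summarise mutation spectra in
# PAM-relative coordinates (-1 = 1 nt immediately 5' of the PAM).

#' Define an amplicon target
#'
#' @param site_name Site label.
#' @param amplicon_seq Amplicon reference sequence; must contain the
#'   guide's protospacer + a matching PAM in forward orientation.
#' @param guide A one-row `editscan_guides` tibble.
#' @param cut_offset Optional 0-based offset of the blunt cut (the cut
#'   lies between `cut_offset` and `cut_offset + 1`); located
#'   automatically from the protospacer when omitted.
#' @param count_flank Half-width (nt) of the indel counting window
#'   around the cut (default 10).
#' @return A list of class `amplicon_spec`.
#' @export
amplicon_spec <- function(site_name, amplicon_seq, guide,
                          cut_offset = NULL, count_flank = 10L) {
  amplicon_seq <- toupper(amplicon_seq)
  proto <- guide$protospacer
  L <- nchar(proto)
  pam_rx <- paste(vapply(pam_patterns(guide$pam), pam_pattern_regex,
                         character(1)), collapse = "|")
  if (is.null(cut_offset)) {
    at <- as.integer(
      gregexpr(proto, amplicon_seq, fixed = TRUE)[[1]])
    at <- at[at > 0]
    at <- at[vapply(at, function(a) {
      pam <- substr(amplicon_seq, a + L, a + L + 2)
      nchar(pam) == 3 && grepl(paste0("^(", pam_rx, ")$"), pam)
    }, logical(1))]
    if (length(at) == 0) {
      abort("protospacer + PAM not found in amplicon_seq (forward strand)")
    }
    proto_start0 <- at[1] - 1L
  } else {
    proto_start0 <- as.integer(cut_offset) - L + 4L
    found <- substr(amplicon_seq, proto_start0 + 1L, proto_start0 + L)
    pam <- substr(amplicon_seq, proto_start0 + L + 1L, proto_start0 + L + 3L)
    if (!identical(found, proto) ||
        !grepl(paste0("^(", pam_rx, ")$"), pam)) {
      abort("protospacer + PAM not found at the position implied by cut_offset")
    }
  }
  pam_start0 <- proto_start0 + L
  structure(list(site_name = site_name, amplicon_seq = amplicon_seq,
                 guide = guide, proto_start = proto_start0,
                 pam_start = pam_start0,
                 cut_offset = pam_start0 - 4L,
                 count_flank = as.integer(count_flank)),
            class = "amplicon_spec")
}

# PAM-relative coordinate of a 0-based amplicon position: -1 is the base
# immediately 5' of the PAM; +1 the first PAM base (there is no 0).
pam_relative <- function(p, pam_start) {
  ifelse(p < pam_start, p - pam_start, p - pam_start + 1L)
}

# Parse CIGAR strings (against the amplicon) into per-read indel vectors
# and the aligned reference span.  Plain lists, not tibbles: this runs
# once per unique read.
parse_alignment <- function(cigar, reads, ref) {
  purrr::map2(cigar, reads, function(cg, rd) {
    if (is.na(cg)) return(NULL)
    ops <- stringr::str_match_all(cg, "(\\d+)([MID])")[[1]]
    len <- as.integer(ops[, 2]); op <- ops[, 3]
    i <- 0L; j <- 0L  # consumed read / ref bases
    first_m <- NA_integer_; last_m <- NA_integer_
    kind <- character(); size <- integer()
    start0 <- integer(); end0 <- integer(); inserted <- character()
    for (t in seq_along(op)) {
      if (op[t] == "M") {
        if (is.na(first_m)) first_m <- j
        last_m <- j + len[t] - 1L
        i <- i + len[t]; j <- j + len[t]
      } else if (op[t] == "D") {
        kind <- c(kind, "deletion"); size <- c(size, len[t])
        start0 <- c(start0, j); end0 <- c(end0, j + len[t] - 1L)
        inserted <- c(inserted, NA_character_)
        j <- j + len[t]
      } else {
        kind <- c(kind, "insertion"); size <- c(size, len[t])
        start0 <- c(start0, j); end0 <- c(end0, j)
        inserted <- c(inserted, substr(rd, i + 1L, i + len[t]))
        i <- i + len[t]
      }
    }
    list(first_m = first_m, last_m = last_m, kind = kind, size = size,
         start0 = start0, end0 = end0, inserted = inserted)
  })
}

as_read_vector <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  unname(toupper(reads))
}

# Align unique reads to the amplicon.  Reads of equal length within a
# small Hamming distance of the reference are substitution-only by
# construction of the scoring scheme and skip the DP.
align_amplicon_reads <- function(uniq, ref, hamming_cap = 3L) {
  n <- length(uniq)
  cigar <- rep(NA_character_, n)
  same_len <- nchar(uniq) == nchar(ref)
  if (any(same_len)) {
    refc <- strsplit(ref, "", fixed = TRUE)[[1]]
    idx <- which(same_len)
    mm <- vapply(idx, function(i) {
      sum(strsplit(uniq[i], "", fixed = TRUE)[[1]] != refc)
    }, integer(1))
    hit <- idx[mm <= hamming_cap]
    cigar[hit] <- paste0(nchar(ref), "M")
  }
  todo <- which(is.na(cigar))
  if (length(todo) > 0) {
    cigar[todo] <- .nw_align_batch(uniq[todo], ref)
  }
  cigar
}

#' Quantify editing from amplicon reads
#'
#' A read is mutant when its alignment to the amplicon contains at least
#' one insertion or deletion overlapping the counting window
#' `cut_offset +/- count_flank`.  The editing efficiency is the ratio of
#' mutant reads to total reads spanning the window.  Distinct indel
#' signatures supported by fewer than `min_indel_reads` reads are not
#' counted as mutations; signatures with frequency below
#' `bona_fide_threshold` (default 1 per mille, the sequencing-error
#' floor) stay in the mutant count but are dropped from the reported
#' spectrum.
#'
#' @param reads Character vector of read sequences, a `DNAStringSet`,
#'   or a FASTQ path.
#' @param spec An [amplicon_spec()].
#' @param bona_fide_threshold Minimum spectrum frequency (default 0.001).
#' @param min_indel_reads Minimum supporting reads per distinct indel
#'   signature (default 2).
#' @param include_substitutions Also count substitution-only reads
#'   carrying a mismatch inside the window as mutant (default `FALSE`).
#' @return An object of class `editing_report`; see [tidy.editing_report()]
#'   and [glance.editing_report()].
#' @export
quantify_editing <- function(reads, spec, bona_fide_threshold = 0.001,
                             min_indel_reads = 2L,
                             include_substitutions = FALSE) {
  stopifnot(inherits(spec, "amplicon_spec"))
  reads <- as_read_vector(reads)
  ref <- spec$amplicon_seq
  win0 <- spec$cut_offset - spec$count_flank
  win1 <- spec$cut_offset + spec$count_flank

  if (length(reads) == 0) {
    return(new_editing_report(spec, 0L, 0L, empty_spectrum(),
                              bona_fide_threshold, flagged = TRUE))
  }

  tab <- table(reads)
  uniq <- names(tab)
  counts <- as.integer(tab)
  cigar <- align_amplicon_reads(uniq, ref)
  parsed <- parse_alignment(cigar, uniq, ref)

  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  n_u <- length(uniq)
  spanning <- logical(n_u)
  signature <- rep(NA_character_, n_u)
  sub_mutant <- logical(n_u)
  for (i in seq_len(n_u)) {
    p <- parsed[[i]]
    if (is.null(p) || is.na(p$first_m)) next
    spanning[i] <- p$first_m <= win0 && p$last_m >= win1
    sel <- (p$kind == "deletion" & p$start0 <= win1 & p$end0 >= win0) |
      (p$kind == "insertion" & p$start0 >= win0 & p$start0 <= win1 + 1L)
    if (any(sel)) {
      parts <- character(sum(sel))
      ks <- which(sel)
      for (q in seq_along(ks)) {
        k <- ks[q]
        parts[q] <- if (p$kind[k] == "deletion") {
          sprintf("%dD@[%d,%d]", p$size[k],
                  pam_relative(p$start0[k], spec$pam_start),
                  pam_relative(p$end0[k], spec$pam_start))
        } else {
          sprintf("%dI%s@%d", p$size[k], p$inserted[k],
                  pam_relative(p$start0[k], spec$pam_start))
        }
      }
      signature[i] <- paste(parts, collapse = ";")
    } else if (include_substitutions && spanning[i] &&
               nchar(uniq[i]) == nchar(ref)) {
      seg <- (win0 + 1L):(win1 + 1L)
      sub_mutant[i] <- any(strsplit(uniq[i], "", fixed = TRUE)[[1]][seg] !=
                             refc[seg])
    }
  }

  total <- sum(counts[spanning])
  sig_ok <- spanning & !is.na(signature)
  sig_counts <- vapply(split(counts[sig_ok], signature[sig_ok]), sum,
                       integer(1))
  sig_counts <- sig_counts[sig_counts >= min_indel_reads]
  sigs <- tibble(signature = names(sig_counts),
                 count = as.integer(unname(sig_counts))) %>%
    mutate(frequency = .data$count / max(total, 1L)) %>%
    arrange(desc(.data$count), .data$signature)

  mutant <- sum(sigs$count) +
    if (include_substitutions) sum(counts[spanning & sub_mutant])
    else 0L
  spectrum <- sigs %>% filter(.data$frequency >= bona_fide_threshold)

  new_editing_report(spec, total, as.integer(mutant), spectrum,
                     bona_fide_threshold, flagged = total == 0L)
}

empty_spectrum <- function() {
  tibble(signature = character(), count = integer(), frequency = double())
}

new_editing_report <- function(spec, total, mutant, spectrum, threshold,
                               flagged = FALSE) {
  structure(list(site_name = spec$site_name,
                 total_reads = as.integer(total),
                 mutant_reads = as.integer(mutant),
                 efficiency = if (total > 0) mutant / total else 0,
                 spectrum = spectrum,
                 bona_fide_threshold = threshold,
                 count_flank = spec$count_flank,
                 cut_offset = spec$cut_offset,
                 pam_start = spec$pam_start,
                 flagged = flagged),
            class = "editing_report")
}

#' @method print editing_report
#' @export
print.editing_report <- function(x, ...) {
  cat(sprintf("<editing_report> %s\n", x$site_name))
  cat(sprintf("  total reads:  %d\n", x$total_reads))
  cat(sprintf("  mutant reads: %d\n", x$mutant_reads))
  cat(sprintf("  efficiency:   %.4f%s\n", x$efficiency,
              if (x$flagged) " (flagged: no spanning reads)" else ""))
  cat(sprintf("  spectrum:     %d signature(s) at >= %g frequency\n",
              nrow(x$spectrum), x$bona_fide_threshold))
  invisible(x)
}

#' Tidy an editing report into its mutation spectrum
#'
#' @param x An `editing_report`.
#' @param ... Unused.
#' @return The spectrum tibble (`signature`, `count`, `frequency`),
#'   sorted by descending count.
#' @export
tidy.editing_report <- function(x, ...) x$spectrum

#' One-row summary of an editing report
#'
#' @param x An `editing_report`.
#' @param ... Unused.
#' @return A one-row tibble with `site_name`, `total_reads`,
#'   `mutant_reads`, `efficiency`, `n_signatures` and `flagged`.
#' @export
glance.editing_report <- function(x, ...) {
  tibble(site_name = x$site_name, total_reads = x$total_reads,
         mutant_reads = x$mutant_reads, efficiency = x$efficiency,
         n_signatures = nrow(x$spectrum), flagged = x$flagged)
}

#' Mutation spectrum of an amplicon read set
#'
#' Runs [quantify_editing()] and returns the spectrum: one row per
#' distinct indel signature inside the counting window, with counts and
#' frequencies, sorted by descending count.
#'
#' @inheritParams quantify_editing
#' @return A tibble (`signature`, `count`, `frequency`).
#' @export
variant_spectrum <- function(reads, spec, bona_fide_threshold = 0.001,
                             min_indel_reads = 2L) {
  tidy(quantify_editing(reads, spec, bona_fide_threshold,
                        min_indel_reads))
}

#' Extract PAM-relative mutation records from an editing report
#'
#' @param report An `editing_report`.
#' @return A tibble of mutation records: `kind`
#'   (`insertion`/`deletion`), `size`, `start_rel`, `end_rel` (PAM
#'   relative; -1 is 1 nt upstream of the PAM) and `count`.
#' @export
mutation_records <- function(report) {
  stopifnot(inherits(report, "editing_report"))
  if (nrow(report$spectrum) == 0) {
    return(tibble(kind = character(), size = integer(),
                  start_rel = integer(), end_rel = integer(),
                  count = integer()))
  }
  purrr::map2_dfr(report$spectrum$signature, report$spectrum$count,
                  function(sig, cnt) {
    parts <- strsplit(sig, ";", fixed = TRUE)[[1]]
    purrr::map_dfr(parts, function(p) {
      md <- stringr::str_match(p, "^(\\d+)D@\\[(-?\\d+),(-?\\d+)\\]$")
      if (!is.na(md[1, 1])) {
        return(tibble(kind = "deletion", size = as.integer(md[1, 2]),
                      start_rel = as.integer(md[1, 3]),
                      end_rel = as.integer(md[1, 4]), count = cnt))
      }
      mi <- stringr::str_match(p, "^(\\d+)I([ACGTN]*)@(-?\\d+)$")
      tibble(kind = "insertion", size = as.integer(mi[1, 2]),
             start_rel = as.integer(mi[1, 4]),
             end_rel = as.integer(mi[1, 4]), count = cnt)
    })
  })
}

#' Summarise mutation records into indel-profile histograms
#'
#' Reproduces the standard editing-outcome summary: indel-size histogram
#' (keys `1D`, `2D`, ..., `1I`, ...), insertion-position histogram, and
#' deletion start/end histograms, all in PAM-relative coordinates where
#' -1 is 1 nt upstream of the PAM.
#'
#' @param records A tibble with `kind`, `size`, `start_rel`, `end_rel`
#'   and optionally `count` (weight per record, default 1).
#' @return A list of class `mutation_profile` with tibbles
#'   `size_histogram`, `insertion_position_histogram`,
#'   `deletion_start_histogram`, `deletion_end_histogram`.
#' @export
summarize_mutation_profile <- function(records) {
  if (!"count" %in% names(records)) records$count <- 1L
  size_h <- records %>%
    mutate(key = paste0(.data$size,
                        ifelse(.data$kind == "deletion", "D", "I"))) %>%
    group_by(.data$key) %>%
    summarise(n = sum(.data$count), .groups = "drop") %>%
    arrange(.data$key)
  ins <- filter(records, .data$kind == "insertion") %>%
    group_by(position = .data$start_rel) %>%
    summarise(n = sum(.data$count), .groups = "drop")
  del <- filter(records, .data$kind == "deletion")
  del_s <- del %>% group_by(position = .data$start_rel) %>%
    summarise(n = sum(.data$count), .groups = "drop")
  del_e <- del %>% group_by(position = .data$end_rel) %>%
    summarise(n = sum(.data$count), .groups = "drop")
  structure(list(size_histogram = size_h,
                 insertion_position_histogram = ins,
                 deletion_start_histogram = del_s,
                 deletion_end_histogram = del_e),
            class = "mutation_profile")
}
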