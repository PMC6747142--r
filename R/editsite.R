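# Editing-site detection: candidate windows of +/- 50 nt around each
# surviving consensus variant are matched against the guides.

# 0-based half-open reference footprint of a normalized variant.
# SNV/MNV: the substituted bases; deletion: the deleted bases (anchor
# excluded); insertion: the single anchor base.  For SVs both
# breakpoints are windowed separately by the caller.
variant_footprint <- function(pos, ref, alt, vclass) {
  if (vclass == "del") {
    c(pos, pos + (nchar(ref) - nchar(alt)))
  } else if (vclass == "ins") {
    c(pos - 1L, pos)
  } else {
    c(pos - 1L, pos - 1L + nchar(ref))
  }
}

#' Extract candidate windows around consensus variants
#'
#' Each window spans the variant's reference footprint plus `flank`
#' nucleotides on each side (50 by default), clipped at contig edges.
#' Structural variants contribute one window per breakpoint.
#'
#' @param variants Consensus tibble ([build_consensus()]).
#' @param reference Genome (named character vector, `DNAStringSet`, or
#'   FASTA path).
#' @param flank Flank size in nt on each side (default 50).
#' @return A tibble with `contig`, 0-based half-open `start`/`end`,
#'   `sequence`, and the source-variant key columns.
#' @export
extract_window <- function(variants, reference, flank = 50L) {
  reference <- as_genome(reference)
  flank <- as.integer(flank)
  missing <- setdiff(unique(variants$contig), names(reference))
  if (length(missing) > 0) {
    abort(paste0("contig(s) absent from reference: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(variants) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  sequence = character(), variant_id = integer(),
                  pos = integer(), ref = character(), alt = character(),
                  vclass = character()))
  }
  purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    clen <- nchar(reference[[v$contig]])
    fps <- if (!is.na(v$sv_type %||% NA) && identical(v$vclass, "sv")) {
      list(c(v$pos - 1L, v$pos), c(v$sv_end - 1L, v$sv_end))
    } else {
      list(variant_footprint(v$pos, v$ref, v$alt, v$vclass))
    }
    purrr::map_dfr(fps, function(fp) {
      start0 <- max(0L, fp[1] - flank)
      end0 <- min(clen, fp[2] + flank)
      tibble(contig = v$contig, start = start0, end = end0,
             sequence = substr(reference[[v$contig]], start0 + 1L, end0),
             variant_id = i, pos = v$pos, ref = v$ref, alt = v$alt,
             vclass = v$vclass)
    })
  })
}

#' Detect editing sites among consensus variants
#'
#' For every surviving variant, the +/- `flank` nt candidate window is
#' scanned for each guide; the best hit per (variant, guide) pair is
#' reported (fewest mismatches, then bulge-free, then cut position
#' nearest the variant, then leftmost).  A hit overlapping the guide's
#' designed locus is labelled `on_target`, any other hit `off_target`;
#' variants with no qualifying hit for any guide are labelled
#' `background`.  A `repeat_flag` marks variants whose window sequence
#' occurs more than once in the reference (exact match, either strand) —
#' informational, not a filter.
#'
#' @param variants Consensus tibble ([build_consensus()] /
#'   [subtract_controls()]).
#' @param guides An `editscan_guides` tibble.
#' @param reference Genome.
#' @param params [match_params()] for the window scan.
#' @param flank Window flank in nt (default 50).
#' @param flag_repeats Compute `repeat_flag` (exact window-sequence
#'   multiplicity in the reference); disable to save time on large
#'   genomes.
#' @return A tibble of editing-site calls: variant key columns, `guide`,
#'   `label` (`on_target`/`off_target`/`background`), `mismatches`,
#'   `bulge`, hit coordinates, `frequency` (supporting/total depth) and
#'   `repeat_flag`.
#' @export
detect_editing_sites <- function(variants, guides, reference,
                                 params = match_params(), flank = 50L,
                                 flag_repeats = TRUE) {
  reference <- as_genome(reference)
  windows <- extract_window(variants, reference, flank)
  calls <- purrr::map_dfr(unique(windows$variant_id), function(vid) {
    wins <- windows[windows$variant_id == vid, ]
    v <- variants[vid, ]
    fp <- variant_footprint(v$pos, v$ref, v$alt,
                            if (identical(v$vclass, "sv")) "snv" else v$vclass)
    per_guide <- purrr::map_dfr(seq_len(nrow(guides)), function(gi) {
      g <- guides[gi, ]
      hits <- purrr::map_dfr(seq_len(nrow(wins)), function(wi) {
        w <- wins[wi, ]
        h <- scan_sequence(w$sequence, g, params, contig = w$contig)
        if (nrow(h) == 0) return(h)
        h$start <- h$start + w$start
        h$end <- h$end + w$start
        h$cut_position <- h$cut_position + w$start
        h
      })
      if (nrow(hits) == 0) return(NULL)
      hits <- hits %>%
        mutate(cut_dist = pmin(abs(.data$cut_position - fp[1]),
                               abs(.data$cut_position - (fp[2] - 1L)))) %>%
        arrange(.data$mismatches, bulge_rank[.data$bulge], .data$cut_dist,
                .data$start) %>%
        dplyr::slice(1)
      on_target <- !is.na(g$locus_start) &&
        hits$contig == g$locus_contig &&
        hits$start < g$locus_end && hits$end > g$locus_start
      tibble(guide = g$name,
             label = if (on_target) "on_target" else "off_target",
             mismatches = hits$mismatches, bulge = hits$bulge,
             hit_contig = hits$contig, hit_start = hits$start,
             hit_end = hits$end, hit_strand = hits$strand,
             cut_position = hits$cut_position,
             pam_observed = hits$pam_observed)
    })
    base <- tibble(variant_id = vid, contig = v$contig, pos = v$pos,
                   ref = v$ref, alt = v$alt, vclass = v$vclass,
                   max_alt_depth = v$max_alt_depth,
                   total_depth = v$total_depth)
    if (nrow(per_guide) == 0) {
      out <- base %>%
        mutate(guide = NA_character_, label = "background",
               mismatches = NA_integer_, bulge = NA_character_,
               hit_contig = NA_character_, hit_start = NA_integer_,
               hit_end = NA_integer_, hit_strand = NA_character_,
               cut_position = NA_integer_, pam_observed = NA_character_)
    } else {
      out <- bind_cols(base[rep(1, nrow(per_guide)), ], per_guide)
    }
    if (flag_repeats) {
      n_occ <- sum(vapply(reference, function(ctg) {
        Biostrings::countPattern(wins$sequence[1], Biostrings::DNAString(ctg)) +
          Biostrings::countPattern(revcomp(wins$sequence[1]),
                                   Biostrings::DNAString(ctg))
      }, numeric(1)))
      out$repeat_flag <- n_occ > 1
    } else {
      out$repeat_flag <- NA
    }
    out
  })
  if (nrow(calls) == 0) return(calls)
  site_mutation_frequency(calls)
}

#' Per-site mutation frequency from WGS depths
#'
#' The supporting-read fraction `max_alt_depth / total_depth`, the
#' quantity reported for on-/off-target sites by whole-genome
#' sequencing.  Sites with zero total depth get `NA` and a
#' `depth_flag`.
#'
#' @param variants A tibble with `max_alt_depth` and `total_depth`.
#' @return The input with `frequency` and `depth_flag` columns added.
#' @export
site_mutation_frequency <- function(variants) {
  variants %>%
    mutate(
      depth_flag = is.na(.data$total_depth) | .data$total_depth == 0L,
      frequency = ifelse(.data$depth_flag, NA_real_,
                         .data$max_alt_depth / .data$total_depth)
    )
}

#' Per-guide summary of editing-site calls
#'
#' @param calls Output of [detect_editing_sites()].
#' @return A tibble of counts of on-target, off-target and background
#'   calls per guide (background calls, having no guide, appear under
#'   guide `NA`).
#' @export
summarize_editing_sites <- function(calls) {
  calls %>%
    count(.data$guide, .data$label, name = "n") %>%
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
}
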