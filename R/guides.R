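#' Define one or more guide-RNA targets
#'
#' A guide target is a designed protospacer (the 17-23 nt genomic sequence
#' matched by the guide RNA, 19 nt for typical plant constructs), the PAM
#' pattern(s) required 3' of it (default `NGG` for SpCas9), and optionally
#' the designed genomic locus of the intended on-target site.
#'
#' @param name Guide name(s).
#' @param protospacer Protospacer sequence(s), A/C/G/T only, 17-23 nt.
#' @param pam PAM pattern(s) as IUPAC 3-mers; several alternatives may be
#'   given separated by commas (e.g. `"NGG,NAG"`).
#' @param locus_contig,locus_start,locus_end,locus_strand Optional designed
#'   locus covering protospacer + PAM; `locus_start`/`locus_end` are
#'   0-based half-open coordinates on the forward strand, and the span
#'   must equal protospacer length + 3.
#' @return A tibble with one row per guide (class `editscan_guides`).
#' @examples
#' guide_target("TRY", "GTCACTTACTCGTCATCCA")
#' @export
guide_target <- function(name, protospacer, pam = "NGG",
                         locus_contig = NA_character_,
                         locus_start = NA_integer_,
                         locus_end = NA_integer_,
                         locus_strand = NA_character_) {
  protospacer <- vapply(protospacer, check_protospacer, character(1),
                        USE.NAMES = FALSE)
  guides <- tibble(
    name = as.character(name),
    protospacer = protospacer,
    pam = toupper(as.character(pam)),
    locus_contig = as.character(locus_contig),
    locus_start = as.integer(locus_start),
    locus_end = as.integer(locus_end),
    locus_strand = as.character(locus_strand)
  )
  validate_guides(guides)
}

validate_guides <- function(guides) {
  stopifnot(is.data.frame(guides),
            all(c("name", "protospacer", "pam") %in% names(guides)))
  guides <- as_tibble(guides)
  for (col in c("locus_contig", "locus_start", "locus_end", "locus_strand")) {
    if (!col %in% names(guides)) guides[[col]] <- NA
  }
  if (anyDuplicated(guides$name)) abort("guide names must be unique")
  for (i in seq_len(nrow(guides))) {
    check_protospacer(guides$protospacer[i])
    pats <- pam_patterns(guides$pam[i])
    vapply(pats, check_pam_pattern, character(1))
    if (!is.na(guides$locus_start[i])) {
      span <- guides$locus_end[i] - guides$locus_start[i]
      expect <- nchar(guides$protospacer[i]) + 3L
      if (is.na(span) || span != expect) {
        abort(sprintf(
          "guide '%s': designed locus span (%s) must equal protospacer length + 3 (%d)",
          guides$name[i], span, expect))
      }
      if (!guides$locus_strand[i] %in% c("+", "-")) {
        abort(sprintf("guide '%s': locus_strand must be '+' or '-'",
                      guides$name[i]))
      }
    }
  }
  class(guides) <- c("editscan_guides", class(guides))
  guides
}

pam_patterns <- function(pam) {
  toupper(trimws(strsplit(pam, ",", fixed = TRUE)[[1]]))
}

#' Read guide definitions from a YAML config file
#'
#' The file holds a list of guides, each with fields `name`,
#' `protospacer`, optional `pam` (default `NGG`) and optional `locus`
#' with `contig`, `start`, `end` (1-based inclusive) and `strand`.
#'
#' @param path Path to the YAML file.
#' @return An `editscan_guides` tibble.
#' @export
read_guides <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$guides)) cfg <- cfg$guides
  rows <- purrr::map_dfr(cfg, function(g) {
    loc <- g$locus
    tibble(
      name = g$name,
      protospacer = toupper(g$protospacer),
      pam = toupper(g$pam %||% "NGG"),
      locus_contig = loc$contig %||% NA_character_,
      locus_start = if (is.null(loc)) NA_integer_ else as.integer(loc$start) - 1L,
      locus_end = if (is.null(loc)) NA_integer_ else as.integer(loc$end),
      locus_strand = loc$strand %||% NA_character_
    )
  })
  validate_guides(rows)
}

#' Matching parameters for the guide-site scanner
#'
#' Defaults follow the whole-genome screening criteria for SpCas9: up to
#' six protospacer mismatches, or a single one-nucleotide bulge carrying
#' no mismatch.  PAM mismatches are not counted against the mismatch
#' budget; instead the observed PAM must match the IUPAC pattern, unless
#' `pam_mismatch_counted = TRUE`.
#'
#' @param max_mismatches Maximum protospacer mismatches (default 6).
#' @param allow_bulge Allow a single one-nucleotide DNA or RNA bulge.
#' @param bulge_mismatch_cap Maximum mismatches tolerated alongside a
#'   bulge (default 0).
#' @param pam_mismatch_counted If `TRUE`, PAM positions that fail the
#'   pattern are added to the mismatch count instead of rejecting the hit.
#' @return A list of class `match_params`.
#' @export
match_params <- function(max_mismatches = 6L, allow_bulge = TRUE,
                         bulge_mismatch_cap = 0L,
                         pam_mismatch_counted = FALSE) {
  max_mismatches <- as.integer(max_mismatches)
  bulge_mismatch_cap <- as.integer(bulge_mismatch_cap)
  if (max_mismatches < 0) abort("max_mismatches must be >= 0")
  if (bulge_mismatch_cap > max_mismatches) {
    abort("bulge_mismatch_cap must be <= max_mismatches")
  }
  structure(
    list(max_mismatches = max_mismatches,
         allow_bulge = isTRUE(allow_bulge),
         bulge_mismatch_cap = bulge_mismatch_cap,
         pam_mismatch_counted = isTRUE(pam_mismatch_counted)),
    class = "match_params"
  )
}
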