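# Multi-caller variant consensus: normalization, caller/depth/length
# thresholds, and subtraction of wild-type and different-target controls.

variant_class <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1 & nchar(alt) == 1 ~ "snv",
    nchar(alt) > nchar(ref) ~ "ins",
    nchar(ref) > nchar(alt) ~ "del",
    TRUE ~ "mnv"
  )
}

#' Construct a tibble of per-caller variant calls
#'
#' Convenience constructor used by tests and simulators; [read_caller_vcf()]
#' produces the same layout from a VCF file.
#'
#' @param caller Caller identifier.
#' @param contig,pos,ref,alt Variant coordinates (1-based `pos`) and alleles.
#' @param alt_depth,total_depth Variant-supporting and total read depth.
#' @param sv_type,sv_end For structural variants: type (`DEL`, `INS`,
#'   `DUP`, `INV`) and 1-based end coordinate.
#' @return A tibble with one row per call.
#' @export
variant_calls <- function(caller, contig, pos, ref = NA_character_,
                          alt = NA_character_, alt_depth = 0L,
                          total_depth = 0L, sv_type = NA_character_,
                          sv_end = NA_integer_) {
  tibble(
    caller = as.character(caller), contig = as.character(contig),
    pos = as.integer(pos), ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    vclass = ifelse(!is.na(sv_type), "sv", variant_class(ref, alt)),
    alt_depth = as.integer(alt_depth),
    total_depth = as.integer(total_depth),
    sv_type = as.character(sv_type), sv_end = as.integer(sv_end)
  )
}

normalize_one <- function(contig_seq, pos, ref, alt) {
  obs <- substr(contig_seq, pos, pos + nchar(ref) - 1L)
  if (!identical(obs, ref)) {
    abort(sprintf("REF mismatch at %d: VCF has '%s', reference has '%s'",
                  pos, ref, obs))
  }
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        (nr > 1 || na > 1)) {
      # strip a shared trailing base (left-shifts indels through repeats)
      stripped <- substr(ref, nr, nr)
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0 || nchar(alt) == 0) {
        if (pos == 1L) {  # cannot extend past the contig start; undo strip
          ref <- paste0(ref, stripped); alt <- paste0(alt, stripped)
          break
        }
        pos <- pos - 1L
        b <- substr(contig_seq, pos, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  # trim shared leading bases, keeping one anchor base for indels
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variant calls against the reference
#'
#' Left-aligns indels and trims shared prefix/suffix bases to the minimal
#' representation (one anchor base retained for indels), so that the same
#' event reported differently by different callers compares equal.  The
#' operation is idempotent.  Structural-variant records pass through
#' unchanged.
#'
#' @param calls Tibble of calls ([variant_calls()] / [read_caller_vcf()]).
#' @param reference Genome (named character vector, `DNAStringSet`, or
#'   FASTA path).
#' @return The calls with normalized `pos`/`ref`/`alt` and refreshed
#'   `vclass`.
#' @export
normalize_variants <- function(calls, reference) {
  if (nrow(calls) == 0) return(calls)
  reference <- as_genome(reference)
  missing <- setdiff(unique(calls$contig), names(reference))
  if (length(missing) > 0) {
    abort(paste0("contig(s) absent from reference: ",
                 paste(missing, collapse = ", ")))
  }
  idx <- which(calls$vclass != "sv" | is.na(calls$vclass))
  for (i in idx) {
    nz <- normalize_one(reference[[calls$contig[i]]],
                        calls$pos[i], calls$ref[i], calls$alt[i])
    calls$pos[i] <- nz$pos
    calls$ref[i] <- nz$ref
    calls$alt[i] <- nz$alt
  }
  calls$vclass[idx] <- variant_class(calls$ref[idx], calls$alt[idx])
  calls
}

#' Consensus parameters
#'
#' Defaults implement the whole-genome filtering rules: SNVs present in
#' at least 2 of the 3 SNV callers, indels in at least 2 of 3, structural
#' variants in both SV callers and no longer than 10 kb, and a
#' variant-supporting depth of at least 2 reads in some caller.
#'
#' @param snv_min_callers,indel_min_callers,sv_min_callers Minimum number
#'   of supporting callers per variant class.
#' @param min_depth Minimum variant-supporting read depth (maximum across
#'   callers).
#' @param sv_max_len Maximum structural-variant length in bp.
#' @param sv_wobble Breakpoint tolerance (bp) when matching SVs across
#'   callers.
#' @return A list of class `consensus_params`.
#' @export
consensus_params <- function(snv_min_callers = 2L, indel_min_callers = 2L,
                             sv_min_callers = 2L, min_depth = 2L,
                             sv_max_len = 10000L, sv_wobble = 10L) {
  structure(list(snv_min_callers = as.integer(snv_min_callers),
                 indel_min_callers = as.integer(indel_min_callers),
                 sv_min_callers = as.integer(sv_min_callers),
                 min_depth = as.integer(min_depth),
                 sv_max_len = as.integer(sv_max_len),
                 sv_wobble = as.integer(sv_wobble)),
            class = "consensus_params")
}

#' Build the consensus variant set across callers
#'
#' Variants identical after normalization are merged across callers;
#' structural variants are matched across callers with `sv_wobble`
#' breakpoint tolerance and matching type.  Only variants meeting the
#' class-specific caller count, the depth threshold, and (for SVs) the
#' length cap are retained.
#'
#' @param calls Normalized calls from all callers of one sample.
#' @param params A [consensus_params()] object.
#' @param known_callers Optional character vector; calls from callers not
#'   listed raise an error.
#' @return A sorted tibble of consensus variants with `callers`
#'   (list-column), `n_callers`, `max_alt_depth`, `total_depth` and, for
#'   SVs, `sv_type`, `sv_end`, `sv_length`.
#' @export
build_consensus <- function(calls, params = consensus_params(),
                            known_callers = NULL) {
  stopifnot(inherits(params, "consensus_params"))
  if (!is.null(known_callers)) {
    bad <- setdiff(unique(calls$caller), known_callers)
    if (length(bad) > 0) {
      abort(paste0("unknown caller identifier(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  if (nrow(calls) == 0) return(empty_consensus())

  small <- calls %>%
    filter(.data$vclass != "sv" | is.na(.data$vclass))
  small <- if (nrow(small) == 0) NULL else small %>%
    group_by(.data$contig, .data$pos, .data$ref, .data$alt, .data$vclass) %>%
    summarise(callers = list(sort(unique(.data$caller))),
              n_callers = dplyr::n_distinct(.data$caller),
              max_alt_depth = max(.data$alt_depth),
              total_depth = max(.data$total_depth), .groups = "drop") %>%
    mutate(sv_type = NA_character_, sv_end = NA_integer_,
           sv_length = NA_integer_) %>%
    mutate(min_callers = ifelse(.data$vclass == "snv",
                                params$snv_min_callers,
                                params$indel_min_callers)) %>%
    filter(.data$n_callers >= .data$min_callers,
           .data$max_alt_depth >= params$min_depth) %>%
    select(-"min_callers")

  svs <- calls %>% filter(.data$vclass == "sv")
  sv_out <- NULL
  if (nrow(svs) > 0) {
    sv_out <- cluster_svs(svs, params$sv_wobble) %>%
      filter(.data$n_callers >= params$sv_min_callers,
             .data$max_alt_depth >= params$min_depth,
             .data$sv_length <= params$sv_max_len)
  }

  out <- bind_rows(small, sv_out) %>%
    arrange(.data$contig, .data$pos, .data$ref, .data$alt)
  class(out) <- c("editscan_consensus", class(out))
  out
}

empty_consensus <- function() {
  out <- tibble(contig = character(), pos = integer(), ref = character(),
                alt = character(), vclass = character(), callers = list(),
                n_callers = integer(), max_alt_depth = integer(),
                total_depth = integer(), sv_type = character(),
                sv_end = integer(), sv_length = integer())
  class(out) <- c("editscan_consensus", class(out))
  out
}

# Greedy single-linkage clustering of SV calls of the same type whose
# start and end both lie within `wobble` bp of the cluster seed.
cluster_svs <- function(svs, wobble) {
  svs <- arrange(svs, .data$contig, .data$sv_type, .data$pos, .data$sv_end)
  cl <- integer(nrow(svs))
  seed_pos <- seed_end <- integer(0)
  seed_key <- character(0)
  k <- 0L
  for (i in seq_len(nrow(svs))) {
    key <- paste(svs$contig[i], svs$sv_type[i])
    hit <- which(seed_key == key &
                   abs(seed_pos - svs$pos[i]) <= wobble &
                   abs(seed_end - svs$sv_end[i]) <= wobble)
    if (length(hit) > 0) {
      cl[i] <- hit[1]
    } else {
      k <- k + 1L
      cl[i] <- k
      seed_pos[k] <- svs$pos[i]
      seed_end[k] <- svs$sv_end[i]
      seed_key[k] <- key
    }
  }
  svs$cluster <- cl
  svs %>%
    group_by(.data$cluster) %>%
    summarise(contig = dplyr::first(.data$contig),
              pos = min(.data$pos),
              ref = dplyr::first(.data$ref),
              alt = dplyr::first(.data$alt),
              vclass = "sv",
              callers = list(sort(unique(.data$caller))),
              n_callers = dplyr::n_distinct(.data$caller),
              max_alt_depth = max(.data$alt_depth),
              total_depth = max(.data$total_depth),
              sv_type = dplyr::first(.data$sv_type),
              sv_end = max(.data$sv_end), .groups = "drop") %>%
    mutate(sv_length = .data$sv_end - .data$pos) %>%
    select(-"cluster")
}

#' Subtract control variant sets from a consensus set
#'
#' Removes every variant whose normalized `(contig, pos, ref, alt)`
#' appears in any control consensus (wild-type plants, or mutants edited
#' at different target sites).  Order of the control sets is irrelevant.
#'
#' @param consensus Consensus tibble from [build_consensus()].
#' @param controls A single consensus tibble or a list of them.
#' @return The filtered consensus tibble.
#' @export
subtract_controls <- function(consensus, controls) {
  if (is.data.frame(controls)) controls <- list(controls)
  out <- consensus
  for (ctl in controls) {
    if (is.null(ctl) || nrow(ctl) == 0) next
    out <- anti_join(out, ctl[, c("contig", "pos", "ref", "alt")],
                     by = c("contig", "pos", "ref", "alt"))
  }
  class(out) <- unique(c("editscan_consensus", class(out)))
  out
}
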