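# VCF input/output.  Reading goes through vcfR (plain or bgzipped VCF
# 4.x); writing uses a small text writer since a VCF body is a header
# plus tab-separated records.

#' Read one caller's VCF into a call tibble
#'
#' Multi-allelic records are split into biallelic calls.  The
#' variant-supporting depth is taken from the per-sample `AD` field when
#' present (second and later components), otherwise from an `AD=` INFO
#' key; total depth from `DP`.  Records carrying an `SVTYPE=` INFO key
#' become structural-variant calls with `sv_end` from `END=`.
#'
#' @param path VCF file (plain or gzip).
#' @param caller Caller identifier recorded on every call; VCF headers
#'   are not trusted for this.
#' @return A [variant_calls()] tibble.
#' @export
read_caller_vcf <- function(path, caller) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(variant_calls(character(), character(), integer())[0, ])
  }
  info <- fix$INFO %||% rep(NA_character_, nrow(fix))
  info_get <- function(key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  sv_type <- info_get("SVTYPE")
  sv_end <- suppressWarnings(as.integer(info_get("END")))
  dp_info <- suppressWarnings(as.integer(info_get("DP")))
  ad_info <- info_get("AD")

  ad_fmt <- dp_fmt <- NULL
  if (!is.null(v@gt) && ncol(v@gt) >= 2) {
    fmt <- v@gt[, 1]
    smp <- v@gt[, 2]
    get_fmt <- function(key) {
      purrr::map2_chr(fmt, smp, function(f, s) {
        if (is.na(f) || is.na(s)) return(NA_character_)
        k <- which(strsplit(f, ":", fixed = TRUE)[[1]] == key)
        if (length(k) == 0) return(NA_character_)
        strsplit(s, ":", fixed = TRUE)[[1]][k]
      })
    }
    ad_fmt <- get_fmt("AD")
    dp_fmt <- suppressWarnings(as.integer(get_fmt("DP")))
  }
  ad_str <- if (!is.null(ad_fmt)) dplyr::coalesce(ad_fmt, ad_info) else ad_info
  dp <- if (!is.null(dp_fmt)) dplyr::coalesce(dp_fmt, dp_info) else dp_info

  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ads <- if (!is.na(ad_str[i])) {
      suppressWarnings(as.integer(strsplit(ad_str[i], ",",
                                           fixed = TRUE)[[1]]))
    } else NULL
    purrr::map_dfr(seq_along(alts), function(j) {
      ad_j <- if (!is.null(ads) && length(ads) >= j + 1) ads[j + 1] else {
        if (!is.null(ads) && length(ads) == 1) ads[1] else 0L
      }
      tot <- if (!is.na(dp[i])) dp[i] else sum(ads, na.rm = TRUE)
      variant_calls(caller = caller, contig = fix$CHROM[i],
                    pos = as.integer(fix$POS[i]), ref = fix$REF[i],
                    alt = alts[j], alt_depth = ad_j, total_depth = tot,
                    sv_type = sv_type[i], sv_end = sv_end[i])
    })
  })
  rows
}

vcf_header <- function(contigs = NULL, extra = character()) {
  c("##fileformat=VCFv4.2",
    paste0("##source=editscan-", as.character(utils::packageVersion("editscan"))),
    if (!is.null(contigs)) {
      paste0("##contig=<ID=", names(contigs), ",length=", nchar(contigs), ">")
    },
    extra,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "SAMPLE"), collapse = "\t"))
}

#' Write a consensus variant set to VCF
#'
#' INFO carries `CALLERS` (comma-separated supporting callers) and
#' `MAXAD` (maximum supporting depth), plus `SVTYPE`/`END` for
#' structural variants.  A TSV mirror can be written alongside.
#'
#' @param consensus Tibble from [build_consensus()].
#' @param path Output VCF path.
#' @param reference Optional genome, used to emit `##contig` header lines.
#' @param tsv Optional path for a TSV mirror.
#' @return `path`, invisibly.
#' @export
write_consensus_vcf <- function(consensus, path, reference = NULL,
                                tsv = NULL) {
  contigs <- if (!is.null(reference)) as_genome(reference)
  extra <- c(
    '##INFO=<ID=CALLERS,Number=.,Type=String,Description="Supporting callers">',
    '##INFO=<ID=MAXAD,Number=1,Type=Integer,Description="Max supporting depth across callers">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Max total depth across callers">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="SV end">')
  info <- paste0("CALLERS=",
                 vapply(consensus$callers, paste, character(1), collapse = ","),
                 ";MAXAD=", consensus$max_alt_depth,
                 ";DP=", consensus$total_depth,
                 ifelse(!is.na(consensus$sv_type),
                        paste0(";SVTYPE=", consensus$sv_type,
                               ";END=", consensus$sv_end), ""))
  body <- paste(consensus$contig, consensus$pos, ".",
                ifelse(is.na(consensus$ref), "N", consensus$ref),
                ifelse(is.na(consensus$alt), "<SV>", consensus$alt),
                ".", "PASS", info, "GT", "./.", sep = "\t")
  readr::write_lines(c(vcf_header(contigs, extra), body), path)
  if (!is.null(tsv)) {
    flat <- consensus %>%
      mutate(callers = vapply(.data$callers, paste, character(1),
                              collapse = ","))
    readr::write_tsv(flat, tsv)
  }
  invisible(path)
}

#' Read a consensus VCF written by [write_consensus_vcf()]
#'
#' @param path VCF path.
#' @return A consensus tibble (callers, depths and SV fields restored
#'   from INFO).
#' @export
read_consensus_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_consensus())
  grab <- function(key) {
    stringr::str_match(fix$INFO, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
  }
  callers <- strsplit(grab("CALLERS"), ",", fixed = TRUE)
  sv_type <- grab("SVTYPE")
  sv_end <- suppressWarnings(as.integer(grab("END")))
  out <- tibble(
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    vclass = ifelse(!is.na(sv_type), "sv", variant_class(fix$REF, fix$ALT)),
    callers = callers,
    n_callers = lengths(callers),
    max_alt_depth = suppressWarnings(as.integer(grab("MAXAD"))),
    total_depth = suppressWarnings(as.integer(grab("DP"))),
    sv_type = sv_type, sv_end = sv_end,
    sv_length = ifelse(is.na(sv_end), NA_integer_,
                       sv_end - as.integer(fix$POS))
  ) %>%
    arrange(.data$contig, .data$pos, .data$ref, .data$alt)
  class(out) <- c("editscan_consensus", class(out))
  out
}

# Write per-caller simple VCFs (used by the simulator and the CLI).
write_calls_vcf <- function(calls, path, reference = NULL) {
  contigs <- if (!is.null(reference)) as_genome(reference)
  extra <- c(
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="SV end">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">')
  calls <- arrange(calls, .data$contig, .data$pos)
  info <- paste0("DP=", calls$total_depth,
                 ifelse(!is.na(calls$sv_type),
                        paste0(";SVTYPE=", calls$sv_type,
                               ";END=", calls$sv_end), ""))
  sample_col <- paste0("0/1:",
                       pmax(calls$total_depth - calls$alt_depth, 0L), ",",
                       calls$alt_depth, ":", calls$total_depth)
  body <- paste(calls$contig, calls$pos, ".",
                ifelse(is.na(calls$ref), "N", calls$ref),
                ifelse(is.na(calls$alt), "<SV>", calls$alt),
                ".", "PASS", info, "GT:AD:DP", sample_col, sep = "\t")
  readr::write_lines(c(vcf_header(contigs, extra), body), path)
  invisible(path)
}
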