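# Deterministic synthetic-data generators: every pipeline stage can be
# exercised end-to-end with no external data.  All generators take a
# seed and leave the caller's RNG state untouched.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a random reference genome
#'
#' Bases are drawn i.i.d. with a GC dial (no repeat structure).  The
#' default GC of 0.36 approximates the *Arabidopsis thaliana* genome.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param n_contigs Number of contigs.
#' @param length Length of each contig (>= 200 nt).
#' @param gc Target GC fraction.
#' @param fasta Optional path: write the genome as FASTA (and a
#'   `samtools faidx` index next to it).
#' @return Named character vector of contig sequences (`ctg1`, ...).
#' @export
make_reference <- function(seed, n_contigs = 1L, length = 10000L,
                           gc = 0.36, fasta = NULL) {
  if (length < 200) abort("contig length must be >= 200")
  if (n_contigs < 1) abort("n_contigs must be >= 1")
  if (gc <= 0 || gc >= 1) abort("gc must be in (0, 1)")
  genome <- with_local_seed(seed, {
    setNames(vapply(seq_len(n_contigs),
                    function(i) random_dna(length, gc), character(1)),
             paste0("ctg", seq_len(n_contigs)))
  })
  if (!is.null(fasta)) {
    dss <- Biostrings::DNAStringSet(genome)
    Biostrings::writeXStringSet(dss, fasta)
    try(Rsamtools::indexFa(fasta), silent = TRUE)
  }
  genome
}

concretize_pam <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) sample(IUPAC_SETS[[ch]], 1),
               character(1)), collapse = "")
}

# Build the genomic sequence of one implanted site and its expected hit
# geometry (relative to the insertion point on the forward strand).
build_site_seq <- function(proto, pam_pattern, mismatches, bulge) {
  L <- nchar(proto)
  chars <- strsplit(proto, "", fixed = TRUE)[[1]]
  if (mismatches > 0) {
    at <- sample(L, mismatches)
    for (p in at) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  # bulges are implanted mid-protospacer: near-terminal bulges are
  # nearly indistinguishable from a shifted bulge-free alignment
  if (bulge == "dna_bulge") {
    b <- sample(4:(L - 4L), 1)
    chars <- append(chars, sample(DNA_BASES, 1), after = b)
  } else if (bulge == "rna_bulge") {
    b <- sample(4:(L - 3L), 1)
    chars <- chars[-b]
  }
  paste0(paste(chars, collapse = ""), concretize_pam(pam_pattern))
}

#' Implant guide target sites into a reference
#'
#' Each requested site (mismatch count, bulge state, strand) is written
#' into the reference at a random well-separated position, then the
#' whole genome is re-scanned: every implant must be recovered with
#' exactly its requested geometry and no accidental extra site within
#' the requested mismatch radius may exist (offending loci are
#' re-randomized, bounded retries).
#'
#' @param reference Genome (named character vector or as accepted by
#'   [scan_genome()]).
#' @param guide A one-row `editscan_guides` tibble.
#' @param specs Tibble (or data.frame) with columns `mismatches`,
#'   `bulge` (`none`/`dna_bulge`/`rna_bulge`) and `strand` (`+`/`-`).
#' @param seed Integer seed.
#' @param params [match_params()] defining the mismatch radius that must
#'   be free of accidental sites.
#' @param max_tries Re-randomization attempts before giving up.
#' @return A list with `genome` (modified reference) and `truth`
#'   (tibble: contig, start, end, strand, mismatches, bulge,
#'   cut_position of every implanted site).
#' @export
implant_guide_sites <- function(reference, guide, specs, seed = 1L,
                                params = match_params(),
                                max_tries = 50L) {
  genome <- as_genome(reference)
  specs <- as_tibble(specs)
  L <- nchar(guide$protospacer)
  if (any(specs$mismatches > L)) {
    abort("mismatches cannot exceed the protospacer length")
  }
  if (any(!specs$bulge %in% c("none", "dna_bulge", "rna_bulge")) ||
      any(!specs$strand %in% c("+", "-"))) {
    abort("bulge must be none/dna_bulge/rna_bulge and strand +/-")
  }
  if (any(specs$mismatches > 0 & specs$bulge != "none" &
            specs$mismatches > params$bulge_mismatch_cap)) {
    abort("bulged implant exceeds bulge_mismatch_cap; it would not be recoverable")
  }
  pam_pattern <- pam_patterns(guide$pam)[1]

  with_local_seed(seed, {
    # assign implant positions round-robin across contigs, well separated
    n <- nrow(specs)
    ctgs <- rep_len(names(genome), n)
    margin <- 200L
    truth <- NULL
    for (i in seq_len(n)) {
      ctg <- ctgs[i]
      clen <- nchar(genome[[ctg]])
      site <- build_site_seq(guide$protospacer, pam_pattern,
                             specs$mismatches[i], specs$bulge[i])
      if (specs$strand[i] == "-") site <- revcomp(site)
      slen <- nchar(site)
      repeat {
        start0 <- sample.int(clen - slen - 2L * margin, 1) + margin
        prior <- truth[truth$contig == ctg, , drop = FALSE]
        if (is.null(prior) || nrow(prior) == 0 ||
            all(abs(prior$start - start0) > 3L * slen)) break
      }
      substr(genome[[ctg]], start0 + 1L, start0 + slen) <- site
      truth <- bind_rows(truth, tibble(
        contig = ctg, start = start0, end = start0 + slen,
        strand = specs$strand[i], guide = guide$name,
        mismatches = as.integer(specs$mismatches[i]),
        bulge = specs$bulge[i]))
    }

    # verification / rejection loop: re-scan and re-randomize accidental
    # sites until the scan recovers exactly the truth records
    for (try in seq_len(max_tries)) {
      hits <- scan_genome(genome, guide, params)
      ok <- nrow(hits) == nrow(truth) &&
        nrow(anti_join(truth,
                       hits[, c("contig", "start", "end", "strand",
                                "mismatches", "bulge")],
                       by = c("contig", "start", "end", "strand",
                              "mismatches", "bulge"))) == 0
      if (ok) {
        truth$cut_position <- hits$cut_position[
          match(paste(truth$contig, truth$start),
                paste(hits$contig, hits$start))]
        return(list(genome = genome, truth = truth))
      }
      extra <- anti_join(hits, truth[, c("contig", "start")],
                         by = c("contig", "start"))
      redo <- rep(FALSE, nrow(truth))
      for (j in seq_len(nrow(extra))) {
        ov <- which(truth$contig == extra$contig[j] &
                      truth$start < extra$end[j] &
                      truth$end > extra$start[j])
        if (length(ov) > 0) {
          # accidental alignment entangled with an implant: re-roll it
          redo[ov] <- TRUE
        } else {
          w <- extra$end[j] - extra$start[j]
          substr(genome[[extra$contig[j]]],
                 extra$start[j] + 1L, extra$end[j]) <- random_dna(w)
        }
      }
      # implants whose geometry was not recovered exactly also get re-rolled
      found <- semi_join(truth,
                         hits[, c("contig", "start", "end", "strand",
                                  "mismatches", "bulge")],
                         by = c("contig", "start", "end", "strand",
                                "mismatches", "bulge"))
      redo <- redo | !paste(truth$contig, truth$start) %in%
        paste(found$contig, found$start)
      for (i in which(redo)) {
        old_span <- truth$end[i] - truth$start[i]
        substr(genome[[truth$contig[i]]], truth$start[i] + 1L,
               truth$end[i]) <- random_dna(old_span)
        site <- build_site_seq(guide$protospacer, pam_pattern,
                               truth$mismatches[i], truth$bulge[i])
        if (truth$strand[i] == "-") site <- revcomp(site)
        slen <- nchar(site)
        clen <- nchar(genome[[truth$contig[i]]])
        repeat {
          start0 <- sample.int(clen - slen - 2L * margin, 1) + margin
          others <- truth[-i, ]
          others <- others[others$contig == truth$contig[i], ]
          if (nrow(others) == 0 ||
              all(abs(others$start - start0) > 3L * slen)) break
        }
        substr(genome[[truth$contig[i]]], start0 + 1L,
               start0 + slen) <- site
        truth$start[i] <- start0
        truth$end[i] <- start0 + slen
      }
    }
    abort("could not produce an accident-free implant in max_tries attempts")
  })
}

#' Place truth variants at implanted sites and random background positions
#'
#' Helper for end-to-end simulations: puts one small indel or SNV at the
#' cut position of every implanted site, plus `n_background` random
#' variants elsewhere.
#'
#' @param genome Named character vector (implanted reference).
#' @param truth Truth table from [implant_guide_sites()].
#' @param n_background Number of random background variants.
#' @param seed Integer seed.
#' @param freq Intended allele frequency of the site variants.
#' @return A tibble of normalized truth variants (`contig`, `pos`,
#'   `ref`, `alt`, `vclass`, `freq`, `at_site`).
#' @export
make_truth_variants <- function(genome, truth, n_background = 100L,
                                seed = 1L, freq = 0.5) {
  with_local_seed(seed, {
    site_vars <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      ctg <- truth$contig[i]
      p <- truth$cut_position[i] + 1L  # 1-based base left of the cut
      anchor <- substr(genome[[ctg]], p - 1L, p - 1L)
      deleted <- substr(genome[[ctg]], p, p)
      tibble(contig = ctg, pos = p - 1L,
             ref = paste0(anchor, deleted), alt = anchor,
             vclass = "del", freq = freq, at_site = TRUE)
    })
    bg <- purrr::map_dfr(seq_len(n_background), function(i) {
      # keep background variants clear of the implanted-site windows so
      # they model unrelated noise, not additional editing events
      repeat {
        ctg <- sample(names(genome), 1)
        clen <- nchar(genome[[ctg]])
        p <- sample.int(clen - 20L, 1) + 10L
        tr <- truth[truth$contig == ctg, ]
        if (nrow(tr) == 0 || all(abs(tr$start - p) > 160L)) break
      }
      b <- substr(genome[[ctg]], p, p)
      if (runif(1) < 0.7) {
        tibble(contig = ctg, pos = p, ref = b,
               alt = sample(setdiff(DNA_BASES, b), 1),
               vclass = "snv", freq = runif(1, 0.3, 1), at_site = FALSE)
      } else {
        tibble(contig = ctg, pos = p,
               ref = substr(genome[[ctg]], p, p + 1L),
               alt = b, vclass = "del", freq = runif(1, 0.3, 1),
               at_site = FALSE)
      }
    })
    vars <- bind_rows(site_vars, bg)
    if (nrow(vars) == 0) {
      return(tibble(contig = character(), pos = integer(),
                    ref = character(), alt = character(),
                    vclass = character(), freq = double(),
                    at_site = logical()))
    }
    vars <- distinct(vars, .data$contig, .data$pos, .keep_all = TRUE)
    calls <- normalize_variants(
      mutate(vars, caller = "truth", alt_depth = 0L, total_depth = 0L,
             sv_type = NA_character_, sv_end = NA_integer_),
      genome)
    calls %>%
      select("contig", "pos", "ref", "alt", "vclass", "freq", "at_site") %>%
      arrange(.data$contig, .data$pos)
  })
}

# Right-shift / pad an indel representation to exercise normalization.
denormalize_indel <- function(contig_seq, pos, ref, alt) {
  # pad with one shared trailing base where possible
  tail_pos <- pos + nchar(ref)
  if (tail_pos <= nchar(contig_seq)) {
    b <- substr(contig_seq, tail_pos, tail_pos)
    ref2 <- paste0(ref, b); alt2 <- paste0(alt, b)
    # shift right while the representation stays consistent with the
    # reference (possible inside repeats)
    for (k in 1:3) {
      npos <- pos + 1L
      nref <- substr(contig_seq, npos, npos + nchar(ref2) - 1L)
      shifted_alt <- paste0(substr(nref, 1, 1),
                            substr(alt2, 2, nchar(alt2)))
      # a shift is only valid when deleting nref\alt2 leaves the same
      # sequence; check by applying both edits to a local window
      w0 <- max(1L, pos - 5L); w1 <- min(nchar(contig_seq),
                                         pos + nchar(ref2) + 5L)
      win <- substr(contig_seq, w0, w1)
      apply_edit <- function(p, r, a) {
        paste0(substr(win, 1, p - w0), a,
               substr(win, p - w0 + 1L + nchar(r), nchar(win)))
      }
      if (npos + nchar(ref2) - 1L <= nchar(contig_seq) &&
          identical(apply_edit(pos, ref2, alt2),
                    apply_edit(npos, nref, shifted_alt))) {
        pos <- npos; ref2 <- nref; alt2 <- shifted_alt
      } else break
    }
    return(list(pos = pos, ref = ref2, alt = alt2))
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Simulate per-caller variant calls (and VCFs) from a truth set
#'
#' Truth variants are emitted per caller with the given sensitivity;
#' background variants private to single callers are added at
#' `background_rate` per caller; indel representations are randomly
#' right-shifted/padded to exercise normalization.  Depths follow a
#' Poisson model with binomial allele sampling at each variant's
#' intended frequency.
#'
#' @param truth Truth-variant tibble ([make_truth_variants()]).
#' @param genome Named character vector.
#' @param seed Integer seed.
#' @param snv_callers,indel_callers Caller names per class.
#' @param sensitivity Per-caller detection probability (scalar or named).
#' @param background_rate Expected private false calls per caller.
#' @param mean_depth Mean sequencing depth.
#' @param dir Optional directory: write one VCF per caller.
#' @param unnormalize Fraction of indel emissions written in a
#'   non-minimal right-shifted representation.
#' @return A list with `calls` (all callers, un-normalized) and `paths`
#'   (named VCF paths, when `dir` is given).
#' @export
simulate_caller_vcfs <- function(truth, genome, seed = 1L,
                                 snv_callers = c("lofreq", "mutect2",
                                                 "varscan2"),
                                 indel_callers = c("mutect2", "varscan2",
                                                   "pindel"),
                                 sensitivity = 1.0,
                                 background_rate = 0,
                                 mean_depth = 100L,
                                 dir = NULL, unnormalize = 0.5) {
  all_callers <- unique(c(snv_callers, indel_callers))
  sens <- if (is.null(names(sensitivity))) {
    setNames(rep_len(sensitivity, length(all_callers)), all_callers)
  } else sensitivity
  calls <- with_local_seed(seed, {
    rows <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      v <- truth[i, ]
      callers <- if (v$vclass == "snv") snv_callers else indel_callers
      purrr::map_dfr(callers, function(cl) {
        if (runif(1) > sens[[cl]]) return(NULL)
        depth <- max(10L, rpois(1, mean_depth))
        ad <- rbinom(1, depth, v$freq)
        pos <- v$pos; ref <- v$ref; alt <- v$alt
        if (v$vclass != "snv" && runif(1) < unnormalize) {
          dn <- denormalize_indel(genome[[v$contig]], pos, ref, alt)
          pos <- dn$pos; ref <- dn$ref; alt <- dn$alt
        }
        variant_calls(cl, v$contig, pos, ref, alt, ad, depth)
      })
    })
    bg <- purrr::map_dfr(all_callers, function(cl) {
      nb <- rpois(1, background_rate)
      if (nb == 0) return(NULL)
      purrr::map_dfr(seq_len(nb), function(k) {
        ctg <- sample(names(genome), 1)
        p <- sample.int(nchar(genome[[ctg]]) - 20L, 1) + 10L
        b <- substr(genome[[ctg]], p, p)
        depth <- max(10L, rpois(1, mean_depth))
        variant_calls(cl, ctg, p, b, sample(setdiff(DNA_BASES, b), 1),
                      rbinom(1, depth, 0.3), depth)
      })
    })
    bind_rows(rows, bg)
  })
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- setNames(file.path(dir, paste0(all_callers, ".vcf")),
                      all_callers)
    for (cl in all_callers) {
      write_calls_vcf(calls[calls$caller == cl, ], paths[[cl]], genome)
    }
  }
  list(calls = calls, paths = paths)
}

#' Default indel spectrum for amplicon simulations
#'
#' Single-nucleotide indels at the cleavage site dominate real editing
#' outcomes, with a minority of longer deletions.
#'
#' @return A tibble with `kind`, `size`, `offset` (0-based position of
#'   the indel relative to the cut; deletions start there) and `prop`.
#' @export
default_spectrum <- function() {
  tibble(kind = c("deletion", "insertion", "deletion"),
         size = c(1L, 1L, 3L),
         offset = c(0L, 1L, -2L),
         prop = c(0.5, 0.3, 0.2))
}

apply_signature <- function(amplicon, cut_offset, kind, size, offset) {
  if (kind == "deletion") {
    d0 <- cut_offset + offset  # first deleted base, 0-based
    paste0(substr(amplicon, 1, d0), substr(amplicon, d0 + size + 1L,
                                           nchar(amplicon)))
  } else {
    at <- cut_offset + offset  # insert before this 0-based position
    ins <- random_dna(size)
    paste0(substr(amplicon, 1, at), ins,
           substr(amplicon, at + 1L, nchar(amplicon)))
  }
}

#' Simulate amplicon deep-sequencing reads
#'
#' Reads are mutant with probability `efficiency`; mutant reads carry an
#' indel signature drawn from `spectrum`; every base is substituted at
#' `subst_error_rate` to emulate sequencing error.
#'
#' @param spec An [amplicon_spec()].
#' @param efficiency True editing efficiency in `[0, 1]`.
#' @param spectrum Signature tibble (see [default_spectrum()]); `prop`
#'   must sum to 1.
#' @param n_reads Number of reads.
#' @param subst_error_rate Per-base substitution error rate (default
#'   0.001, a typical Illumina floor).
#' @param seed Integer seed.
#' @param fastq Optional path: write the reads as FASTQ.
#' @return A list with `reads` (character vector) and `truth`
#'   (`efficiency`, `n_mutant`, per-signature counts).
#' @export
simulate_amplicon_reads <- function(spec, efficiency,
                                    spectrum = default_spectrum(),
                                    n_reads = 10000L,
                                    subst_error_rate = 0.001,
                                    seed = 1L, fastq = NULL) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (efficiency < 0 || efficiency > 1) abort("efficiency must be in [0,1]")
  if (abs(sum(spectrum$prop) - 1) > 1e-8) {
    abort("spectrum proportions must sum to 1")
  }
  out <- with_local_seed(seed, {
    templates <- vapply(seq_len(nrow(spectrum)), function(i) {
      apply_signature(spec$amplicon_seq, spec$cut_offset,
                      spectrum$kind[i], spectrum$size[i],
                      spectrum$offset[i])
    }, character(1))
    is_mut <- runif(n_reads) < efficiency
    sig_id <- integer(n_reads)
    sig_id[is_mut] <- sample.int(nrow(spectrum), sum(is_mut),
                                 replace = TRUE, prob = spectrum$prop)
    reads <- ifelse(is_mut, templates[pmax(sig_id, 1L)],
                    spec$amplicon_seq)
    # sparse substitution noise
    lens <- nchar(reads)
    n_err <- rbinom(n_reads, lens, subst_error_rate)
    for (i in which(n_err > 0)) {
      at <- sample.int(lens[i], n_err[i])
      for (p in at) {
        b <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, b), 1)
      }
    }
    list(reads = reads,
         truth = list(efficiency = efficiency,
                      n_mutant = sum(is_mut),
                      signature_counts = table(factor(sig_id[is_mut],
                                                      levels = seq_len(nrow(spectrum))))))
  })
  if (!is.null(fastq)) write_fastq(out$reads, fastq)
  out
}

#' Write reads as FASTQ (uniform quality)
#'
#' @param reads Character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@read", seq_along(reads)), reads,
                           "+", qual))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Simulate digenome read starts
#'
#' Uniform background alignments at `background_depth` coverage plus
#' clustered blunt-cut signatures: at every cut, `f_reads` forward reads
#' start at `cut + 1` and `r_reads` reverse reads end at `cut`.
#'
#' @param reference Genome (named character vector or compatible).
#' @param cuts Tibble with `contig`, `cut` (0-based; cut between `cut`
#'   and `cut+1`), `f_reads`, `r_reads`.  May have zero rows.
#' @param background_depth Mean background coverage.
#' @param read_length Read length (default 150).
#' @param seed Integer seed.
#' @param path Optional path: write the alignment table as TSV.
#' @return A list with `alignments` (sorted tibble: contig, strand,
#'   start, end; 0-based half-open) and `truth` (the cuts).
#' @export
simulate_digenome_readstarts <- function(reference, cuts,
                                         background_depth = 20,
                                         read_length = 150L, seed = 1L,
                                         path = NULL) {
  genome <- as_genome(reference)
  al <- with_local_seed(seed, {
    bg <- purrr::map_dfr(names(genome), function(ctg) {
      clen <- nchar(genome[[ctg]])
      n <- round(background_depth * clen / read_length)
      if (n == 0) return(NULL)
      start <- sample.int(clen - read_length + 1L, n, replace = TRUE) - 1L
      tibble(contig = ctg, strand = sample(c("+", "-"), n, replace = TRUE),
             start = start, end = start + read_length)
    })
    cut_reads <- NULL
    if (nrow(cuts) > 0) {
      cut_reads <- purrr::map_dfr(seq_len(nrow(cuts)), function(i) {
        cc <- cuts[i, ]
        clen <- nchar(genome[[cc$contig]])
        fwd <- tibble(contig = cc$contig, strand = "+",
                      start = rep(cc$cut + 1L, cc$f_reads))
        fwd$end <- pmin(fwd$start + read_length, clen)
        rev <- tibble(contig = cc$contig, strand = "-",
                      end = rep(cc$cut + 1L, cc$r_reads))
        rev$start <- pmax(rev$end - read_length, 0L)
        bind_rows(fwd, rev)
      })
    }
    bind_rows(bg, cut_reads) %>%
      arrange(.data$contig, .data$start, .data$end)
  })
  if (!is.null(path)) readr::write_tsv(al, path)
  list(alignments = al, truth = cuts)
}
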