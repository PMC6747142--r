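# Amplicon editing quantification and mutation-profile summaries.

test_that("the cut offset is located 3 nt 5' of the PAM inside the amplicon", {
  spec <- mk_amplicon()
  expect_equal(spec$proto_start, 90L)
  expect_equal(spec$pam_start, 109L)
  expect_equal(spec$cut_offset, 105L)
  # cut_offset can be supplied and is validated
  spec2 <- amplicon_spec("s", spec$amplicon_seq, spec$guide,
                         cut_offset = 105L)
  expect_equal(spec2$cut_offset, 105L)
  expect_error(amplicon_spec("s", spec$amplicon_seq, spec$guide,
                             cut_offset = 50L), "not found")
})

test_that("efficiency is mutant reads over total reads", {
  spec <- mk_amplicon()
  amp <- spec$amplicon_seq
  del1 <- paste0(substr(amp, 1, spec$cut_offset),
                 substr(amp, spec$cut_offset + 2, nchar(amp)))
  reads <- c(rep(amp, 750), rep(del1, 250))
  rep1 <- quantify_editing(reads, spec)
  expect_equal(rep1$total_reads, 1000L)
  expect_equal(rep1$mutant_reads, 250L)
  expect_equal(rep1$efficiency, 0.25)
  expect_equal(nrow(rep1$spectrum), 1L)
  expect_equal(rep1$spectrum$frequency, 0.25)
  g <- glance(rep1)
  expect_equal(g$efficiency, 0.25)
  expect_false(g$flagged)
})

test_that("substitution-only reads are never mutant by default", {
  spec <- mk_amplicon()
  amp <- spec$amplicon_seq
  sub <- amp
  substr(sub, spec$cut_offset + 1, spec$cut_offset + 1) <-
    setdiff(c("A", "C", "G", "T"),
            substr(amp, spec$cut_offset + 1, spec$cut_offset + 1))[1]
  rep1 <- quantify_editing(rep(sub, 100), spec)
  expect_equal(rep1$mutant_reads, 0L)
  rep2 <- quantify_editing(rep(sub, 100), spec,
                           include_substitutions = TRUE)
  expect_equal(rep2$mutant_reads, 100L)
})

test_that("indels outside the counting window do not count as editing", {
  spec <- mk_amplicon()
  amp <- spec$amplicon_seq
  far_del <- paste0(substr(amp, 1, 10), substr(amp, 12, nchar(amp)))
  rep1 <- quantify_editing(c(rep(amp, 50), rep(far_del, 50)), spec)
  expect_equal(rep1$mutant_reads, 0L)
})

test_that("rare signatures honour the 2-read and 1-per-mille rules", {
  spec <- mk_amplicon()
  amp <- spec$amplicon_seq
  co <- spec$cut_offset
  del1 <- paste0(substr(amp, 1, co), substr(amp, co + 2, nchar(amp)))
  del2 <- paste0(substr(amp, 1, co - 1), substr(amp, co + 2, nchar(amp)))
  ins1 <- paste0(substr(amp, 1, co + 1), "A",
                 substr(amp, co + 2, nchar(amp)))
  n <- 10000L
  reads <- c(rep(amp, n - 25 - 5 - 1), rep(del1, 25),
             rep(ins1, 5), rep(del2, 1))
  rep1 <- quantify_editing(reads, spec)
  # the single-read signature is not counted at all
  expect_equal(rep1$mutant_reads, 30L)
  # the 5/10000 = 0.0005 signature counts as mutant but is below the
  # bona-fide threshold, so it is dropped from the spectrum
  expect_equal(nrow(rep1$spectrum), 1L)
  expect_equal(rep1$spectrum$count, 25L)
  # a 0.002-frequency signature stays in the spectrum
  reads2 <- c(rep(amp, n - 20), rep(ins1, 20))
  rep2 <- quantify_editing(reads2, spec)
  expect_equal(nrow(rep2$spectrum), 1L)
  expect_equal(rep2$spectrum$frequency, 0.002)
})

test_that("simulated efficiencies are recovered within binomial error", {
  spec <- mk_amplicon()
  sim <- simulate_amplicon_reads(spec, efficiency = 0.25,
                                 n_reads = 10000L, seed = 63)
  rep1 <- quantify_editing(sim$reads, spec)
  expect_lt(abs(rep1$efficiency - 0.25), 0.015)
  # degenerate efficiencies
  sim0 <- simulate_amplicon_reads(spec, 0, n_reads = 500, seed = 64)
  expect_equal(quantify_editing(sim0$reads, spec)$efficiency, 0)
  spectrum1 <- tibble::tibble(kind = "insertion", size = 1L, offset = 1L,
                              prop = 1)
  sim1 <- simulate_amplicon_reads(spec, 1, spectrum = spectrum1,
                                  n_reads = 500, seed = 65,
                                  subst_error_rate = 0)
  rep1b <- quantify_editing(sim1$reads, spec)
  expect_equal(rep1b$efficiency, 1)
  expect_equal(nrow(rep1b$spectrum), 1L)
})

test_that("two planted signatures are recovered in their simulated proportions", {
  spec <- mk_amplicon()
  spectrum <- tibble::tibble(kind = c("deletion", "insertion"),
                             size = c(1L, 1L), offset = c(0L, 1L),
                             prop = c(0.7, 0.3))
  sim <- simulate_amplicon_reads(spec, 0.5, spectrum, n_reads = 10000L,
                                 seed = 66)
  sp <- variant_spectrum(sim$reads, spec)
  expect_equal(nrow(sp), 2L)
  props <- sp$count / sum(sp$count)
  expect_lt(abs(max(props) - 0.7), 0.03)
  # empty read set: flagged zero report, empty spectrum
  rep0 <- quantify_editing(character(0), spec)
  expect_true(rep0$flagged)
  expect_equal(rep0$efficiency, 0)
  expect_equal(nrow(tidy(rep0)), 0L)
})

test_that("FASTQ input round-trips through the quantifier", {
  withr::with_tempfile("fq", fileext = ".fastq", {
    spec <- mk_amplicon()
    sim <- simulate_amplicon_reads(spec, 0.4, n_reads = 400, seed = 67,
                                   fastq = fq)
    rep_file <- quantify_editing(fq, spec)
    rep_mem <- quantify_editing(sim$reads, spec)
    expect_equal(rep_file$efficiency, rep_mem$efficiency)
    expect_equal(rep_file$spectrum, rep_mem$spectrum)
  })
})

test_that("PAM-relative coordinates follow the -1 = 1 nt upstream convention", {
  spec <- mk_amplicon()
  amp <- spec$amplicon_seq
  co <- spec$cut_offset
  # delete the 0-based base pam_start - 3: three nt upstream of the PAM.
  # protospacer ends ...CATCCA|TGG; left-alignment keeps the deleted C of
  # the CC pair at its leftmost placement, still rel -3
  del <- paste0(substr(amp, 1, spec$pam_start - 3),
                substr(amp, spec$pam_start - 1, nchar(amp)))
  rep1 <- quantify_editing(rep(del, 10), spec)
  rec <- mutation_records(rep1)
  expect_equal(rec$kind, "deletion")
  expect_equal(rec$start_rel, -3L)
  expect_equal(rec$end_rel, -3L)
  # insertion at the blunt cut (between -4 and -3) is anchored at -3;
  # use a base distinct from both neighbours so the placement is unique
  ins <- paste0(substr(amp, 1, co + 1), "G",
                substr(amp, co + 2, nchar(amp)))
  rep2 <- quantify_editing(rep(ins, 10), spec)
  rec2 <- mutation_records(rep2)
  expect_equal(rec2$kind, "insertion")
  expect_equal(rec2$start_rel, -3L)
})

test_that("mutation-profile histograms bin sizes and positions with mass conservation", {
  records <- tibble::tibble(
    kind = c("deletion", "deletion", "insertion", "insertion"),
    size = c(1L, 3L, 1L, 1L),
    start_rel = c(-3L, -5L, -3L, -1L),
    end_rel = c(-3L, -3L, -3L, -1L),
    count = c(4L, 2L, 3L, 1L))
  prof <- summarize_mutation_profile(records)
  sh <- prof$size_histogram
  expect_equal(sh$n[sh$key == "1D"], 4L)
  expect_equal(sh$n[sh$key == "3D"], 2L)
  expect_equal(sh$n[sh$key == "1I"], 4L)
  expect_equal(sum(sh$n), sum(records$count))
  ins <- prof$insertion_position_histogram
  expect_equal(ins$n[ins$position == -3], 3L)
  expect_equal(sum(prof$deletion_start_histogram$n), 6L)
  expect_equal(sum(prof$deletion_end_histogram$n), 6L)
  # empty input: four empty histograms
  empty <- summarize_mutation_profile(records[0, ])
  expect_equal(nrow(empty$size_histogram), 0L)
  expect_equal(nrow(empty$insertion_position_histogram), 0L)
})

test_that("reads that do not span the counting window are excluded from the total", {
  spec <- mk_amplicon()
  amp <- spec$amplicon_seq
  short <- substr(amp, 1, spec$cut_offset - 5)  # stops before the window end
  rep1 <- quantify_editing(c(rep(amp, 90), rep(short, 10)), spec)
  expect_equal(rep1$total_reads, 90L)
})
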