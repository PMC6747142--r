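# Mismatch/bulge-tolerant guide matching.

test_that("an exact implant is found once, on the right strand, with cut 3 nt 5' of the PAM", {
  set.seed(11)
  g <- test_guide()
  seq1 <- paste0(rand_seq(50), g$protospacer, "TGG", rand_seq(50))
  h <- scan_sequence(seq1, g)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
  expect_equal(h$mismatches, 0L)
  expect_equal(h$bulge, "none")
  expect_equal(h$start, 50L)
  expect_equal(h$end, 50L + 19L + 3L)
  expect_equal(h$pam_observed, "TGG")
  # PAM starts at 69 (0-based); blunt cut between 65 and 66
  expect_equal(h$cut_position, 65L)

  h2 <- scan_sequence(revcomp(seq1), g)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$mismatches, 0L)
  S <- nchar(seq1)
  expect_equal(h2$start, S - h$end)
  expect_equal(h2$end, S - h$start)
  expect_equal(h2$cut_position, S - h$cut_position - 2L)
})

test_that("a 2-mismatch site is reported while a 7-mismatch decoy is not", {
  set.seed(12)
  g <- test_guide()
  site2 <- paste0(mutate_proto(g$protospacer, 2), "AGG")
  decoy <- paste0(mutate_proto(g$protospacer, 7), "TGG")
  host <- rand_seq(400)
  host <- implant_at(host, site2, 60)
  host <- implant_at(host, decoy, 250)
  h <- scan_sequence(host, g)
  orc <- oracle_scan(host, g)
  expect_equal(hit_key(h), hit_key(orc))
  expect_true(any(h$start == 60 & h$mismatches == 2))
  expect_false(any(h$start == 250))
})

test_that("a mid-protospacer DNA bulge is reported as dna_bulge only when bulges are enabled", {
  set.seed(13)
  g <- test_guide()
  chars <- strsplit(g$protospacer, "")[[1]]
  bulged <- paste0(paste(c(chars[1:9], "T", chars[10:19]), collapse = ""),
                   "TGG")
  seq1 <- paste0(rand_seq(60), bulged, rand_seq(60))
  h <- scan_sequence(seq1, g)
  expect_true(any(h$bulge == "dna_bulge" & h$mismatches == 0 &
                    h$start == 60))
  h_nb <- scan_sequence(seq1, g, match_params(allow_bulge = FALSE))
  expect_false(any(h_nb$bulge != "none"))
  expect_false(any(h_nb$mismatches == 0))
  # oracle agrees in both modes
  expect_equal(hit_key(h), hit_key(oracle_scan(seq1, g)))
  expect_equal(hit_key(h_nb),
               hit_key(oracle_scan(seq1, g, match_params(allow_bulge = FALSE))))
})

test_that("an RNA bulge (omitted genomic base) is found with 0 mismatches", {
  set.seed(14)
  g <- test_guide()
  chars <- strsplit(g$protospacer, "")[[1]]
  bulged <- paste0(paste(chars[-10], collapse = ""), "CGG")
  seq1 <- paste0(rand_seq(60), bulged, rand_seq(60))
  h <- scan_sequence(seq1, g)
  expect_true(any(h$bulge == "rna_bulge" & h$mismatches == 0))
  expect_equal(hit_key(h), hit_key(oracle_scan(seq1, g)))
})

test_that("N in the genome counts as a protospacer mismatch and invalid characters error", {
  g <- test_guide()
  chars <- strsplit(g$protospacer, "")[[1]]
  chars[5] <- "N"
  seq1 <- paste0(strrep("A", 30), paste(chars, collapse = ""), "TGG",
                 strrep("C", 30))
  h <- scan_sequence(seq1, g, match_params(max_mismatches = 1))
  expect_true(any(h$mismatches == 1 & h$start == 30))
  h0 <- scan_sequence(seq1, g, match_params(max_mismatches = 0,
                                            allow_bulge = FALSE))
  expect_equal(nrow(h0), 0L)
  expect_error(scan_sequence("ACGTZZZ", g), "invalid")
})

test_that("sequences shorter than protospacer + PAM give an empty result", {
  g <- test_guide()
  expect_equal(nrow(scan_sequence("ACGTACGT", g)), 0L)
})

test_that("PAM must match its IUPAC pattern and mismatches there are not counted by default", {
  set.seed(15)
  g <- test_guide()
  seq_bad_pam <- paste0(rand_seq(40), g$protospacer, "TCG", rand_seq(40))
  expect_equal(nrow(scan_sequence(seq_bad_pam, g)), 0L)
  # with pam_mismatch_counted the same site appears, PAM failure counted
  h <- scan_sequence(seq_bad_pam, g,
                     match_params(pam_mismatch_counted = TRUE))
  expect_true(any(h$start == 40 & h$mismatches == 1))
  # NAG PAM accepted when declared
  g2 <- guide_target("gNAG", g$protospacer, pam = "NGG,NAG")
  seq_nag <- paste0(rand_seq(40), g2$protospacer, "TAG", rand_seq(40))
  h2 <- scan_sequence(seq_nag, g2)
  expect_true(any(h2$start == 40 & h2$mismatches == 0))
})

test_that("scanner equals the brute-force oracle on random sequences across parameter settings", {
  g <- test_guide()
  for (seed in 1:25) {
    set.seed(seed)
    s <- rand_seq(sample(300:1500, 1), gc = runif(1, 0.3, 0.6))
    for (mm in c(0L, 3L, 6L)) {
      for (bulge in c(TRUE, FALSE)) {
        p <- match_params(max_mismatches = mm, allow_bulge = bulge)
        expect_equal(hit_key(scan_sequence(s, g, p)),
                     hit_key(oracle_scan(s, g, p)),
                     info = sprintf("seed %d mm %d bulge %s", seed, mm,
                                    bulge))
      }
    }
  }
})

test_that("raising max_mismatches never removes hits; disabling bulges removes only bulge hits", {
  g <- test_guide()
  for (seed in 1:10) {
    set.seed(100 + seed)
    s <- rand_seq(2000, gc = 0.4)
    prev <- NULL
    for (mm in 0:6) {
      h <- scan_sequence(s, g, match_params(max_mismatches = mm))
      if (!is.null(prev)) {
        expect_true(all(hit_key(prev) %in% hit_key(h)))
      }
      prev <- h
    }
    h6 <- prev
    h6_nb <- scan_sequence(s, g, match_params(allow_bulge = FALSE))
    expect_true(all(hit_key(h6_nb) %in% hit_key(h6[h6$bulge == "none", ])))
  }
})

test_that("hits on a sequence and its reverse complement mirror each other", {
  g <- test_guide()
  for (seed in 1:10) {
    set.seed(200 + seed)
    s <- paste0(rand_seq(300), mutate_proto(g$protospacer, 2), "TGG",
                rand_seq(300))
    h_f <- scan_sequence(s, g)
    h_r <- scan_sequence(revcomp(s), g)
    S <- nchar(s)
    mirrored <- paste(S - h_r$end, S - h_r$start,
                      ifelse(h_r$strand == "+", "-", "+"),
                      h_r$mismatches, h_r$bulge, sep = ":")
    expect_setequal(hit_key(h_f), mirrored)
  }
})

test_that("cut position always sits 3 nt 5' of the observed PAM", {
  g <- test_guide()
  set.seed(31)
  s <- paste0(rand_seq(100), g$protospacer, "TGG", rand_seq(50),
              revcomp(paste0(mutate_proto(g$protospacer, 1), "CGG")),
              rand_seq(100))
  h <- scan_sequence(s, g)
  expect_gt(nrow(h), 1)
  for (i in seq_len(nrow(h))) {
    L_gen <- h$end[i] - h$start[i] - 3L  # genomic protospacer footprint
    if (h$strand[i] == "+") {
      pam0 <- h$start[i] + L_gen
      expect_equal(h$cut_position[i], pam0 - 4L)
    } else {
      pam_end <- h$start[i] + 3L  # PAM occupies [start, start+3) fwd
      expect_equal(h$cut_position[i], h$start[i] + 5L)
    }
  }
})

test_that("scan_genome unions per-contig scans and handles empty guide sets", {
  set.seed(16)
  g <- test_guide()
  c1 <- paste0(rand_seq(200), g$protospacer, "TGG", rand_seq(200))
  c2 <- paste0(rand_seq(150), revcomp(paste0(g$protospacer, "AGG")),
               rand_seq(150))
  genome <- c(ctgA = c1, ctgB = c2)
  h <- scan_genome(genome, g)
  expect_equal(nrow(h), 2L)
  expect_setequal(h$contig, c("ctgA", "ctgB"))
  expect_equal(nrow(scan_genome(genome, g[0, ])), 0L)
})

test_that("guide and parameter validation reject malformed inputs", {
  expect_error(guide_target("g", "GTCACTTACTCGTCATCNA"), "A/C/G/T")
  expect_error(guide_target("g", "ACGT"), "17-23")
  expect_error(guide_target("g", "GTCACTTACTCGTCATCCA", pam = "NGGG"),
               "3 IUPAC")
  expect_error(match_params(bulge_mismatch_cap = 3, max_mismatches = 2),
               "bulge_mismatch_cap")
  expect_error(guide_target("g", "GTCACTTACTCGTCATCCA",
                            locus_contig = "c", locus_start = 10,
                            locus_end = 20, locus_strand = "+"),
               "span")
})
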