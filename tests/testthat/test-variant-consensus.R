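# Variant normalization, consensus thresholds, control subtraction.

# brute-force left-shift oracle: slide a pure indel left one base at a
# time while the edited sequence stays identical
oracle_leftalign <- function(contig_seq, pos, ref, alt) {
  apply_edit <- function(p, r, a) {
    paste0(substr(contig_seq, 1, p - 1), a,
           substr(contig_seq, p + nchar(r), nchar(contig_seq)))
  }
  target <- apply_edit(pos, ref, alt)
  best <- list(pos = pos, ref = ref, alt = alt)
  d <- abs(nchar(ref) - nchar(alt))
  if (d == 0) return(best)
  for (p in seq_len(pos)) {          # every candidate anchor left of pos
    for (len_short in 1:3) {
      r <- substr(contig_seq, p, p + len_short + d - 1)
      a <- substr(contig_seq, p, p + len_short - 1)
      if (nchar(ref) < nchar(alt)) { tmp <- r; r <- a; a <- tmp }
      if (nchar(r) == 0 || nchar(a) == 0) next
      if (identical(apply_edit(p, r, a), target)) {
        # minimal representation at the leftmost anchor
        return(editscan:::normalize_one(contig_seq, p, r, a))
      }
    }
  }
  best
}

test_that("normalization trims, left-aligns and is idempotent", {
  genome <- c(chr = "GGGACAAAATTTTCCCATGCACGTACGT")
  # SNV already minimal
  v <- variant_calls("c1", "chr", 5, "C", "T")
  n <- normalize_variants(v, genome)
  expect_equal(n[, c("pos", "ref", "alt")],
               v[, c("pos", "ref", "alt")])
  # shared prefix/suffix trim: ATG -> ACG becomes T -> C at pos+1
  v2 <- variant_calls("c1", "chr", 17, "ATG", "ACG")
  n2 <- normalize_variants(v2, genome)
  expect_equal(n2$pos, 18L)
  expect_equal(n2$ref, "T")
  expect_equal(n2$alt, "C")
  expect_equal(n2$vclass, "snv")
  # right-shifted homopolymer deletion left-aligns to the run's anchor
  # chr = G G G A C A A A A T ...  (delete two As)
  v3 <- variant_calls("c1", "chr", 7, "AAA", "A")
  n3 <- normalize_variants(v3, genome)
  orc <- oracle_leftalign(genome[["chr"]], 7L, "AAA", "A")
  expect_equal(n3$pos, orc$pos)
  expect_equal(n3$ref, orc$ref)
  expect_equal(n3$alt, orc$alt)
  expect_equal(n3$pos, 5L)  # anchored at the C before the A-run
  expect_equal(n3$ref, "CAA")
  expect_equal(n3$alt, "C")
  # idempotent
  n3b <- normalize_variants(n3, genome)
  expect_equal(n3b[, c("pos", "ref", "alt")], n3[, c("pos", "ref", "alt")])
  # REF/reference mismatch errors
  expect_error(normalize_variants(variant_calls("c1", "chr", 5, "G", "T"),
                                  genome), "mismatch")
})

test_that("normalization matches the left-shift oracle on random homopolymer indels", {
  set.seed(21)
  for (rep in 1:30) {
    genome <- c(chr = rand_seq(120, gc = 0.3))
    p <- sample(30:80, 1)
    d <- sample(1:3, 1)
    ref <- substr(genome[["chr"]], p, p + d)
    alt <- substr(genome[["chr"]], p, p)
    n <- normalize_variants(variant_calls("c", "chr", p, ref, alt), genome)
    orc <- oracle_leftalign(genome[["chr"]], p, ref, alt)
    expect_equal(n$pos, orc$pos)
    expect_equal(n$ref, orc$ref)
    expect_equal(n$alt, orc$alt)
  }
})

test_that("consensus applies caller-count, depth and SV-length thresholds literally", {
  calls <- dplyr::bind_rows(
    # SNV in 2 of 3 callers, good depth -> kept
    variant_calls(c("lofreq", "mutect2"), "c1", 100, "A", "G",
                  alt_depth = 10, total_depth = 80),
    # indel in 1 caller only -> dropped
    variant_calls("pindel", "c1", 200, "CA", "C", alt_depth = 20,
                  total_depth = 90),
    # SNV in all 3 callers but max alt depth 1 -> dropped
    variant_calls(c("lofreq", "mutect2", "varscan2"), "c1", 300, "T", "C",
                  alt_depth = 1, total_depth = 100),
    # 12 kb deletion in both SV callers -> dropped by the length cap
    variant_calls(c("delly", "pindel"), "c1", 1000, sv_type = "DEL",
                  sv_end = 13000, alt_depth = 15, total_depth = 60),
    # 5 kb deletion in both SV callers -> kept
    variant_calls(c("delly", "pindel"), "c2", 500, sv_type = "DEL",
                  sv_end = 5500, alt_depth = 15, total_depth = 60),
    # SV in one caller only -> dropped
    variant_calls("delly", "c2", 9000, sv_type = "INV", sv_end = 9800,
                  alt_depth = 15, total_depth = 60))
  cons <- build_consensus(calls)
  expect_equal(nrow(cons), 2L)
  snv <- cons[cons$vclass == "snv", ]
  expect_equal(snv$pos, 100L)
  expect_setequal(snv$callers[[1]], c("lofreq", "mutect2"))
  sv <- cons[cons$vclass == "sv", ]
  expect_equal(sv$pos, 500L)
  expect_equal(sv$sv_length, 5000L)
})

test_that("SV breakpoints match across callers within the wobble tolerance", {
  calls <- dplyr::bind_rows(
    variant_calls("delly", "c1", 1000, sv_type = "DEL", sv_end = 3000,
                  alt_depth = 10, total_depth = 50),
    variant_calls("pindel", "c1", 1008, sv_type = "DEL", sv_end = 2995,
                  alt_depth = 10, total_depth = 50),
    # same coordinates, different type: no match
    variant_calls("delly", "c1", 5000, sv_type = "DUP", sv_end = 6000,
                  alt_depth = 10, total_depth = 50),
    variant_calls("pindel", "c1", 5000, sv_type = "DEL", sv_end = 6000,
                  alt_depth = 10, total_depth = 50),
    # breakpoints 25 bp apart: no match
    variant_calls("delly", "c2", 100, sv_type = "DEL", sv_end = 900,
                  alt_depth = 10, total_depth = 50),
    variant_calls("pindel", "c2", 125, sv_type = "DEL", sv_end = 900,
                  alt_depth = 10, total_depth = 50))
  cons <- build_consensus(calls)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$n_callers, 2L)
  expect_equal(cons$pos, 1000L)
})

test_that("identical calls merge after normalization even when one caller right-shifts", {
  genome <- c(chr = paste0(rand_seq(40, 0.3), "CAAAAAT", rand_seq(40, 0.3)))
  # left-aligned deletion of one A (anchor C at 41)
  a <- variant_calls("mutect2", "chr", 41, "CA", "C", alt_depth = 30,
                     total_depth = 80)
  # same event right-shifted inside the homopolymer, padded
  b <- variant_calls("varscan2", "chr", 44, "AA", "A", alt_depth = 28,
                     total_depth = 75)
  calls <- normalize_variants(dplyr::bind_rows(a, b), genome)
  cons <- build_consensus(calls)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$n_callers, 2L)
  expect_equal(cons$max_alt_depth, 30L)
  expect_equal(cons$pos, 41L)
})

test_that("control subtraction removes shared variants and keeps unique ones, independent of order", {
  mk <- function(pos) {
    build_consensus(variant_calls(c("lofreq", "mutect2"), "c1", pos,
                                  "A", "G", alt_depth = 10,
                                  total_depth = 50))
  }
  mut <- dplyr::bind_rows(mk(100), mk(200), mk(300))
  wt <- mk(100)
  other <- mk(200)
  out1 <- subtract_controls(mut, list(wt, other))
  out2 <- subtract_controls(mut, list(other, wt))
  expect_equal(out1$pos, 300L)
  expect_equal(out1, out2)
  expect_equal(subtract_controls(mut, list()), mut)
})

test_that("consensus monotonicity: relaxing thresholds never shrinks the set; controls never grow it", {
  set.seed(22)
  genome <- c(chr = rand_seq(5000, 0.4))
  # construct calls with varying support
  calls <- purrr::map_dfr(seq(100, 2000, by = 100), function(p) {
    ncall <- sample(1:3, 1)
    variant_calls(sample(c("lofreq", "mutect2", "varscan2"), ncall),
                  "chr", p, substr(genome[["chr"]], p, p),
                  setdiff(c("A", "C", "G", "T"),
                          substr(genome[["chr"]], p, p))[1],
                  alt_depth = sample(1:10, 1), total_depth = 60)
  })
  strict <- build_consensus(calls, consensus_params(snv_min_callers = 3,
                                                    min_depth = 5))
  loose <- build_consensus(calls, consensus_params(snv_min_callers = 2,
                                                   min_depth = 2))
  key <- function(x) paste(x$contig, x$pos, x$ref, x$alt)
  expect_true(all(key(strict) %in% key(loose)))
  ctl <- loose[seq_len(min(3, nrow(loose))), ]
  expect_lte(nrow(subtract_controls(loose, ctl)), nrow(loose))
})

test_that("consensus VCF round-trips exactly", {
  withr::with_tempfile("vcf", fileext = ".vcf", {
    genome <- c(chr = rand_seq(500, 0.4))
    calls <- dplyr::bind_rows(
      variant_calls(c("lofreq", "mutect2"), "chr", 100, "A", "G",
                    alt_depth = 12, total_depth = 60),
      variant_calls(c("mutect2", "varscan2"), "chr", 250, "CA", "C",
                    alt_depth = 8, total_depth = 55))
    cons <- build_consensus(calls)
    write_consensus_vcf(cons, vcf)
    back <- read_consensus_vcf(vcf)
    cols <- c("contig", "pos", "ref", "alt", "vclass", "n_callers",
              "max_alt_depth", "total_depth")
    expect_equal(as.data.frame(back[, cols]), as.data.frame(cons[, cols]))
    expect_equal(back$callers, cons$callers)
  })
})

test_that("per-caller VCFs written by the simulator read back losslessly", {
  withr::with_tempdir({
    set.seed(23)
    genome <- c(ctg1 = rand_seq(3000, 0.36))
    truth <- tibble::tibble(contig = "ctg1", pos = c(500L, 1500L),
                            ref = c("A", "T"), alt = c("G", "C"),
                            vclass = "snv", freq = 0.5, at_site = FALSE)
    truth$ref <- substr(genome[["ctg1"]], truth$pos, truth$pos)
    truth$alt <- vapply(truth$ref, function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], character(1))
    sim <- simulate_caller_vcfs(truth, genome, seed = 5, dir = ".")
    rd <- read_caller_vcf(sim$paths[["lofreq"]], "lofreq")
    orig <- sim$calls[sim$calls$caller == "lofreq", ]
    expect_equal(nrow(rd), nrow(orig))
    expect_equal(rd$pos, sort(orig$pos))
    expect_equal(rd$alt_depth,
                 orig$alt_depth[order(orig$pos)])
    expect_equal(rd$total_depth, orig$total_depth[order(orig$pos)])
  })
})

test_that("unknown caller identifiers are rejected when a registry is given", {
  calls <- variant_calls("weird", "c1", 10, "A", "G", 5, 50)
  expect_error(build_consensus(calls, known_callers = c("lofreq")),
               "unknown caller")
})
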