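gr_key <- function(gr) {
  paste(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr), GenomicRanges::end(gr))
}

test_that("interval readers normalize all dialects to one container", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t500\t900", "chr2\t0\t50"), bed)
  g_bed <- read_intervals(bed, "bed")
  expect_length(g_bed, 3)
  expect_equal(GenomicRanges::start(g_bed)[1], 101)  # covers bases 100-199
  expect_equal(GenomicRanges::end(g_bed)[1], 200)
  expect_equal(GenomicRanges::width(g_bed)[1], 100)

  # FASTA headers with 1-based closed loci describe the same intervals
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chr1:101-200", "ACGT", ">chr1:501-900", "ACGT",
               ">chr2:1-50", "ACGT"), fa)
  g_fa <- read_intervals(fa, "hot-fasta-headers")
  expect_identical(gr_key(g_fa), gr_key(g_bed))

  # Arrowhead domain list: both coordinate pairs, deduplicated
  ah <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\tx1\tx2\tchr2\ty1\ty2\tcolor",
               "chr1\t100\t200\tchr1\t100\t200\t0,0,255",
               "chr1\t500\t900\tchr1\t500\t900\t0,0,255",
               "chr2\t0\t50\tchr2\t0\t50\t0,0,255"), ah)
  g_ah <- read_intervals(ah, "arrowhead")
  expect_identical(gr_key(g_ah), gr_key(g_bed))

  # a loop list yields the two anchors of each record
  ah2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\tx1\tx2\tchr2\ty1\ty2",
               "chr1\t1000\t2000\tchr1\t50000\t51000"), ah2)
  g_ah2 <- read_intervals(ah2, "arrowhead")
  expect_length(g_ah2, 2)

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_warning(g0 <- read_intervals(empty, "bed"), "empty")
  expect_length(g0, 0)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t500"), bad)
  expect_error(read_intervals(bad, "bed"), "line 2")
})

test_that("decay estimator is exact on noiseless power-law matrices", {
  for (alpha in c(-1, -1.5)) {
    sh <- synth_hic(n_bins = 60, alpha_background = alpha, seed = 1)
    prof <- contact_decay(sh$bins, flank = 20)
    est <- prof$alpha[!is.na(prof$alpha)]
    expect_equal(est, rep(alpha, length(est)), tolerance = 1e-6)
  }
  # constant matrix: slope 0
  const <- contact_bins(matrix(1, 50, 50), bin_size = 50000)
  prof0 <- contact_decay(const)
  expect_equal(prof0$alpha, rep(0, 50), tolerance = 1e-12)
  # all-zero rows give a missing estimate, not 0
  M <- synth_hic(n_bins = 60, alpha_background = -1, seed = 2)$bins$signal
  M[30, ] <- 0
  M[, 30] <- 0
  profz <- contact_decay(contact_bins(M))
  expect_true(is.na(profz$alpha[30]))
  # too-small matrices are refused
  expect_error(contact_decay(contact_bins(matrix(1, 10, 10))), "flank")
})

test_that("enrichment test matches the exact binomial oracle", {
  # 100 HOTs, loops covering 10% of a toy genome, 10 observed overlaps
  sizes <- c(chrA = 1e6)
  loops <- GenomicRanges::GRanges("chrA",
                                  IRanges::IRanges(1, width = 1e5))
  mids <- c(seq(10000, 95000, length.out = 10),      # inside the loop
            seq(150000, 950000, length.out = 90))    # outside
  hots <- GenomicRanges::GRanges("chrA",
                                 IRanges::IRanges(round(mids), width = 1))
  enr <- hot_loop_enrichment(hots, loops, sizes)
  expect_equal(enr$n_hots, 100)
  expect_equal(enr$n_overlapping, 10)
  expect_equal(enr$n_expected, 10)
  expect_equal(enr$p_value, sum(dbinom(10:100, 100, 0.1)),
               tolerance = 1e-12)

  # all HOTs inside loops
  enr_all <- hot_loop_enrichment(hots[1:10], loops, sizes)
  expect_equal(enr_all$n_overlapping, 10)

  # no loops: zero expected, zero observed
  enr0 <- hot_loop_enrichment(hots, GenomicRanges::GRanges(), sizes)
  expect_equal(enr0$n_expected, 0)
  expect_equal(enr0$n_overlapping, 0)

  expect_error(
    hot_loop_enrichment(
      GenomicRanges::GRanges("chrB", IRanges::IRanges(1, 10)),
      loops, sizes),
    "chrB")
})

test_that("decay comparison at intervals reproduces the Welch test", {
  sh <- synth_hic(n_bins = 120, alpha_background = -1.2,
                  alpha_patches = list(list(from = 50, to = 90,
                                            alpha = -1.5)),
                  noise_sdlog = 0.15, seed = 3)
  prof <- contact_decay(sh$bins)
  # intervals centered inside the low-alpha patch (bins 60-80)
  hots <- GenomicRanges::GRanges(
    "synthetic",
    IRanges::IRanges(start = (c(60, 65, 70, 75, 80) - 1) * 50000 + 10000,
                     width = 1000))
  cmp <- decay_at_intervals(prof, hots)
  expect_lt(cmp$mean_at, cmp$mean_all)  # patch windows flagged lower
  w <- oracle_welch(prof$alpha[!is.na(prof$alpha)],
                    prof$alpha[c(60, 65, 70, 75, 80)])
  expect_equal(cmp$statistic, w$statistic, tolerance = 1e-10)
  expect_equal(cmp$df, w$df, tolerance = 1e-10)

  # identical samples: difference 0, p = 1
  all_hots <- GenomicRanges::GRanges(
    "synthetic",
    IRanges::IRanges(start = (seq_len(120) - 1) * 50000 + 25000, width = 1))
  same <- decay_at_intervals(prof, all_hots)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  expect_error(
    decay_at_intervals(prof, GenomicRanges::GRanges(
      "chrZ", IRanges::IRanges(1, 10))),
    "no decay")
})

test_that("synthetic generators are seed-deterministic", {
  a <- synth_hic(40, alpha_background = -1.1, noise_sdlog = 0.2, seed = 9)
  b <- synth_hic(40, alpha_background = -1.1, noise_sdlog = 0.2, seed = 9)
  expect_identical(a$bins$signal, b$bins$signal)
  c <- synth_hic(40, alpha_background = -1.1, noise_sdlog = 0.2, seed = 10)
  expect_false(identical(a$bins$signal, c$bins$signal))

  sizes <- c(chr1 = 5e7, chr2 = 3e7)
  i1 <- synth_intervals(200, 20, sizes, seed = 5)
  i2 <- synth_intervals(200, 20, sizes, seed = 5)
  expect_identical(gr_key(i1$hots), gr_key(i2$hots))
  expect_identical(gr_key(i1$loops), gr_key(i2$loops))
})

test_that("planted enrichment is detected at the stated strength", {
  sizes <- c(chr1 = 3e8, chr2 = 2e8)
  si <- synth_intervals(n_hots = 1000, n_loops = 100, sizes,
                        enrichment_rho = 4, loop_width = 2e5, seed = 6)
  expect_equal(si$truth$p_null, 100 * 2e5 / 5e8, tolerance = 0.02)
  enr <- hot_loop_enrichment(si$hots, si$loops, sizes)
  # observed ~ rho * expected
  expect_equal(enr$n_overlapping / enr$n_expected, 4, tolerance = 0.25)
  expect_lt(enr$p_value, 1e-9)

  # no loops: every HOT lands outside
  s0 <- synth_intervals(50, 0, sizes, seed = 7)
  expect_equal(s0$truth$realized_overlap, 0)

  expect_error(synth_intervals(10, 100, c(chr1 = 1e6),
                               enrichment_rho = 50, loop_width = 2e5,
                               seed = 8),
               "infeasible")
})

test_that("matrix text formats round-trip through the readers", {
  sh <- synth_hic(30, alpha_background = -1.3, seed = 11)
  dense <- withr::local_tempfile(fileext = ".tsv")
  write.table(sh$bins$signal, dense, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  got <- read_contact_bins(dense, "dense", bin_size = 50000)
  expect_equal(got$signal, sh$bins$signal, tolerance = 1e-12)

  sparse <- withr::local_tempfile(fileext = ".tsv")
  idx <- which(upper.tri(sh$bins$signal, diag = TRUE),
               arr.ind = TRUE)
  write.table(data.frame(i = idx[, 1], j = idx[, 2],
                         value = sh$bins$signal[idx]),
              sparse, sep = "\t", row.names = FALSE, col.names = FALSE)
  got2 <- read_contact_bins(sparse, "sparse", n_bins = 30)
  expect_equal(got2$signal, sh$bins$signal, tolerance = 1e-12)
})
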