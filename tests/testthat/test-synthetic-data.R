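# Replication-kinetics generator: timing and copy-number curves, read
# sampling, and its distributional guarantees.

test_that("timing_curve follows the minimum-arrival kinetic model", {
  ls1 <- landscape("chr1", 1e7,
                   data.frame(position = 5e6, firing_time = 0.2), 1e7)
  expect_equal(timing_curve(ls1, 5e6), 0.2)          # value at the origin
  expect_equal(timing_curve(ls1, 6e6), 0.3)          # 0.2 + 1e6/1e7

  ls2 <- landscape("chr1", 1e7,
                   data.frame(position = c(2e6, 8e6),
                              firing_time = c(0.1, 0.1)), 1e7)
  expect_equal(timing_curve(ls2, 5e6), 0.4)
  # brute-force oracle: pointwise min over both origins on a 1-kb grid
  grid <- seq(0, 1e7 - 1e3, by = 1e3)
  bf <- pmin(pmin(0.1 + abs(grid - 2e6) / 1e7,
                  0.1 + abs(grid - 8e6) / 1e7), 1)
  expect_equal(timing_curve(ls2, grid), bf)
  expect_equal(grid[which.max(bf)], 5e6)             # argmax between origins

  # capping at the end of S phase
  ls3 <- landscape("chr1", 1e7,
                   data.frame(position = 0, firing_time = 0.5), 1e6)
  expect_equal(timing_curve(ls3, 9e6), 1)
})

test_that("landscape and timing_curve validate their inputs", {
  expect_error(landscape("chr1", 1e7,
                         data.frame(position = numeric(0),
                                    firing_time = numeric(0)), 1e7),
               "no origins")
  expect_error(landscape("chr1", 1e7,
                         data.frame(position = c(5e6, 2e6),
                                    firing_time = c(0.1, 0.1)), 1e7),
               "strictly increasing")
  expect_error(landscape("chr1", 1e7,
                         data.frame(position = 5e6, firing_time = 1), 1e7),
               "firing_time")
  expect_error(landscape("chr1", 1e7,
                         data.frame(position = 5e6, firing_time = 0.1), 0),
               "fork_speed")
  ls <- landscape("chr1", 1e7,
                  data.frame(position = 5e6, firing_time = 0.1), 1e7)
  expect_error(timing_curve(ls, 1e7), "within")
})

test_that("copy_number_curve is the affine uniform-S-sampling map", {
  expect_equal(copy_number_curve(0), 2)
  expect_equal(copy_number_curve(1), 1)
  expect_equal(copy_number_curve(0.5), 1.5)
  tau <- seq(0, 1, by = 0.01)
  cc <- copy_number_curve(tau)
  expect_true(all(diff(cc) < 0))                     # strictly decreasing
  expect_true(all(cc >= 1 & cc <= 2))
  expect_error(copy_number_curve(1.01), "\\[0, 1\\]")
  expect_error(copy_number_curve(-0.01), "\\[0, 1\\]")
})

test_that("analytic copy-number maxima sit exactly at origin positions", {
  set.seed(31)
  ls <- benchmark_landscape(L = 2e7, n_origins = 8)
  grid <- seq(0, 2e7 - 500, by = 500)
  cc <- copy_number_curve(timing_curve(ls, grid))
  interior <- 2:(length(cc) - 1)
  peaks <- grid[interior][cc[interior] > cc[interior - 1] &
                            cc[interior] >= cc[interior + 1]]
  for (o in ls$origins$position)
    expect_lte(min(abs(peaks - o)), 500)
})

test_that("G1 sampling is uniform, sorted, seed-reproducible", {
  ls <- landscape("chr1", 1e7,
                  data.frame(position = 5e6, firing_time = 0.3), 1e6)
  cfg <- sim_config(1e6, 1e6, seed = 11)
  g1 <- sample_reads(ls, cfg, "G1")
  expect_equal(nrow(g1), 1e6)
  expect_false(is.unsorted(g1$pos))
  expect_true(all(g1$pos >= 0 & g1$pos < 1e7))
  # per-1-Mb counts within 5 binomial SDs of n*p
  counts <- tabulate(g1$pos %/% 1e6 + 1, 10)
  expect_true(all(abs(counts - 1e5) <= 5 * sqrt(1e6 * 0.1 * 0.9)))
  # determinism under the config seed
  expect_identical(g1, sample_reads(ls, cfg, "G1"))
  # S uses an offset seed: same config, different library
  expect_false(identical(g1$pos, sample_reads(ls, cfg, "S")$pos))
})

test_that("multinomial sampling is invariant to constant weight scaling", {
  # flat tau everywhere (huge fork speed): tau ~ t, so c is constant; a
  # t = 0 world (c = 2) and a t = 0.9 world (c = 1.1) must give identical
  # S draws under the same seed.
  ls_a <- landscape("chr1", 1e6,
                    data.frame(position = 5e5, firing_time = 0), 1e12)
  ls_b <- landscape("chr1", 1e6,
                    data.frame(position = 5e5, firing_time = 0.9), 1e12)
  cfg <- sim_config(5e4, 5e4, seed = 4)
  expect_identical(sample_reads(ls_a, cfg, "S"), sample_reads(ls_b, cfg, "S"))
})

test_that("gaps emit zero reads in both phases", {
  ls <- landscape("chr1", 1e6,
                  data.frame(position = 1e5, firing_time = 0.1), 1e6,
                  gaps = data.frame(start = c(3e5, 7e5), end = c(4e5, 7.5e5)))
  cfg <- sim_config(2e4, 2e4, seed = 9)
  for (ph in c("G1", "S")) {
    r <- sample_reads(ls, cfg, ph)
    expect_equal(nrow(r), 2e4)
    expect_false(any((r$pos >= 3e5 & r$pos < 4e5) |
                       (r$pos >= 7e5 & r$pos < 7.5e5)))
  }
  # fully gapped chromosome cannot be sampled
  ls_all <- landscape("chr1", 1e5,
                      data.frame(position = 1e3, firing_time = 0.1), 1e6,
                      gaps = data.frame(start = 0, end = 1e5))
  expect_error(sample_reads(ls_all, cfg, "G1"), "weights are zero")
})

test_that("uniformity holds across 100 seeds (chi-square, alpha = 0.001)", {
  ls <- landscape("chr1", 1e7,
                  data.frame(position = 5e6, firing_time = 0.3), 1e6)
  set.seed(500)
  crit <- stats::qchisq(0.999, df = 99)
  rejections <- 0L
  for (i in 1:100) {
    g1 <- sample_reads(ls, sim_config(1e5, 1e5), "G1")
    counts <- tabulate(g1$pos %/% 1e5 + 1, 100)
    if (sum((counts - 1e3)^2 / 1e3) > crit) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("empirical S/G1 density ratio converges to c(x)/mean(c)", {
  set.seed(77)
  ls <- benchmark_landscape(L = 1e7, n_origins = 5)
  g1 <- sample_reads_genome(list(chr1 = ls), 1e7, "G1")
  s <- sample_reads_genome(list(chr1 = ls), 1e7, "S")
  w <- 1e5
  cg <- tabulate(g1$pos %/% w + 1, 100)
  cs <- tabulate(s$pos %/% w + 1, 100)
  emp <- (cs / sum(cs)) / (cg / sum(cg))
  grid <- seq(500, 1e7 - 500, by = 1e3)
  cfine <- copy_number_curve(timing_curve(ls, grid))
  expected <- as.numeric(tapply(cfine, grid %/% w, mean)) / mean(cfine)
  expect_lt(max(abs(emp / expected - 1)), 0.02)
})

test_that("shift_firing_times shifts only origins inside the region", {
  ls <- landscape("chr1", 5e6,
                  data.frame(position = c(1e6, 2.5e6, 4e6),
                             firing_time = c(0.3, 0.3, 0.3)), 1e6)
  sh <- shift_firing_times(ls, 2e6, 3e6, -0.1)
  expect_equal(sh$origins$firing_time, c(0.3, 0.2, 0.3))
  # clamped at 0
  sh2 <- shift_firing_times(ls, 0, 5e6, -0.5)
  expect_true(all(sh2$origins$firing_time == 0))
})

test_that("genome-level sampling splits reads and stays sorted per chrom", {
  set.seed(12)
  lss <- small_genome(n_chrom = 3, L = 1e6, origins = 2)
  reads <- sample_reads_genome(lss, 3e4, "S")
  expect_equal(nrow(reads), 3e4)
  for (ch in names(lss))
    expect_false(is.unsorted(reads$pos[reads$chrom == ch]))
  # proportional-ish allocation: equal-length chroms within 10%
  tab <- table(reads$chrom)
  expect_true(all(abs(tab / 1e4 - 1) < 0.1))
})
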