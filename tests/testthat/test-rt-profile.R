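# Segmentation, spline smoothing (csaps convention) and autosome-anchored
# normalization.

test_that("segment_profile splits at center gaps, never across chroms", {
  bins <- data.frame(chrom = "chr1",
                     start = c(1e6, 1.05e6, 1.5e6) - 5e3,
                     end = c(1e6, 1.05e6, 1.5e6) + 5e3)
  expect_equal(segment_profile(bins, 1e5), c(1L, 1L, 2L))
  expect_equal(segment_profile(bins[1, ], 1e5), 1L)
  centers <- seq(5e4, 1e6, by = 5e4)
  one <- data.frame(chrom = "chr1", start = centers - 1, end = centers + 1)
  expect_equal(unique(segment_profile(one, 1e5)), 1L)
  two <- one
  two$chrom <- rep(c("chr1", "chr2"), each = 10)
  expect_equal(unique(segment_profile(two, 1e5)), c(1L, 2L))
})

test_that("smoothing spline hits its analytic limits", {
  set.seed(42)
  x <- sort(runif(10, 0, 1e6))
  y <- rnorm(10)
  # p -> 1: interpolation
  expect_lt(max(abs(smooth_segment(x, y, 1 - 1e-12) - y)), 1e-6)
  # p -> 0: the least-squares straight line
  line <- stats::fitted(stats::lm(y ~ x))
  expect_lt(max(abs(smooth_segment(x, y, 1e-30) - line)), 1e-6)
  # constant input is a fixed point for any p
  for (p in c(1e-16, 0.5, 1 - 1e-6))
    expect_equal(smooth_segment(x, rep(2.5, 10), p), rep(2.5, 10))
})

test_that("smoothing spline agrees with the smooth.spline oracle", {
  # independent oracle: stats::smooth.spline penalizes on the x-range-scaled
  # domain, so the csaps parameter maps to lambda = (1-p)/(p*r^3)
  set.seed(7)
  for (rep in 1:3) {
    n <- sample(30:80, 1)
    x <- sort(runif(n, 0, 1e7))
    y <- sin(x / 5e5) + rnorm(n, 0, 0.3)
    for (p in c(1e-18, 1e-16, 1e-12)) {
      f <- smooth_segment(x, y, p)
      lam <- (1 - p) / (p * diff(range(x))^3)
      g <- stats::predict(stats::smooth.spline(x, y, lambda = lam,
                                               all.knots = TRUE), x)$y
      expect_lt(max(abs(f - g)), 5e-4)
    }
  }
})

test_that("smoothing is linear in y and does not extrapolate wildly", {
  set.seed(8)
  for (rep in 1:10) {
    x <- sort(runif(50, 0, 5e6))
    y <- rnorm(50)
    f1 <- smooth_segment(x, 2 * y + 1, 1e-15)
    f2 <- 2 * smooth_segment(x, y, 1e-15) + 1
    expect_lt(max(abs(f1 - f2)), 1e-8)
    f <- smooth_segment(x, y, 1e-16)
    rng <- max(y) - min(y)
    expect_true(all(f >= min(y) - rng & f <= max(y) + rng))
  }
})

test_that("smooth_segment guards its preconditions", {
  expect_error(smooth_segment(c(1, 2, 2, 3), rnorm(4), 0.5),
               "strictly increasing")
  expect_error(smooth_segment(1:10, rnorm(10), 0), "\\(0, 1\\)")
  expect_error(smooth_segment(1:10, rnorm(10), 1), "\\(0, 1\\)")
  expect_warning(out <- smooth_segment(1:3, c(5, 6, 7), 0.5), "fewer than 4")
  expect_equal(out, c(5, 6, 7))
})

test_that("normalize_rt anchors autosomes at mean 0, SD 1; X rides along", {
  set.seed(9)
  vals <- rnorm(200, mean = 3, sd = 2)
  chrom <- rep(c("chr1", "chr2"), each = 100)
  rt <- normalize_rt(vals, chrom)
  expect_lt(abs(mean(rt)), 1e-9)
  expect_lt(abs(stats::sd(rt) - 1), 1e-9)
  # chrX scaled with autosomal statistics, not recentred
  mu <- mean(vals)
  sigma <- stats::sd(vals)
  chrom2 <- c(chrom, rep("chrX", 5))
  vals2 <- c(vals, rep(mu + sigma, 5))
  rt2 <- normalize_rt(vals2, chrom2)
  expect_equal(as.numeric(rt2[201:205]), rep(1, 5))
  # degenerate inputs
  expect_error(normalize_rt(rep(1, 10), rep("chr1", 10)), "degenerate")
  expect_error(normalize_rt(1:5, rep("chrX", 5)), "autosomal")
})

test_that("rt_profile recovers simulated timing and is deterministic", {
  set.seed(13)
  ls <- benchmark_landscape(L = 1e7, n_origins = 5)
  g1 <- sample_reads_genome(list(chr1 = ls), 2e5, "G1")
  s <- sample_reads_genome(list(chr1 = ls), 2e5, "S")
  prof <- rt_pipeline(g1, s)
  expect_lt(abs(mean(prof$rt)), 1e-9)
  expect_lt(abs(stats::sd(prof$rt) - 1), 1e-9)
  # monotone in true timing: -rt tracks tau
  tau <- timing_curve(ls, prof$center)
  expect_gt(stats::cor(-prof$rt, tau, method = "spearman"), 0.95)
  # smoothing stays within the no-extrapolation band per segment
  for (sg in unique(prof$segment_id)) {
    sel <- prof$segment_id == sg
    if (sum(sel) < 4) next
    rng <- max(prof$raw_ratio[sel]) - min(prof$raw_ratio[sel])
    expect_true(all(prof$smoothed[sel] >= min(prof$raw_ratio[sel]) - rng &
                      prof$smoothed[sel] <= max(prof$raw_ratio[sel]) + rng))
  }
  # byte-identical output for identical input
  p1 <- tempfile(); p2 <- tempfile()
  profile_to_bedgraph(prof, p1)
  profile_to_bedgraph(rt_pipeline(g1, s), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("rt_profile drops chrY and splits segments at gaps", {
  set.seed(14)
  ls <- landscape("chr1", 4e6,
                  data.frame(position = c(1e6, 3e6),
                             firing_time = c(0.1, 0.1)), 1e6,
                  gaps = data.frame(start = 1.8e6, end = 2.4e6))
  g1 <- sample_reads_genome(list(chr1 = ls), 4e4, "G1")
  s <- sample_reads_genome(list(chr1 = ls), 4e4, "S")
  bins <- bin_reads(g1, s)
  # pretend a second chromosome is chrY: it must vanish from the profile
  binsY <- bins
  binsY$chrom <- "chrY"
  both <- rbind(bins, binsY)
  suppressWarnings(expect_message(prof <- rt_profile(both), "chrY"))
  expect_false(any(prof$chrom == "chrY"))
  # the 600-kb read void forces a segment break
  expect_gt(length(unique(prof$segment_id)), 1L)
})

test_that("profile_at finds nearest bins within max_gap only", {
  prof <- fake_profile(c(1, 2, 3), centers = c(1e5, 2e5, 3e5))
  expect_equal(profile_at(prof, rep("chr1", 3), c(1.1e5, 2.6e5, 9e5)),
               c(1, 3, NA))
  expect_equal(profile_at(prof, "chr9", 1e5), NA_real_)
})
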