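test_that("normalization against a uniform control is the identity", {
  g <- binned_genome("chr1", 30000, bin_size = 10000)
  smp <- binned_track(g, c(20, 10, 0))
  ctl <- binned_track(g, c(10, 10, 10))
  expect_equal(mv_values(normalize_to_control(smp, ctl)), c(20, 10, 0))
})

test_that("low-coverage control bins rescale by the unmasked median", {
  g <- binned_genome("chr1", 5e4, bin_size = 10000)
  # control median 10; the 5-count bin stays above the 25% floor
  smp <- binned_track(g, c(20, 10, 10, 10, 10))
  ctl <- binned_track(g, c(5, 10, 10, 10, 10))
  v <- mv_values(normalize_to_control(smp, ctl))
  expect_equal(v[1], 40)   # ratio x2, rescaled by median 10
  # a zero-control bin is masked, not infinite
  ctl0 <- binned_track(g, c(0, 10, 10, 10, 10))
  nv <- normalize_to_control(smp, ctl0)
  expect_true(nv$mask[1])
  expect_true(all(is.finite(mv_values(nv, drop_masked = TRUE))))
})

test_that("normalization is control-scale invariant and sample-linear", {
  g <- toy_genome()
  set.seed(21)
  smp <- binned_track(g, rpois(g$total_bins, 50))
  ctl <- binned_track(g, rpois(g$total_bins, 100))
  base <- mv_values(normalize_to_control(smp, ctl))
  ctl3 <- binned_track(g, ctl$counts * 3)
  expect_equal(mv_values(normalize_to_control(smp, ctl3)), base)
  smp2 <- binned_track(g, smp$counts * 2)
  expect_equal(mv_values(normalize_to_control(smp2, ctl)), base * 2)
})

test_that("normalization enforces its contracts", {
  g <- binned_genome("chr1", 30000, bin_size = 10000)
  g2 <- binned_genome("chr2", 30000, bin_size = 10000)
  smp <- binned_track(g, c(1, 2, 3))
  expect_error(normalize_to_control(smp, binned_track(g2, c(1, 1, 1))),
               "different genomes")
  expect_error(normalize_to_control(smp, binned_track(g, c(0, 0, 0))),
               "no reads")
})

test_that("sigma is the normalized count over sqrt(background lambda)", {
  g <- binned_genome("chr1", 1e6, bin_size = 10000)
  sig <- compute_sigma(masked_vector(rep(100, 100)), g)
  expect_equal(sig$background_mean, 100)
  expect_equal(mv_values(sig$sigma), rep(10, 100))
  expect_equal(background_sigma(sig), 10)

  v <- rep(100, 100); v[7] <- 400
  sig2 <- compute_sigma(masked_vector(v), g)
  expect_equal(sig2$background_mean, 100)  # peak trimmed out of the mean
  expect_equal(mv_values(sig2$sigma)[7], 40)
})

test_that("background estimation refuses tiny unmasked sets", {
  g <- binned_genome("chr1", 1e6, bin_size = 10000)
  mv <- masked_vector(rep(100, 100), c(rep(FALSE, 40), rep(TRUE, 60)))
  expect_error(compute_sigma(mv, g), "fewer than 50")
})

test_that("sigma fluctuations on a Poisson background are unit scale", {
  g <- binned_genome("chr1", 1e8, bin_size = 10000)
  set.seed(100)
  sig <- compute_sigma(masked_vector(rpois(10000, 100)), g)
  expect_equal(sd(mv_values(sig$sigma)), 1.0, tolerance = 0.05)
})

test_that("adjusted sigma subtracts the no-release sample per bin", {
  s1 <- make_sigma_track(c(5, 3), lambda = 100)
  s0 <- make_sigma_track(c(2, 3), lambda = 100)
  a <- adjust_sigma(s1, s0)
  expect_equal(mv_values(a$sigma)[1:2], c(3, 0))
  # identity: adjusting a track against itself is exactly 0
  self <- adjust_sigma(s1, s1)
  expect_true(all(mv_values(self$sigma) == 0))
  # antisymmetry
  b <- adjust_sigma(s0, s1)
  expect_equal(mv_values(a$sigma), -mv_values(b$sigma))
})

test_that("adjusted sigma masks the union of input masks", {
  s1 <- make_sigma_track(c(5, 3, 4), mask = c(TRUE, FALSE, FALSE))
  s0 <- make_sigma_track(c(2, 3, 4), mask = c(FALSE, TRUE, FALSE))
  a <- adjust_sigma(s1, s0)
  expect_identical(a$sigma$mask[1:3], c(TRUE, TRUE, FALSE))
})

test_that("adjusting across conditions warns, across genomes errors", {
  s1 <- make_sigma_track(c(5, 3), condition = "NE")
  s0 <- make_sigma_track(c(2, 3), condition = "OE")
  expect_warning(adjust_sigma(s1, s0), "condition")
  g2 <- binned_genome("other", 1e6, bin_size = 10000)
  s2 <- compute_sigma(masked_vector(rep(100, 100)), g2)
  expect_error(suppressWarnings(adjust_sigma(s1, s2)), "different genomes")
})

test_that("masked-vector arithmetic propagates masks", {
  a <- masked_vector(c(1, 2, 3), c(TRUE, FALSE, FALSE))
  b <- masked_vector(c(4, 5, 6), c(FALSE, TRUE, FALSE))
  s <- a + b
  expect_identical(s$mask, c(TRUE, TRUE, FALSE))
  expect_equal(s$values[3], 9)
})
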