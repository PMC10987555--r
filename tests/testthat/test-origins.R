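test_that("peak calling finds nothing on a flat background", {
  sig <- make_sigma_track(rep(0, 0), n_pad = 300)  # pure background track
  expect_equal(nrow(call_peaks(sig)), 0L)
})

test_that("a rectangular supra-threshold run yields one summit at its max", {
  # 3 bins at background+10 over a flat background (background sigma = 10)
  sig <- make_sigma_track(c(10, 10, 20.2, 20.1, 20.0, 10, 10))
  pk <- call_peaks(sig)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$bin, 3L)                       # argmax bin
  expect_equal(pk$summit, 25000)                 # centre of bin 3
})

test_that("runs are merged across single-bin dropouts but not wider gaps", {
  bg <- 10
  sig <- make_sigma_track(c(20, 20, bg, 20, 20,    # 1-bin gap: merged
                            bg, bg, bg,
                            21, 21))               # separate peak
  pk <- call_peaks(sig)
  expect_equal(nrow(pk), 2L)
  # short runs below min_run are dropped
  sig2 <- make_sigma_track(c(bg, 20, bg))
  expect_equal(nrow(call_peaks(sig2, min_run = 2)), 0L)
})

test_that("efficiency is the summit-neighbourhood maximum, floored at 0", {
  sig <- make_sigma_track(c(9, 12, 7))
  loci <- data.frame(chrom = "chrS", bin = 2L, summit = 15000)
  expect_equal(quantify_efficiency(sig, loci), 12)
  # fully masked neighbourhood reports NA
  sigm <- make_sigma_track(c(9, 12, 7), mask = c(TRUE, TRUE, TRUE))
  expect_true(is.na(quantify_efficiency(sigm, loci)))
  expect_error(quantify_efficiency(sig, data.frame(bin = 10^6)),
               "outside genome")
})

test_that("classification applies the four-fold and two-fold boundaries", {
  expect_equal(as.character(classify_origins(1, 9)), "Oi")         # rho 5
  expect_equal(as.character(classify_origins(4, 4)), "CN")         # rho 1
  expect_equal(as.character(classify_origins(3, 11)), "intermediate") # rho 3
  # exact boundaries are inclusive upwards
  expect_equal(as.character(classify_origins(1, 3)), "intermediate") # rho 2
  expect_equal(as.character(classify_origins(1, 7)), "Oi")           # rho 4
  expect_equal(as.character(classify_origins(0, 0)), "CN")
  expect_error(classify_origins(-1, 2), "non-negative")
})

test_that("classification partitions any efficiency set", {
  set.seed(31)
  ne <- runif(200, 0, 50)
  oe <- ne * sample(c(1, 3, 6), 200, replace = TRUE)
  cl <- classify_origins(ne, oe)
  expect_false(anyNA(cl))
  expect_equal(sum(table(cl)), 200)
  # with pseudocount 0 the rule is exactly scale invariant
  cl0 <- classify_origins(ne, oe, pseudocount = 0)
  cl0s <- classify_origins(ne * 7, oe * 7, pseudocount = 0)
  expect_identical(cl0, cl0s)
})

test_that("correlations are 1 for identical or rescaled tracks", {
  set.seed(32)
  sig <- make_sigma_track(runif(30, 22, 40))
  loci <- data.frame(chrom = "chrS", bin = 1:30, summit = (1:30) * 10000 - 5000)
  cat <- origin_catalog(loci, eff_NE = runif(30, 20, 40),
                        eff_OE = runif(30, 20, 40))
  cs <- correlate_catalogs(cat, sig, sig)
  expect_true(all(abs(cs$pearson_r[cs$n >= 3] - 1) < 1e-12))
  # doubling the track leaves r = 1 (correlation is scale free)
  sig2 <- make_sigma_track(runif(30, 22, 40))
  sig2$sigma <- sig$sigma * 2
  cs2 <- correlate_catalogs(cat, sig, sig2)
  expect_true(all(abs(cs2$pearson_r[cs2$n >= 3] - 1) < 1e-12))
})

test_that("replicate simulations of one truth correlate per class", {
  cfg <- sim_config(seed = 33)
  truth <- sim_truth(cfg)
  ctl <- simulate_control(cfg)
  a <- sigma_from_tracks(simulate_edu_hu(cfg, "NE", replicate = 1)$track, ctl)
  b <- sigma_from_tracks(simulate_edu_hu(cfg, "NE", replicate = 2)$track, ctl)
  cs <- correlate_catalogs(truth_catalog(truth), a, b)
  expect_gte(cs$pearson_r[cs$class == "all"], 0.9)
})

test_that("rank correlation between planted strength and recovered efficiency is high", {
  cfg <- sim_config(seed = 34)
  truth <- sim_truth(cfg)
  ctl <- simulate_control(cfg)
  sig <- sigma_from_tracks(simulate_edu_hu(cfg, "NE")$track, ctl)
  eff <- quantify_efficiency(sig, truth$origins)
  expect_gte(cor(truth$origins$eff_NE, eff, method = "spearman",
                 use = "complete.obs"), 0.9)
})

test_that("origin catalogs round-trip through BED6", {
  g <- toy_genome()
  loci <- data.frame(chrom = c("chrT1", "chrT1", "chrT2"),
                     bin = c(3L, 50L, 101L),
                     summit = c(25000, 495000, 5000))
  cat <- origin_catalog(loci, eff_NE = c(10, 20, 30), eff_OE = c(10, 50, 200))
  path <- withr::local_tempfile(fileext = ".bed")
  write_origins_bed(cat, path)
  cat2 <- read_origins_bed(path, g)
  expect_equal(cat2$bin, cat$bin)
  expect_equal(cat2$eff_NE, cat$eff_NE)
  expect_equal(as.character(cat2$class), as.character(cat$class))
})
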