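test_that("fixed seeds give bit-identical outputs across calls", {
  cfg <- sim_config(seed = 61)
  expect_identical(simulate_control(cfg)$counts, simulate_control(cfg)$counts)
  expect_identical(simulate_edu_hu(cfg, "NE")$track$counts,
                   simulate_edu_hu(cfg, "NE")$track$counts)
  expect_identical(simulate_fibers(cfg, "WT"), simulate_fibers(cfg, "WT"))
  expect_identical(simulate_midas(cfg, "WT")$foci,
                   simulate_midas(cfg, "WT")$foci)
  # different replicates draw different noise from the same truth
  expect_false(identical(simulate_control(cfg, replicate = 2)$counts,
                         simulate_control(cfg)$counts))
  expect_identical(sim_truth(cfg)$origins, sim_truth(cfg)$origins)
})

test_that("control totals obey the configured depth and zero fraction", {
  cfg <- sim_config(seed = 62)
  ctl <- simulate_control(cfg)
  g <- ctl$genome
  expected <- cfg$control_depth_reads_per_bin * g$total_bins *
    (1 - cfg$zero_bin_fraction)
  expect_lt(abs(sum(ctl$counts) - expected) / expected, 0.01)
  # zero-depth config produces empty tracks
  cfg0 <- sim_config(seed = 62, depth_mean_reads_per_bin = 0,
                     control_depth_reads_per_bin = 0)
  expect_true(all(simulate_control(cfg0)$counts == 0))
})

test_that("the control's mappability bias cancels out of normalization", {
  cfg <- sim_config(seed = 63)
  ctl <- simulate_control(cfg, noise = FALSE)
  edu <- simulate_edu_hu(cfg, "NE", noise = FALSE)
  norm <- normalize_to_control(edu$track, ctl)
  # background bins (far from any origin) are exactly flat after division
  near <- unlist(lapply(edu$truth$bin, function(b) (b - 5):(b + 5)))
  bg <- setdiff(which(!norm$mask), near)
  vals <- mv_values(norm)[bg]
  expect_lt(diff(range(vals)), 1e-9)
})

test_that("planted classes are recovered exactly from noise-free tracks", {
  cfg <- sim_config(seed = 64)
  truth <- sim_truth(cfg)
  ctl <- simulate_control(cfg, noise = FALSE)
  sne <- sigma_from_tracks(simulate_edu_hu(cfg, "NE", noise = FALSE)$track, ctl)
  soe <- sigma_from_tracks(simulate_edu_hu(cfg, "OE", noise = FALSE)$track, ctl)
  cl <- classify_origins(quantify_efficiency(sne, truth$origins),
                         quantify_efficiency(soe, truth$origins))
  expect_identical(as.character(cl), as.character(truth$origins$class))
})

test_that("an oncogene-induced origin's OE/NE normalized ratio equals its fold", {
  cfg <- sim_config(seed = 65)
  truth <- sim_truth(cfg)
  ctl <- simulate_control(cfg, noise = FALSE)
  ne <- normalize_to_control(simulate_edu_hu(cfg, "NE", noise = FALSE)$track, ctl)
  oe <- normalize_to_control(simulate_edu_hu(cfg, "OE", noise = FALSE)$track, ctl)
  oi <- truth$origins[truth$origins$class == "Oi", ][1, ]
  ratio <- mv_values(oe)[oi$bin] / mv_values(ne)[oi$bin]
  expect_equal(ratio, 6, tolerance = 1e-6)
})

test_that("the 0-min release sample is the HU-arrest track", {
  cfg <- sim_config(seed = 66)
  rel <- simulate_release(cfg, c(0, 30))
  hu <- simulate_edu_hu(cfg, "NE")$track
  expect_identical(rel$tracks$t0$counts, hu$counts)
})

test_that("dNTP coupling raises the effective speed when fewer origins fire", {
  cfg <- sim_config(seed = 67, fired_fraction = c(WT = 1, KO = 0.6),
                    dntp_coupling = 0.5)
  wt <- simulate_release(cfg, 30, genotype = "WT")
  ko <- simulate_release(cfg, 30, genotype = "KO")
  expect_equal(length(ko$fired), 30)
  expect_equal(wt$speed_kb_min, 1.0)
  expect_equal(ko$speed_kb_min, 1.0 * (30 / 50)^-0.5)
})

test_that("release rings spread outward at the configured speed", {
  cfg <- sim_config(seed = 68, n_origins = 2)  # isolated origins
  truth <- sim_truth(cfg)
  rel <- simulate_release(cfg, c(30, 90), noise = FALSE)
  # signal at t=90 sits beyond the t=30 ring: compare occupied offsets
  o <- truth$origins[1, ]
  off <- function(tr) {
    ci <- which(truth$genome$chrom == o$chrom)
    w <- (o$bin - 20):(o$bin + 20)
    w <- w[w >= truth$genome$offset[ci] + 1]
    sig <- tr$counts[w] / truth$bias[w] - cfg$depth_mean_reads_per_bin
    (w - o$bin)[sig > 1]
  }
  expect_lt(max(abs(off(rel$tracks$t30))), max(abs(off(rel$tracks$t90))))
})

test_that("fiber draws are positive and reproducible", {
  cfg <- sim_config(seed = 69, fiber_rate_sd = 0)
  fb <- simulate_fibers(cfg, "WT")
  # zero rate spread: lengths differ only by measurement noise
  expect_lt(sd(fb$idu_um), 3 * cfg$fiber_noise_um)
  expect_equal(mean(fb$idu_um),
               1.2 * cfg$idu_duration_min / cfg$kb_per_um,
               tolerance = 0.05)
})

test_that("zero MiDAS signal leaves a background-only track", {
  cfg <- sim_config(seed = 70, midas_signal_sigma = 0)
  md <- simulate_midas(cfg, "WT", noise = FALSE)
  truth <- sim_truth(cfg)
  unmasked <- truth$bias > 0
  norm <- md$track$counts[unmasked] / truth$bias[unmasked]
  expect_lt(diff(range(norm)), 1e-9)
})
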