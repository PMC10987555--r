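test_that("metagene of a delta peak is the peak at offset zero", {
  vals <- rep(10, 61); vals[31] <- 20   # one elevated bin on sigma scale
  sig <- make_sigma_track(vals, lambda = 100)
  loci <- data.frame(chrom = "chrS", bin = 31L, summit = 305000)
  prof <- metagene(sig, loci, half_window_bp = 100000)
  expect_equal(prof$mean_asigma[prof$offset == 0], 20)
  expect_true(all(prof$mean_asigma[prof$offset != 0] == 10))

  # averaging two origins with identical surroundings changes nothing
  vals2 <- rep(10, 121); vals2[c(31, 91)] <- 20
  sig2 <- make_sigma_track(vals2, lambda = 100)
  loci2 <- data.frame(chrom = "chrS", bin = c(31L, 91L))
  prof2 <- metagene(sig2, loci2, half_window_bp = 100000)
  expect_equal(prof2$mean_asigma, prof$mean_asigma)
})

test_that("metagene equals the brute-force loop exactly", {
  cfg <- sim_config(seed = 41)
  truth <- sim_truth(cfg)
  ctl <- simulate_control(cfg)
  sig <- sigma_from_tracks(simulate_edu_hu(cfg, "NE")$track, ctl)
  prof <- metagene(sig, truth$origins, half_window_bp = 150000)
  brute <- brute_metagene(sig, truth$origins, 150000)
  expect_equal(prof$offset, brute$offsets)
  expect_equal(prof$mean_asigma, brute$mean)
  expect_equal(prof$n, brute$n)
})

test_that("metagene requires loci and windows respect chromosome ends", {
  sig <- make_sigma_track(rep(10, 20))
  expect_error(metagene(sig, data.frame(chrom = character(), bin = integer())),
               "empty locus list")
  loci <- data.frame(chrom = "chrS", bin = 1L)  # window clipped on the left
  prof <- metagene(sig, loci, half_window_bp = 50000)
  expect_true(all(prof$n[prof$offset < 0] == 0))
  expect_true(all(prof$n[prof$offset >= 0] == 1))
})

test_that("halfwidth recovers simple geometric shapes", {
  sig <- make_sigma_track(rep(10, 61))
  loci <- data.frame(chrom = "chrS", bin = 31L)
  # rectangle of width 100 kb (10 bins): FWHM within one bin of 100 kb
  vals <- rep(0, 61); vals[27:36] <- 10
  sigr <- make_sigma_track(vals)
  profr <- metagene(sigr, loci, half_window_bp = 300000)
  expect_lt(abs(profile_halfwidth(profr) - 100000), 10000)
  # triangle: peak 10 at 0, linear to 0 at +-100 kb: FWHM = 100 kb
  tri <- pmax(0, 10 * (1 - abs(-30:30) / 10))
  sigt <- make_sigma_track(tri)
  proft <- metagene(sigt, loci, half_window_bp = 300000)
  expect_equal(profile_halfwidth(proft), 100000)
  # non-positive profiles are rejected
  sigz <- make_sigma_track(rep(0, 61))
  profz <- metagene(sigz, loci, half_window_bp = 100000)
  expect_error(profile_halfwidth(profz), "not positive")
})

test_that("progression rate is the half-width growth over time", {
  mk <- function(fwhm_bp, t) {
    # triangular profile with the requested FWHM, carrying a timepoint
    halfmax_off <- fwhm_bp / 2
    vals <- pmax(0, 10 * (1 - abs(-30:30) * 10000 / (2 * halfmax_off)))
    prof <- metagene(make_sigma_track(vals),
                     data.frame(chrom = "chrS", bin = 31L),
                     half_window_bp = 300000)
    attr(prof, "timepoint_min") <- t
    prof
  }
  p30 <- mk(60000, 30); p90 <- mk(180000, 90)
  est <- estimate_progression(list(p90, p30), n_boot = 0)
  expect_equal(est$rate_kb_min, 1.0, tolerance = 1e-6)
  # identical profiles: rate 0
  est0 <- estimate_progression(list(mk(60000, 30), mk(60000, 90)), n_boot = 0)
  expect_equal(est0$rate_kb_min, 0)
  expect_error(estimate_progression(list(p30)), ">= 2 timepoints")
})

test_that("fiber rates follow length x stretch / duration", {
  fb <- fiber_set(data.frame(sample = "WT", condition = "NE",
                             cldu_um = 10, idu_um = 10),
                  idu_duration_min = 40)
  expect_equal(fiber_rates(fb, kb_per_um = 2)$rate_kb_min, 0.5)
  expect_error(fiber_set(data.frame(sample = "WT", condition = "NE",
                                    cldu_um = 0, idu_um = 1)),
               "positive")
})

test_that("simulated fiber rates recover the planted mean", {
  cfg <- sim_config(seed = 43)
  fb <- simulate_fibers(cfg, "WT")
  expect_true(all(fb$cldu_um > 0 & fb$idu_um > 0))
  rates <- fiber_rates(fb, kb_per_um = cfg$kb_per_um)
  expect_lt(abs(mean(rates$rate_kb_min) - 1.2), 0.05)
})

test_that("fiber group comparison: self-contrast is null, big shifts are ****", {
  set.seed(44)
  x <- rnorm(50, 1.2, 0.2)
  df <- data.frame(rate_kb_min = c(x, x, x + 3 * 0.2),
                   genotype = rep(c("A", "B", "C"), each = 50),
                   condition = "NE")
  rep_ <- compare_fiber_groups(df)
  ab <- rep_$contrasts[rep_$contrasts$group1 == "A:NE" &
                         rep_$contrasts$group2 == "B:NE", ]
  expect_equal(ab$p, 1)            # identical groups differ by exactly 0
  ac <- rep_$contrasts[rep_$contrasts$group2 == "C:NE" &
                         rep_$contrasts$group1 == "A:NE", ]
  expect_lt(ac$p, 1e-4)
  expect_equal(ac$tier, "****")
})

test_that("a two-way design reports main effects, interaction and LSD tiers", {
  set.seed(45)
  df <- expand.grid(genotype = c("WT", "KO"), condition = c("NE", "OE"),
                    rep = 1:20)
  df$rate_kb_min <- rnorm(nrow(df), 1.2, 0.2) +
    ifelse(df$condition == "OE", -0.3, 0)
  out <- compare_fiber_groups(df)
  expect_setequal(rownames(out$anova)[1:3],
                  c("genotype", "condition", "genotype:condition"))
  expect_equal(nrow(out$contrasts), choose(4, 2))
  expect_true(all(out$contrasts$tier %in% c("ns", "*", "**", "***", "****")))
})

test_that("IdU/CldU ratios summarize per group with type-7 quantiles", {
  fb <- fiber_set(data.frame(sample = rep("WT", 4), condition = "NE",
                             cldu_um = c(8, 4, 2, 5), idu_um = c(4, 4, 2, 10)))
  out <- cldu_idu_ratio(fb)
  expect_equal(sort(out$per_fiber$ratio), c(0.5, 1, 1, 2))
  expect_equal(out$summary$median, 1)
  expect_equal(out$summary$q25, unname(quantile(c(0.5, 1, 1, 2), 0.25)))
  expect_equal(out$n_excluded, 0)
})
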