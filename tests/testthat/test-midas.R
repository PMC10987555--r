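test_that("MiDAS positivity counts cells at or above the foci threshold", {
  foci <- data.frame(genotype = "WT", n_edu_foci = c(0, 1, 2, 3))
  expect_equal(score_midas_positive(foci)$fraction, 0.5)
  zeros <- data.frame(genotype = "WT", n_edu_foci = rep(0, 5))
  expect_equal(score_midas_positive(zeros)$fraction, 0)
  expect_error(score_midas_positive(data.frame(genotype = character(),
                                               n_edu_foci = integer())),
               "empty group")
  expect_error(score_midas_positive(data.frame(genotype = "WT",
                                               n_edu_foci = 1.5)),
               "integer")
})

test_that("positivity is monotone non-increasing in the threshold", {
  set.seed(51)
  foci <- data.frame(genotype = rep(c("WT", "KO"), each = 100),
                     n_edu_foci = rpois(200, 1.3))
  fr <- vapply(0:5, function(k)
    mean(score_midas_positive(foci, min_foci = k)$fraction), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("simulated foci fractions match the Poisson tail probability", {
  cfg <- sim_config(seed = 52, foci_n_cells = 1000,
                    foci_lambda = c(WT = 2.15))  # P(X >= 2) approx 0.635
  md <- simulate_midas(cfg, "WT")
  fr <- score_midas_positive(md$foci)$fraction
  p_true <- 1 - ppois(1, 2.15)
  expect_lt(abs(fr - p_true), 3 * sqrt(p_true * (1 - p_true) / 1000))
})

test_that("53BP1-body fractions use their own threshold and closed form", {
  cells <- data.frame(genotype = "WT", n_bodies = c(0, 0, 1, 2))
  expect_equal(fraction_53bp1(cells)$fraction, 0.5)
  expect_equal(fraction_53bp1(cells, min_bodies = 5)$fraction, 0)
  set.seed(53)
  sim <- data.frame(genotype = "WT", n_bodies = rpois(500, 0.5))
  fr <- fraction_53bp1(sim)$fraction
  p_true <- 1 - exp(-0.5)
  expect_lt(abs(fr - p_true), 3 * sqrt(p_true * (1 - p_true) / 500))
})

test_that("region profiles recover flat and duplicated regions", {
  vals <- rep(10, 100)
  sig <- make_sigma_track(vals, lambda = 100)
  regions <- midas_regions(data.frame(
    chrom = "chrS", start = c(200000, 600000), end = c(300000, 700000),
    peak_type = "single"))
  prof <- region_profiles(sig, regions)
  # uniform track: profile constant at the sigma level over span and flanks
  expect_true(all(abs(prof$average - 10) < 1e-9))
  expect_equal(prof$matrix[1, ], prof$matrix[2, ], ignore_attr = TRUE)
})

test_that("heatmap rows are ordered by size (double) then sigma (single)", {
  cfg <- sim_config(seed = 54)
  md <- simulate_midas(cfg, "WT", noise = FALSE)
  ctl <- simulate_control(cfg, noise = FALSE)
  sig <- sigma_from_tracks(md$track, ctl)
  prof <- region_profiles(sig, md$regions)
  expect_setequal(prof$order, md$regions$region_id)
  # independent sort oracle
  dbl <- md$regions[md$regions$peak_type == "double", ]
  expected_dbl <- dbl$region_id[order(-dbl$size, dbl$chrom, dbl$start)]
  expect_identical(prof$order[seq_len(nrow(dbl))], expected_dbl)
  stats <- prof$region_stats
  sgl_stats <- stats[stats$peak_type == "single", ]
  expected_sgl <- sgl_stats$region_id[order(-sgl_stats$max_sigma)]
  expect_identical(prof$order[-seq_len(nrow(dbl))], expected_sgl)
})

test_that("double-peak regions show two maxima in the average profile", {
  cfg <- sim_config(seed = 55)
  md <- simulate_midas(cfg, "WT", noise = FALSE)
  ctl <- simulate_control(cfg, noise = FALSE)
  sig <- sigma_from_tracks(md$track, ctl)
  dbl <- midas_regions(md$regions[md$regions$peak_type == "double", ])
  prof <- region_profiles(sig, dbl)
  avg <- prof$average
  n <- length(avg)
  left <- avg[seq_len(floor(n / 2))]
  right <- avg[(floor(n / 2) + 1):n]
  mid <- avg[(floor(n * 0.45)):(ceiling(n * 0.55))]
  expect_gt(max(left), max(mid) + 1)
  expect_gt(max(right), max(mid) + 1)
})

test_that("fraction comparison needs replicates and finds planted shifts", {
  base <- expand.grid(genotype = c("WT", "KO"), treatment = c("NE", "OE"),
                      rep = 1:3)
  base$fraction <- 0.3
  out <- suppressWarnings(compare_fractions(base))  # zero-variance fit
  expect_true(all(out$tukey$p_adj > 0.999))
  expect_error(compare_fractions(base[base$rep == 1, ]), "replicate")
  set.seed(56)
  shifted <- base
  shifted$fraction <- rnorm(nrow(shifted), 0.3, 0.01) +
    ifelse(shifted$genotype == "KO", 0.05 * 5, 0)
  out2 <- compare_fractions(shifted)
  ko_wt <- out2$tukey[grepl("KO:NE", out2$tukey$contrast) &
                        grepl("WT:NE", out2$tukey$contrast), ]
  expect_lt(ko_wt$p_adj, 0.001)
})
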