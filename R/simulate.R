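#' Simulation configuration with known ground truth
#'
#' Bundles every parameter of the synthetic-data generator. Defaults describe
#' a desk-scale experiment: a 2-chromosome, 10 Mb genome of 10 kb bins with 50
#' origins whose firing efficiencies (on the sigma scale) are planted together
#' with their class fold-changes (constitutive 1x, intermediate 3x,
#' oncogene-induced 6x), a genomic-DNA control with lognormal bin-to-bin
#' mappability bias shared by every EdU track, negative-binomial count noise,
#' hydroxyurea-release fork rings at a configurable speed, DNA-fiber rate
#' distributions, and MiDAS region signal plus EdU-foci counts.
#'
#' @param seed Integer master seed; every generator derives its own stream
#'   from it, so a fixed config reproduces bit-identical outputs.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width (bp).
#' @param n_origins Total planted origins.
#' @param min_spacing_bp Minimum inter-origin distance.
#' @param eff_ne_range Range of planted NE firing efficiencies, in raw sigma
#'   units (must exceed the background level `sqrt(depth)`; the default depth
#'   400 puts the background at sigma 20, so 25-60 plants peaks 5-40 sigma
#'   above background).
#' @param oi_fraction,intermediate_fraction Class mix (the remainder is
#'   constitutive); defaults one sixth each.
#' @param fold_cn,fold_intermediate,fold_oi Planted OE/NE fold-changes per
#'   class.
#' @param hu_travel_bp Fork travel under HU arrest: half-width of the
#'   rectangular origin peak.
#' @param fork_speed_kb_min Named per-genotype base fork speed.
#' @param fired_fraction Named per-genotype fraction of origins that fire in
#'   release timecourses.
#' @param dntp_coupling Exponent coupling effective speed to the fired-origin
#'   count: `v = base * (n_fired / n_origins)^-coupling` (0 disables; positive
#'   values emulate dNTP-limited fork progression).
#' @param label_window_min EdU labelling window before each harvest (min).
#' @param release_signal_mass Total EdU signal per release sample in
#'   normalized-count units, split over fired origins (emulates a fixed
#'   sequencing budget: fewer fired origins concentrate more signal each).
#' @param depth_mean_reads_per_bin EdU background depth per bin.
#' @param control_depth_reads_per_bin Genomic-DNA control depth per bin
#'   (controls are sequenced deep so the quotient adds little noise).
#' @param dispersion Negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson.
#' @param zero_bin_fraction Fraction of unmappable bins (control count 0).
#' @param mappability_sd Lognormal sd of the per-bin mappability bias.
#' @param fiber_n,fiber_rate_mean,fiber_rate_sd,cldu_duration_min,idu_duration_min,kb_per_um,fiber_noise_um
#'   DNA-fiber generator: fibers per sample, per-genotype truncated-normal
#'   rate distribution (kb/min), labelling durations, stretching factor and
#'   length measurement noise (um).
#' @param midas_n_regions,midas_size_range,midas_signal_sigma,midas_edge_fraction
#'   MiDAS region generator: number of regions, size range (bp), signal
#'   height (sigma units above background), and edge-strip fraction of the
#'   span carrying the signal (double-peak regions at both edges, single-peak
#'   centred).
#' @param foci_lambda,foci_n_cells Per-genotype Poisson mean of EdU foci per
#'   mitotic cell, and cells scored per genotype.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(simA = 5e6, simB = 5e6),
                       bin_size = 10000,
                       n_origins = 50,
                       min_spacing_bp = 100000,
                       eff_ne_range = c(25, 60),
                       oi_fraction = 1 / 6,
                       intermediate_fraction = 1 / 6,
                       fold_cn = 1, fold_intermediate = 3, fold_oi = 6,
                       hu_travel_bp = 30000,
                       fork_speed_kb_min = c(WT = 1.0, KO = 1.0),
                       fired_fraction = c(WT = 1.0, KO = 1.0),
                       dntp_coupling = 0,
                       label_window_min = 30,
                       release_signal_mass = 60000,
                       depth_mean_reads_per_bin = 400,
                       control_depth_reads_per_bin = 1200,
                       dispersion = 0.002,
                       zero_bin_fraction = 0.02,
                       mappability_sd = 0.15,
                       fiber_n = 200,
                       fiber_rate_mean = c(WT = 1.2, KO = 1.2),
                       fiber_rate_sd = 0.3,
                       cldu_duration_min = 40,
                       idu_duration_min = 40,
                       kb_per_um = 2.0,
                       fiber_noise_um = 0.2,
                       midas_n_regions = 20,
                       midas_size_range = c(50000, 200000),
                       midas_signal_sigma = 8,
                       midas_edge_fraction = 0.2,
                       foci_lambda = c(WT = 1.0, KO = 1.0),
                       foci_n_cells = 300) {
  cfg <- as.list(environment())
  if (cfg$oi_fraction < 0 || cfg$intermediate_fraction < 0 ||
      cfg$oi_fraction + cfg$intermediate_fraction > 1)
    stop("class fractions must be in [0, 1] and sum to <= 1")
  if (cfg$depth_mean_reads_per_bin < 0 ||
      cfg$control_depth_reads_per_bin < 0)
    stop("depths must be non-negative")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (any(cfg$eff_ne_range <= sqrt(cfg$depth_mean_reads_per_bin)) &&
      cfg$depth_mean_reads_per_bin > 0)
    stop("eff_ne_range must exceed the background sigma level sqrt(depth)")
  structure(cfg, class = "sim_config")
}

# independent, reproducible RNG stream per generator: hash the key into the
# master seed, staying inside 32-bit integer range
.sub_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 48271 + h * 1299709) %% 2147483563) + 1L
}

.rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# add `height * overlap_fraction` to the bins overlapping [from, to) bp
.add_interval <- function(vec, genome, chrom, from, to, height) {
  if (to <= from) return(vec)
  ci <- match(chrom, genome$chrom)
  from <- max(0, from); to <- min(genome$length[ci], to)
  if (to <= from) return(vec)
  bs <- genome$bin_size
  b1 <- as.integer(from %/% bs)
  b2 <- as.integer((to - 1e-9) %/% bs)
  for (b in b1:b2) {
    lo <- b * bs; hi <- min((b + 1) * bs, genome$length[ci])
    frac <- (min(to, hi) - max(from, lo)) / bs
    g <- genome$offset[ci] + b + 1L
    vec[g] <- vec[g] + height * frac
  }
  vec
}

#' Ground truth shared by all generators
#'
#' Deterministically derives, from the config seed alone, the per-bin
#' mappability bias, the unmappable-bin set, the origin catalog (positions,
#' classes, planted NE efficiencies and OE fold-changes) and the MiDAS region
#' set. Every `simulate_*` function rebuilds the same truth, so tracks from
#' separate calls are mutually consistent.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([binned_genome()]), `bias` (per-bin factor, 0
#'   at unmappable bins), `origins` (data.frame: `chrom`, `pos`, `bin`,
#'   `summit`, `class`, `fold`, `eff_NE`, `eff_OE`) and `midas_regions`
#'   (a [midas_regions()] set).
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- binned_genome(names(config$chrom_lengths), config$chrom_lengths,
                          config$bin_size)
  set.seed(.sub_seed(config$seed, "truth"))
  nb <- genome$total_bins
  bias <- stats::rlnorm(nb, meanlog = -config$mappability_sd^2 / 2,
                        sdlog = config$mappability_sd)
  zero <- sample.int(nb, round(config$zero_bin_fraction * nb))
  bias[zero] <- 0
  # origins: allocate per chromosome proportionally, place with a minimum
  # spacing by the spaced-uniform construction
  n <- config$n_origins
  alloc <- floor(n * genome$length / sum(genome$length))
  rem <- n - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  s <- config$min_spacing_bp
  pos_list <- lapply(seq_along(genome$chrom), function(ci) {
    k <- alloc[ci]
    if (k == 0) return(numeric(0))
    L <- genome$length[ci]
    if (k * s >= L) stop("origins do not fit at the requested spacing")
    u <- sort(stats::runif(k, 0, L - k * s))
    u + s * (seq_len(k) - 1) + s / 2
  })
  chrom <- rep(genome$chrom, lengths(pos_list))
  pos <- unlist(pos_list)
  n_oi <- round(n * config$oi_fraction)
  n_int <- round(n * config$intermediate_fraction)
  cls <- sample(c(rep("Oi", n_oi), rep("intermediate", n_int),
                  rep("CN", n - n_oi - n_int)))
  fold <- c(CN = config$fold_cn, intermediate = config$fold_intermediate,
            Oi = config$fold_oi)[cls]
  eff_ne <- stats::runif(n, config$eff_ne_range[1], config$eff_ne_range[2])
  bins <- bin_index(genome, chrom, pos)
  loc <- bin_location(genome, bins)
  origins <- data.frame(
    chrom = chrom, pos = pos, bin = bins,
    summit = (loc$start + loc$end) / 2,
    class = factor(cls, levels = c("CN", "intermediate", "Oi")),
    fold = unname(fold), eff_NE = eff_ne, eff_OE = unname(fold) * eff_ne,
    stringsAsFactors = FALSE)
  origins <- origins[order(origins$bin), , drop = FALSE]
  rownames(origins) <- NULL
  # MiDAS regions: one per equal-width slot so spans plus flanks never overlap
  nr <- config$midas_n_regions
  r_alloc <- floor(nr * genome$length / sum(genome$length))
  r_rem <- nr - sum(r_alloc)
  if (r_rem > 0) r_alloc[seq_len(r_rem)] <- r_alloc[seq_len(r_rem)] + 1
  reg <- list()
  for (ci in seq_along(genome$chrom)) {
    k <- r_alloc[ci]
    if (k == 0) next
    W <- genome$length[ci] / k
    for (j in seq_len(k)) {
      size <- stats::runif(1, config$midas_size_range[1],
                           config$midas_size_range[2])
      lo <- (j - 1) * W + size
      hi <- j * W - 2 * size
      start <- if (hi > lo) stats::runif(1, lo, hi)
               else (j - 0.5) * W - size / 2   # centre large regions in slot
      reg[[length(reg) + 1L]] <- data.frame(
        chrom = genome$chrom[ci], start = round(start),
        end = round(start + size), stringsAsFactors = FALSE)
    }
  }
  reg <- do.call(rbind, reg)
  reg$peak_type <- sample(rep(c("double", "single"), length.out = nrow(reg)))
  list(genome = genome, bias = bias, origins = origins,
       midas_regions = midas_regions(reg))
}

#' Planted origin truth as an origin catalog
#' @param truth Output of [sim_truth()].
#' @return An [origin_catalog()] carrying the planted efficiencies and classes.
#' @export
truth_catalog <- function(truth) {
  origin_catalog(truth$origins, truth$origins$eff_NE, truth$origins$eff_OE,
                 class_label = truth$origins$class)
}

#' Simulate the genomic-DNA control track
#'
#' Per-bin counts are negative-binomial around `control_depth x mappability
#' bias`; unmappable bins are 0. The bias field is shared with every EdU track
#' of the same config, so [normalize_to_control()] removes it.
#'
#' @param config A [sim_config()].
#' @param replicate Integer; changes the noise stream only.
#' @param noise If `FALSE`, return expected counts (no sampling).
#' @return A [binned_track()].
#' @export
simulate_control <- function(config, replicate = 1, noise = TRUE) {
  truth <- sim_truth(config)
  mu <- config$control_depth_reads_per_bin * truth$bias
  set.seed(.sub_seed(config$seed, paste0("control", replicate)))
  counts <- if (noise) .rcounts(length(mu), mu, config$dispersion) else mu
  binned_track(truth$genome, counts, label = "gDNA_control")
}

#' Simulate an HU-arrested early-S EdU track
#'
#' Background reads everywhere plus, around each origin summit, a rectangular
#' block of EdU signal of half-width `hu_travel_bp` whose height is chosen so
#' that the origin's sigma value reproduces its planted efficiency (NE) or
#' planted efficiency times its class fold-change (OE). All tracks share the
#' control's mappability bias.
#'
#' @param config A [sim_config()].
#' @param condition `"NE"` or `"OE"`.
#' @param genotype Label carried into the track's noise stream and metadata
#'   (the planted truth is genotype-independent: the null regime).
#' @param replicate Integer; changes the noise stream only.
#' @param noise If `FALSE`, return expected counts.
#' @return List with `track` (a [binned_track()]) and `truth` (the planted
#'   origin table, see [sim_truth()]).
#' @export
simulate_edu_hu <- function(config, condition = c("NE", "OE"),
                            genotype = "WT", replicate = 1, noise = TRUE) {
  condition <- match.arg(condition)
  truth <- sim_truth(config)
  genome <- truth$genome
  depth <- config$depth_mean_reads_per_bin
  eff <- if (condition == "NE") truth$origins$eff_NE else truth$origins$eff_OE
  norm <- rep(depth, genome$total_bins)
  for (i in seq_len(nrow(truth$origins))) {
    excess <- eff[i] * sqrt(depth) - depth   # normalized-count excess
    if (excess <= 0) next
    norm <- .add_interval(norm, genome, truth$origins$chrom[i],
                          truth$origins$pos[i] - config$hu_travel_bp,
                          truth$origins$pos[i] + config$hu_travel_bp,
                          excess)
  }
  mu <- norm * truth$bias
  set.seed(.sub_seed(config$seed,
                     paste0("edu_hu", condition, genotype, replicate)))
  counts <- if (noise) .rcounts(length(mu), mu, config$dispersion) else mu
  track <- binned_track(genome, counts,
                        label = paste0(genotype, "_", condition, "_HU"),
                        condition = condition, timepoint_min = 0)
  list(track = track, truth = truth$origins)
}

#' Simulate an HU-release timecourse
#'
#' At release timepoint `t`, forks resume from the HU-arrest boundary
#' (`hu_travel_bp` from the summit) and the EdU pulse covering the last
#' `label_window_min` minutes before harvest labels the interval
#' `hu_travel + v*(t - w) .. hu_travel + v*t` on each side of every fired
#' origin, where `v` is the genotype's effective speed after dNTP coupling to
#' the fired-origin count. The 0-min sample is the HU-arrest track itself.
#' Each sample's total EdU signal is fixed (`release_signal_mass`) and split
#' over fired origins, emulating a fixed sequencing budget.
#'
#' @param config A [sim_config()].
#' @param timepoints_min Numeric vector of release timepoints (minutes).
#' @param genotype Genotype label: selects `fork_speed_kb_min` and
#'   `fired_fraction` entries.
#' @param condition `"NE"` or `"OE"` (metadata and noise stream only).
#' @param replicate Integer; changes the noise stream only.
#' @param noise If `FALSE`, return expected counts.
#' @return List with `tracks` (named list of [binned_track()], one per
#'   timepoint), `truth` (origin table), `fired` (indices of fired origins)
#'   and `speed_kb_min` (the effective speed).
#' @export
simulate_release <- function(config, timepoints_min = c(0, 30, 90),
                             genotype = "WT", condition = "NE",
                             replicate = 1, noise = TRUE) {
  truth <- sim_truth(config)
  genome <- truth$genome
  depth <- config$depth_mean_reads_per_bin
  frac <- config$fired_fraction[[genotype]]
  if (is.null(frac)) stop("no fired_fraction entry for genotype ", genotype)
  n <- nrow(truth$origins)
  n_fired <- max(1L, round(frac * n))
  set.seed(.sub_seed(config$seed, paste0("fired", genotype)))
  fired <- sort(sample.int(n, n_fired))
  v_kb <- config$fork_speed_kb_min[[genotype]] *
    (n_fired / n)^(-config$dntp_coupling)
  v_bp <- v_kb * 1000
  w <- config$label_window_min
  tracks <- list()
  for (t in timepoints_min) {
    if (t == 0) {
      tr <- simulate_edu_hu(config, condition = condition,
                            genotype = genotype, replicate = replicate,
                            noise = noise)$track
      tr$timepoint_min <- 0
      tr$label <- paste0(genotype, "_", condition, "_t0")
      tracks[[paste0("t", t)]] <- tr
      next
    }
    inner <- config$hu_travel_bp + v_bp * max(t - w, 0)
    outer <- config$hu_travel_bp + v_bp * t
    ring_bp <- 2 * (outer - inner)
    mass <- config$release_signal_mass / n_fired   # normalized units/origin
    height <- mass / ring_bp * genome$bin_size     # per fully covered bin
    norm <- rep(depth, genome$total_bins)
    for (i in fired) {
      p <- truth$origins$pos[i]
      ch <- truth$origins$chrom[i]
      norm <- .add_interval(norm, genome, ch, p - outer, p - inner, height)
      norm <- .add_interval(norm, genome, ch, p + inner, p + outer, height)
    }
    mu <- norm * truth$bias
    set.seed(.sub_seed(config$seed, paste0("release", genotype, condition,
                                           t, replicate)))
    counts <- if (noise) .rcounts(length(mu), mu, config$dispersion) else mu
    tracks[[paste0("t", t)]] <- binned_track(
      genome, counts, label = sprintf("%s_%s_t%g", genotype, condition, t),
      condition = condition, timepoint_min = t)
  }
  list(tracks = tracks, truth = truth$origins, fired = fired,
       speed_kb_min = v_kb)
}

#' Simulate a DNA-fiber (combing) experiment
#'
#' Per-fiber fork rates are drawn from the genotype's truncated-normal rate
#' distribution; both analog track lengths derive from the same fiber's rate
#' (`length = rate x duration / kb_per_um`) with independent measurement
#' noise, truncated positive.
#'
#' @param config A [sim_config()].
#' @param genotype,condition Sample labels; `genotype` selects the rate mean.
#' @param n Number of fibers; defaults to `config$fiber_n`.
#' @param replicate Integer; changes the noise stream only.
#' @return A [fiber_set()] with the config's labelling durations.
#' @export
simulate_fibers <- function(config, genotype = "WT", condition = "NE",
                            n = config$fiber_n, replicate = 1) {
  mu <- config$fiber_rate_mean[[genotype]]
  if (is.null(mu)) stop("no fiber_rate_mean entry for genotype ", genotype)
  set.seed(.sub_seed(config$seed, paste0("fibers", genotype, condition,
                                         replicate)))
  draw_pos <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(x <= 0)) {
      bad <- x <= 0
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    x
  }
  rate <- draw_pos(n, mu, config$fiber_rate_sd)
  cldu <- draw_pos(n, rate * config$cldu_duration_min / config$kb_per_um,
                   config$fiber_noise_um)
  idu <- draw_pos(n, rate * config$idu_duration_min / config$kb_per_um,
                  config$fiber_noise_um)
  fiber_set(data.frame(sample = genotype, condition = condition,
                       cldu_um = cldu, idu_um = idu,
                       stringsAsFactors = FALSE),
            cldu_duration_min = config$cldu_duration_min,
            idu_duration_min = config$idu_duration_min)
}

#' Simulate a MiDAS-seq track and EdU-foci table
#'
#' EdU signal is confined to the configured region set: double-peak regions
#' get edge strips of signal at both ends of the span (the unreplicated
#' interior), single-peak regions one centred strip. Per-cell EdU-foci counts
#' are Poisson with the genotype's mean.
#'
#' @param config A [sim_config()].
#' @param genotype Genotype label; selects `foci_lambda`.
#' @param replicate Integer; changes the noise stream only.
#' @param noise If `FALSE`, the track holds expected counts.
#' @return List with `track` (a [binned_track()]), `foci` (data.frame:
#'   `cell`, `genotype`, `n_edu_foci`) and `regions`.
#' @export
simulate_midas <- function(config, genotype = "WT", replicate = 1,
                           noise = TRUE) {
  truth <- sim_truth(config)
  genome <- truth$genome
  depth <- config$depth_mean_reads_per_bin
  h <- config$midas_signal_sigma * sqrt(depth)  # normalized excess
  norm <- rep(depth, genome$total_bins)
  reg <- truth$midas_regions
  for (i in seq_len(nrow(reg))) {
    strip <- config$midas_edge_fraction * reg$size[i]
    if (reg$peak_type[i] == "double") {
      norm <- .add_interval(norm, genome, reg$chrom[i],
                            reg$start[i], reg$start[i] + strip, h)
      norm <- .add_interval(norm, genome, reg$chrom[i],
                            reg$end[i] - strip, reg$end[i], h)
    } else {
      mid <- (reg$start[i] + reg$end[i]) / 2
      norm <- .add_interval(norm, genome, reg$chrom[i],
                            mid - strip, mid + strip, h)
    }
  }
  mu <- norm * truth$bias
  set.seed(.sub_seed(config$seed, paste0("midas", genotype, replicate)))
  counts <- if (noise) .rcounts(length(mu), mu, config$dispersion) else mu
  lam <- config$foci_lambda[[genotype]]
  if (is.null(lam)) stop("no foci_lambda entry for genotype ", genotype)
  foci <- data.frame(cell = seq_len(config$foci_n_cells),
                     genotype = genotype,
                     n_edu_foci = stats::rpois(config$foci_n_cells, lam),
                     stringsAsFactors = FALSE)
  list(track = binned_track(genome, counts,
                            label = paste0(genotype, "_MiDAS")),
       foci = foci, regions = reg)
}
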