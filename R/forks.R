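#' Per-origin window matrix of sigma values
#'
#' Internal workhorse shared by [metagene()] and the bootstrap in
#' [estimate_progression()]: one row per origin, one column per offset
#' (multiples of the bin size, symmetric about the summit bin). Out-of-bounds
#' and masked bins are `NA`; windows never cross a chromosome boundary.
#' @noRd
.origin_windows <- function(sigma, loci, half_window_bp) {
  genome <- sigma$genome
  n_off <- as.integer(half_window_bp %/% genome$bin_size)
  offsets <- (-n_off:n_off) * genome$bin_size
  bins <- as.integer(loci$bin)
  if (any(bins < 1 | bins > genome$total_bins)) stop("locus outside genome")
  ci <- findInterval(bins - 1L, genome$offset)
  lo_chr <- genome$offset[ci] + 1L
  hi_chr <- genome$offset[ci] + genome$n_bins[ci]
  vals <- sigma$sigma$values
  vals[sigma$sigma$mask] <- NA_real_
  mat <- matrix(NA_real_, nrow = length(bins), ncol = length(offsets))
  for (i in seq_along(bins)) {
    idx <- bins[i] + (-n_off:n_off)
    ok <- idx >= lo_chr[i] & idx <= hi_chr[i]
    mat[i, ok] <- vals[idx[ok]]
  }
  list(offsets = offsets, mat = mat)
}

#' Metagene profile of (adjusted) sigma around origins
#'
#' Averages a sigma track over windows centred on origin summits — the
#' genome-wide view of fork progression after hydroxyurea release when applied
#' to adjusted-sigma tracks at successive timepoints. Origins whose window
#' leaves the chromosome contribute only their in-bounds offsets; masked bins
#' are excluded, with the per-offset contributing count tracked.
#'
#' @param asigma A `sigma_track`, typically adjusted via [adjust_sigma()].
#' @param loci Data.frame of origins with a global `bin` column
#'   ([origin_catalog()], [call_peaks()] output, or [read_origins_bed()]).
#' @param half_window_bp Half-window in bp; default 300000 (0.6 Mb span).
#' @return An object of class `metagene_profile`: a data.frame with columns
#'   `offset` (bp relative to summit), `mean_asigma`, `n` (origins
#'   contributing). Attributes: `timepoint_min`, `condition`, `n_origins`, and
#'   `windows` (the origin x offset matrix, used for origin-level
#'   bootstraps).
#' @export
metagene <- function(asigma, loci, half_window_bp = 300000) {
  stopifnot(inherits(asigma, "sigma_track"))
  if (is.null(loci) || nrow(loci) == 0) stop("empty locus list")
  w <- .origin_windows(asigma, loci, half_window_bp)
  n <- colSums(!is.na(w$mat))
  mean_asigma <- ifelse(n > 0, colMeans(w$mat, na.rm = TRUE), NA_real_)
  out <- data.frame(offset = w$offsets, mean_asigma = mean_asigma, n = n)
  attr(out, "timepoint_min") <- asigma$timepoint_min
  attr(out, "condition") <- asigma$condition
  attr(out, "n_origins") <- nrow(loci)
  attr(out, "windows") <- w$mat
  class(out) <- c("metagene_profile", "data.frame")
  out
}

# FWHM of an offset/value profile: outermost half-maximum crossings by linear
# interpolation, measured above a far-field baseline (median of the outermost
# 20% of offsets, floored at 0) so that background signal from neighbouring
# loci inside the window does not masquerade as peak width. On profiles that
# decay to zero the baseline is ~0 and this is the plain FWHM.
.fwhm <- function(offset, y) {
  ok <- !is.na(y)
  offset <- offset[ok]; y <- y[ok]
  m <- max(y)
  if (!is.finite(m) || m <= 0) stop("profile maximum is not positive")
  k <- max(2L, ceiling(length(y) * 0.1))
  base <- max(0, stats::median(c(utils::head(y, k), utils::tail(y, k))))
  if (m <= base) stop("profile maximum is not positive above baseline")
  half <- base + (m - base) / 2
  ge <- y >= half
  i1 <- which(ge)[1]
  i2 <- which(ge)[sum(ge)]
  left <- if (i1 == 1) offset[1] else {
    # interpolate between (i1-1, i1)
    offset[i1 - 1] + (half - y[i1 - 1]) / (y[i1] - y[i1 - 1]) *
      (offset[i1] - offset[i1 - 1])
  }
  right <- if (i2 == length(y)) offset[length(y)] else {
    offset[i2] + (y[i2] - half) / (y[i2] - y[i2 + 1]) *
      (offset[i2 + 1] - offset[i2])
  }
  right - left
}

#' Full width at half maximum of a metagene profile
#'
#' Summarizes a profile as a fork-travel distance: the distance between the
#' outermost points where the profile crosses half its maximum, by linear
#' interpolation between offsets. Using the outermost crossings makes the
#' summary robust to the central trough that adjusted-sigma profiles develop
#' once forks have moved away from the origin.
#'
#' @param profile A [metagene()] profile.
#' @return Width in bp.
#' @export
profile_halfwidth <- function(profile) {
  stopifnot(inherits(profile, "metagene_profile"))
  .fwhm(profile$offset, profile$mean_asigma)
}

#' Fork progression rate from metagene profiles at several timepoints
#'
#' The per-fork progression rate is the growth of the metagene half-width:
#' `rate = delta(FWHM) / 2 / delta(t)` (each peak has two divergent forks).
#' With more than two timepoints the rate is the least-squares slope of
#' `FWHM / 2` against time. A bootstrap over origins (resampling rows of the
#' stored window matrices jointly across timepoints) gives a confidence
#' interval.
#'
#' @param profiles List of [metagene()] profiles of the same condition and
#'   locus set at two or more release timepoints (timepoints are read from the
#'   profiles' attributes).
#' @param n_boot Bootstrap resamples over origins; default 1000. Set 0 to skip.
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level; default 0.95.
#' @return List with `rate_kb_min`, `ci` (length-2, `NA` if `n_boot = 0`),
#'   `fwhm_bp` (named by timepoint), `timepoints_min`, `boot_rates`.
#' @export
estimate_progression <- function(profiles, n_boot = 1000, seed = 1,
                                 conf = 0.95) {
  if (length(profiles) < 2) stop("need profiles at >= 2 timepoints")
  tp <- vapply(profiles, function(p) attr(p, "timepoint_min"), numeric(1))
  if (anyNA(tp)) stop("profiles must carry timepoint_min")
  ord <- order(tp)
  profiles <- profiles[ord]; tp <- tp[ord]
  fwhm <- vapply(profiles, profile_halfwidth, numeric(1))
  rate_bp_min <- if (length(tp) == 2) {
    (fwhm[2] - fwhm[1]) / 2 / (tp[2] - tp[1])
  } else {
    unname(stats::coef(stats::lm(I(fwhm / 2) ~ tp))[2])
  }
  boot <- numeric(0)
  if (n_boot > 0) {
    mats <- lapply(profiles, attr, "windows")
    offs <- profiles[[1]]$offset
    n_orig <- nrow(mats[[1]])
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(b) {
      rows <- sample.int(n_orig, n_orig, replace = TRUE)
      fw <- vapply(mats, function(m) {
        .fwhm(offs, colMeans(m[rows, , drop = FALSE], na.rm = TRUE))
      }, numeric(1))
      if (length(tp) == 2) (fw[2] - fw[1]) / 2 / (tp[2] - tp[1])
      else unname(stats::coef(stats::lm(I(fw / 2) ~ tp))[2])
    }, numeric(1))
  }
  alpha <- (1 - conf) / 2
  list(
    rate_kb_min = rate_bp_min / 1000,
    ci = if (n_boot > 0)
      unname(stats::quantile(boot / 1000, c(alpha, 1 - alpha))) else
        c(NA_real_, NA_real_),
    fwhm_bp = stats::setNames(fwhm, tp),
    timepoints_min = tp,
    boot_rates = boot / 1000
  )
}

#' DNA-fiber track-length set
#'
#' Per-molecule CldU and IdU track lengths from DNA combing, with sample and
#' condition labels and the labelling durations needed to convert lengths to
#' fork rates.
#'
#' @param records Data.frame with columns `sample`, `condition`, `cldu_um`,
#'   `idu_um`.
#' @param cldu_duration_min,idu_duration_min Analog labelling durations in
#'   minutes (defaults 40 and 40).
#' @return A data.frame of class `fiber_set` with duration attributes.
#' @export
fiber_set <- function(records, cldu_duration_min = 40, idu_duration_min = 40) {
  need <- c("sample", "condition", "cldu_um", "idu_um")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$cldu_um <= 0) || any(records$idu_um <= 0))
    stop("track lengths must be positive")
  if (cldu_duration_min <= 0 || idu_duration_min <= 0)
    stop("labelling durations must be positive")
  out <- as.data.frame(records, stringsAsFactors = FALSE)
  attr(out, "cldu_duration_min") <- cldu_duration_min
  attr(out, "idu_duration_min") <- idu_duration_min
  class(out) <- c("fiber_set", "data.frame")
  out
}

#' Read / write fiber sets as TSV
#' @param path TSV with header columns `sample`, `condition`, `cldu_um`,
#'   `idu_um`.
#' @param cldu_duration_min,idu_duration_min Labelling durations (minutes).
#' @return A [fiber_set()].
#' @export
read_fibers <- function(path, cldu_duration_min = 40, idu_duration_min = 40) {
  if (!file.exists(path)) stop("fiber table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  fiber_set(tab, cldu_duration_min, idu_duration_min)
}

#' @rdname read_fibers
#' @param fibers A [fiber_set()].
#' @export
write_fibers <- function(fibers, path) {
  stopifnot(inherits(fibers, "fiber_set"))
  utils::write.table(fibers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fork progression rates from IdU track lengths
#'
#' After hydroxyurea removal, the IdU pulse marks the distance each fork
#' travels in the labelling window, so
#' `rate = IdU length (um) x kb_per_um / duration (min)`.
#'
#' @param fibers A [fiber_set()].
#' @param kb_per_um Stretching factor for combed DNA; default 2.0 kb/um.
#' @return The fiber set with an added `rate_kb_min` column.
#' @export
fiber_rates <- function(fibers, kb_per_um = 2.0) {
  stopifnot(inherits(fibers, "fiber_set"))
  dur <- attr(fibers, "idu_duration_min")
  if (is.null(dur) || dur <= 0) stop("IdU labelling duration must be positive")
  fibers$rate_kb_min <- fibers$idu_um * kb_per_um / dur
  fibers
}

.sig_tier <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Two-way ANOVA with Fisher's LSD on fiber fork rates
#'
#' Fits a fixed-effects two-way ANOVA (genotype, condition, interaction) on
#' per-fiber rates and compares every pair of design cells with Fisher's
#' Least Significant Difference test: unprotected pairwise t statistics on the
#' pooled residual mean square. Significance tiers follow the usual figure
#' annotation (`****` P < 0.0001, `*` P < 0.05, `ns`). With an empty design
#' cell the fit falls back to a one-way ANOVA on the genotype-condition groups
#' with a warning.
#'
#' @param rates Data.frame with columns `rate_kb_min`, `genotype` (or
#'   `sample`) and `condition`.
#' @return List of class `fiber_test_report`: `anova` (the ANOVA table),
#'   `contrasts` (data.frame with `group1`, `group2`, `diff`, `se`, `t`, `df`,
#'   `p`, `tier`), `design` (cell means and sizes).
#' @export
compare_fiber_groups <- function(rates) {
  df <- as.data.frame(rates)
  if (!"genotype" %in% names(df) && "sample" %in% names(df))
    df$genotype <- df$sample
  need <- c("rate_kb_min", "genotype", "condition")
  if (!all(need %in% names(df)))
    stop("rates must have columns: ", paste(need, collapse = ", "))
  df$genotype <- factor(df$genotype)
  df$condition <- factor(df$condition)
  cells <- table(df$genotype, df$condition)
  if (nlevels(df$genotype) < 2 && nlevels(df$condition) < 2)
    stop("need at least 2 groups")
  if (any(table(interaction(df$genotype, df$condition, drop = TRUE)) < 3))
    stop("every non-empty group needs n >= 3")
  two_way <- nlevels(df$genotype) >= 2 && nlevels(df$condition) >= 2 &&
    all(cells > 0)
  if (two_way) {
    fit <- stats::aov(rate_kb_min ~ genotype * condition, data = df)
  } else {
    if (nlevels(df$genotype) >= 2 && nlevels(df$condition) >= 2)
      warning("empty design cell: falling back to one-way ANOVA")
    df$group_ <- interaction(df$genotype, df$condition, drop = TRUE)
    fit <- stats::aov(rate_kb_min ~ group_, data = df)
  }
  atab <- stats::anova(fit)
  mse <- atab[nrow(atab), "Mean Sq"]
  dfe <- atab[nrow(atab), "Df"]
  grp <- interaction(df$genotype, df$condition, drop = TRUE, sep = ":")
  means <- tapply(df$rate_kb_min, grp, mean)
  ns <- tapply(df$rate_kb_min, grp, length)
  g <- names(means)
  pairs <- utils::combn(seq_along(g), 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d <- means[i] - means[j]
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tval <- d / se
    p <- 2 * stats::pt(-abs(tval), dfe)
    data.frame(group1 = g[i], group2 = g[j], diff = unname(d),
               se = unname(se), t = unname(tval), df = dfe, p = unname(p),
               tier = .sig_tier(unname(p)), stringsAsFactors = FALSE)
  }))
  structure(list(anova = atab, contrasts = contrasts,
                 design = data.frame(group = g, mean = unname(means),
                                     n = unname(as.vector(ns)))),
            class = "fiber_test_report")
}

#' @export
print.fiber_test_report <- function(x, ...) {
  cat("Two-way ANOVA:\n"); print(x$anova)
  cat("\nFisher's LSD pairwise contrasts:\n")
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Per-fiber IdU/CldU length ratios
#'
#' Ratio of the second-analog to first-analog track length per double-labelled
#' fiber; a ratio near the labelling-duration ratio indicates steady fork
#' progression without stalling across the analog switch. Fibers with a zero
#' CldU length are excluded and counted.
#'
#' @param fibers A [fiber_set()].
#' @return List with `per_fiber` (fiber set plus `ratio` column), `summary`
#'   (per sample x condition group: `n`, `median`, `q25`, `q75`, type-7
#'   quantiles) and `n_excluded`.
#' @export
cldu_idu_ratio <- function(fibers) {
  stopifnot(inherits(fibers, "fiber_set"))
  excl <- fibers$cldu_um == 0
  keep <- fibers[!excl, , drop = FALSE]
  keep$ratio <- keep$idu_um / keep$cldu_um
  grp <- interaction(keep$sample, keep$condition, drop = TRUE, sep = ":")
  qs <- tapply(keep$ratio, grp, function(r)
    c(n = length(r), median = stats::median(r),
      q25 = unname(stats::quantile(r, 0.25)),
      q75 = unname(stats::quantile(r, 0.75))))
  summ <- do.call(rbind, qs)
  summ <- data.frame(group = rownames(summ), summ, row.names = NULL,
                     stringsAsFactors = FALSE)
  list(per_fiber = keep, summary = summ, n_excluded = sum(excl))
}
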