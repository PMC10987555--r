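#' Normalize an EdU track against a genomic-DNA control
#'
#' Divides the sample's per-bin counts by the matched genomic-DNA control's
#' counts, then rescales by the median control count over reliable bins so the
#' output stays on the count scale. The control corrects for library-
#' preparation bias and for the fraction of masked (unmappable) sequence per
#' bin. Bins where the control is unreliable — below `min_control_frac` of the
#' median control count — are masked rather than divided, since the quotient
#' explodes at low-mappability bins.
#'
#' The operation is invariant to uniform rescaling of the control and linear
#' in uniform rescaling of the sample.
#'
#' @param sample A [binned_track()] of EdU (nascent-strand) read counts.
#' @param control A [binned_track()] of genomic-DNA read counts on the same
#'   genome.
#' @param min_control_frac Reliability floor: bins whose control count is
#'   below this fraction of the median control count are masked. Default 0.25.
#' @return A [masked_vector()] of normalized counts.
#' @export
normalize_to_control <- function(sample, control, min_control_frac = 0.25) {
  stopifnot(inherits(sample, "binned_track"), inherits(control, "binned_track"))
  if (!same_genome(sample$genome, control$genome))
    stop("sample and control are on different genomes")
  if (sum(control$counts) <= 0)
    stop("control track has no reads")
  med_all <- stats::median(control$counts)
  floor_ct <- min_control_frac * med_all
  mask <- control$counts < floor_ct | control$counts <= 0
  if (all(mask)) stop("all bins masked: control median too low")
  med_ok <- stats::median(control$counts[!mask])
  vals <- rep(NA_real_, length(sample$counts))
  vals[!mask] <- sample$counts[!mask] / control$counts[!mask] * med_ok
  masked_vector(vals, mask)
}

#' Convert a normalized track to sigma values
#'
#' The sigma value is the per-bin measure of peak height: the normalized read
#' count divided by its standard deviation. The standard deviation is taken
#' from a Poisson background model: the background rate `lambda` is the
#' central-50% trimmed mean of the unmasked normalized counts (trimming keeps
#' origin peaks from inflating the estimate), and `sd = sqrt(lambda)`. Sigma
#' is not mean-centered, so background bins fluctuate around `sqrt(lambda)`
#' with unit-scale noise and peaks are measured in count-noise units.
#'
#' @param normalized A [masked_vector()] of normalized counts, typically from
#'   [normalize_to_control()].
#' @param genome The [binned_genome()] the vector lives on.
#' @param label,condition,timepoint_min Sample metadata (see [binned_track()]).
#' @return An object of class `sigma_track` with elements `genome`, `sigma`
#'   (a [masked_vector()]), `background_mean` (`lambda`), `label`, `condition`
#'   and `timepoint_min`. The background sigma level is `sqrt(lambda)`,
#'   available via [background_sigma()].
#' @export
compute_sigma <- function(normalized, genome, label = "sample",
                          condition = NA_character_,
                          timepoint_min = NA_real_) {
  stopifnot(inherits(normalized, "masked_vector"),
            inherits(genome, "binned_genome"))
  if (length(normalized) != genome$total_bins)
    stop("normalized vector length does not match genome bin count")
  vals <- mv_values(normalized, drop_masked = TRUE)
  if (length(vals) < 50)
    stop("fewer than 50 unmasked bins: background estimation unreliable")
  lambda <- mean(vals, trim = 0.25)
  if (lambda <= 0) stop("background mean is not positive")
  sig <- masked_vector(normalized$values / sqrt(lambda), normalized$mask)
  structure(
    list(genome = genome, sigma = sig, background_mean = lambda,
         label = as.character(label), condition = as.character(condition),
         timepoint_min = as.numeric(timepoint_min)),
    class = "sigma_track"
  )
}

#' One-call sigma track from sample and control counts
#'
#' Convenience wrapper: [normalize_to_control()] followed by
#' [compute_sigma()], carrying over the sample's metadata.
#'
#' @inheritParams normalize_to_control
#' @return A `sigma_track` (see [compute_sigma()]).
#' @export
sigma_from_tracks <- function(sample, control, min_control_frac = 0.25) {
  norm <- normalize_to_control(sample, control, min_control_frac)
  compute_sigma(norm, sample$genome, label = sample$label,
                condition = sample$condition,
                timepoint_min = sample$timepoint_min)
}

#' Background sigma level of a track
#'
#' Under the Poisson background model, background bins sit near
#' `sqrt(lambda)`; peak thresholds are expressed as an excess over this level.
#'
#' @param sigma A `sigma_track`.
#' @return `sqrt(background_mean)`, or `NA` for adjusted tracks.
#' @export
background_sigma <- function(sigma) {
  stopifnot(inherits(sigma, "sigma_track"))
  if (is.na(sigma$background_mean)) NA_real_ else sqrt(sigma$background_mean)
}

#' @export
print.sigma_track <- function(x, ...) {
  cat(sprintf(
    "sigma_track '%s'%s: %d bins (%d masked), background lambda %s\n",
    x$label,
    ifelse(is.na(x$timepoint_min), "", sprintf(" t=%g min", x$timepoint_min)),
    length(x$sigma), sum(x$sigma$mask),
    ifelse(is.na(x$background_mean), "NA (adjusted)",
           sprintf("%.2f", x$background_mean))))
  invisible(x)
}

#' Adjusted sigma relative to a no-release sample
#'
#' Subtracts the 0-minute (no hydroxyurea release) sample's sigma values from
#' a release-timepoint track, bin by bin, isolating DNA synthesized after
#' release. The result's mask is the union of the two input masks, and
#' adjusting a track against itself gives exactly zero. The operation is
#' antisymmetric.
#'
#' @param sigma_t `sigma_track` at a release timepoint.
#' @param sigma_0 `sigma_track` of the matched 0-min (no-release) sample of
#'   the same cell line and condition.
#' @return A `sigma_track` of adjusted sigma values; `background_mean` is `NA`
#'   since the background cancels in the subtraction.
#' @export
adjust_sigma <- function(sigma_t, sigma_0) {
  stopifnot(inherits(sigma_t, "sigma_track"), inherits(sigma_0, "sigma_track"))
  if (!same_genome(sigma_t$genome, sigma_0$genome))
    stop("sigma tracks are on different genomes")
  if (!identical(sigma_t$condition, sigma_0$condition))
    warning("condition labels differ between timepoint and no-release tracks")
  adj <- sigma_t$sigma - sigma_0$sigma
  structure(
    list(genome = sigma_t$genome, sigma = adj, background_mean = NA_real_,
         label = paste0(sigma_t$label, "_adj"), condition = sigma_t$condition,
         timepoint_min = sigma_t$timepoint_min),
    class = "sigma_track"
  )
}
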