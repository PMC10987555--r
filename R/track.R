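#' Per-bin read-count track
#'
#' A `binned_track` holds one sample's per-bin read counts on a
#' [binned_genome()], together with the sample metadata carried through the
#' pipeline (label, Cyclin E condition, minutes since hydroxyurea release).
#'
#' @param genome A [binned_genome()].
#' @param counts Numeric vector of non-negative per-bin counts, one per global
#'   bin. Counts are integers for real and simulated data; the simulator's
#'   noise-free mode produces expected (real-valued) counts.
#' @param label Sample identifier.
#' @param condition Cyclin E condition, one of `"NE"` (normal expression),
#'   `"OE"` (overexpression) or `NA`.
#' @param timepoint_min Minutes since hydroxyurea release, or `NA`.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(genome, counts, label = "sample",
                         condition = NA_character_,
                         timepoint_min = NA_real_) {
  stopifnot(inherits(genome, "binned_genome"))
  counts <- as.numeric(counts)
  if (length(counts) != genome$total_bins)
    stop(sprintf("counts length %d does not match genome bin count %d",
                 length(counts), genome$total_bins))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  condition <- as.character(condition)
  if (!is.na(condition) && !condition %in% c("NE", "OE"))
    stop("condition must be 'NE', 'OE' or NA")
  structure(
    list(genome = genome, counts = counts, label = as.character(label),
         condition = condition, timepoint_min = as.numeric(timepoint_min)),
    class = "binned_track"
  )
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf(
    "binned_track '%s' (%s%s): %d bins, %s reads\n", x$label,
    ifelse(is.na(x$condition), "condition NA", x$condition),
    ifelse(is.na(x$timepoint_min), "",
           sprintf(", t=%g min", x$timepoint_min)),
    x$genome$total_bins,
    format(sum(x$counts), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Bin genomic positions into a count track
#'
#' Counts events (e.g. read start positions) per genomic bin. Each position
#' `p` on a chromosome is assigned to the bin `floor(p / bin_size)`; total
#' counts are conserved.
#'
#' @param positions A data.frame with columns `chrom` and `pos` (0-based bp),
#'   or a list of `(chrom, pos)` pairs.
#' @param genome A [binned_genome()].
#' @param label Sample label for the resulting track.
#' @return A [binned_track()] whose counts sum to `nrow(positions)`.
#' @examples
#' g <- binned_genome("chr1", 30000, bin_size = 10000)
#' p <- data.frame(chrom = "chr1", pos = c(0, 9999, 10000))
#' bin_positions(p, g)$counts   # 2, 1, 0
#' @export
bin_positions <- function(positions, genome, label = "binned") {
  stopifnot(inherits(genome, "binned_genome"))
  if (is.list(positions) && !is.data.frame(positions)) {
    positions <- data.frame(
      chrom = vapply(positions, function(p) as.character(p[[1]]), ""),
      pos = vapply(positions, function(p) as.numeric(p[[2]]), 0),
      stringsAsFactors = FALSE)
  }
  counts <- numeric(genome$total_bins)
  if (nrow(positions) > 0) {
    idx <- bin_index(genome, positions$chrom, positions$pos)
    tab <- tabulate(idx, nbins = genome$total_bins)
    counts <- as.numeric(tab)
  }
  binned_track(genome, counts, label = label)
}
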