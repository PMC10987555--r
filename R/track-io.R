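#' @importFrom rtracklayer import export
#' @importFrom GenomicRanges GRanges seqnames start width mcols
#' @importFrom IRanges IRanges
NULL

# GRanges of every bin of the genome, with seqlengths set (needed for BigWig).
.genome_granges <- function(genome) {
  loc <- bin_location(genome, seq_len(genome$total_bins))
  gr <- GenomicRanges::GRanges(
    seqnames = loc$chrom,
    ranges = IRanges::IRanges(start = loc$start + 1, end = loc$end))
  sl <- genome$length
  names(sl) <- genome$chrom
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  gr
}

# Map an imported GRanges (bedGraph-style intervals) onto genome bins.
# Intervals must start on a bin boundary; intervals spanning several bins
# assign their score to each covered bin.
.granges_to_counts <- function(gr, genome, what = "count") {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  unknown <- !chrom %in% genome$chrom
  if (any(unknown))
    stop("unknown chromosome in track file: ", chrom[which(unknown)[1]])
  start0 <- GenomicRanges::start(gr) - 1
  misaligned <- start0 %% genome$bin_size != 0
  if (any(misaligned)) {
    i <- which(misaligned)[1]
    stop(sprintf(
      "line %d: start %s is not a multiple of the bin size (%g)",
      i, format(start0[i], scientific = FALSE), genome$bin_size))
  }
  vals <- rep(NA_real_, genome$total_bins)
  score <- GenomicRanges::mcols(gr)$score
  for (i in seq_along(gr)) {
    nb <- max(1L, as.integer(ceiling(GenomicRanges::width(gr)[i] /
                                       genome$bin_size)))
    for (k in seq_len(nb)) {
      pos <- start0[i] + (k - 1) * genome$bin_size
      if (pos >= genome$length[match(chrom[i], genome$chrom)]) break
      vals[bin_index(genome, chrom[i], pos)] <- score[i]
    }
  }
  vals
}

#' Read a binned count track from bedGraph or chrom/start/count TSV
#'
#' Accepts 4-column bedGraph (0-based half-open intervals aligned to bin
#' boundaries) or headerless 3-column tab-separated chrom/start/count. Bins
#' absent from the file are set to 0.
#'
#' @param path Input file.
#' @param genome A [binned_genome()].
#' @param label,condition,timepoint_min Sample metadata (see [binned_track()]).
#' @return A [binned_track()].
#' @export
read_track <- function(path, genome, label = basename(path),
                       condition = NA_character_, timepoint_min = NA_real_) {
  stopifnot(inherits(genome, "binned_genome"))
  if (!file.exists(path)) stop("track file not found: ", path)
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (length(first) == 3) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(
      tab[[1]], IRanges::IRanges(start = tab[[2]] + 1, width = 1),
      score = tab[[3]])
  } else {
    gr <- rtracklayer::import(path, format = "bedGraph")
  }
  vals <- .granges_to_counts(gr, genome)
  vals[is.na(vals)] <- 0
  binned_track(genome, vals, label = label, condition = condition,
               timepoint_min = timepoint_min)
}

#' Write a binned count track as bedGraph
#'
#' Every bin is written (including zeros) so that reading the file back
#' reproduces the track bin-exactly.
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  gr <- .genome_granges(track$genome)
  GenomicRanges::mcols(gr)$score <- track$counts
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a sigma track as bedGraph
#'
#' Values are written with 4-decimal fixed-point precision; masked bins are
#' omitted from the file.
#'
#' @param sigma A `sigma_track` (see [compute_sigma()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sigma <- function(sigma, path) {
  stopifnot(inherits(sigma, "sigma_track"))
  keep <- !sigma$sigma$mask
  loc <- bin_location(sigma$genome, which(keep))
  lines <- sprintf("%s\t%s\t%s\t%.4f",
                   loc$chrom,
                   format(loc$start, scientific = FALSE, trim = TRUE),
                   format(loc$end, scientific = FALSE, trim = TRUE),
                   sigma$sigma$values[keep])
  writeLines(lines, path)
  invisible(path)
}

#' Read a sigma track from bedGraph
#'
#' Bins absent from the file are treated as masked. The background mean is
#' re-estimated from the values (central-50% trimmed mean of the squared
#' count-scale values is not recoverable, so `lambda` is re-derived as the
#' squared trimmed mean of sigma only when the track has not been adjusted;
#' see Details).
#'
#' @details For an unadjusted sigma track, `sigma = normalized / sqrt(lambda)`
#' with `lambda` the trimmed mean of `normalized`, so the trimmed mean of
#' sigma equals `sqrt(lambda)` and `lambda` is recovered as its square. For
#' adjusted tracks (values centred near 0) pass `adjusted = TRUE` to leave
#' `background_mean` as `NA`.
#'
#' @param path Input bedGraph.
#' @param genome A [binned_genome()].
#' @param label,condition,timepoint_min Sample metadata.
#' @param adjusted If `TRUE`, do not re-estimate a background mean.
#' @return A `sigma_track`.
#' @export
read_sigma <- function(path, genome, label = basename(path),
                       condition = NA_character_, timepoint_min = NA_real_,
                       adjusted = FALSE) {
  stopifnot(inherits(genome, "binned_genome"))
  if (!file.exists(path)) stop("sigma file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- .granges_to_counts(gr, genome)
  mv <- masked_vector(vals, is.na(vals))
  lambda <- if (adjusted) NA_real_
            else mean(mv_values(mv, drop_masked = TRUE), trim = 0.25)^2
  structure(
    list(genome = genome, sigma = mv, background_mean = lambda,
         label = as.character(label), condition = as.character(condition),
         timepoint_min = as.numeric(timepoint_min)),
    class = "sigma_track"
  )
}

#' Export a track or sigma track as BigWig
#'
#' Optional genome-browser export; requires the genome's chromosome lengths,
#' which a [binned_genome()] always carries.
#'
#' @param x A [binned_track()] or `sigma_track`.
#' @param path Output `.bw` path.
#' @return `path`, invisibly.
#' @export
write_bigwig <- function(x, path) {
  if (inherits(x, "binned_track")) {
    genome <- x$genome; vals <- x$counts; keep <- rep(TRUE, length(vals))
  } else if (inherits(x, "sigma_track")) {
    genome <- x$genome; vals <- x$sigma$values; keep <- !x$sigma$mask
  } else stop("x must be a binned_track or sigma_track")
  gr <- .genome_granges(genome)[keep]
  GenomicRanges::mcols(gr)$score <- vals[keep]
  rtracklayer::export(gr, path, format = "BigWig")
  invisible(path)
}
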