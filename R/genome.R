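#' Binned genome coordinate system
#'
#' Defines the shared coordinate system used by every track in the package: the
#' genome is cut into fixed-width bins (10 kb by default) per chromosome, and
#' bins are addressed either locally (chromosome + 0-based bin) or through a
#' stable global index that concatenates chromosomes in the order given.
#' Coordinates are 0-based, half-open, matching BED/bedGraph conventions.
#'
#' @param chrom_names Character vector of chromosome identifiers (order is
#'   preserved and defines the global bin index).
#' @param chrom_lengths Numeric vector of chromosome lengths in bp, parallel to
#'   `chrom_names`.
#' @param bin_size Bin width in bp; default 10000.
#'
#' @return An object of class `binned_genome` with elements `chrom`, `length`,
#'   `bin_size`, `n_bins` (bins per chromosome), `offset` (global index of the
#'   bin preceding each chromosome's first bin) and `total_bins`.
#' @examples
#' g <- binned_genome(c("chr1", "chr2"), c(55000, 30000), bin_size = 10000)
#' g$n_bins   # 6 and 3: partial terminal bins are kept
#' @export
binned_genome <- function(chrom_names, chrom_lengths, bin_size = 10000) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have the same length")
  if (length(chrom_names) == 0) stop("genome must have at least one chromosome")
  if (anyDuplicated(chrom_names)) stop("duplicated chromosome names")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  bin_size <- as.numeric(bin_size)
  if (!is.finite(bin_size) || bin_size <= 0) stop("bin_size must be > 0")
  n_bins <- as.integer(ceiling(chrom_lengths / bin_size))
  structure(
    list(
      chrom = chrom_names,
      length = chrom_lengths,
      bin_size = bin_size,
      n_bins = n_bins,
      offset = c(0L, cumsum(n_bins)[-length(n_bins)]),
      total_bins = sum(n_bins)
    ),
    class = "binned_genome"
  )
}

#' @export
print.binned_genome <- function(x, ...) {
  cat(sprintf("binned_genome: %d chromosome(s), bin size %g bp, %d bins\n",
              length(x$chrom), x$bin_size, x$total_bins))
  invisible(x)
}

#' Read a genome definition from a chrom.sizes file
#'
#' Reads a UCSC-style 2-column tab-separated file (chromosome name, length in
#' bp). Chromosome order in the file defines the global bin order.
#'
#' @param path Path to the chrom.sizes file.
#' @param bin_size Bin width in bp; default 10000.
#' @return A [binned_genome()].
#' @export
read_chrom_sizes <- function(path, bin_size = 10000) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric"))
  binned_genome(tab[[1]], tab[[2]], bin_size = bin_size)
}

#' Write a genome definition as a chrom.sizes file
#' @param genome A [binned_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "binned_genome"))
  utils::write.table(
    data.frame(genome$chrom, format(genome$length, scientific = FALSE,
                                    trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map genomic positions to global bin indices
#'
#' The global bin index is 1-based and runs over chromosomes in genome order;
#' within a chromosome, position `p` falls in local bin `floor(p / bin_size)`
#' (bins are 0-based half-open intervals `[start, start + bin_size)`).
#'
#' @param genome A [binned_genome()].
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of 0-based bp positions, parallel to `chrom`.
#' @return Integer vector of global bin indices in `1..total_bins`.
#' @export
bin_index <- function(genome, chrom, pos) {
  stopifnot(inherits(genome, "binned_genome"))
  ci <- match(as.character(chrom), genome$chrom)
  if (anyNA(ci)) {
    bad <- which(is.na(ci))[1]
    stop("unknown chromosome: ", chrom[bad])
  }
  pos <- as.numeric(pos)
  out <- pos < 0 | pos >= genome$length[ci]
  if (any(out)) {
    bad <- which(out)[1]
    stop(sprintf("position outside chromosome bounds: %s:%s",
                 chrom[bad], format(pos[bad], scientific = FALSE)))
  }
  as.integer(genome$offset[ci] + pos %/% genome$bin_size + 1)
}

#' Locate global bins on the genome
#'
#' Inverse of [bin_index()]: maps global bin indices back to chromosome, local
#' bin and bin start.
#'
#' @param genome A [binned_genome()].
#' @param bins Integer vector of global bin indices.
#' @return A data.frame with columns `chrom`, `local_bin` (0-based), `start`
#'   (bp) and `end` (bp, clipped to the chromosome length).
#' @export
bin_location <- function(genome, bins) {
  stopifnot(inherits(genome, "binned_genome"))
  bins <- as.integer(bins)
  if (any(bins < 1 | bins > genome$total_bins))
    stop("global bin index out of range")
  ci <- findInterval(bins - 1L, genome$offset)
  local <- bins - 1L - genome$offset[ci]
  start <- local * genome$bin_size
  data.frame(
    chrom = genome$chrom[ci],
    local_bin = local,
    start = start,
    end = pmin(start + genome$bin_size, genome$length[ci]),
    stringsAsFactors = FALSE
  )
}

same_genome <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$length, b$length) &&
    identical(a$bin_size, b$bin_size)
}
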