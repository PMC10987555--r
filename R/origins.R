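#' Call origin peaks from an early-S sigma track
#'
#' In hydroxyurea-arrested early-S cells, EdU incorporation is confined to the
#' vicinity of fired origins, so origins appear as narrow sigma peaks over a
#' flat background. A peak is a maximal run of at least `min_run` consecutive
#' unmasked bins with `sigma >= background + min_sigma_excess`, where the
#' background level is `sqrt(lambda)` (see [background_sigma()]); runs
#' separated by fewer than `merge_gap` sub-threshold bins are merged. One
#' locus is reported per run, at the bin of maximal sigma, with the summit at
#' that bin's centre.
#'
#' @param sigma `sigma_track` of an HU-arrested early-S sample (must carry a
#'   background mean; adjusted tracks do not).
#' @param min_sigma_excess Threshold above the background sigma level;
#'   default 3.
#' @param min_run Minimum number of supra-threshold bins per peak; default 2.
#' @param merge_gap Runs separated by fewer than this many sub-threshold bins
#'   are merged; default 2 (i.e. single-bin dropouts are bridged).
#' @return A data.frame of loci with columns `chrom`, `bin` (global index) and
#'   `summit` (bp), sorted by genome position.
#' @export
call_peaks <- function(sigma, min_sigma_excess = 3, min_run = 2,
                       merge_gap = 2) {
  stopifnot(inherits(sigma, "sigma_track"))
  bg <- background_sigma(sigma)
  if (is.na(bg))
    stop("track has no background level (adjusted tracks cannot be peak-called)")
  thr <- bg + min_sigma_excess
  genome <- sigma$genome
  vals <- sigma$sigma$values
  above <- !sigma$sigma$mask & !is.na(vals) & vals >= thr
  loci <- list()
  for (ci in seq_along(genome$chrom)) {
    lo <- genome$offset[ci] + 1L
    hi <- genome$offset[ci] + genome$n_bins[ci]
    a <- above[lo:hi]
    if (!any(a)) next
    r <- rle(a)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # merge TRUE runs across FALSE gaps shorter than merge_gap
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) {
      for (k in 2:nrow(runs)) {
        gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
        if (gap < merge_gap) {
          merged$end[nrow(merged)] <- runs$end[k]
        } else {
          merged <- rbind(merged, runs[k, ])
        }
      }
    }
    for (k in seq_len(nrow(merged))) {
      idx <- merged$start[k]:merged$end[k]
      n_above <- sum(a[idx])
      if (n_above < min_run) next
      vseg <- vals[lo - 1L + idx]
      vseg[!a[idx]] <- -Inf     # argmax over supra-threshold bins only
      peak_local <- idx[which.max(vseg)]
      gbin <- lo - 1L + peak_local
      loc <- bin_location(genome, gbin)
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = loc$chrom, bin = gbin,
        summit = (loc$start + loc$end) / 2,
        stringsAsFactors = FALSE)
    }
  }
  if (length(loci) == 0)
    return(data.frame(chrom = character(), bin = integer(),
                      summit = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, loci)
  out[order(out$bin), , drop = FALSE]
}

#' Per-origin firing efficiency from a sigma track
#'
#' The firing efficiency of an origin is read off as the maximum sigma value
#' within one bin of its summit (peaks are narrow under HU arrest, and figure
#' axes are in sigma units), floored at 0. Origins whose whole summit
#' neighbourhood is masked get `NA` and are excluded (and counted) downstream.
#'
#' @param sigma A `sigma_track`.
#' @param loci Data.frame of loci with a global `bin` column, as produced by
#'   [call_peaks()] or [read_origins_bed()].
#' @return Numeric vector of efficiencies (sigma units), `NA` where masked.
#' @export
quantify_efficiency <- function(sigma, loci) {
  stopifnot(inherits(sigma, "sigma_track"))
  genome <- sigma$genome
  bins <- as.integer(loci$bin)
  if (any(bins < 1 | bins > genome$total_bins))
    stop("locus outside genome")
  ci <- findInterval(bins - 1L, genome$offset)
  lo_chr <- genome$offset[ci] + 1L
  hi_chr <- genome$offset[ci] + genome$n_bins[ci]
  vapply(seq_along(bins), function(i) {
    win <- max(bins[i] - 1L, lo_chr[i]):min(bins[i] + 1L, hi_chr[i])
    v <- sigma$sigma$values[win]
    v <- v[!sigma$sigma$mask[win]]
    if (length(v) == 0) NA_real_ else max(0, max(v))
  }, numeric(1))
}

#' Classify origins as constitutive, intermediate or oncogene-induced
#'
#' Origins firing with at least four-fold higher efficiency under Cyclin E
#' overexpression are oncogene-induced (`Oi`); those firing at least two-fold
#' but less than four-fold more efficiently are `intermediate`; the rest are
#' constitutive (`CN`). The fold change is computed on pseudocount-stabilized
#' efficiencies: `rho = (eff_OE + pseudocount) / (eff_NE + pseudocount)`.
#'
#' @param eff_NE,eff_OE Paired per-origin efficiencies (sigma units) under
#'   normal and overexpressed Cyclin E.
#' @param pseudocount Added to both efficiencies before the ratio; stabilizes
#'   near-zero NE efficiencies. Default 1. With `pseudocount = 0` the rule is
#'   exactly scale-invariant.
#' @param oi_fold,intermediate_fold Class boundaries; defaults 4 and 2.
#' @return Factor with levels `CN`, `intermediate`, `Oi` (`NA` where either
#'   efficiency is missing).
#' @export
classify_origins <- function(eff_NE, eff_OE, pseudocount = 1,
                             oi_fold = 4, intermediate_fold = 2) {
  if (length(eff_NE) != length(eff_OE))
    stop("eff_NE and eff_OE must be paired")
  if (any(eff_NE < 0, na.rm = TRUE) || any(eff_OE < 0, na.rm = TRUE))
    stop("efficiencies must be non-negative")
  rho <- (eff_OE + pseudocount) / (eff_NE + pseudocount)
  lab <- ifelse(rho >= oi_fold, "Oi",
                ifelse(rho >= intermediate_fold, "intermediate", "CN"))
  factor(lab, levels = c("CN", "intermediate", "Oi"))
}

#' Assemble an origin catalog
#'
#' @param loci Data.frame with columns `chrom`, `bin`, `summit`.
#' @param eff_NE,eff_OE Per-origin efficiencies (sigma units).
#' @param class_label Optional class factor; computed with
#'   [classify_origins()] defaults when omitted.
#' @param pseudocount Passed to [classify_origins()] when classifying.
#' @return A data.frame of class `origin_catalog`, sorted by genome position,
#'   with columns `chrom`, `bin`, `summit`, `eff_NE`, `eff_OE`, `class`.
#' @export
origin_catalog <- function(loci, eff_NE, eff_OE, class_label = NULL,
                           pseudocount = 1) {
  if (is.null(class_label))
    class_label <- classify_origins(eff_NE, eff_OE, pseudocount)
  out <- data.frame(
    chrom = loci$chrom, bin = as.integer(loci$bin), summit = loci$summit,
    eff_NE = eff_NE, eff_OE = eff_OE,
    class = factor(class_label, levels = c("CN", "intermediate", "Oi")),
    stringsAsFactors = FALSE)
  out <- out[order(out$bin), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("origin_catalog", "data.frame")
  out
}

#' Cross-sample origin-efficiency correlation by class
#'
#' Re-quantifies each catalogued origin's efficiency in two sigma tracks (e.g.
#' parental versus mutant cells under the same Cyclin E condition) and
#' summarizes the agreement per origin class with Pearson (headline) and
#' Spearman correlations. Origins with a missing efficiency in either track
#' are excluded and counted.
#'
#' @param catalog An [origin_catalog()].
#' @param sigma_A,sigma_B `sigma_track`s on the catalog's genome.
#' @return An object of class `correlation_summary`: a data.frame with one row
#'   per class (plus an `all` row) and columns `class`, `n`, `n_excluded`,
#'   `pearson_r`, `spearman_r`, `mean_A`, `mean_B`. The paired per-origin
#'   points are attached as attribute `points`.
#' @export
correlate_catalogs <- function(catalog, sigma_A, sigma_B) {
  stopifnot(inherits(catalog, "origin_catalog"))
  eff_A <- quantify_efficiency(sigma_A, catalog)
  eff_B <- quantify_efficiency(sigma_B, catalog)
  pts <- data.frame(class = catalog$class, eff_A = eff_A, eff_B = eff_B)
  classes <- c(levels(catalog$class), "all")
  rows <- lapply(classes, function(cl) {
    sel <- if (cl == "all") rep(TRUE, nrow(pts)) else pts$class == cl
    a <- eff_A[sel]; b <- eff_B[sel]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    data.frame(
      class = cl, n = n, n_excluded = sum(sel) - n,
      pearson_r = if (n >= 3) stats::cor(a[ok], b[ok]) else NA_real_,
      spearman_r = if (n >= 3) stats::cor(a[ok], b[ok], method = "spearman")
                   else NA_real_,
      mean_A = if (n > 0) mean(a[ok]) else NA_real_,
      mean_B = if (n > 0) mean(b[ok]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "points") <- pts
  class(out) <- c("correlation_summary", "data.frame")
  out
}

#' Write / read an origin catalog as BED6
#'
#' The class label goes in the BED name field and the chosen efficiency in the
#' score field; the interval is the summit bin.
#'
#' @param catalog An [origin_catalog()].
#' @param path Output path.
#' @param score Which efficiency to place in the score field.
#' @param bin_size Interval width written around each summit; default 10000.
#' @return `path`, invisibly.
#' @export
write_origins_bed <- function(catalog, path, score = c("eff_NE", "eff_OE"),
                              bin_size = 10000) {
  stopifnot(inherits(catalog, "origin_catalog"))
  score <- match.arg(score)
  # carry both efficiencies: name = class|eff_NE|eff_OE
  name <- sprintf("%s|%.4f|%.4f", as.character(catalog$class),
                  catalog$eff_NE, catalog$eff_OE)
  half <- bin_size / 2
  lines <- sprintf("%s\t%s\t%s\t%s\t%.4f\t.",
                   catalog$chrom,
                   format(floor(catalog$summit - half), scientific = FALSE,
                          trim = TRUE),
                   format(floor(catalog$summit + half), scientific = FALSE,
                          trim = TRUE),
                   name, catalog[[score]])
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_origins_bed
#' @param genome A [binned_genome()] used to recover global bin indices.
#' @return `read_origins_bed()`: an [origin_catalog()] (efficiencies and class
#'   restored from the name field when present; plain BED yields `NA`
#'   efficiencies and `CN` labels).
#' @export
read_origins_bed <- function(path, genome) {
  stopifnot(inherits(genome, "binned_genome"))
  if (!file.exists(path)) stop("origin BED not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  chrom <- tab[[1]]
  summit <- (tab[[2]] + tab[[3]]) / 2
  eff_NE <- rep(NA_real_, nrow(tab)); eff_OE <- rep(NA_real_, nrow(tab))
  cls <- rep("CN", nrow(tab))
  if (ncol(tab) >= 4) {
    parts <- strsplit(as.character(tab[[4]]), "|", fixed = TRUE)
    has3 <- lengths(parts) == 3
    cls <- vapply(parts, `[[`, "", 1)
    eff_NE[has3] <- as.numeric(vapply(parts[has3], `[[`, "", 2))
    eff_OE[has3] <- as.numeric(vapply(parts[has3], `[[`, "", 3))
  }
  bins <- bin_index(genome, chrom, pmin(summit, genome$length[
    match(chrom, genome$chrom)] - 1))
  loci <- data.frame(chrom = chrom, bin = bins, summit = summit,
                     stringsAsFactors = FALSE)
  cls[!cls %in% c("CN", "intermediate", "Oi")] <- "CN"
  origin_catalog(loci, eff_NE, eff_OE,
                 class_label = factor(cls,
                                      levels = c("CN", "intermediate", "Oi")))
}
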