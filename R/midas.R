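#' MiDAS region set
#'
#' Genomic regions where mitotic DNA synthesis completes under-replicated DNA.
#' Each region is classified as `double` (signal at both edges of a long
#' unreplicated span) or `single` (one central peak in a short span).
#'
#' @param regions Data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open bp) and `peak_type` (`"single"` or `"double"`).
#' @return A data.frame of class `midas_region_set` with an added `size`
#'   column and a stable `region_id`.
#' @export
midas_regions <- function(regions) {
  need <- c("chrom", "start", "end", "peak_type")
  if (!all(need %in% names(regions)))
    stop("regions must have columns: ", paste(need, collapse = ", "))
  if (any(regions$start >= regions$end))
    stop("region start must be < end")
  if (!all(regions$peak_type %in% c("single", "double")))
    stop("peak_type must be 'single' or 'double'")
  out <- as.data.frame(regions, stringsAsFactors = FALSE)
  out$size <- out$end - out$start
  out$region_id <- sprintf("%s:%s-%s", out$chrom,
                           format(out$start, scientific = FALSE, trim = TRUE),
                           format(out$end, scientific = FALSE, trim = TRUE))
  class(out) <- c("midas_region_set", "data.frame")
  out
}

#' Read / write MiDAS regions as BED4
#'
#' The peak type (`single`/`double`) is stored in the BED name field.
#'
#' @param path BED4 file path.
#' @return A [midas_regions()] set.
#' @export
read_midas_bed <- function(path) {
  if (!file.exists(path)) stop("MiDAS region BED not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  midas_regions(data.frame(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
                           peak_type = tab[[4]], stringsAsFactors = FALSE))
}

#' @rdname read_midas_bed
#' @param regions A [midas_regions()] set.
#' @export
write_midas_bed <- function(regions, path) {
  stopifnot(inherits(regions, "midas_region_set"))
  lines <- sprintf("%s\t%s\t%s\t%s", regions$chrom,
                   format(regions$start, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE),
                   regions$peak_type)
  writeLines(lines, path)
  invisible(path)
}

# fraction of records with count >= threshold, per group; exact integer
# arithmetic until the final division
.fraction_by_group <- function(group, counts, threshold) {
  if (length(group) == 0) stop("empty group")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  group <- factor(group)
  n <- tapply(counts, group, length)
  if (any(is.na(n) | n == 0)) stop("empty group")
  pos <- tapply(counts, group, function(x) sum(x >= threshold))
  data.frame(group = levels(group), n = as.vector(n),
             n_positive = as.vector(pos),
             fraction = as.vector(pos) / as.vector(n),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of MiDAS-positive mitotic cells per genotype
#'
#' A mitotic cell is scored MiDAS-positive when it shows at least `min_foci`
#' EdU foci.
#'
#' @param foci Data.frame with columns `genotype` and `n_edu_foci`
#'   (non-negative integer per cell).
#' @param min_foci Positivity threshold; default 2.
#' @return Data.frame with one row per genotype: `genotype`, `n`,
#'   `n_positive`, `fraction`.
#' @export
score_midas_positive <- function(foci, min_foci = 2) {
  need <- c("genotype", "n_edu_foci")
  if (!all(need %in% names(foci)))
    stop("foci table must have columns: ", paste(need, collapse = ", "))
  out <- .fraction_by_group(foci$genotype, foci$n_edu_foci, min_foci)
  names(out)[1] <- "genotype"
  out
}

#' Fraction of early-G1 cells with 53BP1 nuclear bodies
#'
#' 53BP1 bodies in G1 mark lesions inherited from incomplete replication; a
#' cell is counted positive at `min_bodies` or more.
#'
#' @param cells Data.frame with columns `genotype` and `n_bodies`.
#' @param min_bodies Threshold; default 1.
#' @return Data.frame as in [score_midas_positive()].
#' @export
fraction_53bp1 <- function(cells, min_bodies = 1) {
  need <- c("genotype", "n_bodies")
  if (!all(need %in% names(cells)))
    stop("cells table must have columns: ", paste(need, collapse = ", "))
  out <- .fraction_by_group(cells$genotype, cells$n_bodies, min_bodies)
  names(out)[1] <- "genotype"
  out
}

#' MiDAS-seq signal profiles over a region set
#'
#' Extracts each region's sigma signal over its span plus flanks, rescales it
#' to a common relative-coordinate axis by linear interpolation (regions
#' differ in length), and averages across regions. The per-region matrix is
#' ordered for heatmap display: double-peak regions first, ranked by genomic
#' size (descending, ties by position), then single-peak regions ranked by
#' their sigma value (descending; the region maximum by default, switchable to
#' the mean).
#'
#' @param sigma A `sigma_track` (see [compute_sigma()]).
#' @param regions A [midas_regions()] set on the track's genome.
#' @param flank_frac Flank added on each side, as a fraction of the region
#'   span; default 0.5.
#' @param n_positions Number of points on the relative axis; default 100.
#' @param single_rank Ranking statistic for single-peak rows: `"max"`
#'   (default) or `"mean"` sigma over the region span.
#' @return List of class `midas_profile`: `positions` (relative coordinate,
#'   0 = region start, 1 = region end), `average` (mean profile over regions),
#'   `matrix` (region x position, rows in display order), `order` (region ids
#'   in display order), `region_stats` (per-region size, peak type, max and
#'   mean sigma).
#' @export
region_profiles <- function(sigma, regions, flank_frac = 0.5,
                            n_positions = 100,
                            single_rank = c("max", "mean")) {
  stopifnot(inherits(sigma, "sigma_track"),
            inherits(regions, "midas_region_set"))
  single_rank <- match.arg(single_rank)
  genome <- sigma$genome
  ci <- match(regions$chrom, genome$chrom)
  if (anyNA(ci)) stop("region chromosome not in genome")
  rel <- seq(-flank_frac, 1 + flank_frac, length.out = n_positions)
  vals <- sigma$sigma$values
  vals[sigma$sigma$mask] <- NA_real_
  centers_all <- (bin_location(genome, seq_len(genome$total_bins))$start +
                    bin_location(genome, seq_len(genome$total_bins))$end) / 2
  prof <- matrix(NA_real_, nrow = nrow(regions), ncol = n_positions)
  stat_max <- numeric(nrow(regions)); stat_mean <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    span <- regions$size[i]
    lo <- regions$start[i] - flank_frac * span
    hi <- regions$end[i] + flank_frac * span
    clip <- lo < 0 || hi > genome$length[ci[i]]
    if (clip) {
      warning(sprintf("region %s clipped to chromosome bounds",
                      regions$region_id[i]))
      lo <- max(0, lo); hi <- min(genome$length[ci[i]], hi)
    }
    b1 <- bin_index(genome, regions$chrom[i], lo)
    b2 <- bin_index(genome, regions$chrom[i],
                    min(hi, genome$length[ci[i]] - 1))
    idx <- b1:b2
    x <- centers_all[idx]; y <- vals[idx]
    ok <- !is.na(y)
    if (sum(ok) >= 2) {
      abs_pos <- regions$start[i] + rel * span
      abs_pos <- pmin(pmax(abs_pos, min(x[ok])), max(x[ok]))
      prof[i, ] <- stats::approx(x[ok], y[ok], xout = abs_pos)$y
    }
    in_span <- idx >= bin_index(genome, regions$chrom[i], regions$start[i]) &
      idx <= bin_index(genome, regions$chrom[i],
                       min(regions$end[i] - 1, genome$length[ci[i]] - 1))
    yy <- vals[idx[in_span]]
    stat_max[i] <- if (all(is.na(yy))) NA_real_ else max(yy, na.rm = TRUE)
    stat_mean[i] <- if (all(is.na(yy))) NA_real_ else mean(yy, na.rm = TRUE)
  }
  avg <- colMeans(prof, na.rm = TRUE)
  is_double <- regions$peak_type == "double"
  ord_double <- which(is_double)[order(-regions$size[is_double],
                                       regions$chrom[is_double],
                                       regions$start[is_double])]
  rank_stat <- if (single_rank == "max") stat_max else stat_mean
  ord_single <- which(!is_double)[order(-rank_stat[!is_double])]
  ord <- c(ord_double, ord_single)
  mat <- prof[ord, , drop = FALSE]
  rownames(mat) <- regions$region_id[ord]
  structure(list(
    positions = rel, average = avg, matrix = mat,
    order = regions$region_id[ord],
    region_stats = data.frame(region_id = regions$region_id,
                              size = regions$size,
                              peak_type = regions$peak_type,
                              max_sigma = stat_max, mean_sigma = stat_mean,
                              stringsAsFactors = FALSE)),
    class = "midas_profile")
}

#' Two-way ANOVA with Tukey comparisons on replicate fractions
#'
#' Compares MiDAS-positivity (or 53BP1-body) fractions across genotypes and
#' treatments using per-experiment replicate fractions as observations:
#' two-way fixed-effects ANOVA with Tukey's honest significant difference on
#' the genotype-by-treatment cells. With a single treatment level a one-way
#' layout is fitted.
#'
#' @param fractions Data.frame with columns `genotype`, `treatment` and
#'   `fraction`, one row per independent experiment.
#' @return List of class `fraction_test_report`: `anova`, `tukey` (data.frame
#'   with `contrast`, `diff`, `lwr`, `upr`, `p_adj`, `tier`).
#' @export
compare_fractions <- function(fractions) {
  df <- as.data.frame(fractions)
  need <- c("genotype", "treatment", "fraction")
  if (!all(need %in% names(df)))
    stop("fractions must have columns: ", paste(need, collapse = ", "))
  df$genotype <- factor(df$genotype)
  df$treatment <- factor(df$treatment)
  cell <- interaction(df$genotype, df$treatment, drop = TRUE, sep = ":")
  if (any(table(cell) < 2))
    stop("need >= 2 replicate fractions per genotype x treatment cell")
  if (nlevels(df$treatment) >= 2) {
    fit <- stats::aov(fraction ~ genotype * treatment, data = df)
    df$cell_ <- cell
    fit_cells <- stats::aov(fraction ~ cell_, data = df)
  } else {
    fit <- stats::aov(fraction ~ genotype, data = df)
    fit_cells <- fit
  }
  tk <- stats::TukeyHSD(fit_cells)[[1]]
  # a zero residual mean square makes the studentized range undefined; the
  # degenerate limit is p = 1 for identical cells and p = 0 otherwise
  bad <- !is.finite(tk[, "p adj"])
  tk[bad, "p adj"] <- ifelse(tk[bad, "diff"] == 0, 1, 0)
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      tier = .sig_tier(tk[, "p adj"]),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(anova = stats::anova(fit), tukey = tukey),
            class = "fraction_test_report")
}

#' @export
print.fraction_test_report <- function(x, ...) {
  cat("ANOVA on replicate fractions:\n"); print(x$anova)
  cat("\nTukey pairwise comparisons:\n"); print(x$tukey, digits = 4)
  invisible(x)
}
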