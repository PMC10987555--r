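# shared fixture builders; everything is generated in code

toy_genome <- function(bin_size = 10000) {
  binned_genome(c("chrT1", "chrT2"), c(1e6, 5e5), bin_size = bin_size)
}

# sigma_track with exactly known values and background lambda: background
# bins dominate (>75%) so the central-50% trimmed mean equals `lambda`
# exactly and sigma values come out as requested.
make_sigma_track <- function(sigma_values, lambda = 100, n_pad = NULL,
                             mask = NULL, ...) {
  k <- length(sigma_values)
  if (is.null(n_pad)) n_pad <- max(200, 4 * k)
  vals <- c(sigma_values * sqrt(lambda), rep(lambda, n_pad))
  if (is.null(mask)) mask <- rep(FALSE, k)
  g <- binned_genome("chrS", (k + n_pad) * 10000, bin_size = 10000)
  compute_sigma(masked_vector(vals, c(mask, rep(FALSE, n_pad))), g, ...)
}

# recall/precision of called loci against planted origins
match_loci <- function(called, truth, tol_bp = 30000) {
  if (nrow(called) == 0) return(list(recall = 0, precision = NA_real_))
  hit <- abs(outer(called$summit, truth$summit, "-")) <= tol_bp &
    outer(called$chrom, truth$chrom, "==")
  list(recall = mean(apply(hit, 2, any)),
       precision = mean(apply(hit, 1, any)))
}

# brute-force metagene: plain double loop over origins and offsets
brute_metagene <- function(sigma, loci, half_window_bp) {
  genome <- sigma$genome
  n_off <- half_window_bp %/% genome$bin_size
  offsets <- (-n_off:n_off) * genome$bin_size
  means <- numeric(length(offsets)); ns <- integer(length(offsets))
  for (j in seq_along(offsets)) {
    acc <- c()
    for (i in seq_len(nrow(loci))) {
      b <- loci$bin[i] + offsets[j] / genome$bin_size
      loc_ci <- findInterval(loci$bin[i] - 1, genome$offset)
      lo <- genome$offset[loc_ci] + 1; hi <- genome$offset[loc_ci] +
        genome$n_bins[loc_ci]
      if (b < lo || b > hi) next
      if (sigma$sigma$mask[b]) next
      acc <- c(acc, sigma$sigma$values[b])
    }
    means[j] <- if (length(acc)) mean(acc) else NA_real_
    ns[j] <- length(acc)
  }
  list(offsets = offsets, mean = means, n = ns)
}
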