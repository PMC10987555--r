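#' @importFrom jsonlite write_json read_json
NULL

# manifest: the audit trail of a pipeline stage. Records parameters, input
# digests, outputs and timings so a rerun with identical inputs and seed can
# be verified byte for byte.
.write_manifest <- function(stage, out_dir, params, inputs, outputs, t0) {
  manifest <- list(
    stage = stage,
    tool_version = as.character(utils::packageVersion("repliquant")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = outputs,
    elapsed_sec = round(as.numeric(Sys.time()) - t0, 3))
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.need_files <- function(stage, ...) {
  for (p in c(...)) {
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("[%s] input file not found: %s", stage, p))
  }
}

#' Write a complete synthetic fixture directory
#'
#' Runs every generator of the config and writes the results in the formats
#' the analysis commands consume: `genome.chrom.sizes`, bedGraph count
#' tracks (control, NE/OE HU-arrest EdU, release timecourse), the planted
#' origin truth as BED6, the MiDAS region BED, track and foci TSV, and the
#' fiber TSV.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param genotypes Genotypes to simulate; default `"WT"`.
#' @param timepoints_min Release timepoints; default `c(0, 30, 90)`.
#' @return Named list of output paths, invisibly; a JSON manifest is written
#'   alongside.
#' @export
pipeline_simulate <- function(config, out_dir, genotypes = "WT",
                              timepoints_min = c(0, 30, 90)) {
  t0 <- as.numeric(Sys.time())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- sim_truth(config)
  paths <- list()
  p <- file.path(out_dir, "genome.chrom.sizes")
  write_chrom_sizes(truth$genome, p); paths$genome <- p
  ctrl <- simulate_control(config)
  p <- file.path(out_dir, "control.bedGraph")
  write_track(ctrl, p); paths$control <- p
  p <- file.path(out_dir, "origins_truth.bed")
  write_origins_bed(truth_catalog(truth), p, bin_size = config$bin_size)
  paths$origins_truth <- p
  write_midas_bed(truth$midas_regions,
                  file.path(out_dir, "midas_regions.bed"))
  paths$midas_regions <- file.path(out_dir, "midas_regions.bed")
  for (gt in genotypes) {
    for (cond in c("NE", "OE")) {
      tr <- simulate_edu_hu(config, cond, genotype = gt)$track
      p <- file.path(out_dir, sprintf("edu_%s_%s.bedGraph", gt, cond))
      write_track(tr, p)
      paths[[sprintf("edu_%s_%s", gt, cond)]] <- p
    }
    rel <- simulate_release(config, timepoints_min, genotype = gt)
    for (nm in names(rel$tracks)) {
      p <- file.path(out_dir, sprintf("release_%s_%s.bedGraph", gt, nm))
      write_track(rel$tracks[[nm]], p)
      paths[[sprintf("release_%s_%s", gt, nm)]] <- p
    }
    fb <- simulate_fibers(config, genotype = gt)
    p <- file.path(out_dir, sprintf("fibers_%s.tsv", gt))
    write_fibers(fb, p); paths[[sprintf("fibers_%s", gt)]] <- p
    md <- simulate_midas(config, genotype = gt)
    p <- file.path(out_dir, sprintf("midas_%s.bedGraph", gt))
    write_track(md$track, p); paths[[sprintf("midas_%s", gt)]] <- p
    p <- file.path(out_dir, sprintf("foci_%s.tsv", gt))
    utils::write.table(md$foci, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[sprintf("foci_%s", gt)]] <- p
  }
  .write_manifest("simulate", out_dir,
                  params = list(seed = config$seed,
                                n_origins = config$n_origins,
                                genotypes = genotypes,
                                timepoints_min = timepoints_min),
                  inputs = list(), outputs = paths, t0 = t0)
  invisible(paths)
}

#' Sigma track from EdU and control bedGraphs
#'
#' Reads the sample and control count tracks, normalizes, converts to sigma
#' values and writes the result as bedGraph (optionally BigWig).
#'
#' @param sample_path,control_path bedGraph count tracks.
#' @param genome_path chrom.sizes file.
#' @param out Output sigma bedGraph path.
#' @param bin_size Bin width; default 10000.
#' @param bigwig Also write a `.bw` next to `out`.
#' @return The `sigma_track`, invisibly.
#' @export
pipeline_sigma <- function(sample_path, control_path, genome_path, out,
                           bin_size = 10000, bigwig = FALSE) {
  t0 <- as.numeric(Sys.time())
  .need_files("sigma", sample_path, control_path, genome_path)
  genome <- read_chrom_sizes(genome_path, bin_size)
  smp <- read_track(sample_path, genome)
  ctl <- read_track(control_path, genome)
  sig <- sigma_from_tracks(smp, ctl)
  write_sigma(sig, out)
  outs <- list(sigma = out)
  if (bigwig) {
    bw <- sub("\\.[^.]+$", ".bw", out)
    write_bigwig(sig, bw); outs$bigwig <- bw
  }
  message(sprintf("[sigma] %d bins, %d masked, background lambda %.2f",
                  length(sig$sigma), sum(sig$sigma$mask),
                  sig$background_mean))
  .write_manifest("sigma", dirname(out),
                  params = list(bin_size = bin_size),
                  inputs = list(sample_path, control_path, genome_path),
                  outputs = outs, t0 = t0)
  invisible(sig)
}

#' Origin catalog and cross-sample correlation from sigma tracks
#'
#' Calls origin peaks on the NE track (or takes an external origin BED),
#' quantifies per-origin efficiency in the NE and OE tracks, classifies
#' origins by OE/NE fold-change, and — when a second sample's tracks are
#' given — correlates per-class efficiencies between the two samples.
#'
#' @param sigma_ne_path,sigma_oe_path Sigma bedGraphs of the reference sample.
#' @param genome_path chrom.sizes file.
#' @param out_dir Output directory.
#' @param origins_bed Optional BED of known origins (bypasses peak calling).
#' @param compare_ne_path Optional sigma bedGraph of a second sample (same
#'   condition as `sigma_ne_path`) for the correlation report.
#' @param bin_size Bin width; default 10000.
#' @param min_sigma_excess,min_run Peak-calling parameters (see
#'   [call_peaks()]).
#' @param pseudocount Classification pseudocount (see [classify_origins()]).
#' @return List with `catalog` and (if requested) `correlation`, invisibly.
#' @export
pipeline_origins <- function(sigma_ne_path, sigma_oe_path, genome_path,
                             out_dir, origins_bed = NULL,
                             compare_ne_path = NULL, bin_size = 10000,
                             min_sigma_excess = 3, min_run = 2,
                             pseudocount = 1) {
  t0 <- as.numeric(Sys.time())
  .need_files("origins", sigma_ne_path, sigma_oe_path, genome_path,
              origins_bed, compare_ne_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_chrom_sizes(genome_path, bin_size)
  sig_ne <- read_sigma(sigma_ne_path, genome, condition = "NE")
  sig_oe <- read_sigma(sigma_oe_path, genome, condition = "OE")
  loci <- if (is.null(origins_bed)) {
    call_peaks(sig_ne, min_sigma_excess = min_sigma_excess,
               min_run = min_run)
  } else {
    read_origins_bed(origins_bed, genome)
  }
  eff_ne <- quantify_efficiency(sig_ne, loci)
  eff_oe <- quantify_efficiency(sig_oe, loci)
  catalog <- origin_catalog(loci, eff_ne, eff_oe, pseudocount = pseudocount)
  bed <- file.path(out_dir, "origin_catalog.bed")
  write_origins_bed(catalog, bed, bin_size = bin_size)
  outs <- list(catalog = bed)
  message(sprintf("[origins] %d origins called (%s)", nrow(catalog),
                  paste(sprintf("%s=%d", levels(catalog$class),
                                table(catalog$class)), collapse = ", ")))
  result <- list(catalog = catalog)
  if (!is.null(compare_ne_path)) {
    sig_b <- read_sigma(compare_ne_path, genome, condition = "NE")
    corr <- correlate_catalogs(catalog, sig_ne, sig_b)
    ctsv <- file.path(out_dir, "correlation_summary.tsv")
    utils::write.table(as.data.frame(corr), ctsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outs$correlation <- ctsv
    result$correlation <- corr
  }
  .write_manifest("origins", out_dir,
                  params = list(bin_size = bin_size,
                                min_sigma_excess = min_sigma_excess,
                                min_run = min_run, pseudocount = pseudocount,
                                external_origins = !is.null(origins_bed)),
                  inputs = c(list(sigma_ne_path, sigma_oe_path, genome_path),
                             Filter(Negate(is.null),
                                    list(origins_bed, compare_ne_path))),
                  outputs = outs, t0 = t0)
  invisible(result)
}

#' Metagene fork-recovery analysis from release-timecourse sigma tracks
#'
#' Adjusts each release-timepoint sigma track against the 0-min (no-release)
#' track, computes the metagene profile of adjusted sigma around the supplied
#' origins, writes the profiles as TSV, and estimates the fork progression
#' rate from the growth of the profile half-width.
#'
#' @param sigma_paths Named list/vector of sigma bedGraphs; names are the
#'   timepoints in minutes (e.g. `c("30" = ..., "90" = ...)`).
#' @param zero_path Sigma bedGraph of the 0-min sample.
#' @param origins_bed BED of origins to centre windows on.
#' @param genome_path chrom.sizes file.
#' @param out_dir Output directory.
#' @param bin_size Bin width; default 10000.
#' @param half_window_bp Metagene half-window; default 300000.
#' @param n_boot,seed Bootstrap settings for [estimate_progression()].
#' @return List with `profiles` and `progression`, invisibly.
#' @export
pipeline_forks <- function(sigma_paths, zero_path, origins_bed, genome_path,
                           out_dir, bin_size = 10000, half_window_bp = 300000,
                           n_boot = 1000, seed = 1) {
  t0 <- as.numeric(Sys.time())
  .need_files("forks", unlist(sigma_paths), zero_path, origins_bed,
              genome_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_chrom_sizes(genome_path, bin_size)
  sig0 <- read_sigma(zero_path, genome, timepoint_min = 0)
  loci <- read_origins_bed(origins_bed, genome)
  profiles <- list(); outs <- list()
  for (nm in names(sigma_paths)) {
    tp <- as.numeric(nm)
    sig <- read_sigma(sigma_paths[[nm]], genome, timepoint_min = tp)
    asig <- adjust_sigma(sig, sig0)
    prof <- metagene(asig, loci, half_window_bp = half_window_bp)
    profiles[[nm]] <- prof
    p <- file.path(out_dir, sprintf("metagene_t%s.tsv", nm))
    utils::write.table(as.data.frame(prof)[, c("offset", "mean_asigma", "n")],
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    outs[[paste0("metagene_t", nm)]] <- p
  }
  prog <- estimate_progression(profiles, n_boot = n_boot, seed = seed)
  ptsv <- file.path(out_dir, "progression.tsv")
  utils::write.table(
    data.frame(rate_kb_min = prog$rate_kb_min,
               ci_lo = prog$ci[1], ci_hi = prog$ci[2],
               fwhm = paste(sprintf("%s:%0.0f", names(prog$fwhm_bp),
                                    prog$fwhm_bp), collapse = ";")),
    ptsv, sep = "\t", quote = FALSE, row.names = FALSE)
  outs$progression <- ptsv
  message(sprintf("[forks] %d origins, rate %.3f kb/min [%.3f, %.3f]",
                  nrow(loci), prog$rate_kb_min, prog$ci[1], prog$ci[2]))
  .write_manifest("forks", out_dir,
                  params = list(bin_size = bin_size,
                                half_window_bp = half_window_bp,
                                n_boot = n_boot, seed = seed),
                  inputs = c(as.list(unlist(sigma_paths)),
                             list(zero_path, origins_bed, genome_path)),
                  outputs = outs, t0 = t0)
  invisible(list(profiles = profiles, progression = prog))
}

#' Fiber fork-rate statistics from a fiber TSV
#'
#' Converts IdU track lengths to fork rates and runs the two-way
#' ANOVA/Fisher's LSD comparison across genotype-condition groups.
#'
#' @param fiber_tsv TSV with columns `sample`, `condition`, `cldu_um`,
#'   `idu_um`.
#' @param out_dir Output directory.
#' @param kb_per_um Stretching factor; default 2.0.
#' @param idu_duration_min IdU labelling duration; default 40.
#' @return List with `rates` and `report`, invisibly.
#' @export
pipeline_fibers <- function(fiber_tsv, out_dir, kb_per_um = 2.0,
                            idu_duration_min = 40) {
  t0 <- as.numeric(Sys.time())
  .need_files("fibers", fiber_tsv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fibers <- read_fibers(fiber_tsv, idu_duration_min = idu_duration_min)
  rates <- fiber_rates(fibers, kb_per_um = kb_per_um)
  rtsv <- file.path(out_dir, "fiber_rates.tsv")
  utils::write.table(rates, rtsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report <- compare_fiber_groups(rates)
  ctsv <- file.path(out_dir, "fiber_lsd.tsv")
  utils::write.table(report$contrasts, ctsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message(sprintf("[fibers] %d fibers in %d groups", nrow(rates),
                  nrow(report$design)))
  .write_manifest("fibers", out_dir,
                  params = list(kb_per_um = kb_per_um,
                                idu_duration_min = idu_duration_min),
                  inputs = list(fiber_tsv),
                  outputs = list(rates = rtsv, lsd = ctsv), t0 = t0)
  invisible(list(rates = rates, report = report))
}

#' MiDAS region profiles and foci positivity from track and tables
#'
#' Computes the average MiDAS-seq signal profile and the ranked per-region
#' heatmap matrix over a region set, and/or the MiDAS-positive fraction per
#' genotype from an EdU-foci table.
#'
#' @param sigma_path Optional sigma bedGraph of a MiDAS-seq sample.
#' @param regions_bed Optional BED4 region set (required with `sigma_path`).
#' @param foci_tsv Optional TSV with columns `genotype`, `n_edu_foci`.
#' @param genome_path chrom.sizes file (required with `sigma_path`).
#' @param out_dir Output directory.
#' @param bin_size Bin width; default 10000.
#' @param min_foci Positivity threshold; default 2.
#' @return List with `profiles` and/or `fractions`, invisibly.
#' @export
pipeline_midas <- function(sigma_path = NULL, regions_bed = NULL,
                           foci_tsv = NULL, genome_path = NULL, out_dir,
                           bin_size = 10000, min_foci = 2) {
  t0 <- as.numeric(Sys.time())
  .need_files("midas", sigma_path, regions_bed, foci_tsv, genome_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- list(); result <- list()
  if (!is.null(sigma_path)) {
    if (is.null(regions_bed) || is.null(genome_path))
      stop("[midas] sigma_path requires regions_bed and genome_path")
    genome <- read_chrom_sizes(genome_path, bin_size)
    sig <- read_sigma(sigma_path, genome)
    regions <- read_midas_bed(regions_bed)
    prof <- region_profiles(sig, regions)
    avg <- file.path(out_dir, "midas_average_profile.tsv")
    utils::write.table(data.frame(position = prof$positions,
                                  mean_sigma = prof$average),
                       avg, sep = "\t", quote = FALSE, row.names = FALSE)
    mat <- file.path(out_dir, "midas_heatmap_matrix.tsv")
    utils::write.table(
      data.frame(region_id = rownames(prof$matrix), prof$matrix,
                 check.names = FALSE),
      mat, sep = "\t", quote = FALSE, row.names = FALSE)
    outs$average <- avg; outs$matrix <- mat
    result$profiles <- prof
  }
  if (!is.null(foci_tsv)) {
    foci <- utils::read.delim(foci_tsv, stringsAsFactors = FALSE)
    fr <- score_midas_positive(foci, min_foci = min_foci)
    ftsv <- file.path(out_dir, "midas_fractions.tsv")
    utils::write.table(fr, ftsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outs$fractions <- ftsv
    result$fractions <- fr
    message(sprintf("[midas] positivity: %s",
                    paste(sprintf("%s=%.3f", fr$genotype, fr$fraction),
                          collapse = ", ")))
  }
  .write_manifest("midas", out_dir,
                  params = list(bin_size = bin_size, min_foci = min_foci),
                  inputs = Filter(Negate(is.null),
                                  list(sigma_path, regions_bed, foci_tsv,
                                       genome_path)),
                  outputs = outs, t0 = t0)
  invisible(result)
}
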