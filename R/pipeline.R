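# Umbrella pipeline: generate -> measure -> summarize -> stats, with a
# run log making every exclusion and parameter choice traceable.

#' Run the full comparative analysis on a species summary table
#'
#' Executes the statistical layer in summary-only mode: group mean
#' comparison by inversion status, pairwise contrasts with the
#' Q = 1/(2m) FDR rule, the correlation set (heterochromatin vs
#' distance; distance vs area; distance vs proportion out; proportion
#' out vs area, with and without the large-dot outlier species), and
#' the phylogenetically pair-averaged correlation.
#'
#' @param summaries species summary table in the layout of
#'   \code{\link{loadSpeciesSummaryTable}}.
#' @param pairs species pairs in the layout of
#'   \code{\link{loadSpeciesPairs}}.
#' @param excludeOutlier species excluded in the sensitivity rerun of
#'   the proportion-out vs area correlation.
#' @param pairSingletons species retained unaveraged in the
#'   pair-averaged correlation.
#' @return list with elements \code{groups} (see
#'   \code{\link{groupMeanComparison}}), \code{contrasts} (see
#'   \code{\link{pairwiseContrasts}}) and \code{correlations} (named
#'   list of \code{\link{pearsonCorrelation}} results plus the
#'   pair-averaged one).
#' @examples
#' rep <- runSummaryStats(loadSpeciesSummaryTable(), loadSpeciesPairs())
#' rep$groups$meanPolymorphic
#' @export
runSummaryStats <- function(summaries, pairs,
                            excludeOutlier = "sig",
                            pairSingletons = c("sec", "pse")) {
  groups <- groupMeanComparison(summaries)
  contrasts <- pairwiseContrasts(pairs, summaries = summaries,
                                 pvalues = pairs$published_p)
  s <- summaries
  correlations <- list(
    hc_vs_distance = pearsonCorrelation(
      s$pct_heterochromatin, s$mean_distance_um),
    distance_vs_area = pearsonCorrelation(
      s$mean_distance_um, s$mean_area_um2),
    distance_vs_proportion = pearsonCorrelation(
      s$mean_distance_um, s$proportion_out),
    proportion_vs_area = pearsonCorrelation(
      s$proportion_out, s$mean_area_um2),
    proportion_vs_area_excl = pearsonCorrelation(
      s$proportion_out, s$mean_area_um2,
      labels = s$species, exclude = excludeOutlier),
    proportion_vs_area_pair_averaged = pairAveragedCorrelation(
      s[!is.na(s$mean_area_um2), ],
      "proportion_out", "mean_area_um2",
      pairs, singletons = pairSingletons))
  list(groups = groups, contrasts = contrasts,
       correlations = correlations)
}

#' Measure a directory of stacks
#'
#' Applies \code{\link{measureOocyte}} to every TIFF stack in a
#' directory and collects the per-oocyte rows plus a run log naming
#' each oocyte's configuration and, for excluded oocytes, the exclusion
#' reason mirroring the protocol's triage.
#'
#' @param stackDir directory of multi-page TIFF stacks.
#' @param pixelSizeXY,sectionThicknessZ physical scales (um) overriding
#'   sidecar metadata.
#' @param threshold,dipThreshold,dotAreaFraction measurement settings
#'   (see \code{\link{measureOocyte}}).
#' @return list: \code{measurements} (data.frame), \code{log}
#'   (character vector of per-oocyte decisions).
#' @export
measureStackDir <- function(stackDir, pixelSizeXY = NULL,
                            sectionThicknessZ = NULL,
                            threshold = "otsu", dipThreshold = 0.5,
                            dotAreaFraction = 0.25) {
  files <- sort(list.files(stackDir, pattern = "\\.tiff?$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no TIFF stacks found in ", stackDir)
  rows <- vector("list", length(files))
  log <- character(length(files))
  for (i in seq_along(files)) {
    id <- sub("\\.tiff?$", "", basename(files[i]))
    st <- readStack(files[i], pixelSizeXY = pixelSizeXY,
                    sectionThicknessZ = sectionThicknessZ)
    row <- measureOocyte(st, oocyteId = id, threshold = threshold,
                         dipThreshold = dipThreshold,
                         dotAreaFraction = dotAreaFraction)
    rows[[i]] <- row
    reason <- if (row$configuration %in%
                  c("both_out", "one_out_other_locatable")) "measured"
      else if (row$configuration == "none_out") "no chromosome out"
      else paste("excluded from distance:", row$configuration)
    log[i] <- sprintf("%s: configuration=%s (%s)", id,
                      row$configuration, reason)
  }
  list(measurements = do.call(rbind, rows), log = log)
}

#' Run the reproducible generate -> measure -> summarize -> stats
#' pipeline
#'
#' Synthesises \code{nStacks} oocyte stacks under a fixed seed, measures
#' each, summarises them as one species, and (when a summary table is
#' supplied) runs the comparative statistics in summary-only mode. All
#' outputs are plain CSV/text; identical config + seed give identical
#' outputs.
#'
#' @param outDir output directory (created).
#' @param nStacks number of synthetic stacks.
#' @param params a \linkS4class{SimulationParams} template; the seed
#'   slot is replaced by \code{seed + i} for stack i.
#' @param seed base seed.
#' @param summaryTable optional species summary table for the
#'   statistical layer (e.g. \code{\link{loadSpeciesSummaryTable}()}).
#' @param pairs species pairs for the contrasts; default the bundled
#'   pairs when \code{summaryTable} is given.
#' @return list: measurements, summary, stats (or NULL), logPath.
#' @export
runPipeline <- function(outDir, nStacks = 5L,
                        params = SimulationParams(), seed = 1L,
                        summaryTable = NULL, pairs = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stackDir <- file.path(outDir, "stacks")
  dir.create(stackDir, showWarnings = FALSE)
  for (i in seq_len(nStacks)) {
    p <- params
    p@seed <- as.integer(seed + i)
    sim <- generateOocyteStack(p)
    base <- file.path(stackDir, sprintf("oocyte_%03d", i))
    writeStack(sim$stack, paste0(base, ".tif"))
    writeGroundTruth(sim$truth, paste0(base, ".truth.txt"))
  }
  meas <- measureStackDir(stackDir)
  utils::write.csv(meas$measurements,
                   file.path(outDir, "measurements.csv"),
                   row.names = FALSE)
  summ <- suppressWarnings(
    summarizeSpecies(meas$measurements, species = "synthetic"))
  utils::write.csv(summ, file.path(outDir, "summary.csv"),
                   row.names = FALSE)
  stats <- NULL
  if (!is.null(summaryTable)) {
    if (is.null(pairs)) pairs <- loadSpeciesPairs()
    stats <- runSummaryStats(summaryTable, pairs)
    writeStatsReport(stats, file.path(outDir, "stats_report.txt"))
  }
  logPath <- file.path(outDir, "run_log.txt")
  writeLines(c(
    sprintf("seed: %d", seed),
    sprintf("n_stacks: %d", nStacks),
    sprintf("pixel_size_xy_um: %g", params@pixelSizeXY),
    sprintf("section_thickness_z_um: %g", params@sectionThicknessZ),
    sprintf("dip_threshold: 0.5"),
    "", meas$log), logPath)
  list(measurements = meas$measurements, summary = summ,
       stats = stats, logPath = logPath)
}

writeStatsReport <- function(stats, path) {
  g <- stats$groups
  lines <- c(
    "Group mean dot-dot distance by inversion status",
    sprintf("  polymorphic: %.2f um (n=%d)", g$meanPolymorphic, g$nPoly),
    sprintf("  monomorphic: %.2f um (n=%d)", g$meanMonomorphic, g$nMono),
    sprintf("  Welch t-test on species means: P = %.2f", g$p),
    "",
    "Pairwise inversion-type contrasts (poly - mono)")
  ct <- stats$contrasts
  for (i in seq_len(nrow(ct)))
    lines <- c(lines, sprintf(
      "  %s - %s: delta = %s um, p = %g, FDR cutoff = %.3f%s",
      ct$poly[i], ct$mono[i], format(ct$delta_printed[i]), ct$p[i],
      ct$fdr_cutoff[i], ifelse(ct$significant[i], " *", "")))
  lines <- c(lines, "", "Correlations (Pearson r, regression p)")
  for (nm in names(stats$correlations)) {
    co <- stats$correlations[[nm]]
    lines <- c(lines, sprintf("  %s: r = %.3f, p = %.3g, n = %d",
                              nm, co$r, co$p, co$n))
  }
  writeLines(lines, path)
  invisible(path)
}
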