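# Comparative statistical layer: species summaries, pairwise
# inversion-type contrasts with the Q = 1/(2m) step-up FDR rule, group
# mean comparisons, Pearson correlations with regression significance,
# and phylogenetic pair-averaging.

distanceEligibleConfigs <- c("both_out", "one_out_other_locatable")

#' Summarise one species' per-oocyte measurements
#'
#' Computes the species-level quantities of the survey: mean 3D dot-dot
#' distance over distance-eligible oocytes (both dots out, or one out
#' with the other locatable; same-side, extra-chromosome and abnormal
#' figures are excluded from distance but counted as out), the
#' proportion of oocytes with 1+ chromosomes out, and the mean dot
#' cross-sectional area. Warns when fewer than 30 distance-eligible
#' oocytes or fewer than 20 area measurements are available, the
#' sampling targets of the protocol.
#'
#' @param measurements data.frame with columns out_flag, configuration,
#'   distance_um, area1_um2, area2_um2 (the schema written by
#'   \code{\link{generateSpeciesDataset}} and
#'   \code{\link{measureOocyte}}).
#' @param species species label for the output row.
#' @return one-row data.frame: species, mean_distance_um, n_out,
#'   n_total, proportion_out, mean_area_um2, n_distance, n_area.
#' @export
summarizeSpecies <- function(measurements, species = "species") {
  stopifnot(all(c("out_flag", "configuration", "distance_um") %in%
                names(measurements)))
  elig <- measurements$configuration %in% distanceEligibleConfigs &
    !is.na(measurements$distance_um)
  nOut <- sum(measurements$out_flag, na.rm = TRUE)
  nTot <- nrow(measurements)
  areas <- c(measurements$area1_um2, measurements$area2_um2)
  areas <- areas[!is.na(areas)]
  if (sum(elig) < 30L)
    warning(sprintf("%s: only %d distance-eligible oocytes (target 30)",
                    species, sum(elig)))
  if (length(areas) < 20L)
    warning(sprintf("%s: only %d area measurements (target 20)",
                    species, length(areas)))
  data.frame(
    species = species,
    mean_distance_um = if (any(elig))
      mean(measurements$distance_um[elig]) else NA_real_,
    n_out = nOut,
    n_total = nTot,
    proportion_out = if (nTot > 0) proportionOut(nOut, nTot) else NA_real_,
    mean_area_um2 = if (length(areas)) mean(areas) else NA_real_,
    n_distance = sum(elig),
    n_area = length(areas),
    stringsAsFactors = FALSE)
}

#' Step-up false discovery rate evaluation with custom Q
#'
#' Implements the FDR rule used for the pairwise contrasts: with m tests
#' ranked by ascending p-value, the per-rank cutoff is (i/m) * Q, and
#' significance is granted to every test whose rank is at or below the
#' largest rank i whose p-value falls strictly below its cutoff. The
#' default Q = 1/(2m) gives cutoffs i/(2 m^2) — a deliberately
#' conservative choice for small test families.
#'
#' @param pvalues numeric p-values in (0, 1].
#' @param Q the FDR budget; default \code{1/(2 * length(pvalues))}.
#' @return data.frame in input order: p, rank, cutoff, significant.
#'   Ties in p share the input order (stable ranking).
#' @examples
#' fdrEvaluate(c(2.2e-16, 0.017, 0.018, 0.065, 0.0755, 0.1145))
#' @export
fdrEvaluate <- function(pvalues, Q = NULL) {
  m <- length(pvalues)
  if (m == 0L)
    return(data.frame(p = numeric(0), rank = integer(0),
                      cutoff = numeric(0), significant = logical(0)))
  if (any(is.na(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  if (is.null(Q)) Q <- 1 / (2 * m)
  ord <- order(pvalues)              # stable for ties
  ranks <- integer(m); ranks[ord] <- seq_len(m)
  cutoff <- (ranks / m) * Q
  passes <- pvalues < cutoff
  maxRank <- if (any(passes)) max(ranks[passes]) else 0L
  data.frame(p = pvalues, rank = ranks, cutoff = cutoff,
             significant = ranks <= maxRank)
}

#' Pairwise contrasts between inversion-type divergent species pairs
#'
#' For each (polymorphic, monomorphic) species pair, computes the mean
#' distance difference poly - mono and a two-sided Welch t-test on the
#' per-oocyte distances, then applies \code{\link{fdrEvaluate}} across
#' the m pairs. In summary-only mode (no per-oocyte data) the deltas
#' come from species mean distances and externally supplied p-values
#' (e.g. published ones) are carried through the FDR step.
#'
#' @param pairs data.frame with columns \code{poly} and \code{mono}
#'   (species labels).
#' @param summaries species summary table with columns species and
#'   mean_distance_um (summary-only mode).
#' @param measurements per-oocyte table with columns species,
#'   configuration and distance_um (per-oocyte mode; overrides
#'   summaries for both delta and p).
#' @param pvalues optional p-values for summary-only mode, in pair
#'   order.
#' @param Q FDR budget passed to \code{\link{fdrEvaluate}}.
#' @return data.frame: poly, mono, delta_um, delta_printed (2
#'   significant figures), p, rank, fdr_cutoff, significant.
#' @export
pairwiseContrasts <- function(pairs, summaries = NULL,
                              measurements = NULL, pvalues = NULL,
                              Q = NULL) {
  m <- nrow(pairs)
  delta <- numeric(m)
  p <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    poly <- pairs$poly[i]; mono <- pairs$mono[i]
    if (!is.null(measurements)) {
      dOf <- function(sp) {
        rows <- measurements$species == sp &
          measurements$configuration %in% distanceEligibleConfigs &
          !is.na(measurements$distance_um)
        if (!any(rows)) stop("no distance measurements for species ", sp)
        measurements$distance_um[rows]
      }
      a <- dOf(poly); b <- dOf(mono)
      delta[i] <- mean(a) - mean(b)
      if (identical(a, b)) {
        p[i] <- 1
      } else {
        p[i] <- stats::t.test(a, b)$p.value   # Welch, two-sided
      }
    } else {
      mOf <- function(sp) {
        j <- match(sp, summaries$species)
        if (is.na(j)) stop("unknown species: ", sp)
        summaries$mean_distance_um[j]
      }
      delta[i] <- mOf(poly) - mOf(mono)
    }
  }
  if (!is.null(pvalues)) p <- pvalues
  res <- data.frame(poly = pairs$poly, mono = pairs$mono,
                    delta_um = delta,
                    delta_printed = signif(delta, 2),
                    stringsAsFactors = FALSE)
  if (all(!is.na(p))) {
    fdr <- fdrEvaluate(p, Q = Q)
    res$p <- p
    res$rank <- fdr$rank
    res$fdr_cutoff <- fdr$cutoff
    res$significant <- fdr$significant
  }
  res
}

#' Compare mean dot-dot distance between inversion groups
#'
#' Unweighted means of the species mean distances for species with and
#' without common inversions, compared by a two-sided Welch t-test on
#' the species means. Species without a distance (no free dot
#' chromosome) are excluded.
#'
#' @param summaries table with columns species, common_inversions
#'   (logical or "Yes"/"No") and mean_distance_um.
#' @return list: meanPolymorphic, meanMonomorphic, delta, p, nPoly,
#'   nMono.
#' @export
groupMeanComparison <- function(summaries) {
  inv <- summaries$common_inversions
  if (!is.logical(inv)) inv <- inv %in% c("Yes", "yes", "TRUE", "true")
  keep <- !is.na(summaries$mean_distance_um)
  poly <- summaries$mean_distance_um[keep & inv]
  mono <- summaries$mean_distance_um[keep & !inv]
  if (length(poly) < 2L || length(mono) < 2L)
    stop("each inversion group needs at least two species with distances")
  tt <- stats::t.test(poly, mono)
  list(meanPolymorphic = mean(poly), meanMonomorphic = mean(mono),
       delta = mean(poly) - mean(mono), p = tt$p.value,
       nPoly = length(poly), nMono = length(mono))
}

#' Pearson correlation with regression significance
#'
#' Pearson r on pairwise-complete observations, with the two-sided
#' p-value of the corresponding regression slope obtained through the t
#' transform \code{t = r * sqrt(n - 2) / sqrt(1 - r^2)} on n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @param labels optional observation labels (species), used with
#'   \code{exclude}.
#' @param exclude labels to drop before the analysis.
#' @return list: r, p, n, excluded.
#' @examples
#' pearsonCorrelation(1:10, 2 * (1:10) + 1)$r   # exactly 1
#' @export
pearsonCorrelation <- function(x, y, labels = NULL, exclude = NULL) {
  if (!is.null(exclude)) {
    if (is.null(labels)) stop("exclude requires labels")
    keep <- !(labels %in% exclude)
    x <- x[keep]; y <- y[keep]
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) .Machine$double.xmin else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n,
       excluded = if (is.null(exclude)) character(0) else exclude)
}

#' Correlation after phylogenetic pair-averaging
#'
#' Replaces each closely related species pair by the midpoint of its two
#' species' values (in both variables) while retaining unpaired species
#' as they are, then computes the Pearson correlation on the reduced
#' points. This removes the pseudo-replication of sister species that
#' share most of their evolutionary history.
#'
#' @param data table with a \code{species} column and the two variables.
#' @param xVar,yVar column names of the variables to correlate.
#' @param pairs data.frame with columns poly, mono (each species in at
#'   most one pair).
#' @param singletons species retained unaveraged.
#' @return list: r, p, n (number of points after averaging).
#' @export
pairAveragedCorrelation <- function(data, xVar, yVar, pairs,
                                    singletons = character(0)) {
  paired <- c(pairs$poly, pairs$mono)
  if (anyDuplicated(paired))
    stop("a species appears in more than one pair")
  if (any(singletons %in% paired))
    stop("a singleton species also appears in a pair")
  val <- function(sp, var) {
    j <- match(sp, data$species)
    if (is.na(j)) stop("unknown species: ", sp)
    data[[var]][j]
  }
  xs <- ys <- numeric(0)
  for (i in seq_len(nrow(pairs))) {
    xs <- c(xs, mean(c(val(pairs$poly[i], xVar),
                       val(pairs$mono[i], xVar))))
    ys <- c(ys, mean(c(val(pairs$poly[i], yVar),
                       val(pairs$mono[i], yVar))))
  }
  for (sp in singletons) {
    xs <- c(xs, val(sp, xVar))
    ys <- c(ys, val(sp, yVar))
  }
  res <- pearsonCorrelation(xs, ys)
  list(r = res$r, p = res$p, n = res$n)
}
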