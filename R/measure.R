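# The image-measurement protocol: out-classification by a 50% dip in
# background-subtracted intensity along a line profile, outer-edge XY
# distance, light-cone Z localisation, 3D distance by the Pythagorean
# theorem, and cross-sectional area.

#' Estimate the background intensity of an image or profile
#'
#' Background is the median of the lowest-decile intensities, a robust
#' low-order statistic of the off-chromosome field. The karyosome
#' occupies a small fraction of the field, so the lowest decile is
#' dominated by true background.
#'
#' @param x numeric vector (line profile) or matrix (image).
#' @return a single background intensity, between 0 and \code{max(x)}.
#' @examples
#' estimateBackground(c(rep(20, 10), 200, 180, rep(20, 10)))
#' @export
estimateBackground <- function(x) {
  v <- as.numeric(x)
  if (length(v) == 0L) stop("empty input")
  q <- stats::quantile(v, 0.10, names = FALSE, type = 7)
  low <- v[v <= q]
  max(0, stats::median(low))
}

findLocalMaxima <- function(v) {
  # indices of local maxima, plateaus reported at their midpoint
  n <- length(v)
  if (n < 3L) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    leftUp <- i == 1L || r$values[i - 1L] < r$values[i]
    rightUp <- i == k || r$values[i + 1L] < r$values[i]
    if (leftUp && rightUp && !(i == 1L && i == k))
      out <- c(out, as.integer(floor((starts[i] + ends[i]) / 2)))
  }
  out
}

#' Classify a dot chromosome as out on the spindle from a line profile
#'
#' A chromosome is scored "out" when the background-subtracted intensity
#' along a line from the dot across the gap to the adjacent chromosome
#' dips to at most 50\% of the reference peak. The reference is the
#' lower of the two flanking background-subtracted peaks, so a dip
#' relative to the dimmer structure guarantees a dip relative to both.
#' A dip of exactly 50\% counts as out.
#'
#' @param profile numeric vector of intensities sampled along the line,
#'   running from the dot peak to the adjacent chromosome peak.
#' @param background background intensity to subtract; by default
#'   estimated from the profile itself via
#'   \code{\link{estimateBackground}}.
#' @param dipThreshold dip depth defining "out"; default 0.5.
#' @return character: \code{"out"}, \code{"not_out"}, or
#'   \code{"abnormal"} when fewer than two peaks are detectable.
#' @examples
#' # dot peak 180, valley 80, adjacent peak 220, background 20:
#' # bg-subtracted valley 60 vs reference 160 -> 37.5% of peak -> out
#' classifyDotOut(c(20, 180, 80, 220, 20), background = 20)
#' @export
classifyDotOut <- function(profile, background = NULL,
                           dipThreshold = 0.5) {
  v <- as.numeric(profile)
  if (length(v) < 3L) return("abnormal")
  if (is.null(background)) background <- estimateBackground(v)
  b <- pmax(v - background, 0)
  peaks <- findLocalMaxima(b)
  peaks <- peaks[b[peaks] > 0]
  if (length(peaks) < 2L) return("abnormal")
  i1 <- peaks[1L]
  i2 <- peaks[length(peaks)]
  ref <- min(b[i1], b[i2])
  valley <- min(b[i1:i2])
  if (valley <= dipThreshold * ref) "out" else "not_out"
}

#' Segment chromosome blobs in a projected image
#'
#' Thresholds the maximum-intensity projection (Otsu by default, or an
#' absolute intensity override) and labels connected components. Blobs
#' are returned sorted by area, largest first; blobs smaller than
#' \code{dotAreaFraction} of the largest blob are flagged as
#' dot-chromosome candidates.
#'
#' @param img numeric matrix (projected image).
#' @param threshold \code{"otsu"} or an absolute intensity.
#' @param dotAreaFraction area fraction of the largest blob below which
#'   a blob is a dot candidate; default 0.25.
#' @param pixelSizeXY XY pixel size (um) used for areas.
#' @return a list of blobs, each a list with elements \code{pixels}
#'   (2-column matrix of row, col indices, 1-based), \code{centroid}
#'   (row, col), \code{areaPx}, \code{areaUm2}, \code{peak},
#'   \code{isDot}; empty list when nothing is above threshold.
#' @export
segmentBlobs <- function(img, threshold = "otsu", dotAreaFraction = 0.25,
                         pixelSizeXY = 0.054) {
  if (length(img) == 0L) stop("empty image")
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (rng[1] == rng[2]) return(list())
    thr <- EBImage::otsu(EBImage::Image(img), range = rng, levels = 256)
  } else {
    thr <- as.numeric(threshold)
  }
  mask <- img > thr
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- EBImage::imageData(lab)
  nlab <- max(lab)
  blobs <- vector("list", nlab)
  for (i in seq_len(nlab)) {
    idx <- which(lab == i, arr.ind = TRUE)
    blobs[[i]] <- list(
      pixels = idx,
      centroid = colMeans(idx),
      areaPx = nrow(idx),
      areaUm2 = nrow(idx) * pixelSizeXY^2,
      peak = max(img[idx]))
  }
  ord <- order(vapply(blobs, `[[`, numeric(1), "areaPx"),
               decreasing = TRUE)
  blobs <- blobs[ord]
  amax <- blobs[[1L]]$areaPx
  for (i in seq_along(blobs))
    blobs[[i]]$isDot <- blobs[[i]]$areaPx < dotAreaFraction * amax
  blobs
}

#' Outer-edge XY distance between two blobs
#'
#' The length of the segment joining the two blobs' outer edges: the
#' span between the farthest-apart boundary pixels of the two blobs
#' along the direction of the line through their centroids, extended by
#' one pixel on each side (the outer face of the edge pixels), converted
#' to micrometres.
#'
#' @param blobA,blobB blobs as returned by \code{\link{segmentBlobs}}.
#' @param pixelSizeXY XY pixel size (um).
#' @return distance in micrometres; 0 (with a warning) for overlapping
#'   blobs.
#' @examples
#' a <- list(pixels = cbind(10, 10), centroid = c(10, 10))
#' b <- list(pixels = cbind(10, 110), centroid = c(10, 110))
#' xyDistance(a, b, pixelSizeXY = 0.054)  # (100 + 2) * 0.054
#' @export
xyDistance <- function(blobA, blobB, pixelSizeXY = 0.054) {
  keyA <- paste(blobA$pixels[, 1], blobA$pixels[, 2])
  keyB <- paste(blobB$pixels[, 1], blobB$pixels[, 2])
  if (any(keyA %in% keyB)) {
    warning("blobs overlap; XY distance set to 0")
    return(0)
  }
  u <- blobB$centroid - blobA$centroid
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(0)
  u <- u / nu
  projA <- blobA$pixels %*% u
  projB <- blobB$pixels %*% u
  span <- max(projA, projB) - min(projA, projB)
  (span + 2) * pixelSizeXY
}

lightConeCenter <- function(stack, blob) {
  vox <- if (is(stack, "ConfocalStack")) voxels(stack) else stack
  nz <- dim(vox)[1]
  idx <- blob$pixels
  prof <- vapply(seq_len(nz), function(s) {
    sum(vox[s, , ][idx])
  }, numeric(1))
  if (all(prof == 0)) stop("blob has no intensity in the stack")
  which.max(prof) - 1L   # 0-based section index
}

#' Z offset between two blobs in confocal sections
#'
#' Localises each blob in Z at the centre of its light cone: the section
#' maximising the summed intensity over the blob's XY footprint. The
#' offset is the absolute difference of the two centre sections.
#'
#' @param stack a \linkS4class{ConfocalStack} or 3D array.
#' @param blobA,blobB blobs as returned by \code{\link{segmentBlobs}}.
#' @return integer section count (>= 0).
#' @export
zOffsetSections <- function(stack, blobA, blobB) {
  abs(lightConeCenter(stack, blobA) - lightConeCenter(stack, blobB))
}

#' 3D dot-dot distance from XY distance and section offset
#'
#' Combines the projected XY distance with the Z distance (sections
#' times section thickness) by the Pythagorean theorem:
#' \code{sqrt(dXY^2 + (zSections * sectionThickness)^2)}.
#'
#' @param dXY XY distance in the projected image (um), >= 0.
#' @param zSections number of sections between the light-cone centres.
#' @param sectionThickness section thickness (um), > 0.
#' @return 3D distance in micrometres.
#' @examples
#' compute3dDistance(3, 8, 0.5)   # 3-4-5 triangle -> 5
#' @export
compute3dDistance <- function(dXY, zSections, sectionThickness) {
  if (any(dXY < 0) || any(zSections < 0))
    stop("dXY and zSections must be non-negative")
  if (any(sectionThickness <= 0))
    stop("sectionThickness must be positive")
  sqrt(dXY^2 + (zSections * sectionThickness)^2)
}

#' Cross-sectional area of a blob
#'
#' Pixel count of the segmented blob converted to square micrometres.
#'
#' @param blob a blob as returned by \code{\link{segmentBlobs}}.
#' @param pixelSizeXY XY pixel size (um).
#' @return area in um^2.
#' @export
measureArea <- function(blob, pixelSizeXY = 0.054) {
  if (is.null(blob$pixels) || nrow(blob$pixels) == 0L)
    stop("empty blob")
  nrow(blob$pixels) * pixelSizeXY^2
}

#' Refine a dot blob at half its background-subtracted peak
#'
#' Global thresholds (Otsu) sit relative to the bright main mass, so
#' dimmer dot chromosomes segment systematically small. This re-grows a
#' dot candidate inside a local window at 50\% of its own
#' background-subtracted peak (the full-width-half-maximum footprint),
#' which is unbiased for a symmetric blur and robust to the mass/dot
#' brightness asymmetry. Only the connected component containing the
#' peak is kept.
#'
#' @param img projected image.
#' @param blob a dot-candidate blob from \code{\link{segmentBlobs}}.
#' @param background background intensity.
#' @param level fraction of the background-subtracted peak defining the
#'   footprint; default 0.5.
#' @param pixelSizeXY XY pixel size (um).
#' @return the refined blob (same structure as
#'   \code{\link{segmentBlobs}} output).
#' @export
refineDotBlob <- function(img, blob, background, level = 0.5,
                          pixelSizeXY = 0.054) {
  win <- max(4L, ceiling(3 * sqrt(blob$areaPx)))
  pk <- blob$pixels[which.max(img[blob$pixels]), , drop = FALSE]
  rs <- max(1L, pk[1] - win):min(nrow(img), pk[1] + win)
  cs <- max(1L, pk[2] - win):min(ncol(img), pk[2] + win)
  sub <- img[rs, cs, drop = FALSE]
  # anchor the level to the dot's own peak; the window may graze the
  # much brighter main mass. The peak is the median of the 3x3
  # neighbourhood of the maximum, which drops the upward selection
  # bias of a noisy argmax.
  nb <- img[max(1L, pk[1] - 1L):min(nrow(img), pk[1] + 1L),
            max(1L, pk[2] - 1L):min(ncol(img), pk[2] + 1L)]
  thr <- background + level * (stats::median(nb) - background)
  mask <- EBImage::fillHull(EBImage::Image(sub > thr))
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  keep <- lab[pk[1] - rs[1] + 1L, pk[2] - cs[1] + 1L]
  if (keep == 0) return(blob)
  idx <- which(lab == keep, arr.ind = TRUE)
  idx[, 1] <- idx[, 1] + rs[1] - 1L
  idx[, 2] <- idx[, 2] + cs[1] - 1L
  list(pixels = idx, centroid = colMeans(idx), areaPx = nrow(idx),
       areaUm2 = nrow(idx) * pixelSizeXY^2, peak = img[pk],
       isDot = TRUE)
}

#' Classify the oocyte configuration from dot candidates
#'
#' Applies the triage of the measurement protocol: oocytes with both
#' dots on the same side of the spindle, with additional nonexchange
#' chromosomes, or otherwise abnormal are excluded from distance
#' measurement but still counted toward the proportion of oocytes with
#' chromosomes out. Distance-eligible configurations are
#' \code{both_out} and \code{one_out_other_locatable}.
#'
#' @param dots data.frame with one row per dot candidate: logical
#'   \code{out} and numeric \code{side} (signed position along the
#'   spindle axis relative to the main mass).
#' @param otherLocatable for the single-candidate case, whether the
#'   companion dot can be located (e.g. as an intensity lobe at the
#'   mass edge).
#' @return a list with \code{configuration}, \code{outCount},
#'   \code{anyOut}, and \code{distanceEligible}.
#' @export
classifyConfiguration <- function(dots, otherLocatable = FALSE) {
  n <- nrow(dots)
  outCount <- if (n) sum(dots$out) else 0L
  lab <-
    if (n == 0L) "none_out"
    else if (n > 2L) "extra_nonexchange"
    else if (n == 2L && all(sign(dots$side) == sign(dots$side[1L])) &&
             outCount >= 1L) "both_same_side"
    else if (n == 2L && outCount == 2L) "both_out"
    else if (outCount == 1L && (n == 2L || otherLocatable))
      "one_out_other_locatable"
    else if (outCount == 0L) "none_out"
    else "abnormal"
  list(configuration = lab,
       outCount = as.integer(outCount),
       anyOut = outCount > 0L,
       distanceEligible = lab %in%
         c("both_out", "one_out_other_locatable"))
}

#' Proportion of oocytes with chromosomes out on the spindle
#'
#' The number of oocytes with one or more chromosomes out divided by the
#' total number of oocytes that matured past Prophase.
#'
#' @param nWithAnyOut oocytes with 1+ chromosomes out.
#' @param nTotalPastProphase total scored oocytes.
#' @return the exact quotient, in [0, 1].
#' @examples
#' proportionOut(71, 147)   # 0.48
#' proportionOut(14, 115)   # 0.12
#' @export
proportionOut <- function(nWithAnyOut, nTotalPastProphase) {
  if (nTotalPastProphase <= 0) stop("total oocyte count must be > 0")
  if (nWithAnyOut < 0 || nWithAnyOut > nTotalPastProphase)
    stop("out count must be between 0 and the total count")
  nWithAnyOut / nTotalPastProphase
}

# Bilinearly sample img along the segment p0 -> p1 (row, col), ~1 px step.
sampleLineProfile <- function(img, p0, p1) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(3L, ceiling(len) + 1L)
  t <- seq(0, 1, length.out = n)
  r <- p0[1] + t * (p1[1] - p0[1])
  c <- p0[2] + t * (p1[2] - p0[2])
  r0 <- pmin(pmax(floor(r), 1L), nrow(img) - 1L)
  c0 <- pmin(pmax(floor(c), 1L), ncol(img) - 1L)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Measure one oocyte stack
#'
#' Runs the full per-oocyte protocol: maximum-intensity projection,
#' segmentation, out-classification of each dot candidate by the 50\%
#' dip rule along the line from the dot to the main mass, configuration
#' triage, and — for distance-eligible configurations — outer-edge XY
#' distance, light-cone Z offset, 3D distance and dot areas.
#'
#' When only one dot candidate is segmented and it is out, the companion
#' dot is searched for as an intensity lobe along the line from the out
#' dot through the main mass (chromatin overlap makes an embedded dot
#' brighter than the mass around it); if found, the configuration is
#' \code{one_out_other_locatable} and the distance runs to the lobe's
#' outer edge, using the out dot's apparent radius for the embedded dot.
#'
#' @param stack a \linkS4class{ConfocalStack}.
#' @param oocyteId identifier for the output row.
#' @param threshold segmentation threshold policy (see
#'   \code{\link{segmentBlobs}}).
#' @param dipThreshold dip depth for the out rule; default 0.5.
#' @param dotAreaFraction dot-candidate area fraction; default 0.25.
#' @param minDotAreaPx minimum pixel area for a dot candidate; smaller
#'   blobs (noise specks) are ignored. Default 9 px, well below any
#'   plausible chromosome cross-section at 54 nm pixels.
#' @param smoothSigmaPx Gaussian smoothing (pixels) applied to every
#'   section of the stack (with a matched light axial pass) before
#'   projection; suppresses shot-like noise before the maximum
#'   projection can rectify it into an inflated background, without
#'   materially widening half-maximum footprints. 0 disables.
#'   Default 1.
#' @return one-row data.frame: oocyte_id, out_flag, configuration,
#'   d_xy_um, z_sections, distance_um, area1_um2, area2_um2.
#' @export
measureOocyte <- function(stack, oocyteId = "oocyte",
                          threshold = "otsu", dipThreshold = 0.5,
                          dotAreaFraction = 0.25, minDotAreaPx = 9L,
                          smoothSigmaPx = 1) {
  stopifnot(is(stack, "ConfocalStack"))
  px <- pixelSizeXY(stack)
  dz <- sectionThicknessZ(stack)
  vox <- voxels(stack)
  if (smoothSigmaPx > 0) {
    vox <- blurAnisotropic3d(vox, sigmaZVox = 0.5,
                             sigmaXYVox = smoothSigmaPx)
    stack <- ConfocalStack(vox, pixelSizeXY = px,
                           sectionThicknessZ = dz)
  }
  proj <- maxProjection(vox)
  bg <- estimateBackground(proj)
  # absolute half-maximum footprints are anchored at the stack-wide
  # median: the projection's noise floor sits above true background
  # (a maximum projection rectifies noise), which would shrink them
  bgStack <- stats::median(vox)
  blobs <- segmentBlobs(proj, threshold = threshold,
                        dotAreaFraction = dotAreaFraction,
                        pixelSizeXY = px)

  empty <- data.frame(oocyte_id = oocyteId, out_flag = FALSE,
                      configuration = "none_out", d_xy_um = NA_real_,
                      z_sections = NA_integer_, distance_um = NA_real_,
                      area1_um2 = NA_real_, area2_um2 = NA_real_,
                      stringsAsFactors = FALSE)
  if (length(blobs) == 0L) return(empty)
  mass <- blobs[[1L]]
  dots <- blobs[-1L]
  dots <- dots[vapply(dots, `[[`, logical(1), "isDot") &
               vapply(dots, `[[`, numeric(1), "areaPx") >= minDotAreaPx]
  if (length(dots) == 0L) return(empty)
  dots <- lapply(dots, refineDotBlob, img = proj,
                 background = bgStack, pixelSizeXY = px)

  outFlag <- vapply(dots, function(d) {
    prof <- sampleLineProfile(proj, d$centroid, mass$centroid)
    identical(classifyDotOut(prof, background = bg,
                             dipThreshold = dipThreshold), "out")
  }, logical(1))
  side <- vapply(dots, function(d) {
    # signed position along the dot-mass axis; sides defined by the
    # principal axis through the mass centroid
    d$centroid[2] - mass$centroid[2]
  }, numeric(1))

  embedded <- NULL
  if (length(dots) == 1L && outFlag[1L]) {
    embedded <- locateEmbeddedDot(proj, dots[[1L]], mass, bg, px)
  }
  cls <- classifyConfiguration(
    data.frame(out = outFlag, side = side),
    otherLocatable = !is.null(embedded))

  res <- empty
  res$out_flag <- cls$anyOut
  res$configuration <- cls$configuration
  if (!cls$distanceEligible) return(res)

  if (length(dots) >= 2L) {
    a <- dots[[1L]]; b <- dots[[2L]]
    dxy <- xyDistance(a, b, pixelSizeXY = px)
    zs <- zOffsetSections(stack, a, b)
    res$area1_um2 <- measureArea(a, px)
    res$area2_um2 <- measureArea(b, px)
  } else {
    a <- dots[[1L]]
    dxy <- embedded$dXYUm
    zs <- abs(lightConeCenter(stack, a) -
              lightConeCenter(stack, embedded$blob))
    res$area1_um2 <- measureArea(a, px)
  }
  res$d_xy_um <- dxy
  res$z_sections <- as.integer(zs)
  res$distance_um <- compute3dDistance(dxy, zs, dz)
  res
}

# Locate a dot embedded at the mass edge as the intensity lobe along the
# line from the out dot through the mass, past the mass centroid.
locateEmbeddedDot <- function(proj, dot, mass, bg, px) {
  u <- mass$centroid - dot$centroid
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(NULL)
  u <- u / nu
  far <- mass$centroid + u * (nu + 2 * sqrt(mass$areaPx / pi))
  far[1] <- min(max(far[1], 1), nrow(proj))
  far[2] <- min(max(far[2], 1), ncol(proj))
  prof <- sampleLineProfile(proj, mass$centroid, far)
  if (length(prof) < 3L) return(NULL)
  pk <- which.max(prof)
  # a genuine lobe stands clearly above the mass plateau
  if (prof[pk] - bg < 1.25 * (prof[1L] - bg)) return(NULL)
  step <- sqrt(sum((far - mass$centroid)^2)) / (length(prof) - 1L)
  center <- mass$centroid + u * (pk - 1L) * step
  rApparent <- sqrt(dot$areaPx / pi)
  proj2 <- sum((center - dot$centroid) * u)  # centre-centre span, px
  blob <- list(pixels = cbind(round(center[1]), round(center[2])),
               centroid = center,
               areaPx = 1L, peak = prof[pk])
  # span from the out dot's centre, plus its apparent radius on the far
  # side, the embedded dot's radius (approximated by the out dot's) on
  # this side, and the one-pixel outer faces
  list(blob = blob,
       dXYUm = (proj2 + 2 * rApparent + 2) * px)
}
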