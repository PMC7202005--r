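# Synthetic Prometaphase I karyosome stacks with ground truth.
#
# Geometry is rendered in physical coordinates (um) on the voxel grid
# (0-based; voxel (s, r, c) has its centre at (s*dz, r*px, c*px)), as
# additive binary solids scaled by intensity, then blurred with a
# separable anisotropic Gaussian, offset by a constant background and
# degraded with additive Gaussian noise.

# Preserve the caller's RNG state while seeding deterministically.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

gaussKernel1d <- function(sigmaVox) {
  if (sigmaVox <= 0) return(1)
  K <- max(1L, ceiling(3 * sigmaVox))
  w <- exp(-((-K:K)^2) / (2 * sigmaVox^2))
  w / sum(w)
}

# Shift a 3D array by `by` voxels along `axis`, zero-padded.
shiftPad3d <- function(a, axis, by) {
  if (by == 0L) return(a)
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0L) 1:(n - by) else (1 - by):n
  dst <- if (by > 0L) (1 + by):n else 1:(n + by)
  ix <- rep(list(quote(expr = )), 3L)
  ixs <- ix; ixs[[axis]] <- src
  ixd <- ix; ixd[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), ixd,
                          list(do.call(`[`, c(list(a), ixs)))))
  out
}

blurAnisotropic3d <- function(a, sigmaZVox, sigmaXYVox) {
  for (axis in 1:3) {
    w <- gaussKernel1d(if (axis == 1L) sigmaZVox else sigmaXYVox)
    if (length(w) == 1L) next
    K <- (length(w) - 1L) %/% 2L
    acc <- array(0, dim(a))
    for (j in -K:K) acc <- acc + w[j + K + 1L] * shiftPad3d(a, axis, j)
    a <- acc
  }
  a
}

# Add a solid sphere (radius um) scaled by `value` into the accumulator,
# computed only inside its bounding box.
addSphere <- function(acc, centerUm, radiusUm, value, px, dz) {
  d <- dim(acc)
  zs <- pmax(0L, floor((centerUm[1] - radiusUm) / dz)):
        pmin(d[1] - 1L, ceiling((centerUm[1] + radiusUm) / dz))
  ys <- pmax(0L, floor((centerUm[2] - radiusUm) / px)):
        pmin(d[2] - 1L, ceiling((centerUm[2] + radiusUm) / px))
  xs <- pmax(0L, floor((centerUm[3] - radiusUm) / px)):
        pmin(d[3] - 1L, ceiling((centerUm[3] + radiusUm) / px))
  dz2 <- (zs * dz - centerUm[1])^2
  dy2 <- (ys * px - centerUm[2])^2
  dx2 <- (xs * px - centerUm[3])^2
  inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= radiusUm^2
  box <- acc[zs + 1L, ys + 1L, xs + 1L, drop = FALSE]
  acc[zs + 1L, ys + 1L, xs + 1L] <- box + value * inside
  acc
}

addEllipsoid <- function(acc, centerUm, radiusXYUm, radiusZUm, value,
                         px, dz) {
  d <- dim(acc)
  zs <- pmax(0L, floor((centerUm[1] - radiusZUm) / dz)):
        pmin(d[1] - 1L, ceiling((centerUm[1] + radiusZUm) / dz))
  ys <- pmax(0L, floor((centerUm[2] - radiusXYUm) / px)):
        pmin(d[2] - 1L, ceiling((centerUm[2] + radiusXYUm) / px))
  xs <- pmax(0L, floor((centerUm[3] - radiusXYUm) / px)):
        pmin(d[3] - 1L, ceiling((centerUm[3] + radiusXYUm) / px))
  dz2 <- ((zs * dz - centerUm[1]) / radiusZUm)^2
  dy2 <- ((ys * px - centerUm[2]) / radiusXYUm)^2
  dx2 <- ((xs * px - centerUm[3]) / radiusXYUm)^2
  inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
  box <- acc[zs + 1L, ys + 1L, xs + 1L, drop = FALSE]
  acc[zs + 1L, ys + 1L, xs + 1L] <- box + value * inside
  acc
}

#' Generate one synthetic oocyte stack with ground truth
#'
#' Renders a Prometaphase I karyosome: a bright exchange-chromosome mass
#' at the spindle midzone and dot-chromosome foci along the spindle (x)
#' axis. With \code{nDotsOut = 2} the foci are displaced toward opposite
#' poles so that their outer-edge 3D separation equals
#' \code{trueSeparation3d}; with \code{nDotsOut = 1} the second focus is
#' embedded at the mass boundary (its chromatin adds to the mass signal,
#' leaving a locatable intensity lobe); with \code{nDotsOut = 0} both
#' foci sit at the mass boundary. The \code{both_same_side} and
#' \code{extra_nonexchange} configurations reproduce the abnormal
#' figures the measurement protocol must exclude from distance
#' measurement while still counting them as "out".
#'
#' The dot centres are placed on exact section planes, so the Z offset in
#' the ground truth is an integer number of sections, matching how the
#' light-cone rule localises foci in Z.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @return a list with elements \code{stack} (\linkS4class{ConfocalStack})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' sim <- generateOocyteStack(SimulationParams(seed = 7L))
#' sim$truth
#' @export
generateOocyteStack <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  d <- params@dim
  px <- params@pixelSizeXY
  dz <- params@sectionThicknessZ
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  extentX <- (nx - 1) * px; extentY <- (ny - 1) * px
  extentZ <- (nz - 1) * dz

  rDot <- sqrt(rep(params@dotAreaUm2, length.out = 2L) / pi)
  rMass <- sqrt(params@mainMassAreaUm2 / pi)
  rMassZ <- max(dz, 0.75)
  massCenter <- c(floor((nz - 1) / 2) * dz, extentY / 2, extentX / 2)
  sMid <- floor((nz - 1) / 2)

  s3d <- params@trueSeparation3d
  k <- params@zOffsetSections
  if (is.na(k)) {
    k <- as.integer(round(0.25 * s3d / dz))
    while (k > 0L && k * dz >= s3d) k <- k - 1L
  }
  if (k * dz >= s3d && s3d > 0)
    stop("zOffsetSections * sectionThicknessZ must be below the 3D separation")
  zUm <- k * dz
  dXY <- if (s3d > 0) sqrt(s3d^2 - zUm^2) else 0
  # centre-to-centre XY span implied by the outer-edge convention
  cc <- dXY - sum(rDot) - 2 * px

  geom <- array(0, c(nz, ny, nx))
  geom <- addEllipsoid(geom, massCenter, rMass, rMassZ,
                       params@peakIntensity, px, dz)
  dotVal <- params@dotPeakFraction * params@peakIntensity
  pad <- 3 * params@blurSigmaXY + px
  clearance <- 0.15   # minimal um of dark gap between an out dot and the mass

  checkBounds <- function(center, radius) {
    if (center[3] - radius - pad < 0 || center[3] + radius + pad > extentX)
      stop("separation too large for stack bounds along cols (x)")
    if (center[2] - radius - pad < 0 || center[2] + radius + pad > extentY)
      stop("separation too large for stack bounds along rows (y)")
    if (center[1] < 0 || center[1] > extentZ)
      stop("separation too large for stack bounds along sections (z)")
  }

  config <- params@configuration
  centers <- NULL
  if (config == "normal") {
    if (params@nDotsOut == 2L) {
      if (cc / 2 - rMass - max(rDot) < clearance)
        stop("separation too small: dot foci would not clear the main mass")
      sA <- sMid - (k %/% 2L); sB <- sA + k
      if (sA < 0L || sB > nz - 1L)
        stop("separation too large for stack bounds along sections (z)")
      centers <- rbind(
        c(sA * dz, massCenter[2], massCenter[3] - cc / 2),
        c(sB * dz, massCenter[2], massCenter[3] + cc / 2))
    } else if (params@nDotsOut == 1L) {
      # dot B embedded just inside the -x boundary of the mass (its
      # chromatin adds to the mass signal, leaving a locatable lobe),
      # dot A out at +x
      xB <- massCenter[3] - rMass + rDot[2]
      xA <- xB + cc
      if (xA - massCenter[3] - rMass - rDot[1] < clearance)
        stop("separation too small: the out focus would not clear the main mass")
      sB <- sMid
      sA <- if (sMid + k <= nz - 1L) sMid + k else sMid - k
      if (sA < 0L || sA > nz - 1L)
        stop("separation too large for stack bounds along sections (z)")
      centers <- rbind(c(sA * dz, massCenter[2], xA),
                       c(sB * dz, massCenter[2], xB))
    } else {
      centers <- rbind(
        c(sMid * dz, massCenter[2], massCenter[3] - rMass),
        c(sMid * dz, massCenter[2], massCenter[3] + rMass))
    }
  } else if (config == "both_same_side") {
    off <- rMass + max(rDot) + 1.0
    dy <- 0.8
    centers <- rbind(
      c(sMid * dz, massCenter[2] - dy, massCenter[3] + off),
      c(sMid * dz, massCenter[2] + dy, massCenter[3] + off))
  } else {  # extra_nonexchange: three displaced foci
    off <- rMass + max(rDot) + 1.0
    centers <- rbind(
      c(sMid * dz, massCenter[2], massCenter[3] - off),
      c(sMid * dz, massCenter[2], massCenter[3] + off),
      c(sMid * dz, massCenter[2] + off, massCenter[3]))
  }
  radii <- rep(rDot, length.out = nrow(centers))
  for (i in seq_len(nrow(centers))) {
    checkBounds(centers[i, ], radii[i])
    geom <- addSphere(geom, centers[i, ], radii[i], dotVal, px, dz)
  }

  img <- blurAnisotropic3d(geom, params@blurSigmaZ / dz,
                           params@blurSigmaXY / px)
  img <- img + params@backgroundLevel
  if (params@noiseSD > 0)
    img <- withSeed(params@seed,
                    img + rnorm(length(img), 0, params@noiseSD))
  img <- pmin(pmax(img, 0), 65535)
  dim(img) <- c(nz, ny, nx)

  if (config == "normal" && params@nDotsOut > 0L) {
    tdXY <- abs(centers[2, 3] - centers[1, 3]) + sum(radii[1:2]) + 2 * px
    tz <- abs(centers[2, 1] - centers[1, 1])
    tsep <- sqrt(tdXY^2 + tz^2)
  } else {
    tdXY <- NA_real_; tz <- NA_real_; tsep <- NA_real_
  }
  truth <- new("GroundTruth",
    dotCentersUm = centers,
    dotAreasUm2 = pi * radii^2,
    dXYUm = tdXY, zOffsetUm = if (is.na(tdXY)) NA_real_ else tz,
    separation3dUm = tsep,
    configuration = config,
    nDotsOut = params@nDotsOut,
    seed = params@seed)

  list(stack = ConfocalStack(img, pixelSizeXY = px,
                             sectionThicknessZ = dz),
       truth = truth)
}

#' Generate a per-oocyte measurement table for one simulated species
#'
#' Emulates the sampling structure of a slide survey: each scored oocyte
#' independently shows one or more chromosomes out on the spindle with a
#' species-specific probability; oocytes with chromosomes out carry a
#' 3D dot-dot distance draw (normal, truncated at zero) decomposed into
#' an XY component and an integer section offset, plus two dot-area
#' draws.
#'
#' @param species species label.
#' @param nOocytes number of scored oocytes.
#' @param probabilityOut probability an oocyte has 1+ chromosomes out.
#' @param distanceMean,distanceSD 3D distance distribution (um).
#' @param areaMean,areaSD dot cross-sectional area distribution (um^2).
#' @param sectionThicknessZ section thickness used to decompose the
#'   distance draw (um).
#' @param seed integer seed; output is reproducible.
#' @return data.frame with columns oocyte_id, out_flag, configuration,
#'   d_xy_um, z_sections, distance_um, area1_um2, area2_um2.
#' @examples
#' tab <- generateSpeciesDataset("mel", nOocytes = 20,
#'   probabilityOut = 0.48, distanceMean = 11.33, distanceSD = 2,
#'   areaMean = 0.85, areaSD = 0.2, seed = 1L)
#' mean(tab$out_flag)
#' @export
generateSpeciesDataset <- function(species, nOocytes, probabilityOut,
                                   distanceMean, distanceSD,
                                   areaMean, areaSD,
                                   sectionThicknessZ = 0.5, seed = 1L) {
  if (nOocytes < 0) stop("nOocytes must be >= 0")
  if (probabilityOut < 0 || probabilityOut > 1)
    stop("probabilityOut must be in [0, 1]")
  if (distanceSD < 0 || areaSD < 0)
    stop("standard deviations must be non-negative")
  withSeed(seed, {
    out <- runif(nOocytes) < probabilityOut
    n <- nOocytes
    rtrunc0 <- function(n, mean, sd, strict = FALSE) {
      x <- rnorm(n, mean, sd)
      bad <- if (strict) x <= 0 else x < 0
      while (any(bad)) {
        x[bad] <- rnorm(sum(bad), mean, sd)
        bad <- if (strict) x <= 0 else x < 0
      }
      x
    }
    dist <- rep(NA_real_, n)
    a1 <- rep(NA_real_, n); a2 <- rep(NA_real_, n)
    zsec <- rep(NA_integer_, n)
    dxy <- rep(NA_real_, n)
    config <- rep("none_out", n)
    nout <- sum(out)
    if (nout > 0) {
      dist[out] <- rtrunc0(nout, distanceMean, distanceSD)
      a1[out] <- rtrunc0(nout, areaMean, areaSD, strict = TRUE)
      a2[out] <- rtrunc0(nout, areaMean, areaSD, strict = TRUE)
      config[out] <- sample(
        c("both_out", "one_out_other_locatable", "both_same_side"),
        nout, replace = TRUE, prob = c(0.6, 0.3, 0.1))
      kmax <- pmax(0L, pmin(4L, floor(dist[out] / sectionThicknessZ)))
      zsec[out] <- as.integer(floor(runif(nout) * (kmax + 1L)))
      dxy[out] <- sqrt(pmax(dist[out]^2 -
                            (zsec[out] * sectionThicknessZ)^2, 0))
    }
    data.frame(
      oocyte_id = sprintf("%s_%04d", species, seq_len(n)),
      out_flag = out,
      configuration = config,
      d_xy_um = dxy,
      z_sections = zsec,
      distance_um = dist,
      area1_um2 = a1,
      area2_um2 = a2,
      stringsAsFactors = FALSE)
  })
}
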