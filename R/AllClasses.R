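#' ConfocalStack: a single-channel confocal z-stack with physical scales
#'
#' Container for one 3D grayscale voxel grid (sections x rows x cols, Z
#' leading) together with the XY pixel size and the Z section thickness.
#' All downstream measurements (projection, segmentation, 3D dot-dot
#' distance) operate on this class.
#'
#' @slot voxels numeric 3D array, dimensions sections x rows x cols.
#' @slot pixelSizeXY XY pixel size in micrometres per pixel (> 0).
#' @slot sectionThicknessZ Z section thickness in micrometres (> 0).
#'
#' @examples
#' st <- ConfocalStack(array(0, c(4, 8, 8)), pixelSizeXY = 0.054,
#'                     sectionThicknessZ = 0.5)
#' dim(st)
#' @export
setClass("ConfocalStack",
  representation(
    voxels = "array",
    pixelSizeXY = "numeric",
    sectionThicknessZ = "numeric"
  )
)

setValidity("ConfocalStack", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L)
    return("voxels must be a 3D array (sections x rows x cols)")
  if (any(d < 1L))
    return("all stack dimensions must be >= 1")
  if (length(object@pixelSizeXY) != 1L || !is.finite(object@pixelSizeXY) ||
      object@pixelSizeXY <= 0)
    return("pixelSizeXY must be a single positive number (micrometres)")
  if (length(object@sectionThicknessZ) != 1L ||
      !is.finite(object@sectionThicknessZ) || object@sectionThicknessZ <= 0)
    return("sectionThicknessZ must be a single positive number (micrometres)")
  if (any(!is.finite(object@voxels)))
    return("voxels must be finite")
  TRUE
})

#' Construct a ConfocalStack
#'
#' @param voxels numeric 3D array, sections x rows x cols (Z leading).
#' @param pixelSizeXY XY pixel size, micrometres per pixel.
#' @param sectionThicknessZ Z section thickness, micrometres per section.
#' @return A \linkS4class{ConfocalStack}.
#' @export
ConfocalStack <- function(voxels, pixelSizeXY = 0.054,
                          sectionThicknessZ = 0.5) {
  new("ConfocalStack", voxels = voxels, pixelSizeXY = pixelSizeXY,
      sectionThicknessZ = sectionThicknessZ)
}

#' GroundTruth: simulator record of the geometry placed in a stack
#'
#' Stored alongside every generated stack so that parameter-recovery tests
#' can compare measured quantities against the values actually placed.
#' Distances follow the same outer-edge convention the measurement protocol
#' uses, so truth and measurement are directly comparable.
#'
#' @slot dotCentersUm numeric matrix, one row per dot focus, columns
#'   z, y, x in micrometres (continuous coordinates, 0-based voxel grid).
#' @slot dotAreasUm2 per-dot cross-sectional area, square micrometres.
#' @slot dXYUm outer-edge XY separation of the two dot foci, micrometres
#'   (NA unless two foci were placed).
#' @slot zOffsetUm Z offset between the dot centres, micrometres.
#' @slot separation3dUm 3D separation sqrt(dXY^2 + z^2), micrometres.
#' @slot configuration placement label (normal, both_same_side,
#'   extra_nonexchange).
#' @slot nDotsOut number of dot foci displaced out toward the poles.
#' @slot seed integer seed used for the stack.
#' @export
setClass("GroundTruth",
  representation(
    dotCentersUm = "matrix",
    dotAreasUm2 = "numeric",
    dXYUm = "numeric",
    zOffsetUm = "numeric",
    separation3dUm = "numeric",
    configuration = "character",
    nDotsOut = "integer",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  if (!is.na(object@separation3dUm) && !is.na(object@dXYUm)) {
    expected <- sqrt(object@dXYUm^2 + object@zOffsetUm^2)
    if (abs(object@separation3dUm - expected) >
        1e-9 * max(1, abs(expected)))
      return("separation3dUm must equal sqrt(dXYUm^2 + zOffsetUm^2)")
  }
  if (!object@nDotsOut %in% 0:2 &&
      object@configuration != "extra_nonexchange")
    return("nDotsOut must be 0, 1 or 2")
  TRUE
})

#' SimulationParams: parameters of one synthetic oocyte stack
#'
#' Defines the geometry, optics and noise of a simulated Prometaphase I
#' karyosome: a bright exchange-chromosome mass at the spindle midzone and
#' zero, one or two small dot-chromosome foci displaced toward the poles.
#'
#' @slot dim integer 3-vector: sections, rows, cols.
#' @slot pixelSizeXY XY pixel size, micrometres (field standard 0.054).
#' @slot sectionThicknessZ Z section thickness, micrometres.
#' @slot trueSeparation3d target outer-edge 3D dot-dot separation,
#'   micrometres (used when two foci are displaced).
#' @slot dotAreaUm2 cross-sectional area per dot focus, square micrometres
#'   (length 1, recycled to both dots, or length 2).
#' @slot mainMassAreaUm2 projected area of the central chromosome mass.
#' @slot peakIntensity rendered intensity of the main mass, arbitrary
#'   units on the 16-bit scale.
#' @slot dotPeakFraction dot rendering intensity as a fraction of
#'   \code{peakIntensity}; dots are smaller and dimmer than the mass.
#' @slot backgroundLevel constant additive background, arbitrary units.
#' @slot noiseSD standard deviation of additive Gaussian noise.
#' @slot blurSigmaXY Gaussian blur sigma in XY, micrometres.
#' @slot blurSigmaZ Gaussian blur sigma in Z, micrometres (anisotropic
#'   blur mimics the axial elongation of the confocal light cone).
#' @slot nDotsOut number of dot foci displaced out (0, 1 or 2).
#' @slot configuration placement label: normal, both_same_side or
#'   extra_nonexchange.
#' @slot zOffsetSections integer number of sections separating the two
#'   dot light-cone centres; NA picks a default from the separation.
#' @slot seed integer seed; identical params + seed give bit-identical
#'   stacks.
#' @export
setClass("SimulationParams",
  representation(
    dim = "integer",
    pixelSizeXY = "numeric",
    sectionThicknessZ = "numeric",
    trueSeparation3d = "numeric",
    dotAreaUm2 = "numeric",
    mainMassAreaUm2 = "numeric",
    peakIntensity = "numeric",
    dotPeakFraction = "numeric",
    backgroundLevel = "numeric",
    noiseSD = "numeric",
    blurSigmaXY = "numeric",
    blurSigmaZ = "numeric",
    nDotsOut = "integer",
    configuration = "character",
    zOffsetSections = "integer",
    seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1L))
    return("dim must be three positive integers (sections, rows, cols)")
  if (object@pixelSizeXY <= 0) return("pixelSizeXY must be > 0")
  if (object@sectionThicknessZ <= 0)
    return("sectionThicknessZ must be > 0")
  if (object@trueSeparation3d < 0)
    return("trueSeparation3d must be >= 0")
  if (any(object@dotAreaUm2 <= 0)) return("dotAreaUm2 must be > 0")
  if (!length(object@dotAreaUm2) %in% 1:2)
    return("dotAreaUm2 must have length 1 or 2")
  if (object@mainMassAreaUm2 <= 0) return("mainMassAreaUm2 must be > 0")
  if (!object@nDotsOut %in% 0:2) return("nDotsOut must be 0, 1 or 2")
  if (!object@configuration %in%
      c("normal", "both_same_side", "extra_nonexchange"))
    return("unknown configuration label")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (object@dotPeakFraction <= 0 || object@dotPeakFraction > 1)
    return("dotPeakFraction must be in (0, 1]")
  TRUE
})

#' Construct SimulationParams with field-typical defaults
#'
#' Defaults emulate the imaging standard of the measurement protocol:
#' 54 nm XY pixels, 0.5 um sections, a dot-dot separation and dot sizes in
#' the range reported across Drosophila species, and a signal-to-noise
#' ratio comfortably above the classifier's working regime.
#'
#' @param dim sections, rows, cols of the stack.
#' @param pixelSizeXY,sectionThicknessZ physical scales in micrometres.
#' @param trueSeparation3d target 3D outer-edge separation (um).
#' @param dotAreaUm2 per-dot cross-sectional area (um^2).
#' @param mainMassAreaUm2 projected area of the main mass (um^2).
#' @param peakIntensity,dotPeakFraction,backgroundLevel,noiseSD intensity
#'   model (16-bit arbitrary units).
#' @param blurSigmaXY,blurSigmaZ anisotropic Gaussian blur sigmas (um).
#' @param nDotsOut number of displaced dot foci (0, 1, 2).
#' @param configuration normal, both_same_side or extra_nonexchange.
#' @param zOffsetSections Z offset between the dots in sections; NA
#'   derives a default from the separation.
#' @param seed integer seed.
#' @return A \linkS4class{SimulationParams}.
#' @export
SimulationParams <- function(dim = c(32L, 192L, 192L),
                             pixelSizeXY = 0.054,
                             sectionThicknessZ = 0.5,
                             trueSeparation3d = 6,
                             dotAreaUm2 = 0.4,
                             mainMassAreaUm2 = 4,
                             peakIntensity = 30000,
                             dotPeakFraction = 0.8,
                             backgroundLevel = 1500,
                             noiseSD = 0,
                             blurSigmaXY = 0.08,
                             blurSigmaZ = 0.3,
                             nDotsOut = 2L,
                             configuration = "normal",
                             zOffsetSections = NA_integer_,
                             seed = 1L) {
  new("SimulationParams", dim = as.integer(dim),
      pixelSizeXY = pixelSizeXY, sectionThicknessZ = sectionThicknessZ,
      trueSeparation3d = trueSeparation3d, dotAreaUm2 = dotAreaUm2,
      mainMassAreaUm2 = mainMassAreaUm2, peakIntensity = peakIntensity,
      dotPeakFraction = dotPeakFraction,
      backgroundLevel = backgroundLevel, noiseSD = noiseSD,
      blurSigmaXY = blurSigmaXY, blurSigmaZ = blurSigmaZ,
      nDotsOut = as.integer(nDotsOut), configuration = configuration,
      zOffsetSections = as.integer(zOffsetSections),
      seed = as.integer(seed))
}
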