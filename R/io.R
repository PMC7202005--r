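# Stack and table I/O, bundled fixtures, and the umbrella pipeline.

#' Write a ConfocalStack as a multi-page grayscale TIFF
#'
#' Intensities are stored as 16-bit unsigned values (clipped to
#' [0, 65535]); the Z axis maps to TIFF pages, leading section first.
#' Physical scales are written to a plain-text sidecar next to the TIFF
#' so a round trip restores them.
#'
#' @param stack a \linkS4class{ConfocalStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ConfocalStack"))
  v <- voxels(stack)
  pages <- lapply(seq_len(dim(v)[1]), function(s)
    round(pmin(pmax(v[s, , ], 0), 65535)) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  writeLines(c(
    sprintf("pixel_size_xy_um: %.17g", pixelSizeXY(stack)),
    sprintf("section_thickness_z_um: %.17g", sectionThicknessZ(stack)),
    "intensity: 16-bit unsigned, z-leading, 0-based sections"),
    sidecarPath(path))
  invisible(path)
}

sidecarPath <- function(path) paste0(path, ".meta.txt")

#' Read a multi-page grayscale TIFF as a ConfocalStack
#'
#' @param path TIFF path. Multichannel (RGB) pages are rejected.
#' @param pixelSizeXY,sectionThicknessZ physical scales (um); when NULL,
#'   taken from the sidecar written by \code{\link{writeStack}}, else
#'   the field defaults 0.054 and 0.5.
#' @return a \linkS4class{ConfocalStack} with intensities on the 16-bit
#'   scale.
#' @export
readStack <- function(path, pixelSizeXY = NULL,
                      sectionThicknessZ = NULL) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF has zero pages: ", path)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop("multichannel TIFF: expected a single grayscale channel")
  meta <- sidecarPath(path)
  if (file.exists(meta)) {
    kv <- readLines(meta)
    getNum <- function(key) {
      ln <- grep(paste0("^", key, ":"), kv, value = TRUE)
      if (length(ln)) as.numeric(sub(".*: *", "", ln[1])) else NULL
    }
    if (is.null(pixelSizeXY)) pixelSizeXY <- getNum("pixel_size_xy_um")
    if (is.null(sectionThicknessZ))
      sectionThicknessZ <- getNum("section_thickness_z_um")
  }
  if (is.null(pixelSizeXY)) pixelSizeXY <- 0.054
  if (is.null(sectionThicknessZ)) sectionThicknessZ <- 0.5
  d2 <- dim(pages[[1L]])
  v <- array(0, c(length(pages), d2[1], d2[2]))
  for (s in seq_along(pages)) v[s, , ] <- pages[[s]] * 65535
  ConfocalStack(v, pixelSizeXY = pixelSizeXY,
                sectionThicknessZ = sectionThicknessZ)
}

#' Write / read a ground-truth sidecar record
#'
#' Plain key-value text stored next to each generated stack.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path output path.
#' @return \code{writeGroundTruth}: \code{path} invisibly;
#'   \code{readGroundTruth}: a \linkS4class{GroundTruth}.
#' @export
writeGroundTruth <- function(truth, path) {
  ctr <- apply(truth@dotCentersUm, 1, paste, collapse = " ")
  writeLines(c(
    sprintf("configuration: %s", truth@configuration),
    sprintf("n_dots_out: %d", truth@nDotsOut),
    sprintf("seed: %d", truth@seed),
    sprintf("d_xy_um: %.17g", truth@dXYUm),
    sprintf("z_offset_um: %.17g", truth@zOffsetUm),
    sprintf("separation_3d_um: %.17g", truth@separation3dUm),
    sprintf("dot_areas_um2: %s",
            paste(sprintf("%.17g", truth@dotAreasUm2), collapse = " ")),
    sprintf("dot_centers_um_zyx: %s", paste(ctr, collapse = " ; "))),
    path)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  kv <- readLines(path)
  getv <- function(key) sub("^[^:]*: *", "",
                            grep(paste0("^", key, ":"), kv, value = TRUE)[1])
  centers <- do.call(rbind, lapply(
    strsplit(getv("dot_centers_um_zyx"), " ; ")[[1]],
    function(s) as.numeric(strsplit(s, " ")[[1]])))
  new("GroundTruth",
      dotCentersUm = centers,
      dotAreasUm2 = as.numeric(strsplit(getv("dot_areas_um2"), " ")[[1]]),
      dXYUm = as.numeric(getv("d_xy_um")),
      zOffsetUm = as.numeric(getv("z_offset_um")),
      separation3dUm = as.numeric(getv("separation_3d_um")),
      configuration = getv("configuration"),
      nDotsOut = as.integer(getv("n_dots_out")),
      seed = as.integer(getv("seed")))
}

fixtureChecksums <- c(
  table1.csv = "e233ca38c807b5ba09a625a518c8ca46",
  table2_pairs.csv = "4042e43c4f6e89ff6eef6049350353ac")

loadFixture <- function(name) {
  path <- system.file("extdata", name, package = "SpindleDots",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(fixtureChecksums[name])))
    stop("bundled fixture ", name, " fails its integrity checksum")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled per-species summary table
#'
#' The transcribed species summary used by the comparative statistics:
#' percent genomic heterochromatin (missing for five species), common
#' inversion status, mean dot-dot distance (um), oocyte counts,
#' proportion of oocytes with chromosomes out, and mean dot chromosome
#' cross-sectional area (um^2). D. willistoni, which lacks a free dot
#' chromosome, has no distance or area. Fixture integrity is verified
#' by checksum at load.
#'
#' @return data.frame with one row per species.
#' @examples
#' t1 <- loadSpeciesSummaryTable()
#' groupMeanComparison(t1)
#' @export
loadSpeciesSummaryTable <- function() {
  t1 <- loadFixture("table1.csv")
  t1$species <- t1$abbrev
  t1
}

#' Bundled inversion-type divergent species pairs
#'
#' The six closely related (polymorphic, monomorphic) species pairs used
#' for the pairwise contrasts, with the published per-pair t-test
#' p-values for summary-only analyses.
#'
#' @return data.frame with columns poly, mono, published_p.
#' @export
loadSpeciesPairs <- function() {
  loadFixture("table2_pairs.csv")
}
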