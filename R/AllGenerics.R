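#' @import methods
NULL

#' Accessors for ConfocalStack
#'
#' @param object,x a \linkS4class{ConfocalStack}.
#' @return \code{voxels} the 3D array; \code{pixelSizeXY} and
#'   \code{sectionThicknessZ} the physical scales in micrometres;
#'   \code{dim} the sections x rows x cols dimensions.
#' @name ConfocalStack-accessors
NULL

#' @rdname ConfocalStack-accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname ConfocalStack-accessors
#' @export
setMethod("voxels", "ConfocalStack", function(object) object@voxels)

#' @rdname ConfocalStack-accessors
#' @export
setGeneric("pixelSizeXY", function(object) standardGeneric("pixelSizeXY"))

#' @rdname ConfocalStack-accessors
#' @export
setMethod("pixelSizeXY", "ConfocalStack",
          function(object) object@pixelSizeXY)

#' @rdname ConfocalStack-accessors
#' @export
setGeneric("sectionThicknessZ",
           function(object) standardGeneric("sectionThicknessZ"))

#' @rdname ConfocalStack-accessors
#' @export
setMethod("sectionThicknessZ", "ConfocalStack",
          function(object) object@sectionThicknessZ)

#' @rdname ConfocalStack-accessors
#' @export
setMethod("dim", "ConfocalStack", function(x) dim(x@voxels))

setMethod("show", "ConfocalStack", function(object) {
  d <- dim(object@voxels)
  cat("ConfocalStack:", d[1], "sections x", d[2], "rows x", d[3], "cols\n")
  cat("  pixel size XY:", object@pixelSizeXY, "um/px;",
      "section thickness Z:", object@sectionThicknessZ, "um\n")
  cat("  intensity range: [", round(min(object@voxels), 1), ",",
      round(max(object@voxels), 1), "]\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@dotCentersUm), "dot foci,",
      object@nDotsOut, "out;", "configuration", object@configuration, "\n")
  if (!is.na(object@separation3dUm))
    cat("  3D separation:", round(object@separation3dUm, 3), "um",
        "(dXY", round(object@dXYUm, 3), "um, z",
        round(object@zOffsetUm, 3), "um)\n")
})

#' Maximum-intensity projection of a stack
#'
#' Projects a z-stack to a single 2D image, each output pixel being the
#' maximum of that pixel across sections. All XY measurements of the
#' protocol (segmentation, line profiles, outer-edge distances, areas)
#' are taken on this projection.
#'
#' @param object a \linkS4class{ConfocalStack} or a 3D array
#'   (sections x rows x cols).
#' @return a numeric matrix, rows x cols.
#' @examples
#' st <- ConfocalStack(array(runif(4 * 6 * 6), c(4, 6, 6)))
#' p <- maxProjection(st)
#' all(p >= voxels(st)[1, , ])
#' @export
setGeneric("maxProjection", function(object) standardGeneric("maxProjection"))

#' @rdname maxProjection
#' @export
setMethod("maxProjection", "ConfocalStack",
          function(object) maxProjection(object@voxels))

#' @rdname maxProjection
#' @export
setMethod("maxProjection", "array", function(object) {
  d <- dim(object)
  if (length(d) != 3L || any(d < 1L))
    stop("maxProjection needs a non-empty 3D array")
  apply(object, c(2L, 3L), max)
})
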