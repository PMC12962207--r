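#' @rdname nufftForward
#' @export
setGeneric("nufftForward", function(op, m, ...) standardGeneric("nufftForward"))

#' @rdname nufftAdjoint
#' @export
setGeneric("nufftAdjoint", function(op, y, ...) standardGeneric("nufftAdjoint"))

#' Number of phase encodes
#' @param x a HelixSet or Trajectory.
#' @return integer(1).
#' @export
setGeneric("nPhaseEncodes", function(x) standardGeneric("nPhaseEncodes"))

#' Trajectory coordinates
#' @param x a Trajectory.
#' @return the NPE x NRO x 3 coordinate array.
#' @export
setGeneric("trajCoords", function(x) standardGeneric("trajCoords"))

#' Coil maps accessor
#' @param x a CoilSet or PhantomCase.
#' @return complex array of coil sensitivities.
#' @export
setGeneric("coilMaps", function(x) standardGeneric("coilMaps"))

#' @export
setMethod("nPhaseEncodes", "HelixSet", function(x) length(x@kyc))

#' @export
setMethod("nPhaseEncodes", "Trajectory", function(x) dim(x@coords)[1])

#' @export
setMethod("trajCoords", "Trajectory", function(x) x@coords)

#' @export
setMethod("coilMaps", "CoilSet", function(x) x@maps)

#' @export
setMethod("coilMaps", "PhantomCase", function(x) x@coils@maps)

setMethod("show", "WaveParams", function(object) {
  cat("WaveParams: r =", signif(object@radius, 4), "grid units, C =",
      object@cycles, ", ef =", object@echoFraction, ", NRO =",
      object@nReadout, "\n  gmax =", object@gmax, "mT/m, smax =",
      object@smax, "T/m/s, dwell =", object@dwell * 1e6,
      "us, FOV =", object@fov, "mm, N =", object@matrixSize, "\n")
})

setMethod("show", "HelixSet", function(object) {
  cat("HelixSet with", length(object@kyc), "phase encodes; learnable:",
      paste(object@learnable, collapse = ", "), "\n  sr in [",
      signif(min(object@sr), 3), ",", signif(max(object@sr), 3), "]\n")
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat("Trajectory (", object@mode, "): ", d[1], " x ", d[2],
      " x 3 coordinates, |k| <= ", signif(max(abs(object@coords)), 4),
      "\n", sep = "")
})

setMethod("show", "EncodingOperator", function(object) {
  cat("EncodingOperator (", object@method, "): N = ", object@gridSize,
      ", ", dim(object@coils@maps)[4], " coils, ", nrow(object@coords),
      " k-space samples\n", sep = "")
})

setMethod("show", "PhantomCase", function(object) {
  cat("PhantomCase: N =", object@spec@gridSize, ", voxel =",
      object@spec@voxel, "mm,", length(object@spec@tubes), "tube(s),",
      dim(object@coils@maps)[4], "coils\n")
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf(
    "AgreementReport: slope %.4f (95%% CI %.4f..%.4f), R^2 %.4f\n  Bland-Altman: mean diff %.4f, LoA [%.4f, %.4f], n = %d\n",
    object@slope, object@slopeCI[1], object@slopeCI[2], object@rSquared,
    object@meanDiff, object@loaLow, object@loaHigh, object@nPixels))
})
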