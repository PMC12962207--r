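#' @useDynLib WaveRecon, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats fft rnorm runif median qnorm sd lm coef confint anova
#' @importFrom utils head object.size
NULL

GAMMA_HZ_PER_T <- 42.577478518e6  # proton gyromagnetic ratio / 2pi, Hz/T

#' Wave readout parameterization
#'
#' Holds the shared helix parameters of a wave-encoded readout: maximum helix
#' radius \code{radius} (k-space grid units, i.e. cycles across the FOV),
#' number of helix cycles \code{cycles}, echo fraction \code{echoFraction}
#' (acquired fraction of the frequency-encode direction, partial echo),
#' readout length \code{nReadout}, and the hardware/geometry context needed to
#' check gradient amplitude and slew-rate compliance.
#'
#' @slot radius numeric(1), maximum helix radius in grid units.
#' @slot cycles integer(1), helix cycles per readout.
#' @slot echoFraction numeric(1) in (0.5, 1].
#' @slot nReadout integer(1), readout samples per helix.
#' @slot gmax numeric(1), maximum gradient amplitude (mT/m).
#' @slot smax numeric(1), maximum slew rate (T/m/s).
#' @slot dwell numeric(1), readout sample spacing (s).
#' @slot fov numeric(1), field of view per axis (mm).
#' @slot matrixSize integer(1), grid size N per axis.
#' @export
setClass("WaveParams", representation(
  radius = "numeric", cycles = "integer", echoFraction = "numeric",
  nReadout = "integer", gmax = "numeric", smax = "numeric",
  dwell = "numeric", fov = "numeric", matrixSize = "integer"))

setValidity("WaveParams", function(object) {
  msg <- character()
  if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
  if (object@echoFraction <= 0.5 || object@echoFraction > 1)
    msg <- c(msg, "echoFraction must be in (0.5, 1]")
  if (object@cycles < 1L) msg <- c(msg, "cycles must be >= 1")
  if (object@nReadout < 2L) msg <- c(msg, "nReadout must be >= 2")
  if (object@dwell <= 0) msg <- c(msg, "dwell must be > 0")
  if (object@matrixSize < 2L) msg <- c(msg, "matrixSize must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Per-phase-encode helix learnables
#'
#' The per-helix learnable sampling parameters: phase-encode center
#' coordinates (\code{kyc}, \code{kzc}, grid units), radius scaling
#' \code{sr} in (0, 1] (the helix radius can only be scaled down), and
#' rotation \code{theta} (radians) about the kx axis.
#'
#' @slot kyc,kzc numeric(NPE), helix center coordinates.
#' @slot sr numeric(NPE) in (0, 1].
#' @slot theta numeric(NPE), rotations in radians.
#' @slot learnable character, names of fields that participate in training.
#' @export
setClass("HelixSet", representation(
  kyc = "numeric", kzc = "numeric", sr = "numeric", theta = "numeric",
  learnable = "character"))

setValidity("HelixSet", function(object) {
  n <- length(object@kyc)
  msg <- character()
  if (length(object@kzc) != n || length(object@sr) != n ||
      length(object@theta) != n)
    msg <- c(msg, "kyc, kzc, sr, theta must have equal length")
  if (any(object@sr <= 0) || any(object@sr > 1))
    msg <- c(msg, "sr must lie in (0, 1]")
  if (!all(object@learnable %in% c("kyc", "kzc", "sr", "theta")))
    msg <- c(msg, "learnable must be a subset of kyc,kzc,sr,theta")
  if (length(msg)) msg else TRUE
})

#' Sampling trajectory
#'
#' Full k-space sampling coordinates, NPE x NRO x 3 (kx, ky, kz) in grid
#' units; the coordinates are floating point and not confined to the grid.
#'
#' @slot coords numeric array NPE x NRO x 3.
#' @slot mode character(1), "wave" or "no_wave".
#' @slot provenance list, parameters used to build the trajectory.
#' @export
setClass("Trajectory", representation(
  coords = "array", mode = "character", provenance = "list"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be an NPE x NRO x 3 array")
  if (!object@mode %in% c("wave", "no_wave"))
    msg <- c(msg, "mode must be 'wave' or 'no_wave'")
  if (length(msg)) msg else TRUE
})

#' Coil sensitivity maps
#'
#' @slot maps complex array N1 x N2 x N3 x ncoil; root-sum-of-squares is
#'   approximately 1 inside the support.
#' @slot supportMask logical array N1 x N2 x N3.
#' @export
setClass("CoilSet", representation(maps = "array", supportMask = "array"))

setValidity("CoilSet", function(object) {
  d <- dim(object@maps)
  msg <- character()
  if (length(d) != 4L) msg <- c(msg, "maps must be a 4D array")
  if (!all(is.finite(Re(object@maps))) || !all(is.finite(Im(object@maps))))
    msg <- c(msg, "maps must be finite")
  if (!identical(dim(object@supportMask), d[1:3]))
    msg <- c(msg, "supportMask must match the spatial dimensions of maps")
  if (length(msg)) msg else TRUE
})

#' Multi-coil non-uniform Fourier encoding operator
#'
#' Represents A = C F S of the acquisition model y = A m + noise: coil
#' sensitivity weighting, (non-uniform) Fourier transform, and the sampling
#' scheme given by off-grid coordinates. \code{method = "nufft"} uses
#' Kaiser-Bessel gridding (kernel width 4, oversampling 1.25 by default);
#' \code{method = "dft"} evaluates the exact discrete transform and serves as
#' the float64 oracle on small problems.
#'
#' @slot gridSize integer(1), image grid size N (cubic).
#' @slot coils CoilSet.
#' @slot coords numeric matrix K x 3, sample coordinates in grid units.
#' @slot method character(1), "nufft" or "dft".
#' @slot oversamp,width numeric(1), gridding parameters.
#' @slot cache list of precomputed gridding quantities.
#' @export
setClass("EncodingOperator", representation(
  gridSize = "integer", coils = "CoilSet", coords = "matrix",
  method = "character", oversamp = "numeric", width = "numeric",
  cache = "list"))

#' Unrolled reconstruction configuration
#'
#' @slot nUnrolls integer(1), number of DC-CNN unrolls (default 6).
#' @slot nLayers integer(1), complex conv layers in the denoiser (default 5).
#' @slot features integer(1), hidden width per layer.
#' @slot kernel integer(1), spatial kernel size (default 3).
#' @slot blockSize integer(1), voxels per block edge for blockwise apply.
#' @slot blockOverlap integer(1), overlap voxels.
#' @slot shareWeights logical(1), share denoiser weights across unrolls.
#' @export
setClass("MoDLConfig", representation(
  nUnrolls = "integer", nLayers = "integer", features = "integer",
  kernel = "integer", blockSize = "integer", blockOverlap = "integer",
  shareWeights = "logical"))

setValidity("MoDLConfig", function(object) {
  msg <- character()
  if (object@nUnrolls < 1L) msg <- c(msg, "nUnrolls must be >= 1")
  if (object@blockOverlap >= object@blockSize)
    msg <- c(msg, "blockOverlap must be < blockSize")
  if (object@kernel %% 2L != 1L) msg <- c(msg, "kernel must be odd")
  if (length(msg)) msg else TRUE
})

#' Flow phantom specification
#'
#' Describes a numerical flow phantom: a box of hydrogel-like background
#' signal with cylindrical tubes carrying steady laminar flow. Tube flow is
#' parameterized either by mean volumetric flow rate (L/min) or peak velocity
#' (cm/s); a parabolic (Poiseuille) or plug profile is laid along the local
#' centerline tangent.
#'
#' @slot gridSize integer(1), grid size N per axis.
#' @slot voxel numeric(1), voxel size (mm).
#' @slot tubes list of tube descriptions (see \code{\link{phantomSpec}}).
#' @slot background numeric(1), background signal level.
#' @slot venc numeric(1), velocity encoding (cm/s), default 80.
#' @slot nCoils integer(1), number of synthetic coils, default 8.
#' @slot noiseSigma numeric(1), k-space noise standard deviation.
#' @slot seed integer(1).
#' @export
setClass("PhantomSpec", representation(
  gridSize = "integer", voxel = "numeric", tubes = "list",
  background = "numeric", venc = "numeric", nCoils = "integer",
  noiseSigma = "numeric", seed = "integer"))

#' A synthetic flow-encoded phantom case
#'
#' Ground-truth magnitude, velocity field, vessel mask, the 4-point
#' flow-encoded complex volumes, and coil maps.
#'
#' @slot spec PhantomSpec.
#' @slot magnitude numeric array N^3.
#' @slot velocity numeric array N x N x N x 3 (cm/s).
#' @slot mask logical array N^3 (vessel voxels, including partial-volume rim).
#' @slot encodes complex array N x N x N x 4 (reference + x/y/z encodes).
#' @slot coils CoilSet.
#' @export
setClass("PhantomCase", representation(
  spec = "PhantomSpec", magnitude = "array", velocity = "array",
  mask = "array", encodes = "array", coils = "CoilSet"))

#' Vessel cross-section for flow measurement
#'
#' @slot origin numeric(3), voxel-grid coordinates of the section center.
#' @slot normal numeric(3), unit normal.
#' @slot pixelArea numeric(1), in-plane pixel area (cm^2).
#' @slot members integer matrix n x 3 of voxel indices.
#' @export
setClass("CrossSection", representation(
  origin = "numeric", normal = "numeric", pixelArea = "numeric",
  members = "matrix"))

setValidity("CrossSection", function(object) {
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-8) "normal must be unit length"
  else TRUE
})

#' Pixelwise agreement report
#'
#' Ordinary least squares regression of one velocity set on another plus
#' Bland-Altman statistics (mean difference and 1.96 SD limits of agreement).
#'
#' @slot slope,intercept,rSquared numeric(1), regression results.
#' @slot slopeCI numeric(2), 95 percent confidence interval of the slope.
#' @slot meanDiff,loaLow,loaHigh numeric(1), Bland-Altman statistics.
#' @slot nPixels integer(1).
#' @export
setClass("AgreementReport", representation(
  slope = "numeric", intercept = "numeric", rSquared = "numeric",
  slopeCI = "numeric", meanDiff = "numeric", loaLow = "numeric",
  loaHigh = "numeric", nPixels = "integer"))

setValidity("AgreementReport", function(object) {
  TRUE
})

#' Joint training configuration
#'
#' Mirrors the published training setup (Adam, learning rate 1e-3, weight
#' decay 1e-3, linear-phase augmentation coefficients drawn from [-10, 10],
#' amplitude scale from [0.3, 3], noise factor from [0.5, 1.5]) with
#' desk-scale knobs (grid, unrolls, features, epochs) exposed.
#'
#' @slot mode character(1), "wave", "no_wave" or "fixed".
#' @slot lr,lrCoords,weightDecay numeric(1), optimizer settings; lrCoords is
#'   the Adam step used for the coordinate/wave learnables.
#' @slot epochs,seed integer(1).
#' @slot phaseCoeffRange,scaleRange,noiseFactorRange numeric(2), augmentation
#'   draw ranges.
#' @slot nUnrolls,features integer(1), MoDL size used during training.
#' @slot encodes integer, which flow encodes of each case are used as
#'   training volumes.
#' @export
setClass("TrainConfig", representation(
  mode = "character", lr = "numeric", lrCoords = "numeric",
  weightDecay = "numeric", epochs = "integer", seed = "integer",
  phaseCoeffRange = "numeric", scaleRange = "numeric",
  noiseFactorRange = "numeric", nUnrolls = "integer", features = "integer",
  encodes = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("wave", "no_wave", "fixed"))
    msg <- c(msg, "mode must be one of wave, no_wave, fixed")
  if (object@lr <= 0) msg <- c(msg, "lr must be > 0")
  for (s in c("phaseCoeffRange", "scaleRange", "noiseFactorRange")) {
    v <- slot(object, s)
    if (length(v) != 2L || v[1] > v[2]) msg <- c(msg, paste(s, "must be an ordered pair"))
  }
  if (length(msg)) msg else TRUE
})
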