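# On-disk containers. The environment provides no HDF5 binding for R, so
# artifacts are stored as schema-tagged RDS containers with a JSON metadata
# string; readers validate the schema and fail with descriptive errors rather
# than crashing on foreign files. Roundtrips are bit-exact for complex data.

containerWrite <- function(obj, path, schema) {
  stopifnot(is.list(obj))
  obj$.schema <- schema
  obj$.version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

containerRead <- function(path, schema, fields) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read container '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  if (!is.list(obj) || !identical(obj$.schema, schema))
    stop(sprintf("'%s' is not a %s container", path, schema), call. = FALSE)
  missing <- setdiff(fields, names(obj))
  if (length(missing))
    stop(sprintf("%s container '%s' lacks fields: %s", schema, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  obj
}

#' Write / read a trajectory container
#'
#' Stores the full coordinate array together with the per-helix learnables
#' and a JSON metadata string describing the wave parameterization.
#'
#' @param traj a \linkS4class{Trajectory} (with HelixSet provenance).
#' @param path file path.
#' @return \code{writeTrajectory}: the path, invisibly;
#'   \code{readTrajectory}: the \linkS4class{Trajectory}.
#' @export
writeTrajectory <- function(traj, path) {
  wp <- traj@provenance$waveParams
  hs <- traj@provenance$helixSet
  meta <- if (!is.null(wp)) jsonlite::toJSON(list(
    radius = wp@radius, cycles = wp@cycles, echoFraction = wp@echoFraction,
    nReadout = wp@nReadout, gmax = wp@gmax, smax = wp@smax, dwell = wp@dwell,
    fov = wp@fov, matrixSize = wp@matrixSize,
    kxMapping = traj@provenance$kxMapping), auto_unbox = TRUE) else "{}"
  containerWrite(list(
    coords = traj@coords, mode = traj@mode,
    sr = if (!is.null(hs)) hs@sr, theta = if (!is.null(hs)) hs@theta,
    kyc = if (!is.null(hs)) hs@kyc, kzc = if (!is.null(hs)) hs@kzc,
    meta = as.character(meta)), path, "trajectory")
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  obj <- containerRead(path, "trajectory", c("coords", "mode", "meta"))
  prov <- list()
  meta <- jsonlite::fromJSON(obj$meta)
  if (length(meta)) {
    prov$waveParams <- waveParams(
      radius = meta$radius, cycles = meta$cycles,
      echoFraction = meta$echoFraction, nReadout = meta$nReadout,
      gmax = meta$gmax, smax = meta$smax, dwell = meta$dwell, fov = meta$fov,
      matrixSize = meta$matrixSize)
    prov$kxMapping <- meta$kxMapping
  }
  if (!is.null(obj$kyc))
    prov$helixSet <- helixSet(obj$kyc, obj$kzc, obj$sr, obj$theta)
  new("Trajectory", coords = obj$coords, mode = obj$mode, provenance = prov)
}

#' Write / read a phantom case container
#'
#' @param case a \linkS4class{PhantomCase}.
#' @param path file path.
#' @return \code{writePhantomCase}: the path, invisibly;
#'   \code{readPhantomCase}: the \linkS4class{PhantomCase}.
#' @export
writePhantomCase <- function(case, path) {
  sp <- case@spec
  containerWrite(list(
    encodes = case@encodes, coils = case@coils@maps,
    support = case@coils@supportMask, velocity = case@velocity,
    magnitude = case@magnitude, mask = case@mask,
    spec = jsonlite::toJSON(list(
      gridSize = sp@gridSize, voxel = sp@voxel, tubes = sp@tubes,
      background = sp@background, venc = sp@venc, nCoils = sp@nCoils,
      noiseSigma = sp@noiseSigma, seed = sp@seed), auto_unbox = TRUE,
      digits = NA)), path, "phantom_case")
}

#' @rdname writePhantomCase
#' @export
readPhantomCase <- function(path) {
  obj <- containerRead(path, "phantom_case",
                       c("encodes", "coils", "velocity", "magnitude", "mask",
                         "spec"))
  sj <- jsonlite::fromJSON(obj$spec, simplifyDataFrame = FALSE)
  tubes <- lapply(sj$tubes, function(t) {
    t$center <- unlist(t$center)
    if (!is.null(t$control)) t$control <- do.call(rbind, t$control)
    t
  })
  spec <- phantomSpec(gridSize = sj$gridSize, voxel = sj$voxel, tubes = tubes,
                      background = sj$background, venc = sj$venc,
                      nCoils = sj$nCoils, noiseSigma = sj$noiseSigma,
                      seed = sj$seed)
  new("PhantomCase", spec = spec, magnitude = obj$magnitude,
      velocity = obj$velocity, mask = obj$mask, encodes = obj$encodes,
      coils = coilSet(obj$coils, obj$support))
}

#' Write / read a model checkpoint container
#'
#' Stores denoiser weights, the DC step size, the learned helix set and the
#' training configuration summary.
#'
#' @param state trained state from \code{\link{trainJoint}}.
#' @param path file path.
#' @return \code{writeCheckpoint}: the path, invisibly;
#'   \code{readCheckpoint}: the state list.
#' @export
writeCheckpoint <- function(state, path) {
  hs <- state$helixSet
  wp <- state$wp
  containerWrite(list(
    weights = state$weights, alpha = state$alpha, mode = state$mode,
    nUnrolls = state$nUnrolls, kyc = hs@kyc, kzc = hs@kzc, sr = hs@sr,
    theta = hs@theta, history = state$history,
    waveParams = list(radius = wp@radius, cycles = wp@cycles,
                      echoFraction = wp@echoFraction, nReadout = wp@nReadout,
                      gmax = wp@gmax, smax = wp@smax, dwell = wp@dwell,
                      fov = wp@fov, matrixSize = wp@matrixSize)),
    path, "checkpoint")
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  obj <- containerRead(path, "checkpoint",
                       c("weights", "alpha", "mode", "nUnrolls", "kyc"))
  wpl <- obj$waveParams
  list(weights = obj$weights, alpha = obj$alpha, mode = obj$mode,
       nUnrolls = obj$nUnrolls,
       helixSet = helixSet(obj$kyc, obj$kzc, obj$sr, obj$theta),
       history = obj$history,
       wp = waveParams(radius = wpl$radius, cycles = wpl$cycles,
                       echoFraction = wpl$echoFraction,
                       nReadout = wpl$nReadout, gmax = wpl$gmax,
                       smax = wpl$smax, dwell = wpl$dwell, fov = wpl$fov,
                       matrixSize = wpl$matrixSize))
}
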