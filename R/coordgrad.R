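# Spatial weighting field (-2 pi i x_d / N) used by the analytic Jacobians:
# differentiating exp(-2 pi i k.x/N) w.r.t. k_d pulls down this factor.
coordWeightField <- function(N, d) {
  x <- (0:(N - 1)) - N %/% 2
  w <- -2i * pi * x / N
  switch(d,
         array(rep(w, times = N * N), rep(N, 3)),
         array(rep(rep(w, each = N), times = N), rep(N, 3)),
         array(rep(w, each = N * N), rep(N, 3)))
}

# forward transform of an x_d-weighted image, per coil: J_d[k, c] =
# d y[k, c] / d k_d, computed as one extra NUFFT per axis (no dense matrices).
jacobianForwardAxis <- function(op, m, d) {
  wimg <- m * coordWeightField(op@gridSize, d)
  nufftForward(op, wimg)
}

#' Coordinate gradient through the forward model
#'
#' Given the cotangent gy = dL/d(Re y) + i dL/d(Im y) on the simulated
#' k-space data, returns dL/d(coords): for axis d,
#' grad_d[k] = sum_c Re[conj(gy[k,c]) J_d[k,c]] with
#' J_d the NUFFT of the x_d-weighted coil image. Coils share coordinates, so
#' their contributions accumulate by summation.
#'
#' @param op an \linkS4class{EncodingOperator}.
#' @param m the complex image the forward model was applied to.
#' @param gy complex cotangent, K x ncoil.
#' @return real K x 3 matrix of coordinate gradients.
#' @export
coordGradForward <- function(op, m, gy) {
  if (is.null(dim(gy))) gy <- matrix(gy, ncol = 1L)
  if (!all(dim(gy) == c(nrow(op@coords), dim(op@coils@maps)[4])))
    stop("cotangent shape mismatch")
  out <- matrix(0, nrow(op@coords), 3)
  for (d in 1:3) {
    J <- jacobianForwardAxis(op, m, d)
    out[, d] <- rowSums(Re(Conj(gy) * J))
  }
  out
}

#' Coordinate gradient through the adjoint model
#'
#' Given the cotangent gm on the image produced by \code{nufftAdjoint},
#' returns dL/d(coords). Differentiating the adjoint exponent
#' exp(+2 pi i k.x/N) gives, per axis and sample,
#' grad_d[k] = sum_c Re[conj(Jt_d[k,c]) y[k,c]] with Jt_d the forward NUFFT of
#' the x_d-weighted cotangent image.
#'
#' @param op an \linkS4class{EncodingOperator}.
#' @param y the k-space data the adjoint was applied to (K x ncoil).
#' @param gm complex cotangent image, N^3.
#' @return real K x 3 matrix.
#' @export
coordGradAdjoint <- function(op, y, gm) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1L)
  out <- matrix(0, nrow(op@coords), 3)
  for (d in 1:3) {
    Jt <- jacobianForwardAxis(op, gm, d)
    out[, d] <- rowSums(Re(Conj(Jt) * y))
  }
  out
}

#' Naive interpolation-kernel coordinate gradient
#'
#' What a framework's autodiff produces when differentiating through the
#' gridding interpolation itself: the derivative of the Kaiser-Bessel kernel
#' weights with respect to the sample position. Provided for comparison; the
#' analytic Jacobian route (\code{\link{coordGradForward}}) is the gradient of
#' the true transform, whereas this differentiates the approximation, which
#' amplifies the interpolation error.
#'
#' @inheritParams coordGradForward
#' @return real K x 3 matrix.
#' @export
coordGradForwardNaive <- function(op, m, gy) {
  if (op@method != "nufft") stop("naive gradient requires the nufft method")
  if (is.null(dim(gy))) gy <- matrix(gy, ncol = 1L)
  ca <- op@cache
  maps <- op@coils@maps
  nc <- dim(maps)[4]
  G <- ca$Gdim[1]
  N <- op@gridSize
  out <- matrix(0, nrow(op@coords), 3)
  ix <- ca$embedIdx
  for (c in seq_len(nc)) {
    md <- (m * maps[, , , c]) / ca$deapod3
    arr <- array(0i, ca$Gdim)
    arr[ix, ix, ix] <- md
    Fg <- fft(arr)
    dY <- cpp_kb_interp_dcoord(Fg, ca$Gdim, ca$scoords, op@width,
                               ca$tab, ca$dtab)
    # chain: d(scaled coord)/d(coord) = G/N
    for (d in 1:3)
      out[, d] <- out[, d] +
        Re(Conj(gy[, c]) * dY[, d]) * ca$scale * (G / N)
  }
  out
}

#' Chain coordinate gradients to the wave learnables
#'
#' Accumulates per-helix gradients for the learnable sampling parameters from
#' the per-sample coordinate gradients, using the analytic partials of the
#' helix parameterization: d ky/d theta = sr r cos(phi+theta),
#' d ky/d sr = r sin(phi+theta), d ky/d kyc = 1 (and the cos/-sin analogues
#' for kz). In no_wave mode only the center gradients are nonzero.
#'
#' @param dcoords K x 3 matrix (readout fastest, as from
#'   \code{\link{trajCoordsMatrix}} ordering) or NPE x NRO x 3 array.
#' @param hs the \linkS4class{HelixSet} the trajectory was built from.
#' @param wp the \linkS4class{WaveParams}.
#' @param mode "wave" or "no_wave".
#' @return list with numeric vectors \code{d_sr}, \code{d_theta},
#'   \code{d_kyc}, \code{d_kzc} (length NPE).
#' @export
chainToWaveParams <- function(dcoords, hs, wp, mode = c("wave", "no_wave")) {
  mode <- match.arg(mode)
  npe <- nPhaseEncodes(hs)
  nro <- wp@nReadout
  if (is.matrix(dcoords)) {
    stopifnot(nrow(dcoords) == npe * nro)
    dky <- matrix(dcoords[, 2], nro, npe)   # readout fastest
    dkz <- matrix(dcoords[, 3], nro, npe)
  } else {
    dky <- t(dcoords[, , 2]); dkz <- t(dcoords[, , 3])
  }
  dkyc <- colSums(dky)
  dkzc <- colSums(dkz)
  if (mode == "no_wave")
    return(list(d_sr = numeric(npe), d_theta = numeric(npe),
                d_kyc = dkyc, d_kzc = dkzc))
  phi <- helixPhase(seq_len(nro) - 1, wp)
  ph <- outer(phi, hs@theta, "+")            # NRO x NPE
  sn <- sin(ph); cs <- cos(ph)
  r <- wp@radius
  d_sr <- colSums(r * (sn * dky + cs * dkz))
  d_theta <- hs@sr * colSums(r * (cs * dky - sn * dkz))
  list(d_sr = d_sr, d_theta = d_theta, d_kyc = dkyc, d_kzc = dkzc)
}
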