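# Kaiser-Bessel gridding internals. Kernel shape parameter from Beatty's
# formula; lookup tables sampled densely enough that linear interpolation
# error is negligible against the gridding approximation itself.
kbBeta <- function(width, oversamp)
  pi * sqrt((width / oversamp)^2 * (oversamp - 0.5)^2 - 0.8)

kbTables <- function(width, oversamp, nt = 4096L) {
  beta <- kbBeta(width, oversamp)
  u <- seq(0, width / 2, length.out = nt)
  s <- sqrt(pmax(1 - (2 * u / width)^2, 0))
  tab <- besselI(beta * s, 0)
  # d/du I0(beta s) = beta I1(beta s) * ds/du, ds/du = -4u / (W^2 s)
  dtab <- ifelse(s > 1e-12,
                 besselI(beta * s, 1) * beta * (-4 * u / width^2) / s,
                 -2 * beta^2 * u / width^2 * 0.5)
  list(beta = beta, tab = tab, dtab = dtab)
}

# Fourier transform of the (unnormalized) KB kernel, evaluated at image
# positions x for deapodization: w_hat(x) = W sinh(sqrt(beta^2 - z^2)) /
# sqrt(beta^2 - z^2), z = pi W x / G (sin branch for z > beta).
kbDeapod1d <- function(N, G, width, beta) {
  x <- (0:(N - 1)) - N %/% 2
  z2 <- (pi * width * x / G)^2
  t <- beta^2 - z2
  f <- ifelse(abs(t) < 1e-12, 1,
              ifelse(t > 0, sinh(sqrt(pmax(t, 0))) / sqrt(pmax(t, 1e-300)),
                     sin(sqrt(pmax(-t, 0))) / sqrt(pmax(-t, 1e-300))))
  width * f
}

#' Construct the multi-coil encoding operator A = C F S
#'
#' @param coils a \linkS4class{CoilSet}, or a complex array N x N x N x nc.
#' @param traj a \linkS4class{Trajectory} or a K x 3 coordinate matrix in
#'   grid units (|k| <= N/2).
#' @param method "nufft" (Kaiser-Bessel gridding) or "dft" (exact slow
#'   transform, the float64 oracle for small problems).
#' @param oversamp gridding oversampling factor (default 1.25).
#' @param width interpolation kernel width (default 4).
#' @return an \linkS4class{EncodingOperator}.
#' @export
encodingOperator <- function(coils, traj, method = c("nufft", "dft"),
                             oversamp = 1.25, width = 4) {
  method <- match.arg(method)
  if (is(coils, "CoilSet")) cs <- coils
  else cs <- coilSet(coils)
  N <- dim(cs@maps)[1]
  if (!all(dim(cs@maps)[1:3] == N)) stop("cubic grids only")
  coords <- if (is(traj, "Trajectory")) trajCoordsMatrix(traj) else as.matrix(traj)
  if (ncol(coords) != 3L) stop("coords must be K x 3")
  if (max(abs(coords)) > N / 2 + 1e-9)
    stop("coordinates must satisfy |k| <= N/2")
  cache <- list()
  if (method == "nufft") {
    G <- 2L * as.integer(ceiling(oversamp * N / 2))
    kt <- kbTables(width, oversamp)
    d1 <- kbDeapod1d(N, G, width, kt$beta)
    x <- (0:(N - 1)) - N %/% 2
    scoords <- coords * (G / N)
    plan <- cpp_kb_plan(scoords, rep(G, 3L), width, kt$tab)
    cache <- list(
      Gdim = rep(G, 3L), tab = kt$tab, dtab = kt$dtab, beta = kt$beta,
      deapod3 = outer(outer(d1, d1), d1),
      embedIdx = (x %% G) + 1L,
      scoords = scoords, plan = plan,
      scale = N^(-3 / 2))
  } else {
    cache <- list(scale = N^(-3 / 2))
  }
  new("EncodingOperator", gridSize = as.integer(N), coils = cs,
      coords = coords, method = method, oversamp = oversamp, width = width,
      cache = cache)
}

#' Construct a CoilSet
#'
#' @param maps complex array N1 x N2 x N3 x ncoil (a 3D array is treated as
#'   a single coil).
#' @param supportMask optional logical array; defaults to voxels where the
#'   root-sum-of-squares is positive.
#' @return a \linkS4class{CoilSet}.
#' @export
coilSet <- function(maps, supportMask = NULL) {
  if (length(dim(maps)) == 3L) dim(maps) <- c(dim(maps), 1L)
  maps <- maps + 0i
  if (is.null(supportMask)) {
    rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
    supportMask <- rss > 0
  }
  new("CoilSet", maps = maps, supportMask = supportMask)
}

# Flatten trajectory coordinates to a K x 3 matrix, readout index fastest:
# row (j-1)*NRO + i holds readout point i of helix j.
#' @export
#' @rdname trajCoords
trajCoordsMatrix <- function(x) {
  co <- trajCoords(x)
  d <- dim(co)
  matrix(aperm(co, c(2, 1, 3)), d[1] * d[2], 3)
}

# single-volume gridding forward: y[k] = scale * sum_x img(x) e^{-2pi i kx/N}
gridForward <- function(op, img) {
  ca <- op@cache
  if (op@method == "dft") {
    return(cpp_dft3_forward(img + 0i, rep(op@gridSize, 3L), op@coords) *
             ca$scale)
  }
  G <- ca$Gdim[1]
  md <- img / ca$deapod3
  arr <- array(0i, ca$Gdim)
  ix <- ca$embedIdx
  arr[ix, ix, ix] <- md
  Fg <- fft(arr)
  cpp_kb_interp_plan(Fg, ca$Gdim, ca$plan$idx, ca$plan$wgt, ca$plan$taps) *
    ca$scale
}

gridAdjoint <- function(op, yv) {
  ca <- op@cache
  N <- op@gridSize
  if (op@method == "dft") {
    img <- cpp_dft3_adjoint(yv + 0i, rep(N, 3L), op@coords) * ca$scale
    dim(img) <- rep(N, 3L)
    return(img)
  }
  H <- cpp_kb_spread_plan(yv + 0i, ca$Gdim, ca$plan$idx, ca$plan$wgt,
                          ca$plan$taps)
  dim(H) <- ca$Gdim
  B <- fft(H, inverse = TRUE)
  ix <- ca$embedIdx
  B[ix, ix, ix] / ca$deapod3 * ca$scale
}

#' Forward acquisition model
#'
#' Simulates multi-coil non-Cartesian k-space data
#' y[k, c] = scale * sum_x C_c(x) m(x) exp(-2 pi i k . x / N), with voxel
#' coordinates centered at zero and the unitary-style scale N^(-3/2) chosen
#' so the fully sampled Cartesian case matches the orthonormal FFT.
#'
#' @param op an \linkS4class{EncodingOperator}.
#' @param m complex image array N^3.
#' @return complex matrix K x ncoil.
#' @export
setMethod("nufftForward", "EncodingOperator", function(op, m, ...) {
  maps <- op@coils@maps
  nc <- dim(maps)[4]
  out <- matrix(0i, nrow(op@coords), nc)
  for (c in seq_len(nc)) out[, c] <- gridForward(op, m * maps[, , , c])
  out
})

#' Adjoint acquisition model
#'
#' A^H y = sum_c conj(C_c) F^H y_c; density compensation is deliberately not
#' applied (the data-consistency step of the unrolled reconstruction uses the
#' plain adjoint).
#'
#' @param op an \linkS4class{EncodingOperator}.
#' @param y complex matrix K x ncoil (a vector is treated as one coil).
#' @return complex image array N^3.
#' @export
setMethod("nufftAdjoint", "EncodingOperator", function(op, y, ...) {
  maps <- op@coils@maps
  nc <- dim(maps)[4]
  if (is.null(dim(y))) y <- matrix(y, ncol = 1L)
  if (ncol(y) != nc || nrow(y) != nrow(op@coords))
    stop("k-space data shape inconsistent with operator")
  N <- op@gridSize
  m <- array(0i, rep(N, 3L))
  for (c in seq_len(nc)) m <- m + Conj(maps[, , , c]) * gridAdjoint(op, y[, c])
  m
})

#' Add complex Gaussian noise to k-space data
#'
#' Independent zero-mean Gaussian noise of standard deviation \code{sigma} is
#' added to the real and imaginary parts.
#'
#' @param y complex k-space data (any shape).
#' @param sigma noise standard deviation (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @return noisy data with the same shape.
#' @export
addNoise <- function(y, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(y)
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  y + sigma * (rnorm(n) + 1i * rnorm(n))
}
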