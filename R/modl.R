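#' Complex ReLU activation
#'
#' CReLU(d) = ReLU(a) + i ReLU(b) for d = a + i b: the real and imaginary
#' parts are rectified independently, preserving the complex structure the
#' phase-contrast signal lives in.
#'
#' @param d complex array.
#' @return complex array of the same shape.
#' @export
crelu <- function(d) {
  out <- complex(real = pmax(Re(d), 0), imaginary = pmax(Im(d), 0))
  dim(out) <- dim(d)
  out
}

creluBackward <- function(pre, g) {
  out <- complex(real = Re(g) * (Re(pre) > 0),
                 imaginary = Im(g) * (Im(pre) > 0))
  dim(out) <- dim(pre)
  out
}

#' Complex 3D convolution layer
#'
#' For complex kernel W = X + iY and data d = a + ib the layer computes
#' W * d = (X*a - Y*b) + i(Y*a + X*b) -- four real convolutions, with no
#' real/imaginary channel mixing beyond this formula -- plus a complex bias
#' per output channel. "Convolution" follows CNN convention
#' (cross-correlation, zero 'same' padding).
#'
#' @param d complex array nx x ny x nz x cin (a 3D array is one channel).
#' @param layer list with real arrays \code{X}, \code{Y} of shape
#'   kw^3 x cin x cout and numeric \code{biasRe}, \code{biasIm} (length cout).
#' @return complex array nx x ny x nz x cout.
#' @export
complexConv <- function(d, layer) {
  if (length(dim(d)) == 3L) dim(d) <- c(dim(d), 1L)
  dims <- dim(d)
  kd <- dim(layer$X)
  a <- Re(d); b <- Im(d)
  re <- cpp_conv3d(a, dims, layer$X, kd) - cpp_conv3d(b, dims, layer$Y, kd)
  im <- cpp_conv3d(a, dims, layer$Y, kd) + cpp_conv3d(b, dims, layer$X, kd)
  cout <- kd[5]
  if (!is.null(layer$biasRe)) {
    bre <- rep(layer$biasRe, each = prod(dims[1:3]))
    bim <- rep(layer$biasIm, each = prod(dims[1:3]))
    re <- re + bre; im <- im + bim
  }
  out <- complex(real = re, imaginary = im)
  dim(out) <- c(dims[1:3], cout)
  out
}

flipKernel <- function(k) {
  kw <- dim(k)[1]
  aperm(k[kw:1, kw:1, kw:1, , , drop = FALSE], c(1, 2, 3, 5, 4))
}

# VJP of complexConv: returns cotangent on the input and gradients of the
# layer parameters.
complexConvBackward <- function(d, layer, g) {
  if (length(dim(d)) == 3L) dim(d) <- c(dim(d), 1L)
  dims <- dim(d)
  odims <- dim(g)
  kd <- dim(layer$X)
  kw <- kd[1]; cin <- kd[4]; cout <- kd[5]
  a <- Re(d); b <- Im(d)
  gr <- Re(g); gi <- Im(g)
  fX <- flipKernel(layer$X); fY <- flipKernel(layer$Y)
  fkd <- dim(fX)
  ga <- cpp_conv3d(gr, odims, fX, fkd) + cpp_conv3d(gi, odims, fY, fkd)
  gb <- cpp_conv3d(gi, odims, fX, fkd) - cpp_conv3d(gr, odims, fY, fkd)
  gX <- cpp_conv3d_wgrad(a, dims, gr, kw, cout) +
    cpp_conv3d_wgrad(b, dims, gi, kw, cout)
  gY <- cpp_conv3d_wgrad(a, dims, gi, kw, cout) -
    cpp_conv3d_wgrad(b, dims, gr, kw, cout)
  gin <- complex(real = ga, imaginary = gb)
  dim(gin) <- dims
  list(gin = gin, gX = gX, gY = gY,
       gbiasRe = apply(gr, 4, sum), gbiasIm = apply(gi, 4, sum))
}

#' MoDL configuration constructor
#'
#' Defaults follow the published architecture: 6 unrolls of shared-weight
#' DC-CNN layers, a 5-layer complex ResNet denoiser with 3^3 kernels. The
#' hidden width defaults to 29 features, the width whose closed-form
#' parameter count (see \code{\link{modlParamCount}}) is nearest the
#' published 139,680.
#'
#' @param nUnrolls,nLayers,features,kernel,blockSize,blockOverlap,shareWeights
#'   see \linkS4class{MoDLConfig}.
#' @return a \linkS4class{MoDLConfig}.
#' @export
modlConfig <- function(nUnrolls = 6L, nLayers = 5L, features = 29L,
                       kernel = 3L, blockSize = 64L, blockOverlap = 8L,
                       shareWeights = TRUE) {
  new("MoDLConfig", nUnrolls = as.integer(nUnrolls),
      nLayers = as.integer(nLayers), features = as.integer(features),
      kernel = as.integer(kernel), blockSize = as.integer(blockSize),
      blockOverlap = as.integer(blockOverlap), shareWeights = shareWeights)
}

#' Closed-form trainable parameter count of the denoiser
#'
#' Channel widths are (1, F, ..., F, 1) over nLayers complex conv layers with
#' k^3 kernels and complex biases; every complex kernel/bias contributes two
#' real parameters: count = 2 * sum_l (k^3 cin_l cout_l + cout_l). For the
#' default depth 5 and kernel 3 this is 162 F^2 + 116 F + 2; F = 29 gives
#' 139,608, the width nearest the published total.
#'
#' @param cfg a \linkS4class{MoDLConfig}.
#' @return integer parameter count.
#' @export
modlParamCount <- function(cfg) {
  w <- c(1L, rep(cfg@features, cfg@nLayers - 1L), 1L)
  k3 <- cfg@kernel^3
  total <- 0L
  for (l in seq_len(cfg@nLayers))
    total <- total + 2L * (k3 * w[l] * w[l + 1L] + w[l + 1L])
  total
}

#' Initialize denoiser weights
#'
#' He-style scaled Gaussian initialization of the real and imaginary kernel
#' parts, damped by \code{initScale} so the residual network starts close to
#' the identity; biases start at zero.
#'
#' @param cfg a \linkS4class{MoDLConfig}.
#' @param seed integer seed.
#' @param initScale multiplier on the init standard deviation.
#' @return list of layers (fields X, Y, biasRe, biasIm).
#' @export
initDenoiser <- function(cfg, seed = 1L, initScale = 0.1) {
  set.seed(seed)
  w <- c(1L, rep(cfg@features, cfg@nLayers - 1L), 1L)
  kw <- cfg@kernel
  lapply(seq_len(cfg@nLayers), function(l) {
    cin <- w[l]; cout <- w[l + 1L]
    sdv <- sqrt(1 / (kw^3 * cin * 2)) * initScale
    list(X = array(rnorm(kw^3 * cin * cout, sd = sdv), c(kw, kw, kw, cin, cout)),
         Y = array(rnorm(kw^3 * cin * cout, sd = sdv), c(kw, kw, kw, cin, cout)),
         biasRe = numeric(cout), biasIm = numeric(cout))
  })
}

zeroDenoiser <- function(cfg) {
  w <- c(1L, rep(cfg@features, cfg@nLayers - 1L), 1L)
  kw <- cfg@kernel
  lapply(seq_len(cfg@nLayers), function(l)
    list(X = array(0, c(kw, kw, kw, w[l], w[l + 1L])),
         Y = array(0, c(kw, kw, kw, w[l], w[l + 1L])),
         biasRe = numeric(w[l + 1L]), biasIm = numeric(w[l + 1L])))
}

# forward pass; optionally keep the per-layer tape (inputs + preactivations)
denoiserForwardInternal <- function(z, weights, keepTape = FALSE) {
  L <- length(weights)
  h <- z
  dim(h) <- c(dim(z), 1L)
  tape <- if (keepTape) vector("list", L) else NULL
  for (l in seq_len(L)) {
    pre <- complexConv(h, weights[[l]])
    if (keepTape) tape[[l]] <- list(input = h, pre = pre)
    h <- if (l < L) crelu(pre) else pre
  }
  out <- z + array(h, dim(z))       # global residual connection
  list(out = out, tape = tape)
}

#' Apply the complex ResNet denoiser
#'
#' nLayers complex convolutions with CReLU between hidden layers and a global
#' residual connection (input added to output): with all-zero weights the
#' denoiser is exactly the identity.
#'
#' @param z complex image array N^3.
#' @param weights layer list from \code{\link{initDenoiser}}.
#' @return denoised complex array, same shape.
#' @export
denoiserApply <- function(z, weights) {
  denoiserForwardInternal(z, weights)$out
}

# Backward through the denoiser given cotangent g on the output.
# checkpoint = TRUE stores only the input and recomputes the activations in
# the backward pass (gradients are bit-identical; stored bytes are smaller).
#' Denoiser gradients (optionally gradient-checkpointed)
#'
#' Returns the cotangent on the input and the weight gradients for a scalar
#' loss with output cotangent \code{g}. With \code{checkpoint = TRUE} only
#' the denoiser input is stored during the forward pass and the per-layer
#' activations are recomputed during backward: gradients are identical and
#' stored memory is lower, at the cost of recomputation.
#'
#' @param z complex input array.
#' @param weights layer list.
#' @param g complex cotangent on the output (same shape as z).
#' @param checkpoint logical.
#' @return list(gz, gWeights, storedBytes).
#' @export
denoiserGrad <- function(z, weights, g, checkpoint = FALSE, tape = NULL) {
  if (checkpoint) {
    # only the input was stored; recompute the activations now
    storedBytes <- as.numeric(object.size(z))
    fw <- denoiserForwardInternal(z, weights, keepTape = TRUE)
  } else if (!is.null(tape)) {
    # activations were stored during the forward pass
    fw <- list(tape = tape)
    storedBytes <- sum(vapply(tape, function(t)
      as.numeric(object.size(t$input)) + as.numeric(object.size(t$pre)),
      numeric(1)))
  } else {
    fw <- denoiserForwardInternal(z, weights, keepTape = TRUE)
    storedBytes <- sum(vapply(fw$tape, function(t)
      as.numeric(object.size(t$input)) + as.numeric(object.size(t$pre)),
      numeric(1)))
  }
  L <- length(weights)
  gW <- vector("list", L)
  gcur <- g
  dim(gcur) <- c(dim(z), 1L)
  for (l in L:1) {
    bk <- complexConvBackward(fw$tape[[l]]$input, weights[[l]], gcur)
    gW[[l]] <- list(gX = bk$gX, gY = bk$gY, gbiasRe = bk$gbiasRe,
                    gbiasIm = bk$gbiasIm)
    if (l > 1) gcur <- creluBackward(fw$tape[[l - 1]]$pre, bk$gin)
    else gcur <- bk$gin
  }
  gz <- g + array(gcur, dim(z))     # residual path
  list(gz = gz, gWeights = gW, storedBytes = storedBytes)
}

#' Data-consistency step
#'
#' One proximal-gradient step on ||A m - y||^2:
#' z = m - 2 alpha A^H (A m - y).
#'
#' @param m current complex image estimate.
#' @param y measured k-space data K x ncoil.
#' @param op an \linkS4class{EncodingOperator}.
#' @param alpha real step size.
#' @return updated complex image.
#' @export
dcStep <- function(m, y, op, alpha) {
  m - 2 * alpha * nufftAdjoint(op, nufftForward(op, m) - y)
}

#' Unrolled model-based reconstruction
#'
#' m0 = A^H y, then \code{nUnrolls} alternations of the data-consistency step
#' and the complex ResNet denoiser (weights shared across unrolls). The
#' denoiser can be applied blockwise for large volumes.
#'
#' @param y k-space data K x ncoil.
#' @param op an \linkS4class{EncodingOperator}.
#' @param cfg a \linkS4class{MoDLConfig}.
#' @param weights denoiser layer list.
#' @param alpha step size.
#' @param blockwise apply the denoiser via \code{\link{blockwiseApply}}.
#' @return reconstructed complex image.
#' @export
unrolledRecon <- function(y, op, cfg, weights, alpha, blockwise = FALSE) {
  m <- nufftAdjoint(op, y)
  norm0 <- sqrt(sum(Mod(m)^2))
  for (t in seq_len(cfg@nUnrolls)) {
    z <- dcStep(m, y, op, alpha)
    m <- if (blockwise)
      blockwiseApply(z, function(b) denoiserApply(b, weights),
                     cfg@blockSize, cfg@blockOverlap)
    else denoiserApply(z, weights)
    nm <- sqrt(sum(Mod(m)^2))
    if (!is.finite(nm) || nm > 1e6 * max(norm0, 1e-12))
      stop("unrolled reconstruction diverged")
  }
  m
}

# per-axis tiling: block start positions and, for crop blending, the owned
# core [ownStart, ownEnd] of each block (an exact partition of the axis).
blockAxisPlan <- function(N, blockSize, overlap) {
  if (blockSize >= N)
    return(list(start = 1L, end = N, own0 = 1L, own1 = N))
  step <- blockSize - overlap
  starts <- seq(1L, N - blockSize, by = step)
  starts <- c(starts, N - blockSize + 1L)
  starts <- unique(pmin(starts, N - blockSize + 1L))
  ends <- starts + blockSize - 1L
  nb <- length(starts)
  own0 <- integer(nb); own1 <- integer(nb)
  for (i in seq_len(nb)) {
    own0[i] <- if (i == 1L) 1L else (starts[i] + ends[i - 1L]) %/% 2L + 1L
    own1[i] <- if (i == nb) N else (starts[i + 1L] + ends[i]) %/% 2L
  }
  list(start = starts, end = ends, own0 = own0, own1 = own1)
}

#' Apply a function to a volume in overlapping blocks
#'
#' The volume is tiled into cubes of edge \code{blockSize} overlapping by
#' \code{overlap}; \code{fn} is applied per block and the results are
#' reassembled. \code{blend = "crop"} (default) assigns every voxel to
#' exactly one block core (the overlap is split at its midpoint) -- an exact
#' partition of unity, so \code{fn = identity} returns the input bit-equal.
#' \code{blend = "average"} averages all overlapping contributions uniformly.
#' Blocks larger than the volume fall back to a single block.
#'
#' @param vol 3D array (numeric or complex).
#' @param fn function taking and returning a block of identical shape.
#' @param blockSize block edge length (voxels).
#' @param overlap overlap (voxels), < blockSize.
#' @param blend "crop" or "average".
#' @return array of the same shape as \code{vol}.
#' @export
blockwiseApply <- function(vol, fn, blockSize, overlap,
                           blend = c("crop", "average")) {
  blend <- match.arg(blend)
  if (overlap >= blockSize) stop("overlap must be < blockSize")
  d <- dim(vol)
  px <- blockAxisPlan(d[1], blockSize, overlap)
  py <- blockAxisPlan(d[2], blockSize, overlap)
  pz <- blockAxisPlan(d[3], blockSize, overlap)
  out <- array(if (is.complex(vol)) 0i else 0, d)
  den <- if (blend == "average") array(0, d) else NULL
  for (iz in seq_along(pz$start)) for (iy in seq_along(py$start))
    for (ix in seq_along(px$start)) {
      bx <- px$start[ix]:px$end[ix]
      by <- py$start[iy]:py$end[iy]
      bz <- pz$start[iz]:pz$end[iz]
      res <- fn(vol[bx, by, bz, drop = FALSE])
      if (!identical(dim(res), c(length(bx), length(by), length(bz))))
        stop("fn must preserve block shape")
      if (blend == "crop") {
        ox <- px$own0[ix]:px$own1[ix]; oy <- py$own0[iy]:py$own1[iy]
        oz <- pz$own0[iz]:pz$own1[iz]
        out[ox, oy, oz] <- res[ox - bx[1] + 1L, oy - by[1] + 1L,
                               oz - bz[1] + 1L]
      } else {
        out[bx, by, bz] <- out[bx, by, bz] + res
        den[bx, by, bz] <- den[bx, by, bz] + 1
      }
    }
  if (blend == "average") out <- out / den
  out
}
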