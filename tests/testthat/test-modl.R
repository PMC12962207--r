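test_that("complex ReLU rectifies real and imaginary parts independently", {
  z <- c(1 + 2i, -1 - 2i, -1 + 2i, 3 - 0.5i)
  expect_equal(crelu(z), c(1 + 2i, 0 + 0i, 0 + 2i, 3 + 0i))
  arr <- array(c(1 + 2i, -1 - 2i), c(1, 2, 1))
  expect_equal(dim(crelu(arr)), dim(arr))
})

test_that("complex convolution implements (X*a - Y*b) + i(Y*a + X*b) exactly", {
  set.seed(4)
  d <- array(rnorm(125) + 1i * rnorm(125), c(5, 5, 5, 1))
  layer <- list(X = array(rnorm(27), c(3, 3, 3, 1, 1)),
                Y = array(rnorm(27), c(3, 3, 3, 1, 1)),
                biasRe = 0.3, biasIm = -0.2)
  out <- complexConv(d, layer)
  # brute-force complex multiply-accumulate oracle
  W <- layer$X + 1i * layer$Y
  bf <- array(0i, c(5, 5, 5, 1))
  for (x in 1:5) for (y in 1:5) for (z in 1:5) {
    acc <- 0i
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (min(xx, yy, zz) >= 1 && max(xx, yy, zz) <= 5)
        acc <- acc + W[dx + 2, dy + 2, dz + 2, 1, 1] * d[xx, yy, zz, 1]
    }
    bf[x, y, z, 1] <- acc + layer$biasRe + 1i * layer$biasIm
  }
  expect_lt(max(Mod(out - bf)), 1e-12)
  # 1x1x1 kernel W = i multiplies the input by i
  li <- list(X = array(0, c(1, 1, 1, 1, 1)), Y = array(1, c(1, 1, 1, 1, 1)),
             biasRe = 0, biasIm = 0)
  expect_equal(complexConv(d, li), 1i * d)
  # real kernel (Y = 0): identical real convolution of both parts
  lr <- list(X = layer$X, Y = array(0, c(3, 3, 3, 1, 1)), biasRe = 0,
             biasIm = 0)
  outR <- complexConv(d, lr)
  outRe <- complexConv(Re(d) + 0i, lr)
  outIm <- complexConv(Im(d) + 0i, lr)
  expect_lt(max(Mod(outR - (Re(outRe) + 1i * Re(outIm)))), 1e-12)
})

test_that("denoiser with zero weights is the identity and parameter count follows the closed form", {
  cfg <- modlConfig(features = 4L)
  z <- randomImage(8L, seed = 1)
  zw <- WaveRecon:::zeroDenoiser(cfg)
  expect_identical(denoiserApply(z, zw), z)
  # closed-form count 2 * sum(k^3 cin cout + cout); 162 F^2 + 116 F + 2 at
  # depth 5 / kernel 3; width 29 is nearest the published 139,680 total
  for (f in c(4L, 8L, 29L)) {
    cf <- modlConfig(features = f)
    expect_equal(modlParamCount(cf), 162L * f^2 + 116L * f + 2L)
    w <- initDenoiser(cf, seed = 1)
    actual <- sum(vapply(w, function(l)
      2L * length(l$X) + 2L * length(l$biasRe), integer(1)))
    expect_equal(actual, modlParamCount(cf))
  }
  expect_equal(modlParamCount(modlConfig()), 139608L)
  # finite outputs over many random inits
  for (s in 1:20) {
    w <- initDenoiser(modlConfig(features = 3L), seed = s)
    o <- denoiserApply(randomImage(6L, seed = s), w)
    expect_true(all(is.finite(Re(o))) && all(is.finite(Im(o))))
  }
})

test_that("data-consistency step matches a dense-matrix oracle and its degeneracies", {
  N <- 8L
  m <- randomImage(N, seed = 2)
  g <- cartesianCoords(N)
  op <- encodingOperator(uniformCoil(N), g, method = "dft")
  y <- nufftForward(op, m)
  # zero residual and zero step size are both identities
  expect_lt(max(Mod(dcStep(m, y, op, 0.4) - m)), 1e-10)
  set.seed(3)
  m2 <- randomImage(N, seed = 3)
  expect_identical(dcStep(m2, y, op, 0), m2)
  # dense-matrix oracle: A explicitly as a K x N^3 matrix
  xs <- (0:(N - 1)) - N / 2
  X <- as.matrix(expand.grid(x = xs, y = xs, z = xs))
  A <- exp(-2i * pi * (g %*% t(X)) / N) / N^(3 / 2)
  z <- dcStep(m2, y, op, 0.37)
  zDense <- as.vector(m2) - 2 * 0.37 *
    (Conj(t(A)) %*% (A %*% as.vector(m2) - as.vector(y)))
  expect_lt(relErr(as.vector(z), as.vector(zDense)), 1e-6)
})

test_that("unrolled reconstruction reduces to gradient descent and converges on clean Cartesian data", {
  N <- 8L
  m <- randomImage(N, seed = 5)
  g <- cartesianCoords(N)
  op <- encodingOperator(uniformCoil(N), g, method = "dft")
  y <- nufftForward(op, m)
  cfg1 <- modlConfig(nUnrolls = 1L, features = 2L)
  zw <- WaveRecon:::zeroDenoiser(cfg1)
  rec1 <- unrolledRecon(y, op, cfg1, zw, 0.3)
  m0 <- nufftAdjoint(op, y)
  expect_lt(max(Mod(rec1 - dcStep(m0, y, op, 0.3))), 1e-12)
  # identity denoiser: error decreases monotonically with unroll count
  errs <- vapply(1:4, function(u) {
    cfg <- modlConfig(nUnrolls = u, features = 2L)
    sqrt(sum(Mod(unrolledRecon(y, op, cfg, zw, 0.2) - m)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("blockwise application is an exact partition of unity and localizes denoiser discrepancy", {
  v <- randomImage(20L, seed = 6)
  expect_identical(blockwiseApply(v, identity, 8L, 4L), v)
  # uniform averaging is exact only to rounding (n identical terms summed),
  # which is why crop blending is the default
  expect_equal(blockwiseApply(v, identity, 8L, 4L, blend = "average"), v,
               tolerance = 1e-12)
  doubled <- blockwiseApply(v, function(b) 2 * b, 8L, 4L)
  expect_equal(doubled, 2 * v)
  # block larger than volume: single-block fallback
  expect_identical(blockwiseApply(v, identity, 64L, 8L), v)
  expect_error(blockwiseApply(v, identity, 8L, 8L), "overlap")
  # denoiser blockwise vs whole-volume: discrepancy confined to block
  # borders and small relative to the dynamic range (8-voxel overlap)
  cfg <- modlConfig(features = 3L)
  w <- initDenoiser(cfg, seed = 7, initScale = 0.5)
  vol <- randomImage(32L, seed = 8)
  whole <- denoiserApply(vol, w)
  blocked <- blockwiseApply(vol, function(b) denoiserApply(b, w), 16L, 8L)
  d <- Mod(blocked - whole)
  expect_lt(max(d), 0.05 * diff(range(Mod(whole))))
  # interior of the first block core matches exactly
  expect_lt(max(d[2:7, 2:7, 2:7]), 1e-12)
})

test_that("gradient checkpointing reproduces gradients bit-for-bit with less stored memory", {
  cfg <- modlConfig(features = 4L)
  w <- initDenoiser(cfg, seed = 9, initScale = 0.5)
  z <- randomImage(12L, seed = 10)
  g <- randomImage(12L, seed = 11)
  full <- denoiserGrad(z, w, g, checkpoint = FALSE)
  ckpt <- denoiserGrad(z, w, g, checkpoint = TRUE)
  expect_identical(full$gz, ckpt$gz)
  expect_identical(full$gWeights, ckpt$gWeights)
  expect_lt(ckpt$storedBytes, full$storedBytes)
  # forward outputs are unaffected by how gradients will be computed
  expect_identical(denoiserApply(z, w), denoiserApply(z, w))
})

test_that("the DC step is non-expansive for step sizes below the spectral bound", {
  N <- 8L
  set.seed(12)
  coords <- randomCoords(300L, N, seed = 12)
  op <- encodingOperator(synthCoils(N, 2L, seed = 13), coords, method = "dft")
  L <- powerIterNormalOp(op, iters = 30L, seed = 14)
  alpha <- 0.5 / L
  m <- randomImage(N, seed = 15)
  y <- nufftForward(op, m)
  # iterates contract toward the data-consistent solution m
  x <- randomImage(N, seed = 16)
  d0 <- sqrt(sum(Mod(x - m)^2))
  for (i in 1:5) x <- dcStep(x, y, op, alpha)
  expect_lt(sqrt(sum(Mod(x - m)^2)), d0)
})

test_that("reconstruction preserves a pure phase ramp on noiseless data", {
  # phase fidelity: the motivation for the fully complex network
  N <- 16L
  xn <- (((0:(N - 1)) - N / 2) / N)
  ramp <- array(rep(xn, times = N * N), rep(N, 3))
  m <- exp(2i * pi * 1.5 * ramp)
  g <- cartesianCoords(N)
  op <- encodingOperator(uniformCoil(N), g, method = "nufft", width = 6,
                         oversamp = 2)
  y <- nufftForward(op, m)
  cfg <- modlConfig(nUnrolls = 2L, features = 2L)
  rec <- unrolledRecon(y, op, cfg, WaveRecon:::zeroDenoiser(cfg), 0.5)
  # fit the recovered phase slope along x through the volume center
  ph <- Arg(rec[, N / 2 + 1, N / 2 + 1] * Conj(m[, N / 2 + 1, N / 2 + 1]))
  expect_lt(max(abs(ph)), 2 * pi * 0.01)
})
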