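# Finite-difference oracles for the analytic coordinate Jacobians, run in the
# exact-DFT float64 mode so the FD reference differentiates the true
# transform (central differences, step 1e-4 grid units).

fdLoss <- function(lossFn, coords, k, d, h = 1e-4) {
  cp <- coords; cp[k, d] <- cp[k, d] + h
  cm <- coords; cm[k, d] <- cm[k, d] - h
  (lossFn(cp) - lossFn(cm)) / (2 * h)
}

test_that("forward-model coordinate gradient matches central finite differences", {
  N <- 12L
  m <- randomImage(N, seed = 1)
  coils <- synthCoils(N, 2L, seed = 2)
  set.seed(3)
  for (rep in 1:4) {
    coords <- randomCoords(40L, N, seed = 10 + rep, margin = 1)
    y0 <- matrix(rnorm(80) + 1i * rnorm(80), 40, 2)
    lossFn <- function(cm) {
      op <- encodingOperator(coils, cm, method = "dft")
      sum(Mod(nufftForward(op, m) - y0)^2)
    }
    op <- encodingOperator(coils, coords, method = "dft")
    gy <- 2 * (nufftForward(op, m) - y0)
    gc <- coordGradForward(op, m, gy)
    for (t in 1:3) {
      k <- sample(40, 1); d <- sample(3, 1)
      fd <- fdLoss(lossFn, coords, k, d)
      expect_lt(abs(gc[k, d] - fd) / max(abs(fd), 1e-8), 1e-4)
    }
    # zero cotangent -> zero gradient
    expect_equal(max(abs(coordGradForward(op, m, gy * 0))), 0)
  }
})

test_that("adjoint-model coordinate gradient matches finite differences and forward/adjoint duality", {
  N <- 12L
  coils <- synthCoils(N, 2L, seed = 5)
  b <- randomImage(N, seed = 6)
  set.seed(7)
  for (rep in 1:3) {
    coords <- randomCoords(30L, N, seed = 20 + rep, margin = 1)
    y <- matrix(rnorm(60) + 1i * rnorm(60), 30, 2)
    lossFn <- function(cm) {
      op <- encodingOperator(coils, cm, method = "dft")
      sum(Mod(nufftAdjoint(op, y) - b)^2)
    }
    op <- encodingOperator(coils, coords, method = "dft")
    gm <- 2 * (nufftAdjoint(op, y) - b)
    ga <- coordGradAdjoint(op, y, gm)
    for (t in 1:3) {
      k <- sample(30, 1); d <- sample(3, 1)
      fd <- fdLoss(lossFn, coords, k, d)
      expect_lt(abs(ga[k, d] - fd) / max(abs(fd), 1e-8), 1e-4)
    }
    expect_equal(max(abs(coordGradAdjoint(op, y, gm * 0))), 0)
    # duality: d/dw Re<A m, y> through the forward path equals d/dw
    # Re<m, A^H y> through the adjoint path
    m <- randomImage(N, seed = 30 + rep)
    gF <- coordGradForward(op, m, y)        # cotangent y on forward output
    gA <- coordGradAdjoint(op, y, m)        # cotangent m on adjoint output
    expect_lt(max(abs(gF - gA)) / max(abs(gF)), 1e-5)
  }
})

test_that("a real even-symmetric image has zero gradient at the k-space center", {
  N <- 12L
  set.seed(9)
  half <- array(rnorm(N^3), rep(N, 3))
  # symmetrize about the center voxel (indices 1 and N/2+1 are self-conjugate)
  ix <- c(1, N:2)
  even <- (half + half[ix, ix, ix]) / 2
  op <- encodingOperator(uniformCoil(N), matrix(0, 1, 3), method = "dft")
  g <- coordGradForward(op, even + 0i, matrix(1 + 0i, 1, 1))
  expect_lt(max(abs(g)), 1e-12)
})

test_that("chained wave-parameter gradients match finite differences over theta, sr and centers", {
  s <- tinyWaveSetup(N = 10L, npe = 5L, nro = 8L, seed = 13)
  wp <- s$wp; hs <- s$hs
  N <- wp@matrixSize
  m <- randomImage(N, seed = 14)
  coils <- synthCoils(N, 2L, seed = 15)
  K <- 5L * wp@nReadout
  set.seed(16)
  y0 <- matrix(rnorm(2 * K) + 1i * rnorm(2 * K), K, 2)
  lossHS <- function(hs2) {
    tr <- buildTrajectory(wp, hs2, "wave")
    op <- encodingOperator(coils, trajCoordsMatrix(tr), method = "dft")
    sum(Mod(nufftForward(op, m) - y0)^2)
  }
  tr <- buildTrajectory(wp, hs, "wave")
  op <- encodingOperator(coils, trajCoordsMatrix(tr), method = "dft")
  gy <- 2 * (nufftForward(op, m) - y0)
  gc <- coordGradForward(op, m, gy)
  cw <- chainToWaveParams(gc, hs, wp, "wave")
  h <- 1e-5
  for (j in c(1L, 3L, 5L)) for (fld in c("theta", "sr", "kyc", "kzc")) {
    hp <- hs; hm <- hs
    slot(hp, fld)[j] <- slot(hp, fld)[j] + h
    slot(hm, fld)[j] <- slot(hm, fld)[j] - h
    fd <- (lossHS(hp) - lossHS(hm)) / (2 * h)
    expect_lt(abs(cw[[paste0("d_", fld)]][j] - fd) / max(abs(fd), 1e-8), 1e-4)
  }
  # unit partial: d_kyc is the sum of ky-axis gradients along each readout
  dky <- matrix(gc[, 2], wp@nReadout, 5L)
  expect_equal(cw$d_kyc, colSums(dky), tolerance = 1e-12)
  # zero coordinate gradients chain to zeros
  cw0 <- chainToWaveParams(gc * 0, hs, wp, "wave")
  expect_true(all(unlist(cw0) == 0))
  # no-wave mode exposes only the center gradients
  cwN <- chainToWaveParams(gc, hs, wp, "no_wave")
  expect_true(all(cwN$d_sr == 0) && all(cwN$d_theta == 0))
  expect_equal(cwN$d_kyc, colSums(dky), tolerance = 1e-12)
})

test_that("end-to-end gradient through the unrolled reconstruction matches finite differences", {
  s <- tinyWaveSetup(N = 10L, npe = 4L, nro = 8L, seed = 21)
  wp <- s$wp; hs <- s$hs
  N <- wp@matrixSize
  mRef <- randomImage(N, seed = 22)
  coils <- synthCoils(N, 2L, seed = 23)
  cfg <- modlConfig(features = 3L, nUnrolls = 2L)
  w <- initDenoiser(cfg, seed = 24, initScale = 0.4)
  alpha <- 0.3
  K <- 4L * wp@nReadout
  set.seed(25)
  noise <- matrix(rnorm(2 * K, sd = 0.01) + 1i * rnorm(2 * K, sd = 0.01), K, 2)
  lossFull <- function(hs2) {
    tr <- buildTrajectory(wp, hs2, "wave")
    op <- encodingOperator(coils, trajCoordsMatrix(tr), method = "dft")
    caseLossGrad(mRef, op, w, alpha, 2L, noise = noise,
                 wantCoordGrad = FALSE, wantWeightGrad = FALSE)$loss
  }
  tr <- buildTrajectory(wp, hs, "wave")
  op <- encodingOperator(coils, trajCoordsMatrix(tr), method = "dft")
  res <- caseLossGrad(mRef, op, w, alpha, 2L, noise = noise)
  cw <- chainToWaveParams(res$gCoords, hs, wp, "wave")
  h <- 1e-5
  for (j in c(2L, 4L)) for (fld in c("theta", "kyc")) {
    hp <- hs; hm <- hs
    slot(hp, fld)[j] <- slot(hp, fld)[j] + h
    slot(hm, fld)[j] <- slot(hm, fld)[j] - h
    fd <- (lossFull(hp) - lossFull(hm)) / (2 * h)
    expect_lt(abs(cw[[paste0("d_", fld)]][j] - fd) / max(abs(fd), 1e-8), 1e-3)
  }
})

test_that("interpolation-kernel autodiff is less accurate than the analytic Jacobian", {
  # the motivation for custom gradients: differentiating the gridding
  # interpolator amplifies its approximation error, while the analytic
  # Jacobian (a NUFFT of the x-weighted image) tracks the true transform.
  N <- 12L
  m <- randomImage(N, seed = 31)
  coils <- synthCoils(N, 2L, seed = 32)
  coords <- randomCoords(60L, N, seed = 33, margin = 1)
  set.seed(34)
  y0 <- matrix(rnorm(120) + 1i * rnorm(120), 60, 2)
  opD <- encodingOperator(coils, coords, method = "dft")
  gy <- 2 * (nufftForward(opD, m) - y0)
  exact <- coordGradForward(opD, m, gy)         # gradient of the true loss
  opN <- encodingOperator(coils, coords, method = "nufft")
  analytic <- coordGradForward(opN, m, gy)      # Jacobian route through NUFFT
  naive <- coordGradForwardNaive(opN, m, gy)    # kernel-derivative route
  errAnalytic <- max(abs(analytic - exact)) / max(abs(exact))
  errNaive <- max(abs(naive - exact)) / max(abs(exact))
  expect_lt(errAnalytic, errNaive)
})
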