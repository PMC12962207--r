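test_that("helix phase is monotone, crosses the echo, and matches direct substitution", {
  wp <- waveParams(radius = 6, cycles = 8L, echoFraction = 0.75,
                   nReadout = 96L, matrixSize = 64L, dwell = 2.7e-3 / 96)
  i <- 0:wp@nReadout
  phi <- helixPhase(i, wp)
  expect_true(all(diff(phi) > 0))
  iEcho <- wp@nReadout * (wp@echoFraction - 0.5) / wp@echoFraction
  expect_equal(helixPhase(iEcho, wp), 0, tolerance = 1e-12)
  expect_equal(helixPhase(0, wp), -4 * pi)
  expect_equal(helixPhase(wp@nReadout, wp), 8 * pi)
  expect_error(helixPhase(-1, wp), "out of range")
  expect_error(helixPhase(wp@nReadout + 1, wp), "out of range")
  # kx mapping: echo at kx = 0, partial echo spans -(ef-1/2)N .. N/2
  kx <- kxFromPhase(phi, wp)
  expect_equal(min(kx), -0.25 * wp@matrixSize)
  expect_equal(max(kx), 0.5 * wp@matrixSize)
  expect_equal(kxFromPhase(helixPhase(iEcho, wp), wp), 0)
})

test_that("helix readouts satisfy the circle identity, periodicity and degeneracies", {
  wp <- waveParams(radius = 5, cycles = 4L, matrixSize = 32L, nReadout = 64L,
                   dwell = 2.7e-3 / 64)
  h <- buildHelix(wp, sr = 0.7, theta = 1.2, center = c(3, -2))
  rad <- sqrt((h[, 2] - 3)^2 + (h[, 3] + 2)^2)
  expect_lt(max(abs(rad - 0.7 * wp@radius)), 1e-12)
  h2 <- buildHelix(wp, sr = 0.7, theta = 1.2 + 2 * pi, center = c(3, -2))
  expect_equal(h, h2, tolerance = 1e-12)
  # straight-line readout is the zero-radius degenerate helix
  h0 <- buildHelix(wp, center = c(3, -2), mode = "no_wave")
  expect_true(all(h0[, 2] == 3) && all(h0[, 3] == -2))
  expect_error(buildHelix(wp, sr = 1.5), "sr")
  expect_error(buildHelix(wp, sr = 0), "sr")
})

test_that("full trajectories have the stated shape and share the base helix", {
  wp <- waveParams(radius = 4, cycles = 4L, matrixSize = 32L, nReadout = 48L,
                   dwell = 2.7e-3 / 48)
  hs <- helixSet(c(-5, 0, 5, 2), c(1, -3, 0, 4))
  tr <- buildTrajectory(wp, hs, "wave")
  expect_equal(dim(tr@coords), c(4L, 48L, 3L))
  # with sr = 1, theta = 0 every helix is a translate of the base helix
  base <- buildHelix(wp, sr = 1, theta = 0, center = c(0, 0))
  for (j in 1:4) {
    expect_equal(tr@coords[j, , 2], base[, 2] + hs@kyc[j], tolerance = 1e-12)
    expect_equal(tr@coords[j, , 3], base[, 3] + hs@kzc[j], tolerance = 1e-12)
  }
  # no-wave mode: zero variance along the readout
  tr0 <- buildTrajectory(wp, hs, "no_wave")
  expect_equal(max(apply(tr0@coords[, , 2], 1, var)), 0)
  expect_equal(max(apply(tr0@coords[, , 3], 1, var)), 0)
})

test_that("gradient conversion matches hand arithmetic and closed-form slew bounds", {
  N <- 32L
  wp <- waveParams(radius = 2, cycles = 2L, matrixSize = N, nReadout = 64L,
                   dwell = 1e-5, fov = 220)
  # constant coordinates -> zero gradient
  hs <- helixSet(0, 0)
  tr0 <- buildTrajectory(wp, hs, "no_wave")
  tr0@coords[1, , 1] <- 0
  gw0 <- trajToGradient(tr0, wp)
  expect_equal(max(abs(gw0$g)), 0)
  # linear kx ramp of 1 grid unit per dwell
  trR <- tr0
  trR@coords[1, , 1] <- seq_len(wp@nReadout) * 1 - 10
  gwR <- trajToGradient(trR, wp)
  gExpect <- 1 / (42.577478518e6 * 1e-5 * 0.22) * 1000     # mT/m
  expect_equal(max(abs(gwR$g[1, , 1] - gExpect)), 0, tolerance = 1e-9)
  # sinusoidal ky: peak slew approx amplitude * omega^2 / (gamma FOV)
  a <- 3
  omega <- 2 * pi * wp@cycles * wp@echoFraction / (wp@nReadout * wp@dwell)
  trS <- buildTrajectory(wp, helixSet(0, 0, sr = 1, theta = 0), "wave")
  trS@coords[1, , 2] <- a * sin(omega * wp@dwell * (seq_len(wp@nReadout) - 1))
  gwS <- trajToGradient(trS, wp)
  slewPeak <- max(abs(gwS$slew[1, , 2]))
  analytic <- a * omega^2 / (42.577478518e6 * 0.22)
  expect_equal(slewPeak, analytic, tolerance = 0.02)
})

test_that("hardware enforcement scales radii to compliance and is idempotent on compliant input", {
  N <- 32L
  wp <- deskWaveParams(N)
  set.seed(3)
  hs <- helixSet(runif(8, -8, 8), runif(8, -8, 8), sr = 1,
                 theta = runif(8, 0, 2 * pi))
  tr <- buildTrajectory(wp, hs, "wave")
  out <- enforceHardware(tr, wp)
  gw <- trajToGradient(out, wp)
  expect_lte(max(sqrt(apply(gw$g^2, c(1, 2), sum))), wp@gmax + 1e-9)
  expect_lte(max(sqrt(apply(gw$slew^2, c(1, 2), sum))), wp@smax + 1e-9)
  expect_lte(max(abs(out@coords)), N / 2 + 1e-9)
  # already-compliant trajectory: scale factors are all 1
  hsIn <- helixSet(runif(4, -4, 4), runif(4, -4, 4), sr = 0.5)
  trIn <- buildTrajectory(wp, hsIn, "wave")
  outIn <- enforceHardware(trIn, wp)
  expect_equal(outIn@provenance$hardwareScale, rep(1, 4))
  expect_equal(outIn@coords, trIn@coords, tolerance = 1e-14)
  # unlimited hardware: identity scaling (box constraint still applies)
  wpInf <- waveParams(radius = 2, cycles = 2L, matrixSize = N,
                      nReadout = 32L, dwell = 2.7e-3 / 32, gmax = Inf,
                      smax = Inf)
  trI <- buildTrajectory(wpInf, hsIn, "wave")
  expect_equal(enforceHardware(trI, wpInf)@provenance$hardwareScale, rep(1, 4))
  # the straight-line kx gradient cannot be fixed by radius scaling
  wpBad <- waveParams(radius = 2, cycles = 2L, matrixSize = N,
                      nReadout = 32L, dwell = 2.7e-3 / 32, gmax = 1e-3)
  trB <- buildTrajectory(wpBad, hsIn, "wave")
  expect_error(enforceHardware(trB, wpBad), "unrecoverable|straight-line")
})

test_that("hardware enforcement agrees with a binary-search oracle on the scale factor", {
  N <- 32L
  # deliberately over-aggressive radius so scaling must kick in
  wp <- waveParams(radius = 8, cycles = 8L, matrixSize = N, nReadout = 96L,
                   dwell = 2.7e-3 / 96, gmax = 4, smax = 60)
  hs <- helixSet(0, 0, sr = 1, theta = 0.3)
  tr <- buildTrajectory(wp, hs, "wave")
  out <- enforceHardware(tr, wp)
  s <- out@provenance$hardwareScale[1]
  expect_lt(s, 1)
  compliant <- function(scale) {
    hs2 <- helixSet(0, 0, sr = scale, theta = 0.3)
    gw <- trajToGradient(buildTrajectory(wp, hs2, "wave"), wp)
    max(sqrt(apply(gw$g^2, c(1, 2), sum))) <= wp@gmax &&
      max(sqrt(apply(gw$slew^2, c(1, 2), sum))) <= wp@smax
  }
  lo <- 0; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (compliant(mid)) lo <- mid else hi <- mid
  }
  expect_equal(s, lo, tolerance = 1e-6)
  expect_true(compliant(s))
})

test_that("variable-density Poisson-disc initialization is exact, deterministic and radially thinning", {
  N <- 64
  pd <- poissonDiscInit(200L, N, seed = 42L)
  expect_length(pd$kyc, 200L)
  expect_true(all(abs(pd$kyc) <= N / 2) && all(abs(pd$kzc) <= N / 2))
  pd2 <- poissonDiscInit(200L, N, seed = 42L)
  expect_identical(pd, pd2)
  # pairwise distance >= min of the two local radii
  pts <- cbind(pd$kyc, pd$kzc)
  D <- as.matrix(dist(pts))
  rad <- sqrt(rowSums(pts^2))
  rho <- pmax(1, 1 + pd$slope * (rad - N / 32))
  lim <- outer(rho, rho, pmin)
  diag(D) <- Inf
  expect_true(all(D >= lim - 1e-9))
  # density decreases with radius under a fixed decreasing profile
  counts <- c(0, 0)
  areas <- c(pi * 8^2, pi * (24^2 - 16^2))
  for (s in 1:6) {
    p <- poissonDiscInit(150L, N, slope = 0.15, seed = s)
    r <- sqrt(p$kyc^2 + p$kzc^2)
    counts <- counts + c(sum(r < 8), sum(r >= 16 & r < 24))
  }
  expect_gt(counts[1] / areas[1], counts[2] / areas[2])
})

test_that("the published phase-encode count is feasible at full scale", {
  pd <- poissonDiscInit(4385L, 256, seed = 7L)
  expect_length(pd$kyc, 4385L)
  expect_length(pd$kzc, 4385L)
})
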