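test_that("velocity decoding and the complex-difference angiogram behave as defined", {
  N <- 10L
  mag <- array(runif(N^3, 0.5, 1), rep(N, 3))
  enc <- array(0i, c(N, N, N, 4))
  for (k in 1:4) enc[, , , k] <- mag
  # identical encodes -> zero velocity, zero CD, empty mask
  v <- velocityFromPhase(enc, 80)
  expect_equal(max(abs(v)), 0)
  cd <- complexDifferenceAngiogram(enc)
  expect_equal(max(cd), 0)
  expect_false(any(vesselMask(cd)))
  # phase difference of pi decodes to venc
  enc2 <- enc
  enc2[, , , 2] <- mag * exp(1i * pi * 0.999999)
  v2 <- velocityFromPhase(enc2, 80)
  expect_equal(max(v2[, , , 1]), 80, tolerance = 1e-4)
  # CD scales linearly with the data; the relative mask does not move
  spec <- phantomSpec(gridSize = 24L, voxel = 1.5, tubes = list(
    list(axis = "z", center = c(0, 0), diameter = 9, peakVelocity = 40)))
  geo <- buildGeometry(spec)
  e <- flowEncode(geo$magnitude, geo$velocity, 80)
  cdE <- complexDifferenceAngiogram(e)
  expect_equal(complexDifferenceAngiogram(e * 3.7), 3.7 * cdE,
               tolerance = 1e-12)
  expect_identical(vesselMask(cdE * 3.7), vesselMask(cdE))
  # the mask covers the vessel core
  core <- sqrt(apply(geo$velocity^2, 1:3, sum)) > 30
  expect_true(all(vesselMask(cdE)[core]))
})

test_that("flow rate integration follows the unit conversion and flips with the normal", {
  N <- 12L
  v <- array(0, c(N, N, N, 3))
  v[, , , 3] <- 10                       # uniform 10 cm/s along z
  # 1 cm^2 section: 100 pixels of 1 mm^2
  members <- as.matrix(expand.grid(1:10, 1:10))
  members <- cbind(members, 6L)
  cs <- new("CrossSection", origin = c(5.5, 5.5, 6), normal = c(0, 0, 1),
            pixelArea = 0.01, members = members)
  expect_equal(flowRate(v, cs), 0.6, tolerance = 1e-12)
  csNeg <- new("CrossSection", origin = cs@origin, normal = c(0, 0, -1),
               pixelArea = 0.01, members = members)
  expect_equal(flowRate(v, csNeg), -0.6, tolerance = 1e-12)
})

test_that("vmax variability reproduces hand arithmetic and grows with noise", {
  # five sections engineered to have vmax = 10, 12, 11, 13, 14
  N <- 8L
  v <- array(0, c(N, N, N, 3))
  vmaxes <- c(10, 12, 11, 13, 14)
  sections <- lapply(1:5, function(i) {
    v[4, 4, i, 3] <<- vmaxes[i]
    members <- cbind(as.matrix(expand.grid(1:N, 1:N)), i)
    new("CrossSection", origin = c(4, 4, i), normal = c(0, 0, 1),
        pixelArea = 0.01, members = members)
  })
  expect_equal(vmaxVariability(v, sections), sd(vmaxes), tolerance = 1e-12)
  expect_equal(sd(vmaxes), 1.5811388, tolerance = 1e-6)
  # identical sections -> zero
  v0 <- array(0, c(N, N, N, 3)); v0[4, 4, , 3] <- 10
  expect_equal(vmaxVariability(v0, sections), 0)
  # monotone in injected noise level (averaged over seeds)
  spec <- phantomSpec(gridSize = 24L, voxel = 1.5, tubes = list(
    list(axis = "z", center = c(0, 0), diameter = 12, peakVelocity = 40)))
  geo <- buildGeometry(spec)
  cs <- tubeCrossSections(spec, 1L, n = 5L)
  sv <- vapply(c(0, 0.5, 2), function(sig) {
    mean(vapply(1:6, function(s) {
      set.seed(100 + s)
      vn <- geo$velocity + array(rnorm(length(geo$velocity), sd = sig),
                                 dim(geo$velocity))
      vmaxVariability(vn, cs)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sv) > 0))
})

test_that("pixelwise agreement matches independent regression and Bland-Altman formulas", {
  N <- 10L
  mask <- array(TRUE, rep(N, 3))
  set.seed(8)
  vA <- array(rnorm(N^3 * 3, sd = 10), c(N, N, N, 3))
  # exact linear relation: slope recovered exactly, R^2 = 1
  rep1 <- suppressWarnings(pixelwiseAgreement(vA, vA, mask))
  expect_equal(rep1@slope, 1, tolerance = 1e-12)
  expect_equal(rep1@rSquared, 1, tolerance = 1e-12)
  expect_equal(rep1@loaHigh - rep1@loaLow, 0, tolerance = 1e-12)
  rep2 <- suppressWarnings(pixelwiseAgreement(vA, 0.9 * vA, mask))
  expect_equal(rep2@slope, 0.9, tolerance = 1e-12)
  # noisy case against textbook formulas computed independently
  vB <- 0.95 * vA + array(rnorm(N^3 * 3, sd = 2), c(N, N, N, 3))
  rep3 <- pixelwiseAgreement(vA, vB, mask)
  a <- as.vector(vA); b <- as.vector(vB)
  sxy <- sum((a - mean(a)) * (b - mean(b)))
  sxx <- sum((a - mean(a))^2)
  slope <- sxy / sxx
  expect_equal(rep3@slope, slope, tolerance = 1e-10)
  expect_equal(rep3@intercept, mean(b) - slope * mean(a), tolerance = 1e-10)
  expect_equal(rep3@rSquared, cor(a, b)^2, tolerance = 1e-10)
  d <- b - a
  expect_equal(rep3@meanDiff, mean(d), tolerance = 1e-12)
  expect_equal(rep3@loaLow, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(rep3@loaHigh, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(rep3@loaHigh - rep3@loaLow, 2 * 1.96 * sd(d),
               tolerance = 1e-12)
  # degenerate mask
  small <- array(FALSE, rep(N, 3)); small[1:2, 1, 1] <- TRUE
  expect_error(pixelwiseAgreement(vA, vB, small), "mask")
})

test_that("CV and ICC(3,1) match the ANOVA mean-squares oracle and its invariances", {
  m <- matrix(c(9, 10, 11,
                8, 10, 12,
                10, 11, 12), 3, 3, byrow = TRUE)
  st <- consistencyStats(m)
  expect_equal(st$cv, 100 * sd(as.vector(m)) / mean(m), tolerance = 1e-12)
  # two-way ANOVA mean squares computed by hand
  n <- nrow(m); k <- ncol(m); mu <- mean(m)
  MSR <- k * sum((rowMeans(m) - mu)^2) / (n - 1)
  SSE <- sum((m - mu)^2) - k * sum((rowMeans(m) - mu)^2) -
    n * sum((colMeans(m) - mu)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  expect_equal(st$icc, (MSR - MSE) / (MSR + (k - 1) * MSE), tolerance = 1e-12)
  # adding a constant leaves ICC unchanged and lowers CV
  st2 <- consistencyStats(m + 5)
  expect_equal(st2$icc, st$icc, tolerance = 1e-12)
  expect_lt(st2$cv, st$cv)
  # all-equal table: CV 0, ICC degenerate -> 1 with a flag
  st3 <- consistencyStats(matrix(4, 4, 5))
  expect_equal(st3$cv, 0)
  expect_equal(st3$icc, 1)
  expect_true(st3$degenerate)
  expect_error(consistencyStats(matrix(c(1, NA, 2, 3), 2, 2)), "incomplete")
  expect_error(consistencyStats(matrix(c(-1, 1, -1, 1), 2, 2)), "zero mean")
})
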