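#' Decode velocities from 4-point encoded volumes
#'
#' v_d = (venc / pi) * angle(m_d conj(m_0)): the phase difference of each
#' velocity encode against the reference encode mapped to cm/s. No phase
#' unwrapping is applied (venc is chosen above the true speeds); decoded
#' components therefore satisfy |v| <= venc.
#'
#' @param encodes complex array N x N x N x 4 (reference first).
#' @param venc velocity encoding (cm/s).
#' @return real array N x N x N x 3 (cm/s).
#' @export
velocityFromPhase <- function(encodes, venc) {
  d <- dim(encodes)
  out <- array(0, c(d[1:3], 3))
  ref <- encodes[, , , 1]
  for (k in 1:3)
    out[, , , k] <- (venc / pi) * Arg(encodes[, , , k + 1] * Conj(ref))
  out
}

#' Complex-difference angiogram
#'
#' CD = sqrt(sum_d |m_d - m_0|^2): bright where flow-induced phase makes the
#' velocity encodes differ from the reference.
#'
#' @param encodes complex array N x N x N x 4.
#' @return real array N^3.
#' @export
complexDifferenceAngiogram <- function(encodes) {
  cd <- array(0, dim(encodes)[1:3])
  for (k in 2:4) cd <- cd + Mod(encodes[, , , k] - encodes[, , , 1])^2
  sqrt(cd)
}

#' Vessel mask by relative thresholding of the CD angiogram
#'
#' @param cd complex-difference image.
#' @param fraction threshold as a fraction of the maximum intensity
#'   (default 0.10).
#' @return logical array.
#' @export
vesselMask <- function(cd, fraction = 0.10) {
  mx <- max(cd)
  if (mx == 0) return(array(FALSE, dim(cd)))
  cd >= fraction * mx
}

#' Cross-sections along a straight tube
#'
#' Builds n consecutive cross-sections perpendicular to an axis-aligned
#' tube's centerline (synthetic centerlines are known, so no vessel-tracking
#' tool is needed). Member pixels cover the tube lumen plus a one-voxel rim
#' to include partial-volume voxels.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param tubeIndex which tube.
#' @param n number of consecutive sections (default 5).
#' @return list of \linkS4class{CrossSection}.
#' @export
tubeCrossSections <- function(spec, tubeIndex, n = 5L) {
  tube <- spec@tubes[[tubeIndex]]
  if (is.null(tube$axis)) stop("cross-sections require a straight tube")
  N <- spec@gridSize
  vox <- spec@voxel
  ax <- match(tube$axis, c("x", "y", "z"))
  perp <- setdiff(1:3, ax)
  ctrIdx <- tube$center / vox + N / 2 + 0.5    # voxel-grid position
  Rvox <- tube$diameter / 2 / vox
  axPos <- round(N / 2 + seq(-(n - 1) / 2, (n - 1) / 2))
  grid <- expand.grid(seq_len(N), seq_len(N))
  d <- sqrt((grid[, 1] - ctrIdx[1])^2 + (grid[, 2] - ctrIdx[2])^2)
  sel <- d <= Rvox + 1.5
  lapply(axPos, function(p) {
    members <- matrix(0L, sum(sel), 3)
    members[, perp[1]] <- as.integer(grid[sel, 1])
    members[, perp[2]] <- as.integer(grid[sel, 2])
    members[, ax] <- p
    origin <- numeric(3)
    origin[perp] <- ctrIdx
    origin[ax] <- p
    normal <- numeric(3); normal[ax] <- 1
    new("CrossSection", origin = origin, normal = normal,
        pixelArea = (vox / 10)^2, members = members)
  })
}

#' Flow rate through a cross-section
#'
#' Q = sum over member pixels of (v . normal) * pixelArea, converted from
#' cm^3/s to L/min (factor 0.06).
#'
#' @param v velocity array N x N x N x 3 (cm/s).
#' @param cs a \linkS4class{CrossSection}.
#' @return flow rate in L/min.
#' @export
flowRate <- function(v, cs) {
  m <- cs@members
  if (nrow(m) == 0) stop("empty cross-section")
  vn <- cs@normal[1] * v[cbind(m, 1)] + cs@normal[2] * v[cbind(m, 2)] +
    cs@normal[3] * v[cbind(m, 3)]
  sum(vn) * cs@pixelArea * 0.06
}

#' Variability of the per-section maximum speed
#'
#' Records the maximum speed within each cross-section and returns the
#' sample standard deviation across sections; with no true vessel change
#' between consecutive sections this is a noise-level surrogate.
#'
#' @param v velocity array (cm/s).
#' @param sections list of \linkS4class{CrossSection} (>= 2).
#' @return sigma_vmax (cm/s).
#' @export
vmaxVariability <- function(v, sections) {
  if (length(sections) < 2) stop("need at least 2 sections")
  vmax <- vapply(sections, function(cs) {
    m <- cs@members
    if (nrow(m) == 0) stop("empty cross-section")
    sp <- sqrt(v[cbind(m, 1)]^2 + v[cbind(m, 2)]^2 + v[cbind(m, 3)]^2)
    max(sp)
  }, numeric(1))
  sd(vmax)
}

#' Pixelwise velocity agreement
#'
#' Pools all three velocity components over the mask voxels and computes (i)
#' ordinary least squares of B on A with the 95 percent confidence interval
#' of the slope and R^2, and (ii) Bland-Altman mean difference with 1.96 SD
#' limits of agreement.
#'
#' @param vA,vB velocity arrays N x N x N x 3 (cm/s); A is the reference.
#' @param mask logical array N^3 (>= 10 voxels).
#' @return an \linkS4class{AgreementReport}.
#' @export
pixelwiseAgreement <- function(vA, vB, mask) {
  if (sum(mask) < 10) stop("mask too small (< 10 voxels)")
  sel <- which(mask)
  nv <- prod(dim(mask))
  a <- c(vA[sel], vA[sel + nv], vA[sel + 2 * nv])
  b <- c(vB[sel], vB[sel + nv], vB[sel + 2 * nv])
  fit <- lm(b ~ a)
  ci <- suppressMessages(confint(fit, "a", level = 0.95))
  dif <- b - a
  sdd <- sd(dif)
  new("AgreementReport",
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      rSquared = summary(fit)$r.squared, slopeCI = as.numeric(ci),
      meanDiff = mean(dif), loaLow = mean(dif) - 1.96 * sdd,
      loaHigh = mean(dif) + 1.96 * sdd, nPixels = length(a))
}

#' Coefficient of variation and ICC(3,1) of repeated flow measurements
#'
#' For a segments x repeats table of flow rates that should agree by
#' conservation of mass: CV = 100 SD/mean pooled over all entries, and the
#' two-way mixed-effects, consistency, single-measurement intraclass
#' correlation ICC(3,1) = (MSR - MSE) / (MSR + (k - 1) MSE) from the two-way
#' ANOVA mean squares (rows = segments, columns = repeats). A perfectly
#' constant table has CV = 0 and degenerate ICC, reported as 1 with
#' \code{degenerate = TRUE}.
#'
#' @param measurements numeric matrix, segments x repeats, complete.
#' @return list(cv, icc, degenerate).
#' @export
consistencyStats <- function(measurements) {
  m <- as.matrix(measurements)
  if (any(!is.finite(m))) stop("incomplete table")
  mu <- mean(m)
  if (mu == 0) stop("zero mean")
  cv <- 100 * sd(as.vector(m)) / mu
  n <- nrow(m); k <- ncol(m)
  rowM <- rowMeans(m); colM <- colMeans(m)
  SSR <- k * sum((rowM - mu)^2)
  SSC <- n * sum((colM - mu)^2)
  SST <- sum((m - mu)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR + (k - 1) * MSE == 0)
    return(list(cv = cv, icc = 1, degenerate = TRUE))
  list(cv = cv, icc = (MSR - MSE) / (MSR + (k - 1) * MSE),
       degenerate = FALSE)
}
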