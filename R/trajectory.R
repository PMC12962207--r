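#' Construct wave readout parameters
#'
#' Defaults reproduce the published protocol: C = 8 cycles, echo fraction
#' 0.75, FOV 220 mm, matrix 256 (0.86 mm isotropic), gmax = 9 mT/m. The dwell
#' time (4 us) and slew limit (150 T/m/s) are typical 3T values; the readout
#' length defaults to 675 samples so that the readout duration is about
#' 2.7 ms at the default dwell. When \code{radius} is NULL the maximum helix
#' radius is derived from the hardware limits (see
#' \code{\link{deriveWaveRadius}}), since only gmax is specified by the
#' protocol.
#'
#' @param radius maximum helix radius in grid units, or NULL to derive.
#' @param cycles helix cycles per readout.
#' @param echoFraction acquired fraction of the frequency encode, in (0.5, 1].
#' @param nReadout readout samples per helix.
#' @param gmax maximum gradient amplitude (mT/m).
#' @param smax maximum slew rate (T/m/s).
#' @param dwell readout sample spacing (s).
#' @param fov field of view (mm).
#' @param matrixSize grid size N.
#' @return a \linkS4class{WaveParams} object.
#' @export
waveParams <- function(radius = NULL, cycles = 8L, echoFraction = 0.75,
                       nReadout = 675L, gmax = 9, smax = 150, dwell = 4e-6,
                       fov = 220, matrixSize = 256L) {
  wp <- new("WaveParams", radius = 1, cycles = as.integer(cycles),
            echoFraction = echoFraction, nReadout = as.integer(nReadout),
            gmax = gmax, smax = smax, dwell = dwell, fov = fov,
            matrixSize = as.integer(matrixSize))
  wp@radius <- if (is.null(radius)) deriveWaveRadius(wp) else radius
  validObject(wp)
  wp
}

#' Derive the maximum helix radius from hardware limits
#'
#' The transverse k-space excursion of a helix of radius r (grid units) with
#' angular rate omega = 2 pi C ef / (NRO dwell) needs peak gradient
#' r omega / (gamma FOV) and peak slew r omega^2 / (gamma FOV). The largest
#' radius compatible with both gmax and smax is returned.
#'
#' @param wp a \linkS4class{WaveParams} object.
#' @return radius in grid units.
#' @export
deriveWaveRadius <- function(wp) {
  omega <- 2 * pi * wp@cycles * wp@echoFraction / (wp@nReadout * wp@dwell)
  fovm <- wp@fov / 1000
  rg <- (wp@gmax / 1000) * GAMMA_HZ_PER_T * fovm / omega
  rs <- wp@smax * GAMMA_HZ_PER_T * fovm / omega^2
  min(rg, rs)
}

#' Helix phase along the readout
#'
#' phi[i] = -2 pi C ((ef - 1/2) - ef i / NRO), monotonically increasing in i
#' and zero at the echo index i_echo = NRO (ef - 1/2) / ef. This phase is
#' both the sin/cos argument of the transverse helix coordinates and, after
#' linear mapping (\code{\link{kxFromPhase}}), the kx grid coordinate.
#'
#' @param i readout index (vectorized), 0 <= i <= NRO.
#' @param wp a \linkS4class{WaveParams} object.
#' @return phase in radians.
#' @export
helixPhase <- function(i, wp) {
  if (any(i < 0) || any(i > wp@nReadout))
    stop("readout index out of range [0, NRO]")
  -2 * pi * wp@cycles *
    ((wp@echoFraction - 0.5) - wp@echoFraction * i / wp@nReadout)
}

#' Map helix phase to the kx grid coordinate
#'
#' kx = phi N / (2 pi C): the partial echo spans kx in
#' [-(ef - 1/2) N, N/2] with the echo (kx = 0) crossed at i_echo.
#'
#' @param phi phase from \code{\link{helixPhase}}.
#' @param wp a \linkS4class{WaveParams} object.
#' @return kx in grid units.
#' @export
kxFromPhase <- function(phi, wp) phi * wp@matrixSize / (2 * pi * wp@cycles)

#' Build one readout (helix or straight line)
#'
#' Wave mode: ky = sr r sin(phi + theta) + kyc, kz = sr r cos(phi + theta) +
#' kzc, with phi the helix phase; the per-sample transverse radius is exactly
#' sr r. No-wave mode: a straight line through (kyc, kzc) (the zero-radius
#' degenerate helix).
#'
#' @param wp a \linkS4class{WaveParams} object.
#' @param sr radius scaling in (0, 1] (ignored in no_wave mode).
#' @param theta rotation (radians).
#' @param center numeric(2), (kyc, kzc) in grid units.
#' @param mode "wave" or "no_wave".
#' @return NRO x 3 matrix of (kx, ky, kz).
#' @export
buildHelix <- function(wp, sr = 1, theta = 0, center = c(0, 0),
                       mode = c("wave", "no_wave")) {
  mode <- match.arg(mode)
  i <- seq_len(wp@nReadout) - 1
  phi <- helixPhase(i, wp)
  kx <- kxFromPhase(phi, wp)
  if (mode == "no_wave") {
    cbind(kx, rep(center[1], wp@nReadout), rep(center[2], wp@nReadout),
          deparse.level = 0)
  } else {
    if (sr <= 0 || sr > 1) stop("sr must lie in (0, 1]")
    cbind(kx, sr * wp@radius * sin(phi + theta) + center[1],
          sr * wp@radius * cos(phi + theta) + center[2], deparse.level = 0)
  }
}

#' Construct a HelixSet
#'
#' @param kyc,kzc numeric(NPE) helix center coordinates (grid units).
#' @param sr numeric, radius scalings in (0, 1] (recycled).
#' @param theta numeric, rotations (recycled).
#' @param learnable character subset of c("kyc","kzc","sr","theta").
#' @return a \linkS4class{HelixSet} object.
#' @export
helixSet <- function(kyc, kzc, sr = 1, theta = 0,
                     learnable = c("kyc", "kzc", "sr", "theta")) {
  n <- length(kyc)
  new("HelixSet", kyc = as.numeric(kyc), kzc = as.numeric(kzc),
      sr = rep_len(as.numeric(sr), n), theta = rep_len(as.numeric(theta), n),
      learnable = learnable)
}

#' Build the full sampling trajectory
#'
#' All helices share the base parameterized helix, individualized by per-helix
#' scaling sr, rotation theta and translation to (kyc, kzc). In no_wave mode
#' every readout is a straight line through its phase-encode center.
#'
#' @param wp a \linkS4class{WaveParams} object.
#' @param hs a \linkS4class{HelixSet} object.
#' @param mode "wave" or "no_wave".
#' @return a \linkS4class{Trajectory} object with coords NPE x NRO x 3.
#' @export
buildTrajectory <- function(wp, hs, mode = c("wave", "no_wave")) {
  mode <- match.arg(mode)
  npe <- nPhaseEncodes(hs)
  nro <- wp@nReadout
  i <- seq_len(nro) - 1
  phi <- helixPhase(i, wp)
  kx <- kxFromPhase(phi, wp)
  coords <- array(0, c(npe, nro, 3))
  coords[, , 1] <- matrix(kx, npe, nro, byrow = TRUE)
  if (mode == "wave") {
    ph <- outer(hs@theta, phi, "+")          # NPE x NRO
    amp <- hs@sr * wp@radius
    coords[, , 2] <- amp * sin(ph) + hs@kyc
    coords[, , 3] <- amp * cos(ph) + hs@kzc
  } else {
    coords[, , 2] <- matrix(hs@kyc, npe, nro)
    coords[, , 3] <- matrix(hs@kzc, npe, nro)
  }
  new("Trajectory", coords = coords, mode = mode,
      provenance = list(waveParams = wp, helixSet = hs,
                        kxMapping = "kx = phi*N/(2*pi*C), echo at kx = 0"))
}

#' Gradient and slew waveforms of a trajectory
#'
#' Finite-difference conversion of k-space coordinates (grid units, i.e.
#' cycles/FOV) to gradient amplitude g[i] = dk[i] / (gamma dwell FOV) in mT/m
#' and slew = dg / dwell in T/m/s. Gradients have length NRO - 1 along the
#' readout, slews NRO - 2; ramps from rest before the first sample are not
#' modeled.
#'
#' @param traj a \linkS4class{Trajectory} object.
#' @param wp a \linkS4class{WaveParams} object.
#' @return list with arrays \code{g} (NPE x NRO-1 x 3, mT/m) and
#'   \code{slew} (NPE x NRO-2 x 3, T/m/s).
#' @export
trajToGradient <- function(traj, wp) {
  co <- traj@coords
  nro <- dim(co)[2]
  dk <- co[, -1, , drop = FALSE] - co[, -nro, , drop = FALSE]
  fovm <- wp@fov / 1000
  g <- dk / (GAMMA_HZ_PER_T * wp@dwell * fovm) * 1000   # mT/m
  slew <- (g[, -1, , drop = FALSE] - g[, -(nro - 1), , drop = FALSE]) /
    wp@dwell / 1000                                      # T/m/s
  list(g = g, slew = slew)
}

#' Enforce hardware and k-space-box limits by scaling helix radii down
#'
#' The straight-line (kx) gradient is fixed by the protocol; if it alone
#' violates the limits the configuration is unrecoverable. Otherwise each
#' helix's transverse excursion is scaled by the largest factor <= 1 such
#' that the combined gradient magnitude stays within gmax and the slew within
#' smax, keeping the readout length unchanged. Scaling sr scales the
#' transverse gradient and slew linearly, so the admissible factor has the
#' closed form s^2 <= min_i (limit^2 - gx_i^2) / (gt_i^2). The same
#' mechanism also keeps every coordinate inside the sampled band:
#' sr r <= N/2 - max(|kyc|, |kzc|), so the trajectory invariant
#' |coords| <= N/2 holds after enforcement.
#'
#' @param traj a \linkS4class{Trajectory} built by \code{\link{buildTrajectory}}.
#' @param wp a \linkS4class{WaveParams} object.
#' @return a \linkS4class{Trajectory} with per-helix sr scaled down;
#'   the applied factors are stored in \code{provenance$hardwareScale}.
#' @export
enforceHardware <- function(traj, wp) {
  hs <- traj@provenance$helixSet
  if (is.null(hs)) stop("trajectory has no HelixSet provenance")
  gw <- trajToGradient(traj, wp)
  gx <- gw$g[1, , 1]
  sx <- gw$slew[1, , 1]
  if (max(abs(gx)) > wp@gmax || max(abs(sx)) > wp@smax)
    stop("straight-line readout gradient alone violates hardware limits")
  npe <- dim(gw$g)[1]
  scale <- rep(1, npe)
  if (traj@mode == "wave") {
    gt2 <- gw$g[, , 2]^2 + gw$g[, , 3]^2
    st2 <- gw$slew[, , 2]^2 + gw$slew[, , 3]^2
    gx2 <- matrix(gx^2, npe, length(gx), byrow = TRUE)
    sx2 <- matrix(sx^2, npe, length(sx), byrow = TRUE)
    sAmp2 <- (wp@gmax^2 - gx2) / pmax(gt2, .Machine$double.xmin)
    sSlew2 <- (wp@smax^2 - sx2) / pmax(st2, .Machine$double.xmin)
    sAmp2[gt2 == 0] <- Inf
    sSlew2[st2 == 0] <- Inf
    s2 <- pmin(apply(sAmp2, 1, min), apply(sSlew2, 1, min))
    scale <- pmin(1, sqrt(pmax(s2, 0)))
    # keep the full helix inside |k| <= N/2
    N2 <- wp@matrixSize / 2
    room <- pmax(N2 - pmax(abs(hs@kyc), abs(hs@kzc)), 0)
    amp <- hs@sr * wp@radius
    sBox <- ifelse(amp > 0, pmin(1, room / amp), 1)
    scale <- pmin(scale, sBox)
    scale <- pmax(scale, 1e-9 / max(amp, 1e-9))   # keep sr > 0
  }
  hs2 <- hs
  hs2@sr <- hs@sr * scale
  out <- buildTrajectory(wp, hs2, traj@mode)
  out@provenance$hardwareScale <- scale
  out
}

#' Variable-density Poisson-disc phase-encode initialization
#'
#' Draws exactly \code{nPE} points in the [-N/2, N/2)^2 phase-encode plane by
#' greedy dart throwing with a radially increasing minimum spacing: spacing 1
#' (fully sampled) inside a central disc of radius \code{rc} (default N/32),
#' growing linearly with slope \code{slope} outside it. Pairs of accepted
#' points satisfy dist >= min(rho(p), rho(q)). When \code{slope} is NULL the
#' largest feasible slope yielding at least nPE points is found by bisection
#' and excess points are dropped at random, so the draw is exactly nPE points
#' and deterministic given \code{seed}.
#'
#' @param nPE number of phase encodes.
#' @param N grid size.
#' @param rc fully sampled central radius (grid units).
#' @param slope density profile slope, or NULL to calibrate.
#' @param seed integer RNG seed.
#' @param maxCandFactor candidate budget per requested point.
#' @return list with numeric vectors \code{kyc}, \code{kzc} and the
#'   \code{slope} used.
#' @export
poissonDiscInit <- function(nPE, N, rc = N / 32, slope = NULL, seed = 1L,
                            maxCandFactor = 60) {
  stopifnot(nPE >= 1)
  set.seed(seed)
  K <- max(20000, ceiling(maxCandFactor * nPE))
  cand <- matrix(runif(2 * K, -N / 2, N / 2), K, 2)
  countFor <- function(s) length(cpp_poisson_disc(cand, N, rc, s))
  if (is.null(slope)) {
    if (countFor(0) < nPE)
      stop("infeasible: requested nPE exceeds capacity at unit spacing")
    lo <- 0; hi <- 2
    while (countFor(hi) >= nPE && hi < 64) hi <- hi * 2
    for (it in 1:18) {
      mid <- (lo + hi) / 2
      if (countFor(mid) >= nPE) lo <- mid else hi <- mid
    }
    slope <- lo
  }
  idx <- cpp_poisson_disc(cand, N, rc, slope)
  if (length(idx) < nPE)
    stop("infeasible density profile for requested nPE after bounded retries")
  pts <- cand[idx, , drop = FALSE]
  if (length(idx) > nPE)
    pts <- pts[sort(sample.int(nrow(pts), nPE)), , drop = FALSE]
  list(kyc = pts[, 1], kzc = pts[, 2], slope = slope)
}
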