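#' Linear-phase and amplitude augmentation
#'
#' Multiplies the image by b exp(2 pi i phi) with phi = a1 x + a2 y + a3 z +
#' a4 and spatial coordinates normalized to [-0.5, 0.5) per axis, so a
#' coefficient of 10 means up to 10 phase cycles across the FOV. Emulates the
#' background-phase variation absent from the flat-phase training references.
#'
#' @param m complex image array N^3.
#' @param a numeric(4) phase coefficients.
#' @param b amplitude scale.
#' @return augmented complex array; |output| = b |input| voxelwise.
#' @export
augmentPhase <- function(m, a, b = 1) {
  d <- dim(m)
  xn <- function(N) (((0:(N - 1)) - N %/% 2) / N)
  phi <- array(0, d)
  phi <- phi + array(rep(a[1] * xn(d[1]), times = d[2] * d[3]), d)
  phi <- phi + array(rep(rep(a[2] * xn(d[2]), each = d[1]), times = d[3]), d)
  phi <- phi + array(rep(a[3] * xn(d[3]), each = d[1] * d[2]), d)
  m * exp(2i * pi * (phi + a[4])) * b
}

#' Estimate per-component noise level from the k-space edge
#'
#' The noise scale is taken as the median of |Re| and |Im| over samples in
#' the outer shell |k| > shell * N/2, calibrated by the half-normal median
#' (median|X| = 0.6745 sigma for X ~ N(0, sigma^2)).
#'
#' @param y complex k-space data K x ncoil (or vector).
#' @param coords K x 3 sample coordinates (grid units).
#' @param N grid size.
#' @param shell edge-shell fraction of N/2 (default 0.9).
#' @return list(sigmaRe, sigmaIm).
#' @export
estimateNoiseSigma <- function(y, coords, N, shell = 0.9) {
  rad <- sqrt(rowSums(coords^2))
  edge <- rad > shell * N / 2
  if (!any(edge)) stop("empty k-space edge shell")
  if (is.null(dim(y))) y <- matrix(y, ncol = 1L)
  ye <- y[edge, , drop = FALSE]
  cal <- qnorm(0.75)
  list(sigmaRe = median(abs(Re(ye))) / cal,
       sigmaIm = median(abs(Im(ye))) / cal)
}

#' Add scaled Gaussian noise to k-space data
#'
#' Real and imaginary parts receive independent Gaussian noise of standard
#' deviations n * sigmaRe and n * sigmaIm.
#'
#' @param y complex k-space data.
#' @param n noise factor.
#' @param sigmaRe,sigmaIm per-component noise scales.
#' @param seed optional seed.
#' @return noisy data, same shape.
#' @export
augmentNoise <- function(y, n, sigmaRe, sigmaIm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n * sigmaRe == 0 && n * sigmaIm == 0) return(y)
  k <- length(y)
  y + complex(real = rnorm(k, sd = n * sigmaRe),
              imaginary = rnorm(k, sd = n * sigmaIm))
}

#' Normalized squared-error loss
#'
#' loss = sum |m - mhat|^2 / sum |m|^2, implemented exactly as the printed
#' ratio of summed squares (no square root), the form the training minimizes.
#'
#' @param mhat reconstructed complex image.
#' @param m reference complex image (not all zero).
#' @return scalar loss.
#' @export
nrmseLoss <- function(mhat, m) {
  den <- sum(Mod(m)^2)
  if (den == 0) stop("all-zero reference image")
  sum(Mod(m - mhat)^2) / den
}

#' Construct a training configuration
#'
#' @param mode "wave", "no_wave" (straight-line readouts, centers learnable)
#'   or "fixed" (sampling frozen at initialization; only the reconstruction
#'   learns).
#' @param lr,weightDecay Adam settings (published defaults 1e-3, 1e-3).
#' @param lrCoords Adam step for the sampling learnables; with Adam the
#'   per-step displacement is about lrCoords grid units.
#' @param epochs,seed integers.
#' @param phaseCoeffRange,scaleRange,noiseFactorRange augmentation ranges.
#' @param nUnrolls,features desk-scale MoDL size used during training.
#' @param encodes which flow encodes of each case serve as training volumes.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(mode = "wave", lr = 1e-3, lrCoords = lr,
                        weightDecay = 1e-3, epochs = 10L, seed = 1L,
                        phaseCoeffRange = c(-10, 10), scaleRange = c(0.3, 3),
                        noiseFactorRange = c(0.5, 1.5), nUnrolls = 2L,
                        features = 4L, encodes = 2L) {
  new("TrainConfig", mode = mode, lr = lr, lrCoords = lrCoords,
      weightDecay = weightDecay, epochs = as.integer(epochs),
      seed = as.integer(seed), phaseCoeffRange = phaseCoeffRange,
      scaleRange = scaleRange, noiseFactorRange = noiseFactorRange,
      nUnrolls = as.integer(nUnrolls), features = as.integer(features),
      encodes = as.integer(encodes))
}

# ---- Adam over a named list of numeric arrays --------------------------------

adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adamStep <- function(params, grads, state, lr, weightDecay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    wd <- if (is.list(weightDecay)) weightDecay[[nm]] else weightDecay
    g <- grads[[nm]] + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    step <- if (is.list(lr)) lr[[nm]] else lr
    params[[nm]] <- params[[nm]] - step * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# flatten/unflatten denoiser weights to a named list for the optimizer
weightsToParams <- function(weights) {
  out <- list()
  for (l in seq_along(weights)) {
    out[[paste0("X", l)]] <- weights[[l]]$X
    out[[paste0("Y", l)]] <- weights[[l]]$Y
    out[[paste0("bRe", l)]] <- weights[[l]]$biasRe
    out[[paste0("bIm", l)]] <- weights[[l]]$biasIm
  }
  out
}

paramsToWeights <- function(params, L) {
  lapply(seq_len(L), function(l)
    list(X = params[[paste0("X", l)]], Y = params[[paste0("Y", l)]],
         biasRe = params[[paste0("bRe", l)]],
         biasIm = params[[paste0("bIm", l)]]))
}

gradsToParams <- function(gW) {
  out <- list()
  for (l in seq_along(gW)) {
    out[[paste0("X", l)]] <- gW[[l]]$gX
    out[[paste0("Y", l)]] <- gW[[l]]$gY
    out[[paste0("bRe", l)]] <- gW[[l]]$gbiasRe
    out[[paste0("bIm", l)]] <- gW[[l]]$gbiasIm
  }
  out
}

#' Loss and gradients for one training case
#'
#' Runs the full differentiable pipeline for one reference image: simulate
#' k-space y = A m + noise, reconstruct with the unrolled network, evaluate
#' the normalized squared-error loss, and backpropagate by hand through every
#' stage. Cotangents follow the convention g = dL/d(Re z) + i dL/d(Im z);
#' image/k-space cotangents use the linear-operator transposes, and
#' coordinate cotangents route through the analytic Jacobians
#' (\code{\link{coordGradForward}}, \code{\link{coordGradAdjoint}}),
#' accumulated over every application of A and A^H including the simulation
#' of y itself. This hand-written tape is the package's "custom backward"
#' registration: native differentiation through the gridding interpolation is
#' never used.
#'
#' @param mRef complex reference image (already augmented if desired).
#' @param op an \linkS4class{EncodingOperator} built at the current
#'   coordinates.
#' @param weights denoiser layer list.
#' @param alpha DC step size.
#' @param nUnrolls number of unrolls.
#' @param noise complex K x ncoil noise to add to the simulated data (or
#'   NULL).
#' @param wantCoordGrad compute coordinate gradients.
#' @param wantWeightGrad compute network gradients.
#' @return list(loss, gWeights, gAlpha, gCoords, recon).
#' @export
caseLossGrad <- function(mRef, op, weights, alpha, nUnrolls, noise = NULL,
                         wantCoordGrad = TRUE, wantWeightGrad = TRUE) {
  y0 <- nufftForward(op, mRef)
  y <- if (is.null(noise)) y0 else y0 + noise
  # forward unrolled pass, storing what backward needs
  m0 <- nufftAdjoint(op, y)
  mList <- vector("list", nUnrolls + 1L); mList[[1]] <- m0
  rList <- vector("list", nUnrolls)
  vList <- vector("list", nUnrolls)
  zList <- vector("list", nUnrolls)
  tapes <- vector("list", nUnrolls)
  for (t in seq_len(nUnrolls)) {
    u <- nufftForward(op, mList[[t]])
    r <- u - y
    v <- nufftAdjoint(op, r)
    z <- mList[[t]] - 2 * alpha * v
    rList[[t]] <- r; vList[[t]] <- v; zList[[t]] <- z
    fw <- denoiserForwardInternal(z, weights, keepTape = TRUE)
    tapes[[t]] <- fw$tape
    mList[[t + 1L]] <- fw$out
  }
  mT <- mList[[nUnrolls + 1L]]
  den <- sum(Mod(mRef)^2)
  loss <- sum(Mod(mT - mRef)^2) / den
  # backward
  g <- 2 * (mT - mRef) / den
  gW <- NULL
  gAlpha <- 0
  K <- nrow(op@coords)
  gCoords <- matrix(0, K, 3)
  gyAcc <- matrix(0i, K, dim(op@coils@maps)[4])
  for (t in nUnrolls:1) {
    dg <- denoiserGrad(zList[[t]], weights, g, tape = tapes[[t]])
    gz <- dg$gz
    if (wantWeightGrad) {
      gp <- gradsToParams(dg$gWeights)
      gW <- if (is.null(gW)) gp else mapply(`+`, gW, gp, SIMPLIFY = FALSE)
    }
    gAlpha <- gAlpha + sum(Re(Conj(gz) * (-2 * vList[[t]])))
    gPrev <- gz
    gv <- -2 * alpha * gz
    if (wantCoordGrad)
      gCoords <- gCoords + coordGradAdjoint(op, rList[[t]], gv)
    gr <- nufftForward(op, gv)
    gyAcc <- gyAcc - gr
    gPrev <- gPrev + nufftAdjoint(op, gr)
    if (wantCoordGrad)
      gCoords <- gCoords + coordGradForward(op, mList[[t]], gr)
    g <- gPrev
  }
  gyAcc <- gyAcc + nufftForward(op, g)
  if (wantCoordGrad) {
    gCoords <- gCoords + coordGradAdjoint(op, y, g)
    gCoords <- gCoords + coordGradForward(op, mRef, gyAcc)
  }
  list(loss = loss, gWeights = gW, gAlpha = gAlpha, gCoords = gCoords,
       recon = mT)
}

# initialize alpha as 0.5 / L with L = ||A^H A|| estimated by power iteration
#' Estimate the spectral norm of A^H A by power iteration
#' @param op an \linkS4class{EncodingOperator}.
#' @param iters power iterations.
#' @param seed seed for the random start vector.
#' @return estimate of the largest eigenvalue of A^H A.
#' @export
powerIterNormalOp <- function(op, iters = 12L, seed = 1L) {
  set.seed(seed)
  N <- op@gridSize
  v <- array(rnorm(N^3) + 1i * rnorm(N^3), rep(N, 3))
  lam <- 1
  for (i in seq_len(iters)) {
    w <- nufftAdjoint(op, nufftForward(op, v))
    lam <- sqrt(sum(Mod(w)^2)) / sqrt(sum(Mod(v)^2))
    v <- w / sqrt(sum(Mod(w)^2))
  }
  lam
}

#' Jointly train sampling and reconstruction
#'
#' End-to-end optimization of the phase-encode centers (and helix scaling and
#' rotation in wave mode), the DC step size alpha and the denoiser weights,
#' by Adam on the normalized squared-error loss. Per case and epoch the
#' reference image is phase/amplitude augmented, k-space is simulated through
#' the current trajectory, noise scaled to the estimated edge-of-k-space
#' level is added (factor drawn from \code{noiseFactorRange}), the unrolled
#' network reconstructs, and one optimizer step is taken on all learnables.
#' After each step sr is projected into (0, 1], centers are clamped to the
#' k-space box, and hardware limits are re-enforced.
#'
#' @param cases list of training cases; each a list with \code{image}
#'   (complex array N^3) and \code{coils} (\linkS4class{CoilSet}), e.g. from
#'   \code{\link{trainingCasesFromPhantom}}.
#' @param valCases list of validation cases (same structure).
#' @param wp a \linkS4class{WaveParams} (desk-scale geometry).
#' @param hs0 initial \linkS4class{HelixSet} (shared across modes).
#' @param cfg a \linkS4class{TrainConfig}.
#' @return list with the trained \code{helixSet}, \code{weights},
#'   \code{alpha}, per-epoch \code{history} (train/validation loss) and the
#'   final \code{trajectory}.
#' @export
trainJoint <- function(cases, valCases, wp, hs0, cfg) {
  set.seed(cfg@seed)
  mode <- cfg@mode
  trajMode <- if (mode == "wave") "wave" else "no_wave"
  mcfg <- modlConfig(nUnrolls = cfg@nUnrolls, features = cfg@features)
  weights <- initDenoiser(mcfg, seed = cfg@seed + 1L)
  hs <- hs0
  N <- wp@matrixSize
  # alpha init from the normal-operator norm at the initial sampling
  traj <- enforceHardware(buildTrajectory(wp, hs, trajMode), wp)
  op0 <- encodingOperator(cases[[1]]$coils, traj)
  alpha <- 0.5 / powerIterNormalOp(op0, iters = 8L, seed = cfg@seed)
  params <- weightsToParams(weights)
  params$alpha <- alpha
  lr <- as.list(rep(cfg@lr, length(params)))
  names(lr) <- names(params)
  wd <- lr
  for (nm in names(wd)) wd[[nm]] <- cfg@weightDecay
  wd$alpha <- 0            # decay only the network weights
  learnCoords <- mode != "fixed"
  if (learnCoords) {
    params$kyc <- hs@kyc; params$kzc <- hs@kzc
    lr$kyc <- cfg@lrCoords; lr$kzc <- cfg@lrCoords
    wd$kyc <- 0; wd$kzc <- 0
    if (mode == "wave") {
      params$sr <- hs@sr; params$theta <- hs@theta
      # scale so one Adam step moves the helix by about lrCoords grid units
      lr$sr <- cfg@lrCoords / wp@radius
      lr$theta <- cfg@lrCoords / wp@radius
      wd$sr <- 0; wd$theta <- 0
    }
  }
  ad <- adamInit(params)
  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric())
  L <- length(weights)
  for (epoch in seq_len(cfg@epochs)) {
    ord <- sample(length(cases))
    eLoss <- 0; nSamp <- 0
    for (ci in ord) {
      case <- cases[[ci]]
      a <- runif(4, cfg@phaseCoeffRange[1], cfg@phaseCoeffRange[2])
      b <- runif(1, cfg@scaleRange[1], cfg@scaleRange[2])
      nFac <- runif(1, cfg@noiseFactorRange[1], cfg@noiseFactorRange[2])
      mAug <- augmentPhase(case$image, a, b)
      hsCur <- helixSet(params$kyc %||% hs@kyc, params$kzc %||% hs@kzc,
                        params$sr %||% hs@sr, params$theta %||% hs@theta)
      traj <- enforceHardware(buildTrajectory(wp, hsCur, trajMode), wp)
      op <- encodingOperator(case$coils, traj)
      y0 <- nufftForward(op, mAug)
      sig <- estimateNoiseSigma(y0, op@coords, N)
      noise <- complex(real = rnorm(length(y0), sd = nFac * sig$sigmaRe),
                       imaginary = rnorm(length(y0), sd = nFac * sig$sigmaIm))
      dim(noise) <- dim(y0)
      res <- caseLossGrad(mAug, op, paramsToWeights(params, L),
                          params$alpha, cfg@nUnrolls, noise = noise,
                          wantCoordGrad = learnCoords)
      if (!is.finite(res$loss)) stop("NaN loss; aborting training")
      grads <- res$gWeights
      grads$alpha <- res$gAlpha
      if (learnCoords) {
        cw <- chainToWaveParams(res$gCoords, hsCur, wp, trajMode)
        grads$kyc <- cw$d_kyc; grads$kzc <- cw$d_kzc
        if (mode == "wave") { grads$sr <- cw$d_sr; grads$theta <- cw$d_theta }
      }
      st <- adamStep(params, grads, ad, lr, wd)
      params <- st$params; ad <- st$state
      if (learnCoords) {
        params$kyc <- pmin(pmax(params$kyc, -N / 2), N / 2 - 1e-6)
        params$kzc <- pmin(pmax(params$kzc, -N / 2), N / 2 - 1e-6)
        if (mode == "wave")
          params$sr <- pmin(pmax(params$sr, 1e-3), 1)
      }
      eLoss <- eLoss + res$loss; nSamp <- nSamp + 1
    }
    hsOut <- helixSet(params$kyc %||% hs@kyc, params$kzc %||% hs@kzc,
                      params$sr %||% hs@sr, params$theta %||% hs@theta)
    state <- list(helixSet = hsOut, weights = paramsToWeights(params, L),
                  alpha = params$alpha, wp = wp, mode = trajMode,
                  nUnrolls = cfg@nUnrolls)
    vl <- validateJoint(valCases, state)
    history <- rbind(history, data.frame(epoch = epoch,
                                         trainLoss = eLoss / nSamp,
                                         valLoss = vl))
  }
  state$history <- history
  state$trajectory <- enforceHardware(
    buildTrajectory(wp, state$helixSet, trajMode), wp)
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validation loss
#'
#' Deterministic forward pass without augmentation or added noise: each
#' validation image is sampled through the trained trajectory, reconstructed,
#' and scored; the mean normalized squared error is returned.
#'
#' @param cases list of validation cases (image + coils).
#' @param state trained state as returned by \code{\link{trainJoint}}.
#' @return mean loss across cases.
#' @export
validateJoint <- function(cases, state) {
  traj <- enforceHardware(buildTrajectory(state$wp, state$helixSet,
                                          state$mode), state$wp)
  losses <- vapply(cases, function(case) {
    op <- encodingOperator(case$coils, traj)
    y <- nufftForward(op, case$image)
    cfg <- modlConfig(nUnrolls = state$nUnrolls)
    mhat <- unrolledRecon(y, op, cfg, state$weights, state$alpha)
    nrmseLoss(mhat, case$image)
  }, numeric(1))
  mean(losses)
}
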