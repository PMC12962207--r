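#' Construct a flow phantom specification
#'
#' The default tube set reproduces the physical phantom used for prospective
#' validation: two small tubes of diameter 3 mm carrying 0.15 and 0.17 L/min
#' and a larger tube of diameter 12.7 mm at 1.83 L/min, in a hydrogel-like
#' background, with Venc = 80 cm/s.
#'
#' @param gridSize grid size N per axis.
#' @param voxel voxel size (mm), default 0.86.
#' @param tubes list of tubes; each a list with fields \code{axis} ("x", "y"
#'   or "z") and \code{center} (numeric(2), mm offsets in the two transverse
#'   axes) for straight tubes, or \code{control} (4 x 3 matrix of cubic
#'   Bezier control points, mm) for curved tubes; plus \code{diameter} (mm),
#'   one of \code{flowRate} (L/min) or \code{peakVelocity} (cm/s), and
#'   optional \code{profile} ("parabolic" or "plug").
#' @param background background signal level.
#' @param venc velocity encoding (cm/s).
#' @param nCoils number of synthetic coils.
#' @param noiseSigma k-space noise level used when simulating acquisitions.
#' @param seed integer seed.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridSize = 48L, voxel = 0.86,
                        tubes = NULL, background = 0.25, venc = 80,
                        nCoils = 8L, noiseSigma = 0, seed = 1L) {
  if (is.null(tubes)) {
    ext <- gridSize * voxel
    off <- ext / 4
    tubes <- list(
      list(axis = "z", center = c(-off, -off), diameter = 3,
           flowRate = 0.17, profile = "parabolic"),
      list(axis = "z", center = c(off, -off), diameter = 3,
           flowRate = 0.15, profile = "parabolic"),
      list(axis = "z", center = c(0, off / 2), diameter = 12.7,
           flowRate = 1.83, profile = "parabolic"))
  }
  for (tb in tubes) {
    prof <- tb$profile %||% "parabolic"
    if (prof == "parabolic" && tb$diameter <= 2 * voxel)
      stop("tube diameters must exceed 2 voxels for parabolic profiles")
  }
  new("PhantomSpec", gridSize = as.integer(gridSize), voxel = voxel,
      tubes = tubes, background = background, venc = venc,
      nCoils = as.integer(nCoils), noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

# peak velocity (cm/s) from flow rate (L/min) and radius (mm), parabolic flow
peakFromFlowRate <- function(Q, radiusMm) {
  Rcm <- radiusMm / 10
  2 * (Q * 1000 / 60) / (pi * Rcm^2)
}

# centerline sample points (M x 3 mm) and unit tangents for a tube
tubeCenterline <- function(tube, extent, nSamp = 256L) {
  if (!is.null(tube$control)) {
    tt <- seq(0, 1, length.out = nSamp)
    P <- tube$control
    B <- outer((1 - tt)^3, P[1, ]) + outer(3 * (1 - tt)^2 * tt, P[2, ]) +
      outer(3 * (1 - tt) * tt^2, P[3, ]) + outer(tt^3, P[4, ])
    dB <- outer(-3 * (1 - tt)^2, P[1, ]) +
      outer(3 * ((1 - tt)^2 - 2 * (1 - tt) * tt), P[2, ]) +
      outer(3 * (2 * tt * (1 - tt) - tt^2), P[3, ]) + outer(3 * tt^2, P[4, ])
    tg <- dB / sqrt(rowSums(dB^2))
    list(points = B, tangents = tg)
  } else {
    ax <- match(tube$axis, c("x", "y", "z"))
    s <- seq(-extent / 2, extent / 2, length.out = nSamp)
    pts <- matrix(0, nSamp, 3)
    pts[, ax] <- s
    perp <- setdiff(1:3, ax)
    pts[, perp[1]] <- tube$center[1]
    pts[, perp[2]] <- tube$center[2]
    tg <- matrix(0, nSamp, 3); tg[, ax] <- 1
    list(points = pts, tangents = tg)
  }
}

#' Build the phantom geometry
#'
#' Evaluates magnitude, velocity (cm/s, along the local centerline tangent)
#' and the vessel mask on a supersampled grid and block-averages down to the
#' target grid, so partial-volume voxels at tube rims carry fractional
#' magnitude and velocity rather than stair-step artifacts. Parabolic flow
#' uses v(rho) = v_peak (1 - (rho/R)^2) with v_peak = 2 Q / (pi R^2) when a
#' flow rate Q is given.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param supersample supersampling factor (default 2).
#' @return list(magnitude, velocity [N x N x N x 3], mask).
#' @export
buildGeometry <- function(spec, supersample = 2L) {
  N <- spec@gridSize
  ss <- as.integer(supersample)
  Nf <- N * ss
  vf <- spec@voxel / ss
  pos <- ((0:(Nf - 1)) - Nf / 2 + 0.5) * vf     # fine voxel centers, mm
  extent <- N * spec@voxel
  mag <- array(spec@background, rep(Nf, 3))
  vel <- array(0, c(Nf, Nf, Nf, 3))
  owner <- array(0L, rep(Nf, 3))
  for (ti in seq_along(spec@tubes)) {
    tube <- spec@tubes[[ti]]
    R <- tube$diameter / 2
    prof <- tube$profile %||% "parabolic"
    cl <- tubeCenterline(tube, extent + 2 * spec@voxel)
    vpk <- if (!is.null(tube$flowRate)) peakFromFlowRate(tube$flowRate, R)
    else tube$peakVelocity
    minD2 <- array(Inf, rep(Nf, 3))
    tgx <- array(0, rep(Nf, 3)); tgy <- tgx; tgz <- tgx
    margin <- R + vf
    for (si in seq_len(nrow(cl$points))) {
      p <- cl$points[si, ]
      ix <- which(abs(pos - p[1]) <= margin)
      iy <- which(abs(pos - p[2]) <= margin)
      iz <- which(abs(pos - p[3]) <= margin)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (pos[ix] - p[1])^2
      dy2 <- (pos[iy] - p[2])^2
      dz2 <- (pos[iz] - p[3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      cur <- minD2[ix, iy, iz, drop = FALSE]
      upd <- d2 < cur
      if (any(upd)) {
        cur[upd] <- d2[upd]
        minD2[ix, iy, iz] <- cur
        tg <- cl$tangents[si, ]
        sub <- tgx[ix, iy, iz, drop = FALSE]
        sub[upd] <- tg[1]; tgx[ix, iy, iz] <- sub
        sub <- tgy[ix, iy, iz, drop = FALSE]
        sub[upd] <- tg[2]; tgy[ix, iy, iz] <- sub
        sub <- tgz[ix, iy, iz, drop = FALSE]
        sub[upd] <- tg[3]; tgz[ix, iy, iz] <- sub
      }
    }
    inside <- minD2 <= R^2
    if (any(owner[inside] != 0L)) stop("overlapping tubes in phantom spec")
    owner[inside] <- ti
    speed <- array(0, rep(Nf, 3))
    if (prof == "parabolic")
      speed[inside] <- vpk * (1 - minD2[inside] / R^2)
    else speed[inside] <- vpk
    mag[inside] <- 1
    vel[, , , 1] <- vel[, , , 1] + speed * tgx
    vel[, , , 2] <- vel[, , , 2] + speed * tgy
    vel[, , , 3] <- vel[, , , 3] + speed * tgz
  }
  # block-average the supersampled grid down to N^3
  down <- function(a) {
    dim(a) <- c(ss, N, ss, N, ss, N)
    apply(a, c(2, 4, 6), mean)
  }
  velC <- array(0, c(N, N, N, 3))
  for (d in 1:3) velC[, , , d] <- down(vel[, , , d])
  frac <- down(array(as.numeric(owner > 0L), rep(Nf, 3)))
  list(magnitude = down(mag), velocity = velC, mask = frac > 0)
}

#' 4-point referenced flow encoding
#'
#' Encode 1 is the flow-compensated reference carrying only the background
#' phase; encode 1 + d (d in x, y, z) additionally carries the velocity phase
#' pi v_d / venc, the standard phase-contrast convention under which
#' |v| = venc maps to a phase difference of pi.
#'
#' @param magnitude real array N^3.
#' @param velocity real array N x N x N x 3 (cm/s).
#' @param venc velocity encoding (cm/s).
#' @param backgroundPhase optional real array N^3 (radians), default 0.
#' @return complex array N x N x N x 4.
#' @export
flowEncode <- function(magnitude, velocity, venc, backgroundPhase = NULL) {
  d <- dim(magnitude)
  if (is.null(backgroundPhase)) backgroundPhase <- array(0, d)
  out <- array(0i, c(d, 4))
  out[, , , 1] <- magnitude * exp(1i * backgroundPhase)
  for (k in 1:3)
    out[, , , k + 1] <- magnitude *
      exp(1i * (backgroundPhase + pi * velocity[, , , k] / venc))
  out
}

#' Synthesize smooth coil sensitivity maps
#'
#' Low-order complex spatial polynomials with per-coil random coefficients
#' and phase offsets, normalized to unit root-sum-of-squares everywhere (so
#' in particular inside any support). A single coil yields the constant unit
#' map.
#'
#' @param N grid size.
#' @param nCoils number of coils.
#' @param seed integer seed.
#' @return a \linkS4class{CoilSet}.
#' @export
synthCoils <- function(N, nCoils, seed = 1L) {
  if (nCoils < 1) stop("nCoils must be >= 1")
  if (nCoils == 1L)
    return(coilSet(array(1 + 0i, c(N, N, N, 1L)),
                   supportMask = array(TRUE, rep(N, 3))))
  set.seed(seed)
  xn <- ((0:(N - 1)) - N %/% 2) / N
  X <- array(rep(xn, times = N * N), rep(N, 3))
  Y <- array(rep(rep(xn, each = N), times = N), rep(N, 3))
  Z <- array(rep(xn, each = N * N), rep(N, 3))
  maps <- array(0i, c(N, N, N, nCoils))
  for (c in seq_len(nCoils)) {
    a <- rnorm(3); b <- rnorm(3, sd = 0.5); ph <- runif(1, -pi, pi)
    p <- rnorm(3, sd = 2)
    amp <- 1 + 0.6 * (a[1] * X + a[2] * Y + a[3] * Z) +
      0.4 * (b[1] * X^2 + b[2] * Y^2 + b[3] * Z^2)
    phase <- ph + p[1] * X + p[2] * Y + p[3] * Z
    maps[, , , c] <- amp * exp(1i * phase)
  }
  rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  rss[rss == 0] <- 1
  for (c in seq_len(nCoils)) maps[, , , c] <- maps[, , , c] / rss
  coilSet(maps, supportMask = array(TRUE, rep(N, 3)))
}

#' Build a complete phantom case
#'
#' Geometry, coil maps and noiseless 4-point flow-encoded volumes for one
#' specification; deterministic given the spec's seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param supersample geometry supersampling factor.
#' @return a \linkS4class{PhantomCase}.
#' @export
makePhantomCase <- function(spec, supersample = 2L) {
  geo <- buildGeometry(spec, supersample)
  coils <- synthCoils(spec@gridSize, spec@nCoils, seed = spec@seed)
  enc <- flowEncode(geo$magnitude, geo$velocity, spec@venc)
  new("PhantomCase", spec = spec, magnitude = geo$magnitude,
      velocity = geo$velocity, mask = geo$mask, encodes = enc, coils = coils)
}

#' Randomized phantom specification
#'
#' Draws a spec with randomized straight (or curved) tubes spanning vessel
#' scales from small cortical-artery calibre to the large-tube calibre of the
#' physical phantom; used to build training/validation collections.
#'
#' @param gridSize,voxel,nCoils,venc,noiseSigma passed to
#'   \code{\link{phantomSpec}}.
#' @param nTubes number of tubes (default drawn from 2:4).
#' @param curved use random cubic Bezier centerlines.
#' @param seed integer seed.
#' @return a \linkS4class{PhantomSpec}.
#' @export
randomPhantomSpec <- function(gridSize = 32L, voxel = 2, nTubes = NULL,
                              curved = FALSE, nCoils = 4L, venc = 80,
                              noiseSigma = 0, seed = 1L) {
  set.seed(seed)
  if (is.null(nTubes)) nTubes <- sample(2:4, 1)
  ext <- gridSize * voxel
  tubes <- list()
  tries <- 0
  while (length(tubes) < nTubes && tries < 200) {
    tries <- tries + 1
    dia <- runif(1, max(2.2 * voxel, 0.08 * ext), 0.22 * ext)
    if (curved) {
      P <- cbind(runif(4, -ext / 3, ext / 3), runif(4, -ext / 3, ext / 3),
                 seq(-ext / 2, ext / 2, length.out = 4))
      cand <- list(control = P, diameter = dia,
                   peakVelocity = runif(1, 10, 60), profile = "parabolic")
      ok <- TRUE
    } else {
      ax <- sample(c("x", "y", "z"), 1)
      ctr <- runif(2, -0.3 * ext, 0.3 * ext)
      cand <- list(axis = ax, center = ctr, diameter = dia,
                   peakVelocity = runif(1, 10, 60), profile = "parabolic")
      # reject overlap with same-axis tubes (crossing axes would collide too;
      # keep all tubes on one axis for guaranteed disjointness)
      cand$axis <- "z"
      ok <- all(vapply(tubes, function(t0)
        sqrt(sum((t0$center - ctr)^2)) > (t0$diameter + dia) / 2 + voxel,
        logical(1)))
      ok <- ok && all(abs(ctr) + dia / 2 < ext / 2 - voxel)
    }
    if (ok) tubes[[length(tubes) + 1L]] <- cand
  }
  if (length(tubes) < nTubes) stop("could not place non-overlapping tubes")
  phantomSpec(gridSize = gridSize, voxel = voxel, tubes = tubes,
              nCoils = nCoils, venc = venc, noiseSigma = noiseSigma,
              seed = seed + 1000L)
}

#' Materialize a dataset of phantom cases on disk
#'
#' Writes one container file per specification plus a train/validation
#' manifest split 9:1 (seeded); bit-identical given the same seed.
#'
#' @param specs list of \linkS4class{PhantomSpec}.
#' @param dir output directory.
#' @param seed split seed.
#' @return invisibly, the manifest list.
#' @export
makeDataset <- function(specs, dir, seed = 1L) {
  if (length(specs) < 2) stop("need at least 2 specs")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(specs))
  for (i in seq_along(specs)) {
    case <- makePhantomCase(specs[[i]])
    files[i] <- file.path(dir, sprintf("case_%03d.rds", i))
    writePhantomCase(case, files[i])
  }
  set.seed(seed)
  n <- length(specs)
  nVal <- max(1L, round(n / 10))
  valIdx <- sort(sample.int(n, nVal))
  manifest <- list(train = files[-valIdx], val = files[valIdx],
                   seed = seed, nCases = n)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(manifest)
}

#' Turn phantom cases into training samples
#'
#' Each selected flow encode of each case becomes one complex training
#' volume paired with the case's coil maps.
#'
#' @param cases list of \linkS4class{PhantomCase}.
#' @param encodes integer vector of encode indices (1 = reference,
#'   2:4 = x/y/z).
#' @return list of lists with fields \code{image} and \code{coils}.
#' @export
trainingCasesFromPhantom <- function(cases, encodes = 2L) {
  out <- list()
  for (case in cases) for (e in encodes)
    out[[length(out) + 1L]] <- list(image = case@encodes[, , , e],
                                    coils = case@coils)
  out
}
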