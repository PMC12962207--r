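# Small in-code fixtures shared across tests.

randomImage <- function(N, seed = 1) {
  set.seed(seed)
  array(rnorm(N^3) + 1i * rnorm(N^3), rep(N, 3))
}

randomCoords <- function(K, N, seed = 1, margin = 0) {
  set.seed(seed)
  matrix(runif(K * 3, -N / 2 + margin, N / 2 - margin - 1e-9), K, 3)
}

uniformCoil <- function(N) coilSet(array(1 + 0i, c(N, N, N, 1L)))

# full Cartesian integer grid coordinates
cartesianCoords <- function(N) {
  as.matrix(expand.grid(kx = (-N / 2):(N / 2 - 1), ky = (-N / 2):(N / 2 - 1),
                        kz = (-N / 2):(N / 2 - 1)))
}

relErr <- function(a, b) sqrt(sum(Mod(a - b)^2) / max(sum(Mod(b)^2),
                                                      .Machine$double.xmin))

# tiny wave geometry for gradient tests
tinyWaveSetup <- function(N = 10L, npe = 5L, nro = 8L, seed = 1) {
  set.seed(seed)
  wp <- waveParams(radius = N / 8, cycles = 2L, matrixSize = N,
                   nReadout = as.integer(nro), dwell = 2.7e-3 / nro)
  hs <- helixSet(runif(npe, -N / 4, N / 4), runif(npe, -N / 4, N / 4),
                 sr = runif(npe, 0.6, 0.95), theta = runif(npe, 0, 2 * pi))
  list(wp = wp, hs = hs)
}
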