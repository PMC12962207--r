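#' Scan time of a phase-contrast protocol
#'
#' Total acquisition time = TR x (phase encodes) x (flow-encoding points),
#' in minutes. With the published protocol (TR = 7.7 ms, 4 flow points) the
#' accelerated scan's 4385 phase encodings give 2.25 min and the reference
#' scan's 11000 spokes give 5.65 min.
#'
#' @param tr repetition time (s).
#' @param nEncodes phase encodes (or spokes).
#' @param nFlowPoints flow-encoding points per encode (default 4).
#' @return scan time in minutes.
#' @export
scanTimeMinutes <- function(tr, nEncodes, nFlowPoints = 4L)
  tr * nEncodes * nFlowPoints / 60

#' Acceleration factor of the partial-echo accelerated scan
#'
#' R = ef N^2 / NPE: the acquired phase-encode count NPE against the ef N^2
#' samples a fully sampled partial-echo Cartesian acquisition of the same
#' matrix would need. The published protocol (N = 256 from 220 mm / 0.86 mm,
#' ef = 0.75, NPE = 4385) gives R = 11.2.
#'
#' @param matrixSize grid size N per axis.
#' @param echoFraction echo fraction ef.
#' @param nPhaseEncodes acquired phase encodes.
#' @return acceleration factor.
#' @export
accelerationFactor <- function(matrixSize, echoFraction, nPhaseEncodes)
  echoFraction * matrixSize^2 / nPhaseEncodes
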