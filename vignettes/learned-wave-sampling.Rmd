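---
title: "Learned wave-encoded sampling and model-based reconstruction: methods"
author: "WaveRecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned wave-encoded sampling and model-based reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(WaveRecon)
```

This vignette documents the model the package implements, the assumptions
and numerical choices behind it, what the synthetic data generator does and
does not emulate, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. The acquisition model

A 3D phase-contrast acquisition is modeled as

$$y = A m + \epsilon, \qquad A = C\,F\,S,$$

where $m \in \mathbb{C}^{N^3}$ is the complex image, $C$ applies coil
sensitivity maps, $F S$ evaluates the Fourier transform at arbitrary
off-grid sample coordinates (a type-2 NUFFT), and $\epsilon$ is complex
Gaussian noise. Coordinates are expressed in *grid units* (cycles across the
FOV), so valid samples satisfy $|k| \le N/2$; image voxel indices are
centered at zero. The operator is scaled by $N^{-3/2}$ so that the fully
sampled Cartesian case coincides with the orthonormal FFT and
$A^{\mathsf H}A = I$ there. Density compensation is deliberately **not**
applied in the adjoint: the data-consistency step of the unrolled
reconstruction uses the plain $A^{\mathsf H}$.

Two implementations share this contract:

* `method = "nufft"`: Kaiser–Bessel gridding with kernel width 4 and
  oversampling 1.25 (the protocol's settings). These parameters are a
  speed/accuracy compromise: their intrinsic aliasing level is about
  $10^{-2}$ in relative $\ell_2$ on small grids, which is a property of the
  kernel design, not of this implementation — the same code reaches
  $5\cdot10^{-5}$ at width 6 / oversampling 1.5 and $2\cdot10^{-7}$ at
  width 8 / oversampling 2 (both verified in the tests). The adjoint is the
  exact matrix transpose of the implemented forward (real interpolation
  weights), so the dot-product identity holds to machine precision at any
  kernel setting.
* `method = "dft"`: the exact discrete transform by direct summation, used
  as the float64 oracle on small problems and as the reference that
  finite-difference gradient checks differentiate.

All computation is float64 throughout; R has no 32-bit float arrays, so the
float32 training mode a GPU implementation would use has no counterpart
here.

## 2. Wave (helix) readouts and their learnables

A wave readout is a helix: a linear kx traversal with sinusoidal ky/kz.
The phase along the readout is
$\phi[i] = -2\pi C\,[(e_f - \tfrac12) - e_f\, i / N_{RO}]$,
monotone in $i$ and zero at the echo index
$i_\mathrm{echo} = N_{RO}(e_f - \tfrac12)/e_f$. The printed form of this
expression in the source material is typographically ambiguous; the adopted
reading is the one above, chosen because it (i) preserves the partial-echo
structure at $e_f = 0.75$, (ii) makes the sin/cos argument of the
transverse coordinates equal to the kx phase, and (iii) maps linearly onto
the kx grid extent $[-(e_f-\tfrac12)N,\, N/2]$ with the echo crossed at
$k_x = 0$ (`kxFromPhase`). The mapping is recorded in trajectory metadata.

Per helix $j$ the learnables are the center $(k_{yc}, k_{zc})$, the radius
scaling $s_r \in (0, 1]$ and the rotation $\theta$:
$k_y[j,i] = s_r[j]\, r \sin(\phi[i] + \theta[j]) + k_{yc}[j]$ and the
cosine analogue for $k_z$. The base radius $r$ is never printed by the
protocol (only $g_{max} = 9$ mT/m is); it is derived from the hardware
limits via the helix's angular rate
$\omega = 2\pi C e_f/(N_{RO}\,\delta t)$:
$r = \min(g_{max}\gamma\,\mathrm{FOV}/\omega,\; s_{max}\gamma\,\mathrm{FOV}/\omega^2)$
(`deriveWaveRadius`). Dwell time (4 µs) and slew limit (150 T/m/s) are not
printed either; typical 3T values are defaults and both are configurable.

**Hardware enforcement.** Instead of time-optimal gradient redesign, the
package checks the discrete gradient ($g = \Delta k/(\gamma\,\delta t\,
\mathrm{FOV})$) and slew waveforms and scales each helix's $s_r$ by the
largest factor $\le 1$ that achieves compliance — the readout length never
changes, matching the constraint that radii can only shrink. Because
scaling $s_r$ scales the transverse gradient and slew linearly, the factor
has a closed form, which the tests verify against a binary-search oracle.
The same mechanism keeps every coordinate inside the sampled band
($s_r r \le N/2 - \max(|k_{yc}|,|k_{zc}|)$), so the invariant
$|k| \le N/2$ holds after enforcement. When enforcement is active the
chain-rule partials are taken at the nominal $s_r$; at the projection
boundary this overestimates the effective partial by the (clamped) scale
factor, a standard projected-gradient approximation.

**Poisson-disc initialization.** Phase-encode centers are initialized by
variable-density dart throwing: minimum spacing 1 grid unit (fully sampled)
inside a central disc of radius $N/32$, growing linearly outside. The
profile slope is the free parameter used to hit the requested count
exactly (bisection to the steepest feasible slope, then seeded random
thinning); accepted pairs satisfy
$\mathrm{dist} \ge \min(\rho(p), \rho(q))$. Identical seeds give bitwise
identical draws, and wave/no-wave/fixed modes share one draw.

## 3. Coordinate gradients

For a real loss $L$ of complex data, the gradient with respect to a sample
coordinate $k_d$ pulls the factor $-2\pi i x_d/N$ into the transform:
the Jacobian-vector products are NUFFTs of spatially weighted images, three
extra transforms per backward pass rather than any dense matrix. With the
cotangent convention $g = \partial L/\partial\,\mathrm{Re} +
i\,\partial L/\partial\,\mathrm{Im}$,

$$\frac{\partial L}{\partial k_d}\Big|_{\text{fwd}} =
\sum_c \mathrm{Re}\!\left[\overline{g_y}\cdot
\mathcal{F}\{x_d\,C_c\,m\}\cdot(-2\pi i/N)\right],$$

and the adjoint case routes the image cotangent through the same weighted
forward transform. Coils share coordinates, so their contributions sum. The
equivalent Wirtinger form carries an explicit factor $2\,\mathrm{Re}[\cdot]$
because its cotangents are half-derivatives; the two conventions agree, and
central finite differences in the exact-DFT mode (step $10^{-4}$ grid
units, float64) confirm the implementation to $\sim10^{-8}$ relative error.

Why analytic Jacobians rather than autodiff through the gridding kernel?
Differentiating the interpolator yields the exact gradient *of the
approximation*, whose error is the derivative of the oscillatory aliasing
error — systematically larger than the error of approximating the true
Jacobian by one more NUFFT. The package implements both routes
(`coordGradForward` vs `coordGradForwardNaive`) and a test measures both
against the exact-DFT gradient; the analytic route wins. This asymmetry is
the reason finite differences of the *NUFFT-mode* loss are not the right
oracle for the analytic Jacobian: FD checks run in the exact-DFT mode.

There is no autodiff engine in R, so the "registered custom backward" is a
hand-written vector-Jacobian tape (`caseLossGrad`) covering the entire
pipeline — the simulation of $y$ itself, $m_0 = A^{\mathsf H}y$, every
data-consistency step, the complex convolutions, CReLU and biases — with
coordinate cotangents accumulated across every application of $A$ and
$A^{\mathsf H}$. End-to-end finite-difference checks through a 2-unroll
reconstruction agree to $10^{-9}$–$10^{-6}$.

## 4. The unrolled reconstruction

The reconstruction alternates a proximal-gradient data-consistency step
$z^{t+1} = \hat m^t - 2\alpha A^{\mathsf H}(A\hat m^t - y)$ with a learned
regularizer $\hat m^{t+1} = D_\phi(z^{t+1})$, unrolled (default six times)
with shared weights, from $m_0 = A^{\mathsf H} y$ (the initialization is
unstated in the source; the adjoint is the standard choice). $\alpha$ is
learnable, initialized to $0.5/L$ with $L = \|A^{\mathsf H}A\|$ estimated
by power iteration. The regularization weight $\lambda$ of the variational
form has no separate housing in the unrolled scheme; it is absorbed into
$\alpha$ and the denoiser.

$D_\phi$ is a fully complex 5-layer ResNet: complex convolutions
$W\!*\!d = (X\!*\!a - Y\!*\!b) + i(Y\!*\!a + X\!*\!b)$ with $3^3$ kernels
and complex biases, CReLU ($\mathrm{ReLU}(a) + i\,\mathrm{ReLU}(b)$)
between hidden layers, and a single global residual connection — so
all-zero weights give exactly the identity, a property the tests pin down.
Per-layer residuals are not used. The published parameter count (139,680 at
depth 5) does not determine the width uniquely; with the count formula
$2\sum_l (k^3 c_{in} c_{out} + c_{out}) = 162F^2 + 116F + 2$, width
$F = 29$ gives 139,608, the nearest achievable total, and is the full-scale
default. Desk-scale training uses smaller widths.

**Blockwise application and checkpointing.** Large volumes pass through the
denoiser in overlapping cubes. The default blending assigns every voxel to
exactly one block core (overlaps split at their midpoints): an exact
partition of unity, so the identity function reproduces the volume
bit-for-bit. Uniform averaging over overlaps — the natural alternative — is
available (`blend = "average"`) but cannot be bit-exact in floating point
(summing $n$ identical contributions and dividing by $n$ rounds for most
$n$), which is why cropping is the default. Gradient checkpointing stores
only the denoiser input and recomputes activations in the backward pass;
gradients are bit-identical to the stored-activation path and the stored
bytes measurably smaller.

## 5. Joint training

Adam (lr $10^{-3}$, weight decay $10^{-3}$ — decay applied to network
weights only) minimizes the image-domain loss
$\sum|m - \hat m|^2 / \sum|m|^2$. The loss is implemented exactly as this
ratio of summed squares: it is conventionally *named* NRMSE although no
square root is printed, and the package follows the printed form.
Per epoch all cases are visited in random order with no gradient
accumulation; per case the reference is augmented, k-space simulated,
noise added, and one optimizer step taken on all learnables. After each
step $s_r$ is clamped into $(0, 1]$, centers into the k-space box, and
hardware limits re-enforced at trajectory build time.

**Augmentation.** A random first-order phase
$\phi = a_1 x + a_2 y + a_3 z + a_4$ (coefficients uniform in $[-10, 10]$,
spatial coordinates normalized to $[-0.5, 0.5)$ so $a_i$ counts phase
cycles across the FOV — the units are unstated in the source and this
choice is recorded) and amplitude scale $b \in [0.3, 3]$ are applied to the
reference; complex Gaussian noise scaled by $n \in [0.5, 1.5]$ times the
estimated noise level is added to k-space. The noise level is the median of
$|\mathrm{Re}|$ and $|\mathrm{Im}|$ over the edge shell $|k| > 0.9\,(N/2)$,
calibrated by the half-normal median ($0.6745\,\sigma$); per-component
medians are one admissible reading of the stated "median at the edge of
k-space" and are documented as such.

## 6. Desk-scale world

The published experiment trains for ~140 GPU-hours on 36 in-vivo cases at
$256^3$. The package's validation world is deliberately small, and the
scaling choices are stated once here:

* **Grid** $N = 32$, FOV kept at 220 mm, 4 coils, 6 training + 2 validation
  phantom cases, 2 unrolls, width 4, 4 epochs.
* **Acceleration**: 64 phase encodes, i.e. $R = e_f N^2/\mathrm{NPE} = 12$,
  matching the protocol's $R = 11.2$ regime.
* **Readout**: cycles stay at the published $C = 8$; the readout sample
  count scales to $3N$ so a helix turn keeps $\ge 12$ samples (the
  full-scale protocol has 84/turn). Cutting samples-per-turn much below
  this aliases the helix into a few discrete azimuths and destroys the
  wave benefit — an artifact of desk scaling, not of the method. The dwell
  grows to keep the 2.7 ms readout duration, and the helix radius scales
  with the matrix ($N/16$) to preserve relative k-space coverage.
* **Phase-augmentation range** scales with the matrix:
  $a_i \in [-10\,N/256,\, 10\,N/256] = [-1.25, 1.25]$ at $N = 32$. The
  coefficients displace the object spectrum by $a_i$ grid units; $\pm10$ is
  4 % of k-space at $N = 256$ but a third of it at $N = 32$, which would
  drown the coordinate-learning signal in wholesale spectrum shifts.
* **Coordinate learning rate**: the sampling learnables use an Adam step of
  0.05 grid units (network weights keep $10^{-3}$). With Adam the per-step
  displacement is approximately the learning rate; the published training
  reorganizes coordinates by grid units over $\sim10^5$ steps, so a
  ~25-step desk budget needs a proportionally larger step for coordinate
  learning to act at all. 0.1 was also piloted and found less stable for
  straight-line (no-wave) learning.

With this world the acceptance suite reproduces, from scratch and over five
seeds, the ordering *learned wave $\le$ learned no-wave $\le$ fixed
initialization* in seed-mean validation NRMSE — the desk-scale mirror of
the published image-quality ordering. A green ordering test establishes
that the implemented gradients and training loop move each mode's
learnables in the right direction at this scale; it does not establish
in-vivo image quality, g-factor behavior, robustness to motion or
off-resonance, or any property of prospective scanning.

## 7. The synthetic phantom

`phantomSpec()` defaults to a digital copy of the physical validation
phantom: two 3 mm tubes at 0.17 and 0.15 L/min and one 12.7 mm tube at
1.83 L/min in a hydrogel-like background, Venc = 80 cm/s. Flow is steady
laminar Poiseuille flow, $v(\rho) = v_{peak}(1 - (\rho/R)^2)$ with
$v_{peak} = 2Q/(\pi R^2)$, directed along the local centerline tangent
(straight or cubic-Bézier centerlines). Geometry is evaluated on a
2× supersampled grid and block-averaged down, so rim voxels carry
partial-volume magnitude and velocity; encoding then applies the standard
4-point referenced convention (reference plus three orthogonal encodes,
phase $\pi v_d/\mathrm{venc}$). Averaging geometry *before* encoding makes
the encode→decode roundtrip exact by construction and keeps the
cross-sectional flux conservative; it does **not** model intravoxel phase
dispersion, pulsatility (the pump waveform is time-averaged), relaxometry,
or the 5-point balanced encoding of the contrast-enhanced training data
(a stated non-goal). Coil maps are smooth low-order complex polynomials
normalized to unit root-sum-of-squares.

Note the small-tube peak velocity at 0.17 L/min is 80.2 cm/s, marginally
above Venc — exactly as in the physical protocol; after partial-volume
averaging no voxel wraps at desk resolutions, and no unwrapping is
implemented (wrap handling is a flagged non-default).

## 8. Flow statistics

Velocities decode as $v_d = (\mathrm{venc}/\pi)\,
\angle(m_d\,\overline{m_0})$. The complex-difference angiogram is
$\sqrt{\sum_d |m_d - m_0|^2}$, thresholded at 10 % of its maximum for the
vessel mask. Cross-sections are taken perpendicular to the *known*
synthetic centerlines (the clinical centerline-tracking tool is out of
scope); flow is the summed normal velocity times pixel area (cm³/s → L/min
by 0.06), $\sigma_{vmax}$ is the sample SD of per-section maximum speed,
and pixelwise agreement pools all three velocity components over the mask
(OLS slope with 95 % CI, $R^2$, Bland–Altman mean difference ± 1.96 SD).
The ICC is fixed to the two-way mixed-effects, consistency,
single-measurement form ICC(3,1) $= (MS_R - MS_E)/(MS_R + (k-1)MS_E)$ —
the source states only "two-way mixed effects"; rows are vessel segments,
columns repeated cross-sections, and CV is pooled over all entries of the
table before any averaging across subjects. A perfectly constant table has
degenerate ICC and is reported as 1 with a flag.

## 9. Known limitations

* The NUFFT at the protocol's kernel settings is a ~1 % interpolator by
  design; quantitative operator tests use accuracy-grade kernels.
* Training at desk scale is minutes, not GPU-days; learned patterns are
  directionally meaningful but far from converged.
* File containers are RDS-with-schema rather than HDF5/NIfTI (no R
  bindings available in the supported environment); layouts and roundtrip
  contracts are documented and tested.
* Steady flow only; no off-resonance, trajectory-measurement correction,
  eddy currents, or scanner waveform export.
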