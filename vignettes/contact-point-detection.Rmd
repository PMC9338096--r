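---
title: "Locating the contact point in AFM force curves with 1D convolutional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the contact point in AFM force curves with 1D convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An AFM force measurement records the photodetector (PSD) signal — a proxy
for cantilever deflection — against the sample vertical position while probe
and sample approach. Almost every downstream analysis (force–separation
transformation, indentation depths, long-range force fits) hinges on one
scalar: the **contact point** `zc`, the sample position at which mechanical
contact is established. On stiff charged surfaces the contact region is a
near-unity-slope line and a jump-to-contact often marks the transition; on
soft films the steric repulsion blends smoothly into a compliant contact
regime and thresholds or derivative rules need per-dataset retuning.

`forcepoint` treats contact-point location as a supervised 1D regression
problem: a fixed-length, normalized approach signal goes into a 1D
convolutional network whose single output is the normalized sample position
of the contact point. Because labelled experimental curves are expensive,
the package pairs the networks with a physics-based simulator that produces
unlimited labelled curves with *exact* ground truth, which is also what the
test suite trains and evaluates on.

## The synthetic force-curve model

All simulator forces are in nN, distances in nm, and spring constants in
N/m (numerically equal to nN/nm). The cantilever is quasi-static: at
undeflected tip–sample separation \(s\), the deflection \(\delta\) solves

\[ k\,\delta = F(s + \delta), \]

with \(\delta > 0\) bending away from the sample. Along an approach ramp
\(s\) decreases and the solution is tracked on the stable branch connected
to large separations.

### Hard charged surface (mica-like)

\[ F(d) = A\, e^{-d/\lambda_D} \;-\; \frac{H}{d^2 + d_0^2}, \]

an exponential electrostatic double-layer repulsion with Debye length
\(\lambda_D\) (computed from the ionic strength via the standard closed
form with CODATA constants) plus an inverse-square van der Waals
attraction smoothly saturated at a molecular-scale softening length
\(d_0\) (default 0.3 nm). A hard cutoff `max(d, d0)` was deliberately
avoided: its gradient discontinuity pins equilibrium folds at the cutoff
and creates picometre-scale jump artifacts for a whole region of
parameter space.

The stable branch ends where \(F'(d) = k\) — the textbook
**jump-to-contact** instability. The fold separation `d_crit` and the
contact-onset separation \(s^* = d_{\rm crit} - F(d_{\rm crit})/k\) are
computed in closed form from the force law; folds whose landing amplitude
is below 0.05 nm (sub-noise, produced by near-critical parameters) are
followed through onto the inner stable branch and the curve continues to
smooth contact at \(d = 0\). In contact the deflection grows linearly
with slope `hard_wall_slope` per nm of sample travel; the default range
(0.97–1) reflects the stiffness contrast of a mica-like surface
(tens of N/m) against a 0.1 N/m lever, for which deflection tracks sample
displacement almost one-to-one.

The ground-truth label is the sample position where mechanical contact is
established: the jump landing position if a jump occurred, else the
position where the separation reaches zero. Both have closed forms, so
labels are exact rather than read off the sampled grid.

### Soft film (salivary-pellicle-like)

The diffuse outer layer exerts an exponential steric repulsion
\(F(d) = A_s e^{-d/\lambda_s}\); at the film-compression point the curve
enters a compliant-contact regime with a 3/2-power force law
\(F = A_s + C\,\delta_i^{3/2}\) in the indentation \(\delta_i\), and once
\(\delta_i\) exceeds the film thickness the response becomes constant
compliance (the substrate). `n_indent_events` instantaneous deflection
drops of random depth are inserted strictly inside the contact branch,
mimicking breakthrough events. The label `zc` marks the steric-to-contact
regime transition.

### Acquisition model

Deflection is converted to volts with the photodetector sensitivity; a
linear baseline tilt and i.i.d. Gaussian noise are added, with the noise
sd switching from `noise_sigma_noncontact` to the (smaller)
`noise_sigma_contact` exactly at `zc` — the squeeze-film damping cue that
practitioners use on soft samples. The ramp is laid out so the deflection
trigger `max_deflection` is met exactly at its far end, as a real
instrument would stop a ramp. Draws whose contact travel would occupy
less than max(2 % of the ramp, 3 samples) — or more than 95 % of it — are
generation errors: the labelled transition would have no support inside
the curve. Dataset generation redraws such curves deterministically
within the curve's own RNG sub-stream.

### Default parameter ranges

`default_param_ranges()` defines the study conditions: ramp length
50–500 nm, 256–4096 samples per curve, trigger 0.2–0.8 V, sensitivity
0.02–0.08 V/nm, contact-noise sd 1–4 mV with a non-contact/contact ratio
of 1–4, spring constant fixed at 0.1 N/m (the soft levers appropriate for
long-range force work), ionic strengths {1, 10, 100} mM. The force
amplitudes (electrostatic 0.05–1 nN, lumped Hamaker term 0.01–0.1 nN nm²,
steric 0.1–2 nN with 2–20 nm decay, film thickness 5–30 nm, Hertz-like
prefactor 0.05–0.5 nN/nm^1.5) are order-of-magnitude values typical for
these systems; all are configurable per dataset.

### What the simulator does *not* emulate

Noise is white and Gaussian with one regime switch — no 1/f drift beyond
a linear tilt, no interference fringes; indentation events have zero
width; retract curves, adhesion, hydrodynamic drag and tip-shape effects
are absent; each curve has exactly one contact event. Success on these
curves therefore demonstrates that the pipeline can learn the contact
geometry under randomized acquisition conditions, not that a network
trained here transfers to any particular instrument's data — for that,
train on curves from that instrument through the same interface.

## Preprocessing

Networks need a fixed input size while experimental curves arrive at
arbitrary lengths, so every curve is linearly interpolated onto 5120
uniformly spaced positions over its own z range (larger than typical
experimental curve sizes; longer curves are downsampled by the same
path). The PSD axis is then min–max normalized per curve to [0, 1], and
the label is encoded as the normalized sample position. Min–max is the
simplest scheme consistent with that label encoding; it makes predictions
exactly invariant to positive affine changes of the PSD scale. Linear
interpolation is shape-preserving (no overshoot at the contact kink).
Predictions are decoded back to nm by the exact algebraic inverse;
outputs outside [0, 1] are decoded by extrapolation and flagged rather
than clipped, which would bias the error distribution.

## The two architectures

**ConvNet-1D** — three blocks of (1D convolution → ReLU → max-pool),
then a flatten and two fully connected layers, the last a single linear
unit. Package defaults: filters 16/32/64, kernels 11/7/5, pools 4/4/4,
128 dense units, L2 weight decay 1e-4 on every kernel (about 0.67 M
parameters at input length 5120). These widths are this package's
defaults, exposed in `convnet_spec()`.

**ResNet50-1D** — the standard 50-layer residual network with every 2D
convolution and pooling replaced 1:1 by its 1D counterpart: a stride-2
stem (kernel 7), max-pool 3/stride 2, four stages of bottleneck blocks
with counts [3, 4, 6, 3] and stage strides 1, 2, 2, 2, batch
normalization after every convolution, identity/projection shortcuts,
global average pooling and a one-unit linear head (about 23.5 M
parameters). The layer census is pinned by tests.

Both are implemented natively in R: convolutions are im2col gathers
followed by a single BLAS matrix multiplication, and all backward passes
are hand-derived and validated against central finite differences on
micro networks (worst relative error below 1e-6 for exact-gradient
layers). Outputs are unconstrained reals; the loss handles the rest.

## Training

Mean-squared error on normalized positions, minimized with Adam at an
initial learning rate of 1e-4, first momentum 0.9, second momentum 0.999.
No schedule, no early stopping, no augmentation: training runs a fixed
number of epochs and the weights from the epoch with minimum validation
loss are restored — on re-evaluation they reproduce that recorded loss
exactly, which the suite asserts. Batch size defaults to 32;
initialization is seeded Glorot-uniform. L2 enters as a per-layer weight
penalty in the loss (gradient \(2\lambda W\)), not as optimizer decay.
Batch-norm layers use batch statistics (momentum 0.99 running updates)
during training and running statistics for validation and inference.
Reproducibility is promised for a fixed seed on a fixed platform, not
bitwise across BLAS implementations.

## Evaluation and classical baselines

`evaluate_model()` reports the signed error `zc - zc_pred` in nm on the
original (non-normalized) z axis, with its mean and sample (n−1) standard
deviation and a Freedman–Diaconis histogram. `baseline_locate()` provides
the two classical detector families for comparison and as an independent
cross-check of the simulator labels:

* *deflection threshold* — first sample exceeding the non-contact
  baseline mean plus a multiple of its sd;
* *derivative threshold* — a two-step rule, as such detectors are used in
  practice: the smoothed first difference crossing its baseline threshold
  gives a coarse location, refined to the border of the linear
  constant-compliance region by walking backward from the tail slope.
  The refinement matters: under smooth long-range forces the raw
  crossing systematically fires early, and under near-critical attraction
  even the strongest curvature feature sits before the true contact. The
  baseline sd is floored at 5 % of the derivative's dynamic range so the
  rule stays defined on noise-free signals.

On noise-free hard-surface curves the derivative baseline, the simulator
label and (after training) the network prediction agree — the "oracle
triangle" the test suite checks.

## Numerical choices

* Non-contact deflection profiles are generated by inverting
  \(s(d) = d - F(d)/k\) on a dense grid (log-refined near the fold where
  \(d(s)\) has a square-root singularity); the d-window bypassed by a
  sub-threshold fold is excised because \(s(d)\) is multi-valued there.
* Root brackets for the jump landing stop below the unstable band's lower
  edge — a bracket touching the fold's double root makes Brent's method
  converge to the wrong root.
* The scalar equilibrium solver uses `uniroot` at tolerance 1e-13 on the
  branch bracket; the Hertz contact branch is solved by inverting
  \(t(\delta_i) = \delta_i + (C/k)\delta_i^{3/2}\) on a grid.
* Max-pool ties (exact equals) resolve to the earliest window position;
  with continuous inputs they occur with probability zero.
* Degenerate inputs fail loudly with typed conditions: constant signals
  (`fp_degenerate_error`), non-monotonic z, infeasible acquisitions
  (`fp_generation_error`), diverged training (`fp_diverged_error`).

## Scaled-down study sizes

The self-contained recovery study used by the tests and the acceptance
script trains the default ConvNet-1D on 400 synthetic hard-surface curves
(70/30 split) for 100 epochs — problem sizes chosen so the whole study
runs comfortably on a single CPU while still giving the network enough
signal to localize contact to well under 2 % of the ramp length on the
held-out split. The noise-contrast check fixes
\(\sigma_{nc} = 3\sigma_c\) and compares detrended (first-differenced)
sds in 100-sample windows on each side of the label; differencing removes
the deterministic slope, which would otherwise dominate the raw sd in the
contact region.

## Known limitations

Training the full ResNet50-1D at input length 5120 is functional but
slow on CPU in this implementation; the test suite exercises its
contracts (shapes, census, gradient flow, gradient correctness on micro
variants) rather than a full training run. The simulator's soft-film
model uses one diffuse layer over one substrate; multilayer films, and
multi-event localization generally, are out of scope. Baseline detectors
are comparison tools — their windows and multipliers are conventional
defaults, not tuned optima.
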