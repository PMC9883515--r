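---
title: "Directing Min-protein surface waves with bulk flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directing Min-protein surface waves with bulk flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system and the question

The MinD/MinE system of *E. coli* is the canonical mass-conserving
reaction–diffusion system: MinD-ATP binds a lipid membrane and recruits more
of itself plus its activating protein MinE; membrane-bound MinDE complexes
hydrolyze ATP and detach; MinD exchanges nucleotide in solution and rebinds.
Reconstituted on a supported bilayer, this cycle self-organizes into
traveling surface waves with wavelengths of tens of micrometers and crest
speeds of hundreds of nm/s.

`minflow` asks what a *uniform hydrodynamic flow of the bulk solution* does
to those waves.  The flow advects proteins in solution but not on the
membrane — a *differential flow* — so it acts on the surface pattern only
through the attachment–detachment coupling.  The package simulates this
system, analyzes its linear stability, maps the direction of wave
propagation over the control plane of flow speed and MinE:MinD density
ratio (E:D), and quantifies wave direction in image stacks with a
crest-velocity analysis that also applies to microscopy data.

## Model

Six concentration fields live on a laterally periodic 1D domain after
integrating out the dimension orthogonal to the membrane: membrane MinD
`m_d`, membrane MinDE complex `m_de`, and the vertically integrated bulk
densities of MinD-ADP `c_DD`, MinD-ATP `c_DT`, reactive MinE `c_Er` and
latent MinE `c_Ei` (all in 1/µm²).  Membrane species diffuse with `D_m`;
bulk species diffuse with `D_c` and are advected at the flow velocity
`v_f` (membrane species are never advected).  The reactions are
mass-action:

* attachment: `(k_D + k_dD m_d) c_DT` converts bulk MinD-ATP to `m_d`
  (basal plus self-recruitment),
* MinE recruitment: `(k_dEr c_Er + k_dEi c_Ei) m_d` converts `m_d` into
  the complex `m_de`,
* detachment: `k_de m_de` releases MinD-ADP and reactive MinE to the bulk,
* nucleotide exchange: `lambda c_DD` converts MinD-ADP to MinD-ATP,
* the MinE switch: reactive bulk MinE converts to the latent conformation
  at rate `mu`; latent MinE is recruited much more slowly
  (`k_dEi << k_dEr`).

These dynamics conserve the total MinD density `n_D` (mean of
`m_d + m_de + c_DD + c_DT`) and the total MinE density `n_E` (mean of
`m_de + c_Er + c_Ei`); the ratio `n_E / n_D` (E:D) is the main control
parameter.

Because the bulk is vertically integrated, bulk fields are areal
densities and the bulk-height factor of the attachment rates is absorbed
into `k_D`, `k_dD`, `k_dEr`, `k_dEi` (units 1/s and µm²/s).  This is
recorded in the parameter registry documentation.

### Model variants

* **Full switch model** — all six fields, as above.
* **Skeleton model** (`as_skeleton()`) — no MinE switch: `mu = 0` and the
  latent pool is identically zero.  It reproduces the full model's behavior
  at low E:D, where bulk MinE is predominantly reactive and cycles rapidly.
* **Reduced switch model** (`reduce_switch_model()`) — the high-E:D,
  fast-switching limit.  Bulk MinE gradients are negligible there, so the
  MinE pools are eliminated by a quasi-steady-state approximation: at every
  instant the uniform reactive pool is
  `c_Er = k_de <m_de> / (k_dEr <m_d> + mu)` and the latent pool follows
  from MinE conservation, `c_Ei = n_E - <m_de> - c_Er`.  Only `m_d`,
  `m_de`, `c_DD`, `c_DT` remain dynamical.  Since no MinE gradients exist,
  the MinE-advection flag provably has no effect on this variant.

### Sign conventions

Perturbations of the homogeneous steady state are written
`exp(i q x + sigma t)`; the phase velocity of a mode is `-Im(sigma)/q`;
"downstream" means the phase (or pattern) velocity has the sign of `v_f`.
These conventions are set once in `dispersion_relation()` and used
everywhere, including the sign of `pattern_velocity()`.

## Parameter registry and its calibration

Every run names its parameter set (`min_param_set()`), so parameter
provenance travels with results.  The shipped default,
`invitro_switch_v1`, was calibrated once, against the qualitative
structure the in vitro system is known to show, and then frozen:

* a lateral oscillatory instability (traveling waves, wavelength
  ~40–70 µm) at high E:D without flow;
* a laterally *stable* homogeneous state at low E:D (~0.05) without flow
  that becomes unstable under moderate flow — the flow-driven
  instability — with downstream-propagating modes;
* a short-wavelength instability branch with upstream phase velocity
  appearing at E:D ≈ 0.10 under moderate flow (`v_f` ≈ 1–3 µm/s), on top
  of the long-wavelength flow-driven band;
* total densities of order 10²–10³ µm⁻², the scale of a ~1 µM solution
  within the bulk-gradient penetration depth.

The calibration explored literature-plausible ranges (basal attachment
much slower than self-recruitment; MinE recruitment stronger per molecule
than MinD self-recruitment; nucleotide exchange ~1 s⁻¹ in the integrated
geometry; switch rate of order seconds; membrane diffusion 0.25 µm²/s and
bulk diffusion 56 µm²/s) by scanning dispersion relations and then
verifying the nonlinear direction selection by simulation.  The registry
records the set under a version name precisely so that a different
transcription of the kinetics can be slotted in as a new named set without
touching any analysis code.

One quantitative property resisted calibration: although the *linear*
upstream branch appears at E:D ≈ 0.10, the *saturated* waves just above
that onset coarsen under flow toward long wavelengths and travel
downstream, so the adiabatic upward sweep classifies its first upstream
pattern only several-fold higher in E:D (in the 0.4–0.7 range at
`v_f = 2 µm/s`), where the short-wavelength upstream wavetrain finally
out-competes the coarsened downstream pulse.  Scans of this model's
kinetics (including a targeted search for sets whose pattern onset occurs
with bulk-dominated MinD) did not locate a regime in which the saturated
upstream onset coincides with the linear one, so the measured adiabatic
onset of this parameter set is reported as such.  This mirrors the known
difficulty of pinning the critical E:D ratio of the transition
quantitatively; the registry-versioning exists precisely so an improved
kinetic transcription can replace the default set wholesale.

## Numerics

**Integrator.**  The transport part (diffusion + advection) is applied
exactly in Fourier space — each mode is multiplied by
`exp(dt(-D q^2 - i a v_f q))`, where the advection mask `a` is 1 for bulk
MinD, `advect_minE` for bulk MinE and 0 for membrane species — and
composed with the reaction part by Strang splitting.  Reactions are
advanced with classical RK4 under *adaptive substepping*: the substep
resolves the fastest local kinetic rate (dominated by
`k_dEr × max(m_d)` once spiky pulses saturate), so the scheme stays stable
as patterns sharpen without a globally tiny time step.  The `q = 0`
multiplier is exactly 1 and the reaction right-hand side sums to zero
pointwise for both proteins, so the totals `n_D`, `n_E` are conserved to
round-off (drift is logged on every trajectory and a run is flagged
invalid above 1e-4 relative).

**Negative undershoot.**  The saturated pulses of this model are steep
(membrane MinD spikes of order 1000/µm² whose width approaches the grid
spacing), and their spectral representation rings at a few permille of
the pulse amplitude.  A 36th-order exponential spectral filter suppresses
grid-scale content without touching resolved scales or the mass mode.
Values are never clipped (clipping would break exact conservation);
instead the integrator aborts if any field falls below
`-1e-2 (n_D + n_E)`, a bound far above round-off but far below any
physically meaningful density.  In long saturated runs the observed
minima stay near -1/µm² and the grid-refinement check (N = 256 vs 512)
confirms the measured wavelengths and speeds are insensitive to the
residual ringing.

**Resolution.**  Production runs use `L = 200 µm`, `N = 256`
(`dx ≈ 0.8 µm`) and `dt = 0.02 s`.  The grid-refinement test doubles `N`
and requires the measured wavelength and speed of a developed wave to
change by less than a few percent.  `N = 128` is *not* sufficient at high
E:D, where pulses are steep; the test suite therefore runs its refinement
check between `N = 256` and `N = 512`.

**Steady states.**  The homogeneous steady state reduces to a single
scalar root equation in `m_d` (all other fields follow in closed form);
when several roots exist the one reached by relaxing the well-mixed rate
equations from the uniform partition (all MinD as `c_DT`, all MinE as
`c_Er`) is selected, and the result is verified by a flux-residual check.

## Direction measurement and sweep protocols

`pattern_velocity()` measures the drift of the dominant spatial Fourier
mode of `m_d`: the mode's complex phase is unwrapped over the measurement
window and regressed on time; the slope divided by the wavenumber is the
signed velocity.  A pattern is "present" when the spatial standard
deviation of `m_d` exceeds 1% of its mean; `|velocity|` below the
resolution bound `dx / T_measure` is classified "stationary".

`adiabatic_sweep()` walks an ordered path of one control (`v_f` or E:D),
continuing each stage from the final state of the previous one (relax,
then measure; the measured period is logged so the window adequacy is
auditable).  An E:D step changes a conserved quantity, so the carried
state is adjusted: added MinE goes into the bulk pools proportionally;
removed MinE drains the bulk first and then strips the membrane complex,
leaving its MinD behind as `m_d` — the numerical analogue of exchanging
the solution above the bilayer.

`classify_point()` implements the three-seed multistability protocol:
noisy homogeneous (multiplicative uniform noise of relative amplitude
1e-3, seeded), a downstream-seeded and an upstream-seeded traveling wave
(finite-amplitude eigenmode ansatz at the chosen wavelength).  A point is
multistable when different seeds retain opposite nonzero directions.

## Crest velocimetry

The image-analysis chain quantifies wave direction exactly as one would
for microscopy stacks (single channel, known pixel size, 15 s frame
interval):

1. **Bleach correction** divides out a mono-exponential trend fitted to
   the per-frame median intensities.  A fitted trend — rather than
   frame-by-frame normalization — is used deliberately: the spatial median
   of a finite field of view oscillates with the wave itself, and dividing
   frame-by-frame imprints that oscillation on every pixel (this shows up
   as a spurious bimodal velocity histogram on ground-truth stacks).
2. **Phase images**: the dominant temporal frequency is found on the mean
   power spectrum and refined by a matched-filter search; the per-pixel
   phase is then extracted by weighted local harmonic regression
   (`a + b cos + c sin` on a sliding ~1.5-period window).  The regression
   jointly removes the local offset and the conjugate-frequency leakage
   that biases Hilbert-transform phase estimates when the stack does not
   contain an integer number of oscillation cycles.  Non-oscillatory
   pixels (fitted oscillation power below 20% of the pixel variance) are
   masked, never fabricated.  Frames within half a window of the stack
   ends are excluded from displacement measurements.
3. **Crests** are the zero-phase level set, located to sub-pixel accuracy
   as wrap-aware zero crossings along rows and columns.
4. **Displacements**: for each crest point the zero-phase crossing of the
   *next* frame is searched along the local phase-gradient direction
   within a quarter of the local wavelength; among several crossings the
   one closest to zero displacement is taken.  Velocities are reported in
   nm/s.
5. **Filtering** removes records with speed below 10% of the median
   speed, which eliminates static bright objects (protein aggregates).
6. **Summaries**: 2D velocity histogram (25 nm/s bins), normalized
   angular histogram in 15° segments (half-open `(a-15, a]`, 0° =
   downstream, counter-clockwise), downstream fraction (angles in
   `(-30, 30]`), upstream fraction (`(150, 210]`), and the peak speed ±
   FWHM/2 from the 10 nm/s speed histogram.  Summaries from fewer than 10
   records are flagged low-confidence.

On synthetic planar waves with noise, bleaching and aggregates the chain
recovers speeds of 100–600 nm/s to within about 1% in the mean and well
within 5% at the histogram peak, and orientations to within a couple of
degrees — the ground-truth validation that stands in for matching any
particular published implementation step-for-step.

## What the synthetic generator does and does not emulate

`planar_wave_stack()`, `spiral_stack()` and `static_stack()` generate
stacks at Min-like scales: default 15 s interval, 2 µm pixels, wavelengths
of tens of µm, speeds 100–600 nm/s, additive Gaussian noise with optional
Poisson shot noise, mono-exponential bleaching, and static Gaussian
aggregates with a known mask.  They are pure functions of (spec, seed).
They do *not* model optics (no PSF beyond the smoothness of the patterns),
camera gain, stage drift, stitching seams between fields of view, or the
gradual pattern reorganization real Min samples show; passing the
recovery tests therefore demonstrates correctness of the estimator on
ideal-but-noisy planar and spiral kinematics, not robustness to every
microscopy artifact.

## Problem sizes used by the shipped analyses

The analysis scripts and the acceptance checks run at desk scale, chosen
as the smallest sizes at which the qualitative phenomena are stable under
grid refinement: domain 200 µm at `N = 256`, sweeps of ~12 E:D values
with 3000 s relaxation and 1500 s measurement per stage, 3×3 variant
grids, and image stacks of 96×96×48 frames.  The phase diagram and the
hysteresis loop in `analysis/` are coarse by design; their grids are
configurable.

## Known limitations

* The integrator is 1D in the lateral direction.  Two-dimensional
  wave-front alignment is represented by extruding 1D profiles into planar
  fronts (`trajectory_to_stack()`), which is the post-alignment geometry;
  transverse destabilization of fronts is out of scope.
* The reduced switch model's linearization is global (the slaved pools
  couple to spatial means), so `jacobian_at_q()` deliberately rejects it;
  its behavior is assessed by simulation.
* Near the flow-driven threshold growth rates are of order 1e-4 1/s, so
  patterns take hours of simulated time to develop from small noise; the
  shipped analyses therefore seed finite-amplitude waves where the
  question is direction selection rather than spontaneous emergence.
* The upstream-onset ratio depends on the kinetic parameter set; the
  registry freezes one calibrated set, and different transcriptions of
  the kinetics belong in new named sets.
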