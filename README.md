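# minflow

Self-organized MinD/MinE protein patterns on a membrane respond to a
hydrodynamic flow of the bulk solution above it.  Because the flow advects
proteins in solution but not on the membrane (*differential flow*), it
steers the surface pattern only indirectly, through attachment and
detachment — and the direction the waves pick depends on the reaction
kinetics: at low MinE:MinD density ratios (E:D) the waves travel
*downstream*, at high ratios *upstream*, with a multistable band in
between.  `minflow` is an R package plus analysis workflow for studying
this system end to end: it simulates the mass-conserving
reaction–diffusion–advection dynamics of the MinE-switch model (with
skeleton and reduced-switch variants), computes dispersion relations and
flow-driven instability thresholds, maps propagation direction over the
(E:D, flow) plane including hysteresis, and quantifies wave direction in
fluorescence-style image stacks by crest velocimetry with a ground-truth
synthetic stack generator.

## Model in brief

Six fields on a laterally periodic domain (bulk integrated out): membrane
MinD `m_d`, membrane MinDE `m_de`, bulk MinD-ADP `c_DD`, MinD-ATP `c_DT`,
reactive MinE `c_Er`, latent MinE `c_Ei`.  Membrane species diffuse
(`D_m`); bulk species diffuse (`D_c`) and are advected at `v_f`.
Reactions (mass action): attachment `(k_D + k_dD m_d) c_DT`, MinE
recruitment `(k_dEr c_Er + k_dEi c_Ei) m_d`, detachment `k_de m_de`,
nucleotide exchange `lambda c_DD`, MinE switching `mu c_Er`
(reactive → latent).  Total MinD and MinE densities are conserved; the
E:D ratio is the main control parameter.  Perturbations go as
`exp(iqx + sigma t)`; phase velocity is `-Im sigma / q`; "downstream"
means the same sign as `v_f`.

## Worked example

Simulate a high-E:D point under flow, measure the pattern drift, render
the run as an image stack and re-analyze it with the crest velocimetry:

```r
library(minflow)

p  <- min_params_at_ratio(1, v_f = 2)       # E:D = 1, flow 2 um/s
g  <- min_grid(200, 256)                    # 200 um, periodic
tr <- simulate_min(noisy_homogeneous_state(p, g, seed = 5), p, g,
                   min_schedule(dt = 0.02, t_end = 900, save_every = 750))
tr <- simulate_min(tr$states[[length(tr$states)]], p, g,
                   min_schedule(0.02, 720, 750))
pattern_velocity(tr, window = 1)$velocity
#> [1] -0.1495242

st  <- trajectory_to_stack(tr, H = 48)      # extrude to planar 2D fronts
res <- analyze_crests(st)
res$summary
#> Crest direction summary (n = 11410)
#>   downstream fraction: 0.000   upstream fraction: 0.981
#>   peak speed: 145 +/- 15 nm/s (peak +/- FWHM/2)
```

The Fourier-mode drift is negative (against the flow) and the
image-analysis chain sees the same thing: ~98% of crest displacement
vectors point upstream at ~150 nm/s.  At E:D = 0.05 the same code yields
downstream propagation, and `instability_bands()` /
`flow_driven_threshold()` show that point is linearly stable without flow
— pattern formation there is flow-driven.

The numbered scripts under `analysis/` run the full workflow (dispersion
maps, the upstream-onset sweep, the phase diagram and hysteresis loop,
variant dichotomy and MinE-advection ablation, crest-velocimetry
validation) and write tables under `results/`.

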