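# stackpol

Quantifying how strand polarity modulates DNA base stacking, from two
directions at once.

A single base-stacking interaction across a nick in a duplex is worth
roughly −0.5 to −2.5 kcal/mol, and the stack X|Y (X on the 5′ side, Y on
the 3′) is not energetically the same as Y|X. `stackpol` is an R package
for the two computational pipelines behind that measurement:

* **Force-clamp kinetics.** Microspheres tethered by nicked-duplex DNA
  constructs dissociate under constant centrifugal force
  (F = mω²r; the calibrated working point — 6.9×10⁻¹² g effective bead
  mass, 0.119 m rotor radius, 1291 rpm — applies ~15 pN). Bead movies are
  tracked (matched-filter detection, screening of clusters/debris,
  intensity-variance event calling), per-tether dissociation times are
  binned into survival curves, fit with y(t) = y₀ + A·e^(−kt), and the
  stacking free energy is extracted from the off-rate ratio of a stacked
  construct and its no-stack control:

  ΔG_base-stack = RT·ln(k_off,stack / k_off,ctrl),

  with replicate-based uncertainty propagated to ΔG.

* **Nicked-interface geometry.** Multi-frame coordinates of the two
  nucleotides flanking the nick are projected onto a two-component
  coordinate system: ρ, the distance between six-membered-ring centers
  (stable stacking sits near 0.5 nm), and θ, the xy-plane angle between
  the bases' Watson–Crick-face bisectors on [0°, 180°]. The package
  summarizes these series as temperature ladders, polar densities,
  stacked-state occupancies, and Gaussian-mixture bimodality reports with
  centroid frames.

Seeded synthetic generators (exponential dissociation with censoring and a
non-dissociating baseline, bead image stacks with deliberate clusters and
debris, two-state stacked/unstacked interface trajectories on an idealized
B-form step) provide ground truth for every stage, so the whole chain is
testable without instrument data.

## Worked example

Recover a known stacking energy through the full kinetics pipeline:
simulate stacked and control datasets whose true off-rate ratio encodes
−2.1 kcal/mol (500 tethers × 3 replicates each, k_ctrl = 0.01 s⁻¹,
observation window long enough that >95 % dissociate), fit survival curves
with 50 bins, and extract ΔG:

```r
library(stackpol)

res <- recover_stacking_energy(-2.1, k_ctrl = 0.01, n_per_rep = 500,
                               n_rep = 3, seed = 1)
res$energy
#> delta_G(base-stack) = -2.117 +/- 0.036 kcal/mol (T = 298.15 K)

centrifugal_force(rpm = 1291, r = 0.119, m_eff = 6.9e-12)
#> [1] 15.00741
```

The recovered −2.117 ± 0.036 kcal/mol agrees with the generating value
within one propagated standard deviation; the force at the calibrated
working point is ~15 pN.

On the geometry side, generate a 2000-frame trajectory of a bimodal
stacked interface, project it, and ask whether the stacked basin is one
state or two:

```r
tr <- generate_interface_trajectory(
  stack_sim_params(-2.3, n_frames = 2000, bimodal = TRUE, seed = 1))
series <- project_trajectory(tr, align = FALSE)
cluster_interface_states(series, seed = 1)
#> cluster_report: 2 component(s) over 1780 frames
#>   1: rho 0.480 nm, theta 35.9 deg, weight 0.41, centroid frame 309
#>   2: rho 0.360 nm, theta 94.2 deg, weight 0.59, centroid frame 390
```

The two substates (the ideal stacked geometry near ρ ≈ 0.48 nm and the
offset substate at smaller ρ, rotated θ) are recovered with their weights
and representative (centroid) frames.

A thin command-line interface wraps the same functions
(`inst/cli/stackpol.R`; subcommands `simulate-kinetics`, `simulate-traj`,
`simulate-movie`, `track`, `fit`, `project`, `ensemble`).

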