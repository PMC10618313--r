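# dsbsim

Coarse-grained, implicit-solvent simulation of dense multichain protein
systems with **dynamic structure-based (DSB) contacts**, plus the
diagnostics needed to answer a deceptively simple question: *what
residue density should an implicit-solvent simulation use to represent
a concentrated protein system?*

With no explicit water, the only density an implicit-solvent model
controls is the residue density ρ (beads per nm³). For dilute systems ρ
tracks the protein concentration, but as ρ grows the system crosses
from a solution into a network and then a dense phase where solvent
would survive only inside cavities. `dsbsim` implements:

* **The simulator** — one bead per residue, Langevin dynamics
  (m r̈ = F − γṙ + Γ, γ = 2m/τ, noise variance σ² = 2γk_BT, dt = τ/200),
  harmonic bonds (k = 50 ε/Å², r_b = 3.8 Å), tabulated angle/dihedral
  stiffness, excluded volume (LJ cut at 5 Å), directional bb/bs/ss
  contact wells (5 Å / 6.8 Å / pair matrix, depth ε) switched on and
  off quasi-adiabatically over 10 τ with rupture at (3/2)·r₀/2^(1/6),
  coordination-number limits, dynamic disulfides (depth 4ε, one per
  cysteine), Debye–Hückel electrostatics with distance-dependent
  permittivity, Go contact maps, and a slab geometry (periodic X/Y,
  repulsive/adhesive walls in Z).
* **The protocol** — self-avoiding-walk initialisation below 0.1 nm⁻³,
  equilibration, quasi-static squeezing at 0.02 Å/τ to the target ρ,
  wall adhesion (4ε wells), and oscillatory shear/normal-strain box
  deformation with period 40,000 τ.
* **The diagnostics** — grid-of-balls cavity detection (probe radius
  1.9 Å, spacing 1 Å), pairwise entanglement counting by
  primitive-path shrinking with pinned termini, density profiles,
  slab-corrected radial distribution functions, chain shape metrics
  (R_ee, R_g, asphericity W), and the four-regime density classifier
  (infinitely dilute / dilute ρ<1 / intermediate 1–3 / dense >3 nm⁻³).

## Worked example

Ten gluten-like chains (Q-rich, uncharged, a few cysteines), run
through the full protocol at a compressed desk-scale schedule, then
interrogated for cavities and entanglements:

```r
library(dsbsim)

fx     <- generate_fixture("gluten_like_system", M = 10, L = 50, seed = 1)
params <- dsb_params(contact_stride = 4L)
sched  <- dsb_schedule(rho_target = 3.5, scale = 5e-4)  # desk scale
run    <- run_protocol(fx$topology, sched, params, seed = 11)

residue_density(run$state)
#> [1] 3.5
spaceball(run$state)
#> cavities: 22 found, V_C_max = 0.011 nm^3, total 0.054 nm^3
#>   (ball 1.90 A, residue 3.80 A, spacing 1.00 A, 1 rotation(s))
entanglements(run$state, fx$topology)
#> entanglements: 0 pair(s), 0 kink(s)
classify_regime(residue_density(run$state))
#> [1] dense
#> Levels: infinitely-dilute dilute intermediate dense
```

`box_side_for_density(4271, 3.5)` reproduces the reference arithmetic:
a 4271-residue system at ρ = 3.5 nm⁻³ needs a ≈ 10.7 nm cube. A
`density_sweep()` over ρ ∈ {0.5 … 4} with repeated seeds returns
per-density means and error bars of every diagnostic; at desk scale it
already shows the biggest-cavity volume rising to an interior maximum
and falling again, the cavity count rising in the dense regime, and
chains compacting relative to the free-chain (ρ = 0) reference (the
methods vignette discusses which cluster-scale trends desk-scale runs
cannot show).

The methods vignette
(`vignettes/dsb-model-and-diagnostics.Rmd`) documents the model, every
tunable parameter with units and defaults, the stand-in tables used
where no published values exist, and what the synthetic fixtures do and
do not validate.

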