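---
title: "The DSB coarse-grained model and its density diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DSB coarse-grained model and its density diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbsim)
```

## The problem

Implicit-solvent coarse-grained simulations of dense protein systems --
condensates, gels, gluten-like networks -- have no water, so the one
number they control, the residue density $\rho$ (residues per nm$^3$ of
box), is not the experimental protein concentration. At low $\rho$ the
two are proportional; at high $\rho$ the system stops being a solution
and single solvent molecules would sit in cavities between chains.
`dsbsim` implements both the simulation engine for such systems and the
diagnostics that locate the crossover: cavity statistics, pairwise
entanglements, density profiles, radial distribution functions, chain
shape metrics and a four-regime classifier.

## The model

Each residue is one bead of mass $m$ (the average amino-acid mass)
moving under the Langevin equation
$m\ddot{\vec r} = \vec F - \gamma \dot{\vec r} + \vec\Gamma$ with
$\gamma = 2m/\tau$ and white noise of variance $\sigma^2 = 2\gamma k_BT$
-- the noise is the only thermostat, and this $\gamma$ puts the dynamics
in the overdamped regime. Internal units are Angstrom, the energy unit
$\epsilon$, the time unit $\tau \approx 1$ ns, and $m$; one $\tau$ is
200 integration steps, so $dt = \tau/200$. Room temperature corresponds
to $k_BT = 0.3\text{--}0.38\,\epsilon$; the default is `kBT = 0.35`.

The force field:

* **Bonds**: harmonic, $V = k (r - r_b)^2$ with $k = 50\,\epsilon/\text{A}^2$
  and $r_b = 3.8$ A. The spring-constant unit implies no $\tfrac12$
  factor; the convention is stated on `bond_energy()`.
* **Chain stiffness**: tabulated bond-angle and dihedral potentials,
  evaluated by cubic splines (natural ends for angles, periodic for
  dihedrals) with analytic derivatives. Random-coil-library tables are
  not distributed with this package; it ships smooth synthetic
  stand-ins (a soft quadratic angle well centred at 1.9 rad; a gentle
  two-term cosine dihedral) and reads any two-column grid file via
  `read_potential_table()`.
* **Excluded volume**: Lennard-Jones repulsion cut and shifted at
  $r_0 = 5$ A, $V(r \le r_0) = \epsilon((r_0/r)^{12} - 2 (r_0/r)^6 + 1)$
  and exactly zero beyond; pairs two apart along a chain ($j = i+2$)
  interact only through this term.
* **Dynamic contacts**: backbone--backbone (5 A), backbone--side chain
  (6.8 A) and side chain--side chain (per-pair matrix) wells, each a
  full 6--12 LJ of depth $\epsilon$. Since there is one bead per
  residue, directionality comes from per-residue local frames built
  from beads $(i-1, i, i+1)$: the binormal (cross product of adjacent
  bond vectors) marks the backbone hydrogen-bond direction and the
  negative normal (bisector construction) the side-chain direction. A
  contact can switch on only when the kind-specific direction cosines
  pass their thresholds, the pair is within capture range, and both
  residues have spare coordination capacity $n_c$ in the relevant slot.
  Contacts switch on quasi-adiabatically -- a linear activation ramp
  over 10 $\tau$ -- and off the same way once the distance exceeds
  $\tfrac32 r_0 / 2^{1/6}$.
* **Disulfides**: cysteine pairs use the ss mechanism with depth
  $4\epsilon$; a cysteine holds at most one such bond at a time, and
  bonds form and rupture dynamically.
* **Go contacts**: optional always-attractive intra-chain pairs from a
  contact map (for partially structured regions), full LJ wells at the
  mapped distance, exempt from the geometric criteria and coordination
  limits.
* **Electrostatics**: Debye-Hueckel with a relative permittivity that
  grows linearly with distance, $\epsilon_r(r) = 4\,\text{A}^{-1} r$,
  which turns the Coulomb factor into $1/r^2$. Only D/E ($-1$) and K/R
  ($+1$) carry charge by default; gluten-like systems are essentially
  uncharged, so this term rarely matters here.
* **Walls and slab geometry**: X and Y are periodic (the cell may shear
  into a parallelepiped); Z has solid walls. The wall is repulsive,
  $(\epsilon/9)(\sigma/z)^9$ with $\sigma = 0.5$ nm -- a solid wall
  must repel, so the attractive sign of the compact printed form is
  available only behind the `wall_printed_sign` switch. When adhesion
  is enabled the walls additionally attract residues through
  quasi-adiabatically switched wells of depth $4\epsilon$.

### Integration

The integrator is BAOAB Langevin splitting. Its Ornstein-Uhlenbeck
sub-step damps velocities by exactly $e^{-\gamma\,dt/m}$, so the free
damped particle decays at exactly $\gamma/m$ and the free-particle
velocity variance is exactly $k_BT/m$ -- both are regression-tested.
With the thermostat disabled the scheme reduces to velocity Verlet. All
randomness comes from one seeded 64-bit generator inside the engine;
identical seeds give bitwise-identical trajectories.

### Contact bookkeeping choices

Where the contact machinery needed constants that have no published
value, the package takes configurable defaults and documents them as
implementation choices: direction-cosine thresholds of 0.5 for all
three criteria, a capture range of $1.1\,r_0$, per-type coordination
limits (backbone 2, except proline 1; side chains 2, or 3 for the bulky
hydrophobics F/W/Y/L/I/M/V), and a side-chain distance matrix built
from per-residue size parameters (4.5--6.8 A) averaged pairwise. During
a switching ramp the pair energy is
$\lambda V_{\text{contact}} + (1-\lambda) V_{\text{excl}}$, continuous
at both birth and death. Off-ramping contacts keep their coordination
slot and keep ramping off even if the pair re-enters range; this
hysteresis prevents flip-flopping at the threshold. When more
candidates than free slots exist, the closest pair wins, then
lexicographic order -- deterministic and physically sensible. The
optional solvation rule (neighbours within 0.75 nm counted against a
threshold $n_t$) is off by default, matching the base model; both signs
of the $n_c$ adjustment are supported because the direction is a
modelling choice.

## The protocol

`run_protocol()` drives the published schedule: chains grown as
self-avoiding random walks at a dilute density ($\rho_{start} < 0.1$
nm$^{-3}$, placed so no inter-chain pair is within contact capture),
equilibration, quasi-static squeezing of every box dimension at 0.02
A/$\tau$ until the target $\rho$ (fractional coordinates rescaled in
the periodic plane, walls moved in Z), a second equilibration, wall
adhesion switched on, a third equilibration, then sinusoidal box
deformation with period 40,000 $\tau$, alternating shear and
volume-preserving normal strain. The full spans are 200,000 $\tau$ per
equilibration. A single `scale` factor in `dsb_schedule()` compresses
the whole schedule coherently -- spans and period multiplied by
`scale`, squeeze speed divided by it -- so desk-scale studies keep the
protocol's shape. The oscillation amplitude is not a published
quantity; the default is 10% strain.

## Diagnostics

* **Cavities** (`spaceball()`): a grid of probe balls (radius 1.9 A --
  half the 3.8 A coarse-grained length unit, since a water-sized probe
  would be meaningless at this resolution -- spacing 1 A, one rotation)
  covers the box; balls overlapping a residue (occlusion radius 3.8 A
  by default) are occupied; empty balls reachable from outside the slab
  through the periodic images or the open Z faces are flood-filled away
  (6-neighbour adjacency; 26 available); what remains clusters into
  cavities with volume = ball count x cell volume. Extra rotations (about
  Z) intersect the interior sets, so they can only remove cavity balls.
  The detector is regression-tested against an independent voxel
  flood-fill oracle (exact agreement) and an analytic hollow-shell
  volume (within grid discretisation error).
* **Entanglements** (`entanglements()`): every chain is shrunk toward
  the straight segment between its pinned termini by vertex-removal and
  vertex-straightening moves; a move is rejected if its swept triangle
  crosses any other chain (with in-plane periodic images). Both move
  types are non-increasing in contour length, so convergence (relative
  decrease below $10^{-6}$ per sweep) is guaranteed. Surviving interior
  vertices whose removal is blocked are kinks; the blocking chain
  (ties broken by closest approach) attributes the kink, and the number
  of unordered chain pairs with at least one kink is the entanglement
  count.
* **Profiles, g(r), shapes**: single-frame density histograms (frame
  averaging washes the cavities out; bin width default 2 A), a
  minimum-image radial distribution function whose ideal-gas
  normalisation corrects for the finite slab height by averaging the
  in-slab shell fraction over the actual residue heights, and per-chain
  end-to-end distance, gyration radius and asphericity. The asphericity
  W is the relative shape anisotropy
  $\kappa^2 = ((\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
  (\lambda_3-\lambda_1)^2) / (2\,\mathrm{tr}^2)$ of the gyration
  tensor -- 0 for an isotropic cloud, 1 for a rod -- chosen because the
  quantity is bounded, dimensionless and standard; no published formula
  was available to match.
* **Regimes** (`classify_regime()`): infinitely dilute ($\rho = 0$),
  dilute ($\rho < 1$), intermediate ($1 \le \rho \le 3$), dense
  ($\rho > 3$ nm$^{-3}$). The thresholds are arguments because they are
  system-dependent; the defaults describe long, sticky, essentially
  uncharged chains.

## What the synthetic systems do and do not show

`generate_fixture()` provides the test systems. The gluten-like
generator emits uncharged Q/P/G-rich chains (glutamine at least 30%,
with a small cysteine fraction) -- the composition statistics of the
real system, but not its true sequences, its 4271-residue size, or its
gliadin/glutenin length distribution. The geometric fixtures (rods,
hollow bead shells, interlocked open hooks, ideal gases, slab-confined
chains) have closed-form answers and exist purely to pin the
diagnostics down. Passing tests on these fixtures validates the
machinery -- gradients, switching clocks, detectors -- not the
biological realism of any particular run; conclusions about a real
protein system still require that system's sequences, contact maps and
cluster-scale spans.

## Problem sizes used by the tests

The packaged checks run the complete protocol at desk scale: 8 chains
of 40 residues, schedule scale $10^{-3}$ (200 $\tau$ equilibrations,
40 $\tau$ oscillation period, squeeze at 20 A/$\tau$), contact
maintenance every 4 steps, three random repeats per density over
$\rho \in \{0.5, 1, 2, 3, 3.5, 4\}$ plus single free chains for
$\rho = 0$. These sizes balance two pressures: short enough for a full
sweep to complete in minutes on one core, but with enough relaxation
after the squeeze for the density trends to emerge -- compressing the
schedule much further leaves the dense systems with unrelaxed voids
and the dilute ones without a connected network, washing the cavity
trends out. At the chosen scale the sweep shows the biggest-cavity
volume $V^C_{max}(\rho)$ rising to an interior maximum and falling
again, the cavity count rising in the dense regime (squeezing collapses
large cavities into many small ones), and mean chain size shrinking
from the free-chain reference toward high density.

One published trend does **not** reproduce at desk scale: the high
cavity count at low density, which falls as small cavities merge on the
way to $\rho \approx 2$ nm$^{-3}$. That branch requires a sparse
percolating network of long chains enclosing many pockets, and forming
one at $\rho < 1$ nm$^{-3}$ is a diffusion-limited aggregation process
far beyond compressed desk-scale spans (chain centres move by a couple
of Angstrom per 200 $\tau$). Desk-scale sweeps therefore show a cavity
count that increases monotonically with density; the interior minimum
should only be expected from cluster-scale runs. Quantities read off
cluster-scale runs (absolute cavity volumes, entanglement counts of
hundred-residue chains) are likewise not reproduced at this scale.

## Numerical choices and degenerate inputs

Minimum images in the sheared cell go through fractional coordinates of
the periodic plane with a 9-image check when the cell is tilted; Z is
never wrapped. Overlapping residues are an error (the potentials
diverge), as are residues beyond the walls, degenerate boxes,
non-covering potential tables and oscillation amplitudes that would
degenerate the cell. Collinear bead triples have no local frame; such
residues are flagged and simply skip directional contacts that step.
Chain termini likewise have no frame. Neighbour bookkeeping uses a
Verlet list with a 2 A skin rebuilt on a fixed short interval;
acceptance of a contact is independent of the list construction.
Spaceball requires a rectangular cell, so cavity reports are taken at
the closed points of the deformation cycle where the cell returns to
rectangular; the grid anchors its layers to the lower wall so reports
are comparable across probe radii.

## Known limitations

The angle/dihedral tables, side-chain distance matrix, coordination
limits and direction thresholds are stand-ins for unpublished
parameterisations; absolute energies and contact statistics will differ
from runs using the original tables, though every interface accepts
replacements. The Debye-Hueckel prefactor adopts
$\epsilon \approx 1.5$ kcal/mol; for strongly charged systems both the
prefactor and the Debye length should be set explicitly. Entanglement
analysis treats each chain as a phantom with respect to itself (no
self-knot detection). The primitive-path moves are a local relaxation;
like the algorithm they follow, they find a locally tight path, which
for pathological initial conformations may overcount kinks. Cavity
rotations break exact X/Y periodicity and are therefore best left at
the default single rotation.
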