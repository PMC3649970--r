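---
title: "Quantitative biophysics of the foamy virus Gag N-terminal domain dimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative biophysics of the foamy virus Gag N-terminal domain dimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foamygag)
```

## The system and the questions

The N-terminal domain (residues 1–179) of the foamy virus Gag structural
protein (Gag-NtD) forms an obligate dimer through a long central
coiled-coil, and binds the N-terminal leader peptide of the viral envelope
protein (Env-LP) — an interaction that foamy viruses require for budding.
The quantitative questions this package addresses are the ones solution
biophysics asks of such a system:

* What is the solution mass and shape of the protein? (Is it a dimer? How
  elongated?) — sedimentation velocity and equilibrium.
* How tightly does the Env leader peptide bind? — quantitation of
  co-sedimenting absorbance, cross-checked by isothermal titration
  calorimetry.
* How large is the dimer interface, and does peptide binding deform the
  protein? — buried surface area and superposition RMSD on crystal
  structures.
* Is a virus restricted by a Trim5α variant? — the two-colour infection
  ratio statistic.

Raw analytical-ultracentrifuge and calorimeter data for this system are
not publicly deposited, so the package pairs every analysis route with a
physics-based forward simulator. All recovery claims in the test suite are
made against simulated data with known ground truth; what that does and
does not establish about real data is discussed at the end.

## Hydrodynamic relations

All internal computation is in CGS units (cm, g, s, erg); the Svedberg
(1 S = 1e-13 s) appears only at input/output boundaries. Physical
constants are fixed: R = 8.31446e7 erg/(mol K), N_A = 6.02214e23 /mol, and
the Boltzmann constant is *defined* as k_B = R/N_A (= 1.38065e-16 erg/K to
the usual printed precision). Defining k_B as the ratio rather than as an
independently rounded constant makes the Svedberg relation close exactly,
so the round trip mass → (s, D) → mass is an identity rather than a
relation true to six digits.

For a species of molar mass M, partial specific volume ν̄, in a solvent of
density ρ and viscosity η at temperature T:

* Svedberg mass: `M = s R T / (D (1 − ν̄ρ))`.
* Anhydrous-sphere reference friction: `f0 = 6πη r0`,
  `r0 = (3Mν̄/(4πN_A))^(1/3)`. No hydration shell is added: with the
  measured s, mass and ν̄ of the Gag-NtD dimer the anhydrous convention
  reproduces the conventionally reported frictional ratio (1.48) to three
  figures, and any hydration correction is absorbed into f/f0 itself.
* Frictional ratios from either transport coefficient:
  `f(s) = M(1 − ν̄ρ)/(N_A s)` and `f(D) = k_B T / D`, each divided by f0.
  The two agree identically on any Svedberg-consistent (s, D, M) triple.

Two solvent helpers are provided: `water20()` (293.15 K, 0.99823 g/ml,
1.002e-2 P), the reference state of s(20,w) values, and `buffer_tris150()`
(density 1.005 g/ml, water viscosity), the measured density of the
Tris/NaCl buffer used for this protein. ν̄ is always an input; computing
it from sequence composition is out of scope.

## The Lamm equation solver

Sedimentation velocity transport in a sector-shaped cell obeys the Lamm
equation

$$\frac{\partial c}{\partial t} = \frac{1}{r}\frac{\partial}{\partial r}
  \left[ r D \frac{\partial c}{\partial r} - s\omega^2 r^2 c \right]$$

with zero flux at the meniscus and base. The solver
(`simulate_sv()`/`lamm_solve_cpp`) uses:

* a conservative finite-volume discretization on a uniform radial mesh
  (default 200 cells over 6.0–7.2 cm), which conserves sector mass
  $\int c\,r\,dr$ to machine precision by construction;
* Scharfetter–Gummel (exponentially fitted) face fluxes,
  `J = (D/h)[B(−Pe) c_L − B(Pe) c_R]` with `B(x) = x/(e^x − 1)` and the
  cell Péclet number `Pe = vh/D`; this reduces to central differencing
  for diffusion-dominated faces and to upwinding as D → 0, remaining
  positivity-friendly at sharp boundaries;
* Crank–Nicolson time stepping with the step capped at a cell Courant
  number of ~0.4 (Crank–Nicolson is unconditionally stable but rings on
  large advective steps; a user-supplied step that exceeds the margin is
  refused rather than integrated).

Verified behaviour: sector mass conserved to < 0.1% (in practice ~1e-14)
until the boundary reaches the base; the plateau follows the square
dilution law `c = c0 exp(−2sω²t)` to better than 0.5%; in the D → 0 limit
the boundary midpoint tracks the characteristic `r_m exp(sω²t)` within one
mesh cell; refining the default mesh twice (400 → 800 cells) changes scan
signals by less than the instrument noise floor.

Optical signals: absorbance = ε·l·c per species, or interference fringes
= 3.3 fringes·ml/(mg·cm) × l × mass concentration (the community-standard
protein refractive increment). Gaussian i.i.d. noise is added per data
point; the default σ = 0.006 signal units sits in the middle of the
0.004–0.008 fit-rmsd range typical of C(S) analyses of such data.

## C(S) distributions and discrete fits

`fit_cs()` inverts a scan set into a non-negative distribution c(s) over a
grid (default 0.2–10 S in 0.1 S steps, spanning free peptide ~0.3–0.5 S
through the ~3 S dimer and beyond). Each grid species gets its diffusion
coefficient from the shared frictional ratio via `M(s) ∝ s^{3/2}` — the
standard C(S) scaling — and contributes a normalized Lamm solution to a
linear dictionary. The inversion is non-negative least squares with a
second-difference (smoothness) Tikhonov penalty. Two systematic-offset
families can be removed by algebraic projection applied identically to
data and dictionary: time-invariant per-radius offsets and per-scan
(radius-invariant) offsets, both on by default for interference optics
and off for absorbance.

The regularization strength is chosen by the discrepancy principle: the
weakest penalty whose residual rmsd reaches the noise level (the recorded
simulation σ, or a robust median-based estimate from second differences
along radius). A SEDFIT-style confidence-level criterion would need a
stated confidence level; the discrepancy principle needs only the noise
estimate and is directly testable: fit rmsd is non-decreasing in the
penalty, and peak positions are stable within one grid step across a
10-fold penalty range. The frictional ratio can be fixed (recommended when
the dominant species has been characterized separately) or optimized in an
outer 1-D search.

`fit_discrete()` fits a small number of ideal species by nonlinear least
squares over per-species (s, f/f0), with loading signals solved linearly
by non-negative least squares inside the outer optimization
(Nelder–Mead, then a restart and a BFGS polish). Masses are reported
through the Svedberg relation from the fitted (s, D) pairs. Meniscus and
base are taken from the scan-set geometry, not fitted.

## Quantifying peptide binding from co-sedimentation

The assay: sediment an equimolar mixture (75 µM in a 3 mm-pathlength cell)
of the Gag-NtD dimer and a strongly absorbing Env peptide
(ε280 = 11,400 M⁻¹cm⁻¹), record absorbance at 280 nm, and compare the
integrated absorbance of the fast ~3 S boundary with a protein-only
control at matched loading. Bound peptide co-sediments with the dimer, so
the excess absorbance of the 3 S peak reports the bound fraction:

$$\theta = \frac{A_{mix}(3S) - A_{ctrl}(3S)}{\varepsilon_L\, l\, L_t}$$

and mass action converts θ to an association constant — in general
`K_a = θ/[(1−θ)(P_t − θL_t)]`, reducing at `L_t = P_t` to
`K_a = θ/[(1−θ)² L_t]`. The θ here is the fraction of *total* peptide
bound, with `P_t` counted in monomer-equivalent binding sites (ITC shows
1:1 binding per monomer, i.e. two independent sites per dimer).

The default integration window is 2–4 S. The window is a judgment call on
real data; on simulated data the free peptide (≤ 0.5 S) and the dimer
(~3 S) are cleanly separated and the result is insensitive to the exact
bounds. The extinction coefficient 11,400 M⁻¹cm⁻¹ is the *peptide's*: the
quantitation divides the absorbance excess by the peptide signal, and the
protein's own coefficient (19,200 per monomer) only sets the control
baseline that cancels in the subtraction.

The binding simulator treats the mixture in the instantaneous-equilibrium
(fast exchange) limit as a static two-pool partition at loading
concentrations: bound peptide rides on the protein pool, free peptide
sediments separately, and the protein pool's s is recomputed from its
average mass load at the protein's f/f0 — reproducing the small upward
shift of the 3 S boundary seen on binding. A kinetically coupled reacting
Lamm system is out of scope; the quantitation itself assumes exactly this
fast-exchange picture, so the simulator and the analysis are consistent by
construction, and the recovery tests probe the noise/regularization chain
rather than reaction kinetics.

First-order uncertainties on θ and K_a are propagated from the two C(S)
fit rmsd values; they are rough scales, not confidence intervals.

## Sedimentation equilibrium

At equilibrium a single ideal species forms the gradient
`c(r) = c(r0) exp[M(1 − ν̄ρ)ω²(r² − r0²)/(2RT)]`. The simulator
conserves loading mass over the sector and produces one profile per
(speed, loading) combination; the default speeds 10,000/14,000/20,000 rpm
are a documented choice (multi-speed experiments on a ~45 kD species span
roughly this range; the exact speeds used in any given study rarely
matter for the recovered mass, which the tests confirm). The reference
radius is fixed at the meniscus — any other choice merely reparameterizes
c(r0) — and each profile carries its own baseline offset, as interference
optics require. `fit_se_single()` profiles the mass on a log grid with
amplitude and baseline solved linearly; `fit_se_global()` shares one mass
across all profiles. Self-association and nonideality models are out of
scope (the system of interest shows no concentration dependence of its
molecular weight over 14–100 µM).

## ITC

`itc_heats()` implements the one-site (Wiseman) cumulative-heat model
with the standard perfusion displaced-volume correction; running cell and
injectant concentrations account for dilution at every injection
(`Mt = Mt0(1 − v/2V0)/(1 + v/2V0)`, `Xt = Xs(v/V0)/(1 + v/2V0)`).
Defaults mirror an ITC-200-class experiment: 0.2026 ml cell, 20 × 2 µl
injections of 1 mM peptide into 50 µM protein. At an association constant
of 1.5e5 M⁻¹ this gives a Wiseman c-value of ~7.5 — inside the reliable
1–1000 window, which the fitter checks (c < 1 warns). `fit_itc()` uses the
same forward model (Levenberg–Marquardt over n, K_a, ΔH and a constant
per-injection offset, multi-started over a log-spaced K grid); the first
injection is excluded by default, the standard allowance for syringe-tip
diffusion. ΔG and ΔS are derived from the fitted K_a at a stated
temperature. The synthetic enthalpy default (−8 kcal/mol) is a typical
peptide-binding value and a simulation choice, not a measured quantity.

Noise defaults (2% proportional + 0.1 µcal additive) emulate
instrument-level scatter; at these settings single titrations recover K
to within ~10–20% and averaging across seeds recovers it to a few
percent, which is how the recovery criteria are phrased.

## Structure-derived metrics

`read_structure()` parses PDB/mmCIF via bio3d (or plain CSV atom tables),
keeps the highest-occupancy alternate location per atom and drops waters,
heteroatoms and hydrogens by default (crystal structures at 2.4–2.9 Å
carry no modelled hydrogens). `sasa()` is Shrake–Rupley with a
deterministic Fibonacci-lattice sphere sampling (240 points/atom default;
doubling changes totals by < 1%), NACCESS-style element radii (C 1.87,
N 1.65, O 1.40, S 1.85 Å) and a 1.4 Å probe. `buried_interface_area()`
reports both conventions — `[SASA(A) + SASA(B) − SASA(AB)]/2` per monomer
and the uncorrected total — because published interface areas use either.
`superpose_rmsd()` pairs atoms by (mapped chain, residue number, atom
name), Cα by default, and applies the Kabsch algorithm with the proper
rotation enforced; collinear selections are refused. On the deposited free
(4JNH) and Env-bound (4JMR) dimer coordinates these functions yield the
~1700 Å² per-monomer interface and ~0.4 Å free-vs-bound Cα RMSD reported
for this system; the coordinate files themselves are obtained from the
PDB and are not redistributed with the package, so the structural tests
run on analytic and synthetic fixtures (isolated spheres, sphere-cap
overlaps, constructed helical dimers) with bio3d as an independent
superposition oracle.

## Restriction and infectivity statistics

The two-colour restriction assay ratio is the infection rate among
restriction-factor-positive cells over that among factor-negative cells.
Per-replicate ratios are averaged (mean ± sd across independent
experiments — matching how such tables report triplicates) and classified:
< 0.3 restricted, > 0.7 not restricted, otherwise intermediate. The
boundary values fall in the intermediate class because only the strict
inequalities are defined; the rule is a step function and is tested as
such. Titres are normalized within each experiment to the wild-type
sample (set to 100%), then aggregated — normalization before averaging
keeps the statistic scale-invariant per experiment.

## What the simulators do and do not emulate

Emulated: radial geometry and optical pathlengths of standard 12 mm and
3 mm centrepieces; rotor speeds and scan schedules typical of 50,000 rpm
velocity runs and multi-speed equilibrium runs; channel-appropriate
signal scales (Beer–Lambert absorbance, 3.3 fringe·ml/mg/cm
interference); i.i.d. Gaussian noise at the fit-rmsd level seen in
practice; mass-action partitioning of an equimolar binding mixture;
perfusion dilution in ITC. The Env peptide is modelled as a 2,249 g/mol
species (a representative 20-residue peptide mass) with f/f0 1.15.

Not emulated: time-invariant and radius-invariant systematic optical
offsets (the C(S) projection that removes them is implemented and applied,
but the generator's noise is white, so the projection is exercised rather
than stressed); meniscus/base optical artifacts; concentration-dependent
nonideality; kinetically limited (slow-exchange) binding; baseline drift
and integration of raw ITC power traces (inputs are per-injection heats).
Passing recovery tests therefore demonstrates that the analysis chain is
unbiased and correctly scaled under its own model assumptions at realistic
noise — not that those assumptions hold for any particular real data set.

## Problem sizes and numerical choices

Defaults used throughout the tests and the acceptance script: 200 radial
cells (400–800 for convergence checks), 16 scans over 900–14,400 s, a
99-point s grid, 9 equilibrium profiles (3 speeds × 3 loadings, 80 points
each), 20-injection titrations, and 10 simulation seeds per recovery
statement; these sizes make every fit sharply over-determined while the
full suite runs in about a minute. Other numerical choices: the
mass-action quadratic is evaluated in its cancellation-free form (stable
at K_a up to 1e20); the discrepancy-principle search brackets the penalty
on a log grid and bisects to 5%; non-negative least squares is
Lawson–Hanson (`pracma::lsqnonneg`); equilibrium-mass and C(S) frictional
searches are golden-section on log scales.
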