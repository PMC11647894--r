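---
title: "Nonbonded energetics of cellulose crystals: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonbonded energetics of cellulose crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellenergy)
```

## The scientific question

Native cellulose (the I$\beta$ polymorph, all chains parallel) is less
stable than cellulose II, the antiparallel form obtained on
recrystallization. Whether this difference is driven by hydrogen bonds, by
the overall electrostatics, or by van der Waals (vdW) interactions is a
question one can attack with classical force fields: decompose the pairwise
nonbonded energy of a crystal into interchain and intrachain electrostatic
and Lennard-Jones parts, remove surface effects by comparing crystals of
increasing chain length, and score the hydrogen bonds separately from the
total electrostatics. `cellenergy` implements that analysis pipeline.

## Energy model

Two atoms $i, j$ at distance $r$ (in angstrom) contribute

$$E_{\mathrm{elec}} = \frac{Q_i Q_j}{r}, \qquad Q = 18.2223\,q,$$

with partial charges $q$ in units of the elementary charge (so the
prefactor is $18.2223^2 \approx 332.05$ kcal mol$^{-1}$ Å e$^{-2}$), and

$$E_{\mathrm{vdW}} = \varepsilon\left[\left(\frac{R_{\min}}{r}\right)^{12}
  - 2\left(\frac{R_{\min}}{r}\right)^{6}\right],
  \quad R_{\min} = \frac{R_i + R_j}{2},
  \quad \varepsilon = \sqrt{\varepsilon_i \varepsilon_j}.$$

The packaged parameter table carries the published partial charges of the
non-neutral cellulose atoms (hydroxyl groups C2–O2–H, C3–O3–H, C6–O6–H and
the five remaining charged atoms O4, C1, O5, C5, C4 around the ring oxygen);
all other atoms, in particular the aliphatic hydrogens, carry charge zero,
and the charges of one glucose unit sum exactly to zero. The vdW radii of
the hydroxyl oxygens (3.442 Å) and of the ring/glycosidic oxygens
(3.3674 Å) follow the same source; the remaining radii and all well depths
are standard GLYCAM06 atom-type values and are marked as externally sourced
in the table file. The `GLYCAM06_OSMOr14_TIP5P` variant multiplies well
depths by 0.94 (a recalibration against osmotic pressures of carbohydrate
solutions). Which atom types are exempt from that rescaling is not
enumerated in the sources, so the package default rescales *all*
carbohydrate types and exposes `exempt_types` for users who need a
different convention; charges never differ between variants.

Three modelling conventions are fixed package-wide and deliberately simple:

* **No cutoffs, no periodicity, vacuum permittivity.** The crystals are
  finite nanocrystals; residues are neutral, so interactions between
  glucose units are short-ranged (dipole–dipole, $\sim 1/d^3$) and full
  pairwise sums converge without Ewald machinery.
* **Terminal neutralization.** Chain-terminal residues carry cap atoms and
  would be charged; in a vacuum calculation that net charge would dominate
  the interchain electrostatics. `neutralize_termini()` spreads each
  terminal residue's excess equally over that residue's hydrogen atoms —
  the least-informative choice consistent with "adjust the hydrogens" —
  and is idempotent.
* **Intrachain exclusions.** 1–2 and 1–3 pairs are excluded, 1–4 and
  beyond enter at full strength (the GLYCAM convention of no 1–4 scaling).
  The exclusion set is configurable because conventions differ between
  force-field families. Only the *nonbonded* intrachain energy is
  computed; bond, angle and dihedral terms are out of scope, so totals are
  not comparable to published "total intrachain" numbers that include them.

## Crystal builder and its idealizations

`build_crystal()` places chains on the two-chain monoclinic lattices of the
polymorphs (I$\beta$: $a = 7.784$, $b = 8.201$, $c = 10.380$ Å,
$\gamma = 96.5^\circ$; II: $a = 8.10$, $b = 9.03$, $c = 10.31$ Å,
$\gamma = 117.1^\circ$), with the chain axis along $c$, two residues per
cell related by a two-fold screw, center chains shifted by a quarter cell
along the axis, and — for cellulose II — center chains antiparallel. The
lateral habit takes the `n_chains` lattice sites closest to the lattice
centroid, which gives the compact cross-section of a nanocrystal.

The atomic content is a *synthetic idealized* glucose geometry built from
standard bond lengths, not an experimental structure: a puckered ring, the
three hydroxyl branches, a glycosidic bridge consistent with the
per-residue rise, and an exocyclic arm placed so that consecutive residues
emulate the O2–H···O6 intrachain hydrogen bond. Each chain is rotated
about its own axis by a per-polymorph setting angle (I$\beta$:
30°/0° for origin/center chains; II: 30°/30°) chosen once, by a coarse
scan at build-design time, to keep the closest interchain contact above
1.5 Å. Consequences to keep in mind:

* chain counts, parities, directions, symmetry, connectivity and
  hydrogen-bond *topology* are faithful;
* absolute energies of built crystals are **not** comparable to values
  computed from energy-minimized experimental structures — that comparison
  requires minimized inputs (ingestible via `read_pdb()`), which is why
  every quantitative check in the test suite runs on fixtures pinned to
  tabulated geometries, on analytic two-body systems, or on toy crystals
  with brute-force ledgers, never on absolute energies of built crystals.

Chain parity of ingested structures is classified geometrically: by chain
direction when the crystal is antiparallel, otherwise by the phase of the
chain centroid along the axis modulo the per-residue rise (origin and
center chains are half a rise out of phase). Chains between the two phase
clusters are labelled `unclassified` rather than guessed, and only the
relative labelling is identifiable without lattice registration — a global
origin/center swap cannot be detected from coordinates alone.

## Hydrogen-bond detection and the three scoring modes

Donors are the hydroxyl groups O2–H, O3–H, O6–H; acceptors are O2, O3, O5,
O6. A bond is recorded when $d_{\mathrm{HO}} \le$ `max_d_HO` and the
O–H···O angle at the hydrogen is $\ge$ `min_angle`. The defaults (3.0 Å,
115°) were chosen so that the weak branch bond of cellulose I$\beta$
($d_{\mathrm{HO}}$ up to $\sim$3.0 Å, angle down to $\sim$118°) passes
while ordinary nonbonded contacts do not; both thresholds are arguments,
and reports echo the criteria used. A donor hydrogen may match several
acceptors; each pairing is its own record (branched bonds).

Scoring modes:

* `OH_O` — donor O and H against the acceptor O. With realistic charges
  this is typically *repulsive*: at $d_{\mathrm{OO}} = 2.72$,
  $d_{\mathrm{HO}} = 1.77$ Å the O6/O3 repulsion (+59.5 kcal/mol) exceeds
  the H/O3 attraction (−56.4 kcal/mol). The naive dipole picture fails
  because the hydroxyl oxygen's charge is much larger in magnitude than
  the hydrogen's.
* `COH_O` — donor C, O, H against the acceptor O. Attractive (the C
  carries the balancing positive charge), but summed over bonds it
  *overestimates* hydrogen bonding, exceeding the total interchain
  electrostatics.
* `COH_COX` — donor C–O–H triple against the full near-neutral acceptor
  group: C, O, H for hydroxyl acceptors and the five-atom
  O4–C1–O5–C5–C4 set for the ring oxygen O5. This multipole description
  yields consistent per-bond energies of a few kcal/mol.

Per-glucose aggregation attributes each bond to its donor's glucose unit,
sums per chain parity, normalizes by the glucose count and averages the
origin- and center-chain values; dividing by the bulk interchain
electrostatic energy per glucose gives the hydrogen-bond share of the
interchain electrostatics (≈66% for I$\beta$, ≈73% for II with the
recalibrated variant's published inputs).

## Hydrogen-bond fixtures

`make_hbond_fixture()` realizes a donor triple and an acceptor group at an
exact ($d_{\mathrm{HO}}$, $d_{\mathrm{OO}}$, angle) geometry. Three numbers
underdetermine a 3D arrangement, so the fixture fixes the out-of-plane
freedom to zero and places the donor C and the acceptor group *anti* to
the partner group with standard bond lengths. This planar idealization
reproduces tabulated donor-group/acceptor-O energies to within about
1 kcal/mol — the tolerance used in the per-row fixture tests, which is
wider than the printed crystal-to-crystal standard deviations precisely
because the residual is fixture idealization, not crystal variation. When
a full matrix of donor–acceptor pair distances is available (for example
obtained by inverting tabulated pair energies through the Coulomb law),
the optional `pair_distances` argument refines the free atom positions by
least squares, after which group sums reproduce the tabulated values to
better than 0.2 kcal/mol.

## Bulk energies by finite-size interpolation

The per-chain interchain energy of a chain $c$ is
$\tfrac12 \sum_{i \in c}\sum_{j \notin c} E_{ij}$, the half compensating
double counting when averaging over chains; pair partners range over the
*whole* crystal, while the average runs over the selected central chains
(those closest to the lateral centroid, which have complete neighbour
shells). Per-chain energies of crystals with increasing degree of
polymerization (dp) are fitted by unweighted ordinary least squares
against dp: the slope is the bulk energy per glucose unit, the intercept
absorbs chain-end effects, and the slope's standard error is the usual OLS
error (undefined and flagged for two points). The mean over central chains
(rather than the sum) is the default series statistic; both are supported.
Replica averaging uses the arithmetic mean with the standard error of the
mean.

## Synthetic data: what it emulates and what it does not

The generators cover four needs: `make_two_body()` (analytic oracle for
the pair primitives), `make_hbond_fixture()` (tabulated bond geometries),
`make_toy_crystal()` (chains of point-charge residues with an independent
brute-force $O(N^2)$ unique-pair ledger, the oracle for the
interchain/intrachain decomposition and its exclusions), and
`make_size_series()` (exact or noisy linear series for the bulk fit, with
seed-reproducible Gaussian noise). They emulate the *structure* of the
study's data — pair geometry, lattice topology, linear size scaling — but
not thermal ensembles, minimization trajectories, solvent, or the
correlated residuals of real minimized structures. Passing tests therefore
establish correctness of the energy algebra, the decomposition
bookkeeping, the detection logic and the estimators, not agreement of
absolute built-crystal energies with experiment.

## Numerical choices and problem sizes

* Tolerances: decomposition vs. brute-force ledger at $10^{-8}$ relative;
  exact-line slope recovery at $10^{-10}$; fixture geometry reproduction at
  $10^{-6}$ Å (the angle check relaxes to $10^{-4}$ degrees because the
  angle is degenerate at exact collinearity). PDB I/O keeps coordinates to
  the format's $10^{-3}$ Å, so energies survive a round trip to roughly
  $10^{-2}$ kcal/mol, not better.
* The Monte-Carlo slope-recovery check uses 1000 seeds at noise 0.2
  kcal/mol on the dp set {6, 8, 10, 12}; oracle-equivalence toy crystals
  stay below 500 atoms; pipeline and crystal tests use 4–12 chains at dp
  3–8, and the 52-chain build is exercised for counts and selection only.
  These sizes make the full suite run in seconds while still covering
  every code path; nothing in the science depends on larger inputs, since
  the estimators are size-consistent by construction.
* Ties in central-chain selection are broken by chain id after rounding
  centroid distances to $10^{-6}$ Å, making the selection deterministic
  and permutation-invariant.
* Degenerate inputs error loudly rather than guess: zero/negative
  distances, unsatisfiable bond geometry, residues without hydrogens,
  missing force-field entries, mixed variants in one series, empty
  replica lists.

## Known limitations

* Idealized crystals are topological stand-ins; absolute bulk energies of
  built crystals should not be quoted. Supply externally minimized
  structures through `read_pdb()` for quantitative crystal energetics.
* Bonded energies are absent by design, so no "total intrachain" or
  "overall" crystal energies are produced.
* Hydrogen positions are taken as given; there is no hydrogen placement or
  optimization.
* The 0.94 rescaling is applied to all types by default; if a convention
  with exemptions is needed it must be supplied explicitly.

## A worked fragment

```{r}
ff <- load_forcefield("GLYCAM06")
q <- setNames(ff$charge, ff$name)

# the two bare Coulomb terms of the interchain O6-H...O3 bond
coulomb_energy(q["O6"], q["O3"], 2.72)
coulomb_energy(q["HO6"], q["O3"], 1.77)

# the same bond as a fixture, scored in all three modes
fx <- make_hbond_fixture("O6", "O3", d_HO = 1.77, d_OO = 2.72, angle = 162)
hb <- detect_hbonds(fx)
sapply(c("OH_O", "COH_O", "COH_COX"),
       function(m) hbond_energy(fx, hb, m)$electrostatic)

# bulk-energy extraction from an exact synthetic series
fit_bulk_energy(make_size_series(slope = -13.5, intercept = 4,
                                 noise_sd = 0, dp_list = c(6, 8, 10, 12)))
```
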