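# cellenergy

Nonbonded energy decomposition and hydrogen-bond scoring for cellulose
nanocrystals, in R.

## Who this is for

Native cellulose Iβ packs its chains parallel; cellulose II, the form
obtained on recrystallization, packs neighboring chains antiparallel and is
the more stable polymorph. Deciding *why* — hydrogen bonds, overall
electrostatics, or van der Waals (vdW) packing — requires decomposing crystal
energies term by term. `cellenergy` is for researchers in carbohydrate
modelling who want that decomposition as a reusable pipeline: build or ingest
cellulose Iβ/II nanocrystals, assign GLYCAM-style charges and Lennard-Jones
parameters, split pairwise nonbonded energies into interchain and intrachain
electrostatic and vdW parts, extract bulk (per-glucose) energies from
crystals of increasing chain length, and score hydrogen bonds with a
group-based multipole description.

## The model in brief

Atoms interact through a bare Coulomb term,

    E_elec = Q_i Q_j / r,   Q = 18.2223 q   (q in e, r in Å, E in kcal/mol)

and a 12-6 Lennard-Jones term with arithmetic-mean radii and geometric-mean
well depths,

    E_vdW = ε [ (R_min/r)^12 − 2 (R_min/r)^6 ],
    R_min = (R_i + R_j)/2,   ε = √(ε_i ε_j).

There are no cutoffs and no periodic images: glucose units are neutral
(charges of a central unit sum to zero exactly), so inter-residue
electrostatics are short-ranged multipole interactions and full pairwise
sums converge. Chain-terminal residues are re-neutralized by spreading their
excess charge over the terminal hydrogens.

The per-chain interchain energy of chain *c* is half the pair sum between
*c* and all other chains (the half prevents double counting when averaging
over chains). Averaged over the central chains of crystals built at several
chain lengths (dp), these energies fall on a line in dp; the slope of an
ordinary least-squares fit is the **bulk energy per glucose unit**, with
chain-end effects absorbed in the intercept.

Hydrogen bonds (donors O2‑H, O3‑H, O6‑H; acceptors O2, O3, O5, O6; criteria
d(H···O) ≤ 3.0 Å, O‑H···O angle ≥ 115° by default) are scored three ways:
the naive donor‑OH/acceptor‑O pair (`OH_O`, typically *repulsive* for
realistic charges), the donor C‑O‑H triple against the acceptor oxygen
(`COH_O`), and the triple against the full near-neutral acceptor group
(`COH_COX` — C,O,H for hydroxyl acceptors, the five-atom O4‑C1‑O5‑C5‑C4 set
for the ring oxygen), which yields consistent hydrogen-bond energies of a
few kcal/mol per bond.

## Worked example

```r
library(cellenergy)

ff <- load_forcefield("GLYCAM06")
q  <- setNames(ff$charge, ff$name)

# bare Coulomb terms of the interchain O6-H...O3 hydrogen bond of
# cellulose Ibeta at its tabulated geometry (kcal/mol):
coulomb_energy(q[["O6"]],  q[["O3"]], 2.72)   # 59.54868   O-O repulsion
coulomb_energy(q[["HO6"]], q[["O3"]], 1.77)   # -56.3956   H-O attraction

# the whole bond as an idealized fixture, scored in all three modes:
fx <- make_hbond_fixture("O6", "O3", d_HO = 1.77, d_OO = 2.72, angle = 162)
hb <- detect_hbonds(fx)
sapply(c("OH_O", "COH_O", "COH_COX"),
       function(m) hbond_energy(fx, hb, m)$electrostatic)
#      OH_O      COH_O    COH_COX
#  3.153084 -15.020766  -7.399334
```

The naive OH/O score is *positive* (+3.2 kcal/mol): the O–O repulsion beats
the H–O attraction, so two atoms cannot explain why the bond forms. Adding
the donor carbon (`COH_O`, −15.0) overshoots; the full group–group multipole
score (`COH_COX`, −7.4) gives a sensible hydrogen-bond energy.

```r
# per-glucose aggregation of the interchain bond-class energies
# (origin-chain classes -8.1 and -0.7; center-chain -6.7 and -2.3):
hb_pg <- aggregate_per_glucose(
  data.frame(donor_chain = c("A", "A", "B", "B"), donor_resno = 1L,
             donor_parity = c("origin", "origin", "center", "center"),
             scope = "inter", electrostatic = c(-8.1, -0.7, -6.7, -2.3)),
  scope = "inter")
hb_pg                                            # -8.9 kcal/mol per glucose
fraction_of_interchain_electrostatics(hb_pg, -13.5)   # 66 (percent)

# bulk energy per glucose from a size series (exact line -> exact slope):
fit_bulk_energy(make_size_series(slope = -13.5, intercept = 4,
                                 noise_sd = 0, dp_list = c(6, 8, 10, 12)))
# bulk energy per glucose: -13.5000 kcal/mol (slope)
#   intercept (end term): 4.0000 kcal/mol

# idealized 52-chain nanocrystal (counts, parities, topology):
build_crystal("Ibeta", n_chains = 52, dp = 6)
# cellulose crystal (form Ibeta): 52 chains, dp 6, 6708 atoms
#   parity: center=26, origin=26
```

So: hydrogen bonds scored as group multipoles account for about two thirds
of the bulk interchain electrostatic energy per glucose in cellulose Iβ —
the quantitative sense in which hydrogen bonding is a large, but not the
dominant, part of the interchain electrostatics.

Crystals built by `build_crystal()` are *synthetic idealized* structures
(correct lattice, symmetry, parity, direction and bond topology; cartoon
atomic geometry). For quantitative crystal energetics, ingest externally
energy-minimized structures with `read_pdb()` and run the same pipeline;
`run_pipeline()`/`render_report()` tie all stages together, and
`inst/scripts/cellenergy-cli.R` exposes them as shell subcommands
(`build`, `energy`, `hbonds`, `bulkfit`, `fixtures`, `report`).

See the vignette (`vignettes/cellulose-energetics.Rmd`) for the full model
description, parameter conventions and design decisions.

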