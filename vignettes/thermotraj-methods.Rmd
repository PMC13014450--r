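---
title: "Methods: trajectory descriptors for protein thermal-stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory descriptors for protein thermal-stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotraj)
```

# Scope and model

`thermotraj` analyses protein MD trajectories for thermal-stability
comparisons. The canonical use case is a pair of homologues — here the CheY
chemotaxis regulator from a hyperthermophile (*T. maritima*, "TmY") and a
mesophile (*E. coli*, "EcY") — simulated in replicate at a ladder of
temperatures, with the question: which interactions let one fold survive
heating that unfolds the other? The package computes the descriptor panel
standard in this field and the replica statistics used to compare them. It
does **not** run or prepare simulations: no protonation, solvation,
minimization, equilibration or integration. Inputs are topologies plus
coordinate frames (multi-model PDB natively).

# Units, numbering, conventions

* Internal length unit is Angstrom (PDB native); descriptor series report
  nm, the convention of the GROMACS analysis tools this package mirrors.
* Residue numbering is taken verbatim from the input PDB and never
  renumbered: published residue labels (Asp54, Lys104, ...) stay valid.
  For 1TMY this means the two crystallographically unresolved residues
  (M1, K120) simply never appear.
* Frames are 1-indexed in R style; the reference frame for RMSD/Q defaults
  to frame 1 (the t = 0 conformation).

# Global descriptors

**RMSD.** Each frame is superposed on the reference by weighted Kabsch SVD;
the reflection branch (det = −1) is corrected by flipping the smallest
singular vector. Collinear point sets are rejected rather than silently
fitted. The default selection is the C-alpha trace, with `"backbone"`
(N/CA/C/O) available: published workflows are ambiguous between the two
(methods text says backbone, figure captions say C-alpha), so both are
supported and the choice is always explicit in the call.

**Radius of gyration.** Mass-weighted by default (the `gyrate` convention),
with an unweighted toggle for geometric comparisons.

**Fraction of native contacts.** Best–Hummer–Eaton switching over the
native contact set: heavy-atom pairs at residue separation > 3 within
4.5 Å in the reference frame, β = 5 Å⁻¹, λ = 1.8. These constants are the
published defaults of the contact model; they are parameters of
`native_contacts()` rather than hard-coded. Two transparency choices:

* The smooth switching function gives Q(native) slightly below 1 (each
  term is 1/(1+exp(−4βr⁰/5)) ≈ 1 − 10⁻⁷ at r⁰ ≈ 4 Å, but terms at larger
  r⁰ contribute less). Tables/series default to the *raw* Q;
  `normalize = TRUE` divides by Q(reference) for workflows that want
  Q(native) = 1 by construction. We do not silently renormalize.
* Whether published Q values used heavy-atom or C-alpha contacts is not
  always stated; the atom set is a `selection` argument, defaulting to
  heavy atoms.

**RMSF.** Frames are superposed on the reference over the selection; the
per-atom RMS deviation from the *time-averaged* position is averaged per
residue. A single-frame trajectory is an error (fluctuation undefined),
not a zero.

No periodic-boundary imaging is performed: inputs are assumed whole and
unwrapped, which matches how trajectory tools emit protein-only
coordinates. This is a stated limitation, not a silent assumption.

# Secondary structure

The assignment is a self-contained DSSP-style algorithm:

1. Backbone amide hydrogens are reconstructed when absent (crystal inputs
   lack them): H sits 1.01 Å from N along the external bisector of the
   C(prev)–N–CA angle, anti to the previous carbonyl in the planar trans
   peptide. First residues, prolines and residues after a chain break
   (C–N > 2.5 Å) get no H and are flagged.
2. Backbone H-bonds use the classic electrostatic model
   E = 0.084·332·(1/r~ON~ + 1/r~CH~ − 1/r~OH~ − 1/r~CN~) kcal/mol with the
   −0.5 kcal/mol threshold. Peptide-bonded neighbours (|i−j| < 2) are
   excluded — their covalent geometry trivially satisfies the criterion —
   and a 9 Å C-alpha prefilter bounds the pair search.
3. Two consecutive n-turns (n = 3, 4, 5) define minimal G/H/I helices with
   override priority H > G > I at overlaps; parallel/antiparallel bridge
   patterns give B, runs of bridges merge to E; isolated turn residues get
   T; everything else C.

The three-class collapse maps {H, G, I} → α, {E} → β and all else — B, T,
C, and bends, which we do not compute separately — to coil. This mirrors
the published three-category scheme in which bends, turns, loops and
β-bridges all count as random coil, so skipping the curvature-based S code
loses nothing downstream; the simplification is recorded here and in the
output metadata.

Validation: on ideal fixtures the assignment was checked against an
independent DSSP implementation (MDAnalysis 2.10); the reference
three-state strings are frozen in the test suite, and the acceptance
criterion is ≥ 95% agreement on interior residues (termini are genuinely
ambiguous between implementations).

**Element persistence** is our operationalization of per-helix/per-strand
stability narratives: the fraction of frames in which ≥ 50% (configurable)
of an element's residues hold the element's class. Element definitions for
the two CheY homologues ship as a plain-text table for the ranges that are
published (TmY α3 62–72, α4 87–95; EcY α3 65–74, α4 92–100, α5 113–127);
others are user-supplied.

**ILV composition** counts Ile/Leu/Val per class — a composition summary
only. Spatial ILV *cluster* detection is deliberately unimplemented: no
contact criterion for clusters is published, and inventing one would
manufacture unverifiable results.

# Interactions

**Hydrogen bonds.** Donor–acceptor distance ≤ 3.5 Å and angle ≤ 30°. The
angular criterion is implemented *at the donor* (between D→H and D→A): the
common "donor–hydrogen–acceptor ≤ 30°" phrasing is geometrically
inconsistent with a near-linear bond if read literally as the angle at H,
and the at-donor convention is what the standard analysis tools apply. The
literal at-hydrogen reading (180° − angle at H) is available via
`angle_at = "hydrogen"`. Donors are N/O heavy atoms with an attached
hydrogen (≤ 1.25 Å); donors with no hydrogen are skipped with a warning.
Protein–protein counts exclude intra-residue pairs (the published counts
do not state this; we exclude and record it). Protein–solvent counts take
both donor/acceptor directions.

**Salt bridges.** Lys NZ and Arg NE/NH1/NH2 versus Asp OD1/OD2 and Glu
OE1/OE2; a pair is present when the minimum N···O distance is ≤ 4.0 Å
(Barlow–Thornton). Histidine is excluded (the published criterion names
only Lys/Arg vs Asp/Glu); the Arg atom set is a documented superset choice
since published tools differ on NE. Pairs are identified by residue, so
carboxylate oxygen swaps preserve continuity. Frequencies are per-replica
fractions of frames; the replica mean f̄ classifies stability
(lower-inclusive boundaries 0.75/0.50/0.30) and the ≥ 0.30 formation
threshold applies to the *mean* only — per-replica values are reported but
never filter. Networks are connected components of the formed-pair graph,
named dyad/triad/tetrad by size and "extended network" beyond four (the
published vocabulary stops at tetrads). Non-native bridges are pairs below
threshold at the reference temperature but formed at a higher one.

# Replica statistics

Statistics pool frames across replicas (three 10,001-frame replicas give
30,003 values — the published table convention); a per-replica mode exists
behind `pool_replicas()`'s provenance column. Boxplot summaries use
quartiles by linear interpolation of order statistics (R type 7) — no
quartile convention is published, and the choice affects only boxplot
edges, never means or medians. Whiskers sit at the most extreme datum
within 1.5 IQR; skewness uses the mean-vs-median sign (the criterion the
source narrative itself applies), not a moment statistic, with a 1e-9
symmetric band. Percent changes are computed from full-precision means and
rounded to one decimal only for display. `percent_excess(a, b)` =
100(b−a)/a and `percent_decrease(a, b)` = 100(a−b)/a; the twelve published
comparison figures are reproduced from the printed means by these two
functions in the acceptance suite.

# Synthetic data: what it emulates, what it does not

The generators produce *statistical stand-ins*, not physics: no force
field, thermostat or integrator. Each generator's stated world fixes a
ground truth that the corresponding analysis must recover:

| generator | emulates | exact ground truth |
|---|---|---|
| `make_rigid_trajectory` | global tumbling/drift | RMSD = 0, Rg constant |
| `make_fluctuation_trajectory` | stationary thermal noise | RMSF → σ√3 |
| `make_unfolding_trajectory` | progressive thermal expansion | Rg(t) = s(t)·Rg(0), Q non-increasing |
| `make_contact_trajectory` | intermittent ion pair | f = round(pF)/F exactly |
| `add_water_shell` | first-shell H-bond partners | HBps = plan size |

Defaults follow the study's stated world where one exists (replica
triplicates, 100-ps frame spacing convention, the 0.2/0.3/0.4 engineered
replica frequencies averaging exactly the 0.30 threshold); free choices
were fixed once at field-realistic values: fluctuation σ of 0.1–0.2 Å
(folded-state B-factor scale), expansion schedules up to 2–2.5× (the
unfolded-state Rg ratio seen in heated-trajectory studies), 0.02 Å
expansion jitter.

Two construction notes:

* The ideal helix/strand builders use internal-coordinate (NeRF) chain
  extension with textbook bond geometry; φ/ψ = (−57°, −47°) and
  (−139°, +135°).
* The β-hairpin places a 180°-flipped copy of an ideal strand by a
  deterministic rigid-body fit whose targets are the antiparallel H-bond
  registry (O···N 2.9 Å, O···H 1.92 Å both directions at alternating
  pairs) plus a weak paired-CA spacing target of 5.0 Å; the resulting
  paired C-alpha distances are 4.7–5.1 Å. The two strands are covalently
  unconnected — a flagged chain gap stands in for the turn, which the
  chain-break logic handles. The toy protein similarly parks its hairpin
  away from its helix; segment starts lack amide H exactly as chain
  starts do.

Consequently a green synthetic test establishes *algorithmic correctness
at desk scale* — the analysis recovers known inputs — and nothing about
force-field realism, sampling convergence, or the actual thermal behaviour
of any protein. Published microsecond-scale trajectory statistics (e.g. a
mean folded-state RMSD of 0.131 nm) are therefore treated as fixtures and
worked examples, never as recovery targets.

# Numerical choices and degenerate inputs

* Kabsch: collinearity rejected at a 1e-8 relative singular-value
  threshold; weights must be non-negative, not all zero.
* Q: empty contact sets are an error, not Q = 0.
* altloc resolution: highest occupancy wins, first listed on ties; the
  frame-1 atom set is authoritative for all models.
* PDB output: 3-decimal coordinates (round trips are exact to 5e-4 Å).
* `summary_stats` on a constant vector: sd = 0, IQR = 0, no outliers.
* Stability classes are a total function on [0, 1]; out-of-range
  frequencies are an error.

# Known limitations

* No GRO/XTC/DCD readers: multi-model PDB is the reference dialect; the
  `Trajectory` contract is the seam where an adapter would plug in.
* No periodic-boundary imaging, no solvent-accessibility, no π-helix
  analysis beyond the I code, no energy-based H-bond scoring, no
  hydrophobic-contact or cation–π analyses, no conformational clustering
  or PCA, and no plotting of the published figures (tables are emitted;
  rendering is the caller's concern).
* Desk-scale performance envelope: pure-R implementations are designed for
  toy systems and fixture-sized trajectories (10⁴ frames × 10² atoms);
  production microsecond analyses belong to compiled tools.
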