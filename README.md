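# thermotraj

Trajectory descriptors for comparing the thermal stability of proteins from
molecular-dynamics simulations.

Hyperthermophilic proteins keep their fold at temperatures that unfold their
mesophilic homologues, and MD studies probe why by tracking a standard panel
of descriptors along heated trajectories. `thermotraj` implements that panel
as a tested, reusable R package for structural bioinformaticians:

* **Global descriptors** — RMSD after optimal (Kabsch) superposition,
  radius of gyration
  *R*<sub>g</sub> = √(Σ<sub>i</sub> m<sub>i</sub>‖r<sub>i</sub> − r<sub>com</sub>‖² / Σ<sub>i</sub> m<sub>i</sub>),
  and the Best–Hummer–Eaton fraction of native contacts
  *Q* = |S|⁻¹ Σ<sub>(i,j)∈S</sub> [1 + exp(β(r<sub>ij</sub> − λr⁰<sub>ij</sub>))]⁻¹
  with β = 5 Å⁻¹, λ = 1.8 over heavy-atom pairs within 4.5 Å at sequence
  separation > 3.
* **Local descriptors** — per-residue RMSF about the time-averaged
  superposed structure; a self-contained DSSP-style secondary-structure
  assignment (backbone H-bond energy
  E = 0.084·332·(1/r<sub>ON</sub> + 1/r<sub>CH</sub> − 1/r<sub>OH</sub> − 1/r<sub>CN</sub>) kcal/mol,
  bond if E < −0.5) collapsed to three classes (α = {H, G, I}, β = {E},
  coil = rest); Ile/Leu/Val composition per class.
* **Interactions** — geometric hydrogen bonds (donor–acceptor ≤ 3.5 Å,
  angle at the donor ≤ 30°), salt bridges (minimum Lys/Arg N ···
  Asp/Glu O distance ≤ 4.0 Å), replica-averaged formation frequencies
  *f*<sub>SB</sub>, stability classes (high ≥ 0.75 > moderate ≥ 0.50 >
  low ≥ 0.30 > negligible), and salt-bridge network motifs
  (dyads/triads/tetrads as connected components of the formed-pair graph).
* **Statistics** — replica pooling, Tukey boxplot summaries with the
  mean-vs-median skew criterion, and percent-change comparisons.
* **Synthetic generators** — seeded ideal helices, β-hairpins, toy α/β
  proteins, rigid-body / Gaussian-fluctuation / unfolding / intermittent-
  contact trajectories and engineered water shells, each with an exact
  ground truth, so every analysis stage has a parameter-recovery test
  without running any simulation.

The package ships the published replica-averaged salt-bridge frequency
tables for the CheY chemotaxis protein from *Thermotoga maritima* ("TmY",
PDB 1TMY) and *Escherichia coli* ("EcY", PDB 3CHY) at 302–450 K as worked
examples (`chey_salt_bridge_table()`).

## Worked example

Recover an engineered salt-bridge frequency from three synthetic replicas,
then reproduce the published network analysis of the thermophilic CheY:

```r
library(thermotraj)

tp <- build_toy_protein(8, 4, sequence = "AAKAAAAAAAAADAAA")
reps <- lapply(1:3, function(i)
  make_contact_trajectory(tp, 3, 13, p = c(0.2, 0.3, 0.4)[i],
                          n_frames = 100, seed = i))
freq <- salt_bridge_frequencies(replica_set(reps, temperature = 302))
freq[, c("basic", "acidic", "f_mean")]
#>   basic acidic f_mean
#> 1  Lys3  Asp13    0.3
classify_stability(freq$f_mean)
#> [1] low

tmy <- formed_pairs(chey_salt_bridge_observations("TmY", 302))
nrow(tmy)
#> [1] 15
build_networks(tmy)[1:3]
#> <SaltBridgeNetwork> tetrad: Arg110 - Lys117 - Glu113 - Asp100
#> <SaltBridgeNetwork> tetrad: Arg37 - Lys71 - Glu68 - Asp64
#> <SaltBridgeNetwork> triad: Lys104 - Asp9 - Asp54
```

The replica mean of the engineered presence fractions (0.2, 0.3, 0.4) is
exactly 0.300 — the formation threshold — and the thermophilic table yields
15 formed bridges organised into two tetrads, two triads (one containing
the active-site aspartate) and five dyads.

An unfolding control shows the descriptor phenomenology (rising
R<sub>g</sub>, collapsing Q):

```r
ut <- make_unfolding_trajectory(tp, seq(1, 2, length.out = 5), seed = 1)
round(radius_of_gyration_series(ut)$values, 3)   # nm
#> [1] 0.845 1.055 1.267 1.478 1.689
round(q_series(ut, native_contacts(tp$trajectory))$values, 3)
#> [1] 1.000 1.000 0.995 0.718 0.029
```

## Command line

```sh
Rscript -e 'thermotraj::thermotraj_cli()' rmsd traj.pdb --out rmsd.csv
Rscript -e 'thermotraj::thermotraj_cli()' saltbridges traj.pdb --networks
Rscript -e 'thermotraj::thermotraj_cli()' report config.json
```

(`exec/thermotraj` wraps the same entry point.)

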