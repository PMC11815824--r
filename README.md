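# cgsugar

Systematic coarse-grained (CG) parametrization of glucose- and
mannose-based disaccharides for the Martini 3 force field, in R.

Sugars are hard to resolve experimentally and expensive to simulate at
atomistic resolution, so CG models are the workhorse for studying their
conformational dynamics and aggregation at scale. `cgsugar` implements, as
a reusable toolchain, the pipeline that turns reference all-atom
trajectories of solvated disaccharides into simulation-ready Martini 3
models, plus the analyses used to validate them. It is aimed at force-field
developers and simulators who want reproducible, scriptable disaccharide
parameters rather than hand-tuned topologies.

## What it does

1. **Enumeration** — all homodimeric Glc/Glc and Man/Man disaccharides over
   glycosidic linkages 1,1 / 1,2 / 1,3 / 1,4 / 1,6 and both anomeric
   configurations at each end: 20 glucose combinations, 40 in total, named
   with the GLYCAM scheme (`4GB_0GA` = β-maltose, `1GA_0GA` = trehalose).
2. **Mapping** — graph-based assignment of every atom to one of six Martini
   beads (three per pyranose ring: SP4r/SP4r/SP1r, with the
   glycosidic-oxygen bead typed SN6, or SN6r at 1→6 mannose junctions) plus
   one massless ring-centre virtual site per ring. A manual mapping-file
   dialect covers cases where the automated graph growth must be
   overridden.
3. **Projection & measurement** — centre-of-geometry projection of
   trajectory frames onto beads, then measurement of the 7 distance terms
   (two ring triangles and the inter-monomer bond), 4 junction angles and
   the unique dihedral.
4. **Boltzmann inversion** — for a harmonic term sampled at temperature
   *T*, equipartition gives `Var(x) = k_B T / k`, so the fitted parameters
   are `b0 = mean(x)` and `k = k_B T / Var(x)` (angles in radian space;
   dihedrals via the circular mean, multiplicity 1). Ring edges are emitted
   as constraints; the inter-monomer bond stays harmonic.
5. **Topology output** — GROMACS `.itp`/`.gro` writers (plus readers for
   round-trip testing) and `.mdp`-style run protocols for the "simple" and
   "soft" equilibration schemes (reaction field, 1.1 nm cutoffs, ε_r 15,
   300 K, 1 bar).
6. **Comparison** — shared-bin histogram overlap `O = Σ_i min(p_i, q_i)`
   (full and reference-normalised variants) and per-term mean ± sd /
   %Δ = 100·(AA − CG)/CG report tables.
7. **Aggregation** — composition calculators (e.g. 20 disaccharides per
   7609 waters ≈ 50 g/L; 4:1 water mapping → 1902 CG beads), per-frame
   minimum-distance molecular networks with a 0.47 nm cutoff,
   connected-component aggregate sizes, windowed size distributions and
   time evolution.
8. **Synthetic fixtures** — a generator producing pseudo-all-atom
   trajectories whose mapped bead terms follow prescribed Gaussians, so the
   whole pipeline is testable end-to-end without reference trajectories.

## Worked example

Build a trehalose (`1GA_0GA`) model from a synthetic reference trajectory
with a 0.48 ± 0.02 nm inter-monomer bond:

```r
library(cgsugar)

spec <- disaccharide_spec("GLC", "GLC", linkage_spec(1, "ALPHA", "ALPHA"))
traj <- gen_pseudo_aa_traj(generator_spec(spec = spec, n_frames = 5000, seed = 7))
terms <- measure_terms(traj, traj$mapping, traj$connectivity, traj$graph)
fit <- fit_terms(terms)
fit$bond3
#> <fitted_term> bond eq=0.4801 k=6263.9 n=5000
topo <- build_topology(traj$mapping, traj$connectivity, fit)
sapply(topo[c("constraints", "bonds", "angles", "dihedrals")], nrow)
#> constraints       bonds      angles   dihedrals
#>           6           1           4           1
write_itp(topo, "1GA_0GA.itp")
```

The fitted bond says: the inter-monomer bead distance fluctuates around
0.4801 nm, and inverting its variance at 300 K gives a harmonic force
constant of about 6264 kJ mol⁻¹ nm⁻² (the exact-σ value would be
k_B·300/0.02² ≈ 6236). The topology carries the invariant structure of
every disaccharide model: 6 ring constraints, 1 harmonic bond, 4 angles,
1 dihedral and 2 massless virtual sites.

The same pipeline is scriptable from a shell via the thin launcher in
`inst/scripts/cgsugar`:

```sh
cgsugar enumerate --sugars GLC,MAN            # 40-line table
cgsugar fixtures  --name 1GA_0GA --frames 1000 --seed 7 --out-prefix treh
cgsugar fit       --traj treh.gro --name 1GA_0GA --out-prefix treh
cgsugar sysprep   --n-solute 20 --mw-solute 342.30 --aa-waters 7609
cgsugar aggregate --traj clusters.gro --cutoff 0.47
```

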