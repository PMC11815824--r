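---
title: "Coarse-graining disaccharides: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-graining disaccharides: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgsugar)
```

## The problem

Disaccharides of D-glucopyranose and D-mannopyranose differ only in the
orientation of the C2 hydroxyl, yet every combination of linkage position
(1,1 / 1,2 / 1,3 / 1,4 / 1,6) and anomeric configuration (α/β at both the
glycosidic and the reducing carbon) is a chemically distinct molecule with
its own conformational preferences. `cgsugar` builds Martini 3
coarse-grained models for all of them systematically: the molecule is
represented as a 2D atom graph, partitioned into beads, and the bonded
parameters are inferred from the distributions those beads sample in a
reference all-atom trajectory. This vignette explains the model, the
tunable parameters, the synthetic validation data, and the places where
the design was genuinely open.

## The coarse-grained model

Each pyranose ring maps to three "small" beads grown from consecutive
ring-carbon pairs (A = C1/C2, B = C3/C4, C = C5/C6). Exocyclic heavy atoms
join the bead of the ring carbon they are bonded to, the ring oxygen O5
joins bead C, and hydrogens follow their heavy atom, so each bead collects
3–5 heavy atoms plus hydrogens. A massless virtual site sits at the centre
of geometry of each ring's three beads; it exists to improve ring–ring
packing and carries no bonded terms beyond its construction and
exclusions. Ring beads are typed SP4r/SP4r/SP1r; the one bead containing
the glycosidic oxygen becomes SN6 (SN6r at 1→6 mannose junctions). The
glycosidic oxygen joins the donor A bead for 1→1/2/3/4 linkages and stays
with the acceptor's C6/O6 exocyclic group for 1→6 — these are the two
linkage classes of the mapping, and both the class table and the bead
types are editable data (`default_mapping_rules()`), not code.

The bonded structure of every disaccharide model is invariant:

* 6 distance constraints — the two ring triangles, held rigid;
* 1 harmonic bond between the beads flanking the glycosidic linkage
  (`bond3` in file order, so the single flexible distance term always sits
  between the two rigid triples `bond0–2` and `bond4–6`);
* 4 angles — each flanking bead against the two ring partners of the
  other (`x1–a–b`, `x2–a–b`, `a–b–y1`, `a–b–y2`);
* 1 dihedral `x1–a–b–y1`, partners chosen by lowest bead index.

No scaling is applied to ring-edge lengths: constraint lengths equal the
mean mapped distances, which keeps CG and all-atom distributions directly
comparable.

## Boltzmann inversion

A coordinate governed by a harmonic potential `V(x) = k/2 (x − x₀)²` at
temperature *T* samples a Gaussian with variance `k_B T / k`
(equipartition). The fit is therefore moment matching:

* bonds: `b₀ = mean`, `k = k_B T / Var` (kJ mol⁻¹ nm⁻²), with
  `k_B = 0.0083145` kJ mol⁻¹ K⁻¹ so `k_B T = 2.4944` kJ mol⁻¹ at the
  default 300 K;
* angles: the same inversion with moments taken in radian space. A
  `jacobian` switch enables 1/sin θ reweighting; it is off by default
  because the correction is debatable for CG angles and the plain
  angle-space inversion is self-consistent with how the terms are
  measured;
* dihedrals: phase = circular mean (so distributions straddling ±180° are
  handled without artefacts), `k` from the variance of the wrapped
  deviations, emitted as a single proper periodic term of multiplicity 1.
  Multi-term or tabulated dihedral fits are out of scope.

The inversion assumes a unimodal, approximately Gaussian distribution.
That assumption is screened with the package's own overlap statistic: the
histogram of the data is compared against the mass of the fitted Gaussian
on the same bins, and a fit is accepted when the overlap is at least 0.8
(configurable). Bonds failing the screen are rejected with an error —
routing the user to a manual or tabulated treatment — while angles and
dihedrals only record `normal_ok = FALSE` and still emit the
single-Gaussian fit, because a small secondary population is tolerable
there. The screen's bin count follows a square-root rule capped at 100
bins; a fixed fine grid would starve the per-bin mass at moderate sample
sizes and bias the overlap low. Two further numerical guards: a term with
zero variance is classified as a constraint, and a bond force constant
above 50,000 kJ mol⁻¹ nm⁻² is converted to a constraint (logged), since
such stiffness is numerically indistinguishable from rigid at CG
timesteps.

## Comparison statistics

Two distributions on shared bins are compared with
`O = Σᵢ min(pᵢ, qᵢ)` (0 = disjoint, 1 = identical). The *full* overlap
bins both sample sets over the union of supports; the *reference* overlap
bins over the reference's own support and reports the fraction of the
reference distribution sampled by the new data. The bin count (default
100) is configurable; trivial limits (identical → 1, disjoint → 0,
half-shifted uniform → 0.5) are exact, and intermediate values track the
quadrature of the minimum of the two densities. Mean differences are
reported as `%Δ = 100 (AA − CG) / CG`: the CG mean is the denominator,
the convention consistent with the reference worked values
(0.49 vs 0.48 → 2.08 %, 0.44 vs 0.43 → 2.33 %).

## Aggregation analysis

Composition: the solute-to-water ratio for a target concentration is
computed from molecular weights with the solution volume approximated by
the water mass at 1.000 g cm⁻³. Under that convention 20 trehalose
molecules (342.30 g mol⁻¹) in 7609 waters evaluate to 49.9 g L⁻¹, which
rounds to the nominal 50 g L⁻¹; inverting 50 g L⁻¹ exactly yields 7600
waters — the calculator anchors on the printed pair and documents the
residual. CG solvation uses the standard 4:1 mapping,
`floor(waters / 4)` beads (7609 → 1902). A box-volume-based mode is the
obvious alternative; the mass-based shortcut was kept because it needs no
equilibrated box.

Aggregates: each frame yields a network with one node per molecule and an
edge wherever the minimum bead–bead distance (minimum image, orthorhombic
boxes only — triclinic input is rejected with a clear error) is at most
the cutoff. The cutoff defaults to 0.47 nm and the filter is inclusive,
i.e. an edge exactly at the cutoff is kept. Connected components give the
per-frame aggregate sizes; pooled distributions are computed over a
trailing window with a frame stride (e.g. every 100 ps of a final
500 ns), and the full-trajectory time evolution is reported separately.

## The synthetic-data generator

`gen_pseudo_aa_traj()` emulates a mapped reference trajectory: per frame,
bead positions are built from internal coordinates — the two ring
triangles at their (optionally rigid) edge lengths, then the acceptor ring
attached by sequential internal-to-Cartesian (NeRF) placement using the
sampled inter-monomer bond, two sampled junction angles and the sampled
dihedral. Each bead is then decorated with its mapped atoms at fixed
zero-mean offsets, so the centre-of-geometry projection inverts the
decoration exactly and the full mapping machinery is exercised
end-to-end.

One geometric fact shapes the design: once the ring triangles are rigid,
the junction has only six degrees of freedom (one bond, two cone angles,
one dihedral, two spins), so the four angle targets cannot all be sampled
independently. `bond3`, `angle0`, `angle2` and the dihedral are sampled
from independent Gaussians; the remaining azimuth and spin are solved once
at mean geometry so that `angle1` and `angle3` hit their target *means*,
with their spreads induced rather than prescribed. The manifest records
which terms are sampled and which are implied. Treating the sampled terms
as independent Gaussians matches the fit model's own assumption, which is
exactly why the round trip recovers the targets — and also why passing
these tests says nothing about correlated or multimodal motions in real
trajectories, anharmonic ring puckering, or solvent effects. The
generator's default targets use a reference trehalose distance set
(rings 0.32/0.36/0.45 and 0.33/0.36/0.47 nm held rigid, inter-monomer
bond 0.48 ± 0.02 nm); junction angle and dihedral targets are not printed
anywhere for these models, so the defaults (120°/100°/110°/80° with 5° sd,
dihedral −60° ± 10°) were chosen once as geometrically feasible,
CG-realistic values and are not tuned thereafter.

`gen_clustered_config()` plants aggregation structure: molecules within a
cluster are chained at 0.3 nm (below the network cutoff) and clusters are
separated by more than a configurable gap, with box-size validation so the
plant survives periodic boundaries.

## Problem sizes and determinism

The test suite runs the recovery property at 20,000 frames (means to 1 %,
force constants to 5 % against the equipartition identity) and the
measurement checks at 5,000 frames (means within 3 standard errors);
`scripts/acceptance.R` refits the inter-monomer bond from 100,000 draws,
where the standard error of the mean (6×10⁻⁵ nm) is far below the 0.01 nm
rounding grid, making the reported two-decimal value stable across seeds.
All randomness flows from a single seed argument; identical seeds give
byte-identical trajectories, topologies and reports.

## Known limitations

* Trajectory input is multi-frame GRO (and single-frame PDB via `bio3d`);
  compressed binary formats (XTC/TRR) are not read — convert externally
  or use the fixture generator.
* Nonbonded parameters are not derived: bead types are fixed assignments
  from the mapping rules, and no Lennard-Jones or charge work is done.
* Only homodimers of the two shipped templates are enumerated; the code
  path accepts other `mono_template` data files, but none are shipped,
  and furanoses are out of scope.
* One molecule per topology: no polysaccharide chain assembly.
* The dihedral model is deliberately minimal (single term, multiplicity
  1); strongly bimodal torsions are flagged, not resolved.
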