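---
title: "Methods: docking-guided variant panels for epitope localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: docking-guided variant panels for epitope localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcope)
```

## The model

Antibody–antigen docking produces a small ensemble of rigid-body poses
among which a near-native model is usually — but unidentifiably —
present. `episcope` treats each pose as a falsifiable hypothesis about
the epitope. For every pose it designs antigen variants whose mutations
are predicted to break that pose's interface while leaving the antigen
foldable, then selects a minimal *panel* of variants that jointly
challenge every pose. A binding assay over the panel then either
identifies a disruptive variant (localizing the epitope to its mutated
positions and to the poses consistent with the loss of binding) or
falsifies the whole ensemble.

The pipeline decomposes into geometry, scoring, per-pose design, a
cross-pose merge, and covering-panel selection. Each stage is exposed as
a pipeable function returning a tibble, with `run_episcope()` as the
one-call driver.

## Geometry

**Contacts and footprints.** Two residues are in contact when any pair of
their heavy atoms lies within the contact cutoff (default 5 Å, the same
convention used to define binding-interface epitopes from co-crystal
structures). A pose's footprint is the set of antigen residues in
contact with the antibody. Hydrogens, waters and hetero groups are
discarded at parse time (selenomethionine is kept as methionine);
alternate locations resolve to the highest-occupancy conformer; author
residue numbering is preserved verbatim so that mutation labels such as
`M154E` match the community convention.

**Solvent accessibility.** Relative solvent accessibility (RSA) is
per-residue Shrake–Rupley SASA divided by the amino acid's theoretical
maximal area (Tien et al. 2013 values). The sampler places a fixed
golden-spiral lattice (default 960 points) on each solvent-expanded atom
sphere (element van der Waals radius + 1.4 Å probe). Both the point
count and probe are arguments. Residues with RSA strictly above 7% form
the designable surface. Two consequences of these choices are verified
by the tests rather than assumed: a free residue scores RSA > 1 (the
reference areas are defined in a tripeptide context, so the bound is not
1), and rotating a structure perturbs RSA by the lattice discretization
noise (~1% at 960 points, decaying roughly as the inverse square root of
the point count) — exact rotation invariance is not achievable for any
fixed-lattice SASA implementation.

## Scoring

**Pair potential.** Binding disruption and the stability filter both
consume a symmetric 20×20 residue-contact potential (lower = more
favorable). The default is a two-channel physicochemical potential
computed in code, `p(a,b) = q_a q_b − h_a h_b`, from nominal side-chain
charge and Kyte–Doolittle hydropathy scaled to [−1, 1]: like charges and
hydrophobic/hydrophilic mismatches cost energy, complementary charges
and hydrophobic matching are favorable. Any published contact potential
can be substituted via `read_pair_potential()` (whitespace-delimited
matrix with one-letter headers); the provenance label travels into
outputs. Having two partially independent channels matters: it lets a
substitution be disruptive toward a pose (against the paratope
composition) while remaining neutral or stabilizing in its own
structural neighborhood, which is exactly the trade-off the design
stage optimizes.

**Disruptiveness.** For position `i`, substitution `a`, and pose `m`,
the score is the summed potential change over the antibody residues
contacting `i` in `m`, sign-normalized so that positive = disruptive.
Identity substitutions score 0. Substitutions not disruptive toward the
pose under consideration are removed from its candidate list.

**Stability.** The default stability scorer is a deliberately coarse
surrogate for full side-chain repacking: the potential delta of the
mutated residue against its wild-type structural neighborhood (residues
within the contact cutoff), plus a hard steric veto when the side-chain
proxy atom (Cβ, Cα for glycine) sits within 2.5 Å of another residue.
Because neighborhoods are evaluated at wild-type identities, the score
is additive over mutations, which the implementation exploits. The
scorer is pluggable — any `function(structure, mutations)` can replace
it — and the filter semantics are fixed: designs predicted less stable
than wild type (positive delta) are rejected.

## Per-pose design

Candidate positions are the pose's footprint intersected with the
surface, restricted to positions with homolog-supported substitutions:
an alignment of homologs (antigen row first) defines, per position, the
non-wild-type residues seen in at least `min_homolog_count` rows
(default 1). Restricting to evolutionarily accepted substitutions is the
package's main guard for antigen integrity beyond the coarse stability
score.

Designs are position subsets of size `k` (default 3; when a pose offers
fewer candidate positions, the full candidate set is used so the pose
is not gratuitously abandoned) with one substitution per position.
Subsets and substitution choices are enumerated jointly, filtered by
mean pairwise Cα spread ≤ 12 Å and stability ≤ 0, and reduced to the
Pareto frontier over (maximize summed disruptiveness toward the pose,
minimize stability delta). We enumerate substitution choices inside the
Pareto search rather than fixing each position to its most disruptive
substitution: the two objectives are in genuine tension, and on polar
surface patches the most disruptive choices are systematically the most
destabilizing ones, which would leave some poses with no feasible design
at all. The frontier is truncated to `pareto_cap` (default 50) designs
per pose, in descending disruptiveness then lexicographic order, to
bound the panel-selection search.

**Defaults and units.** `k` (mutations per design, unitless, 1–4): 3 —
triple mutants balance per-variant information against epitope
resolution. `max_spread` (Å): 12 — mutations further apart stop probing
a coherent patch. `contact_cutoff` (Å): 5 — shared by footprints,
disruptiveness environments, stability neighborhoods, and the interface
epitope definition, so one knob moves all contact semantics coherently.
`surface_threshold` (RSA fraction): 0.07, strict inequality.

## Cross-pose merge

Designs from different poses overlap. Three rules reconcile them:
a mutation whose position contacts a pose toward which it is not
disruptive is removed (a design losing all mutations is dropped);
identical positions carrying different substitutions across designs are
unified to the most disruptive surviving substitution; duplicates then
collapse, stability is re-checked for unified mutation sets, and each
design's covered-model set is recomputed (a design covers a pose when at
least one of its mutations lies in that pose's footprint with positive
disruptiveness).

## Panel selection

Designs are clustered by the Hausdorff distance between the Cα point
sets of their mutated positions,

$$h(A,B) = \max\Big\{ \max_{a\in A}\min_{b\in B} d(a,b),\;
\max_{b\in B}\min_{a\in A} d(a,b) \Big\},$$

using K-medoids. The clustering is deterministic PAM (BUILD then SWAP,
lowest-index tie-breaks) implemented in compiled code; it sits on the
baseline's hot path (a thousand point sets per replicate), which is why
it is not delegated to an R-level implementation. K starts at 1 and
grows until some combination of designs, one per cluster, covers every
*coverable* pose; poses no design can touch are excluded from the
requirement and reported. At each K the deterministic clustering plus
ten seeded random-restart local optima are probed before K is allowed to
grow: a single PAM optimum can trap two members of an optimal cover in
one cluster, and probing alternative local optima removes most (not
all — see Limitations) of the resulting overshoot. Among covering
combinations, the one with the highest summed disruptiveness wins, ties
breaking on the lexicographically smallest design-id tuple, so a fixed
input yields a byte-identical panel. When the one-per-cluster
combination count exceeds `combo_budget` (default 10^6) the selection
falls back to greedy max-coverage with a warning recorded in the panel
object.

Pooling ensembles from several antibodies (ids tagged
`antibody:model`) turns the same machinery into a multi-antibody
design: one panel covering every pose of every antibody.
`dock_overlap_matrix()` (fraction of one antibody's poses matching
another's at footprint Jaccard ≥ 0.25 — the matching rule is a package
convention, labeled as such, since percent dock overlap has no unique
definition) and `design_distance_matrix()` (mean pairwise Hausdorff
distance between the antibodies' design sets) support in-silico epitope
binning.

## Evaluation

An epitope is either a curated residue list (`read_epitope_list()`) or
the computed 5 Å heavy-atom interface of a reference complex
(`interface_epitope()`); the provenance tag is carried through.
Localization succeeds when at least one panel design mutates an epitope
residue. After an assay identifies disruptive variants,
`consistent_models()` filters the ensemble to poses whose footprints
contain a disruptive mutation and reports the surface fraction their
footprints occupy — the localization's effective resolution. Docking
model quality against a reference complex is measured by f_nat, the
fraction of reference interface residue pairs reproduced by the pose.

The random-design baseline quantifies what docking contributes: per
replicate, 1000 random k-position surface sets under the same spread
constraint (strict < 12 Å) are clustered with the same
Hausdorff/K-medoids machinery, the medoids of `n_designs` clusters
(matched to the guided panel size) are taken as the selected panel, and
the replicate succeeds if any selected set touches the epitope. Because
success depends only on positions, amino-acid identities are not
sampled. The estimate comes with an exact binomial confidence interval,
and the whole procedure is reproducible from its seed.

`summarize_retrospective()` recomputes, from the packaged 33-target
benchmark table, column means and SDs, success counts under both epitope
definitions and both antigen-structure sources, Kendall rank
correlations between decoy and design counts (tau-b, the tie-corrected
variant, since design counts are small integers with heavy ties), and
Pearson correlations between antigen size and design count (whole-chain
residue count primary; the surface-count variant is also emitted).
Constant columns yield flagged `NA`s rather than errors.

## The synthetic scenario generator

`make_scenario()` builds a fully seeded test world: an α-helical toy
antigen (N, Cα, C, O, Cβ pseudo-atoms; 1.5 Å rise, 100° turn), an
ensemble of rigid antibody pseudo-bodies, and a synthetic homolog
alignment. Choices and what they emulate:

* **Antigen composition.** Residues are drawn with aliphatic/aromatic
  types up-weighted (3:1), giving mildly hydrophobic surface patches.
  This mirrors the enrichment of hydrophobic and aromatic residues at
  real protein-interaction sites, and it matters for the scoring model:
  against a polar paratope, hydrophobicity-raising substitutions are
  then disruptive without being predicted destabilizing, so designable
  scenarios exist for essentially every patch — as they do for real
  antigens under a rotamer-level stability model.
* **Paratopes.** Antibody pseudo-bodies are clouds of 3-atom
  pseudo-residues: one parked ~3.2 Å outside each targeted residue's Cβ
  (guaranteeing the intended footprint) plus a non-contacting bulk shell
  to ~50 atoms. Residue types are drawn from a Tyr/Ser/Gly/Trp/polar
  composition, as in real CDR loops. Poses target randomly centered
  surface patches of the requested footprint size; one pose can be
  declared *true*, and the scenario's epitope is then exactly its
  footprint.
* **Alignment.** Ten homolog rows, per-column substitution probability
  0.3 (uniform over the other 19 residues), gap probability 0.02. At
  this depth ≥ 97% of columns carry at least one allowed substitution,
  matching the generator's declared contract (≥ 80%).

`scenario_self_check()` asserts the generator's invariants (footprint
sizes within ±2 of the request, footprints within the surface, epitope
identity, alignment coverage). `scenario_multi_ab()` extends the world
to several antibodies in disjoint epitope groups for binning tests.

What the toys deliberately do **not** emulate: side-chain packing and
rotamers (so the stability filter exercises only the coarse potential),
conformational change on binding, buried cores (the helix is almost all
surface), sequence-dependent docking errors, and experimental noise in
binding assays. Passing the synthetic suite therefore demonstrates the
correctness and determinism of the algorithms — not wet-lab
transferability of any particular panel.

## Problem sizes used by the tests and the acceptance script

The test suite runs the full pipeline on fifty seeded scenarios with a
60-residue antigen, 20 poses and triple mutants — large enough that
footprints overlap heavily and the covering search is non-trivial, small
enough to iterate comfortably — and the baseline at 200 replicates of
1000 random triples per scenario. The acceptance script uses thirty
scenarios and the same baseline sizes. These sizes are the package's
choices for a self-contained, deterministic study; nothing in the
algorithms depends on them.

## Known limitations

* The covering panel is not guaranteed minimal: selection is constrained
  to one design per spatial cluster, and when two members of an optimal
  cover are mutual nearest neighbors no K-medoids partition separates
  them. With restart probing this affects a few percent of small random
  instances, overshooting the optimum by one design.
* The default stability scorer has no repacking and no backbone
  relaxation; it is a filter, not a ΔΔG predictor. For real campaigns a
  dedicated stability method can be plugged in as the scorer.
* The default pair potential is a two-channel physicochemical surrogate.
  It preserves the design problem's structure (partial independence of
  binding and stability objectives) but not the statistics of any
  particular published potential; swap in a preferred matrix for
  production use.
* On the small toy antigens of the synthetic suite the random baseline
  is only modestly below the guided pipeline's success rate: with ~50
  surface residues, a matched panel of 3–5 spread-constrained triples
  already samples much of the helix. The baseline's value there is the
  strict ordering (and its confidence interval), not the size of the gap,
  which grows with antigen size.
* Dock-overlap percentages depend on the Jaccard matching threshold; the
  default 0.25 is a labeled convention.
* f_nat matching assumes reference and pose share antigen and antibody
  residue numbering; no alignment is attempted.
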