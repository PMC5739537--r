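# episcope

Docking-guided design of antigen variant panels for antibody epitope
localization.

## The problem

Knowing *where* an antibody (Ab) binds its antigen (Ag) — the epitope —
shapes everything from mechanism-of-action studies to vaccine design, but
newly isolated antibodies usually come with a sequence and nothing else.
Crystallography is slow and expensive; alanine scanning needs dozens of
variants; purely computational epitope predictors are not yet reliable
enough to act on alone.

Antibody–antigen docking sits in between: modern docking servers almost
always place a near-native pose *somewhere* in their top ~30 models, but
cannot tell you which one it is. `episcope` treats those docking models as
a set of competing, testable hypotheses. For each pose it designs antigen
variants carrying a few point mutations predicted to disrupt that pose
(while preserving antigen stability), then selects a minimal panel of
variants such that **every** docking model is predicted to be disrupted by
at least one variant. Expressing the panel and testing antibody binding
then localizes the epitope: a variant that ablates binding pins the
epitope to its mutated positions and to the docking models consistent
with that disruption.

The package is aimed at computational structural biologists and antibody
engineers: it takes an antigen structure (PDB), a directory of docking
poses, and a homolog alignment, and returns a ranked, clustered,
covering panel of multi-mutant variants as tidy tables.

## The method in brief

1. **Surface and footprints.** Residues with relative solvent
   accessibility (Shrake–Rupley SASA over per-residue reference maxima)
   above 7% form the mutable surface. Each docking model's *footprint* is
   the set of antigen residues with a heavy atom within 5 Å of the
   antibody pose.
2. **Candidate mutations.** At each footprint ∩ surface position, only
   substitutions observed among homologs are considered
   (evolutionarily-accepted changes); a substitution is kept for a pose
   only if its contact-potential score change toward that pose is
   disruptive (positive, in this package's sign convention).
3. **Per-pose designs.** Sets of up to `k` mutations (default 3) are
   enumerated and filtered: mean pairwise Cα distance ≤ 12 Å, predicted
   stability change ≤ 0. The surviving designs form the Pareto frontier
   over (maximize disruption, minimize stability cost).
4. **Merge.** A mutation touching several poses must disrupt *all* of
   them; repeated positions are unified to the most disruptive surviving
   substitution; duplicates collapse.
5. **Panel selection.** Designs are clustered by the Hausdorff distance

   `h(A,B) = max( max_a min_b d(a,b), max_b min_a d(a,b) )`

   between their mutated-Cα point sets, using K-medoids (PAM). K grows
   from 1 until some combination of designs, one per cluster, covers all
   coverable docking models; among covering combinations the one with the
   highest summed disruptiveness wins.
6. **Evaluation.** Against a curated epitope list or a 5 Å co-crystal
   interface, localization succeeds when some design mutates an epitope
   residue. Interface quality of docking models is measured with the
   CAPRI-style f_nat (fraction of native contact pairs reproduced).

Multiple antibodies against one antigen can be pooled into a single
hypothesis set (one panel probing all of them), and pairwise
dock-overlap / design-distance matrices provide in-silico epitope
binning.

## Worked example

Everything below runs offline on a synthetic scenario: a 60-residue
helical toy antigen, 20 docking poses of ~50-atom antibody pseudo-bodies
(one of them flagged as the true pose), and a synthetic homolog
alignment.

```r
library(episcope)

sc  <- make_scenario(n_res = 60, n_models = 20, seed = 7)
run <- run_scenario(sc)
run$panel
#> <episcope_panel> 8 design(s) at K = 8 covering 20/20 model(s)
#> # A tibble: 8 × 4
#>   design_id label          n_covered total_disruption
#>   <chr>     <chr>              <int>            <dbl>
#> 1 D03       A17C;R19I;R23C         6           4.43
#> 2 D07       G36I;P38I;S39I         5           6.70
#> 3 D13       N54I;H55I              3           5.01
#> 4 D15       P41M;T43I;L47I         6           2.45
#> 5 D17       P6M                    1           0.0691
#> 6 D18       R23C;R25C;R29C         4           5.57
#> 7 D24       R8L;T13F               4           3.36
#> 8 D32       W49F;N54I;H55I         4           6.02

localization_success(run$panel, sc$epitope)
#> # A tibble: 1 × 3
#>   success hit_designs n_hit
#>   <lgl>   <list>      <int>
#> 1 TRUE    <chr [2]>       2
```

Eight variants (mostly triple mutants; positions with fewer candidate
sites yield smaller designs) interrogate all 20 docking hypotheses, and
two designs overlap the true pose's footprint, so a binding assay on this
panel would localize the epitope. `tidy(run)` and `glance(run)` return the panel and its
one-row summary as tibbles, `autoplot(run$panel)` draws the design ×
model coverage map, and `write_panel_tsv()` / `write_panel_json()` export
it.

With real inputs the entry points are the same:

```r
e   <- load_ensemble("docks/", ag_chain = "A")      # ClusPro-style poses
msa <- read_msa_fasta("homologs.fasta")             # antigen row first
run <- run_episcope(e, msa = msa, params = design_params(k = 3))
```

A thin command-line wrapper with `design` / `evaluate` / `bin` /
`simulate` / `stats` subcommands ships at `inst/cli/episcope.R`.

The packaged retrospective benchmark table (33 antibody–antigen pairs) is
available via `packaged_retrospective()`, with
`summarize_retrospective()` recomputing its column means, success rates
and rank correlations; `packaged_prospective()` holds the B7H6
two-antibody design panels as output-format fixtures.

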