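---
title: "Methods: signed Jaccard reversal analysis of drug and disease signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed Jaccard reversal analysis of drug and disease signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gesreversal)
```

## The scientific question

A gene expression signature (GES) is the pair of up- and down-regulated
gene sets induced by a perturbation. The reversal hypothesis of GES-guided
drug repositioning says: if a drug's signature is *opposite* to a disease's
signature, the drug is a candidate treatment for that disease.
`gesreversal` quantifies how well this hypothesis holds on collections of
curated signatures, and — because the effect is known to be weak overall —
*where* it holds: which classes of drugs and diseases show a reliably more
inverse pattern for truly indicated drug–disease pairs than for arbitrary
ones.

## Similarity model

Two direction-labelled signatures are compared with the signed Jaccard
index (SJI). With $J(A, B) = |A \cap B| / |A \cup B|$ the ordinary Jaccard
coefficient,

$$\mathrm{SJI}(G_1, G_2) = \tfrac{1}{2}\left[
  J(G_1^{up}, G_2^{up}) + J(G_1^{down}, G_2^{down})
  - J(G_1^{up}, G_2^{down}) - J(G_1^{down}, G_2^{up})\right]$$

which ranges from $+1$ (identical pattern) to $-1$ (perfectly inverse
pattern); $0$ means no overlap or same- and cross-direction overlap
cancelling. The score is deliberately unranked (set-based): the source
collections publish gene lists, not comparable effect sizes.

Numerical conventions:

* A Jaccard term with two empty sets is defined as 0. Real curated
  signatures always have genes, but empty directions can arise in
  subsetted or simulated data and must not produce `NaN`.
* The four terms are combined as
  `((J_uu + J_dd) - (J_ud + J_du)) / 2`. Because IEEE addition is
  commutative, this grouping makes two properties hold *bit-exactly*, not
  just to tolerance: symmetry in the two arguments, and antisymmetry under
  swapping one signature's up and down sets.
* Gene symbols are matched verbatim after uppercasing and whitespace
  stripping. No alias dictionary is applied: alias resolution would change
  intersection counts in ways that cannot be validated against the source
  collections.
* A gene listed in both directions of one signature is dropped from both
  (with a warning): its direction is contradictory, and keeping it would
  inflate both the same- and cross-terms.

`pairwise_sji_matrix()` evaluates all drug-by-disease combinations through
gene-by-signature incidence matrices and cross-products; the test suite
asserts exact (zero-tolerance) agreement with the set-based
`signed_jaccard()` on every pair, and both against a brute-force
per-gene membership oracle.

## Inclusion protocol

Curated collections mix organisms and annotation quality, so signatures
pass a filtering protocol before analysis, applied in a fixed order so
every exclusion has one reason:

1. organism not on the allow-list (matching is case-insensitive through a
   shipped synonym table, so "Homo sapiens" matches "human");
2. drug signatures whose drug is not on the supplied approved-drug list
   (an explicit input snapshot — approval is time- and agency-dependent,
   so the package never guesses);
3. signatures on an explicit exclusion list of mis-specified entries;
4. series that contributed both a drug and a disease signature: the same
   assay feeding both sides would bias similarity, so one side is dropped
   (`keep_disease` by default, matching how such collisions are resolved
   in curated practice; `keep_drug` and `drop_both` are available).

Finally `prune_unpaired()` removes drug signatures whose drug has no
indicated disease among the retained disease signatures and vice versa,
iterating to a fixed point (removing one side can orphan the other). The
filter report accounts for every input signature exactly once.

## Pairing and overall statistics

Every retained drug signature is scored against every retained disease
signature. A *unique pair* is a (drug name, disease name) combination; its
overall score is the unweighted mean of all its signature-level SJIs
(signature counts are retained so a weighted variant remains possible
downstream). Pairs whose disease appears in the drug's indication table
are the indicated group; *all* remaining unique pairs form the control
group — no sampling, so the control is the full screening background.
The indicated-vs-control mean difference is tested with a two-sided
t-test; the pooled-variance variant is the default for consistency with
the subgroup linear model (Welch by flag).

## Subgroup model: LS-means slice F tests

Pairs are annotated in five categories: ICD-11 level-1 class of the
disease, drug main-target subfamily (after an optional grouping map, e.g.
the three beta-adrenergic receptors collapse into one subfamily),
transcription-factor level of the drug's targets
(`directly` / `not_directly` / `non_human`), chemotherapy status (defined
by eight DNA/microtubule/nucleotide-synthesis target classes; a drug whose
main targets span both sides carries both labels), and ATC level-3 code
(route-specific codes unified to the systemic variant). `disease_class`
and `tf_level` partition the annotated pairs; the other categories may
multi-label. Pairs missing an annotation are dropped from that category
only, which maximizes usable data; the drop is logged.

Within one category the package fits a cell-means model on the unique-pair
SJI with cells (subgroup x indication) and, for each subgroup, tests the
indicated-vs-control least-squares-mean difference with the model-wide
pooled residual mean square:

$$F = \frac{(\bar y_I - \bar y_C)^2}{MSE\,(1/n_I + 1/n_C)},
  \qquad df = (1,\; N - \#\text{cells})$$

This is the classical "slice" (partition) test of an interaction model,
the construction implied by least-squares-means practice on unbalanced
designs. The design was genuinely open in two places and the choices are
deliberate:

* **One model per category**, not a single global model: the categories
  overlap heavily on the drug side, and cross-category interactions are
  neither identifiable at these sample sizes nor part of the reporting
  layout the analysis mirrors.
* **Pooled MSE** rather than per-subgroup variances: subgroup sizes are
  tiny (down to a single indicated pair). The pooled MSE makes a subgroup
  with $n_I = 1$ testable — its SD is reported as undefined
  (`"----------"` in the TSV) but its mean difference still has a
  variance estimate.

The implementation is validated against an independent
`lm()` + `emmeans` oracle in the tests. Because subgroups with only one
indication level are untestable, they are reported with `NA` statistics
rather than silently dropped.

Multiple testing: all tested subgroups across all five categories form a
single Benjamini–Hochberg family by default (the report mixes categories
under one q-value column); a per-category family is available by flag.
`bh_fdr()` delegates to `stats::p.adjust(method = "BH")` and is checked
against a hand-written step-up oracle.

## Gene-level reversal score

For a chosen subgroup (by default the one with the smallest q-value), the
score works at the assay level: over all signature pairs behind the
subgroup's indicated unique pairs, and over all signature pairs behind
control pairs involving the subgroup's drugs, each gene accrues counts
$NS$ (same direction in drug and disease signature) and $NR$ (reverse
direction). Then per group

$$D\% = 100\,\frac{NS - NR}{\text{total pairs}}, \qquad
  G^{I\text{-}R}\% = D^I\% - D^R\%$$

Pairs in which the gene is absent count in the denominator only — the
formula divides by *all* assay pairs; a presence-restricted denominator
(`NS + NR`) is available as a sensitivity flag. Note the difference of two
quantities each bounded by $\pm 100$ ranges over $\pm 200$, although the
score is often described as a percentage on $\pm 100$; the package
implements the formulas as written and does not rescale. Genes are ranked
ascending (most negative = most reversed first) and the top fraction or an
explicit count is exported as text and GMT; ties at the cutoff break by
gene symbol, so selection is deterministic.

## Synthetic studies and what they do (not) show

`generate_study()` builds a complete study with known structure. Its
defaults are the package's reference conditions and were fixed once:

* 20 drugs, 25 diseases, a 1000-gene universe; 1–3 signatures per entity
  with 20–50 genes per direction — the scale of a small curated
  collection, where a unique pair averages a handful of signature pairs;
* indication density 0.05 (indications are rare relative to the full
  drug-by-disease crossing, a few percent in curated data), plus three
  structurally guaranteed indications into the sensitive disease class so
  the planted subgroup is always testable;
* one sensitive subgroup, a disease class: each drug indicated for a
  sensitive disease builds all its signatures against that disease's first
  signature, copying a fraction $\rho$ (`reversal_strength`) of its genes
  with direction flipped — the reversal hypothesis taken literally;
  $\rho = 0$ disables planting and gives a pure null study;
* `background_overlap` 0.02: non-planted signatures draw a small fraction
  of their genes from the pooled disease genes with random direction,
  emulating shared housekeeping biology without directional signal.

Each generation stage derives its own child seed from the study seed, so
adding a stage never perturbs earlier ones and studies are byte-identical
across runs. Ground truth records the planted genes, the
(drug, target-disease) pairs actually planted — a drug indicated for two
sensitive diseases reverses only its designated target, so guarantees
about negative SJI attach to planted pairs, not to every indicated
sensitive pair — and the post-pruning pair bookkeeping.

The generator is set-based by design: the analysis never sees expression
values, so simulating them would add realism the statistics cannot use.
Consequently, passing tests show that the pipeline recovers planted
set-level reversal structure at realistic sizes and controls false
positives under the null; they do not show that real drug–disease
collections contain such structure, nor do they capture tissue mismatch,
curation noise, or correlated signatures from related assays.

Validation conditions used by the test suite (chosen as study conditions,
not tuned to outcomes): null calibration over 200 seeds at $\rho = 0$
(subgroup false-rejection fraction within Monte-Carlo bounds of the 0.05
FDR level, overall t-test p-values uniform); detection of the sensitive
subgroup at $\rho = 0.8$ over 50 seeds; recovery of planted genes at
$\rho = 1$ with recall at least 0.9 at a list size equal to the planted
set.

## Degenerate inputs and edge rules

* Both-groups-zero-variance t-test with equal means returns $p = 1$;
  with unequal means it is an error (no variance estimate exists).
* A category whose model has no residual degrees of freedom raises an
  error advising merged subgroups.
* An empty indicated group anywhere is an error, not an empty result —
  indicated-vs-control quantities are undefined without it.
* `select_top_reversed(fraction =)` takes `floor(n * fraction)` genes; an
  explicit `count` reproduces selections whose published size does not
  match any simple rounding rule.

## Known limitations

* Name-keyed identity: a drug measured in several series is one drug;
  there is no structure-level identity resolution.
* The control group is every non-indicated pair; known contraindications
  are not excluded (they are not part of the input contract).
* Annotation content (targets, TF lists, ATC, ICD-11, approval) is
  consumed as curated tables; the package ships only small synthetic
  fixtures, labelled as such.

## Typical session

```{r, eval = FALSE}
study_dir <- tempfile("study")
simulate_study_dir(simulation_config(seed = 7, reversal_strength = 0.8),
                   study_dir)
cfg <- run_config(
  signatures_json = file.path(study_dir, "signatures.json"),
  indications_tsv = file.path(study_dir, "indications.tsv"),
  annotations_dir = file.path(study_dir, "annotations"),
  out_dir = file.path(study_dir, "results")
)
manifest <- run_pipeline(cfg)
str(manifest$overall_t_test)
```
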