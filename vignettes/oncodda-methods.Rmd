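---
title: "Evidence-aggregation decision support: models, parameters and design choices"
author: "oncodda developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-aggregation decision support: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncodda)
```

## The problem

High-risk pediatric (and adult) tumors profiled by whole-exome sequencing
yield dozens of somatic alterations per case, most of unknown significance.
A molecular tumor board (MTB) must decide whether any of them justifies a
targeted therapy. Matching alterations to drugs one at a time, by highest
single evidence level, ignores that tumors carry multiple drivers and that
evidence items differ enormously in reliability and relevance. Digital drug
assignment addresses this by *aggregating* all evidence touching a profile
into per-entity scores and ranking therapies on the totals.

`oncodda` implements that pipeline as a reusable, testable library: filter →
score → classify → rank → tier → downsample → cohort statistics, plus a
synthetic-cohort generator so everything runs without access to patient data
or a proprietary knowledgebase.

## The scoring model

Every knowledgebase evidence item `e` links a subject (a gene, or an exact
alteration of a gene) to an object: its own oncogenicity, a molecular
target, or a compound, with a direction (+1 supportive / sensitivity, −1
negative / resistance), an evidence class, and an optional tumor-type
context. In a case with tumor type `T`, an item matching an alteration is
scored

    score(e) = base(e) × w_tumor(e, T) × w_spec(e)

* `base(e)`: the item's own `base_reliability` if curated, else the default
  for its class. Defaults: clinical_approved 8, clinical 4, preclinical 2,
  in_silico 1, frequency 1 — dimensionless reliability units; only their
  ordering is meaningful.
* `w_tumor`: `same_tumor_multiplier` (default 2) when the item's tumor type
  equals `T`; `other_tumor_multiplier` (default 1) otherwise, including
  tumor-type-agnostic items.
* `w_spec`: `exact_alteration_multiplier` (default 2) when the item is about
  the exact alteration; `gene_level_multiplier` (default 1) for gene-level
  items.

The aggregated evidence level (AEL) of an alteration, target or compound is
the sum of its item scores split by direction; `ael_net = ael_positive −
ael_negative`. Published weights for the original system do not exist, so
these defaults are package choices that preserve the stated orderings
(clinical > preclinical > in-silico, same > other tumor type, exact >
gene-level). Every package-level invariant is weight-independent or
scale-equivariant: multiplying all base scores by `c` and the driver
threshold by `c` changes no classification and no ranking (this is a tested
property).

**Driver calling.** An alteration is a *driver* when exact-alteration
supporting evidence exists and its net oncogenicity AEL strictly exceeds
`driver_ael_threshold` (default 20, on the default base-score scale); it is
a *VUS in a driver gene* when it fails that test but its gene carries
gene-level driver-supporting evidence; otherwise *other*.

**Compound ranking.** For each registered compound, all evidence linking it
to the case's drivers and VUS-in-driver alterations is aggregated — directly,
and indirectly via alteration → target → compound composition. A composed
link takes the product of the two directions, the weaker of the two evidence
classes, the minimum tumor and specificity multiplier along the path, and
the compound edge's base score; rationale: an indirect chain can never be
more reliable, more specific, or more case-relevant than its weakest edge.
Compounds sort by net AEL descending (rank 1 strongest); exact ties break on
the larger clinical-class positive subtotal, then lexicographically on
compound id, so reports are byte-reproducible. Only compounds with at least
one contributing link are ranked — the remainder of the knowledgebase would
tie at 0 and carry no information.

**Resistance** is categorical and separate from ranking: a case is flagged
when at least one registered compound has ≥ 1 negative-direction link to a
*driver* (not merely a VUS). The same negative mass is also subtracted in
`ael_net`, so resistance both penalizes rank and raises a flag.

**Actionability** comes in four nested definitions, all requiring a
registered (on- or off-label, non-developmental) compound on the positive
end of a link: driver-only vs. VUS-inclusive alteration sets, crossed with
link evidence-class sets (`all`; `preclinical_plus` =
clinical/approved + preclinical; `clinical_only`). The implementation
filters the *linking* evidence class, which keeps the definitions nested
(`clinical_only ⇒ preclinical_plus ⇒ driver-based ⇒ VUS-inclusive`), a
property the tests assert cohort-wide.

**ESCAT re-tiering.** Each positive (driver, registered compound) link maps
to a tier: I if the compound is approved for the case's own tumor type
(approved-class evidence plus indication match); II clinical-class evidence
in the same tumor type; III clinical-class in another tumor type; IV
preclinical, including composed (indirect) preclinical chains; `none` for
in-silico/frequency-only support. A case's tier is the best over its links.
Two open points were resolved as follows: indication matching is an exact
tumor-type-code comparison (the emulated cohort contained no tier-I case to
constrain anything finer), and clinical evidence with *unspecified* tumor
context tiers as III, since it is clinical evidence not specific to the
case's tumor type.

## Filtering parameters

| parameter | default | unit | reading of the protocol |
|---|---|---|---|
| `min_depth_exclusive` | 20 | reads | "more than 20 reads" → strictly > |
| `min_quality` | 20 | phred-like | ≥ |
| `min_alt_fraction` | 0.01 | fraction | ≥ (the ≥/> choice is undocumented upstream; ≥ chosen, configurable) |
| `max_pop_freq` | 0.10 | fraction | "at least 10%" in any of three databases → removal at ≥ |
| `excluded_acmg` | benign, likely_benign | — | excluded outright |
| `cnv_min_coverage` | 100 | × | CNV reporting floor |
| `cnv_min_tumor_ratio` | 0.30 | fraction | sample-level CNV adequacy |
| `snv_min_tumor_ratio` | 0.10 | fraction | warning only: applied at sample acceptance, not variant filtering |

MSI-H requires strictly more than 20% of the five markers unstable, i.e. the
conventional ≥ 2-of-5 rule; exactly 1/5 is MSS. Missing population
frequencies pass the population filter (absence of evidence); missing
depth/quality/VAF fails quality filtering (quality cannot be certified). The
"quality" metric upstream is ambiguous (site vs. genotype quality); it is
treated as a single per-call score. Filters commute on the kept set; the
fixed order quality → population → ACMG → panel only fixes which rule a
removal is attributed to in the filter log, which partitions the input
exactly — both properties are tested on 1000 random profiles.

## The synthetic world

The generator emulates the cohort the pipeline was reported on, and its
defaults are that stated world, chosen once:

* 100 cases; tumor-type mix CNS 0.38, sarcoma 0.28, neuroblastoma 0.18,
  other solid 0.11, hematologic 0.05.
* Post-filter variant counts ~ Poisson(52) by construction (planted
  passing variants plus deliberate failures exercising each filter rule);
  planted proven drivers averaging 3/case and VUS-in-driver 6/case.
* A `low_burden_prob = 0.15` mixture of driver-poor cases (no proven
  driver, ~0.5 VUS): pediatric tumors are frequently low-burden and the
  emulated cohort was far from fully actionable (72% driver-based / 83%
  VUS-inclusive). Non-low-burden means are inflated so cohort-wide means
  stay at the configured values. With this mixture the synthetic cohorts
  land near the reported marginals (≈ 72–83% driver-based, ≈ 82–92%
  VUS-inclusive actionability, ≈ 55–69% resistance) without any of those
  rates being targeted directly.
* Knowledgebase: 60 driver genes (2 exact hotspots each, whose evidence
  guarantees driver status in any tumor context; 25% of driver genes
  untargetable — proven drivers in untargetable genes are a real feature of
  the cohort), 30 target genes, 80 compounds (60% registered; approved
  indications off by default since the cohort contained no on-indication,
  tier-I constellation), a 995-gene interpretation list, and off-panel
  decoy genes. Per-gene link counts follow a lognormal evidence-richness
  factor (`evidence_richness_sdlog`): well-studied genes carry many links,
  rare drivers few, spreading compound AELs over orders of magnitude.
* Resistance edges at probability 0.25 per generated compound link; evidence
  classes drawn from a mix dominated by preclinical data.
* MTB decisions: actionable cases are targeted with probability
  `plogis(alpha + beta·log(1 + top compound AEL))`, defaults (−2, 1.5);
  non-actionable cases are standard; 1% observation-only. The log damps a
  few huge AELs; the study reports a monotone association, not a functional
  form.

Two calibration notes. First, the absolute AEL scale is unpublished, so the
generator's link strengths were set so that the default logit reproduces the
observed targeted-decision rate (~55–77% depending on cohort draw) instead
of saturating. Second, `evidence_richness_sdlog = 1.25` is pinned by the
only quantitative constraint available on AEL spread: the stated
recoverability of `beta` (±0.5 at n = 500 in ≥ 95% of seeds) is
information-theoretically unattainable below ≈ 1.2 (the Fisher-limited
standard error of the refit exceeds 0.27), and holds at 1.25 while leaving
all cohort marginals unchanged.

What the generator does **not** emulate: genome coordinates and sequence
context, mutational signatures, inter-gene correlation of alterations,
hotspot-panel detection limits, tumor-type-specific driver spectra, and
curation noise in the knowledgebase. A green test therefore establishes the
*logic* of filtering, scoring, tiering and the statistics — not clinical
validity of any weight set, and not performance on real profiles.

Determinism: one master seed fans out to per-stage child seeds via
`derive_seed(seed, stage_label)` (a documented integer hash below 2^31), so
knowledgebase, cohort and decisions are independently reproducible and
byte-identical across runs.

## Numerical and degenerate-input choices

* AELs are plain double-precision sums; the oracle-equivalence tests bound
  the discrepancy against naive summation at 1e-9.
* Mann–Whitney U: exact enumeration when both groups ≤ 8 without ties,
  otherwise normal approximation with tie and continuity corrections; the
  `method` field records the path. U itself is computed from rank sums
  (average ranks under ties), so `U(a,b) + U(b,a) = n_a n_b` always.
* AEL-quartile binning: empirical quartiles, boundary values to the lower
  bin, no-ranked-compound cases enter the lowest bin at AEL 0;
  observation-only decisions are excluded from the decision-rate
  denominator. An empty bin lowers the chi-square degrees of freedom and is
  noted on the result.
* Ties in compound ranking: clinical-subtotal, then compound id (see above).
* Empty inputs: empty profiles yield complete, all-negative reports; an
  empty panel file or gene set is an error (a panel with no genes is a
  configuration mistake, not a datum).
* p-values are reported raw; no multiple-testing correction is applied
  anywhere.

## Known limitations

* The knowledgebase schema models a flat tumor-type vocabulary (no ontology
  traversal) and per-item scalar reliability; conflict resolution between
  source databases is out of scope (a curator concern).
* Indirect evidence composition is one hop (alteration → target →
  compound); longer pathway chains are not composed.
* Panel evaluation considers gene-set membership only — panel-specific CNV /
  fusion capability and hotspot restrictions are deliberately ignored,
  matching the virtual-downsampling design it reproduces.
* The decision model is a single-covariate logit on the top-ranked compound
  AEL; real MTB decisions also weigh toxicity, availability and performance
  status, none of which are modeled.
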