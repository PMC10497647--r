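# oncodda

Digital drug assignment (DDA) decision support for precision oncology, as an
R package. It reimplements, end to end and fully testable on synthetic data,
the analysis pipeline used by molecular tumor boards (MTBs) to turn a
patient's somatic variant profile into ranked, evidence-backed treatment
options:

1. **Variant filtering** — annotated exome/panel variant tables are reduced
   to a case profile (read depth > 20, call quality ≥ 20, alternate-allele
   fraction ≥ 1%, population allele frequency < 10% in 1000 Genomes / ExAC /
   NHLBI ESP, ACMG benign and likely-benign excluded, restriction to a
   virtual panel of ~1000 tumorigenesis genes), plus ingestion of FISH / IHC
   / MSI results (MSI-H when > 20% of the five mononucleotide markers NR-21,
   NR-24, BAT-25, BAT-26, MONO-27 are unstable).
2. **Evidence aggregation (AEL)** — each parameterized evidence item linking
   an alteration to its oncogenicity, a target, or a compound is scored as

   `score(e) = base(e) × w_tumor(e) × w_specificity(e)`

   where `base` reflects data reliability (clinical > preclinical >
   in-silico / frequency), `w_tumor` up-weights same-tumor-type evidence and
   `w_specificity` up-weights exact-alteration over gene-level evidence. The
   **aggregated evidence level** of an entity is the weighted sum, split by
   direction: `AEL_net = Σ_{e: +} score(e) − Σ_{e: −} score(e)`. An
   alteration with exact supporting evidence and oncogenicity `AEL_net > 20`
   is a proven **driver**; an unproven variant in a gene with gene-level
   driver evidence is a **VUS in a driver gene**.
3. **Ranking and case classification** — registered compounds (approved on-
   or off-label; developmental compounds excluded) are ranked by net AEL
   over all direct and target-routed links to the case's drivers and VUS
   (rank 1 = strongest support); cases get actionability flags under four
   definitions, a resistance flag (≥ 1 registered drug negatively associated
   with a driver), and an ESCAT tier (I approved same indication, II
   clinical same tumor type, III clinical other tumor type, IV preclinical /
   indirect).
4. **Virtual panel downsampling** — exome results restricted to commercial
   panel gene sets, with or without non-NGS findings, re-scored to estimate
   actionability retention, strongest-driver coverage, and MTB decision
   concordance.
5. **Cohort statistics** — actionability by year / tumor type, Mann–Whitney
   U of AEL by MTB decision, chi-square of targeted-decision rate across AEL
   quartiles, driver landscape tallies.
6. **Synthetic data** — a generator producing knowledgebases and 100-case
   cohorts with the reported structure (tumor mix CNS 38% / sarcoma 28% /
   neuroblastoma 18% / other 11% / hematologic 5%; ≈ 52 filtered variants,
   ≈ 3 drivers, ≈ 6 VUS-in-driver per case) and a logistic decision model
   `P(targeted) = logistic(α + β·log(1 + AEL_top))`, so every stage is
   testable offline.

It is intended for methodologists studying evidence-aggregation scoring,
panel design, and MTB decision statistics — not for clinical use.

## Worked example

```r
library(oncodda)

cfg     <- synth_config(seed = 1)                     # the stated 100-case world
kb      <- generate_knowledgebase(cfg)
cohort  <- generate_cohort(cfg, kb)
fcfg    <- filter_config(virtual_panel = virtual_panel_genes(kb))

cs      <- cohort[[1]]
profile <- run_filter_pipeline(cs$variants, cs$meta, fcfg)
profile
#> <dda_profile CASE001/sarcoma> 58 filtered variants, 0 non-NGS findings, 80 input rows logged

report <- build_case_report(profile, kb)
report
#> <dda_case_report CASE001/sarcoma> 4 drivers, 20 ranked compounds, ESCAT III
#>   actionable: driver=TRUE vus=TRUE preclin+=TRUE clinical=TRUE; resistant=TRUE; 20 associated drugs

head(report$drivers[, c("gene", "alteration", "ael_net", "rank")], 3)
#>    gene alteration ael_net rank
#> 1 DG047    p.X436O      32    1
#> 2 DG058    p.L338Z      30    2
#> 3 DG047    p.S731S      28    3

head(report$compounds[, c("compound_id", "ael_net", "rank")], 3)
#>   compound_id ael_net rank
#> 1        C021    8.00    1
#> 2        C024    7.39    2
#> 3        C012    4.50    3
```

80 raw variant calls were filtered to 58 (each removal logged with its first
failing rule); four alterations exceed the driver threshold (top driver
DG047 p.X436O, oncogenicity AEL 32); twenty registered compounds carry
evidence links, the best-supported one (C021, net AEL 8) obtaining rank 1;
the best evidence link is clinical in another tumor type, hence ESCAT III.

The whole pipeline, cohort-level:

```r
run_end_to_end(out_dir = "run1", seed = 1)   # writes TSV artifacts + manifest
```

or from the shell, `inst/exec/oncodda run --seed 1 --out run1`.

## Limitations

The shipped knowledgebase generator stands in for a curated commercial
evidence database; its contents are synthetic and its numeric weights are
package defaults (the published system's weights are proprietary — all
package-level properties are weight-independent or scale-equivariant). See
`vignettes/oncodda-methods.Rmd` for the model, calibration choices and what
a green test does and does not establish.
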