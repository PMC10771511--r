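# ctarmkg

Arm-level efficacy and safety results from ClinicalTrials.gov registered-results XML.

## What this is for

Registered results on ClinicalTrials.gov are a rich, under-used complement to
journal publications — they report negative results and adverse events far
more completely — but they ship as one legacy XML file per study, with two
structural gaps that block synthesis:

1. the statistical-analysis section names its two compared groups without
   saying which is the **intervention** and which the **comparator** (those
   roles live in the study-design section, under often-inconsistent titles);
2. efficacy is reported as free-text p-values and confidence intervals, not
   as a machine-readable verdict.

`ctarmkg` is for evidence-synthesis and pharmacoepidemiology work that needs
registry results in comparable form. It parses the registry dialect and
produces, per analysis row, an intervention-vs-comparator comparison labelled
statistically **positive** or **negative**; matches serious adverse events
(SAEs) to the same arms; types outcomes as **biomarker / patient-reported
(PRO) / clinical endpoint** via MeSH tree numbers; computes a ratio-weighted
SAE category co-occurrence network; and assembles a typed knowledge graph
(Neo4j bulk CSV, GraphML, JSONL, Cypher exports).

## The core rules

**Significance cascade.** For each two-arm analysis:
p-value first — positive iff the stated relation guarantees *p* ≤ 0.05
(`=`, `<`, `≤` with value ≤ 0.05), negative iff it guarantees *p* > 0.05;
undecidable bounds (e.g. `<0.1`) stay *indeterminate*. Without a p-value,
the confidence interval decides by null containment on the closed interval:
null 1 for ratio-type parameters (odds/hazard/risk ratio), null 0 for
difference-type (mean/risk difference, slope, change) — negative iff the
null is contained, else positive. Everything else is indeterminate and never
enters the graph.

**Arm resolution.** Analysis group titles inherit the role (experimental /
comparator) of their most similar design arm: exact title equality
short-circuits; otherwise argmax cosine similarity under a deterministic
character 3-gram embedding backend (pluggable — any
`list(name, version, embed)` works, e.g. a biomedical transformer encoder);
same-role conflicts resolve to the bijective pairing with the larger total
similarity.

**SAE co-occurrence.** For categories *a ≠ b*,
`w(a,b) = Σ_t c_t(a,b) · r_t(a) · r_t(b)` summed over trials *t*, where
`c_t` indicates both categories report affected subjects in the trial and
`r_t(x)` is the per-trial pooled `affected / at_risk` ratio of category *x*.

## Worked example

```r
library(ctarmkg)

# 1. the significance rules on a reported p-value string
p <- parse_p_value("<0.0001")
#> $op: "lt"   $value: 1e-04
classify_significance(p)$label
#> [1] "positive"

# 2. arm resolution: which analysis group is the intervention?
arms <- tibble::tibble(
  title = c("Canagliflozin (JNJ-28431754)", "Placebo"),
  role  = c("experimental", "comparator")
)
resolve_arms(c("Placebo", "Canagliflozin 50 mg"), arms)
#>   intervention_group  comparator_group score_intervention score_comparator method
#> 1 Canagliflozin 50 mg Placebo                       0.586                1 embedding
```

The dose-suffixed analysis title lands on the experimental design arm by
3-gram cosine similarity (score 0.586); "Placebo" matches exactly (score 1).

```r
# 3. a full pipeline run on a seeded synthetic corpus with known ground truth
cfg <- generator_config(n_trials = 50, seed = 42)
gen <- generate_corpus(cfg, "demo_corpus")
res <- process_corpus(scan_corpus("demo_corpus"))

res$funnel
#>       p_value      ci_ratio ci_difference indeterminate      excluded
#>            58            18            11            23             3
#>      positive      negative
#>            37            50

res$graph
#> <kg: 130 nodes, 256 edges>
#>          adverse_event adverse_event_category       intervention_arm
#>                     29                     10                     44
#>                outcome           outcome_type
#>                     44                      3
#>   has_ae     is_a negative positive
#>       94       80       47       35

head(cooccurrence_edges(res$cooccurrence), 3)
#>   category_a              category_b               weight
#> 1 Cardiac disorders       Psychiatric disorders    0.0149
#> 2 Hepatobiliary disorders Psychiatric disorders    0.0142
#> 3 Hepatobiliary disorders Nervous system disorders 0.0112

unlist(evaluate_against_manifest(res$efficacy, manifest_tables(gen$manifest)))
#>       label_agreement intervention_accuracy   comparator_accuracy   n_rows
#>                     1                     1                     1      110
```

Reading the funnel: of 110 non-excluded analysis rows, 58 were decided by
p-value, 29 by confidence interval (18 ratio-type, 11 difference-type) and 23
remained indeterminate; 3 analyses compared more than two groups and were
excluded. 35 positive and 47 negative efficacy edges enter the graph (only
rows from trials with valid design roles can be arm-resolved), plus one
`has_ae` edge per matched serious adverse event. Against the generator's
manifest, every significance label and arm assignment is recovered.

A command-line wrapper covers the same stages file-to-file:

```sh
ctarmkg simulate --out corpus --n 50 --seed 42
ctarmkg all --input corpus --out artifacts
ctarmkg evaluate --input corpus --out artifacts
```

(`ctarmkg` is installed under `system.file("exec", "ctarmkg", package = "ctarmkg")`.)

## Layout

- `R/` — parsing (`read_trial_xml`, `scan_corpus`), significance
  (`parse_p_value`, `classify_significance`, `classify_rows`), arm
  resolution (`resolve_arms`, `ngram_backend`), outcome typing
  (`classify_outcome`, `dictionary_extractor`), safety linkage
  (`extract_safety`, `match_ae_group`, `compute_cooccurrence`), graph
  (`build_graph`, `export_graph`, `query_subgraph`), generator
  (`generate_corpus`), orchestration (`process_corpus`, `run_pipeline`)
- `inst/extdata/` — toy MeSH dictionary and disease-category table backing
  the offline extractor
- `vignettes/arm-level-results.Rmd` — the model, the rules, design
  decisions and limitations
- `tests/testthat/` — unit, property and acceptance tests
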