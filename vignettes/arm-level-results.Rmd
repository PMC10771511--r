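---
title: "Arm-level efficacy and safety results from registry XML: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arm-level efficacy and safety results from registry XML: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctarmkg)
```

## The problem

ClinicalTrials.gov stores registered *results* — statistical analyses of
outcomes and per-arm adverse-event counts — in a legacy per-study XML dialect
that is searchable but hard to synthesise. Two pieces of structure are
missing from the raw records. First, the analysis section names the two
compared groups but does not say which is the intervention and which the
comparator; that labelling only exists in the study-design section, often
under inconsistent titles. Second, each analysis reports a free-text p-value
or confidence interval rather than a machine-readable verdict. `ctarmkg`
reconstructs both: it turns each two-arm analysis into an
intervention-versus-comparator comparison labelled statistically *positive*
or *negative*, links serious adverse events (SAEs) to the same arms, types
outcomes as biomarker / patient-reported (PRO) / clinical endpoint via MeSH,
and assembles everything into a typed knowledge graph.

## The significance rule cascade

Each analysis row is classified by a fixed cascade:

1. **P-value branch.** The raw string is normalized (blanks removed,
   operator extracted, scientific notation accepted). A result is positive
   when the stated relation guarantees $p \le 0.05$ — `eq`, `le` or `lt`
   with a value at most 0.05 — and negative when it guarantees $p > 0.05$.
   A bound that decides neither way (for example `<0.1`) is left
   *indeterminate* rather than guessed: nothing in the reporting rules says
   how such bounds were intended, and misreading them would contaminate
   both tallies.
2. **Confidence-interval branch**, only when no p-value parses. The
   parameter name decides the null value: ratio-type parameters (odds,
   hazard, risk, rate ratios; relative risk) have null 1; difference-type
   parameters (mean or risk difference, slope, change) have null 0. The
   result is negative iff the null lies in the closed interval
   $[\mathrm{lower}, \mathrm{upper}]$. Containment is closed because the
   reported bounds are printed values: a bound exactly at the null cannot
   exclude it.
3. Anything else — no usable statistic, or an interval with an
   unrecognised parameter kind — is indeterminate, and indeterminate rows
   are retained in tables but never enter the knowledge graph or the
   positive/negative tallies.

No multiple-testing adjustment is applied: each row is classified on its
own reported statistic, so the labels mean "statistically significant as
reported", not "true effect". The confidence level (90% vs 95%) is carried
as metadata but does not alter the rule. Non-inferiority analyses pass
through the same cascade and are flagged rather than treated specially; the
reporting format gives no margin information that a dedicated rule could
use.

## Arm resolution

Group titles from the analysis section are matched to design arms by
similarity. The default backend is a deterministic character 3-gram
term-frequency embedding (hashed to a fixed 4096-length vector) compared by
cosine. This was a deliberate design choice over a pretrained transformer
encoder: the procedure the pipeline actually defines is
*similarity-argmax*, and a lexical backend makes it reproducible on any
machine with no model download, while the backend contract
(`list(name, version, embed)`) lets a biomedical sentence encoder be
plugged in unchanged where higher recall on paraphrased titles matters.

The resolution order is: exact case-insensitive title equality
short-circuits (an exact match can never be overridden by an embedding
score); otherwise each group inherits the role of its most similar design
arm; if both groups inherit the same role, the bijective pairing with the
larger total similarity wins. Ties are broken by design-arm document
order. Trials without at least one experimental and one comparator design
arm are excluded — there is no ground truth to inherit. No minimum
similarity threshold is applied by default (bare argmax); `min_score`
exists for users who prefer abstention over weak matches.

For adverse-event arms the same machinery runs with exact string matching
tried first (`match_method = "string"`), falling back to embedding argmax,
which is how titles like "Laquinimod 0.6 mg" land on the efficacy arm
"Laquinimod".

## Outcome typing

Outcome titles are mapped to MeSH terms by a pluggable extractor. The
default is an offline dictionary extractor over a small shipped MeSH
subset (word-bounded, case-insensitive matching); a client for a full-text
indexing service can be substituted via the same contract, and every label
row records the extractor version that produced it. Three independent
rules then fire:

- **biomarker** — any tree number under roots D (Chemicals and Drugs) or E
  (Analytical, Diagnostic and Therapeutic Techniques), excluding the
  E05.318.308.980 "Surveys and Questionnaires" branch, which is
  questionnaire territory, not laboratory measurement;
- **PRO** — any of the keywords Survey, Questionnaire, Patient Reported,
  Patient-Reported, Scale, Score matched case-insensitively in the title
  *or* in any extracted MeSH name (both sources are searched and the
  matching source is recorded per row, since either alone misses cases);
- **clinical endpoint** — any tree number under root C (Diseases) or F03
  (Mental Disorders).

Tree-number matching is dotted-component prefix matching, so F03 matches
F03.600 but never an F030-like code. Labels are a set — an outcome can be
both biomarker and PRO; where a single label is needed for tabulation the
precedence biomarker > PRO > clinical endpoint is used, and is
configurable, because overlap handling in tabulations is genuinely
underdetermined.

## Safety linkage and co-occurrence

Safety extraction keeps serious events with at least one affected subject,
drops per-arm "Total, serious adverse events" aggregation rows, and
quarantines (rather than silently keeping) records with
`affected > at_risk`. Records are retained only for trials that also have
at least one classified efficacy row, so every graph links both facets of
the same study.

The category co-occurrence statistic is
$$ w(a,b) \;=\; \sum_{t} c_t(a,b)\; r_t(a)\, r_t(b), $$
where $c_t(a,b)$ indicates that categories $a \ne b$ both report affected
subjects in trial $t$, and $r_t(x)$ is the per-trial pooled ratio
$\sum \text{affected} / \sum \text{at\_risk}$ over category $x$'s records
in $t$. Two choices here were genuinely open and are fixed as follows:
$c$ is a per-trial *indicator* (not an event-pair count), and $r$ is
computed *per trial* (not pooled over the corpus), with same-category
events pooled by summing counts before the ratio — the only
order-independent choice when events within a category have different
at-risk denominators. Co-occurrence is computed at trial level, matching
the definition of "co-reported". Records without an at-risk denominator
are counted in the affected tables but skipped (and tallied) in the
co-occurrence sum.

## Knowledge graph

Node identity is `(node_type, case- and whitespace-normalized title)`:
the same arm or outcome title reported by many trials becomes one node,
and per-trial provenance (NCT id, comparator, verbatim statistics,
condition list) lives on the edges. The graph never recomputes statistics;
edge attributes carry the reported strings. Multi-condition trials put a
delimited condition list on one edge rather than duplicating edges, so
edge totals stay conserved against row counts (`positive + negative`
edges equal classified, resolved rows; `has_ae` edges equal matched
safety records). Exports: Neo4j bulk-import CSV, GraphML, JSONL, and a
Cypher script that `MERGE`s on `(type, title)` so replays are idempotent.

## The synthetic corpus generator

Real registry dumps are too large and too unstable to pin tests to, so the
package ships a seeded generator that emits the same XML dialect the
parser reads, together with a manifest of every planted truth (arm roles,
intended label and basis per analysis, outcome label sets, retained safety
records and their expected matches). The generator's defaults are the
study conditions of the test suite, chosen once:

- `target_positive_fraction = 0.4361`, the positive share the corpus-wide
  classification reports, so synthetic funnels resemble real ones;
- a p-value dialect mix (45% plain decimals, 20% `<` bounds, 5% `<=`
  bounds, 10% scientific notation, 20% unparseable strings) and
  `ci_only_fraction = 0.25`, so every branch of the cascade — including
  fall-through and indeterminate — appears in any corpus of n ≥ 100;
- `title_noise = 0.2`: each analysis-section group title receives dose
  suffixes, casing changes, occasional typos or truncation at this rate,
  the level at which arm-role recovery is required to stay at or above
  0.95;
- 5% of trials lack valid design roles and 5% of analyses compare three
  groups, exercising both exclusion paths.

What the generator does *not* emulate: realistic trial-size or p-value
distributions, free-text outcome titles beyond its template pools,
multi-arm factorial designs, or the long tail of malformed registry
records. Passing tests therefore demonstrate that the rules are
implemented correctly and recover planted truth through the full XML
round trip — not that any particular corpus-level percentage would
reproduce on a live registry dump, which depends on the dump date and, for
arm matching, on the embedding backend.

## Numerical and degenerate-input choices

- Similarity ties (within 1e-12) resolve to the earlier design arm in
  document order; equal-total pairings resolve to the first group as
  intervention. Both are logged through the recorded scores.
- P-values outside [0, 1] and intervals with `lower > upper` or
  non-finite bounds are treated as parse failures, falling through the
  cascade rather than erroring.
- Counts appear as XML attributes in some registry vintages and as child
  elements in others; both dialects are accepted (and both are generated).
- Empty corpora, design-only registrations, and zero-row stages all
  produce empty, schema-stable outputs instead of failures.

## Problem sizes used in the checks

The shipped test suite and acceptance script run at desk scale: worked
examples on the five printed rows of each table; a 200 x 200 signed bound
grid for the interval rule; 100 seeded corpora of up to 20 trials for the
co-occurrence oracle; 1,000 generated titles for the typing rules; and a
200-trial generated corpus for end-to-end recovery. These sizes give every
rule branch multiple hits while keeping a full run in well under a minute
on one CPU.

## Known limitations

- Analyses with more than two groups are flagged and excluded, mirroring
  the one-to-one comparison schema; multi-arm designs are not decomposed
  into pairwise comparisons.
- No multiple-testing adjustment; labels are per-row reported
  significance.
- The shipped MeSH subset covers the rule branches, not the vocabulary;
  corpus-scale typing coverage requires a full extractor behind the same
  contract.
- Only trials with both efficacy and safety results appear fully linked
  in the graph; safety-only trials are dropped by design.
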