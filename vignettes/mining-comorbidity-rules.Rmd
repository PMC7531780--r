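---
title: "Mining comorbidity rules from clinical features and gene expression"
author: "ClosedARM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining comorbidity rules from clinical features and gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClosedARM)
```

## The problem

Type 2 diabetes mellitus (T2DM), dyslipidemia (DLP) and periodontitis
(PD) are chronic inflammatory diseases that frequently co-occur, and
their interplay is thought to be mediated by a shared systemic
inflammatory state. ClosedARM implements an association-rule-mining
(ARM) view of this question: patients become *transactions*, discretized
clinical measurements and extreme gene-expression states become *items*,
and co-occurrence patterns across the cohort become *rules* whose
quality is quantified rather than assumed.

The package supports two complementary analyses:

1. **Clinical features alone.** Which combinations of glycemic, lipid
   and anthropometric states predict active periodontal disease?
2. **Clinical features + gene expression.** Which joint
   clinical/transcriptomic profiles are specific to a patient group
   (including a healthy control group), phrased as class association
   rules (CARs) whose consequent is the group label?

## The data model

A transaction database is a binary matrix $A_{n \times m}$: row $i$ is a
patient, column $j$ an item — an attribute=value pair such as `FPG=3`
(established diabetes by fasting plasma glucose) or `229026_at=+1` (the
probeset is over-expressed in this subject). For an itemset
$J \subseteq Y$, $J^{\downarrow}$ is the set of transactions containing
every item of $J$ and the support is $\sigma(J) = |J^{\downarrow}|$.

A rule $J \Rightarrow H$ (disjoint, nonempty $J$, $H$) carries four
metrics:

* support $\sigma(J \Rightarrow H) = \sigma(J \cup H)$,
* confidence $\mathrm{conf} = \sigma(J \cup H)/\sigma(J)$ — predictive
  accuracy,
* completeness (recall) $\mathrm{comp} = \sigma(J \cup H)/\sigma(H)$,
* lift $= n\,\sigma(J \cup H)/(\sigma(J)\,\sigma(H))$ — observed
  co-occurrence relative to independence.

Lift is computed on relative frequencies (the factor $n$), so a value of
1 means independence and values above 1 mean positive association; on
raw counts the ratio would be bounded by $1/\max(\sigma(J),\sigma(H))$
and not comparable across cohort sizes. This normalization reproduces
conventional lift tables; it is stated here prominently because the
count-based formula is a common source of confusion.

## Closed frequent itemsets

Enumerating *all* frequent itemsets duplicates information: many
itemsets share the same supporting transactions. ClosedARM therefore
enumerates only the **closed** frequent itemsets — those with no proper
superset supported by exactly the same transactions. The closed family
uniquely determines the support of every frequent itemset, so no
information is lost, while the output (and the number of generated
rules) shrinks dramatically.

`mineClosed()` is a depth-first closure-extension enumerator: a node
holds a closed set $P$ with tid-set $T$; extending by an item $i$
ordered after the last extension and taking the closure yields a
candidate, accepted only when the closure adds no item ordered before
$i$ outside $P$ (the canonical prefix test). This visits each closed set
exactly once. Because the closed family of a database at a given
`minSup` is unique, correctness is defined by *oracle equivalence*:
`bruteForceClosed()` independently enumerates all $2^m$ itemsets on
small universes, and the test suite checks equality on hundreds of
random databases. The closure of the empty itemset (items present in
every transaction) is always reported; it is the empty itemset itself
iff no item is universal.

Rules are generated only from closed sets, but the antecedent and
consequent supports of each emitted rule are computed exactly by tid-set
intersection even when those sub-itemsets are not closed — no
approximation from the closed lattice.

## Clinical discretization

The 29 clinical attributes are discretized with guideline cutoffs
shipped as data (`inst/extdata/clinical_cutoffs.json`, versioned), not
code: glycemic (FPG, HbA1c, HOMA-IR, INS), lipid (TC, HDL, LDL, TG,
N-HDL-C), anthropometric (BMI, WHR, AC), periodontal (% of tooth sites
measures) and mutagenesis attributes. Interval conventions follow the
printed guideline bins exactly, including asymmetric ones: HDL's middle
bin is closed on both ends ($[40, 60]$ mg/dL) with `>60` strict.

Two attributes have stratified cutoffs:

* **WHR** (waist/hip ratio) by sex and raw age in years, with age strata
  $\le 39$, $(39, 49]$, $> 49$. The binary Age *code* (cut at 50) is
  incompatible with these strata, so `discretizeWHR()` takes the raw
  age.
* **AC** (abdominal circumference) by sex: 80/88 cm (women), 94/102 cm
  (men).

Every discretization is total — the bins partition the measurement axis
with no gaps or overlaps — and this is verified by grid scans in the
test suite. A missing measurement produces *no item* for that attribute
(the transaction is simply shorter) plus a warning; missingness is never
imputed.

The CF-only analysis uses the 17 attributes relevant to routine
diagnosis (`cfAttributes()`); mutagenesis and demographic attributes are
excluded there but participate in the joint CF+DEG analysis.

## Expression preprocessing

Three order-fixed steps (`rangeFilter()`, `zNormalize()`,
`ternaryDiscretize()`):

1. **Range filter** — drop probes whose max–min variation is below 0.1
   (on the scale of the input summaries; applied to the raw values, not
   normalized ones). A range exactly 0.1 is kept.
2. **Zero-mean normalization** — per probe,
   $\hat g = (g - \mathrm{avg}(g))/\mathrm{std}(g)$ with the sample
   ($n-1$) standard deviation. Verified post-hoc to mean 0 / sd 1 within
   $10^{-9}$.
3. **Ternary discretization** — $\hat g > 1.0$ yields an over-expressed
   item (probe, +1); $\hat g < -1.0$ an under-expressed item
   (probe, −1); the boundary values themselves yield nothing (strict
   inequalities, "above"/"below").

A practical consequence of normalizing within a 30-subject cohort: if a
group of $k$ subjects is shifted, the attainable $z$ of the shifted
subjects is bounded by $\sqrt{(n-k)/k}$ as the shift grows, so
signatures planted in large groups saturate near $z \approx 1.8$ rather
than growing without bound. The synthetic recovery tests choose shifts
with this in mind.

## The four analyses

* `runCFAnalysis()` — 17-attribute database, `minSup = 14` (absolute
  count), `minConf = 70%`. A rule is *interesting* when its consequent
  is periodontal and contains at least one disease-activity marker:
  `PPDi6mm=2`, or GI/BOP/CALi3-4mm/CALi5mm/SUPP at code 2 or 3.
* `runCardioAnalysis()` — mining universe restricted to the
  cardiovascular/obesity attributes (BMI, WHR, AC, FPG, N-HDL-C) plus
  the periodontal consequents; antecedents may contain cardiovascular
  attributes only. Although one could read the analysis description as
  also allowing cardiovascular consequents, the published rule tables
  show periodontal consequents throughout, and that is what the package
  implements.
* `runDiabeticDlpAnalysis()` — the diabetic-dyslipidemia subset:
  patients of the two T2DM groups with raw TG $\ge 204$ mg/dL and HDL
  $< 38$ mg/dL. These cutoffs are finer than the category codes (TG
  code 3 starts at 200; HDL code 1 ends at 40), so the filter requires
  raw values; when only codes exist an explicit subject-id list is
  accepted instead. Mining parameters are not fixed by the source
  analyses for this subset; the package defaults to `minSup = 5` (the
  smallest support among the reference subset rules) and
  `minConf = 70%`, with the consequent constraint relaxed to any
  periodontal attribute at any code (the reference rules include
  `PPDi6mm = 1` consequents). Lift uses the subset size as $n$.
* `runCFDEGAnalysis()` — the two-phase joint analysis. Phase 1 mines
  CARs (`minSup = 3`, `minConf = 90%`, group label as target) on gene
  items alone; the covered genes (all probes occurring in a phase-1
  antecedent) are then pruned of *conflicting* genes — a gene item
  appearing both in a control-group rule and in a diseased-group rule
  cannot discriminate — and the surviving genes' items together with all
  29 coded clinical features enter phase-2 CAR mining with the same
  parameters.

For CAR mining, closed itemsets are enumerated *within* each class (so
the rule support is the within-class support), while confidence divides
by the antecedent support over the whole cohort; completeness divides by
the class size. Classes smaller than `minSup` are skipped with a
warning.

### Design points that were genuinely open

* **Conflict keying.** "The same value for the control group and the
  other groups" is read at the signed-item level — (probe, +1) in both a
  control and a non-control rule is a conflict, while (probe, +1) vs
  (probe, −1) is not; the conflicting probe is removed with both its
  items. `findConflictingGenes(key = "gene")` switches to probe-level
  keying, under which opposite directions also conflict.
* **Phase-2 gene directions.** By default both items of each retained
  gene enter phase 2 (`geneDirections = "both"`); `"observed"` forwards
  only the directions seen in phase-1 rules.
* **Phase-2 clinical attributes.** All 29 coded attributes participate,
  including demographic and mutagenesis ones, unlike the CF-only
  analysis's 17.
* **Consequent pool membership.** In the CF analyses the consequent must
  consist of periodontal attributes only; antecedents are unrestricted
  (periodontal items may appear there) except in the cardiovascular
  analysis.

## Rule ranking

`rankRules()` encodes the expert selection requirements as a stable
lexicographic sort with descending keys: the number of antecedent items
at clinically *altered* codes (the altered-code sets are part of the
cutoff config), then — for CF+DEG rules — the presence of an
over-expressed (+1) gene item, then confidence, then completeness. The
package encodes only these stated criteria; the final subjective choice
among top-ranked rules is out of scope.

## Numerical conventions

* Metrics are stored unrounded; display and file output round half-up
  to 2 decimals (`roundHalfUp()`), so 22/26 prints as 84.62 and a lift
  of 1.9324 as 1.93. `base::round()`'s half-to-even rule would disagree
  on exact halves.
* All ordering is deterministic: items are radix-sorted by identifier,
  rules by confidence, then rule support, then antecedent key. Re-running
  an analysis on identical inputs writes byte-identical tables; no stage
  outside the synthetic generator uses randomness.
* Confidence thresholds are compared with a $10^{-12}$ slack to absorb
  division noise.
* `minSup` is always an absolute transaction count, never a fraction.

## The synthetic cohort generator

`generateClinical()` / `generateExpression()` emulate the study design
so every stage is testable without the original (non-redistributable)
cohort files: 143 subjects in five groups (28/29/29/29/28) ranging from
poorly controlled T2DM+DLP+PD to healthy controls, a planted 10-patient
diabetic-dyslipidemia subset inside the two T2DM groups, and a
30-subject microarray subset (5/7/6/6/6) with 54,675 probes of which a
92.26% fraction is near-constant (to exercise the range filter) and 20
probes per group carry a planted over/under-expression shift of 3
noise-sd units.

Each group has a planted clinical pattern (attribute → target code)
reflecting its definition; a subject expresses its group's *whole*
pattern with probability `adherence` (default 0.8, one Bernoulli per
subject), otherwise background codes avoiding the target are drawn, so
the planted pattern's support within a group is exactly
Binomial(group size, adherence). Raw measurements are drawn strictly
inside the chosen code's bin, so discretization round-trips exactly —
including WHR/AC, whose bins depend on the subject's drawn sex and age.

What the generator does **not** emulate: probe-level microarray noise
models, batch effects, correlated clinical attributes beyond the planted
patterns, missing data, or any linkage between a subject's clinical
values and their expression profile apart from shared group membership.
Passing recovery tests therefore demonstrate correctness of the mining
machinery under known ground truth, not clinical validity on real
cohorts.

## Problem sizes used in the test suite

Unit tests run on toy databases (≤ 10 transactions × ≤ 12 items, where
the exhaustive oracle is cheap) and on reduced synthetic arrays
(1,500–2,000 probes). The acceptance checks run the full study-sized
generator (143 subjects; 54,675 probes × 30 subjects), 200
random-database oracle comparisons, and 200 seeded cohorts for the
binomial-support check; the complete suite finishes in a few minutes on
one CPU.

## Known limitations

* Reproducing the published cohort's exact rule counts requires the
  original supplementary data files (see the README's reproduction
  section); the package ships only the machinery and synthetic
  surrogates.
* Closed-set enumeration is exponential in the worst case; the intended
  regime is the study's (tens of attributes at `minSup` ≥ 14, or
  thousands of gene items with class sizes ≤ 10, where within-class
  closed sets are bounded by the small number of transaction subsets).
* The phase-1/phase-2 CAR counts are sensitive to the open conventions
  listed above; the switches make the alternatives explorable.
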