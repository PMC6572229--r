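---
title: "Detecting polypathological patients from ICD-9-CM codes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting polypathological patients from ICD-9-CM codes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppdetect)
```

## The detection rule

A polypathological patient (PP) is defined by chronic disease in at
least two of eight clinical categories, A–H. Each category is a set of
subcategories (15 in all), and each subcategory is a list of ICD-9-CM
patterns. `ppdetect` evaluates one hospital-discharge episode — the
multiset of its coded diagnoses — against this rulebook:

* a subcategory fires when any episode code matches any of its
  patterns, unless a code anywhere in the episode matches one of the
  subcategory's *episode exclusions* (the only such rule is the
  V58 chemotherapy/radiotherapy-admission veto on subcategory G.2:
  a neoplasia code during a treatment admission does not, by itself,
  qualify the patient);
* the episode's categories are the letters of its fired
  subcategories; `pp = n_categories >= 2`. A second flag repeats the
  rule ignoring category H, because osteoarticular disease is the
  category most weakly captured by coded data and reporting both
  variants shows how much the decision depends on it.

Diagnosis position (main vs secondary) is ignored: the definition is
about which categories are met, not why the patient was admitted.
Malformed codes are collected into the profile's `invalid_codes` and
skipped — discharge extracts are expected to contain some incomplete
records, and silently dropping them would bias any validity estimate.

### Code matching semantics

ICD-9-CM codes have a 3-character root (`NNN`, `VNN`, `ENNN`) and an
optional 1–2 digit decimal extension. The rulebook mixes granularities,
so the matcher uses hierarchical prefix semantics: a root-level pattern
(`428`) covers the root and every descendant (`428`, `428.0`,
`428.22`); a pattern with an extension (`402.91`) covers itself and any
further subdivision. Ranges (`410` to `414`) are root-level only —
every range in the rulebook is printed at root granularity — and never
cross the numeric/V/E code spaces. Exceptions are prefixes subtracted
from the matched set; the catalog validator refuses an exception that
does not lie inside its parent pattern. Raw input is normalized first:
whitespace, lowercase `v`/`e`, and the dotless MBDS export dialect
(`4280` → `428.0`, split after the third character, after the fourth
for E-codes) are all accepted, since discharge extracts exist in both
spellings and the matcher must be invariant to formatting.

### The catalog as data

The rulebook ships as JSON
(`system.file("extdata", "pp_catalog_default.json", package = "ppdetect")`)
and is the single source of truth; `read_pp_catalog()` /
`write_pp_catalog()` round-trip it (YAML also supported), and the
loader rejects unknown fields, duplicate ids, malformed patterns and
out-of-scope exceptions with locating messages. Some encoding
decisions deserve a note, because the printed source table this
catalog transcribes misaligns several rows:

* sub-assignments follow the disease names, which are unambiguous even
  where the row layout is not: rheumatic heart failure `398.91` sits
  with heart failure (A.1); `446`, `714`, `725` with the autoimmune
  block (B.1); `585`, `403`, `440.1` with chronic kidney disease
  (B.2); cerebral degenerations `331` with the cognitive-impairment
  block (E.3);
* psoriatic arthropathy is encoded as `696.0` (the whole `696` block
  would sweep in uncomplicated psoriasis);
* one printed code under F.2 is not a valid ICD-9-CM code at all and
  is encoded as `357.2`, diabetic polyneuropathy — the only reading
  consistent with "symptomatic neuropathy" (flagged in the catalog's
  `notes`);
* `518.0` and `518.1` are kept under the respiratory category but
  isolated in the catalog file so a user who reads the garbled source
  rows differently can remove them without touching code;
* the anaemia row `280.0–280.9` is read as its two endpoints, not the
  whole block.

All of this lives in the editable catalog document, none of it in code.

## The consensus reference standard

Up to three clinicians assess each episode. The reference PP label is
granted by 2-of-3 majority; with only two assessments, unanimity is
required and a discordant pair is marked *unresolved* and excluded
(with a count) from every downstream statistic — guessing a label
would contaminate the validity estimates. Per-category consensus uses
the same strict-majority rule among the raters who reported a
category breakdown; majority is the only extension of the 2-of-3 rule
that keeps the flag and the categories consistent.

## Agreement and validity statistics

All statistics treat the automated call as the test and the clinical
consensus as the truth criterion.

* **Cohen's kappa** κ = (pₒ − pₑ)/(1 − pₑ). The default confidence
  interval uses the simple asymptotic standard error
  √(pₒ(1 − pₒ)/(n(1 − pₑ)²)); the full Fleiss–Cohen–Everitt variance
  is available (`se_method = "fce"`) and is what the sample-size
  routine uses. The p-value tests κ = 0 with the null-hypothesis
  variance. Degenerate marginals (pₑ = 1) raise an error rather than
  returning a number.
* **Proportions** (observed agreement, Se, Sp, PPV, NPV, accuracy) get
  Wilson score intervals (via `prop.test` without continuity
  correction; Wald available behind a flag). A metric with a zero
  denominator is reported as undefined, never as 0.
* **ICC of category counts**: one-way random-effects,
  absolute-agreement, single-measures, computed in closed form from
  the two-column ANOVA with the F-based interval. The variance model
  is tagged in the output (`model_tag`) because "the ICC" is ambiguous
  across software defaults; a two-way variant is provided for
  sensitivity analysis.
* **Sample size for a kappa study**: the unique 2×2 probability table
  with the anticipated positive marginals (p₁, p₂) and kappa κ₀ is
  built, its Fleiss–Cohen–Everitt unit variance Var₁ computed, and
  n = ⌈z² Var₁ / d²⌉ returned for half-width d. At the design point
  (κ₀ = 0.7, p₁ = 0.40, p₂ = 0.50, 99% confidence, d = 0.05) the
  implied cells are (.375, .025, .125, .475), Var₁ ≈ 0.4896 and
  n = 1300. The companion power statement sometimes attached to this
  design is not part of a precision formula and is not implemented.
* **Confusion-table reconstruction**: published validity studies print
  rounded Se/Sp/PPV/NPV but not the 2×2 table. `reconstruct_confusion`
  searches the reference-positive count P ∈ [1, n−1] exhaustively,
  rounds cell counts from Se and Sp, and keeps the table minimizing
  the summed squared deviation of its four implied metrics (ties to
  the smaller P). The default failure tolerance of 0.005 per metric is
  the rounding slack of values printed to one decimal in percent.
  No multiplicity correction is applied anywhere; each per-category
  row carries its own p-value.

## The synthetic cohort generator

Real MBDS extracts cannot be shipped, so `pp_generate_cohort()`
produces cohorts whose every layer is known:

1. **Truth.** Each of the 8 categories is present independently with
   its configured prevalence. The defaults (A .277, B .138, C .221,
   D .055, E .221, F .097, G .166, H .069) keep cardiac, respiratory
   and neurological disease the most common PP categories and were
   calibrated — jointly with the default rater error rates, by exact
   enumeration over the 2⁸ truth combinations — so that the expected
   consensus-PP prevalence is 0.35, the prevalence regime of the
   validation study this package targets (true-PP prevalence 0.361).
2. **Coding.** A present category emits one concrete code, uniform
   over the subcategory's expanded pattern set, with probability
   `coding_sensitivity` (default 0.85); an absent one emits with
   `coding_false_rate` (default 0.03). Pattern expansion is filtered
   back through the matcher, so an exception can never be emitted as a
   positive code. The diagnosis list is padded to a target count with
   noise codes drawn from numeric roots untouched by any catalog
   pattern (verified against the matcher at build time). Counts follow
   a negative binomial with size 6 and mean 9.5 — the right-skewed
   shape typical of discharge data, and the unique member of that
   family hitting the target quartiles 6/9/12 exactly; for other
   quartile targets the parameters are refitted numerically.
3. **Raters.** Each rater flips every latent category flag at their
   per-category sensitivity (defaults 0.92/0.90/0.88) and specificity
   (0.99/0.985/0.98 — an expert reviewing the chart rarely invents a
   defining chronic category) and flags PP when their perceived
   categories number ≥ 2. This is the simplest mechanism that is exact
   in the noiseless limit: with error-free raters and perfect coding,
   kappa, sensitivity and specificity all equal 1 by construction, and
   the test suite checks exactly that.
4. **Demographics.** Age is normal around median 71 with the IQR
   (58–80) converted to a standard deviation, truncated to adults; sex
   is 56.1% male; hospital levels 3/2/1 are drawn at 46.4/32.1/21.5%.

One random stream per cohort, seeded from the config: a cohort is a
pure function of its configuration. The coding and rater error
defaults are illustrative — the study the package operationalizes does
not publish them — and parameter-recovery tests therefore pin the
*mechanism* (closed-form binomial composition of episode-level
sensitivity, monotone degradation, chance-level behaviour under
shuffling), not any particular published operating point.

### What passing simulations do and do not show

The generator draws categories independently, emits one code per fired
category, and gives raters independent per-category errors. Real
multimorbidity is correlated (cardiac and renal disease travel
together), real coders emit several codes per condition with
hospital-level habits, and real raters share systematic biases. Green
simulation suites therefore demonstrate that the statistics and the
rule engine are computed correctly and recover known parameters under
the stated mechanism — not that the detector achieves any particular
kappa on real discharge data. The published patient-level results
(per-category kappas, the 0.745 category-count ICC) depend on the real
correlation structure and are deliberately not simulation targets;
what is reproduced instead are the desk-scale quantities: the
confusion table implied by the printed validity metrics, the kappa and
interval recomputed from it, and the 1300-patient sample-size figure
(see `scripts/acceptance.R`).

## Numerical and edge-case choices

* Matching is total on valid codes: every decision is TRUE/FALSE, and
  malformed input fails loudly at parse time with a per-code reason.
* Kappa CIs are truncated to [−1, 1]; reconstruction ties break to the
  smaller reference-positive count; `which.min` makes that
  deterministic.
* The ICC refuses a zero-total-variance input instead of returning
  0/0; kappa refuses pₑ = 1.
* Episode tables exclude under-18 records on read (the adult-inclusion
  rule), with a logged count; exclusion happens in the reader, not the
  classifier, so the rule engine itself stays age-agnostic.
* Test problem sizes are chosen to keep Monte-Carlo error well inside
  the asserted tolerances at desk scale: 2×10⁴ episodes for the
  binomial-composition check, 10⁴ simulated tables for the
  sample-size variance check, 3–4×10³ permutations for the kappa
  p-value oracle.

## Known limitations

* ICD-9-CM only; the 2011/2017 revisions of the PP definition and any
  ICD-10 mapping are out of scope, as is validity checking against the
  official tabular list (the matcher is syntactic).
* The per-category consensus among raters is reconstructed by majority
  vote; a study protocol with formal disagreement resolution would
  need its own adjudication rule.
* Severity weighting and comorbidity indices (Charlson, CIRS, ICED)
  are different instruments and intentionally absent.
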