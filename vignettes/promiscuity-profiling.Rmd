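---
title: "Profiling compound promiscuity from screening outcome records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling compound promiscuity from screening outcome records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promprof)
```

## The problem

Polypharmacology rests on compounds that specifically engage multiple
targets. Estimating how promiscuous screening compounds really are requires
more than collected activity annotations: it needs assay frequencies and
inactivity records, which literature-derived databases do not carry. Public
screening repositories (PubChem BioAssay being the archetype) do carry them,
as raw (compound, assay, outcome) records plus per-assay metadata, but the
records must be curated before any promiscuity statistic is meaningful.
promprof implements that curation and the downstream statistics as a tested
pipeline.

Two degrees are distinguished throughout, per assay category (primary
single-dose screens versus confirmatory dose-response assays):

* **Assay promiscuity** of a compound: the number of qualified assays in
  which it has an active outcome. Different assays for the same target count
  individually.
* **Target promiscuity**: the number of unique annotated targets over the
  assays in which it is active. By construction it can never exceed assay
  promiscuity. A compound tested in assays 1–5 against target T1 and 6–10
  against T2, active in assays 1, 2, 3, 8 and 10, has assay promiscuity 5
  and target promiscuity 2.

Comparing the two reveals whether apparent promiscuity is inflated by
repeated assays against the same target or by interference artifacts.

## The pipeline

1. **Assay qualification.** Primary assays: every chemical screen is kept,
   including targetless cell-based assays; only RNAi screens are removed.
   Confirmatory assays must pass all of: not on hold, chemical substance
   type, confirmatory dose-response stage, exactly one annotated target,
   protein target type, quantitative activity readout specified, at least
   one active outcome reported. Both rules are idempotent filters over the
   metadata table.
2. **Outcome filtering.** Only unambiguous `active`/`inactive` calls on
   qualified assays survive; `inconclusive`, `unspecified` and `probe`
   designations are discarded (a closed whitelist: safer than blacklisting
   unknown labels). Duplicate (compound, assay) observations collapse to a
   single record, active if any duplicate was active — consistent with
   counting a target as hit when the compound is active in at least one of
   its assays; the number of collapses is logged for audit.
3. **Profiles.** Per compound and category: assays tested, assays active,
   unique targets with activity. Targetless (cell-based) and multi-target
   assays contribute to tested/active but never to target counts, because a
   per-target activity cannot be attributed to them.
4. **Partition and censuses.** Compounds split by category coverage
   (both / primary-only / confirmatory-only, with the union identities
   checked), assay-frequency histograms with mean and median, and the dark
   census of compounds tested but never active — reported per category and
   for the both-category subset as a percentage to one decimal.
5. **Promiscuity summaries.** Mean, median and degree histograms over
   *active* compounds only (degree ≥ 1); dark compounds are censused
   separately, so including them would conflate the two questions. Binned
   five-number summaries (the box-plot view of degree versus assay
   frequency) use half-open tested-count bins.
6. **PAINS triage.** Compounds at or above an assay-promiscuity threshold
   are annotated with the pan-assay interference substructures their SMILES
   contain. Flags are annotation only — no statistic changes — because
   interference is an interpretation of the frequent-hitter tail, not a
   reason to rewrite it.

## Numerical and design choices

* **Quartiles** interpolate linearly between order statistics at ranks
  `(n-1)·q` (`stats::quantile` type 7). No convention is canonical for
  box-plot figures, so the method is recorded in the output attributes.
* **Medians** of even-sized samples average the central pair.
* **Displayed percentages and gaps** round half away from zero to one
  decimal (base `round()` rounds half to even, which would turn 27.25 into
  27.2); `round_half_up()` is exported because reports built downstream
  should match.
* **Duplicate outcome conflicts** resolve to active (see above). The
  alternative — majority vote or drop — would silently discard screening
  hits; the collapse count is surfaced so heavy duplication is visible.
* **`probe` outcomes** are members of the closed vocabulary so that they are
  discarded deliberately rather than failing the import.
* **Dialects**: column names and outcome vocabularies differ across exports,
  so readers take a dialect object mapping source columns and labels
  (including the numeric outcome codes 1–5) onto the model; unknown
  enumeration values degrade to `other` with a warning, unknown outcome
  labels are an error (an outcome cannot be guessed).
* **Degenerate inputs**: empty metadata/outcome files yield empty tables;
  an empty profile table errors in `assay_frequency()` (no distribution
  exists); bins must be ordered and non-overlapping; box bins without
  active compounds are omitted with a log note.
* **Interface**: the package's surface is its exported functions plus
  `run_pipeline()`, which chains the stages, logs every filter's in/out
  counts, and returns a report whose every number is re-derivable from the
  tables it carries (asserted in the tests). R users drive pipelines from
  scripts and the console, so no shell wrapper is shipped.

## The synthetic generator

`generate_screening_data()` emulates the statistical structure the analysis
assumes, at desk scale, with ground truth recorded for recovery tests:

* ~500 assays over a couple of hundred targets, 2–5 assays per target (so
  assay promiscuity can exceed target promiscuity), a block of targetless
  cell-based primaries, plus a few RNAi and rule-violating confirmatory
  assays so qualification is exercised end to end;
* per-(compound, assay) testing coverage 0.24 primary / 0.047 confirmatory —
  the tested-to-available ratio of the corpus being emulated, which at this
  assay count puts each compound in roughly a hundred assays (an optional
  per-compound count mode draws the number of tested assays per compound
  instead, mimicking sharper frequency peaks);
* per-tested-assay activity probability 0.01, matching the overwhelming
  dominance of inactivity records in real screening collections;
* 27% of compounds forced dark (never active), and a 0.2% frequent-hitter
  tail hitting with probability 0.5, its structures carrying known
  interference substructures (rhodanine, quinone, catechol cores).

The ground-truth counts are tabulated with base-R code during generation,
independently of the data.table aggregation in `build_profiles()`, so the
exact-match recovery test is a genuine dual-route check, not a tautology.
Class labels record the *design* (dark/normal/hitter); the dark
precision/recall check compares the pipeline's dark set against compounds
whose realized ground-truth active counts are zero, because an ordinary
compound can be inactive everywhere by chance and a correct pipeline must
report it as dark.

What the generator does **not** emulate: correlated activity across assays
of one target, per-assay hit-rate heterogeneity, chemical-series structure,
and the full corpus scale (hundreds of tested assays per compound). One
consequence worth stating: at roughly a hundred tested assays and a 1% hit
rate, `(0.99)^100 ≈ 0.37` of ordinary compounds are dark by chance, so the
realized dark census sits well above the forced 27%; at the real corpus's
~400 tested assays per compound chance darkness is negligible and the dark
fraction approaches the configured value. Passing tests therefore certify
the bookkeeping — counts, censuses, recoveries — on data with the right
sparsity structure, not distributional agreement with any real collection.

Default problem sizes were chosen to keep the whole test suite in well under
a minute: most tests run a few hundred compounds; the recovery and
expectation checks use 5,000; the acceptance script runs 20,000 compounds
over ~800 assays in a few seconds.

## Limitations

* Target identifiers are opaque strings; synonymous protein accessions count
  as distinct targets, exactly as annotated.
* `has_active_outcome` is trusted from metadata (it mirrors a deposition
  search facet), not recomputed from records.
* Substructure matching uses the OpenBabel SMARTS engine; published PAINS
  translations differ across toolkits, so the pattern list is an input file
  and the shipped list is a small demonstration subset, not the full
  480-pattern set. An independent matcher is used as an oracle in the test
  suite.
* Outcome filtering is applied uniformly to both assay categories; sources
  that pre-filter one category will simply see zero drops there.
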