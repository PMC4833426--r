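# promprof

Compound promiscuity profiling from raw screening outcome records.

## What problem this solves

In polypharmacology, *promiscuity* is the ability of a compound to
specifically interact with multiple targets — as opposed to pan-assay
interference (PAINS) or aggregation artifacts that light up many assays
non-specifically. Promiscuity estimates built from literature activity
annotations alone ignore how often each compound was actually tested and
how often it was inactive. Public screening repositories (PubChem BioAssay
style) contain exactly that missing information as raw (compound, assay,
outcome) records plus per-assay metadata, but it needs heavy curation
before the statistics mean anything.

promprof is for cheminformaticians and screening informaticians who want
that curation and analysis as a reproducible, tested R pipeline rather than
ad-hoc scripts.

## The statistics at its core

For a compound $c$ and assay category $X \in \{\text{primary},
\text{confirmatory}\}$, over the qualified assay set:

- $n_{\text{tested}}(c, X)$ — assays with any retained record for $c$;
- assay promiscuity $\;AP(c, X) = \#\{\text{assays with an active outcome}\}$,
  counting same-target assays individually;
- target promiscuity $\;TP(c, X) = \#\{\text{unique annotated targets over
  active assays}\}$, where targetless (cell-based) and multi-target assays
  contribute nothing.

Always $0 \le TP \le AP \le n_{\text{tested}}$. A compound tested in assays
1–5 (target $T_1$) and 6–10 (target $T_2$), active in assays 1, 2, 3, 8, 10,
has $AP = 5$ and $TP = 2$. Around these degrees the package computes
assay-frequency distributions, the partition of compounds by category
coverage, censuses of consistently inactive ("dark chemical matter")
compounds, mean/median degree summaries over active compounds,
five-number-summary box statistics per assay-frequency bin, and PAINS
substructure annotation of frequent hitters (OpenBabel SMARTS engine via
ChemmineR/ChemmineOB).

A seeded synthetic-data generator produces corpora with the right sparsity
structure — overwhelmingly inactive records, a forced dark fraction, a small
frequent-hitter tail — together with ground truth, so the whole pipeline is
testable end to end.

## Worked example

Using the small tables shipped under `inst/extdata/`:

```r
library(promprof)
am  <- read_assay_meta(system.file("extdata", "example_assays.tsv",  package = "promprof"))
rec <- read_outcomes(system.file("extdata", "example_outcomes.tsv", package = "promprof"))
q    <- rbind(qualify_primary(am), qualify_confirmatory(am))
#> [qualify_primary] 11 of 12 primary assays retained
#> [qualify_confirmatory] 2 of 4 confirmatory assays retained
prof <- build_profiles(filter_outcomes(rec, q), q)
#> [filter_outcomes] 24 in; 3 dropped (unqualified assay), 2 dropped (outcome),
#>   0 duplicate pairs collapsed; 19 out
prof
#>       cid n_tested_primary n_tested_confirmatory n_active_primary
#> 1:   CMP1               10                     2                5
#> 2:   CMP2                3                     1                1
#> 3:   CMP3                2                     1                0
#>    n_active_confirmatory n_targets_primary n_targets_confirmatory
#> 1:                     1                 2                      1
#> 2:                     0                 0                      0
#> 3:                     0                 0                      0
assay_promiscuity(prof, "primary")
#> CMP1 CMP2 CMP3
#>    5    1    0
target_promiscuity(prof, "primary")
#> CMP1 CMP2 CMP3
#>    2    0    0
```

One RNAi screen and two rule-violating confirmatory assays were
disqualified; records with `inconclusive`/`unspecified` outcomes were
dropped. CMP1 is the two-target worked example above: active in 5 primary
assays spanning 2 targets. CMP3 was tested but never active — dark in both
categories (`consistently_inactive(prof, "both_categories")` returns it).

`run_pipeline()` chains all stages (optionally from a YAML/JSON config, with
PAINS triage and file outputs), and `generate_screening_data()` +
`recovery_report()` drive the synthetic end-to-end check. See the vignette
in `vignettes/promiscuity-profiling.Rmd` for the model, parameter and design
details.

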