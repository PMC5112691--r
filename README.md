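# prioritize

Scoring, ranking and consensus diagnostics for CHNRI-style crowd-sourced
priority setting.

## What this is for

In crowd-sourced priority setting, a large panel of practitioners first
proposes candidate priorities (for example, patient-safety *problems*
and *solutions* around medication use in primary care), the free-text
proposals are collated into a composite catalogue, and a scoring panel
then judges every suggestion against a small set of agreed criteria —
five for problems (frequency, severity, inequity, economic impact,
responsiveness to solution), two for solutions (feasibility,
cost-effectiveness).  Each (suggestion, criterion) question is answered
with one of four options: **yes** (1), **no** (0), **unsure** (0.5) or a
blank, meaning **unaware**.

This package implements the quantitative stage of that workflow, for
analysts running or replicating such exercises:

* **Intermediate score** per (suggestion, criterion):
  `100 × Σ values / n received answers` — blanks never enter numerator
  or denominator.
* **Priority score** per suggestion: the mean of its defined
  intermediate scores, on a 0–100 scale.
* **Ranking** by priority score with deterministic tie-breaking
  (AEA, then catalogue order).
* **Average Expert Agreement (AEA)** per suggestion: the mean over
  criteria of the fraction of scorers giving the modal response, with
  blanks counted as a valid response category —

  `AEA = (1/|Q|) Σ_q  N(scorers giving the most frequent response on q) / N(scorers)`

  so AEA = 1 is full unanimity and low AEA flags controversy.
* **Validated IO** for long-form scoring-sheet CSVs, suggestion
  catalogues and criterion-set JSON, plus ranked-table reports.
* A **synthetic respondent generator** with closed-form expectations
  (latent merit / unsure / unaware mixture), so the whole pipeline is
  testable at any cohort size even though raw scoring sheets from real
  studies are typically not deposited.

## Worked example

The package ships a tiny synthetic example cohort (5 scorers, 3
solutions scored on 2 criteria):

```r
library(prioritize)

ex <- system.file("extdata/synthetic_example", package = "prioritize")
catalogue <- read_catalogue(file.path(ex, "catalogue.csv"))
criteria  <- read_criteria(file.path(ex, "solution_criteria.json"))
sheets    <- read_scoring_sheets(file.path(ex, "solutions_sheets.csv"),
                                 "solution", criterion_set = criteria,
                                 catalogue = catalogue)
sheets
#> <response_matrix> kind: solution | 5 scorers x 3 suggestions x 2 criteria (30 cells)
#>   responses: yes=25, no=3, unsure=2, unaware=0

ranked <- rank_table(sheets, criteria, catalogue = catalogue)
cat(render_report(ranked, top_n = 3), sep = "\n")
#> RANK  SUGGESTION_ID                            TEXT      KIND  BREAKDOWN_POINT            FACTOR  FEASIBILITY  COST_EFFECTIVENESS  N_CRITERIA_USED  PRIORITY_SCORE     AEA
#>    1           S002  Synthetic solution statement 2  solution       monitoring  individual_staff        100.0               100.0                2           100.0  1.0000
#>    2           S001  Synthetic solution statement 1  solution      prescribing  individual_staff         80.0                90.0                2            85.0  0.8000
#>    3           S003  Synthetic solution statement 3  solution       dispensing       task_design         80.0                70.0                2            75.0  0.7000
```

Reading the top row: every scorer answered *yes* to both criteria for
S002, so both intermediate scores are 100, the priority score (their
mean) is 100, and AEA is 1.0 — unanimous consensus.  S001's feasibility
score of 80 means the received answers averaged 0.8 (e.g. four *yes*
and one *no*); its AEA of 0.8 says that on average four of the five
scorers gave the modal response per criterion.

Participation arithmetic uses the same reporting conventions (one
decimal, half away from zero):

```r
response_rate(500, 113)
#> [1] 22.6
```

To simulate a study-scale cohort (57 sheets, 48 problems + 45
solutions) and rank it:

```r
cohort <- generate_cohort(synthetic_config(seed = 1))
rank_table(cohort$problems, default_criteria("problem"),
           catalogue = cohort$catalogue)
```

A thin command-line front end over the same functions is installed at
`system.file("cli/prioritize.R", package = "prioritize")` with
`simulate`, `score` and `agreement` subcommands.

## Documentation

The methods vignette (`vignettes/priority-scoring.Rmd`) describes the
scoring model and its conventions, the AEA statistic, the synthetic
generator's parameterisation and defaults, and the package's numerical
choices and limitations.
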