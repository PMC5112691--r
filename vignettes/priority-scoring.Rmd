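---
title: "Scoring, ranking and consensus for crowd-sourced priority setting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, ranking and consensus for crowd-sourced priority setting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(prioritize)
```

## The method

CHNRI-style priority setting elicits candidate priorities from a large
panel, collates them into a composite catalogue, and then has a scoring
panel judge every suggestion against a small set of agreed criteria.
This package implements the quantitative half of that workflow for a
patient-safety adaptation in which clinicians score two catalogues —
*problems* (by default judged on frequency, severity, inequity,
economic impact and responsiveness to solution) and *solutions*
(feasibility and cost-effectiveness).  The upstream half — questionnaire
design, free-text collation, category coding — is qualitative, human
work; its outputs (the catalogue with its category labels) enter this
package as inputs and are never recomputed.

Each scorer answers every (suggestion, criterion) question with one of
four options:

| code      | meaning                         | numeric value |
|-----------|---------------------------------|---------------|
| `yes`     | agrees with the criterion       | 1             |
| `no`      | disagrees                       | 0             |
| `unsure`  | cannot decide                   | 0.5           |
| `unaware` | blank: not confident to score   | none          |

A blank cell on a sheet *is* the fourth option: at ingestion every blank
becomes the explicit `unaware` code, so downstream code never needs to
distinguish "skipped" from "unaware".  Whether a scorer skipped a whole
suggestion or a single criterion is not distinguishable from a returned
sheet, so both present as `unaware` cells.

## Scores

For suggestion $s$ and criterion $q$, with $R_{sq}$ the set of received
(non-blank) answers and $v(r) \in \{0, 0.5, 1\}$ the numeric values,

$$ I_{sq} = 100 \times \frac{\sum_{r \in R_{sq}} v(r)}{|R_{sq}|}, $$

the *intermediate score* on a 0–100 scale, undefined when $|R_{sq}| = 0$.
The *priority score* of a suggestion is the unweighted arithmetic mean of
its defined intermediate scores,

$$ P_s = \frac{1}{|Q_s|} \sum_{q \in Q_s} I_{sq}, $$

where $Q_s$ is the set of criteria with at least one received answer.
Because the denominator of $I_{sq}$ is *received* answers, blanks never
enter any average; a criterion nobody answered simply drops out of
$Q_s$.  A suggestion with $Q_s = \emptyset$ cannot be scored at all: by
default it is excluded from the ranking with a warning naming it (an
auditable log line), and `strict = TRUE` turns that into an error.

Scores are kept at full floating precision throughout the pipeline.
Rounding — half away from zero, one decimal for scores, four for AEA —
happens only at the reporting boundary (`render_report()`,
`write_ranked_table()`), matching how such tables are conventionally
printed.  Participation percentages use the same half-away-from-zero
rule (`response_rate(500, 113)` is `22.6`).

## Ranking and ties

`rank_table()` sorts by priority score, descending.  Nothing in the
scoring model forbids exact ties, so the order must be completed
deterministically: ties break by AEA (descending) — scorer consensus as
the secondary merit signal — and then by catalogue order.  Tied rows
keep distinct consecutive ranks in that order, so the rank column is
always $1, 2, \ldots, n$ and re-runs are byte-identical.

## Average Expert Agreement

Chance-corrected agreement statistics (Cohen's/Fleiss' kappa) fit badly
here: panels are moderate, the response scale is categorical but not
standardized, blanks are legitimate responses, and each suggestion kind
uses a different number of criteria.  Instead the package reports, per
suggestion, the *Average Expert Agreement*:

$$ \mathrm{AEA}_s = \frac{1}{|Q|} \sum_{q \in Q}
   \frac{N_{sq}^{\mathrm{modal}}}{N}, $$

the mean over the criterion set of the fraction of scorers giving the
modal response.  Three conventions matter:

* **All four codes are categories.**  A criterion where most scorers
  left a blank has its agreement measured on `unaware` like any other
  code, so widespread unawareness *reduces* agreement about the
  substantive answers rather than inflating it.  (Contrast with the
  scores, where `unaware` is neutral: appending a blank changes no
  intermediate score, but it can move AEA either way.)
* **The denominator is all scorers who returned a sheet**, including
  those blank on the criterion at hand.
* **Modal ties need no winner.**  Two codes sharing the maximum count
  give the same fraction whichever is called "the" mode, so tie-breaking
  is unnecessary and no randomness enters.

The divisor is always the number of criteria actually in the configured
set — 5 for the default problem set, 2 for the default solution set —
so AEA is a true mean of its per-criterion fractions and lies in
$(0, 1]$; a fixed divisor borrowed from a differently-sized criterion
set would silently rescale the statistic.  With $N$ scorers and four
categories the per-criterion fraction is at least $\lceil N/4 \rceil /
N$; AEA is exactly 1 iff every criterion is unanimous.  AEA carries no
significance statement; it is a descriptive consensus diagnostic.

## The synthetic cohort generator

No raw scoring sheets are publicly deposited for studies of this design,
so the package ships a generator that emulates the *structure* of a
scored cohort with known ground truth.  Defaults mirror a realistic
study: 57 returned sheets, 48 problems $\times$ 5 criteria and 45
solutions $\times$ 2 criteria.

Each (suggestion, criterion) cell has a 4-category distribution built
from a latent merit $m \in [0,1]$, an unsure weight $u$ and an unaware
rate $a$:

$$ p_{\mathrm{unaware}} = a, \quad p_{\mathrm{unsure}} = (1-a)\,u, \quad
   p_{\mathrm{yes}} = (1-a)(1-u)\,m, \quad
   p_{\mathrm{no}} = (1-a)(1-u)(1-m). $$

This family was chosen because its expectations are closed-form —
conditional on an answer being received, its expected numeric value is
$(1-u)m + u/2$, so the expected intermediate score is simply
$100\,((1-u)m + u/2)$, implemented in `expected_intermediate_score()` —
and parameter-recovery tests can compare against exact targets instead
of calibrated ones.

Defaults, chosen once on realism grounds:

* **Suggestion merit** $\mu_s \sim \mathrm{Beta}(4.5, 1.5)$ (mean 0.75).
  Catalogues of this kind are pre-filtered by the eliciting panel
  itself, so most entries are broadly endorsable and expected priority
  scores concentrate in the 55–95 range, with the top of the ranking in
  the 90s.
* **Per-criterion merit** $m_{sq} \sim \mathrm{Beta}(20\mu_s,
  20(1-\mu_s))$: criteria agree with the suggestion's overall merit up
  to moderate jitter.
* **Unsure weight 0.2, unaware rate 0.05** at baseline.  Real unaware
  rates are unreported for this design; 0.05 encodes "sheets are mostly
  complete", consistent with enrolment rules that stop at fully
  completed sheets.
* **Consensus coupling (on by default):** $u_s = 2 \cdot 0.2 (1 -
  \mu_s)$ and $a_s = 2 \cdot 0.05 (1 - \mu_s)$, so high-merit
  suggestions attract fewer hedges and blanks.  This reproduces the
  qualitative field observation that top-ranked suggestions carry the
  strongest agreement, and makes the priority-score/AEA Spearman
  correlation positive in essentially every replicate at default scale.
* **Scorer homogeneity:** all scorers share each cell's distribution.
  A `scorer_bias_sd` option adds a per-scorer logit shift on merit; it
  is off by default because the homogeneous model already exercises
  every pipeline branch and keeps cell expectations exact.

What the generator does *not* emulate: item-wording effects, correlated
responses within a scorer's sheet, demographic structure, or any attempt
to reverse-engineer a specific study's response distributions from its
published ranked tables (those are underdetermined).  Green tests on
synthetic cohorts certify the pipeline's arithmetic and invariants, not
the behaviour of real panels.

## Expected AEA and numerical choices

`expected_aea()` gives the expectation of the AEA statistic at a given
panel size.  For $N \le 25$ it enumerates all multinomial splits of the
panel over the four categories ($\binom{N+3}{3}$ compositions, still
tiny at that size) and is exact, also returning the exact standard
deviation of a single cohort's AEA.  Above that it switches to Monte
Carlo with a reported standard error.  The $N \le 25$ cutoff is purely a
cost bound; `method = "exact"` forces enumeration at any size you are
willing to wait for.

Recovery tests in the suite compare empirical against expected scores
using SD-scaled bounds (4.5 SDs per cell) rather than fixed point bands:
at 2000 scorers a mid-merit cell's intermediate score has a sampling SD
of roughly 0.8–1.1 points, and the maximum deviation across several
hundred cells concentrates near 2.2–2.4 points even when every cell
behaves exactly as modelled, so any fixed band tighter than ~3 points
would reject correct code.  The 4.5-SD bound keeps the familywise
false-alarm probability near $10^{-3}$.

Test and example problem sizes (2000-scorer recovery cohorts, 100
replicate cohorts for the consensus correlation, exhaustive enumeration
of all $4^6$ per-suggestion response assignments at 3 scorers $\times$ 2
criteria) were chosen so the whole suite runs in a few minutes on one
CPU while still pinning every formula to an independent recomputation.

## Known limitations

* Criteria are unweighted by design; if a study weights criteria the
  priority score here does not apply unchanged.
* AEA measures concentration on a modal category only; it does not
  distinguish a 50/50 yes/no split from a 50/50 yes/unsure split beyond
  their shared modal fraction, and offers no inference.
* The validator requires a rectangular design (every scorer asked every
  question); staggered or adaptive designs would need an explicit
  enrolment table per suggestion.
* Category vocabularies are closed by default; extending them is a
  deliberate, explicit act (`extra_breakdown_points`, `extra_factors`)
  so typos in hand-coded labels fail loudly.
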