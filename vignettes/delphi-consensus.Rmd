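---
title: "A Delphi consensus pipeline for ICD-9-CM antimicrobial-use coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Delphi consensus pipeline for ICD-9-CM antimicrobial-use coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delphicodes)
```

## The problem

Antimicrobial stewardship programs need consumption data, but in many
health systems hospital drug prescriptions are not centrally recorded.
Hospital discharge records, which *are* routinely transmitted, carry
ICD-9-CM diagnosis and procedure codes. If an expert consensus can mark
which codes denote clinical conditions where systemic antimicrobial
therapy is administered in at least 60% of hospital stays, the marked
code set becomes a large-scale proxy for antimicrobial consumption.

`delphicodes` implements the full consensus machinery for building such
a code list:

1. **Dual review with adjudication** — two specialists independently
   classify every code *for inclusion* or *for exclusion*; a third
   reviewer resolves discrepancies (`adjudicate()`).
2. **Panel voting** — a panel (18 members in study-replication mode)
   scores its agreement with each proposed classification on a 9-point
   Likert scale, 1 = totally disagree to 9 = totally agree
   (`read_votes()`, `validate_votes()`).
3. **Agreement statistic** — per code, the score median, quartiles, IQR,
   and the RAND/UCLA disagreement threshold IPRAS decide whether the
   panel agreed (`classify_round()`).
4. **Round iteration** — codes without agreement are re-voted until all
   settle or a round cap is hit (`run_delphi()`).
5. **Reporting** — flow tallies and chapter breakdowns with explicit
   rounding (`flow_summary()`, `chapter_breakdown()`, `percent()`).
6. **Synthetic panels** — a seeded generator reproduces the statistical
   shape of such a study so every stage is testable without confidential
   vote data (`sim_config()`, `simulate_delphi_study()`).

## The agreement rule

For a code's vote set with lower quartile $q_1$, median $m$, and upper
quartile $q_3$ (interpolated at fractional rank $1+(n-1)p$ by default),
define

$$\mathrm{IQR} = q_3 - q_1, \qquad
\mathrm{IPRAS} = 2.35 + 1.5\,\left|\,5 - \tfrac{q_1+q_3}{2}\right| .$$

IPRAS is the *inter-percentile range adjusted for symmetry* of the
RAND/UCLA appropriateness methodology: a baseline spread tolerance of
2.35 score units that grows as the inter-percentile midpoint departs
from the scale midpoint 5, because spread far from the centre is less
indicative of true disagreement. The round outcome is tripartite:

| median | dispersion | status |
|---|---|---|
| $m < 4$ | any | `AGREE_LOW` — panel firmly rejects the proposal |
| $4 \le m < 7$ | any | `NO_AGREEMENT` |
| $m \ge 7$ | $\mathrm{IQR} \le \mathrm{IPRAS}$ | `AGREE_HIGH` — proposal endorsed |
| $m \ge 7$ | $\mathrm{IQR} > \mathrm{IPRAS}$ | `NO_AGREEMENT` |

```{r}
classify_round(c(rep(1, 6), rep(9, 12)))  # polarized panel
```

Three boundary choices deserve a note, all configurable via
`agreement_config()`:

* **Ties**: `IQR == IPRAS` counts as agreement — disagreement requires
  spread *strictly greater* than the threshold. Even-panel medians of
  exactly 6.5 fall in the uncertain band, making the tripartition total.
* **Low medians**: the enumerated non-agreement rules cover only the
  middle and high bands, so a median below 4 is agreement regardless of
  spread. The symmetric alternative (also requiring
  `IQR <= IPRAS` on the low side) is available as
  `symmetric_low_rule = TRUE` but off by default.
* **Quantile convention**: the interpolated-rank estimator (the common
  default in scientific software) with a nearest-rank alternative; for
  18 integer votes the two rarely differ, but the choice is pinned in
  configuration rather than guessed.

The IPRAS constants (2.35, 1.5, centre 5) likewise live in
configuration, as does the quantile pair — the classic RAND methodology
uses the 0.30/0.70 inter-percentile range where this pipeline defaults
to the quartiles (0.25/0.75).

## Endorsement semantics

Panelists score their agreement **with the proposed classification**,
not with inclusion directly. `AGREE_HIGH` therefore means the proposal
stands — whether it proposed inclusion *or* exclusion — and `AGREE_LOW`
means the panel firmly rejects it. By default a rejected proposal is
overturned (include becomes exclude and vice versa,
`resolve_direction()`); because a real study might instead send such
codes back to review, `delphi_config(low_agreement =
"reclassify_exclude")` offers the conservative alternative. Neither is
presented as what any particular study did: published flows typically
contain no overturned proposal to learn from.

Unresolved codes at the round cap (`max_rounds`, default 10) are
reported as an explicit partial outcome, never silently classified.

## The synthetic panel generator

Each code carries a latent probability `p_abx` that an admission coded
with it receives systemic antimicrobial therapy, drawn from a
two-component Beta mixture: a high mode Beta(10, 2) for codes whose
conditions usually warrant antimicrobials and a low mode Beta(1.5, 8)
for the rest. Chapter-conditional weights on the high mode (0.98 for
infectious/parasitic, 0.54 for injury/poisoning, 0.19 for pregnancy
complications, 0.053 elsewhere) were fixed once, by closed form, so the
expected inclusion fraction is ~18.5% and the included set is dominated
by injury and infectious codes — the composition such a consensus
produces in practice. Reviewers threshold `p_abx` at 0.60 (the boundary
itself is *for inclusion*: "at least 60% of stays"), each flipping
independently at `reviewer_error_rate` (default 0.03), with an
error-free third adjudication for discordant pairs.

Votes are drawn from explicit discrete distributions over 1..9 — exact,
portable, and seed-stable:

* endorsing a correct proposal: mass (0.25, 0.50, 0.25) on {7, 8, 9};
* rejecting an incorrect one: the mirror image on {1, 2, 3};
* contested codes (`controversy_fraction`, default 69/16227 ≈ 0.43%):
  a centred distribution massed on {4, 5, 6} with small tails, which
  fails the agreement rule with probability ≈ 1 (a polarized
  two-tailed alternative is selectable).

Panelist heterogeneity enters through `concordance` (probability of
endorsing a correct proposal, default 0.98 — chosen so that spurious
non-agreement among uncontested codes, at ~2×10⁻⁵ per code, is
negligible against the contested fraction) and an integer
`severity_shift` in −2..2 added to drawn scores before clipping.

**Convergence.** From round 2 on, every drawn score is contracted
toward a majority-side consensus target (8 when the panel converges to
endorse, 2 to reject) by the factor $(1-\text{convergence})^{r-1}$.
At the default `convergence = 0.8` a second-round draw lands within
±1.6 of the target, so contested codes settle in round 2 with
probability ≈ 1, reproducing the two-round termination shape typical of
these studies. We chose score contraction over re-weighting the vote
mixture because, with an 18-member panel, a mixture-weight shift of 0.8
still leaves a few percent of panels dispersed enough to fail the IPRAS
check — it cannot reliably produce full second-round consensus, which
is the empirical behaviour the generator must be able to emulate.
Setting `convergence = 0` disables the mechanism entirely. Which side a
contested panel converges to is itself latent
(`contested_endorse_prob`, default 0.6 toward endorsement).

What the generator does **not** emulate: real codes' clinical meaning
(descriptions are placeholders), per-chapter contested counts, comment
text, panelist identity beyond an opaque label, or any correlation
between a panelist's votes across codes. Passing tests therefore
demonstrate the *procedure's* correctness and calibration, not the
clinical validity of any real code list.

## A worked run

```{r}
st <- simulate_delphi_study(sim_config(n_codes = 2000, n_covid = 5), seed = 7)
flow_summary(st$outcome)
inc <- st$outcome$final$code[st$outcome$final$classification == "include"]
head(chapter_breakdown(inc), 4)
```

## Reporting and rounding

`percent()` rounds half-away-from-zero by default — the convention of
most published tables — and offers `mode = "truncate"` because source
tables occasionally truncate (47.05 for 8/17, where rounding gives
47.06). Reports always store counts and recompute percentages, so an
arithmetic slip in a source can never propagate; `flow_from_counts()`
checks the additive invariants of externally stated tallies and
*surfaces* a mismatched universe size as a warning rather than
reconciling it.

## Numerical and testing choices

* Scores are validated as integers in 1..9 at ingest; nothing is
  coerced or imputed. Missing votes against a roster are an error in
  strict mode, a warning in permissive mode.
* Quartiles are computed from score counts (tabulation), which is exact
  for the 9-point scale and fast at 16,000-code rounds; the test suite
  cross-checks it against the reference quantile estimator and against
  a brute-force enumeration of **all** score vectors for panels of up
  to six votes (597,870 panels) with an independently coded
  transcription of the rule.
* Calibration is checked over 20 seeded replicates of a 16,227-code,
  18-panelist first round: the mean non-agreement fraction must sit
  within three standard errors of the configured contested fraction.
  End-to-end, a noise-free regime must recover the planted
  60%-threshold classification exactly, and study-scale runs must reach
  full consensus in two rounds. These problem sizes keep the full suite
  near a minute while exercising every stage at realistic scale.
* All simulation is driven by explicit integer seeds; identical inputs
  and configuration give byte-identical outcomes and reports.

## Limitations

The pipeline validates and aggregates expert votes; it cannot judge
whether the resulting code list predicts real drug consumption — that
requires linkage to dispensing data, out of scope here. The chapter
table ships the standard 17 numeric ICD-9-CM chapters plus the V and E
supplementary classifications as editable data; ICD-10/11 parsing and
cross-walks are deliberately not modelled. SARS-CoV-2-era codes are
carried as a metadata flag on the input list, never inferred from the
identifier.
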