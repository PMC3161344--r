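---
title: "Prediction configural frequency analysis: model, workflow and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prediction configural frequency analysis: model, workflow and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predcfa)
```

## The method

Configural frequency analysis (CFA) is a person-oriented alternative to
variable-oriented methods such as factor analysis or logistic regression.
Its unit of analysis is the *configuration*: one complete pattern of
category values across a set of categorical attributes, i.e. one cell of
the full multiway cross-classification. CFA asks which cells are occupied
significantly more often (*types*) or less often (*antitypes*) than a base
model predicts. Because whole cells are tested, associations that exist
only as higher-order interactions — invisible to correlation-based methods
— are detected directly.

Two cell tests are implemented.

**First-order chi-square CFA** (`cfa_chisq()`). The base model is total
independence of all attributes: the expected frequency of a cell is
$e = N\prod_j \hat p_{j,c_j}$, the product of the observed marginal
proportions. Each cell is scored with
$X^2 = (o - e)^2 / e$ referred to the upper tail of $\chi^2_1$. This is
the classical symmetric CFA; it is retained as a general capability and as
a cross-check, and its output is flagged as a different test from the
prediction variant below. Cells with a zero marginal have $e = 0$, where
the statistic is undefined; they are reported as `untestable` rather than
silently dropped or tested.

**Prediction CFA** (`run_prediction_cfa()`). Attributes are split into
predictors and one criterion. For every predictor-configuration ×
criterion-category cell, the table is collapsed to a fourfold table

|                      | criterion category | all other categories |
|----------------------|--------------------|----------------------|
| this configuration   | a                  | b                    |
| all other configs    | c                  | d                    |

and tested with a one-sided Fisher exact test: $p = P(A \ge a)$ under the
hypergeometric distribution with both margins fixed. A *prediction type*
is a cell whose joint incidence is over-represented; only the upper tail
defines a type, which is why published p-value matrices of this method
contain values arbitrarily close to 1 (e.g. 0.999980). Lower-tail
(antitype) probabilities are available behind the `antitypes` flag but off
by default. The tail is accumulated from log-scale point probabilities
(`lchoose`), so it neither under- nor overflows at cohort sizes in the
thousands; tests verify agreement with exhaustive enumeration to ten
significant digits for all tables with $N \le 60$ and with R's
hypergeometric tail at larger $N$.

The collapse "this configuration vs all others / this category vs all
others" is the standard prediction-CFA construction; pairwise category
contrasts would answer a different question and are not offered.

## The two-stage split-half workflow

With five predictors of cardinalities $2,2,2,2,3$ and a 3-category
criterion, $48 \times 3 = 144$ cells are tested. Testing them all
confirmatorily would either inflate the family-wise error rate or, after
adjustment for 144 tests, leave almost no power for the sparse cells that
typal analysis cares about. The implemented workflow
(`run_full_pipeline()`) therefore:

1. randomly splits the cohort into two equal halves (`split_sample()`;
   sizes $\lceil n/2\rceil$ and $\lfloor n/2\rfloor$, deterministic given
   the seed);
2. screens all 144 cells in half A at unadjusted $p < \alpha$
   (`exploratory_screen()`, strict inequality — a printed value of
   exactly 0.05 or more is never a candidate);
3. retests *only* the flagged cells in half B and applies the Holm
   sequentially rejective procedure over exactly those $m$ tests
   (`confirmatory_test()`): sorted p-values are compared against
   $\alpha/(m-i+1)$ with non-strict $\le$, rejection stops at the first
   failure. Holm controls the family-wise error rate at $\alpha$ and
   dominates Bonferroni, which is provided as a comparator
   (`bonferroni()`).

Confirmed types are labelled `T1, T2, ...` in the row order of the results
table (predictor configurations lexicographic, last predictor fastest),
not by p-value rank; this matches the labelling convention of the
published application whose p-value matrix ships with the package.

Because the application's raw cohort was never deposited, that printed
48 × 6 matrix is packaged as a *fixture* (`fixture_table2()`), stored both
as the printed 6-decimal strings and their numeric parse, and
`reproduce_published_analysis()` runs stages 2–3 directly on it. On these
inputs the screen flags 21 candidates (8 predicting the active role, 4 the
collaborative, 9 the passive) and Holm confirms exactly four:
(12212)×passive, (12213)×passive, (21121)×active, (22221)×active. One
entry of the matrix is printed as `0.000000`; whether the source software
truncated or underflowed is unknowable, so the fixture keeps the printed
string verbatim and parses it as 0 (which no Holm threshold can fail to
reject at rank 1). The strict-`<` screening rule is load-bearing here:
cell (21113)×collaborative has exploratory $p = 0.051227$ and must not be
flagged, and none of the remaining 123 entries sit in $[0.045, 0.05)$, so
the printed precision of six decimals cannot flip any screening decision.

## Categorization of the survey attributes

`categorize_records()` converts raw item-level records into the six
integer-coded attributes:

* **M1, information-seeking preference** — sum of 8 items on a 1–5 scale,
  median-dichotomized into low/high. Ties (score equal to the median) go
  to *low* by default: the conventional "$\le$ median" split, configurable
  via the codebook. A brute-force test checks that the better of the two
  tie rules always leaves the groups as balanced as the score distribution
  permits.
* **M2, trust in physician** — sum of 5 items on 1–4, split at the sample
  *mean* (the use case is a median degenerate at the scale maximum). A
  score exactly equal to the mean goes *above* by default; for non-integer
  means the case never arises, but it must be defined for integer ones (a
  degenerate constant sample then maps entirely to one category rather
  than splitting arbitrarily).
* **M3, perceived participatory decision-making (PDM) style** — the three
  items use different response scales, so each level is mapped to a
  direction (positive / neutral / negative) and a strict 2-of-3 majority
  decides; no majority means *undetermined*, which is treated as missing.
  The default direction map (levels 1–2 positive, 3 neutral, 4–5 negative
  on a 5-point scale) assumes items keyed with low codes favorable;
  whether the scale midpoint carries direction is a documented choice, and
  the map is an overridable codebook entry because the original item
  keying is instrument-specific.
* **M4, education** — codebook-driven binary mapping (no certificate or
  lower secondary → low; secondary certificate and higher → high);
  unknown labels raise an error listing the accepted ones.
* **M5, age band** — $\le 55$, 56–75, $\ge 76$, boundaries inclusive.
* **M6, control preference** — options 1–2 → active, 3 → collaborative,
  4–5 → passive.

Missing-data policy is listwise deletion only, with a per-reason exclusion
log; nothing is imputed. Split points (median, mean) are computed once on
the full pre-split sample and must be reused for both halves — otherwise
the attribute definitions would differ between the exploratory and
confirmatory stages. The codebook therefore accepts pre-computed
`info_cut` / `trust_cut` values.

## The synthetic cohort generator

`generate_cohort()` draws predictors independently from configurable
marginals (defaulting to the printed exploratory-half distribution:
information low 38.9%, trust above average 65.9%, PDM positive 61.9%,
education low 65.9%, age bands 26.4/48.1/25.5%, criterion
22.4/31.3/46.3%, $n = 3883$, the two halves combined) and the criterion
from a base distribution modified by *planted effects*: for records
matching a predictor pattern (wildcards allowed, e.g. an effect shared
across age bands), the odds of one criterion category are multiplied by a
factor and renormalized. Odds multiplication is used because joint
over-representation is exactly the alternative prediction CFA tests, and
unlike additive probability shifts it cannot leave $[0,1]$. A unit
multiplier is a provable no-op.

What the generator emulates: realistic marginal composition, total
independence under no effects (tests verify the per-cell rejection rate
sits at or below $\alpha$), and sharp planted configuration–criterion
associations. What it does not emulate: dependence *among predictors*,
centre-level clustering (187 dialysis units in the motivating study;
explicitly unmodelled there too), item-level measurement error beyond the
split-point construction, and non-response. Passing tests therefore
demonstrate the statistical machinery, not robustness to those real-data
features.

**Item-level mode** expands each generated category into raw survey
responses: sum scores drawn uniformly from the category's side of a fixed
split point (information: 8–24 vs 25–40; trust: 5–12 vs 13–20), decomposed
into in-range items by a constrained multinomial; two of the three PDM
items forced into the category's direction; labels, ages and options
sampled within their category. Exact recovery through the categorizer is
only guaranteed when the categorizer uses the generator's split points
(attached as attribute `cuts`), because an empirical median computed from
an unbalanced mixture need not fall between the two score blocks; the
tests exercise both that route and the empirical-split route on a balanced
cohort where the sample median provably lands between the blocks.

**Margin-exact reconstruction** (`reconstruct_paper_like_cohort()`) builds
a stand-in for the undeposited cohort: integer cell counts over the
144-cell table whose per-attribute margins equal the printed half-sample
counts *exactly* and whose four confirmed-type cells hold exactly the
printed joint counts (91, 45, 29, 26) in the confirmatory half. The
construction starts from independence-proportional mass, pins the type
cells, rounds by largest remainder, and repairs each attribute's margin by
single-unit moves between cells differing in that attribute alone (such a
move touches no other margin, so one pass per attribute suffices). One
type cell, (21121)×active, lies far above its independence expectation
(~12 records) — its joint count of 29 could not be reached by
independence-proportional rounding, so rows holding a pinned cell receive
the pinned count plus the independence share of the remaining criterion
categories before the rest of the mass is allocated. The reconstruction
matches margins and type counts, not the unknown full joint distribution;
assertions about the printed type sizes are made only in this mode, never
from the p-value fixture alone.

## Numerical and degenerate-input choices

* Fisher tail in log space; upper-tail p is exactly 1 at the minimum
  feasible `a` and complements the lower tail at `a − 1` to machine
  precision (tested).
* Holm uses non-strict $\le$ at each threshold; with 6-decimal printed
  inputs strict vs non-strict cannot change the published result (no
  p-value equals a threshold), and ties are ordered stably by input
  position so tied boundary values are rejected or retained together.
* Zero-margin cells: chi-square CFA reports them untestable; the Fisher
  test handles empty margins naturally ($p = 1$).
* Empty inputs error early and explicitly (empty score vectors, empty
  record sets, a split of fewer than two records); an empty candidate list
  yields an empty confirmation with a warning rather than an error, since
  a null cohort legitimately produces one.
* All package randomness flows through a private RNG scope seeded from the
  single configured seed, so library calls never disturb the caller's RNG
  state and runs are reproducible end to end.

## Simulation design used in the shipped checks

The operating-characteristic simulations (analysis stage 3 and the
acceptance suite) run at $n = 4000$ with the printed marginals: 500 null
replicates for the family-wise false-confirmation rate (observed ≈ 0.04,
consistent with control at 0.05 plus the exact test's conservatism in
sparse cells) and 100 replicates with two planted types at odds
multiplier 3 for recovery. The planted cells are the modal passive
profile (12212)→passive (~100 matching records per half) and a prevalent
active profile (22211)→active (~87 per half), chosen in pilot runs so each
planted cell has enough matching records for the two-stage design to have
meaningful power; planting in a configuration with, say, a dozen matching
records per half would measure sparsity, not the procedure. Both types
are recovered in ≈99% of runs. These problem sizes are the package's
chosen simulation design and are stated here so the reported rates can be
reproduced exactly with the seeds in `analysis/03_error_control_simulation.R`.

## Known limitations

* Only the first-order (total independence) base model is provided;
  higher-order base models, covariate CFA, binomial/z cell tests, mid-p
  corrections and stratified exact tests are out of scope.
* The criterion is single-attribute; multi-attribute criteria would need a
  different fourfold collapse.
* The split is a single random half-split; k-fold or repeated-split
  schemes are not implemented.
* No modelling of clustered sampling; p-values assume independent
  records.
* The published subsample sizes (1969 vs 1914) differ by more than one
  record despite an "equal-sized" split; the package splits to within one
  record and treats the published sizes as the outcome of additional,
  undescribed processing. The split proportion is configurable.
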