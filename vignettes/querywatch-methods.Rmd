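---
title: "Query-log ADR surveillance: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Query-log ADR surveillance: models, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(querywatch)
```

## The surveillance problem

Spontaneous-report databases are the backbone of postmarket drug safety,
but they require someone — a patient or a clinician — to *connect* a
reaction to a drug. That connection is easy for an acute reaction that
appears days after the first dose and hard for a diffuse one that builds up
over months, so the reference databases are biased toward acute, early-onset
reactions. Aggregated web-search behaviour has the complementary bias:
people search for whatever bothers them, whenever it bothers them, whether
or not they attribute it to a drug. `querywatch` operationalises that
observation as a screening statistic and a set of analyses around it.

## The query-log reaction score

**Day Zero.** For a drug, every user receives a reference day. Users who
queried the drug at least once get the day of their first drug query. All
other users get the midpoint of their observed query history,
`floor((first_day + last_day)/2)`. The unexposed users are not a throwaway:
their before/after split absorbs every environmental influence shared by
the population — seasonal allergy load, media events, slow drifts in search
behaviour — which the exposed arm is then measured against.

**The table and the statistic.** For each (drug, symptom) pair, every
symptom query event by every user falls into one cell of a 2x2 table by
(user exposed?, event on or after that user's Day Zero?). The table is
scored with Pearson's goodness-of-fit chi-square without continuity
correction; a table with a zero margin scores 0, and an all-zero table is an
error. The statistic is unsigned, so the package carries
`sign(N22 - E22)` as a separate direction and, when emitting candidate-ADR
lists, keeps only increases — a chi-square also fires when exposed users
query a symptom *less* after Day Zero, which is not an ADR signal.

**Conventions the data forced us to fix.** Three details are unavoidably
convention, all configurable:

- *Day-Zero boundary.* An event exactly on Day Zero counts as "after"
  (`boundary = "after"`). A drug and a reaction to it are often first
  queried in the same session; pushing those events to "before" (or
  dropping them) would discard the most informative data points. The
  flipped convention is available for sensitivity analysis.
- *Counting unit.* Every query event counts. A per-user-per-day
  deduplication (`dedup = TRUE`) is available as a burst-robustness option.
- *Midpoint rounding.* The unexposed midpoint takes the floor.

**Candidate restriction.** Per drug, only the `top_k = 50` symptoms most
queried by that drug's users are scored. This keeps the multiple-testing
burden bounded and concentrates the analysis where the data are.

## Statistical behaviour of the score, and when it is calibrated

The chi-square treats the four cell counts as independent Poisson/multinomial
counts. Real query events are clustered within users, and Day Zero is
*estimated* per user, so the null distribution of the QLRS only approaches
chi-square(1) when no single user contributes a large share of any table.
Two failure modes are worth knowing:

- *Dense per-symptom histories.* If a typical user queries the same symptom
  many times, the per-user clustering and the randomness of Day-Zero
  placement inflate the variance of the statistic. The score remains a
  valid ranking device, but its nominal chi-square tail is optimistic.
- *Sparse total histories.* The midpoint rule needs a history to take the
  midpoint of. A user observed with a single event has Day Zero *on* that
  event, which then counts as "after" under the default boundary; with very
  few events per user the unexposed arm is biased toward "after". In
  practice this matters only when the tracked symptom universe is tiny; at
  a realistic dictionary size (tens to hundreds of symptoms, so users have
  many observed events) the bias is second order. The package's own null
  calibration check runs at 100 tracked symptoms and a per-symptom rate of
  0.001 queries/user/day and lands within two points of the nominal 5%
  tail.

Both regimes are properties of the method itself, not of this
implementation; they are reproduced faithfully and documented rather than
patched.

## Term matching and vocabulary expansion

Queries map to canonical symptom/drug ids through an explicit synonym
dictionary: exact substring matching on normalised text (lower case,
punctuation to spaces) at word boundaries — no stemming, no spelling
correction, so the whole pipeline is reproducible from the dictionary file
alone. Synonyms are matched longest-first and a matched span is consumed:
"double vision" resolves to diplopia without also firing any unigram
synonym embedded in it, while separate occurrences elsewhere in the query
still match.

Two offline expansion methods grow the synonym list the way patients
actually talk:

- `click_expansion()`: the k most frequent queries that led users to click
  a symptom's reference page (supplied as a click log).
- `lexical_affinity_expansion()`: the k most frequent word pairs
  co-occurring within a window (default 5 tokens, stopwords removed) in a
  per-symptom document corpus, emitted as two-word phrases. The window and
  the stopword list are configurable; the built-in stopword list is a small
  fixed set, since no canonical list exists for this purpose. Emitting the
  *pair as a phrase* is a choice; emitting its constituent words separately
  would over-trigger on common single words.

Defaults keep `k = 2` per method per symptom. Conflicts with the base
dictionary always resolve in favour of the base (a warning reports them),
and base synonyms are never removed.

## Reference comparators

Report databases are compared against the QLRS ranking three ways, all on
the same shared symptom set: raw report counts (rho1), EBGM (rho2) and IC
(rho3).

- **IC** uses the shrinkage form `log2((n + 0.5)/(E + 0.5))`. This is the
  standard monotone approximation to the Bayesian confidence propagation
  IC; the exact Dirichlet variant differs only in the shrinkage constants
  and not in the induced ranking behaviour we rely on.
- **EBGM** implements the gamma-Poisson shrinker in full: a two-component
  gamma mixture prior on the rate ratio, hyperparameters estimated by
  maximising the negative-binomial mixture marginal likelihood over all
  cells (Nelder-Mead followed by a BFGS polish, started from the published
  starting point alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
  w = 1/3). The reported score is the posterior geometric mean
  `exp(E[log lambda])`, computed per component via the digamma function.
  Non-convergence raises a typed error carrying the best iterate so callers
  can fall back deliberately; the pipeline falls back to the starting-point
  prior. We report the EBGM point estimate rather than the EB05 lower
  bound: the ranking, not a regulatory threshold, is what the comparison
  consumes.
- **Per-drug correlations** use Spearman's rho with average-rank ties and a
  t-approximation p-value. Correlations pool across drugs by fixed-effect
  Fisher-z meta-analysis with weights n - 3 (a DerSimonian-Laird
  random-effects variant is available); fixed effects is the primary choice
  because the per-drug correlations estimate a common mechanism on disjoint
  data.

## Most discordant ADRs and temporal onset

`greedy_mdadr()` removes, m = 5 times by default, the symptom whose removal
most increases the Spearman correlation between the query-log and reference
rankings (ties broken lexicographically), recording the correlation
trajectory and each removed symptom's direction: overemphasized in the
reference if its reference rank is better than its QLRS rank, and vice
versa. A fixed m rather than a significance target keeps the removed sets
comparable across drugs; particularly discordant drugs can be rerun with a
larger m.

One mathematical caveat, discovered while testing and kept honest: the
removal that *maximises* the correlation does not always *increase* it. For
some score pairs — roughly 1 in 1000 small random instances, e.g.
q = (35, 42, 31, 40, 93, 50) against r = (69, 89, 70, 33, 72, 86) — every
single removal lowers Spearman's rho. The greedy trajectory is therefore
non-decreasing in the overwhelming majority of cases but not provably
always; the test suite asserts the true invariant (each step attains the
maximum over available removals, checked against an exhaustive oracle) and
documents the stronger claim's failures.

Onset is defined as the gap in days between a user's first drug query and
their first symptom query at or after Day Zero — first queries only, since
repeat queries measure persistence, not onset. `temporal_profile()` turns
these into a per-symptom CDF over day offsets among exposed users (per-user
first events, not all events, define the CDF — the alternative normalisation
by all events would conflate onset with chattiness).
`onset_difference_test()` then contrasts the two discordance classes per
drug and applies a two-sided Wilcoxon signed-rank test across drugs. With
binary label sets the ranking is scored by rank-sum AUC (ties count one
half) and an F score binarised at the chi-square(1) 5% cutoff 3.841 — the
binarisation threshold is a convention, exposed as a parameter, since a
ranking has no intrinsic operating point.

## Drug pairs

For a pair (i, j), users split into three disjoint groups — searched only i,
only j, or both — with Day Zero being the first search of the single drug,
or the *later* of the two first searches for the both-group (the earliest
day on which combination exposure can exist). Each symptom's prevalence
change is summarised per group as `r = n_after / (n_before + n_after)`
(missing when never queried), and an ordinary least-squares fit
`r_both ~ c + b_i r_i + b_j r_j` over complete symptoms discounts what the
single drugs explain. Candidate interaction ADRs are the symptoms with the
largest positive standardized residuals (residual over the leave-in residual
standard error; plain OLS because "linear model" is the method's claim, with
the regression fitted per pair, across its symptoms). At least 5 complete
symptoms are required; collinear single-drug profiles are a hard error
because the discounting is then unidentified.

## The synthetic world

The simulator generates the regime the method is designed for, with every
random draw governed by one integer seed (identical configs are
byte-identical):

- **Span and windows**: a 180-day log (a 6-month window); each user is
  active over a window of at least `min_window = 60` days placed uniformly
  in the span.
- **Exposure**: each drug is adopted independently with its configured
  probability (defaults in examples: 0.2-0.35, giving realistically sized
  exposed arms); the first drug query falls uniformly in the user's window.
- **Symptom queries**: per user-day Poisson counts at a baseline rate of
  0.001 queries/user/day per symptom — about 0.18 queries per symptom per
  user per half-year, i.e. a handful of health queries per user across a
  20-50 symptom universe. This sparse regime is what real symptom search
  looks like, and it is also the regime in which the chi-square null is
  calibrated (see above); the value was fixed from that reasoning, not
  fitted to any test outcome.
- **Seasonality**: a shared sinusoid (amplitude 0.2, period 365 days)
  multiplies every rate — exactly the confound the unexposed arm exists to
  absorb.
- **Planted effects**: after a sampled onset delay following Day Zero, the
  symptom rate of an exposed user is multiplied by the effect's multiplier
  for its duration. Two onset presets cover the two reaction classes the
  discordance analysis contrasts: geometric (acute; default success 0.4,
  mean delay 1.5 days) and uniform (late; e.g. 25-45 days). Pair effects
  apply from the later of the two first-search days.
- **Reporting**: expected planted report counts are
  `n_exposed x (multiplier - 1) x per_exposed x acuteness x
  exp(-mean_delay / decay_days)` plus Poisson background in every cell.
  The exponential delay decay and the acuteness weight encode the reporting
  bias the method exists to expose; per_exposed = 0.02, decay = 30 days and
  background = 2 are defaults chosen to give report tables of realistic
  sparsity at a few thousand users.

What a green simulator-based test does establish: the statistics recover
planted structure of the stated effect sizes at the stated sample sizes,
with calibrated nulls. What it does not establish: robustness to real
query-text noise (the simulator emits matched terms directly), protopathic
bias (searching for a symptom *because* it prompted the drug), correlated
multi-drug exposure, or demographic heterogeneity — none of which have a
generative model here.

## Numerical and degenerate-input choices

- Chi-square tables with any zero margin score 0 (association inestimable);
  all-zero tables error.
- Spearman on constant ranks is NA with a warning; the greedy removal
  treats such a candidate as -Inf.
- EBGM requires E > 0; `expected_count()` returns 0 for ids absent from
  the database (and such cells are excluded from prior fitting).
- Fisher-z pooling clamps |rho| at 1 - 1e-6 before transforming; studies
  with n < 4 are excluded with a warning.
- The positive-residual filter of the interaction ranking ignores residuals
  within 1e-10 of zero so that exactly-linear fixtures report no
  candidates.
- Wilcoxon onset tests with all-zero differences return p = 1 directly
  (the test statistic is undefined there).
- All pipeline randomness derives from the single `--seed`; auxiliary
  streams (reporting, label dropout) use fixed large offsets from it, kept
  below 2^31.

## Design choices made where the design was open

- *JSON rather than YAML pipeline configs*: the R environment provides a
  JSON parser but no YAML parser; the config schema is unchanged.
- *Repeated identical queries are not deduplicated by default*: the
  counting unit is the query event; a dedup switch exists.
- *Exposed users' pre-Day-Zero history is not truncated*: no truncation
  rule is better motivated than the full observed span.
- *Expansion terms from lexical affinities are emitted as phrases*; see
  above.
- *The CLI is a thin Rscript* over exported functions — everything it does
  is available (and tested) as library calls.

## Known limitations

- Search intent is unobservable: queries may be for a relative, a patient,
  or out of curiosity. At population scale this is noise, not bias, unless
  it correlates with exposure.
- The unexposed-arm midpoint assignment biases sparse histories toward
  "after"; track a realistic symptom universe (dozens or more) before
  interpreting nominal p-values.
- EBGM hyperparameter likelihoods are multimodal; the fitted prior should
  be inspected (`print()` shows both components and the implied prior
  mean), and the starting-point prior is the documented fallback.
- The pair screen conditions on search order only through Day Zero; it
  cannot distinguish pharmacological interaction from confounding by
  indication when two drugs are co-prescribed for the same condition.
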