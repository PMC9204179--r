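---
title: "Methods: forum-based pharmacovigilance with pvforum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forum-based pharmacovigilance with pvforum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvforum)
```

`pvforum` evaluates what patient-authored forum posts contribute to drug
safety surveillance along three axes: the trend of adverse-event (AE)
discussion frequency among posts mentioning a drug, the medical richness of
longitudinally linked posts from one author, and the feasibility of
actively collecting follow-up information from posters. This vignette is
the package's own account of the models, the tunable parameters, the
synthetic-data design, and the numerical choices behind each step.

## Ingest: from raw posts to a clean analysis set

Raw posts carry `forum`, `post_id`, `thread_id`, `author_id`, a UTC
timestamp, and free text. Four stages run in a fixed order, each a pure
function that records what it removed so that
`|input| = |kept| + Σ |removed|` can be asserted on every run:

1. **Deduplication.** Posts with identical content, poster and timestamp
   are collapsed. Text is compared after Unicode NFC normalization —
   encoding variants of one string are the same post, but nothing looser
   (no near-duplicate detection). Among duplicates the lexicographically
   smallest `post_id` survives; the choice of survivor is arbitrary in
   principle, so the package fixes one deterministically.
2. **Spam removal.** A post is dropped iff its lowercased text contains at
   least one spam-lexicon phrase on word boundaries. Spam detection is a
   keyword scan, not a classifier, because the artifacts it targets
   (storefronts, press releases) announce themselves lexically. An empty
   lexicon raises an error rather than silently passing everything.
3. **Relevance filter.** A post is kept iff a generic, brand or drug-class
   keyword of some configured drug matches on word boundaries,
   case-insensitively; all matched drugs are recorded, so one post can
   count towards several products.
4. **Name masking.** Every dictionary name is replaced with the token
   `[NAME]`, which preserves token boundaries for downstream matching and
   makes the operation idempotent. Masking writes `masked_text` and leaves
   `text` untouched; it is the only stage allowed to edit content.

Whether relevance filtering should precede or follow spam removal is not
determined by the data model; the order above is adopted, and on corpora
whose spam and drug-mention plants are disjoint (as the synthetic generator
guarantees) the two stages commute — asserted as a test.

## Terminology mapping

AE verbatims are mapped through a synonym lexicon to preferred-term (PT)
codes arranged in a strict 4-level hierarchy (PT → HLT → HLGT → SOC), the
structure of a regulatory terminology such as MedDRA. Licensed content is
not distributable, so the package ships a *synthetic* fixture
(`inst/extdata/terminology_synthetic.csv`) with the same structure: 77
synonyms over 37 PTs. Loading validates the structure atomically: one
parent per code at every level, no synonym mapped to two PTs, no PT
without a full path to a SOC.

Matching is case-insensitive on word boundaries (boundaries are
transitions between alphanumeric and non-alphanumeric characters, so
hyphens inside terms are allowed), longest-match-first with lexicographic
tie-break, so results do not depend on lexicon file order. A shorter
synonym wholly inside an accepted longer match is suppressed ("thoracic
vertebral fracture" wins over the contained "vertebral fracture"), and a
PT mentioned repeatedly in one post counts once for that post. No
negation, hypothetical or third-party filtering is applied — "no more
fractures since" still counts as a fracture mention. This is a known
limitation of dictionary extraction, accepted deliberately: the package
measures discussion frequency, not verified incidence, and indication-like
PTs (e.g. osteoporosis for an osteoporosis drug) are likewise counted.

## Frequency trends

For a drug and calendar quarter, `N_q` is the number of clean posts
mentioning the drug, `n_q` the number of those also carrying the event of
interest (or any mapped event), and `f_q = 100 · n_q / N_q`. Overall
figures pool counts before dividing, so the overall frequency is the
post-weighted mean of the quarterly ones. Values are stored at full
precision; presentation rounds half away from zero (one decimal for any-AE
percentages, three decimals for event-of-interest frequencies, integers
for relative changes), matching the conventions of published summary
tables. A quarter with no drug posts has an undefined frequency, reported
as missing rather than zero. The change between two series endpoints is
`100 · (f_end − f_start) / f_start`, defined only for `f_start > 0`.

Trend interpretation is gated on a cumulative event count of at least 50 —
series thinner than that are too noisy to call. The same gate is reused in
the EBGM null-trend tests below.

A note on published inputs: summary tables of this kind occasionally carry
internally inconsistent denominators (a per-forum `N` that does not match
the grand total its percentages imply). The package's fixtures use
internally consistent counts throughout, and the worked arithmetic pools
the printed totals as given; such discrepancies are documented where they
occur, not silently corrected.

## The gamma-Poisson shrinker (EBGM)

Spontaneous-report tables are screened with the empirical-Bayes
gamma-Poisson shrinker. For cell `(i, j)` of a drug × event table with
count `N_ij`, the expected count under independence of the margins is
`E_ij = N_i· N_·j / N_··` (unstratified; stratified baselines are a
documented extension point, not implemented because no stratification
scheme is part of the analyses this package reproduces). The relative
reporting rate is modeled as

$$\lambda \sim \pi\,\Gamma(\alpha_1, \beta_1) + (1-\pi)\,\Gamma(\alpha_2, \beta_2),
\qquad N \mid \lambda \sim \mathrm{Poisson}(\lambda E),$$

with gammas parameterized by shape and rate throughout — fixing the most
common implementation ambiguity, together with the negative-binomial
success probability `β/(β+E)` in the marginal:

$$P(N) = \pi\,\mathrm{NB}\!\left(N;\,\alpha_1, \tfrac{\beta_1}{\beta_1+E}\right)
       + (1-\pi)\,\mathrm{NB}\!\left(N;\,\alpha_2, \tfrac{\beta_2}{\beta_2+E}\right).$$

**Fitting.** The five hyperparameters maximize the marginal log-likelihood,
computed cell-wise in log space with a log-sum-exp mixture combination.
Optimization runs in transformed space (log shapes/rates with box bounds
`[1e-4, 1e4]`, logit mixture fraction bounded to ±12) with L-BFGS-B from
the canonical start `(0.2, 0.1, 2, 4, 1/3)` plus four jittered restarts
drawn with a fixed seed; the best restart is returned, so refits are
bit-reproducible. The fitted log-likelihood is never below the start's — an
asserted contract.

**Scoring.** The posterior is the conjugate mixture
`Q_n Γ(α₁+N, β₁+E) + (1−Q_n) Γ(α₂+N, β₂+E)` with `Q_n` the posterior
weight of the first component. The geometric-mean score uses the digamma
identity `E[ln λ] = ψ(α+N) − ln(β+E)` per component and `EBGM = 2^{E[log₂ λ]}`.
`EB05`/`EB95` are found by vectorized bisection on the mixture CDF to an
interval of 1e-8, giving CDF accuracy well inside 1e-6; bisection is
preferred over general root finders because the CDF is monotone and the
bracket is cheap to establish. The geometric mean of a mixture is not
constrained to lie between its quantiles in general, so the package
asserts only `EB05 ≤ EB95`, `EBGM > 0` and `Q_n ∈ [0, 1]`.

**Cumulative series.** For each quarter, the table of all reports dated in
or before that quarter is rebuilt and the prior refitted from scratch — no
warm starts — so any single quarter is reproducible in isolation.

### Simulation truth for the engine

The report-table generator draws each cell's λ from the mixture, a
baseline `E` uniformly from a configured range, and `N ~ Poisson(λE)`,
recording λ per cell. The recovery harness simulates 5,000 cells with
`E ∈ [1, 100]` from the prior `π = 0.8, Γ(1,1)` (null component centered
at λ = 1) and `Γ(2, 0.5)` (a 20% component with mean 4) — the structure
typical of spontaneous-report databases, where most drug–event pairs
report at baseline and a minority are elevated. This choice matters: under
a heavy-tailed null component (shape ≈ 0.2, as in the canonical optimizer
start), the EBGM of empty cells is hyper-sensitive to the fitted shape
(`∂ ln EBGM / ∂α₁ = ψ′(α₁) ≈ 26` at α₁ = 0.2), and no estimator reproduces
true-prior EBGM within ±10% for 95% of cells at this sample size. Under
the realistic null-plus-signal mixture the harness recovers ≈99% of cells.

A caveat on trend testing: successive values of a *cumulative* series
share nearly all their data, so the Mann–Kendall statistic's iid null
variance grossly understates its dispersion — under the null roughly half
of single series fall outside the nominal 95% band, symmetrically. The
package therefore asserts trend-freeness at the ensemble level (the MK
z-score is centered at zero across 20 simulation seeds, after the
cumulative-count ≥ 50 gate) and signal detection as "last value exceeds
the first at 95% confidence across seeds".

## Longitudinal linking and the complexity score

Posts are partitioned into one dossier per author, ordered by timestamp
with post-id tie-break. Each dossier is scored `S = Σ_k u_k I_k` over a
*registry* of indicator functions, each a pure function of the dossier
returning a value in `[0, 1]`. The default registry has 28 binary
presence/threshold indicators with unit weights:

* volume/structure (5): ≥10 posts, ≥90-day span, ≥3 threads, ≥2 distinct
  PTs, ≥5 distinct PTs;
* clinical-text patterns (6): drug mention, temporal expression, dosage
  pattern, lab-value pattern, negation marker, question form;
* the seven insight-category lexicons (medical history, disease burden,
  non-medical treatments, laboratory results, treatment history,
  concomitant medications, AE mention);
* the six AE sub-element lexicons (time to onset, outcome, treatment of
  the AE, causality statement, dose, rechallenge/dechallenge);
* voice/context (4): first-person narration, HCP-visit mention, co-suspect
  drug, family/caregiver voice.

The exact indicator set of published complexity scores is not public, so
the registry is configuration with this documented default; the count 28
is enforced only for the default profile. All defaults are monotone under
appending a post, so a dossier's score never decreases as its author keeps
posting — asserted over random dossiers. The indicator lexicons are
heuristics adequate for synthetic corpora and exploratory triage; they are
not clinically validated extractors, which is why insight *coverage*
reporting runs on expert annotation files, not on the lexicons.

Coverage reports count, over annotated groups of linked posts, each of the
seven categories, the groups covering all seven, and (when post-level
annotations are supplied) single posts covering all seven. AE sub-element
percentages use all groups as the denominator — the convention of the
published tables this mirrors — even though only AE-mentioning groups can
carry sub-elements; the alternative denominator is a one-line change for
users who prefer it. Ranking of dossiers is total (score desc, earlier
first post, author id), so top-k selection is stable.

## Follow-up workflow

The AE classifier is a multinomial naive Bayes over lowercased word tokens
with Laplace smoothing `a = 1`; per-class token likelihoods normalize over
the vocabulary plus one out-of-vocabulary bucket, and an empty document
scores at the class prior. Naive Bayes is deliberately simple: ranking, not
calibrated probability, is what the workflow consumes, and the model is
exactly reproducible by hand on small corpora (the tests do so).

Completeness assessment takes the data elements a reviewer requires for
the report's AE class (a configurable map over ten elements) and computes
`missing = required \ provided`, drafting one templated question per
missing element. Sent question lists are clamped to 4–11: padded with the
generic elements (outcome, dose, action taken) when shorter — a contact
costs the same whether it asks two questions or four — and truncated at
the lowest-priority end when longer, under the fixed priority order
diagnosis confirmation > time to onset > duration > risk factors > history
of similar events > concomitant medication > relevant medical history >
outcome > dose > action taken.

Candidate selection filters to serious cases that still need follow-up and
draws a seeded random sample of up to 30 with at most two per similarity
class and one per author; if fewer than a batch (15) survive, everything
is returned with a warning — the criteria-widening hook. Seriousness and
similarity classes are *inputs* (annotation columns), not inferred: the
original workflow used expert review there, and the synthetic generator
plants them. The dual independent safety review is modeled as two
annotation tables plus a percent-agreement report, not an algorithmic
adjudicator.

The engagement simulator contacts cases in batches of 15, replacing
declines and 30-day timeouts from the remainder; consent and receipt
default to probabilities 0.205 and 0.75, the observed rates of the
follow-up campaign the package mirrors, and both are configurable.
Metrics round rates half away from zero to integers, use the midpoint
convention for even-n medians, and report time-to-receipt from both clocks
(initial contact and question dispatch).

## The synthetic corpus: what it does and does not emulate

The corpus generator emits a configured number of posts across four fora
and a quarter range (defaults 2010Q3–2021Q1), with a Zipf-skewed
posts-per-author distribution (`author_skew`, default 1 — the shape of
real forum traffic is not published, so skew is a parameter rather than an
assertion). Text is template-based: neutral filler sentences with
slot-filled drug keywords, AE synonyms drawn from the terminology, spam
phrases and person names. The filler vocabulary is disjoint from every
lexicon the pipeline matches against, so planted artifacts are the *only*
matches and precision/recall against ground truth are exactly 1 — the
point is to test the dictionary machinery, not language fidelity.
Artifacts are planted independently per post: duplicates (byte-identical
copies of an earlier post, same author and timestamp — exactly the dedup
key), spam (≥1 lexicon phrase, never a drug keyword), irrelevant posts
(no drug keyword), inserted names, and AE mentions per (drug, PT) plan
with constant, ramp or step quarter profiles. One seed drives the run;
sub-streams are derived at fixed offsets so adding a generator stage never
perturbs another. Default artifact rates (5% duplicates, 5% spam, 10%
names, 20% irrelevant) are round figures in the range such platforms
exhibit; every downstream test recovers the planted rate, whatever it is.

What passing tests on this corpus show is that the pipeline's *mechanics*
are exact: filtering matches planted sets, extraction recovers planted PT
sets, frequencies recover planted rates within binomial error. What they
cannot show is robustness to real language — misspellings, slang,
negation, novel phrasings — which dictionary matching does not attempt.

## Problem sizes and runtime

The test suite generates corpora of 300–24,000 posts, fits priors on
tables of 500–5,000 cells, and runs 20-seed ensembles of 12-quarter
cumulative EBGM series; the full suite completes in under four minutes on
one core, and `scripts/acceptance.R` in well under a minute. These sizes
were chosen so that binomial standard errors are small enough for
3-SE assertions while the suite stays fast to iterate on.

## Known limitations

* Dictionary extraction has no negation/hypothetical handling and exact
  surface matching only; real-text recall is untested by design.
* The terminology fixture is synthetic; results on it validate structure
  and algorithms, not clinical coverage.
* Expected counts are unstratified; confounding by age/sex/year strata is
  out of scope.
* The EBGM values published for proprietary report databases depend on
  unstated deduplication and stratification settings and are not
  bit-reproducible; comparisons run through endpoint relative-change
  arithmetic instead.
* Engagement simulation is a two-probability lifecycle model — adequate
  for validating metric arithmetic, not for forecasting real campaigns.
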