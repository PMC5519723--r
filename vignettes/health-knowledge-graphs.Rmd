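---
title: "Learning disease-symptom knowledge graphs from patient records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning disease-symptom knowledge graphs from patient records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical decision support and symptom-checker tools need a graph of which
diseases cause which symptoms. Curating such a graph by hand is slow and
brittle; emergency-department records contain the raw statistical signal, but
that signal is noisy: notes are informal, mentions are often negated
("denies fever"), comorbid diseases co-occur because they share causes such
as old age, and clinicians chart selectively, so information is missing not
at random. `healthkg` implements a complete pipeline that extracts binary
disease and symptom indicators from records, fits three probabilistic models
by maximum likelihood, converts each fitted model into a scored directed
disease-to-symptom graph, and evaluates candidate graphs against a reference
knowledge base and against pooled expert judgments. Because real emergency
department corpora cannot be shared, the package also contains a synthetic
record generator with known ground truth; every claim the test suite makes
is made on that generator's output.

## Data representation

Extraction produces a binary matrix with one row per patient visit and one
column per concept. Columns are split by role: `y_j` denotes presence of
disease `j`, `x_i` presence of symptom `i`. A cell is 1 when the visit has
at least one non-negated text mention of the concept or carries a diagnosis
code mapped to it. Concepts with weak support are dropped before modeling —
by default diseases with fewer than 100 positive mentions and symptoms with
fewer than 10, mirroring the support rule used to restrict a curated
vocabulary to concepts that can actually be estimated.

## The three models and their importance measures

All parameters are estimated by maximum likelihood on fully observed binary
data. Each model yields an *importance measure*, a per-pair confidence score
used to rank and select edges.

**L1 logistic regression** (one model per disease): the disease indicator is
regressed on all symptom indicators,
`logit P(y_j = 1 | x) = b_0j + sum_i b_ij x_i`. Because features are binary
and unstandardized, weights are directly comparable, and
`IMPT_LR(i, j) = max(b_ij, 0)`. The lasso penalty encourages the sparse
graphs we expect; its strength is chosen per disease by 3-fold stratified
cross-validation on held-out log-loss.

**Naive Bayes** (one model per disease): Laplace-smoothed conditionals
`p(x_i = 1 | y_j)` are closed-form counts, and
`IMPT_NB(i, j) = log p(x_i=1 | y_j=1) - log p(x_i=1 | y_j=0)`,
a log relative risk. The multiplicative form is deliberate: a rare symptom
made three times as likely by a disease should be suggested as readily as a
common one tripled. The pseudocount is selected per disease by 3-fold
cross-validation on the held-out predictive log-likelihood of the symptoms
given the label.

**Noisy-OR network** (all parameters jointly): a two-layer Bayesian network
in which each present disease independently fails to turn on symptom `i`
with probability `f_ij`, and a leak turns it on spontaneously with
probability `l_i`:

```
P(x_i = 1 | y_1, ..., y_n) = 1 - (1 - l_i) * prod_j f_ij^{y_j}
```

`IMPT_noisy-or(i, j) = 1 - f_ij`: under deterministic causation the failure
probability is 0 and the importance 1; a disease that never produces the
symptom has importance 0. Because the measure comes from the conditional
distribution alone, no assumption is made about the joint prior over
diseases — the feature that lets the model share credit among co-occurring
diseases instead of attributing a confounded symptom to each of them in
full.

## Fitting the noisy-OR network

The likelihood is maximized by expectation-maximization over the latent
per-cause activation indicators of each OR gate. Patients are grouped by
identical disease pattern, so one iteration costs
O(symptoms x patterns x diseases) regardless of corpus size. Design
choices that were genuinely open:

* **Initialization.** Leaks start at the symptom rate among disease-free
  records; activations start at the clamped pairwise moment contrast
  `max(0, p(x_i | y_j=1) - p(x_i | y_j=0))`. This is stable and often close
  to the optimum (on a single-pair deterministic instance it is already the
  MLE).
* **Monotone acceptance.** EM increases the likelihood at every step; the
  probability clamp (all probabilities kept within `[1e-6, 1 - 1e-6]`)
  could in principle break that, so any clamped update that would lower the
  likelihood is damped toward the current iterate and rejected if no
  improving damped step exists. The recorded trace is therefore
  non-decreasing and the final log-likelihood never falls below its value
  at initialization.
* **Convergence.** Iteration stops when the relative likelihood improvement
  drops below `tol` (default `1e-6`) or after `max_iter` (default 500)
  iterations. On single-pair instances the fit matches a dense 200 x 200
  grid search within `1e-3` log-likelihood; near-boundary convergence is
  geometric, so callers verifying against exhaustive oracles may prefer
  `tol = 1e-10`.
* **Determinism.** The optimizer is deterministic given the data; the
  `seed` argument exists for interface uniformity across fitters.

## From models to graphs

Scores are assembled into long-format tables and filtered in two ways.
First, a de-noising floor removes naive Bayes and logistic regression pairs
whose disease and symptom co-occur in fewer than 5 records; pairs are
removed outright (not zeroed) so a later threshold of 0 cannot resurrect
them. The floor is scoped to the two pairwise models, whose scores are
unstable at tiny co-occurrence counts; the jointly regularized noisy-OR
scores pass through, though `applies_to` can extend the floor to them.
Second, edges are selected either by a score threshold or by keeping the
top N symptoms per disease; score ties are broken by symptom id so
selection is reproducible. Graphs serialize as TSV edge lists at six
decimal places, ordered by disease, then descending importance, then
symptom id — a total order, so re-serialization is byte-identical.

## Concept extraction conventions

The extraction pipeline is intentionally rudimentary — the point of the
package is that useful graphs emerge even from simple matching — but its
rules are fixed and documented:

* Tokenization is by word characters (letters, digits, apostrophe); other
  punctuation forms single-character tokens. Matching is case-insensitive
  at word boundaries, with no stemming, so "painful" never matches "pain".
* Aliases are matched longest-first; matched spans cannot overlap, so
  "flank pain" blocks a nested bare "pain" match. Alias collisions across
  concepts resolve deterministically to the disease-role concept, then the
  lexicographically smallest id, and are logged.
* Each negation trigger ("denies", "no", "without", "negative for", ...)
  opens a forward scope running to the earliest of a termination token
  ("but", "however", "except", or sentence/list punctuation) or six
  tokens — a fixed, deterministic stand-in for clinical negation tools of
  the NegEx family, whose exact behavior varies by configuration. Mentions
  intersecting a scope are not counted.
* Diagnosis codes are matched exactly, not by prefix.
* Concepts listed under both roles are kept as diseases only, once.

## The synthetic generator

The generator exists so that every stage can be tested against known ground
truth. It emulates four features of real emergency-department data:

* **Correlated diseases.** Each patient draws an age bracket (`child`,
  `young_adult`, `adult`, `senior`); diseases are independent only given
  the bracket, so bracket-dependent prevalences induce marginal
  disease-disease correlation — the minimal structure that produces age
  confounding.
* **Noisy-OR symptoms.** Symptoms are drawn from the same conditional
  family the model fits, with hand-set activations and leaks; common
  presenting complaints (abdominal pain, nausea, headache) carry higher
  leaks.
* **Missing not at random.** An omission probability silences truly present
  symptoms (charting gaps); it applies to symptoms only, a documented
  simplification.
* **Clinical text.** Positive concepts are rendered through alias templates
  into the four free-text fields; with configured probability an absent
  concept is mentioned inside a negation phrase, which extraction must
  ignore. Diseases also emit their diagnosis codes.

The default scenario has 8 acute-care diseases and 25 symptoms with
prevalences and effect sizes in the ranges a practitioner would call
typical for an emergency department (disease prevalences 0.1-12% by
bracket, activations 0.15-0.8, leaks 1-6%). The generator does *not*
emulate realistic clinical language, longitudinal structure, spelling
variation, or vocabulary gaps, so passing tests demonstrate correctness of
the estimation and evaluation machinery — not robustness to the full
messiness of real notes.

### The confounding scenario

A dedicated configuration (`confounded_generator_config()`) makes the
correlation-versus-causation contrast testable. A target disease occurs
almost exclusively in seniors (40% prevalence there, 0.2% elsewhere); one
symptom has *no* disease parent at all and is instead activated directly by
the senior bracket (probability 0.35 against a 1% leak). Two further
senior-prevalent diseases and a uniform disease populate the record. For
the pairwise models the spurious pair is a strong association — on the
relative-risk scale of naive Bayes it outranks the disease's genuine
symptoms, whose leaks are substantial. The noisy-OR network cannot remove
the association either (age is not one of its nodes), but its importance
lives on the absolute activation scale, where the residual spurious
activation (about 0.26 at these settings) falls below the disease's strong
true effects. The contrast is asserted as a rank statement over ten seeded
corpora of 20,000 visits: the confounded symptom ranks strictly better
under the naive Bayes importance than under the noisy-OR importance.

## Evaluation framework

Two complementary frameworks are implemented. The automatic one scores a
candidate graph against a reference knowledge base: the binary target is
edge membership, every distinct score is swept as a threshold, and
precision/recall are micro-averaged from one pooled contingency table per
threshold. The overly general symptom "pain" is excluded from both sides by
default, since reference graphs use it inconsistently. The recall
denominator counts the surviving reference edges. Because reference graphs
are precise but incomplete, this evaluation is treated as a relative
ranking of models, not an absolute quality measure.

The clinical framework implements retrieval-style pooling: the top N
suggestions per disease from each model (plus all reference edges) are
unioned, shuffled under a seed to blind judges to provenance, and rated on
the four-point scale always / sometimes / rarely / never. Two binarizations
are supported: `rarely_positive` (only "never" is negative) and
`rarely_negative` (both "rarely" and "never" are negative). Edges outside
the pool count as irrelevant.

Model comparisons use a Wilcoxon signed-rank test on matched per-disease
precisions at a fixed edge budget. Zero differences are dropped (the
classic treatment; Pratt's is available), absolute differences receive
average ranks under ties, and with up to 25 nonzero pairs the exact null
distribution is computed by dynamic programming — valid under ties, which
the textbook exact tables are not; beyond that a tie-corrected normal
approximation with continuity correction is used. Inter-rater agreement is
Spearman's rho with a percentile bootstrap over edges (default 1000
resamples); replicates with a constant resample are dropped and counted.

## Numerical conventions and degenerate inputs

All estimated probabilities are clamped to `[1e-6, 1 - 1e-6]`, so
log-likelihoods are always finite and "boundary" estimates report as
0.000001 / 0.999999. Constant disease labels raise a "degenerate label"
error rather than fitting silently; cross-validation grid points whose
folds lose a class are skipped with a warning; an all-zero difference
vector in the signed-rank test and a constant rating vector in the
agreement measure are errors. Cross-validation folds are stratified by
label and derived deterministically from the seed by shuffling within the
sorted positive and negative id sets, so fold assignment — and hence
hyperparameter selection — is invariant to patient order.

## Problem sizes

The package's own test suite runs its simulations at sizes chosen to make
the statistical claims sharp while keeping a full run in the tens of
seconds: limiting-behavior fits at 10,000 records, single-pair parameter
recovery at 50,000, recovery-versus-n checks at 1,000 / 10,000 / 100,000,
the confounding contrast at ten corpora of 20,000, and rate checks on the
generator at 100,000. Pattern grouping makes the noisy-OR fit cheap at all
of these sizes.

## Known limitations

The models permit no symptom-symptom edges and assume symptoms conditionally
independent given diseases; graphs are candidate causal relations, not
proven ones — unobserved confounders beyond the modeled age bracket would
mislead all three models. The extraction pipeline has no spelling
normalization, so real-world surface variation ("bullseye", "bull's eye")
fragments support. The pooling protocol is known to be optimistic about
recall while remaining a fair basis for comparing systems, which is how it
is used here.
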