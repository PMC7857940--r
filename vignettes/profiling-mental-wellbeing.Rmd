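---
title: "Latent-factor profiling of mental well-being questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-factor profiling of mental well-being questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spfmProfiles)
```

## The problem

Psychiatric outpatients who use e-mental-health apps answer short
self-report questionnaires about their current well-being. A pooled
assessment of 23 items (a six-item day assessment, the WHO-5 Well-Being
Index, and the GHQ-12), each answered on a 0–100 agreement scale,
yields one response vector per patient. The analytic goal is a *digital
phenotype*: a small number of latent response patterns ("factor sets")
that, combined with an always-present default pattern (the *bias
term*), summarize how patients answer — and patient *profiles* defined
by which factor sets are active, which can then be compared against
clinician-derived variables (ICD-10 diagnostic chapters, the Clinical
Global Impression scale, age, sex).

`spfmProfiles` implements this pipeline end to end: preprocessing,
a sparse Poisson factorization model (SPFM) with an Indian Buffet
Process (IBP) prior, K-means profiling of the latent activations, and
the clinical association tables. Because cohorts of this kind are not
publicly shareable, the package ships a seeded synthetic cohort
generator with planted latent structure; every stage of the pipeline is
tested against that ground truth.

## Preprocessing

Two steps turn raw scores into the model's input:

1. **Valence inversion.** Items 1–15 are phrased positively (high =
   good health) and are reflected, $s \mapsto 100 - s$, so a high score
   on any item means poorer mental health
   (`invertPositiveItems()`).
2. **Top-decile dichotomization.** Each item is cut at its own
   empirical 90th percentile; only scores *strictly above* the
   threshold are coded 1 (`dichotomizeTopDecile()`). This isolates
   extreme responders: respondents avoid scale endpoints unless they
   identify with them, so the top decile carries the discriminative
   signal.

The percentile uses the nearest-rank convention
(`quantile(type = 1)`), and ties at the threshold are coded 0. This
pair of choices guarantees *at most* 10% ones per item — exactly 10% on
tie-free columns of length divisible by 10 — and makes the coding
invariant under strictly increasing transforms of an item's scores.
Thresholds are estimated per item across the analysis cohort, not fixed
a priori, and are returned alongside the binary matrix for
reproducibility. Missing cells stay missing: they are masked inside the
model likelihood rather than imputed, because imputation would
fabricate exactly the extreme responses the method looks for. Per-item
degenerate cases follow from the rule: a constant column yields all
zeros; an all-missing column is an error naming the item.

Clinical analyses use different denominators (`completenessFilter()`):
the model keeps all patients (cell-level masking), the CGI analysis
keeps patients with a recorded CGI, and the diagnosis analysis keeps
patients with at least one ICD-10 chapter.

## The model

Let $X \in \{0,1\}^{N \times D}$ ($D = 23$) be the dichotomized
responses. The SPFM posits a binary activation matrix
$Z \in \{0,1\}^{N \times K}$ (patient $n$ has factor set $k$ active iff
$Z_{nk} = 1$), nonnegative weights $\beta \in \mathbb{R}_{\ge0}^{K
\times D}$, and a nonnegative bias vector $b \in \mathbb{R}_{\ge0}^D$
shared by all patients. Responses follow a Bernoulli–Poisson link,

$$
\lambda_{nd} = b_d + \sum_k Z_{nk}\,\beta_{kd}, \qquad
P(x_{nd} = 1) = 1 - e^{-\lambda_{nd}},
$$

i.e. each cell carries a latent Poisson count with rate
$\lambda_{nd}$ and the response is 1 when the count is positive. The
link keeps all weights nonnegative and additive — a higher weight of an
active factor set on an item means a higher probability of an extreme
answer on that item — and admits exact conjugate updates (below). The
number of factor sets is not fixed: $Z$ has an IBP prior with
concentration $\alpha$, so $K$ is inferred. The bias term is the
"default eHealth-user" pattern: formally a factor active for every
patient, playing the role of an intercept.

Assumptions worth stating: cells are conditionally independent given
the rates; factor effects are additive on the rate scale (never
antagonistic); and missingness is ignorable given the mask.

## Inference

`fitSpfm()` runs an uncollapsed Gibbs sampler written in C++:

* **Activations.** Each existing $Z_{nk}$ is Gibbs-updated with IBP
  prior odds $m_{-nk}/(N - m_{-nk})$ and the likelihood ratio of the
  patient's row; factors currently owned by one patient are updated by
  a Metropolis–Hastings birth/death move that proposes
  $\mathrm{Poisson}(\alpha/N)$ new factors (capped at
  `maxNewFactorsPerStep`) with weights drawn from the prior, so the
  acceptance ratio reduces to a likelihood ratio. Empty factor columns
  are pruned every sweep.
* **Weights.** On each observed $x_{nd} = 1$ a latent count is drawn
  from a zero-truncated Poisson and thinned multinomially over the
  active sources (bias + active factors); all $\beta_{kd}$ and $b_d$
  then have closed-form Gamma posteriors.
* **Concentration.** Under the default Gamma(1, 1) hyperprior,
  $\alpha$ is resampled conjugately from $K$ and the harmonic number
  $H_N$.

**Initialization.** The chain starts from an *overcomplete* random
state: `kInit = 6` factors with Bernoulli(0.2) memberships. Shared
structure then condenses onto a few columns while surplus factors lose
members and die. Starting from the empty matrix instead leaves
nucleation to the single-patient birth move, which must propose, from
the prior, a weight vector that simultaneously fits one row — in 23
dimensions this essentially never seeds a factor that many patients
share, and the chain stalls in a bias-only mode.

**Priors.** Weights default to Gamma(1, 5) (mean 0.2). On top-decile
data, per-item response probabilities rarely exceed ~0.5, i.e. rates
below ~0.7; a mean-1 prior concentrates on implausibly large weights
and has a second, subtler cost: it makes a dedicated factor for one
extreme patient marginally profitable, so the posterior accumulates
persistent single-patient factors and the inferred $K$ creeps upward.
The mean-0.2 prior together with the data-adapted $\alpha$ (about 0.35
when two factors explain a cohort of 1000) keeps such idiosyncrasy
factors unprofitable while leaving well-supported factor weights —
which are estimated from hundreds of active patients — essentially
untouched. Both settings are user-visible (`betaPrior`, `alphaPrior`)
and can be restored to a fixed $\alpha = 1$ with mean-1 weights.

**Defaults.** 2000 sweeps with 1000 burn-in (a $1000 \times 23$ cohort
fits in a few seconds); every 10th post-burn-in sample is stored. The
per-sweep log joint (IBP prior + Gamma priors + likelihood) is recorded
as a trace for convergence inspection.

**Posterior summary.** The reported number of factor sets is the mode
of $K$ over post-burn-in sweeps. `Zmap` is the most recent post-burn-in
sample with the modal $K$; `betaMean` averages the stored samples with
modal $K$ after greedily matching their factor rows to that reference
by cosine similarity. This is deliberately simpler than a full
posterior alignment of the (label-free) factor space and is documented
as such; for well-separated planted structure the matching is
unambiguous.

## Profiles and associations

`kmeansProfiles()` clusters the rows of $Z$ with K-means and a number
of clusters fixed a priori (default $2^K$, i.e. 4 for two factor
sets). When the distinct activation rows number exactly $k$, the
distinct rows seed the centers, so the converged partition equals the
exact group-by-pattern partition for every seed — the group-by oracle
is what the tests compare against, K-means is the shipped path.
Profiles are relabeled canonically from rounded centroids: profile 0
has no active factors (bias only), then profiles are ordered by the
binary code of their active factor indices.

`composeProfileWeights()` builds the profile-by-item weight table: a
profile's column is the sum of its active factors' weight rows, so the
both-factors column equals the sum of the two single-factor columns
exactly; the bias weights are reported as a separate profile-0 column
rather than folded into every profile (published reference tables of
this form satisfy factor-only additivity, which settles the ambiguity
in favor of factor-only columns). `profileItemMeans()` provides the
empirical companion — mean observed inverted scores per profile — since
both readings of a "per-profile item score" table are useful.

`crosstabDiagnosisByProfile()` counts each patient once per carried
ICD-10 chapter (so a comorbid patient appears in several rows; row
totals can exceed the number of diagnosed patients, and the result is
flagged `multiCounting`). `cgiByProfile()` reports per-profile CGI
means, SDs and score distributions (percentages to one decimal, means
and SDs to two, matching conventional reporting). Profiles with no
patients in the filtered cohort are omitted with a note rather than
reported as empty rows. `testProfileHomogeneity()` checks age (one-way
ANOVA F) and sex (Pearson chi-square without continuity correction,
missing sex excluded) across profiles; no multiplicity correction is
applied since exactly two planned tests are run.

## The synthetic cohort generator

`generateCohort()` emulates the cohort structure the pipeline assumes,
with all parameters fixed in `cohortConfig()`:

* Two planted factor sets: items 1–15 (prevalence 0.21) and items
  16–23 (prevalence 0.27), activated independently per patient; a bias
  set {16, 17, 23} (aggressiveness, suicidal thoughts, worthlessness).
* Scores live on a latent distress scale: baseline
  $\mathrm{Beta}(2,5) \times 100$, versus a high-score regime
  $\mathrm{Beta}(8,1.2) \times 100$ on items driven by an active
  factor. Positive-valence items are stored reflected (as the app asks
  them) so preprocessing exercises the inversion. The two regimes are
  an implementer's choice — no per-item distributions are published for
  such data — selected so that the high regime dominates each item's
  upper tail.
* Bias-set items draw the high regime with probability
  `biasRate = 0.25` for *every* patient. This is what makes the bias
  term identifiable: extreme answers on those items occur throughout
  the cohort instead of concentrating in the factor-active minority.
  Note that because dichotomization pins every item's marginal rate at
  10%, an item that belongs to *no* factor set is maximally bias-like
  (its ones are unexplained by any factor), so the default
  configuration assigns every item to a factor set.
* Cell-level missingness is completely at random at rate 0.12; sex,
  CGI and diagnosis missingness, the ICD-10 chapter mixture (dominated
  by F4, F3, F6), a 15% comorbidity rate, the CGI distribution (modal
  scores 3 and 4, mean ≈ 2.95) and the age distribution
  (Normal(52, 15.1), truncated 18–95) match the reported marginals of
  a large outpatient cohort. Where a published summary pins only part
  of a distribution (the CGI frequencies of scores 0, 1, 2, 5), the
  remainder was filled in once to match the reported mean.

What the generator does **not** emulate: real psychometric item
correlations within an instrument, heaped/tied Likert responses (draws
are continuous, so dichotomization is exactly 10% — real data have ties
and can deviate), correlation between the two factor sets (planted
independently; in real cohorts severe patients make factors co-occur),
any dependence of diagnoses or CGI on the latent factors, and repeated
assessments. Passing the recovery tests therefore shows the inference
machinery is correct under the model's own assumptions — it does not
certify behavior on real response data, where the model is at best a
useful approximation.

## Numerical choices and test scale

* Factor "support" (for reporting which items a factor drives) is read
  at weight > 0.05, well above the posterior mean a weight takes when
  no count is ever attributed to it (~1/(5 + members)).
* Recovery checks in the test suite use cohorts of $N = 1000$ patients
  and $D = 23$ items, ten generator seeds, 2000 sweeps each; accuracy
  is Hamming agreement of `Zmap` with the planted activations after
  column matching (≥ 0.9) and Jaccard overlap of recovered versus
  planted item supports (≥ 0.8), with the modal $K = 2$ required in at
  least 8 of 10 seeds. These sizes keep the whole suite under a minute
  on one CPU while leaving the binomial noise floor well below the
  thresholds.
* K-means is run with 25 random starts when clusters do not coincide
  with distinct activation patterns; with two factors and all four
  combinations present the partition is exact regardless.

## Limitations

The posterior summary collapses factor-label uncertainty with a greedy
cosine match; cohorts with genuinely overlapping factors would need a
full relabeling treatment. The Bernoulli–Poisson link cannot express
inhibitory factors (weights are nonnegative). Top-decile coding
discards within-decile severity information by design. And since the
bias term is statistically indistinguishable from "ones unexplained by
any factor", interpreting it as a shared behavioral pattern — rather
than residual noise — requires the substantive argument, not just the
fit.
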