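---
title: "Semantic trajectories in verbal fluency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic trajectories in verbal fluency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In a timed verbal fluency task a participant names as many words as they can
from a cue — a semantic category ("animals") or an initial letter ("p") —
in a fixed interval. The order in which words are produced is not random:
retrieval tends to move between semantically related items, like a forager
moving through patches of food. `semtraj` quantifies this structure by
treating each word list as a *trajectory through a word-embedding space*
and asking, at several levels of description, how strongly semantic and
orthographic proximity guide the next retrieval, and how that guidance
changes with task goals. The package was built for two-group designs
(e.g. patients with schizophrenia vs controls), where a reduction in
semantically guided sampling is a candidate behavioural marker of
disorganized conceptual structure, and where per-participant indices are
subsequently correlated with neural covariates such as replay-associated
ripple power.

# Similarity spaces

Words are embedded as rows of a pretrained word-vector table (fastText-style
`.vec` text format; conventionally 300 dimensions). Two similarity channels
are defined over a task vocabulary:

* **semantic** — cosine similarity `v.w / (||v|| ||w||)`; semantic distance
  is `1 - cosine`.
* **orthographic** — `1 - levenshtein(a, b) / max(nchar(a), nchar(b))`.
  Normalising the edit distance by the longer word length puts both
  channels on comparable bounded scales, so the salience parameters of the
  choice model (below) are comparable across channels. The raw edit
  distance remains available (`normalize = FALSE`); the choice of
  normalisation is a genuine degree of freedom and is therefore exposed.

Words are lowercased, trimmed, and multiword responses joined with
underscores, matching embedding token conventions. Responses missing from
the embedding are excluded from semantic analyses and recorded in an
out-of-vocabulary report — never silently dropped; they remain in
orthographic analyses.

# Path optimality

For a list of $n$ unique items, the *observed* trajectory length is the sum
of consecutive distances. The *optimal* trajectory is the shortest
Hamiltonian path over the same items. Two divergences are computed:

* **global** — observed total minus optimal total;
* **local** — each observed transition (a, b) is scored by the number of
  edges separating a and b in the optimal ordering, and the scores are
  summed. This is sensitive to transition-level agreement with the optimal
  path even when total distance differs.

Both are z-scored against the participant's own shuffled lists: the item
order is permuted uniformly (the optimal path is order-invariant, so only
the observed statistic is recomputed), and
`z = (observed - mean(null)) / sd(null)`. z near 0 is what a random
selection process produces; negative z indicates similarity-guided
clustering. Because each participant is compared only against
rearrangements of their own vocabulary, the z-scores control for
differences in list length and content between participants.

Numerical choices:

* **Solver.** Held–Karp dynamic programming gives the exact optimum up to
  `n = 12`; beyond that a nearest-neighbour construction from multiple
  starts refined by 2-opt reversals (to a local optimum) provides a
  deterministic upper bound. Exactness where checkable, reproducibility
  everywhere: the heuristic contains no randomness.
* **Endpoints.** By default the optimal path's endpoints are free. The
  alternative of anchoring the path at the participant's first word is
  available (`start_policy = "first"`), but holding an anchored optimal
  path fixed across shuffles breaks the exchangeability of the permutation
  null: the anchored item is, by construction, an endpoint of the optimal
  ordering in the observed list but not in shuffled lists, which biases the
  local-divergence null visibly negative. With free endpoints the optimal
  ordering is a pure function of the item *set*, observed and shuffled
  lists are treated identically, and the null is calibrated. This is why
  free endpoints are the default.
* **Shuffles.** 1,000 per list by default; the seed is recorded in every
  output. Degenerate nulls (zero spread, e.g. equidistant items) yield
  `z = NA` with a flag rather than an error.
* **Windows.** To compare groups whose list lengths differ, both
  divergences can be computed in every sliding window of a fixed length
  (stride 1, each window z-scored against within-window shuffles, then
  averaged). The conventional window is the task-wide minimum list length
  (`window = "auto"`). A single whole-list window reproduces the
  unwindowed statistics exactly. Shuffle nulls are per-window; windowed
  and unwindowed z-scores are therefore on the same scale.

# Semantic communities

The similarity matrix of the pooled unique items (per task, across all
participants) is clustered with Louvain modularity maximisation
(resolution 1 by default) on the complete weighted graph with edge weights
`max(cosine, 0)` — negative cosines carry no attachment weight under
modularity, so they are floored at zero rather than shifted. Each list then
becomes a sequence of community labels, summarised by:

* **lifetimes** — lengths of maximal runs of the same community (how long
  retrieval dwells in a patch);
* **returns** — for each community, the number of maximal runs beyond the
  first (how often retrieval revisits an exhausted patch).

Both are z-scored against shuffled lists with the same windowing scheme as
the optimality statistics. Retrieval dynamics are probed with a
per-participant OLS of log inter-item retrieval time on (1) demeaned
semantic distance to the previous item, (2) a community-switch indicator,
(3) response number as a proportion of list length, and (4) an intercept;
the first item has no predecessor and is excluded, and nonpositive
durations are dropped and counted. A positive switch coefficient means
retrieval slows when crossing community boundaries.

# The softmax local-search choice model

The generative model treats word production as a local search: given the
previous word $w_{t-1}$, the next word is drawn from the not-yet-produced
task vocabulary with probability

$$P(w_t = w) \propto \exp\!\big(\beta_{sem} S_{sem}(w_{t-1}, w) +
\beta_{orth} S_{orth}(w_{t-1}, w)\big),$$

where the candidate set is the pooled unique vocabulary for the task minus
the participant's earlier responses (lists contain unique words, so the
generative process cannot re-emit; a with-replacement variant that only
excludes the immediately preceding word is available as a config switch).
The first item of each list is conditioned on, not modelled. Softmax
probabilities are invariant to adding a constant to all similarities, so
only the *spread* of each similarity channel matters; using similarities or
negated distances is equivalent up to the sign convention of β.

The model family crosses the two channels with task sharing: semantic-only,
orthographic-only and both channels, each either shared across the category
and letter tasks or task-specific. The full member has four parameters
(β_sem and β_orth per task) and can be read as two independent 2-parameter
models. Fits are per participant over the concatenated two-task data by
maximum likelihood: the log-likelihood is concave (conditional-logit form),
and is maximised with bounded L-BFGS-B (analytic gradient, bounds
β ∈ [−20, 50], five seeded uniform [0, 5] starts whose role is convergence
checking rather than mode exploration). Models are compared by AIC summed
over participants.

From the full model, per-task **ω = β_sem − β_orth** measures how much
semantic exceeds orthographic guidance, and
**Δω = ω_category − ω_letter** ("goal-induced semantic modulation")
measures how much that balance shifts with task goals. Δω is the package's
headline per-participant index: it is compared between groups, correlated
with path-optimality z-scores and performance, and regressed on neural and
symptom covariates.

# The synthetic cohort generator

Because real fluency datasets of this kind are not freely redistributable,
validation rests on synthetic cohorts with known ground truth
(`simulate_cohort()`). The generator is the package's definition of the
study conditions, not a tuning knob; its defaults are:

* **Spaces.** Per task, 300 words in 300 dimensions around 8 planted
  community centroids; mean within-community cosine 0.55 and
  between-community 0.10 (member dispersion is calibrated by bisection to
  the within target, tolerance 0.05; community loadings on a shared
  component are graded so between-community similarity is a continuum).
  Within-community subclusters (`n_subclusters`) are available for
  analyses that need graded rather than near-binary distances. Lexicons
  are phonotactically plausible pseudowords built from a small
  Zipf-weighted syllable pool — this produces word families with a
  realistic spread of pairwise edit distances (uniform random letter
  strings are nearly equidistant, which starves the orthographic channel
  of information); letter-task words share the initial letter "p".
* **Agents.** Per-participant true salience parameters are drawn from
  group distributions; the defaults plant the group contrast entirely in
  β_sem.CAT (controls N(4.2, 1.9) vs patients N(2.6, 1.9), common
  β_orth.CAT = N(0.5, 0.3), β_sem.LETT = N(0.5, 0.3),
  β_orth.LETT = N(2, 0.5)), giving planted Δω means of 5.2 vs 3.6 with SD
  near 2 — the scale of between-participant spread reported for cohorts of
  this size. List lengths are rounded normals (category mean 42, floor 32;
  letter mean 24, floor 15).
* **Retrieval times.** log RT = 1.8 + 0.5·(community switch) +
  0.3·(semantic distance) + N(0, 0.4), exponentiated and cumulated; the
  intercept corresponds to a ~6 s median inter-item interval.
* **Covariates.** A ripple-power proxy 2.4 + 0.16·Δω_true + N(0, 0.45) for
  all participants; a negative-symptom proxy 14 − 1.0·Δω_true + N(0, 4.3)
  for patients; a medication indicator for half the patients.

What the generator deliberately does *not* emulate: perseverations and
intrusions (lists are valid-unique by construction), real lexical
statistics and word frequency effects, within-session fatigue, embedding
anisotropy, and any model-misspecified retrieval process (agents follow
exactly the fitted model family). Passing recovery tests therefore
demonstrates that the estimation and inference machinery is correct and
calibrated under the assumed process — not that the model is true of human
retrieval.

# Validation design and problem sizes

The test-suite validations run at sizes chosen to give informative
Monte-Carlo precision at desk scale: exhaustive-enumeration checks of the
path solver at n ≤ 8; permutation-null calibration over 200 random lists of
length 32 against a 300-word space at 1,000 shuffles; parameter recovery
over 50 simulated participants per design (list length 40) with true
parameters dispersed (SD 2) around the reference values for the
correlation check and fixed at them for the bias check; model recovery
over 20 cohorts of 26+26 under the task-specific regime and 5 under the
shared regime; effect-direction recovery over 20 cohorts at the planted
group contrast; RT-switch recovery over 100 lists in the mild hierarchical
space described above; and 2,000-replicate type-I calibration of each
routed test at α = 0.05. Two caveats surfaced by the recovery analyses are
worth stating plainly:

* With ~40-item lists the per-parameter standard error of the MLE is near
  1 for the weakly informative channels (a Fisher-information limit, not an
  optimizer issue), so per-parameter recovery correlations at true SD 2 sit
  close to 0.9, and small reference values (β = 0.5) carry finite-sample
  shrinkage of order 1/T that is large *relative to them*. Bias is
  therefore summarised relative to the mean parameter magnitude.
* Group comparisons of fitted Δω inherit this estimation noise on top of
  the planted spread; at the planted contrast the cohort-level effect size
  is ~0.5–0.6, so a single 26+26 cohort detects the group difference in
  roughly half of replicates. The direction-of-effect couplings
  (Δω–optimality, Δω–ripple) are robust.

# Statistical layer

Group comparisons are routed by a Shapiro–Wilk test on pooled group-demeaned
residuals (α = 0.05) to a pooled-variance two-sample t test or a Wilcoxon
rank-sum test whose statistic is reported as the tie-corrected normal z.
Task-by-group designs use a 2×2 mixed ANOVA (between-participant group,
within-participant task), reported on (1, n−2) degrees of freedom.
Correlations are Spearman or Pearson with two-tailed p. Interaction
regressions demean the covariate before forming the product term so the
main and interaction coefficients are interpretable separately; the
raw-covariate fit is reported alongside. No multiple-testing correction is
applied anywhere — the report instead counts the tests it ran so users can
apply their own. Group coding is control = 0, patient = 1 throughout.

# Known limitations

* The heuristic path solver guarantees only a 2-opt local optimum beyond
  12 items; optimality divergences at realistic list lengths are computed
  against an upper bound. Because the same bound enters observed and
  shuffled statistics symmetrically, the z-scores remain internally
  consistent.
* The choice model's candidate set is the pooled task vocabulary, which
  assumes every participant could in principle produce any pooled word.
* Fitted salience parameters are noisy at single-list lengths; analyses
  that depend on their between-participant variance should expect
  attenuation, and Δω group contrasts at n = 26 per group are underpowered
  unless the true contrast is large.
* The RT regression's semantic-distance and community-switch regressors are
  strongly collinear in sharply clustered spaces; coefficient estimates
  remain unbiased but their variance grows, which matters for small lists.

# A minimal session

```{r demo}
library(semtraj)

cohort <- simulate_cohort(cohort_config(seed = 1))
analysis <- analyze_cohort(cohort$lists, cohort$sims, cohort$covariates,
                           window = "full", n_shuffles = 1000, seed = 1,
                           trajectory_tasks = "category")

analysis$report$delta_omega$group_comparison
analysis$report$delta_omega$optimality_global
analysis$report$ripple$correlation
```
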