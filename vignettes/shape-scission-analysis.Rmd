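---
title: "Methods: analysing causal-history categorization experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing causal-history categorization experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapescission)
```

This vignette documents the models, estimators and design choices behind
the package: what is computed, under which assumptions, and where the
design was genuinely open, which option was taken and why.

## The experimental structure

All analyses operate on a long-format trial table over a fully crossed
design: 6 materials × 4 transformations × 30 exemplar photographs
(720 stimuli), 15 observers per task. Three task types share the table:

- **naming**: each stimulus elicits a free-text material name and a
  free-text transformation name (two rows, distinguished by
  `response_domain`); each observer sees one exemplar per cell.
- **rating**: block-wise ratings on a bar mapped linearly to [0, 1]; in
  each block all stimuli are judged against one category label, the
  block set being either all materials or all transformations; each
  observer sees 7 exemplars per cell.
- **afc**: four-alternative forced choice among the transformation
  labels over all 720 stimuli.

Exemplar and viewpoint variation is treated as replication, never as a
factor: responses are averaged over it everywhere. The `repetitions`
field of a design means independent repeats of each stimulus (and, for
rating, of each stimulus-by-scale pairing); the rating task's blocks are
generated from the scale list itself, so a standard rating design has
`repetitions = 1` and one row per observer × stimulus × scale.

## Confusion matrices and their semantics

A confusion matrix here always carries explicit semantics, because the
three tasks produce numbers on different footings:

- `percent_of_responses` (naming): entry (i, j) is 100 × the share of
  responses coded j among *all* responses to category-i stimuli. Free
  naming produces out-of-category answers ("kinked", "plastic"); these
  enter the denominator but not the square matrix, so rows sum to less
  than 100. The per-row OTHER share is kept alongside the matrix. OTHER
  is not a column: the performance statistics compare against a square
  identity matrix, and an OTHER column would have no matching
  prediction entry.
- `mean_rating` (rating): entry (i, j) is the mean rating on scale j
  for category-i stimuli. Rating "accuracy" is taken as the mean
  normalized rating itself; the bar maps linearly onto [0, 1] with no
  further transformation.
- `choice_proportion` (afc): rows are multinomial proportions summing
  to 1.

Group matrices pool trials; per-observer matrices are also available,
and under a balanced design the pooled matrix equals the average of the
per-observer matrices (a test asserts this identity). Undefined cells
(an actual category with no responses) raise errors rather than
becoming silent zeros — in a balanced design they always indicate a data
problem.

## Performance statistics

**perf.** For unit-scale matrices, `perf = 1 − mean(|R − P|)` with the
identity as the default prediction P. Percent matrices are divided by
100 first so that all tasks share the scale on which chance for a
binary response matrix is exactly 0.5 (E|b − U| = 1/2 for b ∈ {0, 1},
U ~ Uniform(0, 1)). perf is symmetric in its arguments and invariant
under a joint row/column permutation of both.

**Bootstrap CI.** The resampling unit is the observer: observers are
drawn with replacement, their matrices averaged, and perf recomputed;
the 95% interval is the percentile interval over `n_boot` resamples
(default 10,000). Resampling observers rather than trials respects the
repeated-measures structure; a coverage simulation in the test suite
checks the interval empirically at reduced replications.

**The random-prediction null.** The null ensemble is, by default,
prediction matrices with i.i.d. Uniform(0, 1) entries compared against
the *observed* response matrix. This choice has a consequence worth
stating: the null mean of perf depends on the response matrix, since
E|r − U| = r² − r + 1/2 is largest at r ∈ {0, 1} and smallest at
r = 1/2. Only a binary response matrix gives exactly 0.5; realistic
response matrices give null means in the 0.55–0.65 range. An
alternative `null_kind = "permutation"` uses random row permutations of
the identity — random relabelings of a perfect categorizer; a test
enumerates all 24 permutations of the 4×4 case (perf ∈
{0.5, 0.625, 0.75, 1}, by fixed-point count) against the sampled
distribution.

**Null R².** The signed correlation between the response matrix and a
random matrix is centred at zero, so its mean across draws — and the
square of that mean, reported as `null_r2` — is the chance-level
reference that prints as 0.00. The mean of the *per-draw squared*
correlations is deliberately reported separately
(`null_r2_draws_mean`): for k matrix cells it concentrates near
1/(k − 1) (about 0.067 for 4×4) and is therefore *not* a chance level,
a distinction that is easy to miss when summarising null correlations.

**Consistency.** Mean Pearson correlation between the flattened
matrices of all unordered observer pairs; observers with constant
matrices (undefined correlation) are excluded with a warning.

## Repeated-measures ANOVA with Huynh–Feldt correction

Per-cell accuracy (proportion correct for afc and coded naming; mean
true-scale rating for rating tasks) feeds a two-way within-subject
decomposition. Each effect is tested against its effect-by-subject
interaction:

F = MS_effect / MS_effect×subject.

Sphericity — equal variances of all pairwise condition differences —
rarely holds for factors with more than two levels, so degrees of
freedom are multiplied by an estimated ε. For each effect, the cell
vectors are projected onto an orthonormal contrast basis of that effect
(main effects averaged over the other factor; the interaction uses the
Kronecker product of both bases), ε_GG = tr(S)²/(d · tr(S²)) is computed
from the covariance S of the d contrast scores, and the Huynh–Feldt
adjustment ε_HF = (n·d·ε_GG − 2)/(d·(n − 1 − d·ε_GG)) is applied and
capped at 1. This is the estimator convention SPSS and `car` use; the
test suite requires agreement with `car::Anova` on SS, F, ε and p to
1e−6 over 50 random balanced tables, and checks that the corrected
test's type-I error stays near 5% under a strongly non-spherical null
(2,000 simulated 8-subject 3×4 tables). Degenerate inputs are defined
rather than accidental: a two-level factor has ε = 1 exactly; data with
no condition variance give F = 0, p = 1; a nonzero effect with zero
error SS warns and reports p = 0.

Post-hoc comparisons are paired two-sided t-tests on observer means
averaged over the other factor, reported with raw p-values and the
conventional star flags (p < .05, p < .001); no multiplicity correction
is applied, matching how such supplementary tables are usually
presented. Greenhouse–Geisser ε is reported in the tidy output but not
used for p-values.

## PCA of rating profiles and separability

Each aggregated stimulus group (by default one row per transformation ×
material combination, 24 rows) becomes a point in the space of rating
scales. PCA uses the eigendecomposition of the covariance of
column-centered profiles. Columns are centered but not rescaled: all
scales already share the [0, 1] rating unit, and rescaling would
inflate scales with little variance. Component signs follow a
deterministic convention (the largest-magnitude loading of each
component is positive), so results are reproducible across platforms;
`prcomp` serves as the test oracle up to sign.

Separability of a labeling is the mean silhouette width of the points
in the first k = 3 components (matching the three-dimensional view such
data are usually inspected in): for each point, (b − a)/max(a, b) with
a the mean distance to same-label points and b the smallest mean
distance to another label. Singleton labels and all-zero distances
score 0 by convention; a single label is an error. The scission
property is then a testable statement: profiles simulated with
material-driven kernels and transformation-independent noise score high
under material labels and near zero under transformation labels, and
the ordering flips when the kernels are transformation-driven. The test
suite verifies the sign of this difference across 20 independently
seeded simulated experiments.

## The observer simulator

The generator exists so the full pipeline, including its edge cases, is
exercisable without any download. It is a stimulus-conditional
categorical model, not an image model:

- **Kernels.** Per material × transformation cell, a probability vector
  over response categories. The default construction puts `accuracy`
  mass on the true category and spreads the rest uniformly; in the
  transformation domain the bent↔folded cross entries are set to
  `bentfold_confusability` times a per-material multiplier (then rows
  are renormalized), encoding the empirically dominant confusion —
  bending and folding leave similar shape traces, most strongly in
  materials like wire whose local features are hard to resolve. With
  confusability 0 the construction reduces to plain accuracy kernels
  (identity at accuracy 1, uniform at accuracy 1/k).
- **Observer heterogeneity.** Kernel rows are jittered in log space
  (Gaussian noise on log-probabilities, renormalized), which keeps rows
  valid probability vectors at any jitter size; zero-probability
  entries stay zero.
- **Responses.** Choices mix the kernel with a uniform lapse:
  (1 − λ)·kernel + λ/k. Ratings are the kernel probability of the scale
  category plus truncated Gaussian noise, clipped to [0, 1] — the
  simplest model of a bounded rating bar. Naming draws a category, then
  emits one of the lexicon strings mapping to it; with probability
  `oov_rate` an out-of-lexicon string is emitted instead, exercising
  the OTHER path.

Default parameters used by the pipeline and the acceptance script:
accuracy 0.8, bent↔folded confusability 0.15 with a ×2 wire multiplier,
lapse 0.02, out-of-vocabulary rate 0.05, rating noise SD 0.1, observer
jitter SD 0.15. These were chosen once as plausible for practised
observers on a clearly supra-threshold task — high but imperfect
accuracy, rare attentional lapses, modest individual differences — and
produce group perf values in the high-0.8s with near-ceiling R² and
inter-observer consistency above 0.9, the qualitative regime such
experiments report.

What the generator does *not* emulate, and what passing tests therefore
do not show about real data: there is no image computation, so nothing
links responses to actual shape features; exemplar variation is i.i.d.
within a cell (real execution/viewpoint variation is structured, and
specific exemplars are systematically mislabeled); naming vocabulary is
a small fixed lexicon plus a fixed out-of-vocabulary pool, far poorer
than real free naming; rating noise is homoscedastic; and kernels are
constant across a session (no learning or fatigue). Tests on simulated
data validate the *estimators* — that known parameters are recovered at
the design's sample sizes — not any empirical claim about perception.

## Reproducibility choices

Every stochastic function takes an explicit seed; a pipeline config
derives stage seeds from one master seed, and a rerun of the same
config is bit-identical (the run manifest carries a content hash over
the numerical results). Problem sizes in the test suite follow the
study design where the check needs it (15 observers × 720 stimuli for
kernel recovery; full 168-stimulus rating runs for the scission sign
test) and are scaled down elsewhere (coverage at 60 replications,
type-I at 2,000 simulations) — sizes chosen to keep Monte-Carlo error
well inside the asserted tolerances while the suite stays quick to run.
Trial tables round-trip through UTF-8 CSV bit-exactly; configs and
lexicons round-trip through YAML. The ingest adapter is deliberately
mapping-driven, since externally deposited data do not document a fixed
column layout.

## Known limitations

- The rating-task "accuracy" is the true-scale rating only; a composite
  that also penalizes high ratings on false scales would be a stricter
  measure. The cell-means builder is the single place to change this.
- The naming lexicon ships with English labels and a few synonyms;
  real multilingual naming data require a user-supplied lexicon, and
  coded results inherit its choices.
- The uniform null's response-dependence (see above) means "chance
  perf" is not a single number across experiments; comparisons across
  tasks should use the per-task null summary, not 0.5.
- `rm_anova` requires a complete balanced table; designs with missing
  cells need imputation or a mixed-model approach outside this
  package's scope.
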