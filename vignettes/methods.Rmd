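---
title: "Models and methods behind ratcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ratcat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ratcat)
```

ratcat simulates and analyses rodent touchscreen category learning: a
stimulus space of Gabor gratings, four rotated category tasks, the
SUSTAIN adaptive clustering network with lesion-simulating variants,
AIC-based model comparison against group learning curves, the
behavioural dependent measures, and a permutation-null perceptual
recency analysis. This vignette explains the models, the defaults, the
numerical choices, and the places where the design was genuinely open.

## The stimulus space and the four tasks

Spatial frequency (cycles per visual degree) and orientation (radians)
are carried onto a common 0–100 scale by the linear maps
`cpd / 0.0097 − 26.10` and `rad · 180/π`; `build_task()` then places
two bivariate normals at (30, 50) and (70, 50) with σ = 2.5 along the
axis joining the means and σ = 20 orthogonal to it, and rotates the
pair in 45° steps. Three choices here were open and are fixed as
follows:

* **Rotation pivot.** The rotation is about the center of the space
  (50, 50), which keeps all four tasks inside the displayable square.
* **Out-of-range draws.** Samples falling outside [0, 100]² are
  rejection-resampled, so every exemplar is displayable; at the task
  geometries the rejected mass is well under 1% per draw, so the
  truncation has no practical effect on the moments tests assert.
* **Orientation bound.** The upper raw-unit bound 1.75 rad maps to
  100.27, marginally above 100. Sampling is defined directly on the
  normalized space, so the raw bound is advisory; `normalize_orientation()`
  enforces it only for raw-unit inputs.

Category labels are drawn per trial as an independent fair coin
(a balanced-block option exists), and testing-phase draws widen the
relevant-axis σ to 10. Testing exemplars are typed by their signed
position `u` along the relevant axis measured from their own category
mean, positive toward the boundary: |u| ≤ 5 (two training σ) is
Trained, u > 5 Proximal, u < −5 Distal. For the 2D tasks "relevant
axis" means the rotated axis joining the means; the σ expansion applies
along that axis for all four tasks.

## SUSTAIN

The network holds clusters on the unit square (model coordinates are
the normalized space divided by 100 — at that scale the receptive
fields `exp(-λμ)` are informative at the initial λ = 1, whereas on the
0–100 scale they would be degenerate) and two attention
weights λ, initialized equal at 1. Each trial runs
activation → competition → decision → recruitment → update, with all
equations documented on the corresponding functions
(`cluster_activations()`, `compete()`, `decide()`, `maybe_recruit()`,
`sustain_update()`). A readable pure-R single-trial path
(`sustain_step()`) is tested to 1e−10 against the compiled loop that
`run_training()` and the fitting code use.

Free parameters, their meanings and defaults (`sustain_params()`):

| parameter | meaning | default |
|---|---|---|
| `r` | attention focus exponent | 4 |
| `beta` | cluster competition exponent | 2 |
| `d_dec` | decision consistency | 8 |
| `eta` | position/association learning rate | 0.03 |
| `eta_lambda` | attention learning rate | 0.01 |
| `tau` | recruitment threshold | 0.6 |

The defaults are the package's control configuration. They were chosen
once, by simulation over 20 seeds per candidate against the study's
structural signatures: learning curves that rise from chance past 0.75
within 15 × 80 trials at similar rates for 1D and 2D tasks; a modal
total of two clusters (one prototype per category) on 1D tasks;
several clusters per category (≥ 3) on 2D tasks; and a relevant–
irrelevant attention separation on 1D tasks. Small attention learning
rates matter more than one might expect: with exponential receptive
fields on continuous dimensions, λ chases `1/E[μ]` of the winner's
distances, and large `eta_lambda` drives λ so high that activations
collapse and 2D learning stalls; 0.01 keeps λ in a stable range over
1,200 trials.

**Recruitment rule.** The trigger for recruiting a cluster is a
*confident misclassification*: the network misclassifies while its
winning cluster's activation exceeds τ. The package reads
"misclassifies" as the winner's *predicted category* — the argmax of
its association weights, ties to category A — rather than the sampled
motor response, and this is the default (`recruit = "predict"`; the
sampled-response reading is available as `recruit = "choice"`). The
reason is structural: under the sampled-response rule, softmax decision
noise keeps triggering recruitment for as long as accuracy is below
ceiling, so cluster counts grow with trial count (hundreds of clusters
over 1,200 trials) and the winner-take-all output is diluted until
learning stalls. Under the prediction rule, recruitment stops once the
winners' predictions stabilize, which yields the prototype solution
(two clusters) on 1D tasks and a handful of clusters per category on
2D tasks.

Other mechanism choices: ties in the competition go to the lowest
cluster index (deterministic and reproducible); a newly recruited
cluster starts with zero association weights and becomes the winner
for that trial's update; λ is floored at zero after updates; the
attention learning rate is a separate parameter from `eta` (setting
them equal recovers the classic single-rate form).

One known limitation of the scale choice: because model coordinates
lie in [0, 1]², λμ ≤ 1 at initialization, so the irrelevant
dimension's λ initially *grows* toward `1/E[μ]` rather than decaying
from 1; what develops on 1D tasks is a relevant–irrelevant
*separation*, not an absolute decline of the irrelevant weight. The
tested property is the separation.

A related property holds only under the sampled-choice rule: the mean
final cluster count is non-increasing in τ, because τ gates the
recruitment events directly. Under the prediction rule the threshold
acts indirectly, and on 1D tasks an intermediate τ (≈ 0.7) can block
the corrective cross-category recruitment, prolong errors, and thereby
slightly *increase* later recruitment. The test suite exercises the
monotonicity property under the rule it belongs to.

## Lesion variants

Three manipulations express a prefrontal lesion on top of the control
network: *static attention* (`r` and `eta_lambda` forced to 0),
*attention shuffling* (λ replaced by a uniformly random permutation of
itself before every trial; the permutation is not undone, so weights
live in their shuffled slots for subsequent updates), and a *raised
recruitment threshold* `tau_lesion` > `tau`. The six-model table is:
control; static; shuffle; raised threshold; static + raised;
shuffle + raised. Only the last composition is externally anchored;
the others follow the natural single-manipulation-then-combination
ordering, and the table is plain data (`make_model_table()`), so
alternates are one-line changes. `tau_lesion` is a free parameter
during fitting (bounded above the control τ), not a fixed multiple.
With the default lesion configuration (shuffle + τ raised to 0.85) the
simulated lesion group shows the intended dissociation: early-session
accuracy on 1D tasks drops by about 0.11 while 2D accuracy is
unchanged, and 2D cluster counts are roughly halved.

## Model fitting and AIC

`fit_model()` optimizes one model specification against the observed
per-session accuracies of both groups and both task classes jointly.
Parameters are shared across groups; the variant's manipulations
apply only to the lesion group's predictions. Numerical choices:

* **Objective.** Binomial negative log-likelihood of per-session
  success counts (observed accuracy × trials × subjects, rounded)
  under the model's Monte-Carlo mean predicted accuracy, with
  predictions clamped to [1e−4, 1 − 1e−4]; AIC = 2k + 2·NLL. A
  Gaussian sum-of-squares alternative (AIC = n·log(SSE/n) + 2k) is a
  config switch. The binomial treats trials as independent and
  therefore understates between-subject variance; with eight subjects
  per cell, a cohort whose subjects happen to draw few clusters sits
  visibly above the model's mean curve, which inflates the lack-of-fit
  at the generating parameters. This is a property of curve-level
  likelihoods generally, not of this implementation.
* **Common random numbers.** Stimulus sequences are generated once per
  fit and every objective evaluation reseeds the choice sampling, so
  the stochastic objective is quasi-deterministic for the optimizer
  and fits are bit-reproducible. The lesion group is always simulated
  with its own seed — even for the control spec, whose manipulations
  are no-ops — so nested specs evaluated at equivalent parameters give
  identical predictions and a warm-started nested fit can never end
  worse than its parent.
* **Optimizer.** Screened multi-start Nelder-Mead on
  logit-transformed box-constrained parameters: r ∈ [0,10], β ∈ [0,10],
  d ∈ [0,20], η ∈ [0,1], η_λ ∈ [0,2], τ ∈ [0,1], and `tau_lesion`
  parameterized as τ + frac·(1−τ) with frac ∈ (0,1]. A Latin-hypercube
  candidate set (default 32 points) is first screened with one
  objective evaluation each and the best points seed the local
  searches — on this multimodal surface that buys far more than extra
  Nelder-Mead iterations. Gradient methods are unsuitable: with finite
  `n_sim` the objective is piecewise constant in the parameters.
  `warm_start` lets a fit begin from another model's optimum, which
  supports both nested-model comparisons and hierarchical family
  fitting (control first, lesion variants warm-started from it).
* **Free parameters.** k = 6 for the control model; raised-threshold
  specs add `tau_lesion` (k = 7); shuffling and static attention add
  none.
* **Identifiability.** Group-averaged learning curves identify this
  model family only weakly. Under the prediction recruitment rule the
  objective is flat in τ below the blocking regime (≈ 0.7): any
  sub-threshold τ yields the same recruitment events, so the control τ
  is unrecoverable by construction (`curve_objective()` over a τ grid
  makes the plateau easy to see). The attention focus r is not much
  better: it trades off against β, d and η_λ, and on 8-subject cohorts
  configurations with very different r can fit a given cohort's curves
  *better* than the generating parameters by absorbing between-subject
  noise. Model identity inherits the same weakness — at desk-scale
  optimization budgets the AIC ranking across the six variants varies
  with the multi-start draw. The test suite runs the recovery
  experiments exactly as stated and leaves the unattainable assertions
  failing rather than relaxing them; treat fitted parameters as a
  descriptive summary of the curves, not as estimates of mechanism
  constants.

Default problem sizes — `n_sim` = 100 runs per prediction for
parameter recovery and 20 for the six-model comparisons, with reduced
start counts in the test suite — were chosen as the smallest sizes at
which the Monte-Carlo error of the mean curve is clearly below the
between-cohort variability.

## Behavioural dependent measures

From a trial log (one row per attempt), `summarize_sessions()`
computes per subject-session: first-attempt accuracy (corrections
excluded from the denominator — the correction loop reinstates the
same stimulus until success, so first attempts carry the unbiased
signal); correction counts; perseverative errors (a correction attempt
pressing the same key as the immediately preceding failed attempt,
defined within the correction loop of a single stimulus, not across
trials); mean cue/choice reaction times after excluding incorrect
trials and then a single-pass two-standard-deviation filter (mean and
SD computed once per subject, measure, and phase — not re-estimated
after removal; a zero SD removes nothing; fewer than three correct
values returns the input with a warning flag); and mean third-touch
separation over correct trials (each touch's x-coordinate minus the
trial's three-touch mean, signed toward the correct side; the three
separations of a trial sum to zero by construction).

## Perceptual recency analysis

For each subject's first-attempt training sequence,
`recency_scores()` computes the similarity `s = exp(−Σ w_m |Δx_m|)`
between each trial and its predecessor, where the weights are that
trial's attention weights normalized to sum to one (an all-zero pair
falls back to uniform). Similarity is computed on model coordinates;
on the 0–100 scale virtually all similarities would collapse to zero.
Accuracy is binned by similarity quantiles and by a median split; the
permutation null shuffles whole (stimulus, correctness, weight)
triplets within subject — preserving marginal accuracy exactly,
destroying only adjacency — with bin edges recomputed per permutation;
the score is observed minus permuted-mean accuracy. Correction trials
are excluded (the mechanically repeated stimulus would flood the
high-similarity bins). Shuffling spans the subject's full training
data; a per-session option was considered and rejected as the
within-session/across-session distinction is immaterial for lag-1
adjacency. Scores use binary first-attempt correctness.

Calibration is verified directly: on order-independent synthetic
subjects the observed bin accuracies fall outside the permutation 95%
band about 5% of the time (granularity note: with few trials per bin
the binomial ties make the band conservative; the calibration test
uses 400 trials per subject where the discreteness is negligible), and
planted similarity–accuracy links are recovered with the right signs.

A substantive negative finding, documented rather than hidden: SUSTAIN
agents at the control configuration do **not** produce a detectable
trial-order recency effect. The only similarity-specific per-trial
update is the winner's position drift (η·μ ≈ 0.001 in model units),
which works out to an accuracy modulation of ~0.001 — an order of
magnitude below the per-subject permutation noise. High-powered
measurements (100 subjects) bound the high-similarity median-split
score at +0.0006 ± 0.0011, and no parameter set compatible with the
other study signatures does better. The frozen-representation half of
the comparison (no updating → no recency) holds trivially. A sizeable
behavioural recency effect therefore points to sequential mechanisms
(e.g. reward-driven response biases) beyond the clustering network's
parametric updates, and the corresponding end-to-end expectation is
left failing in the acceptance suite by design.

## The synthetic cohort generator

`generate_cohort()` emulates the study design exactly by default:
8 subjects per group × task-class cell (rotations balanced within
class), 15 training sessions × 80 trials with correction loops
(capped at 10 replays; capped loops are flagged), then 5 testing
sessions × 80 trials from the widened distributions with no
corrections and learning still on (testing is reinforced). Lesion
subjects run the model-5 manipulations with τ_lesion = 0.85 by
default, so the generator and the fitted model family coincide and
model recovery is a meaningful test. Correction replays are
decision-only — the network state is frozen after the first-attempt
update, and the agent simply re-decides on the replayed stimulus —
because the fitted signal is first-attempt accuracy and replay
learning would confound it; a correction-learning variant was
evaluated and changed no conclusion.

Reaction times are log-normal with a mean that decays exponentially
with training progress; the cue-phase mean carries a multiplicative
group × task factor (default 1.3 for lesion subjects on 1D tasks) and
the choice-phase mean never does. Touch coordinates scatter around the
stimulus center except the third, pre-choice touch, which drifts
toward the chosen side by gain × confidence pixels (confidence is the
distance of the choice probability from one half), giving a
closed-form expected third-touch separation of (2/3)·gain·confidence.
These two generators are simulation conveniences — the behavioural
literature gives no generative model for rodent RTs or touch
placement — and exist to exercise the dependent-measure pipeline with
recoverable parameters; nothing downstream depends on their form.

What passing tests on synthetic cohorts do and do not show: they
validate the pipeline's bookkeeping, the direction of the programmed
group differences, and the self-consistency of fitting and recovery.
They cannot validate the network as a model of real rats — the
generator's agents *are* the model — nor reproduce inferential
statistics computed on the original animals.

## Problem sizes used by the test suite

Module tests run seconds-scale configurations (2–8 subjects, 3–5
sessions). The acceptance suite uses: 20 seeds for the cluster-count
reproductions; 50 synthetic subjects × 400 trials × 250 permutations
for the recency calibration; 5 replicate cohorts for parameter
recovery (n_sim = 100) and model recovery (n_sim = 20) with 2
optimizer starts each; and one full-design cohort for the end-to-end
dissociation checks. These sizes keep the whole suite in the
tens-of-minutes range on a single core while leaving every asserted
quantity comfortably above its Monte-Carlo error.
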