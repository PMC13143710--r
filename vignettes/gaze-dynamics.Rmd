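---
title: "Gaze-state dynamics of aesthetic judgment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-state dynamics of aesthetic judgment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gazephase asks *when*, during free viewing of an artwork, gaze behaviour
starts to carry information about the aesthetic judgment the viewer will
eventually report. The package implements a complete, testable pipeline for
that question: a hidden-Markov representation of gaze states, per-bin
distributional indices, a time-resolved group comparison, and a seeded
synthetic-study generator that makes every stage verifiable without access
to any particular laboratory's recordings.

```{r setup, eval = FALSE}
library(gazephase)
```

## The gaze-state model

Within one artwork, gaze is modelled as a hidden Markov chain over $K$
spatial states. Each state $k$ is a region of interest (ROI): a
two-dimensional Gaussian with mean $\mu_k$ (a location on the image, in
normalised $[0,1)^2$ coordinates) and covariance $\Sigma_k$. The chain has
a row-stochastic transition matrix $A$ and initial distribution $\pi$;
observations are gaze positions (by default fixation centroids, optionally
raw samples). One model is fitted per artwork on the pooled sequences of
all participants, by maximum-likelihood Baum–Welch EM.

Two constraints keep the states interpretable as ROIs, enforced by
projection after every M-step:

* **Area band.** The ellipse containing `area_mass` (default 0.68) of a
  state's probability mass has area
  $\pi\,\chi^2_2(\text{mass})\sqrt{\det\Sigma_k}$. This area is clamped to
  0.1–5% of the image area (in normalised coordinates the image area
  is 1), preventing both a single state swallowing the canvas and
  states collapsing onto single fixations.
* **Axis clamp.** Axis lengths (square roots of covariance eigenvalues)
  are clamped to mean $\pm N\sigma$ across all ROI axis lengths
  (default $N = 2$), so no state deviates markedly in shape from the
  ensemble.

The projection iterates the two operations to a fixed point (at most 25
passes, with a $10^{-9}$ relative tolerance on violation detection), which
makes it idempotent; when the operations genuinely conflict for some state
the area band wins, because it is the primary constraint. EM restarts
(default 20) are seeded k-means++ initialisations; the restart with the
highest log-likelihood is kept, and states are re-indexed by descending
stationary occupancy so that fitted state labels are reproducible. The
log-likelihood is non-decreasing across EM iterations except where the
projection intervenes; such decreases are reported via a message and the
per-iteration trace is kept in the fitted object (`ll_trace`).

The number of states defaults to $K = 14$, treated as a configuration
constant: selecting $K$ by likelihood saturation requires a specific
corpus of recordings and is out of scope here. Remaining numerical
choices: relative log-likelihood tolerance $10^{-6}$, maximum 200
iterations, covariance eigenvalue floor $10^{-6}$, and Viterbi ties broken
toward the lower state index so decoding is deterministic even for fully
symmetric models.

## Per-bin indices

Each episode's first 30 s are divided into half-open 3-s bins. Decoding an
episode under its artwork's model gives per-timepoint posterior state
probabilities (scaled forward–backward) and the most likely state path
(Viterbi). With $p_i$ the mean posterior of state $i$ within a bin:

* $H_{norm} = -\sum_i p_i \log p_i / \log K \in [0,1]$ — dispersion of the
  gaze-state distribution (1 = maximally exploratory, 0 = fully
  converged). Natural logarithms throughout; the base cancels in the
  normalisation but matters for $N_{eff} = \exp(H)$, which equals $K$ at
  the uniform distribution only with base $e$.
* $MaxP = \max_i p_i \in [1/K, 1]$ — dominance of the strongest state.
* $NeffNorm = \exp(H)/K \in [1/K, 1]$ — effective number of states in use,
  as a fraction of $K$.
* $TV(t) = \tfrac12 \sum_i |p_i(t{+}1) - p_i(t)| \in [0,1]$ — the
  reorganisation of the distribution between consecutive bins. TV is
  attributed to the earlier bin of each pair, so the "6–9 s" TV compares
  the $[6,9)$ and $[9,12)$ distributions; an episode with $B$ populated
  bins has exactly $B-1$ TV values.
* $Switch = \frac{1}{T-1}\sum_t \mathbf{1}(S_t \neq S_{t+1}) \in [0,1]$ —
  the per-timepoint state-switching rate of the Viterbi path segment
  inside the bin; undefined (missing) for segments shorter than two
  timepoints.

Because viewing is self-paced, episodes end mid-bin; a partial bin is
retained when it holds at least `min_points` timepoints (default 10% of
the expected count given the sampling interval). Per-bin "visits" to a
state are counted as entries — transitions into the state plus the state
occupied at bin start.

## Group definition and inference

Ratings (integers 1–10) are min–max normalised within participant to
remove idiosyncratic scale use; participants with constant ratings carry
no ordinal information and are mapped to 0.5 and flagged. Artworks are
ranked by mean normalised rating; the top half forms the high-evaluation
group, the bottom half the low-evaluation group, with boundary ties broken
deterministically by artwork id (and reported).

Each bin × metric cell is compared between groups with a two-sided
Wilcoxon rank-sum test. The p-value is exact (Mann–Whitney null
distribution) when both samples have at most 10 observations and no ties;
otherwise the normal approximation with tie-corrected variance is used.
The $z$ statistic is always the normal approximation without continuity
correction, and the rank-biserial effect size is operationalised as
$r = z/\sqrt{N}$ — the one convention that makes a complete-separation
6-vs-6 comparison yield the jointly consistent triple
$p = 2/924 \approx 0.0022$, $z = 18/\sqrt{39} \approx 2.88$,
$r \approx 0.83$ (with continuity correction $z$ would be 2.80). The
U-based alternative $1 - 2U/(n_1 n_2)$ is provided as
`rank_biserial_u()`, clearly labelled.

The default observation unit is the viewing episode (participant ×
artwork), pooled within artwork group; artwork-mean and participant-mean
units are available (`unit` argument). Episode-level testing assumes
episodes exchangeable within groups — artwork-level random effects in a
metric would inflate the effective type-I rate, which is why the null
generator used in calibration checks shares one ground-truth model across
artworks (below). Benjamini–Hochberg FDR correction is applied across the
family of all testable bin × metric cells of the main analysis;
supplementary analyses form separate families. When no cell reaches
$q < 0.05$ the report labels all findings exploratory.

## The synthetic-study generator

`simulate_study()` generates the full crossed design the analysis assumes:
35 participants × 12 artworks (6 per evaluation group) at 300 Hz, with
self-paced episode durations drawn from a normal with mean 13.1 s and SD
1.21 s, truncated to [3, 30] s (guaranteeing at least one populated bin
and respecting the 30-s horizon) and to at least the episode's convergence
onset. Group mean normalised ratings default to 0.668 (high) and 0.357
(low); integer ratings are produced by mapping the normalised value
through a per-participant affine response range and rounding, so the
rating-normalisation code is exercised end-to-end.

The convergence mechanism is deliberately minimal: a time-inhomogeneous
transition matrix. Before the artwork's onset time $\tau$ (defaults: 6 s
for high-group, 12 s for low-group artworks) the chain explores — self
transition `stickiness_explore` (0.989, i.e. a ~0.3 s mean state dwell at
300 Hz), near-uniform off-diagonal. After $\tau$ every row concentrates
`stickiness_converge` (0.995) on a per-episode focus state. This produces
the earlier entropy reduction and faster distributional stabilisation for
the high group without asserting that any real viewer implements this
mechanism.

Emissions have fixation structure: a new location is drawn from the
current state's Gaussian whenever the state changes or a re-fixation
occurs (mean interval 0.3 s), and gaze holds that location with micro
jitter (SD 0.0015 normalised units) in between. This makes dispersion
based fixation detection (I-DT; default dispersion 0.018 normalised
units — about 1° of visual angle for a 23-inch 1920-px display at
52 cm — and 100 ms minimum duration) behave on synthetic data as it does
on real recordings. What the generator does *not* emulate: saccade
trajectories, smooth pursuit, blinks with partial validity, calibration
drift, saliency-driven spatial structure of real paintings, or
inter-participant heterogeneity of dynamics. Passing tests therefore
demonstrate correctness of the estimation and inference machinery under
the generative assumptions, not validity of those assumptions for any
particular dataset.

Depth-point annotations are planted per artwork: by default high-group
artworks carry them at the focus-ROI means (depth cues coincide with gaze
attractors) while low-group artworks carry them at random locations —
the configuration under which cumulative depth-hit differences emerge
from the earliest windows. Placements `"focus"` (all artworks annotated
at focus ROIs) and `"random"` remove the group difference for null
checks. Setting `shared_model = TRUE` gives every artwork the same ROI
geometry, making episodes fully exchangeable — the appropriate null for
episode-unit inference.

A design tension worth recording: truncating low-group judgment times at
$\tau = 12$ s shifts their mean slightly above the configured 13.1 s
(by about 0.2 s). The generator accepts this bias as the price of the
spec'd truncation rule; the duration checks in the test suite allow for
it explicitly.

## Supplementary analyses

*Depth fixations.* A fixation hits a depth-related point when its centroid
lies within `radius` (default 0.05 normalised units — the hit criterion is
a package convention, configurable) of any annotated point of the
artwork. Per episode and bin the pipeline reports hit count, first hit
time, mean dwell of hitting fixations, and the running cumulative hit
count, whose cumulative windows (0–3 s, 0–6 s, ...) are compared between
groups with the same rank-sum machinery as a separate FDR family. Both
episode- and participant-level aggregations are exposed, since group-level
effects need not survive participant-level aggregation.

*Pre-decision gaze bias.* For two-alternative forced-choice preference
trials, each trial's time axis is rescaled to $[0,1]$ with 1 at the
decision; the probability of gazing at the ultimately chosen option is
the fraction of valid samples inside its region among samples inside
either region (off-region samples are excluded from the denominator and
their fraction reported). Ten normalised-time bins are used; the last bin
is the fixed window immediately preceding the response. The paired
generator ramps the chosen-option sampling probability linearly over the
final second of each trial.

## Problem sizes and reproducibility

Every stochastic component is driven by one integer seed; identical
configuration and seed reproduce byte-identical artefacts. The package's
own calibration checks run at sizes chosen to make their Monte-Carlo error
small relative to the margins being tested: the full 35 × 12 design at
300 Hz for effect-direction checks (decoded under the ground-truth
models), 200 replicates of a reduced null design (8 participants × 4
artworks at 50 Hz, 5 shared states) for type-I calibration, 50 episodes
for 3-state parameter recovery, and exhaustive path enumeration up to
$K^T = 3^8$ for decoder verification. `run_pipeline()` writes every
stage's artefact (models as JSON, tables as CSV, a manifest with the
configuration hash, seed, versions and per-stage timings) so any stage can
be re-run from serialised inputs alone.

## Known limitations

The EMHMM here is the constrained maximum-likelihood variant; variational
or hierarchical clustering of individual-specific models is out of scope,
as is automatic selection of $K$. Raw-sample decoding treats consecutive
300 Hz samples as conditionally independent emissions, which real
oculomotor data violate within fixations; fixation-level observation is
the default for fitting for exactly that reason. Episode-unit inference
ignores participant and artwork random effects — acceptable under the
generator's exchangeability, checkable against the artwork- and
participant-unit options on real data. The exact Wilcoxon path requires
tie-free data and small groups; elsewhere the tie-corrected normal
approximation is used, which is slightly anticonservative for heavily
discrete outcomes such as small hit counts.
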