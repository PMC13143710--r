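# gazephase

Time-resolved gaze-state dynamics of aesthetic judgment.

When people view an artwork freely and report an aesthetic rating at their
own pace, *when* does their gaze start to carry information about the
judgment they will eventually make? `gazephase` implements a complete
pipeline for that question: scanpaths are summarised as hidden Markov gaze
states, decoded episode by episode, aggregated into 3-s time bins over the
first 30 s of viewing, and compared between high- and low-evaluation
artwork groups with nonparametric tests and false-discovery-rate control.
A seeded synthetic-study generator emulates the full study design, so
every stage of the pipeline is testable end to end.

## The model and the indices

Within one artwork, gaze is a hidden Markov chain over K states (default
K = 14). Each state is a region of interest (ROI): a two-dimensional
Gaussian N(mu_k, Sigma_k) on the normalised image, with transition matrix
A and initial distribution pi. Fitting is constrained maximum-likelihood
Baum-Welch (multiple seeded restarts, best log-likelihood kept), with ROI
ellipse areas clamped to 0.1-5% of the image area and axis lengths clamped
to mean +/- 2 sigma across ROIs after every M-step.

Decoding each episode yields per-timepoint posteriors and the Viterbi
path. With p_i the mean posterior of state i within a 3-s bin, the five
indices are

- `Hnorm = -sum p_i log p_i / log K` — dispersion of the gaze-state
  distribution (1 exploratory, 0 converged),
- `MaxP = max_i p_i` — dominance of the strongest state,
- `NeffNorm = exp(H) / K` — effective fraction of states in use,
- `TV(t) = (1/2) sum_i |p_i(t+1) - p_i(t)|` — reorganisation between
  consecutive bins (attributed to the earlier bin),
- `Switch = (1/(T-1)) sum 1(S_t != S_{t+1})` — state-switching rate of the
  Viterbi path.

Groups are the top and bottom halves of artworks ranked by mean
within-participant-normalised rating. Each bin x metric cell is tested
with a two-sided Wilcoxon rank-sum test (exact where feasible, otherwise
tie-corrected normal approximation; z without continuity correction),
effect sizes are rank-biserial r = z / sqrt(N), and Benjamini-Hochberg
q-values are computed over the bin x metric family.

## Worked example

Simulate a reduced study (12 participants x 6 artworks at 60 Hz, 6 true
states), decode under the generator's ground-truth models, and compare the
groups:

```r
library(gazephase)

study <- simulate_study(generative_config(
  n_participants = 12, n_artworks = 6,
  sampling_rate_hz = 60, K_true = 6, seed = 2026
))
study
#> <gaze_study> 12 participants x 6 artworks, 72 episodes, 57029 gaze samples

metrics    <- study_metrics(study, study$truth$models)
groups     <- assign_groups(normalize_ratings(
  study$episodes[c("participant_id", "artwork_id", "rating")]
))
comparison <- compare_bins(metrics, groups)
glance(comparison)
#> # A tibble: 1 x 6
#>   n_cells n_testable n_sig_uncorrected n_sig_fdr    min_p    min_q
#>     <int>      <int>             <int>     <int>    <dbl>    <dbl>
#> 1      29         24                13        13 1.92e-11 4.60e-10

cat(report(comparison), sep = "\n")
#> Phase early (0-6 s): 10 cells tested.
#>   tv @ 3-6 s: p = 1.205e-06, r = 0.572, q = 0.000
#> Phase middle (6-12 s): 10 cells tested.
#>   hnorm @ 6-9 s: p = 1.632e-07, r = -0.617, q = 0.000
#>   hnorm @ 9-12 s: p = 8.359e-10, r = -0.723, q = 0.000
#>   maxp @ 6-9 s: p = 1.612e-07, r = 0.617, q = 0.000
#>   maxp @ 9-12 s: p = 1.573e-09, r = 0.711, q = 0.000
#>   neffnorm @ 6-9 s: p = 1.619e-07, r = -0.617, q = 0.000
#>   neffnorm @ 9-12 s: p = 8.357e-10, r = -0.723, q = 0.000
#>   switch @ 6-9 s: p = 0.002669, r = -0.354, q = 0.006
#>   tv @ 6-9 s: p = 1.915e-11, r = -0.791, q = 0.000
#>   tv @ 9-12 s: p = 2.848e-09, r = -0.849, q = 0.000
#> Phase late (12 s onward): 4 cells tested.
#>   hnorm @ 12-15 s: p = 0.008793, r = -0.374, q = 0.018
#>   maxp @ 12-15 s: p = 0.009842, r = 0.369, q = 0.018
#>   neffnorm @ 12-15 s: p = 0.008759, r = -0.374, q = 0.018
#> FDR (Benjamini-Hochberg): 13 cell(s) reach q < 0.05.
```

Reading the output: in the middle phase (6-12 s), episodes of high-rated
artworks show lower state entropy (`hnorm`, negative r: the high group is
lower), lower between-bin reorganisation (`tv`) and a stronger dominant
state (`maxp`, positive r) — gaze converges earlier when the upcoming
evaluation is high. This generator's contrast (convergence onset 6 s vs
12 s) is deliberately strong; the direction, not the magnitude, is the
point.

The artwork-level rating comparison for a complete 6-vs-6 separation
prints the canonical exact triple:

```r
wilcoxon_rank_sum(7:12, 1:6)
#> Wilcoxon rank-sum: W = 57, U = 36, z = 2.882, p = 0.002165 (exact)
```

`run_pipeline(run_config(...))` chains all stages (simulate, fit, metrics,
compare, supplementary, report) and, given an output directory, writes
fitted models (JSON), the tidy bin-metrics table, the comparison tables,
the supplementary outputs and a run manifest. `autoplot()` methods draw
ROI maps and p/q heatmaps; `plot_metric_timecourse()` shows group-mean
index trajectories.

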