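# Per-bin distributional and dynamic indices of the gaze-state distribution.
#
# All entropies use the natural logarithm: normalisation by log K makes the
# base immaterial for hnorm, while neffnorm = exp(H)/K requires base e so
# that the effective number of states equals K for the uniform distribution.

check_simplex <- function(p, arg = "p") {
  if (!is.numeric(p) || length(p) < 1L) {
    stop("`", arg, "` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("`", arg, "` must be non-negative and finite", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6) {
    stop("`", arg, "` must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  }
  invisible(p)
}

#' Normalised Shannon entropy of a gaze-state distribution
#'
#' `hnorm()` measures how evenly gaze probability mass is spread across the
#' K gaze states within a time bin: 1 for the uniform distribution
#' (maximally exploratory gaze), 0 when all mass sits on a single state
#' (fully converged gaze). Entropy uses the natural logarithm and is divided
#' by its theoretical maximum `log(K)`; the `0 * log(0) = 0` convention
#' applies.
#'
#' @param p Numeric probability vector on the K-simplex (mean posterior
#'   state probabilities within a bin).
#' @param K Number of states; defaults to `length(p)`. Supplying `K` larger
#'   than `length(p)` treats the missing states as zero-probability.
#' @return A scalar in `[0, 1]`.
#' @examples
#' hnorm(rep(1 / 14, 14))            # 1: uniform over 14 states
#' hnorm(c(1, rep(0, 13)))           # 0: degenerate
#' hnorm(c(0.5, 0.5, rep(0, 12)))    # log(2)/log(14)
#' @export
hnorm <- function(p, K = length(p)) {
  check_simplex(p)
  if (K < 2) return(0)
  pos <- p[p > 0]
  H <- -sum(pos * log(pos))
  H / log(K)
}

#' Maximum state probability
#'
#' The probability of the single most dominant gaze state in a bin. High
#' values indicate concentration on one region of interest; the minimum
#' attainable value is `1/K` (uniform distribution).
#'
#' @inheritParams hnorm
#' @return A scalar in `[1/K, 1]`.
#' @examples
#' maxp(rep(1 / 14, 14))  # 1/14
#' maxp(c(0.5, 0.3, 0.2)) # 0.5
#' @export
maxp <- function(p) {
  check_simplex(p)
  max(p)
}

#' Normalised effective number of gaze states
#'
#' `neffnorm()` is the entropy-based effective number of states,
#' `Neff = exp(H)`, normalised by K. It indexes how many regions of interest
#' are substantively in use: 1 when all K states are used evenly, `1/K` when
#' a single state absorbs all gaze. Satisfies the identity
#' `neffnorm(p, K) == exp(hnorm(p, K) * log(K)) / K`.
#'
#' @inheritParams hnorm
#' @return A scalar in `[1/K, 1]`.
#' @examples
#' neffnorm(rep(1 / 14, 14))          # 1
#' neffnorm(c(0.5, 0.5, rep(0, 12)))  # 2/14
#' @export
neffnorm <- function(p, K = length(p)) {
  check_simplex(p)
  pos <- p[p > 0]
  H <- -sum(pos * log(pos))
  exp(H) / K
}

#' Total variation distance between two gaze-state distributions
#'
#' Half the L1 distance between the state distributions of two (typically
#' consecutive) time bins: 0 when the distributions coincide, 1 when their
#' supports are disjoint. It measures the magnitude of reorganisation of
#' gaze between windows.
#'
#' @param p,q Probability vectors on the same K-simplex.
#' @return A scalar in `[0, 1]`; symmetric in its arguments.
#' @examples
#' total_variation(c(0.6, 0.4), c(0.4, 0.6)) # 0.2
#' total_variation(c(1, 0), c(0, 1))         # 1: disjoint supports
#' @export
total_variation <- function(p, q) {
  check_simplex(p, "p")
  check_simplex(q, "q")
  if (length(p) != length(q)) {
    stop("`p` and `q` must be distributions over the same state space",
         call. = FALSE)
  }
  sum(abs(p - q)) / 2
}

#' State-switching rate of a Viterbi path segment
#'
#' The fraction of adjacent timepoint pairs whose decoded states differ:
#' `(1/(T-1)) * sum(S_t != S_{t+1})`. 0 for a constant path (stable gaze),
#' 1 for a strictly alternating one (maximal exploratory switching).
#'
#' @param path Integer (or factor-like) vector of decoded states.
#' @return A scalar in `[0, 1]`, or `NA` for segments with fewer than two
#'   timepoints, where the rate is undefined.
#' @examples
#' switch_rate(c(1, 1, 2, 2)) # 1/3
#' switch_rate(c(1, 2, 1, 2)) # 1
#' @export
switch_rate <- function(path) {
  n <- length(path)
  if (n < 2L) return(NA_real_)
  mean(path[-n] != path[-1L])
}

#' Aggregate a decoded state sequence into fixed-width time bins
#'
#' Divides the first `horizon_s` seconds of viewing into half-open bins of
#' `bin_width_s` seconds (`[0, 3), [3, 6), ...` with the defaults) and
#' summarises the decoded sequence within each bin: the mean posterior
#' probability per state, the number of visits to each state on the Viterbi
#' path (entries into the state, counting the state occupied at bin start),
#' and the total dwell time per state.
#'
#' Bins with fewer than `min_points` timepoints (for example bins after the
#' episode ended) are marked unpopulated and carry `NA` distributions; a
#' partial final bin is kept when it meets `min_points`.
#'
#' @param posteriors Numeric `T x K` matrix of per-timepoint posterior state
#'   probabilities (rows on the simplex).
#' @param path Integer length-`T` Viterbi state path.
#' @param times Numeric length-`T` vector of sample times in seconds from
#'   stimulus onset, strictly increasing.
#' @param bin_width_s,horizon_s Bin width and analysis horizon in seconds.
#' @param min_points Minimum number of timepoints for a bin to count as
#'   populated. Default: 10% of the expected points per bin, estimated from
#'   the median sampling interval.
#' @return A tibble with one row per bin x state: `bin` (0-based),
#'   `t_start`, `t_end`, `n_timepoints`, `populated`, `state`, `p`,
#'   `hit_count`, `dwell_time`.
#' @export
bin_sequence <- function(posteriors, path, times, bin_width_s = 3,
                         horizon_s = 30, min_points = NULL) {
  posteriors <- as.matrix(posteriors)
  K <- ncol(posteriors)
  stopifnot(length(path) == nrow(posteriors), length(times) == nrow(posteriors))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  n_bins <- ceiling(horizon_s / bin_width_s)
  dt <- if (length(times) > 1L) median(diff(times)) else bin_width_s
  if (is.null(min_points)) min_points <- max(1, 0.1 * bin_width_s / dt)

  purrr::map_dfr(seq_len(n_bins) - 1L, function(b) {
    t0 <- b * bin_width_s
    t1 <- min((b + 1) * bin_width_s, horizon_s)
    idx <- which(times >= t0 & times < t1)
    n <- length(idx)
    populated <- n >= min_points
    if (!populated) {
      return(tibble::tibble(
        bin = b, t_start = t0, t_end = t1, n_timepoints = n,
        populated = FALSE, state = seq_len(K),
        p = NA_real_, hit_count = NA_integer_, dwell_time = NA_real_
      ))
    }
    pbar <- colMeans(posteriors[idx, , drop = FALSE])
    seg <- path[idx]
    # visits = entries into a state (state at bin start counts as one entry)
    entries <- seg[c(TRUE, seg[-1L] != seg[-length(seg)])]
    hits <- tabulate(entries, nbins = K)
    dwell <- tabulate(seg, nbins = K) * dt
    tibble::tibble(
      bin = b, t_start = t0, t_end = t1, n_timepoints = n,
      populated = TRUE, state = seq_len(K),
      p = pbar, hit_count = as.integer(hits), dwell_time = dwell
    )
  })
}

#' Per-bin index table for one decoded viewing episode
#'
#' Computes the five gaze-dynamics indices for each populated bin of a
#' decoded episode: [hnorm()], [maxp()] and [neffnorm()] from the mean
#' posterior distribution, [switch_rate()] from the Viterbi path segment
#' within the bin, and [total_variation()] between each pair of consecutive
#' populated bins, attributed to the earlier bin of the pair (so `tv` for
#' the `[6, 9)` bin compares the `[6, 9)` and `[9, 12)` distributions). An
#' episode with B populated bins yields exactly B-1 non-missing `tv`
#' values; the last populated bin's `tv` is `NA`.
#'
#' @inheritParams bin_sequence
#' @return A tibble with one row per populated bin: `bin`, `t_start`,
#'   `t_end`, `n_timepoints`, `hnorm`, `maxp`, `neffnorm`, `switch`, `tv`.
#' @export
episode_metrics <- function(posteriors, path, times, bin_width_s = 3,
                            horizon_s = 30, min_points = NULL) {
  K <- ncol(as.matrix(posteriors))
  bins <- bin_sequence(posteriors, path, times, bin_width_s, horizon_s,
                       min_points)
  pop <- bins |>
    dplyr::filter(.data$populated) |>
    tidyr::nest(dist = c("state", "p", "hit_count", "dwell_time"))
  if (nrow(pop) == 0L) {
    return(tibble::tibble(
      bin = integer(), t_start = numeric(), t_end = numeric(),
      n_timepoints = integer(), hnorm = numeric(), maxp = numeric(),
      neffnorm = numeric(), switch = numeric(), tv = numeric()
    ))
  }
  out <- pop |>
    dplyr::mutate(
      hnorm = purrr::map_dbl(.data$dist, ~ hnorm(.x$p, K)),
      maxp = purrr::map_dbl(.data$dist, ~ maxp(.x$p)),
      neffnorm = purrr::map_dbl(.data$dist, ~ neffnorm(.x$p, K)),
      switch = purrr::map2_dbl(.data$t_start, .data$t_end, function(t0, t1) {
        switch_rate(path[times >= t0 & times < t1])
      })
    )
  # TV between consecutive populated bins, attributed to the earlier bin;
  # B populated bins yield exactly B - 1 TV values
  ps <- purrr::map(out$dist, "p")
  tv <- rep(NA_real_, nrow(out))
  if (nrow(out) >= 2L) {
    tv[-nrow(out)] <- purrr::map2_dbl(ps[-length(ps)], ps[-1L], total_variation)
  }
  out$tv <- tv
  out |>
    dplyr::select("bin", "t_start", "t_end", "n_timepoints",
                  "hnorm", "maxp", "neffnorm", "switch", "tv")
}
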