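# High/low evaluation group definition from ratings and the time-resolved
# bin x metric group comparison: Wilcoxon rank-sum tests (exact where
# feasible, tie-corrected normal approximation otherwise), rank-biserial
# effect sizes, and Benjamini-Hochberg FDR control over the bin x metric
# family.

#' Within-participant min-max normalisation of ratings
#'
#' Maps each participant's raw 1-10 ratings onto `[0, 1]` by their own
#' minimum and maximum, removing individual differences in scale use.
#' Participants who gave the same rating to every artwork carry no ordinal
#' information; their normalised ratings are set to 0.5 and flagged.
#'
#' @param ratings Tibble with `participant_id`, `artwork_id`, `rating`
#'   (integers 1-10).
#' @return The input with added columns `rating_norm` and
#'   `constant_rating`.
#' @export
normalize_ratings <- function(ratings) {
  if (any(ratings$rating < 1 | ratings$rating > 10 |
            ratings$rating != round(ratings$rating))) {
    stop("ratings must be integers in 1..10", call. = FALSE)
  }
  ratings |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      constant_rating = max(.data$rating) == min(.data$rating),
      rating_norm = ifelse(
        .data$constant_rating, 0.5,
        (.data$rating - min(.data$rating)) /
          (max(.data$rating) - min(.data$rating))
      )
    ) |>
    dplyr::ungroup()
}

#' Assign artworks to high/low evaluation groups
#'
#' Ranks artworks by their mean within-participant-normalised rating and
#' labels the top half `"high"` and the bottom half `"low"`. Ties at the
#' boundary are broken deterministically by artwork id order and reported
#' via a message.
#'
#' @param rating_table Output of [normalize_ratings()].
#' @return A tibble with `artwork_id`, `mean_norm_rating`, `group`.
#' @export
assign_groups <- function(rating_table) {
  if (!"rating_norm" %in% names(rating_table)) {
    rating_table <- normalize_ratings(rating_table)
  }
  means <- rating_table |>
    dplyr::group_by(.data$artwork_id) |>
    dplyr::summarise(mean_norm_rating = mean(.data$rating_norm),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_norm_rating), .data$artwork_id)
  n <- nrow(means)
  if (n %% 2 != 0) {
    stop("odd number of artworks (", n, "): top/bottom halves undefined",
         call. = FALSE)
  }
  half <- n %/% 2
  boundary_tie <- means$mean_norm_rating[half] ==
    means$mean_norm_rating[half + 1]
  if (boundary_tie) {
    message("tie at the group boundary; broken by artwork id order")
  }
  means$group <- rep(c("high", "low"), each = half)
  dplyr::arrange(means, .data$artwork_id)
}

#' Wilcoxon rank-sum test with explicit W, U and z
#'
#' Two-sided two-sample rank-sum test reporting the rank-sum statistic `W`
#' (sum of ranks of the first sample), the Mann-Whitney `U`, the normal
#' approximation `z` with tie-corrected variance and no continuity
#' correction, and a p-value that is exact (from the Mann-Whitney null
#' distribution) when both samples have at most 10 observations and there
#' are no ties, and asymptotic otherwise. `z` is positive when the first
#' sample tends to be larger.
#'
#' @param a,b Numeric samples (first sample = `a`).
#' @param method `"auto"` (exact when feasible), `"exact"`, or `"normal"`.
#' @return An object of class `gaze_rank_test`: list with `W`, `U`, `z`,
#'   `p`, `p_method`, `n1`, `n2`.
#' @examples
#' # complete 6-vs-6 separation: exact p = 2/924, z = 18/sqrt(39)
#' wilcoxon_rank_sum(7:12, 1:6)
#' @export
wilcoxon_rank_sum <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  use_exact <- switch(method,
    auto = n1 <= 10 && n2 <= 10 && !has_ties,
    exact = TRUE,
    normal = FALSE
  )
  if (use_exact && has_ties) {
    stop("exact p-value unavailable with ties; use method = \"normal\"",
         call. = FALSE)
  }
  if (use_exact) {
    p <- if (U > mu) {
      2 * (1 - pwilcox(U - 1, n1, n2))
    } else {
      2 * pwilcox(U, n1, n2)
    }
    p_method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    p_method <- "normal_tie_corrected"
  }
  structure(list(W = W, U = U, z = z, p = min(p, 1), p_method = p_method,
                 n1 = n1, n2 = n2),
            class = "gaze_rank_test")
}

#' @export
print.gaze_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, U = %g, z = %.3f, p = %.4g (%s)\n",
              x$W, x$U, x$z, x$p, x$p_method))
  invisible(x)
}

#' Rank-biserial effect size from the normal-approximation z
#'
#' The effect-size convention `r = z / sqrt(N)` (N = total observations),
#' clipped to `[-1, 1]`. The U-based alternative
#' [rank_biserial_u()] (`1 - 2U/(n1*n2)`, Cliff's delta up to sign) is
#' provided separately.
#'
#' @param z Normal-approximation z statistic.
#' @param n_total Total number of observations in both samples.
#' @return A scalar in `[-1, 1]`.
#' @export
rank_biserial <- function(z, n_total) {
  stopifnot(n_total >= 2)
  min(max(z / sqrt(n_total), -1), 1)
}

#' U-based rank-biserial correlation
#'
#' @param U Mann-Whitney U of the first sample.
#' @param n1,n2 Sample sizes.
#' @return `1 - 2 * U / (n1 * n2)`, in `[-1, 1]`; negative when the first
#'   sample tends to be larger.
#' @export
rank_biserial_u <- function(U, n1, n2) {
  1 - 2 * U / (n1 * n2)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Adjusts a family of p-values by the Benjamini-Hochberg step-up
#' procedure (`q_(i) = min_{j >= i} m * p_(j) / j`, original order
#' restored), controlling the expected false-discovery proportion.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

window_label <- function(t_start, t_end) {
  sprintf("%g-%g s", t_start, t_end)
}

#' Time-resolved group comparison over the bin x metric family
#'
#' For every time bin and gaze index, compares episodes of high- versus
#' low-evaluation artworks with [wilcoxon_rank_sum()], reports group means,
#' the rank-biserial effect size `r = z / sqrt(N)` (positive when the high
#' group is larger), and Benjamini-Hochberg q-values computed within the
#' declared family (all testable bin x metric cells). Episodes lacking a
#' bin are excluded from that cell; cells with fewer than two observations
#' per group are flagged untestable rather than dropped.
#'
#' @param metrics Per-episode bin metrics table (see [study_metrics()]),
#'   with columns `participant_id`, `artwork_id`, `bin`, `t_start`,
#'   `t_end` and the metric columns.
#' @param group_assignment Output of [assign_groups()] (or the generator's
#'   ground-truth groups): `artwork_id`, `group`.
#' @param metric_cols Metric columns to test.
#' @param unit Observation unit: `"episode"` (default; one value per
#'   participant x artwork), `"artwork"` (artwork means), or
#'   `"participant"` (per-participant means within each artwork group).
#' @return A tibble of class `gaze_comparison`: one row per bin x metric
#'   with `metric`, `bin`, `window`, `n_high`, `n_low`, `mean_high`,
#'   `mean_low`, `W`, `U`, `z`, `p`, `p_method`, `r`, `q`, `untestable`.
#' @export
compare_bins <- function(metrics, group_assignment,
                         metric_cols = c("hnorm", "maxp", "neffnorm",
                                         "switch", "tv"),
                         unit = c("episode", "artwork", "participant")) {
  unit <- match.arg(unit)
  long <- metrics |>
    dplyr::inner_join(group_assignment[c("artwork_id", "group")],
                      by = "artwork_id") |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  long <- switch(unit,
    episode = long,
    artwork = long |>
      dplyr::group_by(.data$artwork_id, .data$group, .data$bin,
                      .data$t_start, .data$t_end, .data$metric) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop"),
    participant = long |>
      dplyr::group_by(.data$participant_id, .data$group, .data$bin,
                      .data$t_start, .data$t_end, .data$metric) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  )
  res <- long |>
    dplyr::group_by(.data$metric, .data$bin, .data$t_start, .data$t_end) |>
    dplyr::group_modify(function(d, key) {
      hi <- d$value[d$group == "high"]
      lo <- d$value[d$group == "low"]
      base <- tibble::tibble(
        n_high = length(hi), n_low = length(lo),
        mean_high = if (length(hi)) mean(hi) else NA_real_,
        mean_low = if (length(lo)) mean(lo) else NA_real_
      )
      if (length(hi) < 2 || length(lo) < 2) {
        return(dplyr::mutate(base, W = NA_real_, U = NA_real_, z = NA_real_,
                             p = NA_real_, p_method = NA_character_,
                             r = NA_real_, untestable = TRUE))
      }
      tst <- wilcoxon_rank_sum(hi, lo)
      dplyr::mutate(base, W = tst$W, U = tst$U, z = tst$z, p = tst$p,
                    p_method = tst$p_method,
                    r = rank_biserial(tst$z, tst$n1 + tst$n2),
                    untestable = FALSE)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(window = window_label(.data$t_start, .data$t_end),
                  .after = "bin")
  res$q <- NA_real_
  testable <- !res$untestable & !is.na(res$p)
  if (any(testable)) res$q[testable] <- bh_fdr(res$p[testable])
  class(res) <- c("gaze_comparison", class(res))
  res
}
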