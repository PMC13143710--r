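# Supplementary analyses: fixation indices toward depth-related annotation
# points (per-bin and cumulatively aggregated), and the decision-aligned
# probability of gazing at the to-be-chosen option in 2AFC preference
# trials.

#' Depth-point fixation indices per episode and time bin
#'
#' A fixation "hits" a depth-related point when its centroid lies within
#' `radius` (normalised units) of any annotated point of the episode's
#' artwork. Per episode and 3-s bin this returns the hit count, the time of
#' the first hitting fixation in the bin, the mean dwell (duration) of
#' hitting fixations, and the running cumulative hit count from viewing
#' onset. Artworks present in `depth_points` with no annotated points
#' simply score zero hits; an entirely empty annotation table skips the
#' analysis with a message.
#'
#' @param fixations Fixation tibble from [detect_fixations()].
#' @param depth_points Tibble `artwork_id`, `x`, `y` of annotation points.
#' @param radius Hit radius in normalised units (default 0.05).
#' @param bin_width_s,horizon_s Bin width and horizon in seconds.
#' @return A tibble with one row per episode x bin: `participant_id`,
#'   `artwork_id`, `bin`, `t_start`, `t_end`, `hit_count`,
#'   `first_hit_time`, `mean_dwell`, `cumulative_hit_count`.
#' @export
depth_hits <- function(fixations, depth_points, radius = 0.05,
                       bin_width_s = 3, horizon_s = 30) {
  if (is.null(depth_points) || nrow(depth_points) == 0) {
    message("no depth-point annotations: depth analysis skipped")
    return(tibble::tibble(
      participant_id = character(), artwork_id = character(),
      bin = integer(), t_start = numeric(), t_end = numeric(),
      hit_count = integer(), first_hit_time = numeric(),
      mean_dwell = numeric(), cumulative_hit_count = integer()
    ))
  }
  n_bins <- ceiling(horizon_s / bin_width_s)
  dp <- split(depth_points[, c("x", "y")], depth_points$artwork_id)
  fixations |>
    dplyr::group_by(.data$participant_id, .data$artwork_id) |>
    dplyr::group_modify(function(fx, key) {
      empty <- tibble::tibble(
        bin = integer(), t_start = numeric(), t_end = numeric(),
        hit_count = integer(), first_hit_time = numeric(),
        mean_dwell = numeric(), cumulative_hit_count = integer()
      )
      if (nrow(key) != 1L) return(empty)
      pts <- dp[[key$artwork_id]]
      hit <- if (is.null(pts) || nrow(pts) == 0 || nrow(fx) == 0) {
        rep(FALSE, nrow(fx))
      } else {
        # min distance of each fixation centroid to any depth point
        d2 <- outer(fx$x, pts$x, "-")^2 + outer(fx$y, pts$y, "-")^2
        sqrt(apply(d2, 1, min)) <= radius
      }
      bin <- pmin(floor(fx$onset / bin_width_s), n_bins - 1L)
      per_bin <- purrr::map_dfr(seq_len(n_bins) - 1L, function(b) {
        inb <- which(bin == b & hit)
        tibble::tibble(
          bin = b, t_start = b * bin_width_s,
          t_end = min((b + 1) * bin_width_s, horizon_s),
          hit_count = length(inb),
          first_hit_time = if (length(inb)) min(fx$onset[inb]) else NA_real_,
          mean_dwell = if (length(inb)) mean(fx$duration[inb]) else NA_real_
        )
      })
      per_bin$cumulative_hit_count <- cumsum(per_bin$hit_count)
      per_bin
    }) |>
    dplyr::ungroup()
}

#' Group comparison of cumulatively aggregated depth hit counts
#'
#' Applies the same Wilcoxon/effect-size machinery as [compare_bins()] to
#' the cumulative hit count per cumulative window (0 to the end of each
#' bin), as its own FDR family, separate from the main bin x metric
#' family.
#'
#' @param summaries Output of [depth_hits()].
#' @param group_assignment Tibble `artwork_id`, `group`.
#' @inheritParams compare_bins
#' @return A `gaze_comparison` tibble with metric
#'   `"cumulative_hit_count"` and windows `"0-3 s"`, `"0-6 s"`, ...
#' @export
cumulative_comparison <- function(summaries, group_assignment,
                                  unit = c("episode", "artwork",
                                           "participant")) {
  unit <- match.arg(unit)
  cum <- summaries |>
    dplyr::transmute(.data$participant_id, .data$artwork_id, .data$bin,
                     t_start = 0, t_end = .data$t_end,
                     cumulative_hit_count = as.numeric(.data$cumulative_hit_count))
  compare_bins(cum, group_assignment,
               metric_cols = "cumulative_hit_count", unit = unit)
}

#' Decision-aligned probability of gazing at the chosen option
#'
#' Rescales each preference trial's time axis to `[0, 1]` (1 = moment of
#' decision), bins normalised time, and estimates per bin the probability
#' that gaze falls on the ultimately chosen option: the fraction of valid
#' samples inside the chosen option's region among samples inside either
#' region, computed per trial and averaged over trials. Samples in neither
#' region are excluded from the denominator; their overall fraction is
#' reported as an attribute.
#'
#' @param samples Preference gaze samples (`trial_id`, `t`, `x`, `y`,
#'   `valid`).
#' @param trials Trial metadata (`trial_id`, `decision_time`, `chosen`).
#' @param regions Option bounding boxes, see [preference_regions()].
#' @param n_time_bins Number of normalised-time bins (default 10); the
#'   last bin is the fixed window immediately preceding the response.
#' @return A tibble with `bin` (1-based), `t_norm_start`, `t_norm_end`,
#'   `p_chosen`, `n_trials`; attributes `final_bin` (the last bin's
#'   estimate) and `excluded_fraction`.
#' @export
choice_gaze_probability <- function(samples, trials,
                                    regions = preference_regions(),
                                    n_time_bins = 10) {
  stopifnot(nrow(trials) >= 1)
  dat <- samples |>
    dplyr::filter(.data$valid) |>
    dplyr::inner_join(trials[c("trial_id", "decision_time", "chosen")],
                      by = "trial_id")
  in_box <- function(x, y, r) {
    x >= r$x0 & x <= r$x1 & y >= r$y0 & y <= r$y1
  }
  rl <- regions[regions$side == "left", ]
  rr <- regions[regions$side == "right", ]
  dat <- dat |>
    dplyr::mutate(
      side = dplyr::case_when(
        in_box(.data$x, .data$y, rl) ~ "left",
        in_box(.data$x, .data$y, rr) ~ "right",
        TRUE ~ NA_character_
      ),
      tau = pmin(pmax(.data$t / .data$decision_time, 0), 1),
      bin = pmin(floor(.data$tau * n_time_bins), n_time_bins - 1L) + 1L
    )
  excluded <- mean(is.na(dat$side))
  dat <- dplyr::filter(dat, !is.na(.data$side))
  per_trial <- dat |>
    dplyr::group_by(.data$trial_id, .data$bin) |>
    dplyr::summarise(p = mean(.data$side == .data$chosen), .groups = "drop")
  curve <- per_trial |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(p_chosen = mean(.data$p),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(t_norm_start = (.data$bin - 1) / n_time_bins,
                  t_norm_end = .data$bin / n_time_bins,
                  .after = "bin")
  attr(curve, "final_bin") <-
    curve$p_chosen[curve$bin == n_time_bins][1]
  attr(curve, "excluded_fraction") <- excluded
  curve
}
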