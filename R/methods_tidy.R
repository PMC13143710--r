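# broom-style accessors and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted gaze-state model
#'
#' @param x A `gaze_state_model`.
#' @param ... Unused.
#' @return One row per state: `state`, `mean_x`, `mean_y`, `area_frac`
#'   (ROI ellipse area as a fraction of image area), `occupancy`
#'   (stationary occupancy), `initial_prob`, `self_transition`.
#' @export
tidy.gaze_state_model <- function(x, ...) {
  areas <- vapply(x$covs, roi_area, numeric(1),
                  area_mass = x$constraints$area_mass)
  occ <- tryCatch(stationary_distribution(x$transition),
                  error = function(e) rep(NA_real_, x$K))
  tibble::tibble(
    state = seq_len(x$K),
    mean_x = x$means[, 1], mean_y = x$means[, 2],
    area_frac = areas, occupancy = occ,
    initial_prob = x$initial, self_transition = diag(x$transition)
  )
}

#' Glance at a fitted gaze-state model
#'
#' @param x A `gaze_state_model`.
#' @param ... Unused.
#' @return One row: `n_states`, `log_lik`, `n_restarts_used`, `n_iter`,
#'   `min_area_frac`, `max_area_frac`.
#' @export
glance.gaze_state_model <- function(x, ...) {
  areas <- vapply(x$covs, roi_area, numeric(1),
                  area_mass = x$constraints$area_mass)
  tibble::tibble(
    n_states = x$K, log_lik = x$log_lik,
    n_restarts_used = x$n_restarts_used, n_iter = length(x$ll_trace),
    min_area_frac = min(areas), max_area_frac = max(areas)
  )
}

#' Tidy a Wilcoxon rank-sum result
#'
#' @param x A `gaze_rank_test`.
#' @param ... Unused.
#' @return One row: `W`, `U`, `z`, `p`, `p_method`, `n1`, `n2`, `r`
#'   (rank-biserial, `z/sqrt(N)`).
#' @export
tidy.gaze_rank_test <- function(x, ...) {
  tibble::tibble(W = x$W, U = x$U, z = x$z, p = x$p, p_method = x$p_method,
                 n1 = x$n1, n2 = x$n2,
                 r = rank_biserial(x$z, x$n1 + x$n2))
}

#' Glance at a bin x metric comparison
#'
#' @param x A `gaze_comparison` from [compare_bins()].
#' @param ... Unused.
#' @return One row: `n_cells`, `n_testable`, `n_sig_uncorrected`,
#'   `n_sig_fdr`, `min_p`, `min_q`.
#' @export
glance.gaze_comparison <- function(x, ...) {
  ok <- !x$untestable & !is.na(x$p)
  tibble::tibble(
    n_cells = nrow(x), n_testable = sum(ok),
    n_sig_uncorrected = sum(x$p[ok] < 0.05),
    n_sig_fdr = sum(x$q[ok] < 0.05),
    min_p = if (any(ok)) min(x$p[ok]) else NA_real_,
    min_q = if (any(ok)) min(x$q[ok]) else NA_real_
  )
}

roi_ellipse_points <- function(mu, sigma, mass, n = 60) {
  r <- sqrt(stats::qchisq(mass, df = 2))
  th <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(cos(th), sin(th)) * r
  L <- t(chol(sigma))
  pts <- L %*% circ + mu
  tibble::tibble(x = pts[1, ], y = pts[2, ])
}

#' Plot the ROI ellipses of a gaze-state model
#'
#' Draws each state's mass ellipse (the area-defining contour) over the
#' unit square, labelled by state index; the y axis is reversed to match
#' image coordinates (origin top-left).
#'
#' @param object A `gaze_state_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gaze_state_model <- function(object, ...) {
  mass <- object$constraints$area_mass
  ell <- purrr::map_dfr(seq_len(object$K), function(k) {
    dplyr::mutate(
      roi_ellipse_points(object$means[k, ], object$covs[[k]], mass),
      state = factor(k)
    )
  })
  centers <- tidy(object)
  ggplot2::ggplot(ell, ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$state)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$state),
                       show.legend = FALSE) +
    ggplot2::geom_text(data = centers,
                       ggplot2::aes(x = .data$mean_x, y = .data$mean_y,
                                    label = .data$state),
                       inherit.aes = FALSE, size = 3) +
    ggplot2::scale_y_reverse(limits = c(1, 0)) +
    ggplot2::xlim(0, 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (normalised)", y = "y (normalised)",
                  title = "Gaze-state ROIs") +
    ggplot2::theme_minimal()
}

#' Heatmap of p- or q-values across bins and metrics
#'
#' @param object A `gaze_comparison` from [compare_bins()].
#' @param value `"q"` (default) or `"p"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gaze_comparison <- function(object, value = c("q", "p"), ...) {
  value <- match.arg(value)
  d <- dplyr::filter(object, !.data$untestable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_start + 1.5, y = .data$metric,
                                  fill = .data[[value]])) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data[[value]])),
                       size = 2.8) +
    ggplot2::scale_fill_gradient(low = "#c51b7d", high = "#f7f7f7",
                                 limits = c(0, 1), name = value) +
    ggplot2::labs(x = "time bin centre (s)", y = NULL,
                  title = paste0("Group comparison ", value, "-values")) +
    ggplot2::theme_minimal()
}

#' Group-mean time course of a gaze index
#'
#' Plots the mean of one metric per 3-s bin for the high- and
#' low-evaluation groups, with standard-error ribbons.
#'
#' @param metrics Per-episode metrics table from [study_metrics()].
#' @param group_assignment Tibble `artwork_id`, `group`.
#' @param metric Metric column name (default `"hnorm"`).
#' @return A ggplot object.
#' @export
plot_metric_timecourse <- function(metrics, group_assignment,
                                   metric = "hnorm") {
  d <- metrics |>
    dplyr::inner_join(group_assignment[c("artwork_id", "group")],
                      by = "artwork_id") |>
    dplyr::filter(!is.na(.data[[metric]])) |>
    dplyr::group_by(.data$group, .data$bin, .data$t_start) |>
    dplyr::summarise(m = mean(.data[[metric]]),
                     se = sd(.data[[metric]]) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_start + 1.5, y = .data$m,
                                  colour = .data$group,
                                  fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$se,
                                      ymax = .data$m + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "time bin centre (s)", y = metric,
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}
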