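# Constrained Gaussian-emission hidden Markov gaze-state model: maximum-
# likelihood Baum-Welch fitting with ROI area/axis constraints projected
# after each M-step, plus per-episode decoding (posteriors and Viterbi path).

#' Constraint configuration for gaze-state ROIs
#'
#' Gaze states are two-dimensional Gaussian regions of interest (ROIs).
#' To prevent degenerate solutions (an ROI swallowing the whole image, or
#' collapsing onto a single fixation), the fit constrains each ROI's
#' ellipse area to a band expressed as a fraction of total image area, and
#' clamps ellipse axis lengths to lie within `axis_clamp_n` standard
#' deviations of the mean axis length across ROIs.
#'
#' The ROI "area" is operationalised as the area of the ellipse containing
#' `area_mass` of the Gaussian's probability mass:
#' `pi * qchisq(area_mass, 2) * sqrt(det(Sigma))`. In normalised image
#' coordinates the total image area is 1, so fractions apply directly.
#'
#' @param area_min_frac,area_max_frac Lower/upper bound on ROI area as a
#'   fraction of total image area (defaults 0.001 and 0.05, i.e. 0.1-5%).
#' @param axis_clamp_n Number of standard deviations for the axis-length
#'   clamp (mean +/- N*sd over all ROI axis lengths).
#' @param area_mass Probability mass defining the ROI ellipse (default
#'   0.68).
#' @return A list of class `constraint_config`.
#' @export
constraint_config <- function(area_min_frac = 0.001, area_max_frac = 0.05,
                              axis_clamp_n = 2, area_mass = 0.68) {
  if (!(area_min_frac > 0 && area_min_frac < area_max_frac && area_max_frac < 1)) {
    stop("require 0 < area_min_frac < area_max_frac < 1", call. = FALSE)
  }
  structure(list(area_min_frac = area_min_frac, area_max_frac = area_max_frac,
                 axis_clamp_n = axis_clamp_n, area_mass = area_mass),
            class = "constraint_config")
}

#' ROI ellipse area of a 2x2 covariance matrix
#'
#' @param sigma A 2x2 covariance matrix.
#' @param area_mass Probability mass the ellipse contains (default 0.68).
#' @return Area in squared normalised coordinate units (image area = 1).
#' @export
roi_area <- function(sigma, area_mass = 0.68) {
  pi * stats::qchisq(area_mass, df = 2) * sqrt(max(det(sigma), 0))
}

new_gaze_state_model <- function(K, means, covs, transition, initial,
                                 image_dims = c(1, 1), log_lik = NA_real_,
                                 n_restarts_used = 0L,
                                 constraints = constraint_config(),
                                 ll_trace = numeric()) {
  structure(
    list(K = K, means = means, covs = covs, transition = transition,
         initial = initial, image_dims = image_dims, log_lik = log_lik,
         n_restarts_used = n_restarts_used, constraints = constraints,
         ll_trace = ll_trace),
    class = "gaze_state_model"
  )
}

#' @export
print.gaze_state_model <- function(x, ...) {
  cat("<gaze_state_model> ", x$K, " states\n", sep = "")
  areas <- vapply(x$covs, roi_area, numeric(1),
                  area_mass = x$constraints$area_mass)
  cat("  ROI areas (% image): ",
      paste(sprintf("%.2f", 100 * range(areas)), collapse = " - "), "\n",
      sep = "")
  if (is.finite(x$log_lik)) {
    cat("  log-likelihood: ", format(x$log_lik), " (", x$n_restarts_used,
        " restarts)\n", sep = "")
  }
  invisible(x)
}

validate_gaze_state_model <- function(m, tol = 1e-8) {
  stopifnot(
    nrow(m$means) == m$K, length(m$covs) == m$K,
    all(abs(rowSums(m$transition) - 1) < tol),
    abs(sum(m$initial) - 1) < tol
  )
  for (S in m$covs) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("covariance not positive definite", call. = FALSE)
  }
  invisible(m)
}

# log N(obs | mu, Sigma) for all K states; obs is n x 2
log_emissions <- function(model, xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  logB <- matrix(NA_real_, n, model$K)
  for (k in seq_len(model$K)) {
    S <- model$covs[[k]]
    dS <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    inv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2, 2) / dS
    dx <- xy[, 1] - model$means[k, 1]
    dy <- xy[, 2] - model$means[k, 2]
    q <- inv[1, 1] * dx^2 + 2 * inv[1, 2] * dx * dy + inv[2, 2] * dy^2
    logB[, k] <- -log(2 * pi) - 0.5 * log(dS) - 0.5 * q
  }
  logB
}

#' Project a model onto the ROI constraint set
#'
#' Applies the two feasibility operations after each M-step until a fixed
#' point is reached: axis lengths (square roots of covariance eigenvalues)
#' are clamped to the band mean +/- N*sd computed over all ROI axis
#' lengths, then each covariance is rescaled so its ellipse area falls
#' inside `[area_min_frac, area_max_frac]` of the image area. Because the
#' result is a fixed point of both operations, the projection is
#' idempotent; applying it to an already-feasible model changes nothing.
#'
#' @param model A `gaze_state_model`.
#' @param constraints A [constraint_config()]; defaults to the model's own.
#' @return The projected model, with attribute `"projected"` indicating
#'   whether any state was altered.
#' @export
project_constraints <- function(model, constraints = model$constraints) {
  changed_any <- FALSE
  for (pass in 1:25) {
    changed <- FALSE
    eigs <- lapply(model$covs, function(S) eigen(S, symmetric = TRUE))
    axes <- sqrt(pmax(unlist(lapply(eigs, `[[`, "values")), 0))
    m_ax <- mean(axes)
    s_ax <- stats::sd(axes)
    lo_ax <- max(m_ax - constraints$axis_clamp_n * s_ax, 1e-4)
    hi_ax <- m_ax + constraints$axis_clamp_n * s_ax
    if (!is.finite(s_ax)) { lo_ax <- 1e-4; hi_ax <- Inf }  # single axis value
    # violations below relative epsilon are ignored so that re-running the
    # projection on its own output is a strict no-op
    eps <- 1e-9
    model$covs <- purrr::map2(model$covs, eigs, function(S0, e) {
      ax <- sqrt(pmax(e$values, 1e-6^2))
      clamped <- any(ax < lo_ax * (1 - eps) | ax > hi_ax * (1 + eps)) ||
        any(e$values < 1e-6^2)
      S <- S0
      if (clamped) {
        ax2 <- pmin(pmax(ax, lo_ax), hi_ax)
        S <- e$vectors %*% diag(ax2^2, 2) %*% t(e$vectors)
      }
      a <- roi_area(S, constraints$area_mass)
      target <- min(max(a, constraints$area_min_frac),
                    constraints$area_max_frac)
      rescaled <- abs(target - a) > eps * a
      if (rescaled) S <- S * (target / a)
      if (clamped || rescaled) changed <<- TRUE else return(S0)
      (S + t(S)) / 2
    })
    changed_any <- changed_any || changed
    if (!changed) break
  }
  attr(model, "projected") <- changed_any
  model
}

# k-means++ style seeding of K centers from n x 2 locations
kmeanspp_centers <- function(xy, K) {
  n <- nrow(xy)
  centers <- matrix(NA_real_, K, 2)
  centers[1, ] <- xy[sample.int(n, 1L), ]
  if (K > 1L) {
    d2 <- rowSums((xy - matrix(centers[1, ], n, 2, byrow = TRUE))^2)
    for (k in 2:K) {
      pr <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[k, ] <- xy[sample.int(n, 1L, prob = pr), ]
      d2 <- pmin(d2, rowSums((xy - matrix(centers[k, ], n, 2, byrow = TRUE))^2))
    }
  }
  centers
}

#' Fit a constrained Gaussian-HMM gaze-state model
#'
#' Estimates K gaze states (two-dimensional Gaussian ROIs), their
#' transition matrix and initial distribution from the gaze sequences of
#' multiple viewing episodes of one stimulus, by maximum-likelihood
#' Baum-Welch EM. After every M-step the ROI constraints are enforced by
#' [project_constraints()]. Multiple seeded restarts are run (k-means++
#' initialisation of the means on the observation locations) and the
#' restart with the highest log-likelihood is returned, with states
#' re-indexed by descending stationary occupancy so that state labels are
#' reproducible.
#'
#' @param observations A data frame of observation points with numeric
#'   columns `x`, `y` in normalised image coordinates. Rows are grouped
#'   into sequences by the columns in `seq_cols` (one sequence per viewing
#'   episode); by default any of `participant_id`, `artwork_id`, `seq_id`
#'   present are used. Observations are typically fixation centroids (one
#'   sequence = one episode's fixation sequence), or raw samples.
#' @param K Number of gaze states (default 14).
#' @param constraints A [constraint_config()].
#' @param n_restarts Number of EM restarts (default 20).
#' @param seed Integer seed fixing all restart randomness.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations per restart (default 200).
#' @param seq_cols Character vector of columns identifying sequences.
#' @param verbose Print per-restart progress.
#' @return A `gaze_state_model` with elements `K`, `means` (K x 2), `covs`
#'   (list of K 2x2 matrices), `transition` (row-stochastic K x K),
#'   `initial`, `log_lik`, `n_restarts_used`, `ll_trace` (per-iteration
#'   log-likelihood of the winning restart) and the constraint
#'   configuration.
#' @export
fit_emhmm <- function(observations, K = 14, constraints = constraint_config(),
                      n_restarts = 20, seed = 1, tol = 1e-6, max_iter = 200,
                      seq_cols = NULL, verbose = FALSE) {
  obs <- tibble::as_tibble(observations)
  stopifnot(all(c("x", "y") %in% names(obs)))
  if (is.null(seq_cols)) {
    seq_cols <- intersect(c("participant_id", "artwork_id", "seq_id"),
                          names(obs))
  }
  if (length(seq_cols) == 0L) {
    obs$.seq <- 1L
  } else {
    obs$.seq <- as.integer(interaction(obs[seq_cols], drop = TRUE))
  }
  xy <- as.matrix(obs[, c("x", "y")])
  if (any(!is.finite(xy))) stop("observations must be finite", call. = FALSE)
  n_distinct_loc <- nrow(unique(round(xy, 12)))
  if (K > n_distinct_loc) {
    stop("degenerate fit: K = ", K, " exceeds the ", n_distinct_loc,
         " distinct observation locations", call. = FALSE)
  }
  seq_idx <- split(seq_len(nrow(xy)), obs$.seq)
  if (any(lengths(seq_idx) < 2L)) {
    seq_idx <- seq_idx[lengths(seq_idx) >= 2L]
  }
  if (length(seq_idx) == 0L) {
    stop("need at least one sequence with >= 2 observations", call. = FALSE)
  }

  best <- NULL
  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max, n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(restart_seeds[r])
    fit <- tryCatch(
      em_single_restart(xy, seq_idx, K, constraints, tol, max_iter),
      error = function(e) {
        stop("numerical error in EM restart ", r, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    if (verbose) {
      message(sprintf("restart %d/%d: log-lik %.4f (%d iters)", r, n_restarts,
                      fit$log_lik, length(fit$ll_trace)))
    }
    if (is.null(best) || fit$log_lik > best$log_lik) best <- fit
  }

  model <- new_gaze_state_model(
    K = K, means = best$means, covs = best$covs, transition = best$transition,
    initial = best$initial, log_lik = best$log_lik,
    n_restarts_used = n_restarts, constraints = constraints,
    ll_trace = best$ll_trace
  )
  model <- reindex_by_occupancy(model)
  validate_gaze_state_model(model)
  model
}

em_single_restart <- function(xy, seq_idx, K, constraints, tol, max_iter) {
  n <- nrow(xy)
  centers <- kmeanspp_centers(xy, K)
  km <- suppressWarnings(stats::kmeans(xy, centers = centers, iter.max = 10))
  means <- km$centers
  covs <- lapply(seq_len(K), function(k) {
    pts <- xy[km$cluster == k, , drop = FALSE]
    S <- if (nrow(pts) >= 3) stats::cov(pts) else diag(1e-3, 2)
    S + diag(1e-5, 2)
  })
  transition <- matrix(0.2 / max(K - 1, 1), K, K)
  diag(transition) <- if (K > 1) 0.8 else 1
  initial <- rep(1 / K, K)
  model <- new_gaze_state_model(K, means, covs, transition, initial,
                                constraints = constraints)
  model <- project_constraints(model, constraints)

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  proj_active <- FALSE
  for (iter in seq_len(max_iter)) {
    logB <- log_emissions(model, xy)
    log_init <- log(model$initial)
    log_trans <- log(model$transition)
    ll <- 0
    gamma <- matrix(0, n, K)
    xi_sum <- matrix(0, K, K)
    init_acc <- rep(0, K)
    for (idx in seq_idx) {
      fb <- cpp_forward_backward(log_init, log_trans,
                                 logB[idx, , drop = FALSE])
      ll <- ll + fb$log_lik
      gamma[idx, ] <- fb$gamma
      xi_sum <- xi_sum + fb$xi_sum
      init_acc <- init_acc + fb$gamma[1, ]
    }
    if (length(ll_trace) > 0 && ll < ll_prev - 1e-8 && proj_active) {
      message(sprintf(
        "constraint projection decreased the log-likelihood at iteration %d (%.3g)",
        iter - 1L, ll - ll_prev))
    }
    ll_trace <- c(ll_trace, ll)

    # M-step
    wsum <- colSums(gamma)
    means <- t(vapply(seq_len(K), function(k) {
      colSums(gamma[, k] * xy) / wsum[k]
    }, numeric(2)))
    covs <- lapply(seq_len(K), function(k) {
      dx <- xy[, 1] - means[k, 1]
      dy <- xy[, 2] - means[k, 2]
      w <- gamma[, k]
      S <- matrix(c(sum(w * dx * dx), sum(w * dx * dy),
                    sum(w * dx * dy), sum(w * dy * dy)), 2, 2) / wsum[k]
      S + diag(1e-6, 2)  # eigenvalue floor against collapse
    })
    rs <- rowSums(xi_sum)
    transition <- xi_sum / ifelse(rs > 0, rs, 1)
    transition[rs == 0, ] <- 1 / K  # state never left: uninformative row
    initial <- init_acc / sum(init_acc)
    model$means <- means
    model$covs <- covs
    model$transition <- transition
    model$initial <- initial
    model <- project_constraints(model, constraints)
    proj_active <- isTRUE(attr(model, "projected"))

    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) break
    ll_prev <- ll
  }
  # final log-likelihood under the projected parameters
  logB <- log_emissions(model, xy)
  ll_final <- sum(vapply(seq_idx, function(idx) {
    cpp_forward_backward(log(model$initial), log(model$transition),
                         logB[idx, , drop = FALSE])$log_lik
  }, numeric(1)))
  list(means = model$means, covs = model$covs, transition = model$transition,
       initial = model$initial, log_lik = ll_final, ll_trace = ll_trace)
}

stationary_distribution <- function(A) {
  K <- nrow(A)
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  if (all(abs(v) < 1e-12)) return(rep(1 / K, K))
  v <- abs(v)
  v / sum(v)
}

reindex_by_occupancy <- function(model) {
  occ <- tryCatch(stationary_distribution(model$transition),
                  error = function(e) rep(1 / model$K, model$K))
  ord <- order(occ, decreasing = TRUE)
  model$means <- model$means[ord, , drop = FALSE]
  model$covs <- model$covs[ord]
  model$transition <- model$transition[ord, ord, drop = FALSE]
  model$initial <- model$initial[ord]
  model
}

#' Posterior state probabilities via the forward-backward algorithm
#'
#' Runs the scaled forward-backward recursion for one observation sequence
#' under a fitted gaze-state model, returning the per-timepoint posterior
#' probability of each state and the exact log-likelihood of the sequence.
#' A timepoint at which every state's emission density underflows to zero
#' raises an error rather than silently renormalising.
#'
#' @param model A `gaze_state_model`.
#' @param observations Data frame or matrix with columns/cols `x`, `y`.
#' @return An object of class `state_sequence`: list with `posteriors`
#'   (T x K, rows on the simplex), `log_lik`, `T`, `K`.
#' @export
forward_backward <- function(model, observations) {
  xy <- obs_xy(observations)
  logB <- log_emissions(model, xy)
  fb <- cpp_forward_backward(log(model$initial), log(model$transition), logB)
  structure(list(posteriors = fb$gamma, log_lik = fb$log_lik,
                 T = nrow(logB), K = model$K),
            class = "state_sequence")
}

#' Most likely state sequence (Viterbi path)
#'
#' Decodes the single most probable hidden-state path for one observation
#' sequence. Ties are broken toward the lower state index, so the result is
#' deterministic even for fully symmetric models.
#'
#' @inheritParams forward_backward
#' @return Integer vector of state indices in `1..K`.
#' @export
viterbi <- function(model, observations) {
  xy <- obs_xy(observations)
  logB <- log_emissions(model, xy)
  as.integer(cpp_viterbi(log(model$initial), log(model$transition), logB))
}

#' Decode one episode: posteriors plus Viterbi path
#'
#' Convenience wrapper combining [forward_backward()] and [viterbi()].
#'
#' @inheritParams forward_backward
#' @return A `state_sequence` with `posteriors`, `viterbi_path`, `log_lik`.
#' @export
decode_episode <- function(model, observations) {
  seq <- forward_backward(model, observations)
  seq$viterbi_path <- viterbi(model, observations)
  seq
}

obs_xy <- function(observations) {
  m <- as.matrix(as.data.frame(observations)[, c("x", "y")])
  if (any(!is.finite(m))) stop("observations must be finite", call. = FALSE)
  m
}

#' Serialise / restore a gaze-state model
#'
#' Writes the full model (means, covariances, transition matrix, initial
#' distribution, constraint configuration, fit metadata) to a versioned
#' JSON bundle at full floating-point precision, and reads it back. The
#' round trip reproduces every numeric field exactly.
#'
#' @param model A `gaze_state_model`.
#' @param path File path for the JSON bundle.
#' @return `write_gaze_state_model()` returns `path` invisibly;
#'   `read_gaze_state_model()` returns the restored `gaze_state_model`.
#' @export
write_gaze_state_model <- function(model, path) {
  payload <- list(
    format = "gazephase_state_model", version = 1L,
    K = model$K,
    means = apply(model$means, 1, function(r) sprintf("%.17g", r),
                  simplify = FALSE),
    covs = lapply(model$covs, function(S) sprintf("%.17g", as.vector(S))),
    transition = apply(model$transition, 1,
                       function(r) sprintf("%.17g", r), simplify = FALSE),
    initial = sprintf("%.17g", model$initial),
    image_dims = model$image_dims,
    log_lik = sprintf("%.17g", model$log_lik),
    n_restarts_used = model$n_restarts_used,
    constraints = unclass(model$constraints)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gaze_state_model
#' @export
read_gaze_state_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "gazephase_state_model")) {
    stop("not a gazephase state-model bundle: ", path, call. = FALSE)
  }
  K <- as.integer(p$K)
  num_row <- function(r) as.numeric(unlist(r))
  means <- do.call(rbind, lapply(p$means, num_row))
  covs <- lapply(p$covs, function(v) matrix(num_row(v), 2, 2))
  transition <- do.call(rbind, lapply(p$transition, num_row))
  cc <- do.call(constraint_config, lapply(p$constraints, as.numeric))
  new_gaze_state_model(
    K = K, means = means, covs = covs, transition = transition,
    initial = num_row(p$initial), image_dims = num_row(p$image_dims),
    log_lik = if (identical(p$log_lik, "NA")) NA_real_ else
      as.numeric(p$log_lik),
    n_restarts_used = as.integer(p$n_restarts_used), constraints = cc
  )
}

#' Optimal state matching between two models
#'
#' Finds the permutation of estimated states that minimises the mean
#' Euclidean distance between estimated and reference ROI means (the
#' assignment problem). Solved exactly by enumeration over permutations,
#' which is practical for the state counts used in recovery checks
#' (K <= 8).
#'
#' @param est_means,ref_means K x 2 matrices of ROI mean locations.
#' @return A list with `perm` (index into rows of `est_means` for each
#'   reference state) and `mean_error` (mean matched Euclidean distance).
#' @export
match_states <- function(est_means, ref_means) {
  K <- nrow(ref_means)
  stopifnot(nrow(est_means) == K)
  if (K > 8) stop("exact enumeration supports K <= 8", call. = FALSE)
  cost <- outer(seq_len(K), seq_len(K), Vectorize(function(i, j) {
    sqrt(sum((ref_means[i, ] - est_means[j, ])^2))
  }))
  perms <- all_permutations(K)
  costs <- vapply(perms, function(pm) {
    sum(cost[cbind(seq_len(K), pm)])
  }, numeric(1))
  best <- perms[[which.min(costs)]]
  list(perm = best, mean_error = min(costs) / K)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
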