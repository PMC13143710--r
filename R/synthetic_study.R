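# Seeded synthetic-study generator. Emulates the structure the analysis
# assumes: a crossed participants x artworks design, 300 Hz gaze sampled
# from Gaussian ROI states under a hidden Markov path, self-paced episode
# durations, and two artwork groups that differ both in rating level and in
# the onset time of gaze-state convergence (exploration -> convergence
# regime switch at tau).

#' Configuration of the synthetic study generator
#'
#' Defaults emulate the study design the pipeline targets: 35 participants
#' by 12 artworks (6 per evaluation group), 300 Hz sampling, self-paced
#' episode durations with mean 13.1 s (SD 1.21), group mean normalised
#' ratings of 0.668 (high) and 0.357 (low), and an earlier
#' exploration-to-convergence transition for the high group (tau 6 s vs
#' 12 s).
#'
#' The convergence mechanism is a time-inhomogeneous transition matrix:
#' before `tau` the chain explores (self-transition
#' `stickiness_explore`, near-uniform off-diagonal); after `tau` every row
#' concentrates mass `stickiness_converge` on a per-episode focus state.
#' With 300 Hz sampling the default `stickiness_explore = 0.989` gives a
#' mean exploratory state dwell of about 0.3 s, and
#' `stickiness_converge = 0.995` keeps gaze on the focus state about 99.5%
#' of post-tau time.
#'
#' @param n_participants,n_artworks Design size (12 artworks = 6 high + 6
#'   low).
#' @param sampling_rate_hz Gaze sampling rate.
#' @param K_true Number of ground-truth ROI states.
#' @param tau_high,tau_low Convergence onset (seconds) for high/low-group
#'   artworks.
#' @param stickiness_explore,stickiness_converge Per-sample self/focus
#'   transition probabilities before/after tau.
#' @param judgment_time_mean_s,judgment_time_sd_s Normal distribution of
#'   the self-paced judgment (click) time, truncated to
#'   `judgment_time_range` and to at least the episode's tau.
#' @param judgment_time_range Truncation bounds in seconds; the default
#'   `c(3, 30)` guarantees at least one populated bin and respects the
#'   30-s analysis horizon.
#' @param rating_mean_high,rating_mean_low Group means of the normalised
#'   rating scale.
#' @param rating_noise_sd SD of per-episode rating noise on the normalised
#'   scale.
#' @param fixation_jitter_sd SD of the within-fixation positional jitter
#'   (normalised units). Gaze holds a fixated location with this micro
#'   jitter rather than re-drawing from the ROI at every sample, giving
#'   episodes a realistic fixation structure that dispersion-based
#'   detection can recover.
#' @param refixation_mean_s Mean interval between successive fixation
#'   locations while gaze stays within one state (re-fixations inside an
#'   ROI).
#' @param n_depth_points Number of synthetic depth-annotation points per
#'   artwork; focus states are drawn from the corresponding ROIs.
#' @param depth_placement Where depth annotations sit: `"group"` (default;
#'   high-group artworks have them at the focus ROI means - depth cues
#'   coincide with gaze attractors - while low-group artworks have them at
#'   random locations), `"focus"` (all artworks at focus ROI means;
#'   removes the group difference, for null checks) or `"random"` (all
#'   random).
#' @param shared_model If `TRUE`, all artworks share one ground-truth
#'   model, making episodes fully exchangeable across artworks (used by
#'   null configurations where artwork-geometry random effects must be
#'   absent); default `FALSE` (one random model per artwork).
#' @param image_dims Stimulus pixel dimensions `c(width, height)`.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `generative_config`.
#' @export
generative_config <- function(n_participants = 35, n_artworks = 12,
                              sampling_rate_hz = 300, K_true = 14,
                              tau_high = 6, tau_low = 12,
                              stickiness_explore = 0.989,
                              stickiness_converge = 0.995,
                              judgment_time_mean_s = 13.1,
                              judgment_time_sd_s = 1.21,
                              judgment_time_range = c(3, 30),
                              rating_mean_high = 0.668,
                              rating_mean_low = 0.357,
                              rating_noise_sd = 0.08,
                              fixation_jitter_sd = 0.0015,
                              refixation_mean_s = 0.3,
                              n_depth_points = 3,
                              depth_placement = c("group", "focus", "random"),
                              shared_model = FALSE,
                              image_dims = c(1920, 1080), seed = 1) {
  depth_placement <- match.arg(depth_placement)
  stopifnot(
    stickiness_explore >= 0, stickiness_explore <= 1,
    stickiness_converge >= 0, stickiness_converge <= 1,
    n_artworks %% 2 == 0, K_true >= 1,
    judgment_time_range[1] > 0, judgment_time_range[2] > judgment_time_range[1]
  )
  structure(as.list(environment()), class = "generative_config")
}

#' Write / read a generator configuration as YAML
#'
#' All generator parameters live in one YAML file, so a synthetic study is
#' fully described by that file plus the seed it contains.
#'
#' @param config A [generative_config()].
#' @param path YAML file path.
#' @return `write_generative_config()` returns `path` invisibly;
#'   `read_generative_config()` returns a validated `generative_config`.
#' @export
write_generative_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_generative_config
#' @export
read_generative_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  do.call(generative_config, vals)
}

#' Sample a ground-truth gaze-state model
#'
#' Draws `K_true` Gaussian ROIs with means inside the unit square and
#' ellipse areas inside the constraint band, a sticky row-stochastic
#' exploration transition matrix and a uniform initial distribution. The
#' same seed yields an identical model.
#'
#' @param K_true Number of states.
#' @param constraints A [constraint_config()]; ROI areas are drawn
#'   log-uniformly inside the band.
#' @param stickiness Self-transition probability of the exploration regime.
#' @param seed Integer seed.
#' @return A `gaze_state_model`.
#' @export
make_ground_truth_model <- function(K_true, constraints = constraint_config(),
                                    stickiness = 0.989, seed = 1) {
  stopifnot(K_true >= 1)
  set.seed(seed)
  scale <- pi * stats::qchisq(constraints$area_mass, df = 2)
  if (constraints$area_min_frac >= constraints$area_max_frac) {
    stop("infeasible ROI area band", call. = FALSE)
  }
  means <- cbind(runif(K_true, 0.12, 0.88), runif(K_true, 0.12, 0.88))
  covs <- lapply(seq_len(K_true), function(k) {
    # area log-uniform strictly inside the band; random orientation and
    # moderate axis anisotropy
    a <- exp(runif(1, log(constraints$area_min_frac * 1.1),
                   log(constraints$area_max_frac * 0.9)))
    sdet <- a / scale
    q <- runif(1, 1, 2)
    l1 <- sdet * q
    l2 <- sdet / q
    th <- runif(1, 0, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    S <- R %*% diag(c(l1, l2)) %*% t(R)
    (S + t(S)) / 2
  })
  if (K_true == 1) {
    transition <- matrix(1, 1, 1)
  } else {
    transition <- matrix((1 - stickiness) / (K_true - 1), K_true, K_true)
    diag(transition) <- stickiness
  }
  new_gaze_state_model(
    K = K_true, means = means, covs = covs, transition = transition,
    initial = rep(1 / K_true, K_true), constraints = constraints
  )
}

convergence_transition <- function(K, focus, stickiness_converge) {
  if (K == 1) return(matrix(1, 1, 1))
  A <- matrix((1 - stickiness_converge) / (K - 1), K, K)
  A[, focus] <- stickiness_converge
  # redistribute each row's residual over the non-focus states
  for (i in seq_len(K)) {
    others <- setdiff(seq_len(K), focus)
    A[i, others] <- (1 - stickiness_converge) / (K - 1)
  }
  A / rowSums(A)
}

sample_markov_path <- function(T_len, initial, A_explore, A_converge,
                               switch_idx) {
  K <- length(initial)
  path <- integer(T_len)
  path[1] <- sample.int(K, 1L, prob = initial)
  if (T_len > 1) {
    for (t in 2:T_len) {
      A <- if (t <= switch_idx) A_explore else A_converge
      path[t] <- sample.int(K, 1L, prob = A[path[t - 1], ])
    }
  }
  path
}

#' Simulate one viewing episode from a ground-truth model
#'
#' Samples a hidden state path (exploration-regime transitions before
#' `tau_s`, convergence-regime transitions concentrated on `focus_state`
#' after `tau_s`), then draws gaze positions from the state-conditional
#' Gaussians at the configured sampling rate. The self-paced judgment time
#' is drawn from the configured truncated normal, bounded below by
#' `tau_s`.
#'
#' @param model Ground-truth `gaze_state_model`.
#' @param tau_s Convergence onset in seconds (may be `Inf` for
#'   never-converging episodes).
#' @param config A [generative_config()] (sampling rate, stickiness,
#'   judgment-time distribution).
#' @param focus_state Focus state index; default drawn uniformly.
#' @param duration_s Optional fixed episode duration overriding the drawn
#'   judgment time.
#' @return A list with `samples` (tibble `t`, `x`, `y`, `valid`), `path`
#'   (true state indices), `judgment_time`, `focus_state`.
#' @export
simulate_episode <- function(model, tau_s, config = generative_config(),
                             focus_state = NULL, duration_s = NULL) {
  K <- model$K
  if (is.null(focus_state)) focus_state <- sample.int(K, 1L)
  jt <- rnorm(1, config$judgment_time_mean_s, config$judgment_time_sd_s)
  jt <- min(max(jt, config$judgment_time_range[1],
                min(tau_s, config$judgment_time_range[2])),
            config$judgment_time_range[2])
  if (!is.null(duration_s)) jt <- duration_s
  dt <- 1 / config$sampling_rate_hz
  times <- seq(0, jt, by = dt)
  T_len <- length(times)
  A_conv <- convergence_transition(K, focus_state, config$stickiness_converge)
  switch_idx <- sum(times < tau_s)
  path <- sample_markov_path(T_len, model$initial, model$transition, A_conv,
                             switch_idx)
  # fixation-structured emissions: a new fixation location is drawn from
  # the current state's Gaussian whenever the state changes or a
  # re-fixation occurs (rate 1/refixation_mean_s); between draws gaze
  # holds the location with micro jitter
  new_fix <- c(TRUE, path[-1] != path[-T_len]) |
    (runif(T_len) < dt / config$refixation_mean_s)
  fix_id <- cumsum(new_fix)
  starts <- which(new_fix)
  n_fix <- length(starts)
  cx <- numeric(n_fix); cy <- numeric(n_fix)
  z1 <- rnorm(n_fix); z2 <- rnorm(n_fix)
  for (k in unique(path[starts])) {
    idx <- which(path[starts] == k)
    L <- t(chol(model$covs[[k]]))
    cx[idx] <- model$means[k, 1] + L[1, 1] * z1[idx]
    cy[idx] <- model$means[k, 2] + L[2, 1] * z1[idx] + L[2, 2] * z2[idx]
  }
  jsd <- config$fixation_jitter_sd
  x <- cx[fix_id] + rnorm(T_len, 0, jsd)
  y <- cy[fix_id] + rnorm(T_len, 0, jsd)
  valid <- x >= 0 & x < 1 & y >= 0 & y < 1
  list(
    samples = tibble::tibble(t = times, x = x, y = y, valid = valid),
    path = path, judgment_time = jt, focus_state = focus_state
  )
}

#' Simulate a full synthetic study
#'
#' Generates the complete crossed design: per-artwork ground-truth models,
#' two artwork groups (first half high: convergence onset `tau_high`,
#' higher normalised ratings; second half low), one viewing episode per
#' participant x artwork, integer ratings obtained by mapping normalised
#' ratings through a per-participant affine response range, and synthetic
#' depth-point annotations at the ROIs from which focus states are drawn.
#' Deterministic given `config$seed`.
#'
#' @param config A [generative_config()].
#' @return An object of class `gaze_study`: list with tibbles `samples`
#'   (`participant_id`, `artwork_id`, `t`, `x`, `y`, `valid`), `episodes`
#'   (`participant_id`, `artwork_id`, `judgment_time`, `rating`),
#'   `stimuli`, `depth_points`, and `truth` (ground-truth models, group
#'   assignment with tau per artwork, per-episode focus states and state
#'   paths).
#' @export
simulate_study <- function(config = generative_config()) {
  set.seed(config$seed)
  n_art <- config$n_artworks
  n_half <- n_art %/% 2
  artworks <- sprintf("art%02d", seq_len(n_art))
  participants <- sprintf("p%02d", seq_len(config$n_participants))
  groups <- tibble::tibble(
    artwork_id = artworks,
    group = rep(c("high", "low"), each = n_half),
    tau = rep(c(config$tau_high, config$tau_low), each = n_half),
    rating_mean = rep(c(config$rating_mean_high, config$rating_mean_low),
                      each = n_half)
  )
  model_seeds <- sample.int(2^31 - 1, n_art)
  if (isTRUE(config$shared_model)) model_seeds[] <- model_seeds[1]
  models <- lapply(seq_len(n_art), function(a) {
    make_ground_truth_model(config$K_true,
                            stickiness = config$stickiness_explore,
                            seed = model_seeds[a])
  })
  names(models) <- artworks

  # focus states are drawn from the first n_focus ROIs; depth annotations
  # coincide with those ROIs or sit at random locations per the placement
  # rule
  n_focus <- max(1L, min(config$n_depth_points, config$K_true))
  depth_points <- purrr::map_dfr(seq_len(n_art), function(a) {
    at_focus <- switch(config$depth_placement,
      focus = TRUE,
      random = FALSE,
      group = groups$group[a] == "high"
    )
    if (at_focus) {
      tibble::tibble(artwork_id = artworks[a],
                     x = models[[a]]$means[seq_len(n_focus), 1],
                     y = models[[a]]$means[seq_len(n_focus), 2])
    } else {
      tibble::tibble(artwork_id = artworks[a],
                     x = runif(n_focus, 0.1, 0.9),
                     y = runif(n_focus, 0.1, 0.9))
    }
  })

  # per-participant affine response range for integer ratings
  resp_lo <- runif(config$n_participants, 1, 2.5)
  resp_hi <- runif(config$n_participants, 8.5, 10)

  grid <- tidyr::expand_grid(participant_id = participants,
                             artwork_id = artworks)
  sim <- purrr::pmap(grid, function(participant_id, artwork_id) {
    a <- match(artwork_id, artworks)
    p <- match(participant_id, participants)
    ep <- simulate_episode(models[[artwork_id]], groups$tau[a], config,
                           focus_state = sample.int(n_focus, 1L))
    v <- groups$rating_mean[a] + rnorm(1, 0, config$rating_noise_sd)
    v <- min(max(v, 0), 1)
    rating <- as.integer(round(resp_lo[p] + (resp_hi[p] - resp_lo[p]) * v))
    rating <- min(max(rating, 1L), 10L)
    list(
      samples = dplyr::mutate(ep$samples, participant_id = participant_id,
                              artwork_id = artwork_id, .before = 1),
      episode = tibble::tibble(participant_id = participant_id,
                               artwork_id = artwork_id,
                               judgment_time = ep$judgment_time,
                               rating = rating,
                               focus_state = ep$focus_state),
      path = ep$path
    )
  })

  episodes <- purrr::map_dfr(sim, "episode")
  samples <- purrr::map_dfr(sim, "samples")
  paths <- purrr::map(sim, "path")
  names(paths) <- paste(grid$participant_id, grid$artwork_id, sep = ":")

  structure(
    list(
      samples = samples,
      episodes = dplyr::select(episodes, -"focus_state"),
      stimuli = tibble::tibble(artwork_id = artworks,
                               width_px = config$image_dims[1],
                               height_px = config$image_dims[2]),
      depth_points = depth_points,
      truth = list(models = models, groups = groups,
                   focus_states = episodes[c("participant_id", "artwork_id",
                                             "focus_state")],
                   paths = paths),
      config = config
    ),
    class = "gaze_study"
  )
}

#' @export
print.gaze_study <- function(x, ...) {
  cat("<gaze_study> ", length(unique(x$episodes$participant_id)),
      " participants x ", length(unique(x$episodes$artwork_id)),
      " artworks, ", nrow(x$episodes), " episodes, ",
      nrow(x$samples), " gaze samples\n", sep = "")
  invisible(x)
}

#' Write / read a study as delimited text
#'
#' `write_study()` serialises the observable part of a study (samples,
#' episodes, stimuli, depth points) as the CSV dialects [read_gaze_table()]
#' and friends read; `read_study()` restores it. Doubles round-trip
#' exactly. Ground truth, when present, is written to a `truth/`
#' subdirectory (group assignment CSV and per-artwork model JSON bundles).
#'
#' @param study A `gaze_study`.
#' @param dir Directory to write into (created if needed).
#' @param write_truth Whether to serialise ground truth (default TRUE when
#'   present).
#' @return `dir` invisibly; `read_study()` returns a `gaze_study` (without
#'   true state paths, which are in-memory artefacts of the generator).
#' @export
write_study <- function(study, dir, write_truth = !is.null(study$truth)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gaze_table(study$samples, file.path(dir, "gaze.csv"))
  readr::write_csv(study$episodes, file.path(dir, "episodes.csv"),
                   progress = FALSE)
  readr::write_csv(study$stimuli, file.path(dir, "stimuli.csv"),
                   progress = FALSE)
  if (!is.null(study$depth_points)) {
    readr::write_csv(study$depth_points, file.path(dir, "depth_points.csv"),
                     progress = FALSE)
  }
  if (write_truth && !is.null(study$truth)) {
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    readr::write_csv(study$truth$groups, file.path(tdir, "groups.csv"),
                     progress = FALSE)
    readr::write_csv(study$truth$focus_states,
                     file.path(tdir, "focus_states.csv"), progress = FALSE)
    for (a in names(study$truth$models)) {
      write_gaze_state_model(study$truth$models[[a]],
                             file.path(tdir, paste0("model_", a, ".json")))
    }
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  samples <- read_gaze_table(file.path(dir, "gaze.csv"))
  episodes <- readr::read_csv(file.path(dir, "episodes.csv"),
                              show_col_types = FALSE, progress = FALSE)
  episodes <- dplyr::mutate(
    episodes, participant_id = as.character(.data$participant_id),
    artwork_id = as.character(.data$artwork_id),
    rating = as.integer(.data$rating)
  )
  stimuli <- read_stimuli(file.path(dir, "stimuli.csv"))
  dp_path <- file.path(dir, "depth_points.csv")
  depth_points <- if (file.exists(dp_path)) read_depth_points(dp_path) else NULL
  truth <- NULL
  tdir <- file.path(dir, "truth")
  if (dir.exists(tdir)) {
    groups <- readr::read_csv(file.path(tdir, "groups.csv"),
                              show_col_types = FALSE, progress = FALSE)
    model_files <- list.files(tdir, pattern = "^model_.*\\.json$",
                              full.names = TRUE)
    models <- lapply(model_files, read_gaze_state_model)
    names(models) <- sub("^model_(.*)\\.json$", "\\1", basename(model_files))
    fs_path <- file.path(tdir, "focus_states.csv")
    focus <- if (file.exists(fs_path)) {
      readr::read_csv(fs_path, show_col_types = FALSE, progress = FALSE)
    } else NULL
    truth <- list(models = models, groups = groups, focus_states = focus)
  }
  structure(list(samples = samples, episodes = episodes, stimuli = stimuli,
                 depth_points = depth_points, truth = truth),
            class = "gaze_study")
}

#' Configuration of the pre-decision gaze-bias generator
#'
#' @param baseline Probability of sampling the to-be-chosen option's region
#'   early in the trial.
#' @param final_prob Probability reached in the moments before the
#'   decision.
#' @param ramp_s Duration of the linear ramp ending at the decision.
#' @param decision_time_mean_s,decision_time_sd_s Normal distribution of
#'   decision times, truncated to be positive.
#' @param sampling_rate_hz Gaze sampling rate.
#' @param presentation_constraint_s Stimulus presentation constraint in
#'   seconds (0.3, 0.9, or `NA` for unconstrained); recorded as trial
#'   metadata.
#' @param off_region_prob Probability that a sample falls in neither
#'   option's region (background gaze).
#' @return A list of class `bias_config`.
#' @export
bias_config <- function(baseline = 0.5, final_prob = 0.9, ramp_s = 1,
                        decision_time_mean_s = 3, decision_time_sd_s = 0.5,
                        sampling_rate_hz = 300,
                        presentation_constraint_s = NA_real_,
                        off_region_prob = 0.05) {
  stopifnot(baseline >= 0, baseline <= 1, final_prob >= 0, final_prob <= 1)
  structure(as.list(environment()), class = "bias_config")
}

#' Default left/right option regions for preference trials
#'
#' @return A tibble with one row per side: `side`, `x0`, `x1`, `y0`, `y1`
#'   (normalised bounding boxes).
#' @export
preference_regions <- function() {
  tibble::tibble(
    side = c("left", "right"),
    x0 = c(0.05, 0.55), x1 = c(0.45, 0.95),
    y0 = c(0.30, 0.30), y1 = c(0.70, 0.70)
  )
}

#' Simulate two-alternative forced-choice preference trials
#'
#' Each trial draws a decision time and a chosen side, then samples a gaze
#' stream whose probability of falling inside the to-be-chosen option's
#' region ramps linearly from `baseline` to `final_prob` over the last
#' `ramp_s` seconds before the decision (the gaze-cascade mechanism). A
#' small fraction of samples falls in neither region.
#'
#' @param n_trials Number of trials.
#' @param config A [bias_config()].
#' @param regions Option bounding boxes, see [preference_regions()].
#' @param seed Integer seed.
#' @return A list with `trials` (tibble `trial_id`, `decision_time`,
#'   `chosen`, `constraint`) and `samples` (tibble `trial_id`, `t`, `x`,
#'   `y`, `valid`).
#' @export
simulate_preference_trials <- function(n_trials, config = bias_config(),
                                       regions = preference_regions(),
                                       seed = 1) {
  set.seed(seed)
  dt <- 1 / config$sampling_rate_hz
  res <- purrr::map(seq_len(n_trials), function(i) {
    D <- max(0.5, rnorm(1, config$decision_time_mean_s,
                        config$decision_time_sd_s))
    chosen <- sample(c("left", "right"), 1L)
    other <- setdiff(c("left", "right"), chosen)
    times <- seq(dt, D, by = dt)
    ramp <- pmin(pmax((times - (D - config$ramp_s)) / config$ramp_s, 0), 1)
    p_chosen <- config$baseline +
      (config$final_prob - config$baseline) * ramp
    off <- runif(length(times)) < config$off_region_prob
    on_chosen <- runif(length(times)) < p_chosen
    side <- ifelse(off, "off", ifelse(on_chosen, chosen, other))
    xy <- t(vapply(side, function(s) {
      if (s == "off") {
        c(runif(1), runif(1, 0, 0.25))  # background above/below options
      } else {
        r <- regions[regions$side == s, ]
        c(runif(1, r$x0, r$x1), runif(1, r$y0, r$y1))
      }
    }, numeric(2)))
    list(
      trial = tibble::tibble(trial_id = sprintf("trial%04d", i),
                             decision_time = D, chosen = chosen,
                             constraint = config$presentation_constraint_s),
      samples = tibble::tibble(trial_id = sprintf("trial%04d", i),
                               t = times, x = xy[, 1], y = xy[, 2],
                               valid = TRUE)
    )
  })
  list(trials = purrr::map_dfr(res, "trial"),
       samples = purrr::map_dfr(res, "samples"))
}
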