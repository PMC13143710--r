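# Constrained Gaussian-HMM fitting and decoding

test_that("forward_backward matches the closed form for a single state", {
  m <- random_toy_model(1, seed = 101)
  set.seed(102)
  xy <- data.frame(x = rnorm(20, m$means[1, 1], 0.05),
                   y = rnorm(20, m$means[1, 2], 0.05))
  seq <- forward_backward(m, xy)
  expect_true(all(seq$posteriors == 1))
  ll_direct <- sum(vapply(seq_len(20), function(t) {
    oracle_ldmvn(as.numeric(xy[t, ]), m$means[1, ], m$covs[[1]])
  }, numeric(1)))
  expect_equal(seq$log_lik, ll_direct, tolerance = 1e-10)
  expect_equal(viterbi(m, xy), rep(1L, 20))
})

test_that("forward likelihood and Viterbi agree with path enumeration on toy instances", {
  set.seed(103)
  for (i in 1:25) {
    K <- sample(2:3, 1)
    T_len <- sample(3:8, 1)
    m <- random_toy_model(K, seed = 1000 + i)
    xy <- cbind(x = runif(T_len), y = runif(T_len))
    ll <- forward_backward(m, xy)$log_lik
    expect_equal(ll, oracle_hmm_loglik(m, xy), tolerance = 1e-8)
    vit <- viterbi(m, xy)
    orc <- oracle_hmm_viterbi(m, xy)
    # compare via path log-probability (unique optimum in these instances)
    expect_equal(vit, orc$path)
  }
})

test_that("posteriors equal the stationary weights for symmetric emissions and identical observations", {
  m <- random_toy_model(2, seed = 104)
  m$transition <- matrix(0.5, 2, 2)
  m$initial <- c(0.5, 0.5)
  m$means <- rbind(c(0.4, 0.5), c(0.6, 0.5))  # equidistant from (0.5, 0.5)
  m$covs <- list(diag(0.01, 2), diag(0.01, 2))
  xy <- matrix(0.5, nrow = 6, ncol = 2, dimnames = list(NULL, c("x", "y")))
  seq <- forward_backward(m, as.data.frame(xy))
  expect_true(all(abs(seq$posteriors - 0.5) < 1e-12))
  # tie-break: Viterbi settles on the lower state index
  expect_equal(viterbi(m, as.data.frame(xy)), rep(1L, 6))
})

test_that("fitting a single tight cluster recovers its centroid with a unit transition", {
  set.seed(105)
  obs <- data.frame(
    seq_id = rep(1:5, each = 40),
    x = rnorm(200, 0.45, 0.02), y = rnorm(200, 0.55, 0.02)
  )
  fit <- fit_emhmm(obs, K = 1, n_restarts = 2, seed = 5)
  expect_equal(as.numeric(fit$means), c(0.45, 0.55), tolerance = 0.01)
  expect_equal(fit$transition, matrix(1, 1, 1))
})

test_that("a known 3-state model is recovered from simulated episodes", {
  truth <- make_ground_truth_model(3, stickiness = 0.9, seed = 106)
  truth$means <- rbind(c(0.2, 0.2), c(0.8, 0.25), c(0.5, 0.8))
  cfg <- generative_config(sampling_rate_hz = 30, K_true = 3, seed = 106,
                           stickiness_explore = 0.9)
  set.seed(106)
  obs <- purrr::map_dfr(1:50, function(i) {
    ep <- simulate_episode(truth, tau_s = Inf, cfg, duration_s = 10)
    dplyr::mutate(ep$samples[ep$samples$valid, ], seq_id = i)
  })
  fit <- fit_emhmm(obs, K = 3, n_restarts = 5, seed = 7)
  match <- match_states(fit$means, truth$means)
  expect_lt(match$mean_error, 0.05)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(107)
  cfg <- generative_config(sampling_rate_hz = 30, K_true = 3, seed = 107)
  truth <- make_ground_truth_model(3, stickiness = 0.9, seed = 107)
  obs <- purrr::map_dfr(1:10, function(i) {
    ep <- simulate_episode(truth, tau_s = Inf, cfg, duration_s = 8)
    dplyr::mutate(ep$samples[ep$samples$valid, ], seq_id = i)
  })
  fit <- fit_emhmm(obs, K = 3, n_restarts = 3, seed = 3)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
})

test_that("localisation error decreases with episode count", {
  truth <- make_ground_truth_model(3, stickiness = 0.9, seed = 108)
  truth$means <- rbind(c(0.2, 0.2), c(0.8, 0.25), c(0.5, 0.8))
  cfg <- generative_config(sampling_rate_hz = 30, K_true = 3, seed = 108,
                           stickiness_explore = 0.9)
  err_for <- function(n_episodes) {
    set.seed(108)
    obs <- purrr::map_dfr(seq_len(n_episodes), function(i) {
      ep <- simulate_episode(truth, tau_s = Inf, cfg, duration_s = 8)
      dplyr::mutate(ep$samples[ep$samples$valid, ], seq_id = i)
    })
    fit <- fit_emhmm(obs, K = 3, n_restarts = 3, seed = 9)
    match_states(fit$means, truth$means)$mean_error
  }
  expect_lt(err_for(40), err_for(3))
})

test_that("constraint projection clamps areas into the band and is idempotent", {
  cc <- constraint_config()
  # a clearly feasible model: equal mid-band circular ROIs
  m <- make_ground_truth_model(6, constraints = cc, seed = 109)
  mid_sd <- sqrt(0.01 / (pi * qchisq(cc$area_mass, 2)))
  m$covs <- replicate(6, diag(mid_sd, 2)^2, simplify = FALSE)
  m2 <- project_constraints(m, cc)
  expect_false(attr(m2, "projected"))
  expect_identical(m2$covs, m$covs)
  # inflate one ROI far beyond the band, shrink another below it
  m$covs[[1]] <- diag(0.5, 2)
  m$covs[[2]] <- diag(1e-9, 2)
  m3 <- project_constraints(m, cc)
  areas <- vapply(m3$covs, roi_area, numeric(1), area_mass = cc$area_mass)
  expect_true(all(areas >= cc$area_min_frac - 1e-12))
  expect_true(all(areas <= cc$area_max_frac + 1e-12))
  # idempotent: a second application is a no-op
  m4 <- project_constraints(m3, cc)
  expect_false(attr(m4, "projected"))
  expect_identical(m4$covs, m3$covs)
  # randomly drawn ground-truth models also reach a fixed point in one call
  m5 <- project_constraints(make_ground_truth_model(8, constraints = cc,
                                                    seed = 119), cc)
  m6 <- project_constraints(m5, cc)
  expect_false(attr(m6, "projected"))
})

test_that("a degenerate K raises an informative error", {
  obs <- data.frame(x = rep(0.5, 30), y = rep(0.5, 30), seq_id = 1)
  expect_error(fit_emhmm(obs, K = 3, n_restarts = 1, seed = 1), "degenerate")
})

test_that("model serialisation round-trips exactly", {
  m <- make_ground_truth_model(5, seed = 110)
  m$log_lik <- -1234.56789012345
  path <- withr::local_tempfile(fileext = ".json")
  write_gaze_state_model(m, path)
  m2 <- read_gaze_state_model(path)
  expect_identical(m2$means, m$means)
  expect_identical(m2$covs, m$covs)
  expect_identical(m2$transition, m$transition)
  expect_identical(m2$initial, m$initial)
  expect_identical(m2$log_lik, m$log_lik)
})

test_that("state matching solves small assignment problems exactly", {
  set.seed(111)
  ref <- cbind(runif(5), runif(5))
  perm <- sample(5)
  est <- ref[perm, ] + matrix(rnorm(10, 0, 1e-3), 5, 2)
  match <- match_states(est, ref)
  expect_equal(match$perm, order(perm))
  expect_lt(match$mean_error, 0.01)
})

test_that("fitted states come re-indexed by descending stationary occupancy", {
  set.seed(112)
  obs <- data.frame(
    seq_id = rep(1:6, each = 60),
    x = c(rnorm(240, 0.3, 0.03), rnorm(120, 0.7, 0.03)),
    y = c(rnorm(240, 0.3, 0.03), rnorm(120, 0.7, 0.03))
  )
  fit <- fit_emhmm(obs, K = 2, n_restarts = 3, seed = 2)
  occ <- gazephase:::stationary_distribution(fit$transition)
  expect_true(occ[1] >= occ[2])
  # the dominant state is the one with twice the data
  expect_equal(as.numeric(fit$means[1, ]), c(0.3, 0.3), tolerance = 0.02)
})
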