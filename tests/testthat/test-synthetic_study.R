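# Synthetic-study generator

test_that("ground-truth models satisfy their construction contract", {
  m1 <- make_ground_truth_model(1, seed = 1)
  expect_equal(m1$transition, matrix(1, 1, 1))
  expect_equal(m1$K, 1L)

  m14 <- make_ground_truth_model(14, seed = 2)
  cc <- m14$constraints
  areas <- vapply(m14$covs, roi_area, numeric(1), area_mass = cc$area_mass)
  expect_true(all(areas >= cc$area_min_frac & areas <= cc$area_max_frac))
  expect_true(all(m14$means >= 0 & m14$means <= 1))
  expect_true(all(abs(rowSums(m14$transition) - 1) < 1e-12))
  expect_equal(sum(m14$initial), 1)

  # determinism
  expect_equal(make_ground_truth_model(14, seed = 2), m14)
})

test_that("degenerate transition regimes produce the expected switch rates", {
  cfg <- generative_config(sampling_rate_hz = 50, K_true = 4,
                           stickiness_converge = 1,
                           judgment_time_range = c(3, 6), seed = 5)
  m <- make_ground_truth_model(4, seed = 5)
  set.seed(5)
  ep <- simulate_episode(m, tau_s = 0, cfg, duration_s = 5)
  # convergence regime with stickiness 1: constant path after the first step
  expect_equal(switch_rate(ep$path[-1]), 0)
  expect_true(all(ep$path[-1] == ep$focus_state))

  cfg2 <- generative_config(sampling_rate_hz = 50, K_true = 2,
                            stickiness_explore = 0, seed = 6)
  m2 <- make_ground_truth_model(2, stickiness = 0, seed = 6)
  set.seed(6)
  ep2 <- simulate_episode(m2, tau_s = Inf, cfg2, duration_s = 5)
  expect_equal(switch_rate(ep2$path), 1)
})

test_that("earlier convergence onset lowers middle-window entropy (Monte Carlo sign check)", {
  cfg <- generative_config(sampling_rate_hz = 30, K_true = 5, seed = 8)
  m <- make_ground_truth_model(5, stickiness = 0.97, seed = 8)
  mean_h_mid <- function(tau, seed) {
    set.seed(seed)
    mean(vapply(1:40, function(i) {
      ep <- simulate_episode(m, tau_s = tau, cfg, duration_s = 13)
      d <- decode_episode(m, ep$samples[ep$samples$valid, ])
      mm <- episode_metrics(d$posteriors, d$viterbi_path,
                            ep$samples$t[ep$samples$valid])
      mean(mm$hnorm[mm$t_start >= 6 & mm$t_end <= 12])
    }, numeric(1)))
  }
  expect_lt(mean_h_mid(6, seed = 81), mean_h_mid(12, seed = 81))
})

test_that("the study-level bookkeeping matches the crossed design", {
  st <- tiny_study(seed = 9, n_participants = 5, n_artworks = 6)
  expect_equal(nrow(st$episodes), 30L)
  expect_equal(sum(st$truth$groups$group == "high"), 3L)
  expect_equal(sum(st$truth$groups$group == "low"), 3L)
  expect_true(all(st$episodes$rating %in% 1:10))
  # every episode has samples and a matching true path
  expect_setequal(
    unique(paste(st$samples$participant_id, st$samples$artwork_id)),
    paste(st$episodes$participant_id, st$episodes$artwork_id)
  )
  expect_equal(length(st$truth$paths), 30L)
})

test_that("the generator is deterministic under a seed and varies across seeds", {
  a <- tiny_study(seed = 10, n_participants = 2, n_artworks = 2, rate = 30)
  b <- tiny_study(seed = 10, n_participants = 2, n_artworks = 2, rate = 30)
  c <- tiny_study(seed = 11, n_participants = 2, n_artworks = 2, rate = 30)
  expect_identical(a$samples, b$samples)
  expect_identical(a$episodes, b$episodes)
  expect_false(isTRUE(all.equal(a$samples$x, c$samples$x)))
})

test_that("noise-free ratings separate the groups completely", {
  st <- simulate_study(generative_config(
    n_participants = 6, n_artworks = 6, sampling_rate_hz = 30, K_true = 4,
    rating_noise_sd = 0, seed = 12
  ))
  rt <- normalize_ratings(st$episodes[c("participant_id", "artwork_id",
                                        "rating")])
  means <- rt |>
    dplyr::group_by(artwork_id) |>
    dplyr::summarise(m = mean(rating_norm))
  hi <- means$m[means$artwork_id %in%
                  st$truth$groups$artwork_id[st$truth$groups$group == "high"]]
  lo <- means$m[means$artwork_id %in%
                  st$truth$groups$artwork_id[st$truth$groups$group == "low"]]
  expect_gt(min(hi), max(lo))
})

test_that("episode durations respect the truncation bounds and the configured mean", {
  st <- tiny_study(seed = 13, n_participants = 10, n_artworks = 6, rate = 30)
  jt <- st$episodes$judgment_time
  cfg <- st$config
  expect_true(all(jt >= cfg$judgment_time_range[1]))
  expect_true(all(jt <= cfg$judgment_time_range[2]))
  # low-group episodes are further truncated at their tau
  low_arts <- st$truth$groups$artwork_id[st$truth$groups$group == "low"]
  expect_true(all(jt[st$episodes$artwork_id %in% low_arts] >= cfg$tau_low))
  se <- sd(jt) / sqrt(length(jt))
  expect_lt(abs(mean(jt) - cfg$judgment_time_mean_s), 3 * se + 0.3)
})

test_that("true paths and emitted samples are mutually consistent", {
  st <- tiny_study(seed = 14, n_participants = 6, n_artworks = 2, rate = 60)
  art <- "art01"
  m <- st$truth$models[[art]]
  eps <- st$episodes[st$episodes$artwork_id == art, ]
  # pool samples by true state across episodes; centroids approach ROI means
  pooled <- purrr::map_dfr(seq_len(nrow(eps)), function(i) {
    key <- paste(eps$participant_id[i], art, sep = ":")
    s <- st$samples[st$samples$participant_id == eps$participant_id[i] &
                      st$samples$artwork_id == art, ]
    tibble::tibble(state = st$truth$paths[[key]], x = s$x, y = s$y)
  })
  cent <- pooled |>
    dplyr::group_by(state) |>
    dplyr::summarise(x = mean(x), y = mean(y), n = dplyr::n()) |>
    dplyr::filter(n > 300)
  err <- sqrt((cent$x - m$means[cent$state, 1])^2 +
                (cent$y - m$means[cent$state, 2])^2)
  expect_true(all(err < 0.05))
})

test_that("generator configurations round-trip through YAML", {
  cfg <- generative_config(n_participants = 9, tau_high = 5.5,
                           rating_noise_sd = 0.11, shared_model = TRUE,
                           seed = 99)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_generative_config(cfg, f)
  cfg2 <- read_generative_config(f)
  expect_equal(cfg2, cfg)
})

test_that("preference trials realise flat and ramped gaze-bias profiles", {
  # all gaze on the chosen option
  pr <- simulate_preference_trials(
    20, bias_config(baseline = 1, final_prob = 1, off_region_prob = 0),
    seed = 15
  )
  curve <- choice_gaze_probability(pr$samples, pr$trials)
  expect_true(all(curve$p_chosen == 1))

  # null ramp: flat at 0.5 within Monte-Carlo error
  pr2 <- simulate_preference_trials(
    300, bias_config(baseline = 0.5, final_prob = 0.5), seed = 16
  )
  curve2 <- choice_gaze_probability(pr2$samples, pr2$trials)
  expect_true(all(abs(curve2$p_chosen - 0.5) < 0.05))

  # ramp from 0.5 to 0.9: final bin exceeds first bin
  pr3 <- simulate_preference_trials(
    300, bias_config(baseline = 0.5, final_prob = 0.9), seed = 17
  )
  curve3 <- choice_gaze_probability(pr3$samples, pr3$trials)
  expect_gt(attr(curve3, "final_bin"), curve3$p_chosen[1])
})
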