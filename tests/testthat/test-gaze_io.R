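# Gaze table I/O, coordinate normalisation, cleaning, fixation detection

write_toy_gaze <- function(path, df, delim = ",") {
  readr::write_delim(df, path, delim = delim, progress = FALSE)
}

test_that("a two-row toy file parses into one episode with rebased times", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_toy_gaze(f, data.frame(
    participant_id = "p1", artwork_id = "a1", t = c(10.0, 10.1),
    x = c(0.2, 0.4), y = c(0.3, 0.5), valid = TRUE
  ))
  g <- read_gaze_table(f)
  expect_equal(nrow(g), 2L)
  expect_equal(g$t, c(0, 0.1))
  expect_equal(g$x, c(0.2, 0.4))
})

test_that("row order in the file is immaterial", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    participant_id = rep(c("p1", "p2"), each = 5),
    artwork_id = "a1", t = rep(seq(0, 0.4, 0.1), 2),
    x = runif(10), y = runif(10), valid = TRUE
  )
  write_toy_gaze(f1, df)
  write_toy_gaze(f2, df[sample(nrow(df)), ])
  expect_equal(read_gaze_table(f1), read_gaze_table(f2))
})

test_that("missing columns and duplicated timestamps raise informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_toy_gaze(f, data.frame(participant_id = "p1", artwork_id = "a1",
                               t = 0, x = 0.5))
  expect_error(read_gaze_table(f), "mandatory column.*y")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_toy_gaze(f2, data.frame(
    participant_id = "p1", artwork_id = "a1", t = c(0, 0.1, 0.1),
    x = 0.5, y = 0.5, valid = TRUE
  ))
  expect_error(read_gaze_table(f2), "non-monotone|duplicated")
})

test_that("dialects with other column names, delimiters and ms timestamps work", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_delim(
    data.frame(subj = "s1", img = "i1", time_ms = c(0, 100, 200),
               gx = c(1, 2, 3), gy = c(4, 5, 6)),
    f, delim = "\t", progress = FALSE
  )
  d <- gaze_dialect(participant = "subj", artwork = "img", t = "time_ms",
                    x = "gx", y = "gy", valid = NULL, delim = "\t",
                    t_unit = "ms")
  g <- read_gaze_table(f, d)
  expect_equal(g$t, c(0, 0.1, 0.2))
  expect_true(all(g$valid))
})

test_that("write-then-read round-trips a generated study's gaze table exactly", {
  st <- tiny_study(seed = 3, n_participants = 2, n_artworks = 2, rate = 30)
  f <- withr::local_tempfile(fileext = ".csv")
  write_gaze_table(st$samples, f)
  g <- read_gaze_table(f)
  expect_equal(g, st$samples)
})

test_that("study write/read round-trips all observable tables", {
  st <- tiny_study(seed = 4, n_participants = 2, n_artworks = 2, rate = 30)
  d <- withr::local_tempdir()
  write_study(st, d)
  st2 <- read_study(d)
  expect_equal(st2$samples, st$samples)
  expect_equal(st2$episodes, st$episodes)
  expect_equal(st2$stimuli, st$stimuli)
  expect_equal(st2$depth_points, st$depth_points)
  expect_equal(st2$truth$models[["art01"]]$means, st$truth$models[["art01"]]$means)
})

test_that("coordinate normalisation divides by stimulus dimensions and flags out-of-bounds", {
  s <- tibble::tibble(
    participant_id = "p1", artwork_id = "a1", t = c(0, 0.1, 0.2),
    x = c(960, 0, 2000), y = c(540, 0, 540), valid = TRUE
  )
  stim <- tibble::tibble(artwork_id = "a1", width_px = 1920, height_px = 1080)
  n <- normalize_coordinates(s, stim)
  expect_equal(n$x, c(0.5, 0, 2000 / 1920))
  expect_equal(n$y, c(0.5, 0, 0.5))
  expect_equal(n$valid, c(TRUE, TRUE, FALSE))  # retained, flagged invalid
  expect_equal(nrow(n), 3L)
  expect_error(normalize_coordinates(s, dplyr::mutate(stim, width_px = 0)),
               "positive")
})

test_that("normalisation is idempotent under unit dimensions", {
  st <- tiny_study(seed = 5, n_participants = 1, n_artworks = 2, rate = 30)
  unit <- tibble::tibble(artwork_id = unique(st$samples$artwork_id),
                         width_px = 1, height_px = 1)
  n <- normalize_coordinates(st$samples, unit)
  keep <- n$valid
  expect_equal(n$x[keep], st$samples$x[keep])
  expect_equal(n$y[keep], st$samples$y[keep])
})

test_that("short invalid gaps are interpolated, long ones are not, quality flags episodes", {
  mk <- function(valid) tibble::tibble(
    participant_id = "p1", artwork_id = "a1",
    t = seq(0, by = 1 / 300, length.out = length(valid)),
    x = seq(0.4, 0.6, length.out = length(valid)),
    y = seq(0.4, 0.6, length.out = length(valid)),
    valid = valid
  )
  # all valid: identity
  ep <- mk(rep(TRUE, 10))
  expect_equal(clean_samples(ep)[names(ep)], ep)

  # single invalid sample between (0.4, 0.4) and (0.6, 0.6)
  ep2 <- tibble::tibble(
    participant_id = "p1", artwork_id = "a1", t = c(0, 0.01, 0.02),
    x = c(0.4, 99, 0.6), y = c(0.4, 99, 0.6), valid = c(TRUE, FALSE, TRUE)
  )
  cl2 <- clean_samples(ep2)
  expect_equal(cl2$x[2], 0.5)
  expect_equal(cl2$y[2], 0.5)
  expect_true(cl2$valid[2])
  expect_false(cl2$episode_rejected[1])

  # a 2-s invalid run stays invalid under the 75 ms default
  v <- rep(TRUE, 900)
  v[151:750] <- FALSE
  cl3 <- clean_samples(mk(v))
  expect_false(any(cl3$valid[151:750]))
  expect_true(all(cl3$episode_rejected))  # valid fraction 1/3 < 0.5
})

test_that("I-DT finds one fixation for a stationary second of gaze", {
  s <- tibble::tibble(
    participant_id = "p1", artwork_id = "a1",
    t = seq(0, by = 1 / 300, length.out = 300),
    x = 0.5, y = 0.5, valid = TRUE
  )
  fx <- detect_fixations(s)
  expect_equal(nrow(fx), 1L)
  expect_equal(fx$duration, 1, tolerance = 1e-9)
  expect_equal(fx$x, 0.5)
  expect_equal(fx$onset, 0)
})

test_that("two stationary clusters separated by a saccade give two fixations", {
  set.seed(41)
  t <- seq(0, by = 1 / 300, length.out = 240)
  x <- c(rnorm(120, 0.3, 0.001), rnorm(120, 0.7, 0.001))
  y <- c(rnorm(120, 0.3, 0.001), rnorm(120, 0.7, 0.001))
  s <- tibble::tibble(participant_id = "p1", artwork_id = "a1",
                      t = t, x = x, y = y, valid = TRUE)
  fx <- detect_fixations(s)
  expect_equal(nrow(fx), 2L)
  expect_equal(fx$x, c(0.3, 0.7), tolerance = 0.005)
  orc <- oracle_idt(t, x, y, 0.018, 0.1)
  expect_equal(nrow(fx), nrow(orc))
  expect_equal(fx$onset, orc$onset)
  expect_equal(fx$duration, orc$duration)
})

test_that("continuous fast drift yields zero fixations", {
  t <- seq(0, by = 1 / 300, length.out = 300)
  s <- tibble::tibble(participant_id = "p1", artwork_id = "a1", t = t,
                      x = seq(0, 0.9, length.out = 300),
                      y = seq(0, 0.9, length.out = 300), valid = TRUE)
  expect_equal(nrow(detect_fixations(s)), 0L)
})

test_that("I-DT agrees with the brute-force oracle on random walks and bounds total time", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(200:900, 1)
    t <- seq(0, by = 1 / 300, length.out = n)
    x <- cumsum(rnorm(n, 0, 0.004)) + 0.5
    y <- cumsum(rnorm(n, 0, 0.004)) + 0.5
    s <- tibble::tibble(participant_id = "p1", artwork_id = "a1",
                        t = t, x = x, y = y, valid = TRUE)
    fx <- detect_fixations(s)
    orc <- oracle_idt(t, x, y, 0.018, 0.1)
    expect_equal(nrow(fx), nrow(orc))
    if (nrow(fx) > 0) {
      expect_equal(fx$onset, orc$onset)
      expect_equal(fx$x, orc$x)
      # ordered, non-overlapping, and total time within the episode span
      expect_true(all(diff(fx$onset) > 0))
      expect_true(all(fx$onset[-1] >= (fx$onset + fx$duration)[-nrow(fx)] - 1e-9))
      expect_lte(sum(fx$duration), max(t) - min(t) + 1 / 300 + 1e-9)
    }
  }
})
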