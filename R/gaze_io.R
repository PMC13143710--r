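# Reading, validation, cleaning and coordinate normalisation of raw gaze
# tables, ratings and stimulus metadata.
#
# Conventions (declared once, used everywhere): origin top-left, y increases
# downward, normalised coordinates half-open [0,1) x [0,1); timestamps in
# seconds with 0 = stimulus onset; one episode = one participant x artwork
# viewing.

#' Column dialect of a delimited gaze table
#'
#' Describes how an on-disk gaze table maps onto the pipeline's data model:
#' column names, delimiter and timestamp unit. The same dialect is used by
#' the reader and the writer, so a write-then-read round trip reproduces
#' every field.
#'
#' @param participant,artwork,t,x,y,valid Column names in the file. Set
#'   `valid = NULL` if the file has no validity column (all samples are
#'   then taken as valid).
#' @param delim Field delimiter (default `","`).
#' @param t_unit Timestamp unit in the file: `"s"` or `"ms"`.
#' @return A list of class `gaze_dialect`.
#' @export
gaze_dialect <- function(participant = "participant_id", artwork = "artwork_id",
                         t = "t", x = "x", y = "y", valid = "valid",
                         delim = ",", t_unit = c("s", "ms")) {
  structure(list(participant = participant, artwork = artwork, t = t,
                 x = x, y = y, valid = valid, delim = delim,
                 t_unit = match.arg(t_unit)),
            class = "gaze_dialect")
}

#' Read a delimited gaze table into tidy viewing-episode samples
#'
#' Parses a delimited text file of raw gaze samples, maps its columns
#' through `dialect`, groups rows into episodes (participant x artwork),
#' sorts samples by time within each episode and rebases timestamps so that
#' 0 is the first sample of the episode (stimulus onset). Row order in the
#' file is immaterial.
#'
#' @param path Path to the delimited file.
#' @param dialect A [gaze_dialect()] describing the file's columns.
#' @return A tibble with columns `participant_id`, `artwork_id`, `t`
#'   (seconds from onset), `x`, `y`, `valid`.
#' @section Errors: a missing mandatory column raises a configuration error
#'   naming the column; duplicated timestamps within an episode raise a
#'   data error reporting the offending row.
#' @export
read_gaze_table <- function(path, dialect = gaze_dialect()) {
  raw <- readr::read_delim(path, delim = dialect$delim,
                           show_col_types = FALSE, progress = FALSE)
  need <- c(participant = dialect$participant, artwork = dialect$artwork,
            t = dialect$t, x = dialect$x, y = dialect$y)
  missing_cols <- need[!need %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("gaze table ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    participant_id = as.character(raw[[dialect$participant]]),
    artwork_id = as.character(raw[[dialect$artwork]]),
    t = as.numeric(raw[[dialect$t]]),
    x = as.numeric(raw[[dialect$x]]),
    y = as.numeric(raw[[dialect$y]]),
    valid = if (!is.null(dialect$valid) && dialect$valid %in% names(raw)) {
      as.logical(raw[[dialect$valid]])
    } else TRUE,
    .row = seq_len(nrow(raw))
  )
  if (dialect$t_unit == "ms") out$t <- out$t / 1000
  out <- dplyr::arrange(out, .data$participant_id, .data$artwork_id, .data$t)
  dup <- out |>
    dplyr::group_by(.data$participant_id, .data$artwork_id) |>
    dplyr::filter(duplicated(.data$t)) |>
    dplyr::ungroup()
  if (nrow(dup) > 0) {
    stop("non-monotone timestamps: duplicated time within episode ",
         dup$participant_id[1], " x ", dup$artwork_id[1],
         " at file row ", dup$.row[1], call. = FALSE)
  }
  out |>
    dplyr::group_by(.data$participant_id, .data$artwork_id) |>
    dplyr::mutate(t = .data$t - min(.data$t)) |>
    dplyr::ungroup() |>
    dplyr::select(-".row")
}

#' Write tidy gaze samples back to a delimited table
#'
#' Emits the same dialect [read_gaze_table()] reads. Doubles are written at
#' full precision, so `read_gaze_table(write_gaze_table(x))` reproduces
#' `x` exactly.
#'
#' @param samples Tidy samples tibble (as returned by [read_gaze_table()]).
#' @param path Output file path.
#' @inheritParams read_gaze_table
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(samples, path, dialect = gaze_dialect()) {
  out <- tibble::tibble(samples$participant_id, samples$artwork_id,
                        if (dialect$t_unit == "ms") samples$t * 1000 else samples$t,
                        samples$x, samples$y, samples$valid)
  names(out) <- c(dialect$participant, dialect$artwork, dialect$t,
                  dialect$x, dialect$y,
                  if (is.null(dialect$valid)) "valid" else dialect$valid)
  readr::write_delim(out, path, delim = dialect$delim, progress = FALSE)
  invisible(path)
}

#' Read a ratings table
#'
#' @param path CSV with columns `participant_id`, `artwork_id`, `rating`
#'   (integers 1-10).
#' @return A tibble with those columns.
#' @export
read_ratings <- function(path) {
  r <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "artwork_id", "rating")
  if (!all(need %in% names(r))) {
    stop("ratings table lacks column(s): ",
         paste(setdiff(need, names(r)), collapse = ", "), call. = FALSE)
  }
  r <- dplyr::mutate(r, participant_id = as.character(.data$participant_id),
                     artwork_id = as.character(.data$artwork_id),
                     rating = as.integer(.data$rating))
  if (any(r$rating < 1L | r$rating > 10L | is.na(r$rating))) {
    stop("ratings must be integers in 1..10", call. = FALSE)
  }
  r[need]
}

#' Read stimulus metadata
#'
#' @param path CSV with columns `artwork_id`, `width_px`, `height_px`.
#' @return A tibble with those columns.
#' @export
read_stimuli <- function(path) {
  s <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("artwork_id", "width_px", "height_px")
  if (!all(need %in% names(s))) {
    stop("stimulus table lacks column(s): ",
         paste(setdiff(need, names(s)), collapse = ", "), call. = FALSE)
  }
  if (any(s$width_px <= 0 | s$height_px <= 0)) {
    stop("stimulus dimensions must be positive", call. = FALSE)
  }
  dplyr::mutate(s[need], artwork_id = as.character(.data$artwork_id))
}

#' Read depth-point annotations
#'
#' @param path CSV with columns `artwork_id`, `x`, `y` (normalised
#'   coordinates of depth-related points).
#' @return A tibble with those columns.
#' @export
read_depth_points <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("artwork_id", "x", "y")
  if (!all(need %in% names(d))) {
    stop("depth-point table lacks column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  if (any(d$x < 0 | d$x > 1 | d$y < 0 | d$y > 1)) {
    stop("depth points must lie in the unit square", call. = FALSE)
  }
  dplyr::mutate(d[need], artwork_id = as.character(.data$artwork_id))
}

#' Normalise pixel gaze coordinates to the unit square
#'
#' Divides raw pixel coordinates by the stimulus dimensions so that gaze
#' positions live in `[0, 1) x [0, 1)` regardless of image size. Samples
#' falling outside the image are flagged invalid but retained.
#'
#' @param samples Tidy samples tibble with pixel `x`, `y`.
#' @param stimuli Stimulus metadata tibble (`artwork_id`, `width_px`,
#'   `height_px`); every artwork in `samples` must appear.
#' @return The samples tibble with normalised `x`, `y` and updated `valid`.
#' @export
normalize_coordinates <- function(samples, stimuli) {
  if (any(stimuli$width_px <= 0 | stimuli$height_px <= 0)) {
    stop("stimulus dimensions must be positive", call. = FALSE)
  }
  miss <- setdiff(unique(samples$artwork_id), stimuli$artwork_id)
  if (length(miss) > 0) {
    stop("no stimulus metadata for artwork(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  samples |>
    dplyr::left_join(stimuli[c("artwork_id", "width_px", "height_px")],
                     by = "artwork_id") |>
    dplyr::mutate(
      x = .data$x / .data$width_px,
      y = .data$y / .data$height_px,
      valid = .data$valid & is.finite(.data$x) & is.finite(.data$y) &
        .data$x >= 0 & .data$x < 1 & .data$y >= 0 & .data$y < 1
    ) |>
    dplyr::select(-"width_px", -"height_px")
}

#' Interpolate short invalid gaps and flag low-quality episodes
#'
#' Runs of invalid samples short enough to be blinks or tracking dropouts
#' (flanked-valid span at most `max_gap_s`) are filled by linear
#' interpolation between the flanking valid samples and marked valid;
#' longer runs, and runs touching the episode boundary, are left invalid.
#' Episodes whose valid fraction after interpolation falls below
#' `min_valid_fraction` are flagged rejected (column `episode_rejected`),
#' not dropped.
#'
#' @param samples Tidy samples tibble with a `valid` column.
#' @param max_gap_s Maximum interpolable gap in seconds (default 0.075,
#'   below typical blink duration).
#' @param min_valid_fraction Minimum post-interpolation valid fraction for
#'   an episode to be retained (default 0.5).
#' @return The samples tibble with interpolated `x`, `y`, updated `valid`,
#'   and a logical `episode_rejected` column (constant within episode).
#' @export
clean_samples <- function(samples, max_gap_s = 0.075,
                          min_valid_fraction = 0.5) {
  samples |>
    dplyr::group_by(.data$participant_id, .data$artwork_id) |>
    dplyr::group_modify(~ clean_one_episode(.x, max_gap_s,
                                            min_valid_fraction)) |>
    dplyr::ungroup()
}

clean_one_episode <- function(ep, max_gap_s, min_valid_fraction) {
  n <- nrow(ep)
  v <- ep$valid
  if (any(!v) && any(v)) {
    runs <- rle(v)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(!runs$values)) {
      i0 <- starts[r]; i1 <- ends[r]
      if (i0 == 1L || i1 == n) next          # boundary run: not interpolable
      span <- ep$t[i1 + 1L] - ep$t[i0 - 1L]  # flanking valid samples
      if (span <= max_gap_s) {
        w <- (ep$t[i0:i1] - ep$t[i0 - 1L]) / span
        ep$x[i0:i1] <- ep$x[i0 - 1L] + w * (ep$x[i1 + 1L] - ep$x[i0 - 1L])
        ep$y[i0:i1] <- ep$y[i0 - 1L] + w * (ep$y[i1 + 1L] - ep$y[i0 - 1L])
        v[i0:i1] <- TRUE
      }
    }
  }
  ep$valid <- v
  ep$episode_rejected <- mean(v) < min_valid_fraction
  ep
}

#' Detect fixations by dispersion thresholding (I-DT)
#'
#' Scans each episode's valid samples for maximal time windows whose
#' spatial dispersion (`(max x - min x) + (max y - min y)`) stays at or
#' below `dispersion` and whose duration is at least `min_duration`. Each
#' such window becomes one fixation with onset at its first sample,
#' duration spanning the window plus one sampling interval, and centroid
#' at the mean of its member samples.
#'
#' The default dispersion of 0.018 normalised units corresponds to about
#' one degree of visual angle for a 23-inch, 1920-pixel-wide display viewed
#' at 52 cm.
#'
#' @param samples Tidy samples tibble in normalised coordinates.
#' @param dispersion Dispersion threshold in normalised units.
#' @param min_duration Minimum fixation duration in seconds.
#' @return A tibble of fixations: `participant_id`, `artwork_id`, `onset`,
#'   `duration`, `x`, `y`, ordered and non-overlapping within episodes.
#' @export
detect_fixations <- function(samples, dispersion = 0.018,
                             min_duration = 0.1) {
  samples |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$participant_id, .data$artwork_id) |>
    dplyr::group_modify(~ idt_one_episode(.x, dispersion, min_duration)) |>
    dplyr::ungroup()
}

idt_one_episode <- function(ep, dispersion, min_duration) {
  n <- nrow(ep)
  empty <- tibble::tibble(onset = numeric(), duration = numeric(),
                          x = numeric(), y = numeric())
  if (n < 2L) return(empty)
  t <- ep$t; x <- ep$x; y <- ep$y
  dt <- median(diff(t))
  res <- list()
  i <- 1L
  while (i <= n) {
    # smallest window [i, j] reaching min_duration
    j <- i
    while (j <= n && t[j] - t[i] < min_duration - 1e-12) j <- j + 1L
    if (j > n) break
    disp <- (max(x[i:j]) - min(x[i:j])) + (max(y[i:j]) - min(y[i:j]))
    if (disp <= dispersion) {
      while (j < n) {
        disp2 <- (max(x[i:(j + 1L)]) - min(x[i:(j + 1L)])) +
          (max(y[i:(j + 1L)]) - min(y[i:(j + 1L)]))
        if (disp2 > dispersion) break
        j <- j + 1L
      }
      res[[length(res) + 1L]] <- tibble::tibble(
        onset = t[i], duration = t[j] - t[i] + dt,
        x = mean(x[i:j]), y = mean(y[i:j])
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(res) == 0L) empty else dplyr::bind_rows(res)
}
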