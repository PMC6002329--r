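#' Parse a frame-schedule string
#'
#' A frame schedule describes how a dynamic PET acquisition is binned into
#' contiguous time frames before reconstruction. Schedules are written as
#' comma-separated `<count>x<duration_s>` blocks, e.g. `"12x5,8x30"` for
#' twelve 5-s frames followed by eight 30-s frames. Frames are contiguous
#' and start at 0 s; by convention each frame covers the half-open interval
#' `[start_s, start_s + duration_s)` and is time-stamped at its midpoint.
#'
#' @param spec Schedule string, `<count>x<seconds>` blocks separated by
#'   commas (dashes are also accepted as separators).
#' @param id Label for the schedule; defaults to the normalized spec string.
#' @param total_s Required total duration in seconds, or `NULL` to skip the
#'   check. Defaults to 300 s (a 5-min dynamic study).
#' @return A `frame_schedule`: a tibble with one row per frame and columns
#'   `frame`, `start_s`, `duration_s`, `mid_s`, carrying the `id` as an
#'   attribute.
#' @examples
#' parse_schedule("12x5,8x30")
#' parse_schedule("1x300")
#' @export
parse_schedule <- function(spec, id = NULL, total_s = 300) {
  stopifnot(is.character(spec), length(spec) == 1L, !is.na(spec))
  blocks <- strsplit(gsub("-", ",", spec, fixed = TRUE), ",", fixed = TRUE)[[1]]
  blocks <- trimws(blocks)
  if (length(blocks) == 0L) stop("empty schedule string", call. = FALSE)
  counts <- integer(length(blocks))
  durs <- numeric(length(blocks))
  for (i in seq_along(blocks)) {
    m <- regmatches(blocks[i],
                    regexec("^([0-9]+)x([0-9]+(?:\\.[0-9]+)?)$", blocks[i]))[[1]]
    if (length(m) != 3L) {
      stop("malformed schedule block '", blocks[i], "' in '", spec,
           "' (expected <count>x<seconds>)", call. = FALSE)
    }
    counts[i] <- as.integer(m[2])
    durs[i] <- as.numeric(m[3])
    if (counts[i] <= 0L || durs[i] <= 0) {
      stop("schedule block '", blocks[i], "' has zero/negative count or duration",
           call. = FALSE)
    }
  }
  duration_s <- rep(durs, counts)
  start_s <- cumsum(c(0, duration_s))[seq_along(duration_s)]
  if (!is.null(total_s)) {
    tot <- sum(duration_s)
    if (abs(tot - total_s) > 1e-9) {
      stop("schedule '", spec, "' totals ", tot, " s, expected ", total_s, " s",
           call. = FALSE)
    }
  }
  if (is.null(id)) id <- paste(sprintf("%dx%g", counts, durs), collapse = ",")
  new_frame_schedule(start_s, duration_s, id)
}

new_frame_schedule <- function(start_s, duration_s, id) {
  out <- tibble::tibble(
    frame = seq_along(start_s),
    start_s = start_s,
    duration_s = duration_s,
    mid_s = start_s + duration_s / 2
  )
  attr(out, "id") <- id
  class(out) <- c("frame_schedule", class(out))
  out
}

#' Schedule label
#'
#' @param schedule A `frame_schedule`.
#' @return The schedule's id string.
#' @export
schedule_id <- function(schedule) {
  id <- attr(schedule, "id", exact = TRUE)
  if (is.null(id)) format_schedule(schedule) else id
}

#' Format a frame schedule back to its string form
#'
#' Run-length encodes the frame durations, so `parse_schedule()` followed by
#' `format_schedule()` is the identity on canonical schedule strings.
#'
#' @param schedule A `frame_schedule`.
#' @return A schedule string such as `"12x5,8x30"`.
#' @export
format_schedule <- function(schedule) {
  r <- rle(schedule$duration_s)
  paste(sprintf("%dx%g", r$lengths, r$values), collapse = ",")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat("<frame_schedule> ", schedule_id(x), " (", nrow(x), " frames, ",
      sum(x$duration_s), " s)\n", sep = "")
  NextMethod()
}

#' Candidate blood-phase frame schedules
#'
#' The seven 5-min schedules compared for sampling the early (blood) phase
#' of a dynamic FCH study: `5x60`, `10x30`, `15x15,1x75`, `6x10,8x30`,
#' `12x5,8x30`, `10x5,4x10,3x20,5x30` and `8x3,8x12,6x30`.
#'
#' @return A list of seven `frame_schedule` objects, each totalling 300 s.
#' @export
blood_phase_schedules <- function() {
  specs <- c(
    "5x60", "10x30", "15x15,1x75", "6x10,8x30", "12x5,8x30",
    "10x5,4x10,3x20,5x30", "8x3,8x12,6x30"
  )
  lapply(specs, parse_schedule)
}

#' Candidate tissue-phase frame schedules
#'
#' Five 5-min schedules sharing the identical `12x5` blood phase but binning
#' the late (tissue) phase differently: `12x5` followed by `16x15`, `8x30`,
#' `4x60`, `2x120` or `1x240`.
#'
#' @return A list of five `frame_schedule` objects, each totalling 300 s.
#' @export
tissue_phase_schedules <- function() {
  specs <- c(
    "12x5,16x15", "12x5,8x30", "12x5,4x60", "12x5,2x120", "12x5,1x240"
  )
  lapply(specs, parse_schedule)
}

#' Rebin a fine-grid curve into schedule frames
#'
#' Each frame value is the time-average of the fine-grid samples falling in
#' the half-open frame interval `[start_s, start_s + duration_s)`. This
#' emulates binning list-mode data into frames. The returned curve is
#' time-stamped at frame midpoints and keeps the frame geometry.
#'
#' @param curve A sampled curve: data frame with columns `t_s` (uniform fine
#'   grid, seconds) and `value` (kBq/mL).
#' @param schedule A `frame_schedule`.
#' @return A tibble with one row per frame: `t_s` (frame midpoint), `value`
#'   (frame average), `start_s`, `duration_s`.
#' @export
rebin_curve <- function(curve, schedule) {
  stopifnot(all(c("t_s", "value") %in% names(curve)))
  total <- sum(schedule$duration_s)
  h <- grid_step(curve$t_s)
  if (max(curve$t_s) + h < total - 1e-9) {
    stop("curve (", max(curve$t_s), " s) is shorter than schedule (",
         total, " s)", call. = FALSE)
  }
  idx <- frame_index(curve$t_s, schedule)
  keep <- !is.na(idx)
  means <- as.numeric(
    rowsum(curve$value[keep], idx[keep], reorder = TRUE) /
      tabulate(idx[keep], nbins = nrow(schedule))
  )
  tibble::tibble(
    t_s = schedule$mid_s,
    value = means,
    start_s = schedule$start_s,
    duration_s = schedule$duration_s
  )
}

# Map fine-grid times to frame numbers (NA outside the schedule support).
frame_index <- function(t_s, schedule) {
  total <- sum(schedule$duration_s)
  idx <- findInterval(t_s + 1e-9, c(schedule$start_s, total))
  idx[t_s < -1e-9 | t_s >= total - 1e-9] <- NA_integer_
  idx
}

grid_step <- function(t_s) {
  if (length(t_s) < 2L) stop("grid needs at least two points", call. = FALSE)
  d <- diff(t_s)
  if (max(d) - min(d) > 1e-6 * max(d)) {
    stop("time grid is not uniform", call. = FALSE)
  }
  mean(d)
}

#' Export a schedule as a two-column data frame
#'
#' @param schedule A `frame_schedule`.
#' @return A tibble with columns `start_s`, `duration_s` (one row per frame),
#'   suitable for writing as CSV.
#' @export
schedule_table <- function(schedule) {
  tibble::tibble(start_s = schedule$start_s, duration_s = schedule$duration_s)
}
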