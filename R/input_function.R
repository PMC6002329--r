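#' Parameters of the synthetic arterial input function
#'
#' A parametric stand-in for an image-derived input function (IDIF): after a
#' transport delay the bolus rises linearly to its peak, then washes out as a
#' mixture of three exponentials whose slowest component models tracer
#' recirculation. Defaults are tuned to the shape of an arterial
#' fluoromethylcholine bolus: peak roughly 30 s after arrival and a 5-min
#' tail at 5-10% of the peak.
#'
#' @param delay_s Bolus arrival delay after scan start (s), `>= 0`.
#' @param amplitude Peak activity concentration (kBq/mL), `> 0`.
#' @param rise_s Duration of the linear rise from arrival to peak (s).
#' @param decay_rates Washout rates of the three exponential components
#'   (s^-1), strictly positive and strictly decreasing (fast washout,
#'   intermediate clearance, slow recirculation).
#' @param decay_weights Non-negative mixture weights of the components;
#'   normalized to sum to 1.
#' @return A `bolus_params` list.
#' @export
bolus_params <- function(delay_s = 5, amplitude = 60, rise_s = 30,
                         decay_rates = c(0.08, 0.015, 8e-4),
                         decay_weights = c(0.70, 0.22, 0.08)) {
  if (delay_s < 0) stop("delay_s must be >= 0", call. = FALSE)
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (rise_s <= 0) stop("rise_s must be > 0", call. = FALSE)
  if (length(decay_rates) != length(decay_weights)) {
    stop("decay_rates and decay_weights must have equal length", call. = FALSE)
  }
  if (any(decay_rates <= 0)) stop("decay rates must be > 0", call. = FALSE)
  if (any(diff(decay_rates) >= 0)) {
    stop("decay rates must be strictly decreasing", call. = FALSE)
  }
  if (any(decay_weights < 0) || sum(decay_weights) <= 0) {
    stop("decay weights must be non-negative with positive sum", call. = FALSE)
  }
  structure(
    list(delay_s = delay_s, amplitude = amplitude, rise_s = rise_s,
         decay_rates = decay_rates,
         decay_weights = decay_weights / sum(decay_weights)),
    class = "bolus_params"
  )
}

#' Synthetic image-derived input function
#'
#' Evaluates the parametric arterial bolus of [bolus_params()] on a time
#' grid: zero before arrival, linear rise to the peak, multi-exponential
#' washout with a slow recirculation tail afterwards.
#'
#' @param params A `bolus_params` object.
#' @param t_s Time grid (s), strictly increasing. Defaults to a 0.1-s grid
#'   over 0-300 s.
#' @return A tibble with columns `t_s` and `value` (kBq/mL).
#' @examples
#' idif <- synthetic_idif()
#' idif$t_s[which.max(idif$value)] # peak within the first minute
#' @export
synthetic_idif <- function(params = bolus_params(),
                           t_s = seq(0, 300, by = 0.1)) {
  stopifnot(inherits(params, "bolus_params"))
  u <- t_s - params$delay_s
  v <- numeric(length(t_s))
  rising <- u > 0 & u < params$rise_s
  v[rising] <- params$amplitude * u[rising] / params$rise_s
  post <- u >= params$rise_s
  if (any(post)) {
    w <- u[post] - params$rise_s
    decay <- vapply(
      seq_along(params$decay_rates),
      function(i) params$decay_weights[i] * exp(-params$decay_rates[i] * w),
      numeric(length(w))
    )
    v[post] <- params$amplitude * rowSums(matrix(decay, nrow = length(w)))
  }
  tibble::tibble(t_s = as.numeric(t_s), value = v)
}

#' Cohort-mean input function on a 1-s grid
#'
#' Averages arterial time-activity curves pointwise across subjects, then
#' linearly interpolates the mean to a 1-s grid with flat extrapolation
#' before the first and after the last sample. This mirrors constructing a
#' single modelled IDIF as the mean of per-patient arterial curves from the
#' fastest frame schedule, interpolated to 1-s resolution.
#'
#' @param curves List of sampled curves (data frames with `t_s`, `value`),
#'   all on the same time points (e.g. the `8x3,8x12,6x30` frame midpoints).
#' @param t_out Output grid (s); defaults to 0-300 s in 1-s steps.
#' @return A tibble with columns `t_s`, `value`.
#' @export
mean_idif <- function(curves, t_out = seq(0, 300, by = 1)) {
  if (length(curves) == 0L) stop("need at least one curve", call. = FALSE)
  t_ref <- curves[[1]]$t_s
  for (cv in curves) {
    if (length(cv$t_s) != length(t_ref) || any(abs(cv$t_s - t_ref) > 1e-9)) {
      stop("all curves must share the same time points", call. = FALSE)
    }
  }
  m <- rowMeans(vapply(curves, function(cv) cv$value, numeric(length(t_ref))))
  out <- stats::approx(t_ref, m, xout = t_out, method = "linear", rule = 2)
  tibble::tibble(t_s = out$x, value = out$y)
}

#' Detect bolus arrival time from an early framed curve
#'
#' Scans short early frames (clinically, twenty 3-s frames) and returns the
#' start time of the first frame whose value exceeds a fraction of the curve
#' maximum. Downstream analysis re-origins time so that this instant is 0.
#'
#' @param early_tac Framed curve: data frame with `start_s` and `value` (one
#'   row per frame).
#' @param threshold_fraction Fraction of the maximum (in `(0, 1)`) a frame
#'   must exceed to count as bolus arrival. Default 0.1.
#' @return Arrival time in seconds (the start of the triggering frame).
#' @export
detect_bolus_arrival <- function(early_tac, threshold_fraction = 0.1) {
  stopifnot(all(c("start_s", "value") %in% names(early_tac)),
            nrow(early_tac) >= 1L)
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0, 1)", call. = FALSE)
  }
  mx <- max(early_tac$value)
  if (mx <= 0) stop("no bolus detected: curve is non-positive", call. = FALSE)
  hit <- which(early_tac$value > threshold_fraction * mx)[1]
  early_tac$start_s[hit]
}
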