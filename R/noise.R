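#' Noise model configuration
#'
#' Frame-duration-scaled Poisson noise: per frame the perturbation is
#' `c * (Poisson(C) - C) / sqrt(dt)` where `C` is the frame value and `dt`
#' the frame duration in seconds. Longer frames accumulate more counts, so
#' their relative noise is smaller - the core trade-off in choosing a frame
#' schedule.
#'
#' @param c Unitless noise scaling factor, `>= 0`. The default is calibrated
#'   (see `scripts/calibrate_noise.R`) so that with the default synthetic
#'   setup the SD of fitted K1 at the `12x5,8x30` schedule over 1000
#'   realizations is about 0.014 mL/ccm/min.
#' @param seed Base RNG seed; realization `i` of a Monte Carlo run uses
#'   `seed + i`.
#' @return A `noise_config` list.
#' @export
noise_config <- function(c = 0.47, seed = 1L) {
  if (c < 0) stop("noise scaling factor c must be >= 0", call. = FALSE)
  structure(list(c = c, seed = as.integer(seed)), class = "noise_config")
}

#' Add frame-duration-scaled Poisson noise to a framed curve
#'
#' For frame `i` with clean value `C_i` and duration `dt_i` (seconds),
#' returns `C_i + c * (P_i - C_i) / sqrt(dt_i)` with `P_i ~ Poisson(C_i)`,
#' draws independent across frames. The added noise has mean 0 and variance
#' `c^2 * C_i / dt_i`. Negative outputs are possible and preserved. The
#' caller controls the RNG state (set a seed beforehand for
#' reproducibility).
#'
#' @param framed_tac Framed curve: data frame with `value` (one row per
#'   frame, all values `>= 0`).
#' @param schedule The `frame_schedule` supplying frame durations.
#' @param cfg A [noise_config()].
#' @return The framed curve with noisy `value`.
#' @export
add_noise <- function(framed_tac, schedule, cfg = noise_config()) {
  stopifnot(inherits(cfg, "noise_config"))
  if (nrow(framed_tac) != nrow(schedule)) {
    stop("framed_tac must have one value per schedule frame", call. = FALSE)
  }
  cvals <- framed_tac$value
  if (any(cvals < 0)) {
    stop("frame values must be >= 0 (Poisson mean)", call. = FALSE)
  }
  if (cfg$c == 0) return(framed_tac)
  draws <- stats::rpois(length(cvals), lambda = cvals)
  out <- framed_tac
  out$value <- cvals + cfg$c * (draws - cvals) / sqrt(schedule$duration_s)
  out
}
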