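#' Kinetic parameters of the one-tissue compartment model
#'
#' @param k1 Influx constant K1, mL blood per mL (ccm) tissue per minute,
#'   `>= 0`.
#' @param k2 Efflux constant, min^-1, `>= 0`. `k2 = 0` is the irreversible
#'   model.
#' @param vb Fractional blood volume of the region, in `[0, 1]`.
#' @return A one-row tibble with columns `k1`, `k2`, `vb` and class
#'   `kinetic_params`.
#' @export
kinetic_params <- function(k1 = 0.506, k2 = 0.150, vb = 0.05) {
  if (k1 < 0 || k2 < 0) stop("rate constants must be >= 0", call. = FALSE)
  if (vb < 0 || vb > 1) stop("vb must be in [0, 1]", call. = FALSE)
  out <- tibble::tibble(k1 = k1, k2 = k2, vb = vb)
  class(out) <- c("kinetic_params", class(out))
  out
}

#' Convolve a curve with an exponential kernel
#'
#' Computes `(e^(-k2 t) (*) C)(t) = \int_0^t e^(-k2 (t - s)) C(s) ds` on the
#' curve's own uniform grid, the convolution term of the one-tissue
#' compartment model. The integral is advanced by the exact state-update
#' recursion for an exponential kernel with the input taken piecewise linear
#' between grid points, so accuracy is second order in the grid step and the
#' scheme is unconditionally stable.
#'
#' @param curve Data frame with `t_s` (uniform grid, seconds) and `value`.
#' @param k2_per_s Kernel decay rate in s^-1 (`>= 0`; 0 gives the running
#'   time-integral of the input).
#' @return A tibble `t_s`, `value` where `value` has units of
#'   `input units x seconds`.
#' @export
exp_convolve <- function(curve, k2_per_s) {
  stopifnot(all(c("t_s", "value") %in% names(curve)), k2_per_s >= 0)
  h <- grid_step(curve$t_s)
  tibble::tibble(t_s = curve$t_s,
                 value = exp_convolve_vec(curve$value, h, k2_per_s))
}

# Vector core of exp_convolve: no data-frame allocation, used in fit loops.
exp_convolve_vec <- function(x, h, k2_per_s) {
  n <- length(x)
  if (k2_per_s == 0) {
    # running trapezoid integral
    return(c(0, cumsum((x[-n] + x[-1]) / 2 * h)))
  }
  a <- k2_per_s * h
  r <- exp(-a)
  # increment over one step with linear input from x0 to x1:
  #   w0 * x0 + w1 * x1, from the closed-form integral of the kernel
  w1 <- (1 - (1 - r) / a) / k2_per_s
  w0 <- (1 - r) / k2_per_s - w1
  b <- c(0, w0 * x[-n] + w1 * x[-1])
  as.numeric(stats::filter(b, r, method = "recursive"))
}

#' One-tissue compartment forward model
#'
#' Generates the continuous tumour time-activity curve
#' `C(t) = VB * C_IDIF(t) + (1 - VB) * K1 * e^(-k2 t) (*) C_IDIF(t)`
#' on the input function's grid. `K1` and `k2` are supplied per minute and
#' converted to per-second internally, matching the seconds-based time grid.
#'
#' @param idif Input function: data frame with `t_s` (uniform grid, s) and
#'   `value` (kBq/mL).
#' @param params A [kinetic_params()] row.
#' @param reversible If `FALSE`, `k2` is forced to 0 (irreversible 1T1K+VB
#'   model); if `TRUE` (default) the reversible 1T2k+VB model.
#' @return A tibble `t_s`, `value` (kBq/mL).
#' @examples
#' idif <- synthetic_idif()
#' tac <- model_tac(idif, kinetic_params(k1 = 0.506, k2 = 0.150, vb = 0.05))
#' @export
model_tac <- function(idif, params, reversible = TRUE) {
  k1_s <- params$k1 / 60
  k2_s <- if (reversible) params$k2 / 60 else 0
  conv <- exp_convolve(idif, k2_s)
  tibble::tibble(
    t_s = idif$t_s,
    value = params$vb * idif$value + (1 - params$vb) * k1_s * conv$value
  )
}

#' Frame-averaged model prediction
#'
#' The forward model evaluated the way framed data are measured: the
#' continuous curve of [model_tac()] averaged over each frame of a schedule.
#'
#' @inheritParams model_tac
#' @param schedule A `frame_schedule`.
#' @return A tibble with one row per frame (`t_s` = midpoint, `value`,
#'   `start_s`, `duration_s`).
#' @export
framed_prediction <- function(idif, params, schedule, reversible = TRUE) {
  rebin_curve(model_tac(idif, params, reversible = reversible), schedule)
}
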