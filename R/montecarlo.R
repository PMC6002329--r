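#' Configuration of a frame-schedule comparison study
#'
#' Bundles everything the Monte Carlo scheme comparison needs: the ground
#' truth kinetic parameters, the target K1 the schedules are ranked
#' against, the input function, the candidate schedules, the noise model
#' and the number of noise realizations.
#'
#' @param truth Generating [kinetic_params()] for the modelled tumour curve.
#'   Defaults to the cohort-average values `K1 = 0.506` mL/ccm/min,
#'   `k2 = 0.150` min^-1.
#' @param target_k1 Target K1 (mL/ccm/min) used for ranking; defaults to
#'   the truth K1.
#' @param idif Fine-grid input function; defaults to [synthetic_idif()].
#' @param schedules List of `frame_schedule`s; defaults to
#'   [blood_phase_schedules()].
#' @param noise A [noise_config()].
#' @param n_realizations Number of noisy realizations per schedule
#'   (default 1000).
#' @param idif_mode IDIF handling during fitting, `"framed"` (default) or
#'   `"fine"`; see [fit_tac()].
#' @return A `study_config` list.
#' @export
study_config <- function(truth = kinetic_params(k1 = 0.506, k2 = 0.150,
                                                vb = 0.05),
                         target_k1 = truth$k1,
                         idif = synthetic_idif(),
                         schedules = blood_phase_schedules(),
                         noise = noise_config(),
                         n_realizations = 1000,
                         idif_mode = c("framed", "fine")) {
  stopifnot(n_realizations >= 1)
  structure(
    list(truth = truth, target_k1 = target_k1, idif = idif,
         schedules = schedules, noise = noise,
         n_realizations = as.integer(n_realizations),
         idif_mode = match.arg(idif_mode)),
    class = "study_config"
  )
}

#' Monte Carlo comparison of frame schedules
#'
#' For each candidate schedule: builds the noiseless framed truth curve
#' from the forward model, adds `n_realizations` independent
#' frame-duration-scaled Poisson noise draws, fits each realization with
#' the reversible model, and summarizes the fitted K1 values. Realization
#' `i` seeds the RNG with `noise$seed + i`, so results are fully
#' reproducible and independent of schedule evaluation order.
#'
#' @param cfg A [study_config()].
#' @return A `scheme_stats` tibble with one row per schedule:
#'   `schedule_id`, `mean_k1`, `sd_k1`, `ci_lo`, `ci_hi` (normal-theory 95%
#'   CI of the mean, `mean +/- 1.96 sd / sqrt(n_converged)`),
#'   `n_realizations`, `n_converged`, `low_convergence` (flag set when
#'   fewer than half the realizations converged).
#' @examples
#' \donttest{
#' cfg <- study_config(n_realizations = 20)
#' run_scheme_comparison(cfg)
#' }
#' @export
run_scheme_comparison <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  rows <- purrr::map(cfg$schedules, function(sch) {
    clean <- framed_prediction(cfg$idif, cfg$truth, sch, reversible = TRUE)
    k1s <- numeric(cfg$n_realizations)
    conv <- logical(cfg$n_realizations)
    for (i in seq_len(cfg$n_realizations)) {
      noisy <- withr::with_seed(
        cfg$noise$seed + i,
        add_noise(clean, sch, cfg$noise)
      )
      f <- fit_tac(noisy, cfg$idif, sch, reversible = TRUE,
                   idif_mode = cfg$idif_mode)
      k1s[i] <- f$params$k1
      conv[i] <- f$converged
    }
    k1c <- k1s[conv]
    nc <- length(k1c)
    m <- mean(k1c)
    s <- if (nc > 1) stats::sd(k1c) else 0
    half <- 1.96 * s / sqrt(max(nc, 1))
    tibble::tibble(
      schedule_id = schedule_id(sch),
      mean_k1 = m, sd_k1 = s,
      ci_lo = m - half, ci_hi = m + half,
      n_realizations = cfg$n_realizations,
      n_converged = nc,
      low_convergence = nc < cfg$n_realizations / 2
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scheme_stats", class(out))
  out
}

#' Rank schedules by closeness to the target K1
#'
#' Orders scheme statistics by ascending absolute difference between the
#' Monte Carlo mean K1 and the target; ties go to the smaller SD.
#'
#' @param stats A `scheme_stats` tibble (from [run_scheme_comparison()]).
#' @param target_k1 Target K1 in mL/ccm/min.
#' @return `stats` reordered, with an added `abs_bias` column.
#' @export
rank_schemes <- function(stats, target_k1) {
  stopifnot(nrow(stats) >= 1L)
  out <- dplyr::mutate(stats, abs_bias = abs(.data$mean_k1 - target_k1))
  out <- dplyr::arrange(out, .data$abs_bias, .data$sd_k1)
  class(out) <- unique(c("scheme_stats", class(out)))
  out
}

#' Pairwise Wilcoxon tests between schedules' realization K1 values
#'
#' Optional descriptive companion to [run_scheme_comparison()]: runs the
#' comparison while retaining every realization's fitted K1, then tests
#' each schedule against each other with the paired Wilcoxon signed-rank
#' test (realizations paired by index, i.e. by shared noise seed).
#'
#' @param cfg A [study_config()].
#' @return A list with `stats` (the `scheme_stats` tibble) and `pairwise`
#'   (tibble: `schedule_a`, `schedule_b`, `statistic`, `p_value`).
#' @export
scheme_pairwise_tests <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  draws <- purrr::map(cfg$schedules, function(sch) {
    clean <- framed_prediction(cfg$idif, cfg$truth, sch, reversible = TRUE)
    vapply(seq_len(cfg$n_realizations), function(i) {
      noisy <- withr::with_seed(cfg$noise$seed + i,
                                add_noise(clean, sch, cfg$noise))
      fit_tac(noisy, cfg$idif, sch, reversible = TRUE,
              idif_mode = cfg$idif_mode)$params$k1
    }, numeric(1))
  })
  ids <- vapply(cfg$schedules, schedule_id, character(1))
  pairs <- utils::combn(seq_along(ids), 2)
  pairwise <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    w <- wilcoxon_signed_rank(draws[[a]], draws[[b]])
    tibble::tibble(schedule_a = ids[a], schedule_b = ids[b],
                   statistic = w$statistic, p_value = w$p_value)
  })
  stats <- run_scheme_comparison(cfg)
  list(stats = stats, pairwise = dplyr::bind_rows(pairwise))
}
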