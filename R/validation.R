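#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired samples, the test used to compare
#' per-lesion K1 values between frame schedules. Zero differences are
#' discarded (the classical convention), absolute differences are ranked
#' with midranks for ties, and the statistic is `min(W+, W-)`. The p-value
#' is exact - computed by enumerating all `2^n` sign assignments - when the
#' effective sample size is at most `exact_max` (default 12), and uses the
#' normal approximation with midrank tie correction and a 0.5 continuity
#' correction otherwise.
#'
#' @param x,y Paired numeric vectors of equal length `>= 2`.
#' @param exact_max Largest effective n for which the exact enumeration is
#'   used.
#' @return A list: `statistic` (`min(W+, W-)`), `p_value` (two-sided),
#'   `n_effective` (pairs with non-zero difference), `method` (`"exact"` or
#'   `"normal"`). If every difference is zero the result is `p_value = 1`
#'   with a warning.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 0, 0, 0))
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d)) # midranks for ties
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  stat <- min(w_pos, w_neg)
  if (n <= exact_max) {
    # enumerate all sign assignments; two-sided p = P(min(W+, W-) <= stat)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.numeric(signs %*% r)
    tot <- sum(r)
    mins <- pmin(w_all, tot - w_all)
    p <- mean(mins <= stat)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (abs(stat - mu) - 0.5) / sigma
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal"
  }
  list(statistic = stat, p_value = min(p, 1), n_effective = n,
       method = method)
}

#' Spearman rank correlation
#'
#' Rank correlation between two samples: the Pearson correlation of
#' midranks, with a two-sided p-value from the t-distribution
#' approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom. Used to relate kinetic K1 to the static SUVmean.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return A list: `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero variance in ranks; correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Compare every schedule's K1 values to the optimal schedule's
#'
#' Clinical-validation table: for each non-optimal schedule, the per-lesion
#' fitted K1 values are compared to those from the optimal schedule with
#' the paired Wilcoxon signed-rank test. The optimal schedule's own row
#' carries `NA` for the p-value (not applicable).
#'
#' @param records Cohort tibble from [simulate_cohort()] (or any table with
#'   `lesion_id`, `schedule_id`, `fitted_k1`).
#' @param optimal_schedule_id The reference schedule's id string.
#' @return A tibble with one row per schedule: `schedule_id`, `mean_k1`,
#'   `sd_k1`, `p_value` (`NA` for the optimal row), ordered with the
#'   optimal schedule's comparisons computed pairwise by lesion.
#' @export
compare_to_optimal <- function(records, optimal_schedule_id) {
  stopifnot(all(c("lesion_id", "schedule_id", "fitted_k1") %in%
                  names(records)))
  ids <- unique(records$schedule_id)
  if (!optimal_schedule_id %in% ids) {
    stop("optimal schedule '", optimal_schedule_id, "' not in records",
         call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    records[, c("lesion_id", "schedule_id", "fitted_k1")],
    names_from = "schedule_id", values_from = "fitted_k1"
  )
  for (id in ids) {
    if (anyNA(wide[[id]])) {
      missing <- wide$lesion_id[is.na(wide[[id]])]
      stop("lesion(s) ", paste(missing, collapse = ", "),
           " missing schedule '", id, "'", call. = FALSE)
    }
  }
  ref <- wide[[optimal_schedule_id]]
  purrr::map_dfr(ids, function(id) {
    v <- wide[[id]]
    p <- if (id == optimal_schedule_id) {
      NA_real_
    } else {
      wilcoxon_signed_rank(v, ref)$p_value
    }
    tibble::tibble(schedule_id = id, mean_k1 = mean(v),
                   sd_k1 = stats::sd(v), p_value = p)
  })
}
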