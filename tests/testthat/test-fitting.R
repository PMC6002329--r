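test_that("AICc follows the small-sample least-squares formula", {
  expect_equal(aicc(rss = 1, n = 20, k = 3), 20 * log(1 / 20) + 6 + 1.5)
  expect_equal(round(aicc(1, 20, 3), 3), -52.415)
  # penalty is monotone in k at equal rss and n
  expect_lt(aicc(2, 20, 2), aicc(2, 20, 3))
  # scaling rss by e raises AICc by exactly n
  expect_equal(aicc(exp(1) * 3, 25, 3) - aicc(3, 25, 3), 25)
  expect_error(aicc(1, 4, 3), "n > k")
  expect_error(aicc(0, 20, 3), "rss")
})

test_that("noiseless curves are recovered to high accuracy with a fine IDIF", {
  idif <- synthetic_idif()
  truth <- default_truth()
  sch <- parse_schedule("8x3,8x12,6x30")
  clean <- framed_prediction(idif, truth, sch)
  f <- fit_tac(clean, idif, sch, idif_mode = "fine")
  expect_true(f$converged)
  expect_lt(abs(f$params$k1 - truth$k1) / truth$k1, 0.01)
  expect_lt(abs(f$params$k2 - truth$k2) / truth$k2, 0.01)
  expect_lt(abs(f$params$vb - truth$vb) / truth$vb, 0.01)
})

test_that("pure blood signal fits to K1 of zero", {
  idif <- test_idif()
  sch <- parse_schedule("12x5,8x30")
  data <- rebin_curve(dplyr::mutate(idif, value = 0.05 * value), sch)
  f <- fit_tac(data, idif, sch, idif_mode = "fine")
  expect_true(f$converged)
  expect_lte(f$params$k1, 1e-3)
})

test_that("all-zero data yield a converged zero fit, not an error", {
  idif <- test_idif()
  sch <- parse_schedule("10x30")
  zero <- tibble::tibble(t_s = sch$mid_s, value = 0)
  f <- fit_tac(zero, idif, sch)
  expect_true(f$converged)
  expect_lt(f$params$k1, 1e-6)
})

test_that("the optimum beats a brute-force parameter lattice", {
  idif <- test_idif()
  truth <- kinetic_params(k1 = 0.4, k2 = 0.2, vb = 0.04)
  sch <- parse_schedule("10x30")
  data <- framed_prediction(idif, truth, sch)
  f <- fit_tac(data, idif, sch, idif_mode = "fine")
  lattice <- expand.grid(k1 = seq(0.1, 0.8, by = 0.1),
                         k2 = seq(0.05, 0.4, by = 0.05),
                         vb = c(0.02, 0.04, 0.08))
  rss_at <- function(k1, k2, vb) {
    pred <- framed_prediction(idif, kinetic_params(k1, k2, vb), sch)
    sum((data$value - pred$value)^2)
  }
  lattice_min <- min(mapply(rss_at, lattice$k1, lattice$k2, lattice$vb))
  expect_lte(f$rss, lattice_min + 1e-12)
})

test_that("nested models satisfy the rss inequality", {
  idif <- test_idif()
  sch <- parse_schedule("12x5,8x30")
  clean <- framed_prediction(idif, default_truth(), sch)
  noisy <- withr::with_seed(5, add_noise(clean, sch, noise_config(c = 0.47)))
  f_rev <- fit_tac(noisy, idif, sch, reversible = TRUE)
  f_irr <- fit_tac(noisy, idif, sch, reversible = FALSE)
  expect_lte(f_rev$rss, f_irr$rss * (1 + 1e-6))
  expect_equal(f_irr$params$k2, 0)
  expect_equal(f_irr$k, 2L)
})

test_that("fits are invariant to joint rescaling of data and input function", {
  idif <- test_idif()
  sch <- parse_schedule("10x30")
  clean <- framed_prediction(idif, default_truth(), sch)
  noisy <- withr::with_seed(9, add_noise(clean, sch, noise_config(c = 0.3)))
  f1 <- fit_tac(noisy, idif, sch)
  s <- 4.7
  f2 <- fit_tac(dplyr::mutate(noisy, value = s * value),
                dplyr::mutate(idif, value = s * value), sch)
  expect_equal(f2$params$k1, f1$params$k1, tolerance = 1e-4)
  expect_equal(f2$params$k2, f1$params$k2, tolerance = 1e-4)
  expect_equal(f2$params$vb, f1$params$vb, tolerance = 1e-4)
  expect_equal(f2$rss, s^2 * f1$rss, tolerance = 1e-3)
})

test_that("the noiseless optimum is reached from multiple starts", {
  idif <- test_idif()
  truth <- default_truth()
  sch <- parse_schedule("12x5,8x30")
  clean <- framed_prediction(idif, truth, sch)
  starts <- default_fit_starts()
  expect_length(starts, 5L)
  k1s <- vapply(starts, function(st) {
    fit_tac(clean, idif, sch, idif_mode = "fine", init = st)$params$k1
  }, numeric(1))
  expect_lt(max(k1s) - min(k1s), 1e-4)
  expect_equal(mean(k1s), truth$k1, tolerance = 1e-3)
})

test_that("tidy and glance summarize fits in broom style", {
  idif <- test_idif()
  sch <- parse_schedule("10x30")
  f <- fit_tac(framed_prediction(idif, default_truth(), sch), idif, sch,
               idif_mode = "fine")
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, c("k1", "k2", "vb"))
  gl <- glance(f)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("schedule_id", "model", "rss", "aicc", "converged")
                  %in% names(gl)))
})

test_that("model selection minimizes AICc with a parsimony tie-break", {
  mk <- function(aicc, k, converged = TRUE) {
    structure(list(aicc = aicc, k = k, converged = converged,
                   reversible = k == 3), class = "tac_fit")
  }
  expect_equal(select_model(list(mk(-52, 3), mk(-48, 2)))$k, 3)
  expect_equal(select_model(list(mk(-50, 3), mk(-50, 2)))$k, 2)
  expect_warning(sel <- select_model(list(mk(-60, 3, FALSE), mk(-48, 2))),
                 "unconverged")
  expect_equal(sel$k, 2)
  expect_error(
    suppressWarnings(select_model(list(mk(-60, 3, FALSE), mk(-48, 2, FALSE)))),
    "no converged"
  )
})

test_that("high-SNR data let AICc identify the generating model", {
  idif <- test_idif()
  sch <- parse_schedule("12x5,8x30")
  n_rep <- 40
  pick_rev <- function(truth, seed0) {
    clean <- framed_prediction(idif, truth, sch)
    picks <- vapply(seq_len(n_rep), function(i) {
      noisy <- withr::with_seed(seed0 + i,
                                add_noise(clean, sch, noise_config(c = 0.1)))
      sel <- select_model(list(
        fit_tac(noisy, idif, sch, reversible = TRUE),
        fit_tac(noisy, idif, sch, reversible = FALSE)
      ))
      sel$reversible
    }, logical(1))
    mean(picks)
  }
  expect_gt(pick_rev(kinetic_params(0.506, 0.150, 0.05), 100), 0.5)
  expect_lt(pick_rev(kinetic_params(0.506, 0, 0.05), 200), 0.5)
})
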