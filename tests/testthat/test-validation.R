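test_that("identical paired samples give p = 1 with a warning", {
  expect_warning(res <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(res$p_value, 1)
  expect_equal(res$n_effective, 0L)
})

test_that("six uniformly positive differences give the exact enumeration p", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), rep(0, 6))
  expect_equal(res$method, "exact")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / 2^6)
})

test_that("exact p-values match an independent exhaustive oracle", {
  cases <- list(
    c(1.2, -0.4, 2.1, 0.3, -1.5, 0.8, 2.2, -0.1, 0.6), # n = 9, no ties
    c(1, 1, -1, 2, 3, -2, 4),                           # midrank ties
    c(0.5, -0.5, 1.5, 2.5, -3.5, 4.5, 0.1, 0.2, -0.3, 1.1, -1.1, 2.2)
  )
  for (d in cases) {
    res <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, enumerate_wilcoxon_p(d))
  }
})

test_that("exact p-values agree with the reference implementation without ties", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      x <- rnorm(10)
      y <- rnorm(10)
      ours <- wilcoxon_signed_rank(x, y)
      ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
      expect_equal(ours$p_value, unname(ref$p.value))
    }
  })
})

test_that("signed-rank p is invariant under monotone rescaling of differences", {
  x <- c(1.2, -0.4, 2.1, 0.3, -1.5, 0.8, 2.2, -0.1)
  base <- wilcoxon_signed_rank(x, rep(0, 8))
  for (f in list(function(d) 3 * d, function(d) sign(d) * abs(d)^3)) {
    expect_equal(wilcoxon_signed_rank(f(x), rep(0, 8))$p_value, base$p_value)
  }
})

test_that("normal approximation tracks the exact p at the threshold n", {
  withr::with_seed(33, {
    for (rep in 1:20) {
      x <- rnorm(12, mean = 0.3)
      y <- rep(0, 12)
      exact <- wilcoxon_signed_rank(x, y, exact_max = 12)
      approx <- wilcoxon_signed_rank(x, y, exact_max = 0)
      expect_equal(approx$method, "normal")
      expect_lt(abs(exact$p_value - approx$p_value), 0.02)
    }
  })
})

test_that("Spearman correlation handles monotone and tied data", {
  expect_equal(spearman_rho(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3)$rho, -1)
  expect_equal(spearman_rho(1:10, (1:10)^2)$p_value, 0)

  # n = 5 with one tie in y: hand-computed midrank Pearson correlation
  x <- c(1, 2, 3, 4, 5)
  y <- c(10, 20, 20, 30, 40)
  ry <- c(1, 2.5, 2.5, 4, 5)
  hand <- sum((1:5 - 3) * (ry - 3)) /
    sqrt(sum((1:5 - 3)^2) * sum((ry - 3)^2))
  res <- spearman_rho(x, y)
  expect_equal(res$rho, hand)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(res$rho, unname(ref$estimate))

  expect_error(spearman_rho(1:5, rep(2, 5)), "zero variance")
})

test_that("random data match the reference Spearman rho and t-approximation p", {
  withr::with_seed(14, {
    for (rep in 1:10) {
      x <- rnorm(15)
      y <- x + rnorm(15, sd = 2)
      res <- spearman_rho(x, y)
      ref <- stats::cor.test(x, y, method = "spearman")
      expect_equal(res$rho, unname(ref$estimate))
    }
  })
})

test_that("the validation table compares every schedule to the optimal one", {
  withr::with_seed(2, {
    k1 <- runif(37, 0.2, 1.2)
    ids <- c("opt", paste0("s", 1:6))
    records <- dplyr::bind_rows(lapply(ids, function(id) {
      shift <- if (id == "opt") 0 else if (id == "s1") 0 else 0.1
      tibble::tibble(lesion_id = 1:37, schedule_id = id,
                     fitted_k1 = k1 + shift)
    }))
  })
  suppressWarnings(tab <- compare_to_optimal(records, "opt"))
  expect_equal(nrow(tab), 7L)
  expect_true(is.na(tab$p_value[tab$schedule_id == "opt"]))
  expect_equal(sum(is.na(tab$p_value)), 1L)
  # identical column -> all differences zero -> p = 1
  expect_equal(tab$p_value[tab$schedule_id == "s1"], 1)
  # a +0.1 shift across all 37 lesions is overwhelmingly significant
  shifted <- tab$p_value[!tab$schedule_id %in% c("opt", "s1")]
  expect_true(all(shifted < 0.001))
})

test_that("missing lesion-schedule pairs are reported by lesion", {
  records <- tibble::tibble(
    lesion_id = c(1, 2, 1), schedule_id = c("opt", "opt", "alt"),
    fitted_k1 = c(0.5, 0.6, 0.55)
  )
  expect_error(compare_to_optimal(records, "opt"), "lesion\\(s\\) 2")
  expect_error(compare_to_optimal(records, "nope"), "not in records")
})
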