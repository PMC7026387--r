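test_that("r_squared and rmse reproduce hand-derived examples", {
  y <- c(0, 1, 2)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, c(0, 1, 1)), 0.5) # SSE 1, SStot 2
  expect_equal(r_squared(c(0, 1), c(2, 3)), 1 - 8 / 0.5) # -15: unbounded below
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, c(0, 1, 1)), sqrt(1 / 3))
  expect_equal(rmse(c(1, 2, 3), c(2, 3, 4)), 1) # constant residual c -> |c|
  expect_error(r_squared(c(1, 1), c(1, 2)), class = "deepsol_data_error")
  expect_error(rmse(numeric(0), numeric(0)), class = "deepsol_data_error")
})

test_that("metrics agree with brute-force transcriptions on random pairs", {
  r2_oracle <- function(y, yh) {
    yb <- sum(y) / length(y)
    1 - sum((y - yh)^2) / sum((y - yb)^2)
  }
  rmse_oracle <- function(y, yh) sqrt(sum((y - yh)^2) / length(y))
  withr::with_seed(51, {
    for (i in 1:1000) {
      n <- sample(2:60, 1)
      y <- rnorm(n, sd = runif(1, 0.5, 3))
      yh <- y + rnorm(n)
      expect_lt(abs(r_squared(y, yh) - r2_oracle(y, yh)), 1e-12)
      expect_lt(abs(rmse(y, yh) - rmse_oracle(y, yh)), 1e-12)
    }
  })
})

test_that("predicting the mean gives exactly R^2 = 0", {
  withr::with_seed(52, y <- rnorm(30))
  expect_equal(r_squared(y, rep(mean(y), 30)), 0)
})

test_that("rmse and pct_within_10fold are permutation invariant", {
  withr::with_seed(53, {
    y <- rnorm(25)
    yh <- y + rnorm(25)
    perm <- sample(25)
  })
  expect_equal(rmse(y[perm], yh[perm]), rmse(y, yh))
  expect_equal(pct_within_10fold(y[perm], yh[perm]), pct_within_10fold(y, yh))
})

test_that("pct_within_10fold counts one log unit inclusively", {
  expect_equal(pct_within_10fold(c(-2, -3), c(-2, -3)), 100)
  # |Delta| = 1 passes, |Delta| = 1.5 fails
  expect_equal(pct_within_10fold(c(-2, -3), c(-1, -4.5)), 50)
  # boundary is inclusive: a 10-fold error counts as within 10-fold
  expect_equal(pct_within_10fold(-2, -3), 100)
  expect_equal(pct_within_10fold(-2, -3.0000001), 0)
})

test_that("solubility categories reproduce the g/L partition", {
  # 1e-4 mol/L x 100 g/mol = 0.01 g/L
  expect_equal(as.character(classify_category(-4, 100)),
               "practically_insoluble")
  # 0.1 mol/L x 200 g/mol = 20 g/L
  expect_equal(as.character(classify_category(-1, 200)), "soluble")
  # exactly 0.1 g/L -> slightly soluble (lower bound inclusive)
  expect_equal(as.character(classify_category(log10(0.1 / 100), 100)),
               "slightly_soluble")
  expect_equal(as.character(classify_category(log10(100 / 100), 100)),
               "freely_soluble")
  expect_equal(as.character(classify_category(log10(10 / 100) - 1e-12, 100)),
               "slightly_soluble")
})

test_that("the four category bins partition every positive g/L value", {
  withr::with_seed(54, {
    log_s <- runif(500, -9, 2)
    mw <- runif(500, 60, 900)
  })
  cats <- classify_category(log_s, mw)
  expect_false(any(is.na(cats)))
  expect_equal(levels(cats), solubility_categories())
  # reflexivity: identical inputs always agree
  expect_true(all(cats == classify_category(log_s, mw)))
})

test_that("category accuracy counts agreements in percent", {
  y <- c(-4, -1, -2, -3)
  mw <- rep(100, 4)
  expect_equal(category_accuracy(y, y, mw), 100)
  # single compound, one category off
  expect_equal(category_accuracy(-4, -1, 100), 0)
  # 3 of 4 matching categories (the last prediction lands freely soluble)
  yh <- c(-4.1, -0.9, -2.2, 0)
  expect_equal(category_accuracy(y, yh, mw), 75)
})

test_that("evaluate_predictions assembles the full panel with tidiers", {
  d <- tibble::tibble(
    compound_id = c("a", "b", "c", "d"),
    y = c(-4, -1, -2, -3), y_hat = c(-4.2, -1.4, -2.0, -1.8),
    molecular_weight = rep(150, 4))
  ev <- evaluate_predictions(d)
  expect_s3_class(ev, "sol_eval")
  g <- glance(ev)
  expect_equal(g$n, 4L)
  expect_equal(g$rmse, rmse(d$y, d$y_hat))
  expect_equal(g$pct_within_10fold, 75)
  td <- tidy(ev)
  expect_true(all(c("abs_error", "within_10fold", "category_true",
                    "category_pred") %in% names(td)))
  expect_error(evaluate_predictions(d[, c("compound_id", "y")]),
               class = "deepsol_config_error")
})

test_that("format_r2 reproduces the '<0.2' display convention", {
  expect_equal(format_r2(c(0.412, 0.16, 0.086)), c("0.412", "<0.2", "<0.2"))
})

test_that("bootstrap of a perfect fit collapses to a zero-width interval", {
  withr::with_seed(55, y <- rnorm(62))
  bs <- bootstrap_metrics(y, y, b = 200, seed = 9)
  r2row <- bs[bs$metric == "r2", ]
  expect_equal(r2row$mean, 1)
  expect_equal(r2row$sd, 0)
  expect_equal(r2row$ci_low, 1)
  expect_equal(r2row$ci_high, 1)
  rmserow <- bs[bs$metric == "rmse", ]
  expect_equal(rmserow$mean, 0)
  expect_equal(rmserow$ci_high, 0)
})

test_that("b = 1 bootstrap reports that resample's metric with sd 0", {
  withr::with_seed(56, {
    y <- rnorm(20)
    yh <- y + rnorm(20, 0, 0.5)
  })
  bs <- bootstrap_metrics(y, yh, b = 1, seed = 3)
  idx <- withr::with_seed(3L, matrix(sample.int(20, 20, replace = TRUE), 20, 1))
  expect_equal(bs$mean[bs$metric == "rmse"], rmse(y[idx], yh[idx]))
  expect_equal(bs$sd, c(0, 0))
})

test_that("bootstrap CI width shrinks as residual dispersion shrinks", {
  withr::with_seed(57, y <- rnorm(62, sd = 1.5))
  widths <- vapply(c(1, 0.3, 0.05), function(s) {
    yh <- y + withr::with_seed(58, rnorm(62, 0, s))
    bs <- bootstrap_metrics(y, yh, b = 500, seed = 4)
    r <- bs[bs$metric == "rmse", ]
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("degenerate resamples are skipped and counted", {
  # constant y: every resample lacks variance -> r2 impossible
  expect_error(bootstrap_metrics(rep(1, 5), rnorm(5), b = 10, seed = 1),
               class = "deepsol_data_error")
})
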