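test_that("generation is fully seed-deterministic and validates n", {
  truth <- synthetic_truth(seed = 13L)
  a <- generate_dataset(50, truth)
  b <- generate_dataset(50, truth)
  expect_identical(a$features$x, b$features$x)
  expect_identical(a$features$y, b$features$y)
  expect_identical(tibble::as_tibble(a$compounds), tibble::as_tibble(b$compounds))
  c <- generate_dataset(50, truth, seed = 14L)
  expect_false(identical(a$features$y, c$features$y))
  expect_error(generate_dataset(0, truth), class = "deepsol_data_error")
})

test_that("noise-free linear truth is recovered exactly by least squares", {
  truth <- synthetic_truth(n_active = 40L, noise_sd = 0, seed = 17L,
                           block_correlated = FALSE)
  ds <- generate_dataset(200, truth) # n >= 2k: identifiable design
  act <- truth$active_bits
  X <- ds$features$x[, act]
  fit <- stats::lm.fit(cbind(1, X), ds$features$y)
  w_hat <- fit$coefficients[-1]
  expect_lt(max(abs(w_hat - truth$bit_weights[act])), 1e-8)
  expect_lt(abs(fit$coefficients[1] - truth$intercept), 1e-8)
})

test_that("generated logS moments match the analytic values within 4 SE", {
  truth <- synthetic_truth(n_active = 40L, noise_sd = 0.4, seed = 19L,
                           logs_range = c(-30, 10)) # no clipping interference
  n <- 4000
  ds <- generate_dataset(n, truth)
  mom <- synthetic_moments(truth)
  se_mean <- sqrt(mom$var / n)
  expect_lt(abs(mean(ds$features$y) - mom$mean), 4 * se_mean)
  # SE of the sample variance ~ var * sqrt(2/(n-1)) under near-normality
  se_var <- mom$var * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(ds$features$y) - mom$var), 4 * se_var)
})

test_that("pairwise interaction terms shift the planted signal", {
  t0 <- synthetic_truth(n_active = 10L, n_pairwise = 5L, noise_sd = 0,
                        seed = 23L)
  expect_equal(nrow(t0$pairwise_terms), 5L)
  ds <- generate_dataset(100, t0)
  lin <- t0$intercept + as.numeric(ds$features$x %*% t0$bit_weights)
  expect_gt(max(abs(ds$features$y - lin)), 0) # interactions present
})

test_that("emitted logS respects the plausible range", {
  truth <- synthetic_truth(noise_sd = 3, seed = 29L)
  ds <- generate_dataset(500, truth)
  expect_true(all(ds$features$y >= truth$logs_range[1]))
  expect_true(all(ds$features$y <= truth$logs_range[2]))
  expect_true(all(ds$features$mw >= 150 & ds$features$mw <= 600))
})

test_that("fixture files are byte-identical across regenerations", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- generate_fixture_tables(d1)
  f2 <- generate_fixture_tables(d2)
  expect_identical(readLines(f1["compounds"]), readLines(f2["compounds"]))
  expect_identical(readLines(f1["descriptors"]), readLines(f2["descriptors"]))
  fp <- read_descriptor_csv(f1["descriptors"])
  expect_equal(ncol(fp), 881L)
  expect_equal(nrow(fp), 20L)
  raw <- readr::read_csv(f1["compounds"], show_col_types = FALSE)
  expect_equal(nrow(raw), 20L)
})

test_that("the fixture curates to 18 records with a full audit trail", {
  skip_if_not(has_openbabel(), "ChemmineOB not installed")
  dir <- withr::local_tempdir()
  files <- generate_fixture_tables(dir)
  cur <- curate_compounds(files["compounds"],
                          format_config(value = "solubility"),
                          chem_backend_openbabel())
  expect_equal(nrow(cur), 18L)
  expect_equal(sum(cur$censored), 1L)
  p <- provenance(cur)
  expect_equal(sum(p$action == "excluded_invalid_smiles"), 1L)
  expect_equal(sum(p$action == "removed_duplicate"), 1L)
  # count conservation: 20 in = 18 out + 1 invalid + 1 duplicate
  expect_equal(20L, nrow(cur) +
                 sum(p$action %in% c("excluded_invalid_smiles",
                                     "removed_duplicate")))
})
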