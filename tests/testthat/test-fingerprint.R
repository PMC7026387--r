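test_that("fingerprint construction enforces the 881-bit binary contract", {
  m <- matrix(0L, 2, 881)
  fp <- fingerprint_set(m, c("a", "b"))
  expect_equal(dim(fp), c(2L, 881L))
  expect_error(fingerprint_set(matrix(0L, 2, 880), c("a", "b")),
               class = "deepsol_data_error")
  m2 <- m; m2[1, 5] <- 2L
  expect_error(fingerprint_set(m2, c("a", "b")), class = "deepsol_data_error")
  expect_error(fingerprint_set(m, c("a", "a")), class = "deepsol_data_error")
})

test_that("descriptor CSV round-trips bit-exactly and flags dialect errors", {
  withr::with_seed(5, {
    bits <- matrix(rbinom(3 * 881, 1, 0.2), 3, 881)
  })
  fp <- fingerprint_set(bits, c("c1", "c2", "c3"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(fp, path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expect_equal(header[1:2], c("Name", "PubchemFP0"))
  expect_equal(header[882], "PubchemFP880")
  back <- read_descriptor_csv(path)
  expect_identical(unclass(back), unclass(fp))

  # wrong column count -> dialect error naming expected vs found
  d <- readr::read_csv(path, show_col_types = FALSE)
  short <- write_tmp_csv(d[, 1:881]) # drops one feature column
  expect_error(read_descriptor_csv(short), "881",
               class = "deepsol_data_error")

  # non-binary cell -> coordinates in the message
  d2 <- d
  d2[[2, "PubchemFP3"]] <- 7
  bad <- write_tmp_csv(d2)
  err <- tryCatch(read_descriptor_csv(bad), error = identity)
  expect_s3_class(err, "deepsol_data_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "PubchemFP3")
})

test_that("empty and single-bit fingerprints read back as expected", {
  d <- as.data.frame(matrix(0, 2, 881))
  names(d) <- paste0("PubchemFP", 0:880)
  d$PubchemFP0[2] <- 1
  d <- cbind(Name = c("z1", "z2"), d)
  path <- write_tmp_csv(d)
  fp <- read_descriptor_csv(path)
  expect_equal(sum(fp[1, ]), 0L)
  expect_equal(sum(fp[2, ]), 1L)
  expect_equal(unname(fp[2, 1]), 1L)
})

make_curated <- function(ids, log_s, censored = FALSE) {
  n <- length(ids)
  deepsol:::new_curated_tbl(tibble::tibble(
    compound_id = ids, smiles = "C", canonical_smiles = "C",
    inchikey = paste0(strrep("Q", 13), LETTERS[seq_len(n)], "-",
                      strrep("A", 10), "-N"),
    solubility_value = 10^log_s, solubility_unit = "mol_per_L",
    molecular_weight = 100, log_s = log_s,
    censored = rep_len(censored, n)), NULL)
}

test_that("align_features pairs records with fingerprints deterministically", {
  withr::with_seed(6, bits <- matrix(rbinom(3 * 881, 1, 0.2), 3, 881))
  fp <- fingerprint_set(bits, c("b", "c", "a"))
  cur <- make_curated(c("c", "a", "b"), c(-1, -2, -3))
  fm <- align_features(fp, cur)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(fm$ids, c("a", "b", "c")) # sorted by compound id
  expect_equal(fm$y, c(-2, -3, -1))
  # invariance to input ordering of either argument
  fp_perm <- fingerprint_set(bits[c(2, 3, 1), ], c("c", "a", "b"))
  fm2 <- align_features(fp_perm, cur[c(2, 3, 1), ])
  fm3 <- align_features(fp, cur[c(3, 1, 2), ])
  for (other in list(fm2, fm3)) {
    expect_equal(other$ids, fm$ids)
    expect_equal(other$y, fm$y)
    expect_equal(other$x, fm$x)
  }
})

test_that("alignment reports every missing fingerprint and drops censored", {
  withr::with_seed(7, bits <- matrix(rbinom(2 * 881, 1, 0.2), 2, 881))
  fp <- fingerprint_set(bits, c("a", "b"))
  cur <- make_curated(c("a", "b", "c", "d"), c(-1, -2, -3, -4))
  err <- tryCatch(align_features(fp, cur), error = identity)
  expect_s3_class(err, "deepsol_data_error")
  expect_match(conditionMessage(err), "c, d")
  # censored records are excluded before alignment
  cur2 <- make_curated(c("a", "b", "c"), c(-1, -2, NA),
                       censored = c(FALSE, FALSE, TRUE))
  fm <- align_features(fp, cur2)
  expect_equal(nrow(fm$x), 2L)
})
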