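#' Fingerprint length of the PubChem substructure keyset
#' @return The integer 881.
#' @export
fingerprint_length <- function() 881L

#' Construct a fingerprint set
#'
#' A fingerprint set is an integer matrix with exactly 881 binary columns
#' (bit 0 ... bit 880, in file order) and one row per compound, with row
#' names holding compound ids. Construction validates the shape and the
#' 0/1 constraint, so malformed vectors are unrepresentable downstream.
#'
#' @param bits A numeric/integer matrix of 0s and 1s with 881 columns.
#' @param ids Character vector of compound ids (one per row).
#' @return A `fingerprint_set` (integer matrix subclass).
#' @export
fingerprint_set <- function(bits, ids = rownames(bits)) {
  bits <- as.matrix(bits)
  if (ncol(bits) != fingerprint_length()) {
    abort_data(sprintf("fingerprints must have exactly %d bits; got %d columns.",
                       fingerprint_length(), ncol(bits)))
  }
  if (is.null(ids) || length(ids) != nrow(bits) || anyDuplicated(ids)) {
    abort_data("`ids` must supply one unique compound id per fingerprint row.")
  }
  storage.mode(bits) <- "integer"
  if (any(is.na(bits)) || !all(bits %in% c(0L, 1L))) {
    abort_data("fingerprint bits must all be 0 or 1.")
  }
  dimnames(bits) <- list(as.character(ids),
                         paste0("PubchemFP", seq_len(ncol(bits)) - 1L))
  class(bits) <- c("fingerprint_set", class(bits))
  bits
}

#' Read / write descriptor CSV files (PaDEL dialect)
#'
#' The descriptor dialect has a leading `Name` column followed by exactly
#' 881 binary feature columns `PubchemFP0` ... `PubchemFP880`; column order
#' is preserved as bit order. A wrong column count raises a dialect error
#' naming expected vs found; a non-binary cell raises a parse error with its
#' row and column coordinates.
#'
#' @param path File path.
#' @param fp A `fingerprint_set` (writer).
#' @return A `fingerprint_set` (reader); `path` invisibly (writer).
#' @export
read_descriptor_csv <- function(path) {
  if (!file.exists(path)) abort_config(paste0("file not found: ", path))
  d <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE, show_col_types = FALSE)
  if (ncol(d) != fingerprint_length() + 1L) {
    abort_data(sprintf(
      "descriptor dialect error: expected 1 id column + %d feature columns, found %d total.",
      fingerprint_length(), ncol(d)))
  }
  ids <- as.character(d[[1]])
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(d[, -1])), nrow = nrow(d))
  )
  bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_data(sprintf(
      "non-binary fingerprint cell at data row %d, column %s (value %s).",
      bad[1, 1], names(d)[bad[1, 2] + 1L],
      as.character(d[bad[1, 1], bad[1, 2] + 1L])))
  }
  fingerprint_set(m, ids)
}

#' @rdname read_descriptor_csv
#' @export
write_descriptor_csv <- function(fp, path) {
  stopifnot(inherits(fp, "fingerprint_set"))
  d <- as_tibble(as.data.frame(unclass(fp)))
  d <- dplyr::bind_cols(tibble(Name = rownames(fp)), d)
  readr::write_csv(d, path)
  invisible(path)
}

#' Feature matrix: fingerprints aligned to curated logS targets
#'
#' Pairs each non-censored curated record with its fingerprint, in
#' deterministic (compound-id-sorted) row order, and carries molecular
#' weights along for category-level evaluation. Missing fingerprints are
#' reported exhaustively.
#'
#' @param fingerprints A `fingerprint_set`.
#' @param dataset A `curated_tbl` (censored records are excluded here).
#' @return A `feature_matrix`: list with `x` (n x 881 double matrix), `y`
#'   (logS), `ids`, `mw`.
#' @export
align_features <- function(fingerprints, dataset) {
  stopifnot(inherits(fingerprints, "fingerprint_set"))
  rec <- as_tibble(dataset)
  rec <- rec[!rec$censored & is.finite(rec$log_s), ]
  if (nrow(rec) == 0) abort_data("no non-censored records with finite logS to align.")
  rec <- rec[order(rec$compound_id), ]
  missing <- setdiff(rec$compound_id, rownames(fingerprints))
  if (length(missing) > 0) {
    abort_data(paste0("missing fingerprints for ", length(missing),
                      " compound(s): ", paste(missing, collapse = ", ")))
  }
  x <- unclass(fingerprints)[rec$compound_id, , drop = FALSE]
  feature_matrix(x, rec$log_s, rec$compound_id, rec$molecular_weight)
}

#' @rdname align_features
#' @param x Binary matrix (n x 881) of fingerprint bits.
#' @param y Numeric logS targets, aligned to rows of `x`.
#' @param ids Compound ids.
#' @param mw Molecular weights (g/mol), `NA` allowed.
#' @export
feature_matrix <- function(x, y, ids = NULL, mw = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != fingerprint_length()) {
    abort_data(sprintf("feature matrix must have %d columns; got %d.",
                       fingerprint_length(), ncol(x)))
  }
  new_feature_matrix(x, y, ids, mw)
}

# width-agnostic constructor (models accept any input_length; the exported
# constructor enforces the 881-bit fingerprint contract)
new_feature_matrix <- function(x, y, ids = NULL, mw = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (length(y) != n) abort_data("row count must equal target count.")
  if (any(!is.finite(y))) abort_data("targets must be finite (censored records are excluded upstream).")
  ids <- ids %||% sprintf("row%05d", seq_len(n))
  mw <- mw %||% rep(NA_real_, n)
  structure(list(x = x, y = as.numeric(y), ids = as.character(ids),
                 mw = as.numeric(mw)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("# Feature matrix: %d compounds x %d bits; logS in [%.2f, %.2f]\n",
              nrow(x$x), ncol(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' Subset a feature matrix by row indices
#'
#' Used with [split_train_test()] and [make_folds()] to carve training and
#' held-out sets out of an aligned feature matrix.
#'
#' @param fm A `feature_matrix`.
#' @param idx Integer row indices.
#' @return The subsetted `feature_matrix`.
#' @export
fm_subset <- function(fm, idx) {
  new_feature_matrix(fm$x[idx, , drop = FALSE], fm$y[idx], fm$ids[idx],
                     fm$mw[idx])
}
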