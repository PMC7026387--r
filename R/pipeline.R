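#' Column mapping for raw compound tables
#'
#' Describes which columns of a delimited compound table hold the SMILES
#' string, the solubility value, its unit, and (optionally) a compound id and
#' a molecular weight. Defaults follow the common `smiles`, `solubility`,
#' `unit`, `id` layout.
#'
#' @param smiles,value,unit Column names (mandatory columns).
#' @param id Optional id column; when absent, stable row ids are generated.
#' @param molecular_weight Optional molecular-weight column (g/mol). When a
#'   chemistry backend is used, missing weights are computed from structure.
#' @return A `format_config` list.
#' @export
format_config <- function(smiles = "smiles", value = "solubility",
                          unit = "unit", id = "id",
                          molecular_weight = NULL) {
  structure(list(smiles = smiles, value = value, unit = unit, id = id,
                 molecular_weight = molecular_weight),
            class = "format_config")
}

new_curated_tbl <- function(records, provenance) {
  out <- as_tibble(records)
  attr(out, "provenance") <- as_tibble(provenance)
  class(out) <- c("curated_tbl", class(out))
  out
}

#' Provenance log of a curated compound table
#'
#' Every curation stage appends one row per conversion, exclusion or
#' deduplication decision, so that record counts reconcile exactly:
#' rows in = rows out + logged removals.
#'
#' @param x A `curated_tbl`.
#' @return A tibble with columns `compound_id`, `stage`, `action`, `detail`.
#' @export
provenance <- function(x) {
  p <- attr(x, "provenance")
  if (is.null(p)) {
    p <- tibble(compound_id = character(), stage = character(),
                action = character(), detail = character())
  }
  p
}

log_provenance <- function(x, compound_id, stage, action, detail) {
  p <- dplyr::bind_rows(provenance(x),
                        tibble(compound_id = as.character(compound_id),
                               stage = stage, action = action,
                               detail = detail))
  attr(x, "provenance") <- p
  x
}

#' Parse a raw compound table
#'
#' Reads a delimited file of compounds with experimental solubility values
#' and builds the raw (pre-curation) dataset. Values are validated row by
#' row: negative or zero solubilities and unrecognised units are rejected
#' with a logged reason rather than silently dropped. A value written as
#' `"<x"` marks a below-detection-limit (censored) measurement retained with
#' `censored = TRUE`.
#'
#' @param path Path to a CSV (or TSV, by extension) file.
#' @param format A [format_config()] column mapping.
#' @return A `curated_tbl` (tibble of records plus a provenance log, see
#'   [provenance()]). Columns: `compound_id`, `smiles`, `canonical_smiles`,
#'   `inchikey`, `solubility_value`, `solubility_unit`, `molecular_weight`,
#'   `log_s`, `censored`.
#' @export
parse_compound_table <- function(path, format = format_config()) {
  if (!file.exists(path)) abort_config(paste0("file not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- tryCatch(
    readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                      progress = FALSE, show_col_types = FALSE),
    error = function(e) abort_data(paste0("could not read ", path, ": ",
                                          conditionMessage(e)))
  )
  if (nrow(raw) == 0) abort_data(paste0("empty dataset: ", path, " has no data rows."))
  for (col in c("smiles", "value", "unit")) {
    nm <- format[[col]]
    if (!nm %in% names(raw)) {
      abort_config(paste0("missing mandatory column `", nm, "` (maps to ", col,
                          "); found: ", paste(names(raw), collapse = ", ")))
    }
  }
  ids <- if (!is.null(format$id) && format$id %in% names(raw)) {
    as.character(raw[[format$id]])
  } else {
    sprintf("row%04d", seq_len(nrow(raw)))
  }
  mw <- if (!is.null(format$molecular_weight) &&
            format$molecular_weight %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[format$molecular_weight]]))
  } else {
    rep(NA_real_, nrow(raw))
  }
  val_raw <- trimws(as.character(raw[[format$value]]))
  censored <- grepl("^<", val_raw)
  val <- suppressWarnings(as.numeric(sub("^<", "", val_raw)))
  unit_raw <- as.character(raw[[format$unit]])
  unit <- ifelse(unit_raw %in% solubility_units(), unit_raw, parse_unit(unit_raw))

  rec <- tibble(
    compound_id = ids,
    smiles = as.character(raw[[format$smiles]]),
    canonical_smiles = NA_character_,
    inchikey = NA_character_,
    solubility_value = val,
    solubility_unit = unit,
    molecular_weight = mw,
    log_s = NA_real_,
    censored = censored
  )

  reason <- rep(NA_character_, nrow(rec))
  reason[is.na(rec$smiles) | !nzchar(trimws(rec$smiles))] <- "missing SMILES"
  reason[is.na(val)] <- "unparseable solubility value"
  reason[!is.na(val) & val < 0] <- "negative solubility"
  reason[!is.na(val) & val == 0 & !censored] <- "zero solubility (logS undefined)"
  reason[is.na(unit)] <- "unknown unit"

  keep <- is.na(reason)
  out <- new_curated_tbl(rec[keep, ], NULL)
  if (any(!keep)) {
    out <- log_provenance(out, ids[!keep], "parse", "rejected_row",
                          reason[!keep])
  }
  out <- log_provenance(out, "*", "parse", "read",
                        sprintf("%d rows read, %d accepted (%s)",
                                nrow(rec), sum(keep), path))
  out
}

#' Canonicalize structures and derive InChIKeys
#'
#' Populates `canonical_smiles`, `inchikey` and (when not supplied in the
#' input) `molecular_weight` using a chemistry backend, and records the
#' backend identity in the provenance log. Records whose SMILES the backend
#' rejects are excluded and logged.
#'
#' @param x A `curated_tbl`.
#' @param backend A [chem_backend()] object.
#' @return The updated `curated_tbl`.
#' @export
canonicalize_and_key <- function(x, backend = chem_backend()) {
  stopifnot(inherits(x, "curated_tbl"))
  if (nrow(x) == 0) return(x)
  uniq <- unique(x$smiles)
  res <- backend$resolve(uniq)
  idx <- match(x$smiles, res$smiles)
  prov <- provenance(x)
  x$canonical_smiles <- res$canonical_smiles[idx]
  x$inchikey <- res$inchikey[idx]
  need_mw <- is.na(x$molecular_weight)
  x$molecular_weight[need_mw] <- res$molecular_weight[idx][need_mw]
  attr(x, "provenance") <- prov

  bad <- is.na(x$canonical_smiles) | is.na(x$inchikey)
  out <- new_curated_tbl(x[!bad, ], provenance(x))
  if (any(bad)) {
    out <- log_provenance(out, x$compound_id[bad], "canonicalize",
                          "excluded_invalid_smiles",
                          paste0("backend rejected SMILES: ", x$smiles[bad]))
  }
  log_provenance(out, "*", "canonicalize", "backend", backend$name)
}

#' Derive logS for every non-censored record
#'
#' Applies [convert_to_logs()] per record. Mass-based units without a
#' molecular weight are a hard error (run [canonicalize_and_key()] first or
#' supply a weight column). Censored records keep `log_s = NA`.
#'
#' @param x A `curated_tbl`.
#' @return The updated `curated_tbl`.
#' @export
compute_log_s <- function(x) {
  stopifnot(inherits(x, "curated_tbl"))
  open <- !x$censored
  if (any(open)) {
    mass <- x$solubility_unit[open] != "mol_per_L"
    mw_missing <- mass & (!is.finite(x$molecular_weight[open]))
    if (any(mw_missing)) {
      abort_data(paste0(
        "molecular weight required for mass-unit conversion but missing for: ",
        paste(x$compound_id[open][mw_missing], collapse = ", ")
      ))
    }
    x$log_s[open] <- convert_to_logs(x$solubility_value[open],
                                     x$solubility_unit[open],
                                     x$molecular_weight[open])
  }
  log_provenance(x, "*", "convert", "log_s",
                 sprintf("logS derived for %d non-censored records", sum(open)))
}

#' Remove duplicate structures by InChIKey
#'
#' Non-censored records sharing an InChIKey are collapsed to one record:
#' groups whose logS values agree keep the first occurrence; conflicting
#' groups keep the first occurrence carrying the median logS of the group
#' (robust to a single bad measurement), with every source value logged.
#' A censored record whose InChIKey matches a kept non-censored record is
#' removed; censored-only duplicate groups keep their first record.
#' Idempotent.
#'
#' @param x A `curated_tbl` with `inchikey` populated (and `log_s` for
#'   non-censored records).
#' @return The deduplicated `curated_tbl`.
#' @export
deduplicate <- function(x) {
  stopifnot(inherits(x, "curated_tbl"))
  if (any(is.na(x$inchikey))) {
    abort_data("deduplicate() requires `inchikey` on all records; run canonicalize_and_key() first.")
  }
  keep <- rep(TRUE, nrow(x))
  out <- x
  for (key in unique(x$inchikey[duplicated(x$inchikey)])) {
    g <- which(x$inchikey == key)
    open <- g[!x$censored[g]]
    cens <- g[x$censored[g]]
    if (length(open) > 0) {
      first <- open[1]
      drop <- setdiff(g, first)
      vals <- x$log_s[open]
      if (length(open) > 1 && diff(range(vals)) > 1e-12) {
        med <- median(vals)
        out$log_s[first] <- med
        out <- log_provenance(out, x$compound_id[first], "deduplicate",
                              "median_of_conflicting_duplicates",
                              paste0("source logS {",
                                     paste(signif(vals, 8), collapse = ", "),
                                     "} -> median ", signif(med, 8)))
      }
    } else {
      first <- cens[1]
      drop <- setdiff(g, first)
    }
    if (length(drop) > 0) {
      keep[drop] <- FALSE
      out <- log_provenance(out, x$compound_id[drop], "deduplicate",
                            "removed_duplicate",
                            paste0("inchikey ", key, " kept as ",
                                   x$compound_id[first]))
    }
  }
  new_curated_tbl(out[keep, ], provenance(out))
}

#' Run the full curation pipeline on a raw table
#'
#' Convenience wrapper:
#' `parse_compound_table() |> canonicalize_and_key() |> compute_log_s() |> deduplicate()`.
#'
#' @inheritParams parse_compound_table
#' @inheritParams canonicalize_and_key
#' @return A curated `curated_tbl`.
#' @export
curate_compounds <- function(path, format = format_config(),
                             backend = chem_backend()) {
  parse_compound_table(path, format) |>
    canonicalize_and_key(backend) |>
    compute_log_s() |>
    deduplicate()
}

#' Write / read the curated table
#'
#' The curated CSV carries `compound_id`, `canonical_smiles`, `inchikey`,
#' `log_s`, `censored` and `molecular_weight`. The provenance log is written
#' as line-oriented JSON (one object per line).
#'
#' @param x A `curated_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly (writers); a `curated_tbl` (reader).
#' @export
write_curated_csv <- function(x, path) {
  cols <- c("compound_id", "canonical_smiles", "inchikey", "log_s",
            "censored", "molecular_weight")
  readr::write_csv(as_tibble(x)[, cols], path)
  invisible(path)
}

#' @rdname write_curated_csv
#' @export
read_curated_csv <- function(path) {
  if (!file.exists(path)) abort_config(paste0("file not found: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         compound_id = "c", canonical_smiles = "c",
                         inchikey = "c", log_s = "d", censored = "l",
                         molecular_weight = "d"))
  if (nrow(d) == 0) abort_data(paste0("empty curated table: ", path))
  d$smiles <- d$canonical_smiles
  d$solubility_value <- 10^d$log_s
  d$solubility_unit <- "mol_per_L"
  new_curated_tbl(d[, c("compound_id", "smiles", "canonical_smiles",
                        "inchikey", "solubility_value", "solubility_unit",
                        "molecular_weight", "log_s", "censored")], NULL)
}

#' @rdname write_curated_csv
#' @export
write_provenance_log <- function(x, path) {
  p <- provenance(x)
  lines <- vapply(seq_len(nrow(p)), function(i) {
    jsonlite::toJSON(as.list(p[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.curated_tbl <- function(x, ...) {
  n_cens <- sum(x$censored)
  cat(sprintf("# Curated compound table: %d records (%d censored), %d provenance entries\n",
              nrow(x), n_cens, nrow(provenance(x))))
  NextMethod()
}
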