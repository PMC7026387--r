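#' Chemistry backends for canonicalization and structure keys
#'
#' The curation pipeline delegates SMILES canonicalization, InChIKey
#' derivation and molecular-weight calculation to a pluggable backend. A
#' backend is a list with a `name` string and a `resolve` function mapping a
#' character vector of SMILES to a tibble with columns `smiles`,
#' `canonical_smiles`, `inchikey` and `molecular_weight`; invalid SMILES are
#' reported as `NA` rows. Canonical forms are toolkit-specific: the contract
#' is internal consistency within one backend, not identity across toolkits.
#'
#' `chem_backend_openbabel()` uses Open Babel through the ChemmineOB package
#' and is the default whenever ChemmineOB is installed.
#'
#' `chem_backend_mock()` is a synthetic, chemistry-free stand-in for plumbing
#' tests: it returns the input string as its own "canonical" form, derives a
#' deterministic InChIKey-shaped hash from the string, reports no molecular
#' weight, and flags empty strings or strings containing `"INVALID"` as
#' invalid. Two spellings of the same molecule do NOT collapse under it.
#'
#' @param backend A backend object, as returned by one of these constructors.
#' @return A chem backend object (list with `name` and `resolve`).
#' @export
chem_backend <- function() {
  if (requireNamespace("ChemmineOB", quietly = TRUE) &&
      requireNamespace("ChemmineR", quietly = TRUE)) {
    chem_backend_openbabel()
  } else {
    warn("ChemmineOB/ChemmineR not installed; falling back to the synthetic mock backend.")
    chem_backend_mock()
  }
}

#' @rdname chem_backend
#' @export
chem_backend_openbabel <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE) ||
      !requireNamespace("ChemmineR", quietly = TRUE)) {
    abort_config("chem_backend_openbabel() requires the ChemmineOB and ChemmineR packages.")
  }
  resolve <- function(smiles) {
    one <- function(s) {
      if (is.na(s) || !nzchar(trimws(s))) {
        return(tibble(canonical_smiles = NA_character_,
                      inchikey = NA_character_,
                      molecular_weight = NA_real_))
      }
      can <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                      error = function(e) "")
      key <- tryCatch(ChemmineOB::convertFormat("SMI", "INCHIKEY", s),
                      error = function(e) "")
      can <- sub("[\t\n ].*$", "", can)
      key <- trimws(sub("\n.*$", "", key))
      if (!nzchar(can) || !is_inchikey(key)) {
        return(tibble(canonical_smiles = NA_character_,
                      inchikey = NA_character_,
                      molecular_weight = NA_real_))
      }
      mw <- tryCatch(
        ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", s, identity))$MW,
        error = function(e) NA_real_
      )
      tibble(canonical_smiles = can, inchikey = key,
             molecular_weight = as.numeric(mw))
    }
    out <- purrr::map_dfr(smiles, one)
    out$smiles <- smiles
    out[, c("smiles", "canonical_smiles", "inchikey", "molecular_weight")]
  }
  structure(list(name = "openbabel/ChemmineOB", resolve = resolve),
            class = "chem_backend")
}

#' @rdname chem_backend
#' @export
chem_backend_mock <- function() {
  resolve <- function(smiles) {
    valid <- !is.na(smiles) & nzchar(trimws(smiles)) &
      !grepl("INVALID", smiles, fixed = TRUE)
    tibble(
      smiles = smiles,
      canonical_smiles = ifelse(valid, smiles, NA_character_),
      inchikey = ifelse(valid, vapply(smiles, mock_inchikey, character(1)),
                        NA_character_),
      molecular_weight = NA_real_
    )
  }
  structure(list(name = "mock (synthetic, no chemistry)", resolve = resolve),
            class = "chem_backend")
}

is_inchikey <- function(x) {
  grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

# deterministic InChIKey-shaped hash of an arbitrary string (mock backend
# and synthetic data only; collides exactly when strings are equal in practice)
mock_inchikey <- function(s) {
  v <- utf8ToInt(s)
  h <- numeric(26)
  state <- 7
  for (i in seq_along(v)) {
    state <- (state * 31 + v[i] * (i %% 97 + 1)) %% 2147483563
    h[(i - 1) %% 26 + 1] <- (h[(i - 1) %% 26 + 1] + state) %% 26
  }
  # keep mixing so short strings fill all positions
  for (j in seq_len(26)) {
    state <- (state * 48271) %% 2147483563
    h[j] <- (h[j] + state) %% 26
  }
  letters26 <- LETTERS[h + 1L]
  paste0(paste(letters26[1:14], collapse = ""), "-",
         paste(letters26[15:24], collapse = ""), "-", letters26[25])
}
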