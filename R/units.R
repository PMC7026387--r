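#' Supported solubility units
#'
#' The units accepted by the curation pipeline. Mass-based units require a
#' molecular weight to reach mol/L.
#'
#' @return Character vector of canonical unit codes.
#' @export
solubility_units <- function() {
  c("ug_per_mL", "mg_per_mL", "mg_per_L", "g_per_L", "mol_per_L")
}

# normalise free-text unit strings ("mg/mL", "µg/ml", "M", ...) to the enum;
# returns NA for unrecognised strings
parse_unit <- function(unit) {
  u <- tolower(gsub("[[:space:]]", "", as.character(unit)))
  u <- gsub("µ|μ", "u", u) # micro signs -> "u"
  lookup <- c(
    "ug/ml" = "ug_per_mL", "ug_per_ml" = "ug_per_mL",
    "mg/ml" = "mg_per_mL", "mg_per_ml" = "mg_per_mL",
    "mg/l"  = "mg_per_L",  "mg_per_l"  = "mg_per_L",
    "g/l"   = "g_per_L",   "g_per_l"   = "g_per_L",
    "mol/l" = "mol_per_L", "mol_per_l" = "mol_per_L", "m" = "mol_per_L"
  )
  out <- unname(lookup[u])
  out
}

#' Convert a solubility measurement to logS (log10 mol/L)
#'
#' Mass-based units are converted to g/L first, then divided by the molecular
#' weight to obtain mol/L; the result is `log10()` of that molar
#' concentration. Vectorised over all three arguments.
#'
#' @param value Positive solubility value(s) in `unit`.
#' @param unit One of [solubility_units()], or a recognisable spelling such
#'   as `"mg/mL"`.
#' @param molecular_weight Molecular weight in g/mol. Required (and checked)
#'   for every mass-based unit; ignored for `mol_per_L`.
#'
#' @return Numeric vector of logS values (log10 of solubility in mol/L).
#' @examples
#' convert_to_logs(1, "mol_per_L")            # 0
#' convert_to_logs(1, "mg_per_mL", 100)       # -2
#' convert_to_logs(100, "ug_per_mL", 100)     # -3
#' @export
convert_to_logs <- function(value, unit, molecular_weight = NULL) {
  value <- as.numeric(value)
  if (any(!is.finite(value))) {
    abort_data("`value` must be finite.")
  }
  if (any(value < 0)) {
    abort_data("negative solubility: logS is undefined for values < 0.")
  }
  if (any(value == 0)) {
    abort_data(paste0(
      "zero solubility: logS is undefined at 0. Below-detection-limit ",
      "measurements must be flagged as censored, not converted."
    ))
  }
  u <- ifelse(unit %in% solubility_units(), unit, parse_unit(unit))
  if (any(is.na(u))) {
    bad <- unique(unit[is.na(u)])
    abort_data(paste0("unknown solubility unit(s): ",
                      paste(bad, collapse = ", ")))
  }
  # to g/L for the mass units (note 1 mg/mL = 1 g/L, 1 ug/mL = 1 mg/L)
  g_per_l <- c(ug_per_mL = 1e-3, mg_per_mL = 1, mg_per_L = 1e-3, g_per_L = 1)
  mass <- u != "mol_per_L"
  mol_l <- numeric(length(value))
  mol_l[!mass] <- value[!mass]
  if (any(mass)) {
    if (is.null(molecular_weight)) {
      abort_data("molecular weight is required to convert mass-based units.")
    }
    mw <- rep_len(as.numeric(molecular_weight), length(value))
    if (any(!is.finite(mw[mass])) || any(mw[mass] <= 0)) {
      abort_data("molecular weight must be a positive finite number for every mass-unit record.")
    }
    mol_l[mass] <- value[mass] * g_per_l[u[mass]] / mw[mass]
  }
  log10(mol_l)
}

# inverse of convert_to_logs, used by the round-trip property tests
logs_to_value <- function(log_s, unit, molecular_weight = NULL) {
  u <- ifelse(unit %in% solubility_units(), unit, parse_unit(unit))
  mol_l <- 10^log_s
  g_per_l <- c(ug_per_mL = 1e-3, mg_per_mL = 1, mg_per_L = 1e-3, g_per_L = 1)
  out <- mol_l
  mass <- u != "mol_per_L"
  if (any(mass)) {
    mw <- rep_len(as.numeric(molecular_weight), length(log_s))
    out[mass] <- mol_l[mass] * mw[mass] / g_per_l[u[mass]]
  }
  out
}
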