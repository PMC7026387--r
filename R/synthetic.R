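#' Planted ground truth for synthetic fingerprint data
#'
#' Defines a recoverable substructure-to-solubility mechanism: a sparse
#' additive weight per fingerprint bit (optionally plus pairwise
#' interactions), an intercept, Gaussian noise, and a bit-occupancy model
#' with realistic density and optional block correlation (adjacent bits
#' co-occurring, as real substructure keys do).
#'
#' Defaults emulate a drug-like logS dataset: 40 active bits with weights
#' uniform in +-0.8 log units, intercept -4 (typical median logS of drug-like
#' sets), bit density 0.12, replicate-level noise 0.5 log units.
#'
#' @param n_active Number of bits with non-zero additive weight.
#' @param weight_range Range of the active additive weights.
#' @param intercept Baseline logS.
#' @param n_pairwise Number of pairwise (bit i AND bit j) interaction terms.
#' @param pairwise_weight_range Range of interaction weights.
#' @param noise_sd Gaussian noise standard deviation (log units).
#' @param bit_density Expected fraction of set bits per compound.
#' @param block_correlated Draw bits with block-level co-occurrence.
#' @param block_size Bits per correlated block.
#' @param block_active_prob Probability a block is "present" in a compound.
#' @param logs_range Plausible range the emitted logS is clipped to.
#' @param seed Integer seed fixing the drawn weights (and, by default,
#'   generation).
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(n_active = 40L, weight_range = c(-0.8, 0.8),
                            intercept = -4, n_pairwise = 0L,
                            pairwise_weight_range = c(-0.4, 0.4),
                            noise_sd = 0.5, bit_density = 0.12,
                            block_correlated = TRUE, block_size = 8L,
                            block_active_prob = 0.25,
                            logs_range = c(-10, 1), seed = 1L) {
  p <- fingerprint_length()
  if (n_active < 0L || n_active > p) abort_config("n_active must lie in [0, 881].")
  if (noise_sd < 0) abort_config("noise_sd must be non-negative.")
  if (!(bit_density > 0 && bit_density < 1)) {
    abort_config("bit_density must lie strictly between 0 and 1.")
  }
  withr::with_seed(as.integer(seed), {
    active <- sort(sample.int(p, n_active))
    w <- numeric(p)
    w[active] <- runif(n_active, weight_range[1], weight_range[2])
    pairs <- if (n_pairwise > 0L) {
      ij <- matrix(sample.int(p, 2L * n_pairwise, replace = FALSE), ncol = 2L)
      tibble(i = pmin(ij[, 1], ij[, 2]), j = pmax(ij[, 1], ij[, 2]),
             weight = runif(n_pairwise, pairwise_weight_range[1],
                            pairwise_weight_range[2]))
    } else {
      tibble(i = integer(), j = integer(), weight = numeric())
    }
  })
  structure(list(bit_weights = w, active_bits = active, intercept = intercept,
                 pairwise_terms = pairs, noise_sd = noise_sd,
                 bit_density = bit_density,
                 block_correlated = isTRUE(block_correlated),
                 block_size = as.integer(block_size),
                 block_active_prob = block_active_prob,
                 logs_range = logs_range, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "# Synthetic ground truth: %d active bits (+%d pairwise), intercept %.2f, noise sd %.2f, bit density %.2f\n",
    length(x$active_bits), nrow(x$pairwise_terms), x$intercept, x$noise_sd,
    x$bit_density))
  invisible(x)
}

#' Analytic moments of a planted synthetic mechanism
#'
#' Expected mean and variance of the generated logS under the Bernoulli bit
#' model (clipping ignored), including the covariance contribution of
#' block-correlated bits. The variance gives the recovery ceiling: no
#' predictor can exceed R-squared of
#' `1 - noise_sd^2 / var` on data from this mechanism.
#'
#' @param truth A [synthetic_truth()].
#' @return List with `mean` and `var`.
#' @export
synthetic_moments <- function(truth) {
  d <- truth$bit_density
  w <- truth$bit_weights[truth$active_bits]
  mu <- truth$intercept + sum(w) * d
  v <- sum(w^2) * d * (1 - d) + truth$noise_sd^2
  # block correlation adds positive covariance between same-block bits
  if (truth$block_correlated && length(truth$active_bits) > 1) {
    blk <- (truth$active_bits - 1L) %/% truth$block_size
    a <- truth$block_active_prob
    p_lo <- d / 4
    p_hi <- (d - (1 - a) * p_lo) / a
    for (b in unique(blk[duplicated(blk)])) {
      ww <- w[blk == b]
      # Cov(bi, bj) for same-block bits: E[bi bj] - d^2
      ebb <- a * p_hi^2 + (1 - a) * p_lo^2
      cv <- ebb - d^2
      v <- v + (sum(ww)^2 - sum(ww^2)) * cv
    }
  }
  list(mean = mu, var = v)
}

#' Generate a synthetic fingerprint dataset
#'
#' Draws `n` compounds' 881-bit fingerprints under the truth's occupancy
#' model, computes logS as intercept + additive bit contributions (+ optional
#' pairwise terms) + Gaussian noise, clips it to the plausible range, and
#' attaches synthetic molecular weights (Uniform(150, 600) g/mol) so
#' category-level evaluation works. Fully seed-deterministic.
#'
#' @param n Number of compounds (>= 1).
#' @param truth A [synthetic_truth()].
#' @param seed Integer seed; defaults to the truth's seed.
#' @return List with `features` (a `feature_matrix`), `compounds` (a
#'   `curated_tbl` flagged as synthetic) and `truth`.
#' @export
generate_dataset <- function(n, truth = synthetic_truth(), seed = truth$seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort_data("n must be at least 1.")
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- fingerprint_length()
  withr::with_seed(as.integer(seed), {
    d <- truth$bit_density
    if (truth$block_correlated) {
      a <- truth$block_active_prob
      p_lo <- d / 4
      p_hi <- (d - (1 - a) * p_lo) / a
      n_blocks <- ceiling(p / truth$block_size)
      z <- matrix(rbinom(n * n_blocks, 1L, a), n, n_blocks)
      blk <- rep(seq_len(n_blocks), each = truth$block_size)[seq_len(p)]
      prob <- p_lo + z[, blk, drop = FALSE] * (p_hi - p_lo)
      bits <- matrix(as.integer(runif(n * p) < prob), n, p)
    } else {
      bits <- matrix(rbinom(n * p, 1L, d), n, p)
    }
    signal <- truth$intercept + as.numeric(bits %*% truth$bit_weights)
    if (nrow(truth$pairwise_terms) > 0) {
      for (r in seq_len(nrow(truth$pairwise_terms))) {
        signal <- signal + truth$pairwise_terms$weight[r] *
          bits[, truth$pairwise_terms$i[r]] * bits[, truth$pairwise_terms$j[r]]
      }
    }
    y <- signal + rnorm(n, 0, truth$noise_sd)
    y <- pmin(pmax(y, truth$logs_range[1]), truth$logs_range[2])
    mw <- runif(n, 150, 600)
  })
  ids <- sprintf("SYN%05d", seq_len(n))
  fm <- feature_matrix(bits, y, ids, mw)
  compounds <- new_curated_tbl(tibble(
    compound_id = ids,
    smiles = NA_character_,
    canonical_smiles = NA_character_,
    inchikey = vapply(paste0("synthetic-", seed, "-", ids), mock_inchikey,
                      character(1)),
    solubility_value = 10^y,
    solubility_unit = "mol_per_L",
    molecular_weight = mw,
    log_s = y,
    censored = FALSE
  ), NULL)
  compounds <- log_provenance(compounds, "*", "synthetic", "generated",
                              sprintf("n=%d, seed=%d (synthetic, planted mechanism)",
                                      n, as.integer(seed)))
  list(features = fm, compounds = compounds, truth = truth)
}

#' Write the end-to-end smoke-test fixture
#'
#' Emits a fixed 20-row raw compound table (mixed units, one duplicate
#' structure under two SMILES spellings with conflicting values, one
#' censored "below detection limit" row, one malformed SMILES) plus a
#' matching 881-bit descriptor CSV with deterministic synthetic bits.
#' Re-generation is byte-identical. Curation keeps 18 records: the
#' duplicate collapses, the malformed row is excluded, the censored row is
#' retained flagged.
#'
#' @param dir Writable directory.
#' @return Named character vector of the two file paths, invisibly.
#' @export
generate_fixture_tables <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  probe <- file.path(dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE)
  if (!ok) abort_config(paste0("directory not writable: ", dir))
  unlink(probe)

  tab <- fixture_compound_table()
  raw_path <- file.path(dir, "fixture_compounds.csv")
  readr::write_csv(tab, raw_path)

  bits <- withr::with_seed(20200211L, {
    matrix(rbinom(nrow(tab) * fingerprint_length(), 1L, 0.12),
           nrow(tab), fingerprint_length())
  })
  fp <- fingerprint_set(bits, tab$id)
  fp_path <- file.path(dir, "fixture_descriptors.csv")
  write_descriptor_csv(fp, fp_path)
  invisible(c(compounds = raw_path, descriptors = fp_path))
}

# the fixed 20-row fixture: 17 unique valid compounds + 1 duplicate spelling
# of ethanol (conflicting value -> median rule) + 1 censored + 1 malformed
fixture_compound_table <- function() {
  tibble(
    id = sprintf("FIX%02d", 1:20),
    smiles = c(
      "CCO",                 # ethanol
      "OCC",                 # ethanol again, different spelling (duplicate)
      "c1ccccc1",            # benzene
      "Cc1ccccc1",           # toluene
      "Oc1ccccc1",           # phenol
      "CC(=O)Oc1ccccc1C(=O)O",        # aspirin
      "Cn1cnc2c1c(=O)n(C)c(=O)n2C",   # caffeine
      "CC(C)Cc1ccc(cc1)C(C)C(=O)O",   # ibuprofen
      "CCCCCC",              # hexane
      "CCCCCCCCO",           # octanol
      "OCC(O)CO",            # glycerol
      "CC(=O)Nc1ccc(O)cc1",  # paracetamol
      "Clc1ccccc1",          # chlorobenzene
      "CCOC(=O)C",           # ethyl acetate
      "c1ccc2ccccc2c1",      # naphthalene
      "CN(C)C(=O)c1ccccc1",  # N,N-dimethylbenzamide
      "CCN(CC)CC",           # triethylamine
      "CC(C)O",              # isopropanol
      "c1ccc2c(c1)ccc3ccccc23",  # phenanthrene, censored row
      "C1CC"                 # malformed: unclosed ring
    ),
    solubility = c(
      "1.2",      # CCO, mol/L
      "92.1",     # OCC, g/L -> ~2 mol/L: conflicts with FIX01
      "1.79",     # benzene g/L
      "0.52",     # toluene g/L
      "82.8",     # phenol g/L
      "3000",     # aspirin mg/L
      "21.6",     # caffeine mg/mL
      "21",       # ibuprofen mg/L
      "9.5",      # hexane mg/L
      "0.3",      # octanol mg/mL
      "10",       # glycerol mol/L... freely miscible, nominal
      "14",       # paracetamol mg/mL
      "499",      # chlorobenzene mg/L
      "80",       # ethyl acetate g/L
      "31.6",     # naphthalene mg/L
      "2.8",      # dimethylbenzamide g/L
      "0.07",     # triethylamine mol/L
      "18",       # isopropanol mol/L
      "<0.0011",  # phenanthrene: below detection limit (censored)
      "1"         # malformed row; value irrelevant
    ),
    unit = c("mol/L", "g/L", "g/L", "g/L", "g/L", "mg/L", "mg/mL", "mg/L",
             "mg/L", "mg/mL", "mol/L", "mg/mL", "mg/L", "g/L", "mg/L",
             "g/L", "mol/L", "mol/L", "mg/L", "mol/L")
  )
}
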