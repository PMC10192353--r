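#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
NULL

# Three-state genotype vocabulary; strict and uppercase throughout.
GENOTYPE_LEVELS <- c("REF", "HET", "VAR")

# Predicted-effect vocabulary for induced coding/splice mutations.
EFFECT_CLASSES <- c(
  "probably_null", "probably_damaging", "possibly_damaging", "probably_benign"
)

# Damaging subset used by the genome-saturation metric.
DAMAGING_CLASSES <- c("probably_null", "probably_damaging")

LINKAGE_MODELS <- c("recessive", "semidominant", "dominant")

# Mouse autosome lengths (GRCm38, Mbp, rounded); used only to place
# simulated mutation positions on a realistic coordinate system.
MOUSE_AUTOSOME_MBP <- c(
  195, 182, 160, 157, 152, 150, 145, 129, 125, 131,
  122, 120, 120, 125, 104, 98, 95, 91, 61
)

abort_arg <- function(msg, ...) {
  abort(msg, class = "fundusmap_error_arg", ...)
}

abort_data <- function(msg, ...) {
  abort(msg, class = "fundusmap_error_data", ...)
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != trunc(x) || x < min) {
    abort_arg(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_prob_vector <- function(p, name, n, tol = 1e-9) {
  if (!is.numeric(p) || length(p) != n || anyNA(p) || any(p < 0)) {
    abort_arg(sprintf("`%s` must be %d non-negative probabilities.", name, n))
  }
  if (abs(sum(p) - 1) > tol) {
    abort_arg(sprintf("`%s` must sum to 1 (got %.12g).", name, sum(p)))
  }
  p
}

check_genotype_calls <- function(calls, name = "calls") {
  if (length(calls) == 0L) {
    abort_arg(sprintf("`%s` must be a non-empty vector of genotype calls.", name))
  }
  bad <- which(!(calls %in% GENOTYPE_LEVELS))
  if (length(bad) > 0L) {
    abort_data(sprintf(
      "`%s` contains invalid genotype calls (must be REF/HET/VAR): %s at position(s) %s.",
      name,
      paste(unique(calls[bad]), collapse = ", "),
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  as.character(calls)
}

match_model <- function(model) {
  if (length(model) != 1L || !model %in% LINKAGE_MODELS) {
    abort_arg(sprintf(
      "`model` must be one of %s.", paste(LINKAGE_MODELS, collapse = ", ")
    ))
  }
  model
}

# Evaluate `expr` under a transient RNG seed when one is supplied;
# with seed = NULL the ambient RNG stream is used (and advanced).
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    seed <- check_count(seed, "seed")
    withr::with_seed(seed, expr)
  }
}

#' Derive a reproducible child seed from a master seed
#'
#' Simulation drivers fan one master seed out to per-replicate child
#' seeds so that any single replicate can be regenerated in isolation.
#' The rule is `(master + 104729 * index) mod (2^31 - 1)`: a fixed
#' large-prime stride reduced into the 32-bit integer range.
#'
#' @param master Single non-negative integer master seed.
#' @param index Replicate index (non-negative integer).
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(1L, 1:3)
child_seed <- function(master, index) {
  master <- check_count(master, "master")
  if (!is.numeric(index) || anyNA(index) || any(index < 0)) {
    abort_arg("`index` must be non-negative integers.")
  }
  as.integer((master + 104729 * as.numeric(index)) %% 2147483647)
}
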