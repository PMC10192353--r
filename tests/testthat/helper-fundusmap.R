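# Shared fixtures, all built in code.

# A tiny deterministic pedigree for structural tests.
tiny_pedigree <- function(n_sites = 4, n_dams = 2, n_pups = 3, seed = 42) {
  breed_pedigree(mutation_sites(n_sites, seed = seed),
                 n_g2_dams = n_dams, n_g3_per_dam = n_pups,
                 seed = seed + 1)
}

# Hand-assembled Manhattan table for candidate-rule tests.
manual_manhattan <- function(neglog10p, genes = NULL, status = NULL) {
  n <- length(neglog10p)
  tibble::tibble(
    site_id = sprintf("site_%03d", seq_len(n)),
    chromosome = "1",
    position_bp = seq_len(n) * 1e6L,
    gene = genes %||% sprintf("gene_%03d", seq_len(n)),
    best_model = "recessive",
    best_p = 10^(-neglog10p),
    neglog10p = neglog10p,
    n_var = 2L,
    two_var = TRUE,
    status = status %||% rep("ok", n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force two-sided exact p for a 2x2 table: enumerate every
# subset of `k` affected mice among n = m + n_other (m susceptible)
# and accumulate the probability of assignments whose table is as or
# less probable than the observed one. Feasible for small n only.
brute_force_exact_p <- function(a, m, n_other, k) {
  n <- m + n_other
  sets <- utils::combn(n, k)
  susceptible <- seq_len(m)
  obs_prob <- stats::dhyper(a, m, n_other, k)
  hit <- 0
  for (j in seq_len(ncol(sets))) {
    aj <- sum(sets[, j] %in% susceptible)
    if (stats::dhyper(aj, m, n_other, k) <= obs_prob * (1 + 1e-7)) {
      hit <- hit + 1
    }
  }
  hit / ncol(sets)
}

# Monte-Carlo permutation p-value for the OLS slope test. |t| is a
# monotone function of |cor(x, y)|, so the absolute correlation is an
# equivalent (and vectorizable) permutation statistic.
permutation_p <- function(y, x, n_perm, seed) {
  r_obs <- abs(stats::cor(x, y))
  withr::with_seed(seed, {
    perms <- replicate(n_perm, sample(y))
    r <- abs(as.numeric(stats::cor(x, perms)))
    mean(r >= r_obs - 1e-12)
  })
}
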