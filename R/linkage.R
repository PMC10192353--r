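#' Encode genotype calls under an inheritance model
#'
#' The three single-locus regression encodings used by the automated
#' mapper: recessive REF/HET/VAR -> 0/0/1, semidominant -> 0/1/2,
#' dominant -> 0/1/1.
#'
#' @param calls Character vector of REF/HET/VAR calls.
#' @param model One of "recessive", "semidominant", "dominant".
#' @return A numeric vector the same length as `calls`.
#' @export
#' @examples
#' encode_genotypes(c("REF", "HET", "VAR"), "semidominant")
encode_genotypes <- function(calls, model) {
  model <- match_model(model)
  calls <- check_genotype_calls(calls)
  code <- switch(model,
    recessive = c(REF = 0, HET = 0, VAR = 1),
    semidominant = c(REF = 0, HET = 1, VAR = 2),
    dominant = c(REF = 0, HET = 1, VAR = 1)
  )
  unname(code[calls])
}

# Vectorized simple-OLS slope tests: y against each column of X.
# Returns a tibble with beta0, beta1, stat, df, p, status. Columns
# with zero genotype variance (or a constant response) are degenerate.
ols_slope_tests <- function(y, X) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  df <- n - 2L
  xbar <- colMeans(X)
  Sxx <- colSums(X^2) - n * xbar^2
  ybar <- mean(y)
  Syy <- sum(y^2) - n * ybar^2
  Sxy <- as.numeric(crossprod(X, y)) - n * xbar * ybar
  eps <- 1e-12
  degenerate <- Sxx <= eps * pmax(1, xbar^2) | Syy <= eps
  beta1 <- ifelse(degenerate, NA_real_, Sxy / Sxx)
  beta0 <- ifelse(degenerate, NA_real_, ybar - beta1 * xbar)
  sse <- pmax(0, Syy - beta1 * Sxy)
  se <- sqrt(sse / df / Sxx)
  stat <- ifelse(degenerate | se == 0,
                 ifelse(degenerate, NA_real_, Inf * sign(beta1)),
                 beta1 / se)
  p <- 2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)
  # keep p in (0, 1] even for numerically perfect fits
  p <- ifelse(is.na(p), NA_real_, pmax(p, 1e-300))
  tibble(
    beta0 = beta0, beta1 = beta1, stat = stat, df = df, p = p,
    neglog10p = -log10(p),
    status = ifelse(degenerate, "degenerate", "ok")
  )
}

#' Single-locus linkage test of a quantitative phenotype
#'
#' Ordinary least-squares regression of the phenotype on the encoded
#' genotype at one mutation site; the two-sided p-value comes from the
#' t distribution of the slope with n - 2 degrees of freedom. A site
#' whose encoded genotypes (or whose phenotype) carry zero variance is
#' reported as degenerate, never silently given p = 1.
#'
#' @param phenotype Numeric phenotype vector (e.g. 0-8 mouse scores).
#' @param calls REF/HET/VAR genotype calls, same length, n >= 3.
#' @param model One of "recessive", "semidominant", "dominant".
#' @return An object of class `locus_fit` with fields `model`, `n`,
#'   `beta0`, `beta1`, `stat`, `df`, `p`, `neglog10p`, `status`.
#' @export
#' @examples
#' single_locus_test(c(1, 2, 3, 7, 8, 9),
#'                   c("REF", "REF", "REF", "VAR", "VAR", "VAR"),
#'                   "recessive")
single_locus_test <- function(phenotype, calls, model) {
  model <- match_model(model)
  if (length(phenotype) != length(calls)) {
    abort_arg("`phenotype` and `calls` must have equal length.")
  }
  if (length(phenotype) < 3L) {
    abort_arg("at least 3 mice are required for a single-locus test.")
  }
  if (!is.numeric(phenotype) || anyNA(phenotype)) {
    abort_arg("`phenotype` must be numeric with no missing values.")
  }
  x <- encode_genotypes(calls, model)
  row <- ols_slope_tests(phenotype, matrix(x, ncol = 1L))
  structure(
    list(model = model, n = length(phenotype), beta0 = row$beta0,
         beta1 = row$beta1, stat = row$stat, df = row$df, p = row$p,
         neglog10p = row$neglog10p, status = row$status,
         method = "ols"),
    class = "locus_fit"
  )
}

#' @export
print.locus_fit <- function(x, ...) {
  if (x$status == "degenerate") {
    cat(sprintf("<locus_fit> %s model, n = %d: degenerate (zero variance)\n",
                x$model, x$n))
  } else {
    cat(sprintf(
      "<locus_fit> %s model (%s), n = %d: slope %.4g, stat %.4g, p %.4g\n",
      x$model, x$method, x$n, if (is.null(x$beta1)) NA else x$beta1,
      x$stat, x$p
    ))
  }
  invisible(x)
}

#' Exact ordinal (dichotomized) association test at one site
#'
#' For an ordered categorical phenotype reduced to affected versus
#' unaffected, genotypes are collapsed to susceptible (encoded > 0
#' under the chosen model) versus non-susceptible, and the resulting
#' 2x2 table is tested with the exact two-sided hypergeometric
#' (Fisher) probability: the sum of all table probabilities no larger
#' than the observed one.
#'
#' @param affected Logical vector, one entry per mouse.
#' @param calls REF/HET/VAR genotype calls, same length.
#' @param model One of "recessive", "semidominant", "dominant".
#' @return A `locus_fit` object (method "exact"); `stat` is the
#'   observed count of affected susceptible mice. If every mouse (or
#'   no mouse) is susceptible the genotype is uninformative and the
#'   fit is degenerate.
#' @export
#' @examples
#' ordinal_association_test(c(TRUE, TRUE, rep(FALSE, 28)),
#'                          c("VAR", "VAR", rep("REF", 28)),
#'                          "recessive")
ordinal_association_test <- function(affected, calls, model) {
  model <- match_model(model)
  if (length(affected) != length(calls)) {
    abort_arg("`affected` and `calls` must have equal length.")
  }
  if (!is.logical(affected) || anyNA(affected)) {
    abort_arg("`affected` must be logical with no missing values.")
  }
  x <- encode_genotypes(calls, model) > 0
  n <- length(x)
  m <- sum(x)            # susceptible
  k <- sum(affected)     # affected
  a <- sum(affected & x) # affected and susceptible
  degenerate <- m == 0L || m == n
  p <- NA_real_
  if (!degenerate) {
    support <- max(0L, k - (n - m)):min(k, m)
    probs <- stats::dhyper(support, m, n - m, k)
    # two-sided exact p: total probability of tables as or less likely
    p <- sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
    p <- min(1, max(p, 1e-300))
  }
  structure(
    list(model = model, n = n, beta0 = NA_real_, beta1 = NA_real_,
         stat = as.numeric(a), df = NA_integer_, p = p,
         neglog10p = if (is.na(p)) NA_real_ else -log10(p),
         status = if (degenerate) "degenerate" else "ok",
         method = "exact"),
    class = "locus_fit"
  )
}

#' Genome scan: single-locus tests at every pedigree site
#'
#' Runs [single_locus_test()] (or, for a dichotomized response, the
#' exact ordinal test) at every mutation site under each requested
#' inheritance encoding and assembles the Manhattan table: one row per
#' site with the per-model p-values, the best (smallest) p across
#' non-degenerate models, and its -log10.
#'
#' @param phenotypes Per-mouse tibble with `mouse_id` and the response
#'   column (see `response`).
#' @param genotypes Wide genotype tibble (`mouse_id` plus one
#'   REF/HET/VAR column per site), e.g. from [genotype_table()] with
#'   `generation = "G3"`.
#' @param sites Optional mutation-site tibble supplying `chromosome`,
#'   `position_bp`, `gene` annotation per `site_id`.
#' @param models Subset of recessive/semidominant/dominant; default
#'   all three.
#' @param response Name of the phenotype column; default
#'   "mouse_score".
#' @param dichotomize If not NULL, an affected cut: mice with response
#'   >= this value are affected and every site/model is tested with
#'   [ordinal_association_test()] instead of the regression.
#' @return A tibble of class `manhattan_scan`: `site_id`,
#'   `chromosome`, `position_bp`, `gene`, per-model p columns
#'   (`p_recessive`, ...), `best_model`, `best_p`, `neglog10p`,
#'   `n_var` (VAR mice at the site), `two_var` (at least two VAR mice)
#'   and `status` ("ok" unless every model was degenerate).
#' @export
#' @examples
#' ped <- breed_pedigree(mutation_sites(6, seed = 1), seed = 2)
#' phen <- phenotype_table(simulate_exams(ped, "site_001", seed = 3))
#' scan_pedigree(phen, genotype_table(ped, "G3"), ped$sites)
scan_pedigree <- function(phenotypes, genotypes, sites = NULL,
                          models = LINKAGE_MODELS,
                          response = "mouse_score",
                          dichotomize = NULL) {
  models <- unique(models)
  if (!all(models %in% LINKAGE_MODELS) || length(models) == 0L) {
    abort_arg(sprintf("`models` must be a non-empty subset of %s.",
                      paste(LINKAGE_MODELS, collapse = ", ")))
  }
  if (!is.data.frame(phenotypes) ||
      !all(c("mouse_id", response) %in% names(phenotypes))) {
    abort_arg(sprintf("`phenotypes` must have columns mouse_id and %s.",
                      response))
  }
  if (!is.data.frame(genotypes) || !"mouse_id" %in% names(genotypes)) {
    abort_arg("`genotypes` must be a wide table with a mouse_id column.")
  }
  missing_geno <- setdiff(phenotypes$mouse_id, genotypes$mouse_id)
  missing_phen <- setdiff(genotypes$mouse_id, phenotypes$mouse_id)
  if (length(missing_geno) > 0L || length(missing_phen) > 0L) {
    abort_data(sprintf(
      "phenotype/genotype mouse sets differ; without genotypes: %s; without phenotypes: %s.",
      paste(c(missing_geno, "-")[1:min(5, max(1, length(missing_geno)))],
            collapse = ", "),
      paste(c(missing_phen, "-")[1:min(5, max(1, length(missing_phen)))],
            collapse = ", ")
    ))
  }
  site_ids <- setdiff(names(genotypes), c("mouse_id", "generation", "sex",
                                          "dam_id", "sire_id", "age_months"))
  if (length(site_ids) == 0L) abort_arg("`genotypes` contains no site columns.")
  G <- as.matrix(genotypes[match(phenotypes$mouse_id, genotypes$mouse_id),
                           site_ids, drop = FALSE])
  for (j in seq_len(ncol(G))) check_genotype_calls(G[, j], site_ids[j])
  y <- phenotypes[[response]]
  if (!is.numeric(y) || anyNA(y)) {
    abort_data(sprintf("response column `%s` must be numeric, no NA.", response))
  }

  p_mat <- matrix(NA_real_, nrow = length(site_ids), ncol = length(models),
                  dimnames = list(site_ids, models))
  if (is.null(dichotomize)) {
    if (length(y) < 3L) abort_arg("at least 3 phenotyped mice are required.")
    for (mdl in models) {
      code <- switch(mdl,
        recessive = c(REF = 0, HET = 0, VAR = 1),
        semidominant = c(REF = 0, HET = 1, VAR = 2),
        dominant = c(REF = 0, HET = 1, VAR = 1)
      )
      X <- matrix(code[G], nrow = nrow(G))
      p_mat[, mdl] <- ols_slope_tests(y, X)$p
    }
  } else {
    affected <- y >= dichotomize
    for (mdl in models) {
      p_mat[, mdl] <- vapply(seq_along(site_ids), function(j) {
        ordinal_association_test(affected, G[, j], mdl)$p
      }, numeric(1))
    }
  }

  best_idx <- apply(p_mat, 1L, function(row) {
    if (all(is.na(row))) NA_integer_ else which.min(row)
  })
  best_p <- unname(ifelse(is.na(best_idx), NA_real_,
                          p_mat[cbind(seq_along(best_idx), best_idx)]))
  out <- tibble(
    site_id = site_ids,
    chromosome = NA_character_, position_bp = NA_integer_, gene = site_ids
  )
  if (!is.null(sites)) {
    idx <- match(site_ids, sites$site_id)
    out$chromosome <- as.character(sites$chromosome)[idx]
    out$position_bp <- sites$position_bp[idx]
    if ("gene" %in% names(sites)) {
      out$gene <- ifelse(is.na(idx), site_ids, sites$gene[idx])
    }
  }
  for (mdl in models) out[[paste0("p_", mdl)]] <- unname(p_mat[, mdl])
  out$best_model <- unname(ifelse(is.na(best_idx), NA_character_,
                                  models[best_idx]))
  out$best_p <- best_p
  out$neglog10p <- -log10(best_p)
  out$n_var <- unname(apply(G == "VAR", 2L, sum))
  out$two_var <- out$n_var >= 2L
  out$status <- ifelse(is.na(best_p), "degenerate", "ok")
  class(out) <- c("manhattan_scan", class(out))
  attr(out, "models") <- models
  attr(out, "n_mice") <- length(y)
  attr(out, "response") <- response
  out
}

#' Bonferroni-corrected genome-scan significance threshold
#'
#' The candidate threshold is the family-wise level alpha divided by
#' the number of tests performed: number of sites times number of
#' inheritance models (set `n_models = 1` for a sites-only divisor).
#'
#' @param n_sites Number of mutation sites tested (>= 1).
#' @param n_models Number of inheritance models tested (>= 1,
#'   default 3).
#' @param alpha Family-wise significance level in (0, 1); default
#'   0.05.
#' @return The p-value threshold (a single number).
#' @export
#' @examples
#' bonferroni_threshold(60, 3) # 0.05 / 180
bonferroni_threshold <- function(n_sites, n_models = 3, alpha = 0.05) {
  n_sites <- check_count(n_sites, "n_sites", min = 1L)
  n_models <- check_count(n_models, "n_models", min = 1L)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort_arg("`alpha` must be a single value in (0, 1).")
  }
  alpha / (n_sites * n_models)
}

#' Call candidate sites from a Manhattan table
#'
#' A site is a candidate when (1) its best p-value is below the
#' Bonferroni-corrected threshold and (2) its peak stands at least
#' `margin_logs_required` (default 3) logs above the highest peak at
#' any other gene. At most one site per scan can satisfy the margin
#' rule; with a single tested site the margin is +Inf and the rule
#' passes vacuously.
#'
#' @param manhattan A `manhattan_scan` tibble from [scan_pedigree()].
#' @param threshold P-value threshold, e.g. from
#'   [bonferroni_threshold()].
#' @param margin_logs_required Required lead over the second-highest
#'   peak, in log10 units; default 3.
#' @return A tibble sorted by decreasing peak height: `site_id`,
#'   `gene`, `best_model`, `best_p`, `neglog10p`, `above_threshold`,
#'   `margin_logs`, `is_candidate`. Empty (with a warning) when every
#'   site is degenerate.
#' @export
#' @examples
#' ped <- breed_pedigree(mutation_sites(6, seed = 1), seed = 2)
#' phen <- phenotype_table(simulate_exams(ped, "site_001", seed = 3))
#' scan <- scan_pedigree(phen, genotype_table(ped, "G3"), ped$sites)
#' call_candidates(scan, bonferroni_threshold(6, 3))
call_candidates <- function(manhattan, threshold, margin_logs_required = 3) {
  if (!is.data.frame(manhattan) || nrow(manhattan) == 0L) {
    abort_arg("`manhattan` must be a non-empty Manhattan table.")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold > 1) {
    abort_arg("`threshold` must be a single p-value in (0, 1].")
  }
  ok <- manhattan[manhattan$status == "ok" & !is.na(manhattan$best_p), ,
                  drop = FALSE]
  empty <- tibble(
    site_id = character(), gene = character(), best_model = character(),
    best_p = numeric(), neglog10p = numeric(), above_threshold = logical(),
    margin_logs = numeric(), is_candidate = logical()
  )
  if (nrow(ok) == 0L) {
    warn("all sites are degenerate; no candidates can be called.")
    return(empty)
  }
  margin <- vapply(seq_len(nrow(ok)), function(i) {
    others <- ok$neglog10p[ok$gene != ok$gene[i]]
    if (length(others) == 0L) Inf else ok$neglog10p[i] - max(others)
  }, numeric(1))
  out <- tibble(
    site_id = ok$site_id,
    gene = ok$gene,
    best_model = ok$best_model,
    best_p = ok$best_p,
    neglog10p = ok$neglog10p,
    above_threshold = ok$best_p < threshold,
    margin_logs = margin,
    is_candidate = ok$best_p < threshold & margin >= margin_logs_required
  )
  dplyr::arrange(out, dplyr::desc(.data$neglog10p))
}
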