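#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single-locus fit
#'
#' @param x A `locus_fit` from [single_locus_test()] or
#'   [ordinal_association_test()].
#' @param ... Unused.
#' @return A tibble with one row per model term (intercept, encoded
#'   genotype) for the regression fit, or one summary row for the
#'   exact test.
#' @export
tidy.locus_fit <- function(x, ...) {
  if (identical(x$method, "exact")) {
    return(tibble(
      term = "susceptible genotype", estimate = x$stat,
      statistic = x$stat, p.value = x$p
    ))
  }
  tibble(
    term = c("(Intercept)", paste0("genotype_", x$model)),
    estimate = c(x$beta0, x$beta1),
    statistic = c(NA_real_, x$stat),
    p.value = c(NA_real_, x$p)
  )
}

#' @rdname tidy.locus_fit
#' @export
glance.locus_fit <- function(x, ...) {
  tibble(
    model = x$model, method = x$method, n = x$n, df = x$df,
    statistic = x$stat, p.value = x$p, neglog10p = x$neglog10p,
    status = x$status
  )
}

#' Tidy an age-trend regression
#'
#' @param x A `trend_fit` from [trend_regression()].
#' @param ... Unused.
#' @return One row per term (`tidy`) or a one-row model summary
#'   (`glance`).
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "age_months"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname tidy.trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, statistic = x$f_statistic, p.value = x$p,
    df = 1L, df.residual = x$n - 2L, nobs = x$n
  )
}

#' Tidy a power study
#'
#' @param x A `power_report` from [power_study()].
#' @param ... Unused.
#' @return `tidy()` returns the per-replicate details tibble;
#'   `glance()` a one-row summary.
#' @export
tidy.power_report <- function(x, ...) {
  x$details
}

#' @rdname tidy.power_report
#' @export
glance.power_report <- function(x, ...) {
  out <- tibble(
    n_reps = x$n_reps, power = x$power,
    familywise_fp_rate = x$familywise_fp_rate,
    encoding_mode = x$encoding_mode, causal = x$causal, seed = x$seed
  )
  for (m in names(x$per_model_power)) {
    out[[paste0("power_", m)]] <- x$per_model_power[[m]]
  }
  out
}
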