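#' Interquartile-range (Tukey fence) outlier split
#'
#' Splits a measurement vector at the fences Q1 - 1.5*IQR and
#' Q3 + 1.5*IQR; values strictly outside the fences are flagged as
#' outliers. With fewer than 4 values no exclusion is attempted and
#' everything is kept (with a notice).
#'
#' @param values Numeric vector (finite, non-empty).
#' @param method Quartile convention: "linear" (interpolated order
#'   statistics, quantile type 7; the default) or "tukey" (Tukey
#'   hinges).
#' @return A list with `kept`, `removed` and `bounds` (lower, upper
#'   fence; NA when n < 4).
#' @export
#' @examples
#' iqr_outliers(c(1, 2, 3, 4, 100))
iqr_outliers <- function(values, method = c("linear", "tukey")) {
  method <- match.arg(method)
  if (length(values) == 0L) abort_arg("`values` must be non-empty.")
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    abort_arg("`values` must be finite numbers.")
  }
  if (length(values) < 4L) {
    inform("fewer than 4 values: no outlier exclusion performed.")
    return(list(kept = values, removed = numeric(0),
                bounds = c(NA_real_, NA_real_)))
  }
  q <- if (method == "linear") {
    stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  } else {
    stats::fivenum(values)[c(2, 4)]
  }
  iqr <- q[2] - q[1]
  bounds <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  outside <- values < bounds[1] | values > bounds[2]
  list(kept = values[!outside], removed = values[outside], bounds = bounds)
}

#' Two-group Student's t test
#'
#' Classical two-tailed unpaired t test; the default is the
#' equal-variance (pooled) form with df = n_a + n_b - 2. Set
#' `var_equal = FALSE` for the Welch form.
#'
#' @param a,b Numeric measurement vectors, each with n >= 2.
#' @param var_equal Pooled-variance Student form (default TRUE).
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
#' @examples
#' two_group_t(c(1, 2, 3), c(4, 5, 6))
two_group_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort_arg("both groups need at least 2 values.")
  }
  if (anyNA(a) || anyNA(b)) abort_arg("groups must not contain NA.")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    # identical constant groups: no evidence of difference
    return(tibble(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
  }
  fit <- stats::t.test(a, b, var.equal = var_equal)
  tibble(
    t = unname(fit$statistic),
    df = unname(fit$parameter),
    p = fit$p.value,
    mean_a = mean(a),
    mean_b = mean(b)
  )
}

#' Region-wise group comparison of flat-mount field counts
#'
#' For each antero-posterior flat-mount region, compares the per-field
#' counts (e.g. Iba1+ cells per 20x field) of the two genotype groups
#' with a two-tailed Student's t test, reported both on all fields and
#' after IQR outlier exclusion (applied within each genotype group).
#'
#' @param counts Tibble with columns `genotype`, `region`, `quadrant`,
#'   `field_count`; exactly two genotype groups overall.
#' @param regions Region vocabulary; defaults to the four standard
#'   flat-mount regions.
#' @return A tibble with one row per reported region: group labels,
#'   per-group n and mean, `p_all`, `p_outliers_removed`, `n_removed`
#'   and the removed counts (list column). Regions in which only one
#'   group was measured are skipped with a notice.
#' @export
region_comparison <- function(counts,
                              regions = c("central", "paracentral",
                                          "midperipheral", "peripheral")) {
  need <- c("genotype", "region", "quadrant", "field_count")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    abort_arg(sprintf("`counts` must have columns %s.",
                      paste(need, collapse = ", ")))
  }
  if (any(counts$field_count < 0) ||
      any(counts$field_count != trunc(counts$field_count))) {
    abort_data("`field_count` must be non-negative integers.")
  }
  bad_region <- setdiff(unique(counts$region), regions)
  if (length(bad_region) > 0L) {
    abort_data(sprintf("unknown region label(s): %s.",
                       paste(bad_region, collapse = ", ")))
  }
  groups <- sort(unique(counts$genotype))
  if (length(groups) != 2L) {
    abort_arg("`counts` must contain exactly two genotype groups.")
  }
  rows <- lapply(intersect(regions, unique(counts$region)), function(rg) {
    sub <- counts[counts$region == rg, , drop = FALSE]
    if (length(unique(sub$genotype)) < 2L) {
      inform(sprintf("region %s has a single genotype group; skipped.", rg))
      return(NULL)
    }
    va <- sub$field_count[sub$genotype == groups[1]]
    vb <- sub$field_count[sub$genotype == groups[2]]
    p_all <- two_group_t(va, vb)$p
    sa <- iqr_outliers(va)
    sb <- iqr_outliers(vb)
    removed <- c(sa$removed, sb$removed)
    p_trim <- if (length(sa$kept) >= 2L && length(sb$kept) >= 2L) {
      two_group_t(sa$kept, sb$kept)$p
    } else {
      NA_real_
    }
    tibble(
      region = rg, group_a = groups[1], group_b = groups[2],
      n_a = length(va), n_b = length(vb),
      mean_a = mean(va), mean_b = mean(vb),
      p_all = p_all, p_outliers_removed = p_trim,
      n_removed = length(removed), removed = list(removed)
    )
  })
  dplyr::bind_rows(rows)
}

#' Age-trend linear regression
#'
#' Ordinary least-squares fit of a phenotype (fundus score, layer
#' thickness, ...) on age, summarised by R-squared and the F statistic
#' `R2 / (1 - R2) * (n - 2)` with p from F(1, n - 2).
#'
#' @param x Ages (months), not constant, n >= 3.
#' @param y Responses, same length.
#' @return An object of class `trend_fit` with `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `p`, `n`.
#' @export
#' @examples
#' trend_regression(1:6, c(2, 4, 5, 7, 10, 11))
trend_regression <- function(x, y) {
  if (length(x) != length(y)) abort_arg("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort_arg("at least 3 observations are required.")
  if (anyNA(x) || anyNA(y)) abort_arg("`x` and `y` must not contain NA.")
  if (stats::sd(x) == 0) abort_arg("`x` must not be constant.")
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  if (syy == 0) {
    r2 <- 0
    f <- 0
    p <- 1
  } else {
    r2 <- min(1, (sxy^2 / sxx) / syy)
    f <- if (r2 >= 1) Inf else r2 / (1 - r2) * (n - 2)
    p <- max(stats::pf(f, 1, n - 2, lower.tail = FALSE), 1e-300)
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         f_statistic = f, p = p, n = n),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> n = %d: slope %.4g, R^2 = %.3f, F = %.3g, p = %.3g\n",
    x$n, x$slope, x$r_squared, x$f_statistic, x$p
  ))
  invisible(x)
}

#' Signed percent change between two group means
#'
#' `100 * (alternative - reference) / reference`; negative values are
#' decreases. Optional integer rounding rounds half away from zero.
#'
#' @param reference_mean Reference group mean (non-zero).
#' @param alternative_mean Comparison group mean.
#' @param round_to_integer Round the result to a whole percent?
#' @return Signed percent change (a single number).
#' @export
#' @examples
#' percent_change(38.4, 32.9, round_to_integer = TRUE) # -14
percent_change <- function(reference_mean, alternative_mean,
                           round_to_integer = FALSE) {
  if (!is.numeric(reference_mean) || reference_mean == 0) {
    abort_arg("`reference_mean` must be a non-zero number.")
  }
  pc <- 100 * (alternative_mean - reference_mean) / reference_mean
  if (round_to_integer) {
    pc <- sign(pc) * floor(abs(pc) + 0.5) # half away from zero
  }
  pc
}

#' Lipid-class balance ratios with per-tissue group comparison
#'
#' Computes, per sample, the triacylglycerol balance TAG/(TAG+DAG) and
#' TAG/DAG and the cholesteryl-ester balance CE/(Chl+CE), then (when a
#' `group` column is present) compares the two groups within each
#' tissue by Student's t test for each ratio.
#'
#' @param samples Tibble with columns `sample_id`, `tissue`, `TAG`,
#'   `DAG`, `Chl`, `CE` (non-negative normalized abundances) and
#'   optionally `group` (exactly two levels) for the comparisons.
#' @return A list of class `lipid_ratio_report`: `ratios` (per-sample
#'   tibble with `tag_frac` = TAG/(TAG+DAG), `tag_dag` = TAG/DAG, and
#'   `ce_frac` = CE/(Chl+CE)) and `tests` (per tissue and ratio, NULL
#'   without a `group` column). A zero DAG leaves `tag_dag` as NA with
#'   a notice.
#' @export
#' @examples
#' lipid_ratios(tibble::tibble(
#'   sample_id = c("s1", "s2"), tissue = "retina",
#'   TAG = c(3, 4), DAG = c(1, 2), Chl = c(5, 5), CE = c(1, 0)
#' ))
lipid_ratios <- function(samples) {
  need <- c("sample_id", "tissue", "TAG", "DAG", "Chl", "CE")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    abort_arg(sprintf("`samples` must have columns %s.",
                      paste(need, collapse = ", ")))
  }
  ab <- as.matrix(samples[c("TAG", "DAG", "Chl", "CE")])
  if (anyNA(ab) || any(ab < 0)) {
    abort_data("lipid abundances must be non-negative with no missing values.")
  }
  ratios <- samples |>
    dplyr::mutate(
      tag_frac = ifelse(.data$TAG + .data$DAG > 0,
                        .data$TAG / (.data$TAG + .data$DAG), NA_real_),
      tag_dag = ifelse(.data$DAG > 0, .data$TAG / .data$DAG, NA_real_),
      ce_frac = ifelse(.data$Chl + .data$CE > 0,
                       .data$CE / (.data$Chl + .data$CE), NA_real_)
    )
  if (any(samples$DAG == 0)) {
    inform("samples with DAG = 0: TAG/DAG left as NA.")
  }
  tests <- NULL
  if ("group" %in% names(samples)) {
    groups <- sort(unique(samples$group))
    if (length(groups) != 2L) {
      abort_arg("`group` must have exactly two levels for comparisons.")
    }
    tests <- tidyr::expand_grid(
      tissue = unique(ratios$tissue),
      ratio = c("tag_frac", "tag_dag", "ce_frac")
    ) |>
      purrr::pmap_dfr(function(tissue, ratio) {
        sub <- ratios[ratios$tissue == tissue, , drop = FALSE]
        va <- sub[[ratio]][sub$group == groups[1]]
        vb <- sub[[ratio]][sub$group == groups[2]]
        va <- va[!is.na(va)]
        vb <- vb[!is.na(vb)]
        if (length(va) < 2L || length(vb) < 2L) {
          return(tibble(tissue = tissue, ratio = ratio,
                        group_a = groups[1], group_b = groups[2],
                        mean_a = NA_real_, mean_b = NA_real_,
                        t = NA_real_, p = NA_real_))
        }
        tt <- two_group_t(va, vb)
        tibble(tissue = tissue, ratio = ratio,
               group_a = groups[1], group_b = groups[2],
               mean_a = tt$mean_a, mean_b = tt$mean_b,
               t = tt$t, p = tt$p)
      })
  }
  structure(list(ratios = ratios, tests = tests),
            class = "lipid_ratio_report")
}

#' @export
print.lipid_ratio_report <- function(x, ...) {
  cat(sprintf("<lipid_ratio_report> %d samples", nrow(x$ratios)))
  if (!is.null(x$tests)) cat(sprintf(", %d group tests", nrow(x$tests)))
  cat("\n")
  invisible(x)
}

#' Genome-saturation fraction of a screen
#'
#' The fraction of the gene universe for which the screen has examined
#' damaging alleles in the homozygous state: a gene qualifies when it
#' carries at least one mutation of class probably_null or
#' probably_damaging that was screened in at least two VAR
#' (homozygous) mice.
#'
#' @param gene_records Tibble with columns `gene`, `effect_class`,
#'   `n_var_mice_screened` (one row per screened mutation).
#' @param gene_universe_size Size of the gene universe used as the
#'   denominator; default 20000 protein-coding genes.
#' @return The saturation fraction (a single number in \[0, 1\]).
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   gene = c("g1", "g2", "g3"),
#'   effect_class = c("probably_null", "probably_damaging", "probably_benign"),
#'   n_var_mice_screened = c(3, 1, 5)
#' )
#' saturation(recs, gene_universe_size = 100) # only g1 qualifies
saturation <- function(gene_records, gene_universe_size = 20000) {
  need <- c("gene", "effect_class", "n_var_mice_screened")
  if (!is.data.frame(gene_records) || !all(need %in% names(gene_records))) {
    abort_arg(sprintf("`gene_records` must have columns %s.",
                      paste(need, collapse = ", ")))
  }
  gene_universe_size <- check_count(gene_universe_size,
                                    "gene_universe_size", min = 1L)
  bad <- setdiff(unique(gene_records$effect_class), EFFECT_CLASSES)
  if (length(bad) > 0L) {
    abort_data(sprintf("unknown effect class(es): %s.",
                       paste(bad, collapse = ", ")))
  }
  qualifying <- unique(gene_records$gene[
    gene_records$effect_class %in% DAMAGING_CLASSES &
      gene_records$n_var_mice_screened >= 2
  ])
  if (gene_universe_size < length(qualifying)) {
    abort_arg("`gene_universe_size` is smaller than the number of qualifying genes.")
  }
  length(qualifying) / gene_universe_size
}
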