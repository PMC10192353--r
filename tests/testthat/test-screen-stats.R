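test_that("IQR fences reproduce the Tukey rule", {
  res <- iqr_outliers(c(1, 2, 3, 4, 100))
  # type-7 quartiles of (1,2,3,4,100): Q1 = 2, Q3 = 4, IQR = 2
  expect_equal(res$bounds, c(-1, 7))
  expect_equal(res$removed, 100)
  expect_equal(sort(res$kept), c(1, 2, 3, 4))

  # equal values: IQR = 0 and nothing is outside the closed fences
  same <- iqr_outliers(rep(5, 10))
  expect_length(same$removed, 0L)
  expect_equal(same$kept, rep(5, 10))

  expect_message(small <- iqr_outliers(c(1, 2, 3)), "fewer than 4")
  expect_equal(small$kept, c(1, 2, 3))
  expect_error(iqr_outliers(numeric(0)), class = "fundusmap_error_arg")

  # Tukey-hinges convention is available and pinned on one example
  hin <- iqr_outliers(c(1, 2, 3, 4, 100), method = "tukey")
  expect_equal(hin$bounds, c(2 - 1.5 * 2, 4 + 1.5 * 2))
})

test_that("outlier splitting conserves the input multiset and ignores order", {
  withr::with_seed(5, {
    for (i in 1:20) {
      v <- rnorm(sample(4:30, 1), sd = sample(c(1, 10), 1))
      res <- iqr_outliers(v)
      expect_equal(sort(c(res$kept, res$removed)), sort(v))
      shuffled <- iqr_outliers(sample(v))
      expect_equal(sort(shuffled$removed), sort(res$removed))
    }
  })
})

test_that("two_group_t is the pooled-variance Student form", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  res <- two_group_t(a, b)
  # closed form: pooled s^2 = 1, se = sqrt(1 * (1/3 + 1/3)), df = 4
  t_hand <- (mean(a) - mean(b)) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(abs(t_hand), 4, lower.tail = FALSE),
               tolerance = 1e-12)

  swapped <- two_group_t(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)

  same <- two_group_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(two_group_t(1, c(1, 2)), class = "fundusmap_error_arg")
})

test_that("trend_regression matches the closed-form R2/F summary", {
  # exact line
  fit <- trend_regression(1:5, 2 * (1:5) + 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)

  # constant response
  flat <- trend_regression(1:5, rep(3, 5))
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$f_statistic, 0)
  expect_equal(flat$p, 1)

  # n = 6 toy against the independent lm/summary oracle
  x <- c(2, 4, 6, 8, 10, 12)
  y <- c(1.2, 2.1, 2.0, 3.7, 3.9, 5.1)
  fit <- trend_regression(x, y)
  ref <- summary(lm(y ~ x))
  expect_equal(fit$slope, unname(coef(ref)[2, 1]), tolerance = 1e-10)
  expect_equal(fit$r_squared, ref$r.squared, tolerance = 1e-10)
  expect_equal(fit$f_statistic, unname(ref$fstatistic[1]), tolerance = 1e-10)
  expect_equal(fit$p,
               pf(ref$fstatistic[1], 1, 4, lower.tail = FALSE),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(glance(fit)$r.squared, fit$r_squared)

  expect_error(trend_regression(rep(2, 5), 1:5),
               class = "fundusmap_error_arg")
  expect_error(trend_regression(1:2, 1:2), class = "fundusmap_error_arg")
})

test_that("percent_change reports signed change with away-from-zero rounding", {
  expect_equal(percent_change(38.4, 32.9), 100 * (32.9 - 38.4) / 38.4)
  expect_equal(percent_change(38.4, 32.9, round_to_integer = TRUE), -14)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(10, 20), 100)
  expect_equal(percent_change(10, 10.55, round_to_integer = TRUE), 6)
  expect_error(percent_change(0, 5), class = "fundusmap_error_arg")
})

test_that("lipid ratios are bounded and group-tested per tissue", {
  samples <- tibble::tibble(
    sample_id = c("s1", "s2"), tissue = "retina",
    TAG = c(3, 1), DAG = c(1, 0), Chl = c(5, 2), CE = c(1, 0)
  )
  rep_ <- lipid_ratios(samples)
  expect_equal(rep_$ratios$tag_frac[1], 0.75)
  expect_equal(rep_$ratios$tag_dag[1], 3)
  expect_true(is.na(rep_$ratios$tag_dag[2])) # DAG = 0 -> NA with notice
  expect_equal(rep_$ratios$ce_frac[2], 0)    # CE = 0

  withr::with_seed(13, {
    rnd <- tibble::tibble(
      sample_id = sprintf("s%d", 1:40),
      tissue = rep(c("retina", "rpe_choroid"), each = 20),
      group = rep(rep(c("ko", "wt"), each = 10), 2),
      TAG = runif(40, 0, 10), DAG = runif(40, 0.1, 5),
      Chl = runif(40, 0.1, 5), CE = runif(40, 0, 5)
    )
    rr <- lipid_ratios(rnd)
    expect_true(all(rr$ratios$tag_frac >= 0 & rr$ratios$tag_frac <= 1))
    expect_true(all(rr$ratios$ce_frac >= 0 & rr$ratios$ce_frac <= 1))
    expect_equal(nrow(rr$tests), 6L) # 2 tissues x 3 ratios
    # group test equals a direct Student's t on the same ratio values
    sub <- rr$ratios[rr$ratios$tissue == "retina", ]
    direct <- two_group_t(sub$tag_frac[sub$group == "ko"],
                          sub$tag_frac[sub$group == "wt"])
    row <- rr$tests[rr$tests$tissue == "retina" &
                      rr$tests$ratio == "tag_frac", ]
    expect_equal(row$p, direct$p)
  })

  neg <- samples
  neg$TAG[1] <- -1
  expect_error(lipid_ratios(neg), class = "fundusmap_error_data")
})

test_that("saturation counts damaging genes screened in >= 2 homozygotes", {
  recs <- tibble::tibble(
    gene = sprintf("g%d", 1:5),
    effect_class = c("probably_null", "probably_damaging",
                     "probably_damaging", "possibly_damaging",
                     "probably_benign"),
    n_var_mice_screened = c(3, 2, 1, 10, 10)
  )
  # g1 and g2 qualify; g3 has a single homozygote, g4/g5 wrong class
  expect_equal(saturation(recs, gene_universe_size = 100), 0.02)
  expect_equal(saturation(recs[0, ], gene_universe_size = 100), 0)

  # monotone: adding homozygotes or damaging mutations never lowers it
  more_var <- recs
  more_var$n_var_mice_screened[3] <- 2
  expect_gte(saturation(more_var, 100), saturation(recs, 100))
  more_gene <- rbind(recs, tibble::tibble(
    gene = "g6", effect_class = "probably_null", n_var_mice_screened = 5
  ))
  expect_gte(saturation(more_gene, 100), saturation(recs, 100))

  expect_error(saturation(recs, gene_universe_size = 1),
               class = "fundusmap_error_arg")
  bad <- recs
  bad$effect_class[1] <- "synonymous"
  expect_error(saturation(bad, 100), class = "fundusmap_error_data")
})

test_that("region comparison reports dual p-values per flat-mount region", {
  withr::with_seed(77, {
    counts <- tidyr::expand_grid(
      genotype = c("ko", "wt"),
      region = c("central", "paracentral", "midperipheral", "peripheral"),
      quadrant = c("superior", "inferior", "nasal", "temporal"),
      field = 1:3
    )
    counts$field_count <- rpois(nrow(counts),
                                ifelse(counts$genotype == "ko", 20, 6))
    counts <- counts[names(counts) != "field"]
  })
  rep_ <- region_comparison(counts)
  expect_lte(nrow(rep_), 4L)
  expect_true(all(rep_$p_all > 0 & rep_$p_all <= 1))

  # without outliers the two p-values coincide
  clean <- rep_[rep_$n_removed == 0, ]
  expect_equal(clean$p_all, clean$p_outliers_removed)

  # an injected extreme field is removed and the trimmed p returns
  # toward the clean-data p
  spiked <- counts
  idx <- which(spiked$genotype == "wt" & spiked$region == "central")[1]
  spiked$field_count[idx] <- 500L
  rep_sp <- region_comparison(spiked)
  central <- rep_sp[rep_sp$region == "central", ]
  central_clean <- rep_[rep_$region == "central", ]
  expect_equal(central$n_removed, 1L)
  expect_equal(central$removed[[1]], 500)
  expect_lt(abs(central$p_outliers_removed - central_clean$p_all),
            abs(central$p_all - central_clean$p_all))

  # a region measured in one group only is skipped with a notice
  lop <- counts[!(counts$genotype == "wt" & counts$region == "peripheral"), ]
  expect_message(rep_lop <- region_comparison(lop), "single genotype")
  expect_false("peripheral" %in% rep_lop$region)

  expect_error(region_comparison(dplyr::mutate(counts, region = "outer")),
               class = "fundusmap_error_data")
})
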