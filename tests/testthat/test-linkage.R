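test_that("genotype encodings follow the three inheritance models", {
  calls <- c("REF", "HET", "VAR")
  expect_equal(encode_genotypes(calls, "recessive"), c(0, 0, 1))
  expect_equal(encode_genotypes(calls, "semidominant"), c(0, 1, 2))
  expect_equal(encode_genotypes(calls, "dominant"), c(0, 1, 1))
  expect_error(encode_genotypes(c("REF", "het"), "recessive"),
               class = "fundusmap_error_data")
  expect_error(encode_genotypes(calls, "codominant"),
               class = "fundusmap_error_arg")
})

test_that("single_locus_test matches the closed-form OLS slope test", {
  calls <- c("REF", "REF", "REF", "VAR", "VAR", "VAR")
  y <- c(1, 2, 3, 7, 8, 9)
  fit <- single_locus_test(y, calls, "recessive")
  # hand-computed: Sxx = 1.5, Sxy = 9, beta1 = 6, SSE = 4, s^2 = 1,
  # se = sqrt(1/1.5), t = 6 / 0.81650, df = 4
  expect_equal(fit$beta1, 6)
  expect_equal(fit$beta0, 2)
  expect_equal(fit$stat, 6 / sqrt(1 / 1.5), tolerance = 1e-12)
  expect_equal(fit$df, 4L)
  expect_equal(fit$p, 2 * pt(-6 / sqrt(1 / 1.5), df = 4), tolerance = 1e-12)
  expect_equal(fit$neglog10p, -log10(fit$p))
  expect_identical(fit$status, "ok")
})

test_that("the regression agrees with lm() on random instances", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(8:40, 1)
      calls <- sample(c("REF", "HET", "VAR"), n, replace = TRUE,
                      prob = c(3, 4, 1) / 8)
      y <- rnorm(n) + encode_genotypes(calls, "semidominant")
      for (mdl in c("recessive", "semidominant", "dominant")) {
        x <- encode_genotypes(calls, mdl)
        if (var(x) == 0) next
        fit <- single_locus_test(y, calls, mdl)
        ref <- summary(lm(y ~ x))$coefficients
        expect_equal(fit$beta1, ref[2, 1], tolerance = 1e-10)
        expect_equal(fit$stat, ref[2, 3], tolerance = 1e-10)
        expect_equal(fit$p, ref[2, 4], tolerance = 1e-10)
      }
    }
  })
})

test_that("degenerate inputs are flagged, not given fake p-values", {
  fit <- single_locus_test(rep(2, 6),
                           c("REF", "REF", "REF", "VAR", "VAR", "VAR"),
                           "recessive")
  expect_identical(fit$status, "degenerate")
  expect_true(is.na(fit$p))
  # zero genotype variance under the recessive encoding
  fit2 <- single_locus_test(c(1, 2, 3, 4), rep("HET", 4), "recessive")
  expect_identical(fit2$status, "degenerate")
  expect_error(single_locus_test(1:4, c("REF", "HET"), "recessive"),
               class = "fundusmap_error_arg")
  expect_error(single_locus_test(1:2, c("REF", "HET"), "recessive"),
               class = "fundusmap_error_arg")
})

test_that("OLS p-values agree with permutation p-values at n = 8", {
  withr::with_seed(23, {
    for (i in 1:5) {
      calls <- sample(c("REF", "HET", "VAR"), 8, replace = TRUE,
                      prob = c(3, 4, 1) / 8)
      x <- encode_genotypes(calls, "semidominant")
      if (var(x) == 0) next
      y <- rnorm(8) + 0.5 * x
      p_ols <- single_locus_test(y, calls, "semidominant")$p
      n_perm <- 10000
      p_perm <- permutation_p(y, x, n_perm, seed = 100 + i)
      mc_se <- sqrt(p_perm * (1 - p_perm) / n_perm) + 1 / n_perm
      # the t reference is an approximation to the exact permutation
      # distribution at n = 8: allow 3 MC SE plus a discreteness pad
      expect_lt(abs(p_ols - p_perm), 3 * mc_se + 0.05)
    }
  })
})

test_that("scan_pedigree composes per-site tests into a Manhattan table", {
  ped <- tiny_pedigree(n_sites = 5, n_dams = 3, n_pups = 6)
  exams <- simulate_exams(ped, ped$sites$site_id[2], phenotype_model(),
                          seed = 9)
  phen <- phenotype_table(exams)
  geno <- genotype_table(ped, "G3")
  scan <- scan_pedigree(phen, geno, ped$sites)
  expect_s3_class(scan, "manhattan_scan")
  expect_equal(nrow(scan), 5L)
  expect_true(all(c("p_recessive", "p_semidominant", "p_dominant",
                    "best_model", "best_p", "neglog10p", "n_var",
                    "two_var", "status") %in% names(scan)))

  # single site, single model: p equals the direct test
  one <- scan_pedigree(phen, geno[c("mouse_id", ped$sites$site_id[1])],
                       ped$sites, models = "semidominant")
  direct <- single_locus_test(
    phen$mouse_score,
    geno[[ped$sites$site_id[1]]][match(phen$mouse_id, geno$mouse_id)],
    "semidominant"
  )
  expect_equal(one$best_p, direct$p, ignore_attr = TRUE)

  # permuting mouse row order changes nothing
  perm <- withr::with_seed(2, sample(nrow(phen)))
  scan2 <- scan_pedigree(phen[perm, ], geno, ped$sites)
  expect_equal(scan2$best_p, scan$best_p)

  # id mismatch is a data error listing offenders
  bad_phen <- phen
  bad_phen$mouse_id[1] <- "ghost_mouse"
  err <- expect_error(scan_pedigree(bad_phen, geno, ped$sites),
                      class = "fundusmap_error_data")
  expect_match(conditionMessage(err), "ghost_mouse", fixed = TRUE)
})

test_that("a null 60-site scan yields complete, finite results", {
  ped <- breed_pedigree(mutation_sites(60, seed = 51), seed = 52)
  exams <- simulate_exams(ped, NULL, phenotype_model(effect_size = 0),
                          seed = 53)
  scan <- scan_pedigree(phenotype_table(exams), genotype_table(ped, "G3"),
                        ped$sites)
  expect_equal(nrow(scan), 60L)
  ok <- scan$status == "ok"
  expect_true(all(is.finite(scan$best_p[ok])))
  expect_true(all(scan$best_p[ok] > 0 & scan$best_p[ok] <= 1))
  # degenerate-everywhere sites are flagged rather than dropped
  expect_true(all(scan$status %in% c("ok", "degenerate")))
})

test_that("the Bonferroni threshold divides alpha by sites times models", {
  expect_equal(bonferroni_threshold(1, 1), 0.05)
  expect_equal(bonferroni_threshold(60, 3), 0.05 / 180)
  thresholds <- vapply(1:10, bonferroni_threshold, numeric(1), n_models = 3)
  expect_true(all(diff(thresholds) < 0))
  expect_error(bonferroni_threshold(60, 3, alpha = 1.2),
               class = "fundusmap_error_arg")
  expect_error(bonferroni_threshold(0, 3), class = "fundusmap_error_arg")
})

test_that("candidate calling applies the threshold and 3-log margin rules", {
  thr <- bonferroni_threshold(60, 3)

  # margin 4 >= 3: the lead is a candidate
  calls <- call_candidates(manual_manhattan(c(15, 11, 1)), thr)
  expect_true(calls$is_candidate[1])
  expect_equal(calls$margin_logs[1], 4)
  expect_equal(sum(calls$is_candidate), 1L)

  # margin 2 < 3: the lead fails the peak-dominance rule
  calls <- call_candidates(manual_manhattan(c(15, 13, 1)), thr)
  expect_false(any(calls$is_candidate))
  expect_true(calls$above_threshold[1])

  # a single tested site has margin +Inf
  calls <- call_candidates(manual_manhattan(8), thr)
  expect_true(calls$is_candidate[1])
  expect_equal(calls$margin_logs[1], Inf)

  # sibling mutations in the same gene do not defeat the peak
  same_gene <- manual_manhattan(c(15, 13, 1),
                                genes = c("geneA", "geneA", "geneB"))
  calls <- call_candidates(same_gene, thr)
  expect_true(calls$is_candidate[1])
  expect_equal(calls$margin_logs[1], 14)

  # all-degenerate scans warn and return an empty table
  degen <- manual_manhattan(c(2, 3), status = c("degenerate", "degenerate"))
  degen$best_p <- NA_real_
  expect_warning(res <- call_candidates(degen, thr), "degenerate")
  expect_equal(nrow(res), 0L)
})

test_that("the exact ordinal test matches brute-force and fisher.test", {
  # both VAR mice affected, nobody else: table [[2,0],[0,28]]
  affected <- c(TRUE, TRUE, rep(FALSE, 28))
  calls <- c("VAR", "VAR", rep("REF", 28))
  fit <- ordinal_association_test(affected, calls, "recessive")
  expect_identical(fit$status, "ok")
  expect_equal(fit$p, brute_force_exact_p(a = 2, m = 2, n_other = 28, k = 2))
  ref <- fisher.test(matrix(c(2, 0, 0, 28), 2))
  expect_equal(fit$p, ref$p.value, tolerance = 1e-12)

  # no affected mice: p = 1
  none <- ordinal_association_test(rep(FALSE, 10),
                                   c(rep("VAR", 3), rep("REF", 7)),
                                   "recessive")
  expect_equal(none$p, 1)

  # row/column order invariance
  perm <- withr::with_seed(3, sample(30))
  fit2 <- ordinal_association_test(affected[perm], calls[perm], "recessive")
  expect_equal(fit2$p, fit$p)

  # random tables agree with fisher.test
  withr::with_seed(8, {
    for (i in 1:20) {
      n <- sample(10:30, 1)
      g <- sample(c("REF", "HET", "VAR"), n, replace = TRUE)
      aff <- sample(c(TRUE, FALSE), n, replace = TRUE)
      for (mdl in c("recessive", "dominant")) {
        x <- encode_genotypes(g, mdl) > 0
        if (sum(x) %in% c(0, n)) next
        fit <- ordinal_association_test(aff, g, mdl)
        tab <- table(factor(x, c(FALSE, TRUE)), factor(aff, c(FALSE, TRUE)))
        expect_equal(fit$p, fisher.test(tab)$p.value, tolerance = 1e-9)
      }
    }
  })

  # uninformative genotype (everyone susceptible) is degenerate
  degen <- ordinal_association_test(c(TRUE, FALSE, TRUE), rep("VAR", 3),
                                    "recessive")
  expect_identical(degen$status, "degenerate")
})

test_that("tidy and glance methods expose fit results as tibbles", {
  fit <- single_locus_test(c(1, 2, 3, 7, 8, 9),
                           c("REF", "REF", "REF", "VAR", "VAR", "VAR"),
                           "recessive")
  td <- tidy(fit)
  expect_equal(nrow(td), 2L)
  expect_equal(td$estimate, c(2, 6))
  gl <- glance(fit)
  expect_equal(gl$p.value, fit$p)
  expect_identical(gl$status, "ok")
})
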