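#' Configuration of a simulated screen pedigree
#'
#' Bundles the pedigree-shape parameters used by [power_study()] and
#' [run_screen()]. Defaults are the screen's typical pedigree: 60
#' founder mutations, 5 G2 dams with 8 G3 pups each (~40 screened
#' mice).
#'
#' @param n_sites Founder mutation count; default 60.
#' @param n_g2_dams G2 dams per pedigree; default 5.
#' @param n_g3_per_dam G3 pups per dam; default 8.
#' @param effect_class_probs Passed to [mutation_sites()].
#' @return A named list of class `pedigree_config`.
#' @export
#' @examples
#' pedigree_config(n_sites = 30)
pedigree_config <- function(n_sites = 60, n_g2_dams = 5, n_g3_per_dam = 8,
                            effect_class_probs = c(0.08, 0.22, 0.25, 0.45)) {
  structure(
    list(
      n_sites = check_count(n_sites, "n_sites", min = 1L),
      n_g2_dams = check_count(n_g2_dams, "n_g2_dams", min = 1L),
      n_g3_per_dam = check_count(n_g3_per_dam, "n_g3_per_dam", min = 1L),
      effect_class_probs = check_prob_vector(effect_class_probs,
                                             "effect_class_probs", 4L)
    ),
    class = "pedigree_config"
  )
}

# One simulated screen replicate: breed -> phenotype -> score -> scan
# -> call. Returns the candidate table plus bookkeeping about the
# causal site. With `causal = TRUE` the pedigree is redrawn (up to
# `max_redraws` times, deterministically) until the causal site has at
# least `min_var_causal` VAR mice, matching the screen's accounting
# requirement of two homozygotes.
simulate_screen_rep <- function(config, model, causal, seed,
                                encoding_mode = "continuous",
                                dichotomize_cut = 6, alpha = 0.05,
                                models = LINKAGE_MODELS,
                                bonferroni_models = TRUE,
                                quadrant_involvement_threshold = 3L,
                                min_var_causal = 2L, max_redraws = 100L) {
  sites <- mutation_sites(config$n_sites, config$effect_class_probs,
                          seed = child_seed(seed, 1L))
  causal_site <- NULL
  ped <- NULL
  if (causal) {
    causal_site <- sites$site_id[
      with_seed_maybe(child_seed(seed, 2L),
                      sample.int(config$n_sites, 1L))]
    for (attempt in seq_len(max_redraws)) {
      cand <- breed_pedigree(sites, config$n_g2_dams, config$n_g3_per_dam,
                             seed = child_seed(seed, 2L + attempt))
      g3 <- cand$genotypes[cand$mice$generation == "G3", causal_site,
                           drop = TRUE]
      if (sum(g3 == "VAR") >= min_var_causal) {
        ped <- cand
        break
      }
    }
    if (is.null(ped)) {
      abort_data("could not realize the required VAR homozygotes at the causal site.")
    }
  } else {
    ped <- breed_pedigree(sites, config$n_g2_dams, config$n_g3_per_dam,
                          seed = child_seed(seed, 3L))
  }
  exams <- simulate_exams(ped, causal_site, model,
                          seed = child_seed(seed, 200L))
  phen <- phenotype_table(exams, quadrant_involvement_threshold)
  geno <- genotype_table(ped, "G3")
  scan <- scan_pedigree(
    phen, geno, ped$sites, models = models,
    dichotomize = if (encoding_mode == "dichotomized") dichotomize_cut else NULL
  )
  thr <- bonferroni_threshold(config$n_sites,
                              if (bonferroni_models) length(models) else 1L,
                              alpha)
  calls <- call_candidates(scan, thr)
  list(pedigree = ped, causal_site = causal_site, exams = exams,
       phenotypes = phen, scan = scan, threshold = thr, candidates = calls)
}

#' Simulate detection power and family-wise false-candidate rate
#'
#' Runs `n_reps` complete screen replicates (breed, phenotype, score,
#' scan, candidate call) under a causal or a null architecture.
#' `power` is the fraction of causal replicates in which the causal
#' site itself is called candidate; `familywise_fp_rate` is the
#' fraction of replicates in which any non-causal site is called. In
#' continuous mode the 0-8 mouse score is the regression response; in
#' dichotomized mode mice with score >= `dichotomize_cut` are
#' "affected" and the exact ordinal test is used instead.
#'
#' @param config A [pedigree_config()].
#' @param model A [phenotype_model()] describing the phenotype
#'   generator (use `effect_size = 0` or `causal = FALSE` for a null
#'   study).
#' @param causal Logical: place a causal site (TRUE) or simulate the
#'   null (FALSE)?
#' @param n_reps Number of replicates (>= 1).
#' @param encoding_mode "continuous" (default) or "dichotomized".
#' @param dichotomize_cut Affected cut on the 0-8 score for
#'   dichotomized mode; default 6.
#' @param alpha Family-wise level for [bonferroni_threshold()].
#' @param models Inheritance encodings to test; default all three.
#' @param min_var_causal Minimum VAR mice required at the causal site
#'   (pedigree redrawn until met); default 2.
#' @param seed Master seed; each replicate uses [child_seed()] so any
#'   replicate is individually reproducible.
#' @return An object of class `power_report`: `n_reps`, `power`,
#'   `familywise_fp_rate`, `per_model_power` (share of replicates
#'   detected with each model best at the causal site),
#'   `encoding_mode`, `seed` and a per-replicate `details` tibble.
#' @export
#' @examples
#' \donttest{
#' power_study(pedigree_config(n_sites = 20), phenotype_model(),
#'             causal = TRUE, n_reps = 5, seed = 1)
#' }
power_study <- function(config = pedigree_config(),
                        model = phenotype_model(),
                        causal = TRUE, n_reps = 100,
                        encoding_mode = c("continuous", "dichotomized"),
                        dichotomize_cut = 6, alpha = 0.05,
                        models = LINKAGE_MODELS,
                        min_var_causal = 2L, seed = 1L) {
  encoding_mode <- match.arg(encoding_mode)
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  if (!inherits(config, "pedigree_config")) {
    abort_arg("`config` must come from pedigree_config().")
  }
  details <- purrr::map_dfr(seq_len(n_reps), function(i) {
    rep_seed <- child_seed(seed, i * 1000L)
    res <- simulate_screen_rep(
      config, model, causal, rep_seed,
      encoding_mode = encoding_mode, dichotomize_cut = dichotomize_cut,
      alpha = alpha, models = models, min_var_causal = min_var_causal
    )
    cand_rows <- res$candidates[res$candidates$is_candidate, , drop = FALSE]
    causal_row <- if (!is.null(res$causal_site)) {
      res$candidates[res$candidates$site_id == res$causal_site, ,
                     drop = FALSE]
    } else {
      res$candidates[0, , drop = FALSE]
    }
    detected <- nrow(causal_row) == 1L && causal_row$is_candidate
    tibble(
      rep = i,
      seed = rep_seed,
      causal_site = res$causal_site %||% NA_character_,
      detected = detected,
      best_model_at_causal = if (nrow(causal_row) == 1L)
        causal_row$best_model else NA_character_,
      causal_p = if (nrow(causal_row) == 1L) causal_row$best_p else NA_real_,
      n_candidates = nrow(cand_rows),
      false_candidate = any(cand_rows$site_id !=
                              (res$causal_site %||% "")) && nrow(cand_rows) > 0
    )
  })
  per_model <- vapply(models, function(m) {
    mean(details$detected & details$best_model_at_causal == m, na.rm = TRUE)
  }, numeric(1))
  structure(
    list(
      n_reps = n_reps,
      power = if (causal) mean(details$detected) else NA_real_,
      familywise_fp_rate = mean(details$false_candidate),
      per_model_power = per_model,
      encoding_mode = encoding_mode,
      causal = causal,
      seed = seed,
      details = details
    ),
    class = "power_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("<power_report> %d replicates, %s response, %s architecture\n",
              x$n_reps, x$encoding_mode,
              if (x$causal) "causal" else "null"))
  if (x$causal) cat(sprintf("  power: %.3f\n", x$power))
  cat(sprintf("  family-wise false-candidate rate: %.3f\n",
              x$familywise_fp_rate))
  cat("  per-model detection share:",
      paste(sprintf("%s %.3f", names(x$per_model_power), x$per_model_power),
            collapse = ", "), "\n")
  invisible(x)
}
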