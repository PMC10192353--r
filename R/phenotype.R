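#' Specify the fundus-spot count generator
#'
#' Spot counts per eye are negative-binomial with mean
#' `baseline_mean + g * effect_size + age_slope * age_months`, where
#' `g` is the susceptibility weight of the mouse's genotype at the
#' causal site under the chosen inheritance mode (recessive: REF 0,
#' HET 0, VAR 1; additive: 0, 0.5, 1; dominant: 0, 1, 1). The total is
#' split over the four retinal quadrants with equal probabilities.
#'
#' @param baseline_mean Expected spots per eye in non-susceptible
#'   genotypes (>= 0). Default 1: wild-type-like eyes show zero or a
#'   handful of spots.
#' @param effect_size Added expected spots per eye in fully
#'   susceptible genotypes (>= 0). Default 40, a reservoir-like severe
#'   effect that drives four-quadrant involvement.
#' @param inheritance One of "recessive", "additive", "dominant".
#' @param age_slope Added expected spots per eye per month of age;
#'   default 0 (the screening window is narrow).
#' @param dispersion Negative-binomial size parameter (> 0); variance
#'   is `mu + mu^2 / dispersion`. Default 8, moderate biological
#'   overdispersion.
#' @param eye_correlation Reserved for intra-mouse correlation of the
#'   two eyes; only 0 (independent eyes given genotype) is supported.
#' @return An object of class `phenotype_model`.
#' @export
#' @examples
#' phenotype_model(effect_size = 12)
phenotype_model <- function(baseline_mean = 1, effect_size = 40,
                            inheritance = c("recessive", "additive", "dominant"),
                            age_slope = 0, dispersion = 8,
                            eye_correlation = 0) {
  inheritance <- match.arg(inheritance)
  if (baseline_mean < 0 || effect_size < 0) {
    abort_arg("`baseline_mean` and `effect_size` must be non-negative.")
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    abort_arg("`dispersion` must be positive.")
  }
  if (!identical(eye_correlation, 0) && !identical(eye_correlation, 0L)) {
    abort_arg("only `eye_correlation = 0` (independent eyes) is implemented.")
  }
  structure(
    list(baseline_mean = baseline_mean, effect_size = effect_size,
         inheritance = inheritance, age_slope = age_slope,
         dispersion = dispersion, eye_correlation = 0),
    class = "phenotype_model"
  )
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat(sprintf(
    "<phenotype_model> %s; baseline %.3g + effect %.3g + %.3g/month; NB size %.3g\n",
    x$inheritance, x$baseline_mean, x$effect_size, x$age_slope, x$dispersion
  ))
  invisible(x)
}

susceptibility_weight <- function(calls, inheritance) {
  w <- switch(inheritance,
    recessive = c(REF = 0, HET = 0, VAR = 1),
    additive = c(REF = 0, HET = 0.5, VAR = 1),
    dominant = c(REF = 0, HET = 1, VAR = 1)
  )
  unname(w[calls])
}

#' Simulate per-eye per-quadrant fundus spot counts for a pedigree
#'
#' Generates two fundus exams (OD, OS) for every G3 mouse of the
#' pedigree under a genotype-dependent count model. With
#' `causal_site = NULL` (or an `effect_size` of 0) the counts are pure
#' noise, i.e. a null pedigree.
#'
#' @param pedigree A `pedigree` object.
#' @param causal_site `site_id` of the causal mutation, or NULL for no
#'   genetic effect.
#' @param model A [phenotype_model()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per eye: `mouse_id`, `eye` (OD/OS),
#'   `q_superior`, `q_inferior`, `q_nasal`, `q_temporal`,
#'   `age_months`.
#' @export
#' @examples
#' ped <- breed_pedigree(mutation_sites(5, seed = 1), seed = 2)
#' exams <- simulate_exams(ped, causal_site = "site_001", seed = 3)
simulate_exams <- function(pedigree, causal_site = NULL,
                           model = phenotype_model(), seed = NULL) {
  if (!inherits(pedigree, "pedigree")) {
    abort_arg("`pedigree` must be a pedigree object.")
  }
  if (!inherits(model, "phenotype_model")) {
    abort_arg("`model` must be a phenotype_model object.")
  }
  g3 <- pedigree$mice[pedigree$mice$generation == "G3", , drop = FALSE]
  if (is.null(causal_site)) {
    g <- rep(0, nrow(g3))
  } else {
    if (!causal_site %in% pedigree$sites$site_id) {
      abort_arg(sprintf("`causal_site` '%s' is not a pedigree site.", causal_site))
    }
    calls <- pedigree$genotypes[[causal_site]][
      match(g3$mouse_id, pedigree$genotypes$mouse_id)]
    g <- susceptibility_weight(calls, model$inheritance)
  }
  lambda <- pmax(0, model$baseline_mean + g * model$effect_size +
                   model$age_slope * g3$age_months)

  draw <- function() {
    n_eyes <- 2L * nrow(g3)
    mu <- rep(lambda, each = 2L)
    totals <- ifelse(mu == 0, 0L,
                     stats::rnbinom(n_eyes, size = model$dispersion, mu = mu))
    quads <- vapply(totals, function(tot) {
      if (tot == 0) integer(4) else
        as.integer(stats::rmultinom(1L, tot, rep(0.25, 4)))
    }, integer(4))
    tibble(
      mouse_id = rep(g3$mouse_id, each = 2L),
      eye = rep(c("OD", "OS"), times = nrow(g3)),
      q_superior = quads[1, ], q_inferior = quads[2, ],
      q_nasal = quads[3, ], q_temporal = quads[4, ],
      age_months = rep(g3$age_months, each = 2L)
    )
  }
  with_seed_maybe(seed, draw())
}

#' Grade one eye on the semiquantitative fundus spot scale
#'
#' The per-eye scale: no spots scores 0; 1 to 10 spots scores 1; more
#' than 10 spots are graded by quadrant involvement — the equivalent
#' of one involved quadrant scores 2, two to three quadrants score 3,
#' and all four quadrants score 4. "Involved" is operationalized as a
#' quadrant holding at least `quadrant_involvement_threshold` spots
#' (default 3).
#'
#' @param quadrant_counts Non-negative integer spot counts for the
#'   four quadrants (superior, inferior, nasal, temporal): a length-4
#'   vector, or a 4-column matrix for several eyes at once.
#' @param quadrant_involvement_threshold Minimum spots for a quadrant
#'   to count as involved (positive integer, default 3); applied only
#'   when the eye total exceeds 10.
#' @return Integer score(s) in 0..4.
#' @export
#' @examples
#' score_eye(c(7, 0, 0, 0))   # 7 spots -> 1
#' score_eye(c(20, 20, 20, 20)) # all quadrants -> 4
score_eye <- function(quadrant_counts, quadrant_involvement_threshold = 3) {
  thr <- check_count(quadrant_involvement_threshold,
                     "quadrant_involvement_threshold", min = 1L)
  m <- if (is.matrix(quadrant_counts)) quadrant_counts else
    matrix(quadrant_counts, nrow = 1L)
  if (ncol(m) != 4L) {
    abort_arg("`quadrant_counts` must have exactly 4 quadrant counts per eye.")
  }
  if (anyNA(m) || any(m < 0) || any(m != trunc(m))) {
    abort_arg("quadrant counts must be non-negative integers.")
  }
  total <- rowSums(m)
  involved <- rowSums(m >= thr)
  score <- integer(nrow(m))
  score[total >= 1 & total <= 10] <- 1L
  high <- total > 10
  score[high & involved <= 1] <- 2L
  score[high & involved %in% c(2, 3)] <- 3L
  score[high & involved == 4] <- 4L
  score
}

#' Combine the two eye scores of a mouse
#'
#' The per-mouse score is the sum of the two per-eye scores, ranging
#' 0 to 8 (9 possible values).
#'
#' @param od,os Integer eye scores in 0..4 (vectorized).
#' @return Integer mouse score(s) in 0..8.
#' @export
#' @examples
#' score_mouse(4, 4)
score_mouse <- function(od, os) {
  if (length(od) != length(os)) {
    abort_arg("`od` and `os` must have equal length.")
  }
  ok <- function(x) is.numeric(x) && !anyNA(x) && all(x %in% 0:4)
  if (!ok(od) || !ok(os)) {
    abort_arg("eye scores must be integers in 0..4.")
  }
  as.integer(od + os)
}

#' Score a table of fundus exams into per-mouse phenotypes
#'
#' Applies [score_eye()] to every exam and [score_mouse()] per mouse.
#' Every mouse must contribute exactly two exams, one OD and one OS.
#'
#' @param exams Tibble of exams as from [simulate_exams()] or
#'   [read_exam_counts()].
#' @param quadrant_involvement_threshold Passed to [score_eye()].
#' @return A tibble with one row per mouse: `mouse_id`, `age_months`,
#'   `od_score`, `os_score`, `mouse_score`.
#' @export
#' @examples
#' ped <- breed_pedigree(mutation_sites(3, seed = 1), seed = 2)
#' phenotype_table(simulate_exams(ped, seed = 3))
phenotype_table <- function(exams, quadrant_involvement_threshold = 3) {
  qcols <- c("q_superior", "q_inferior", "q_nasal", "q_temporal")
  need <- c("mouse_id", "eye", qcols, "age_months")
  if (!is.data.frame(exams) || !all(need %in% names(exams))) {
    abort_arg(sprintf("`exams` must have columns %s.",
                      paste(need, collapse = ", ")))
  }
  eyes_ok <- tapply(exams$eye, exams$mouse_id,
                    function(e) length(e) == 2L && setequal(e, c("OD", "OS")))
  if (!all(eyes_ok)) {
    abort_data(sprintf(
      "each mouse needs exactly one OD and one OS exam; offending mouse/mice: %s.",
      paste(names(eyes_ok)[!eyes_ok], collapse = ", ")
    ))
  }
  scored <- exams |>
    dplyr::mutate(eye_score = score_eye(
      as.matrix(exams[qcols]), quadrant_involvement_threshold))
  out <- scored |>
    dplyr::select("mouse_id", "eye", "eye_score", "age_months") |>
    tidyr::pivot_wider(names_from = "eye", values_from = "eye_score") |>
    dplyr::transmute(
      mouse_id = .data$mouse_id,
      age_months = .data$age_months,
      od_score = .data$OD,
      os_score = .data$OS,
      mouse_score = score_mouse(.data$OD, .data$OS)
    )
  # one row per mouse, in first-appearance order
  out[match(unique(exams$mouse_id), out$mouse_id), , drop = FALSE]
}
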