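# Strict TSV readers/writers. All tables are UTF-8, tab-separated,
# Unix newlines; genotype cells are exactly REF/HET/VAR (uppercase);
# p-values are written in full-precision scientific notation.

read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) abort_arg(sprintf("file not found: %s", path))
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  na = character())
}

check_columns <- function(tab, need, path) {
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    abort_data(sprintf("%s: missing column(s) %s.", path,
                       paste(missing, collapse = ", ")))
  }
}

check_genotype_cells <- function(tab, site_cols, path) {
  for (col in site_cols) {
    bad <- which(!(tab[[col]] %in% GENOTYPE_LEVELS))
    if (length(bad) > 0L) {
      abort_data(sprintf(
        "%s: invalid genotype '%s' in column %s, row %d (must be REF/HET/VAR).",
        path, tab[[col]][bad[1]], col, bad[1]
      ))
    }
  }
}

#' Read / write a wide genotype table
#'
#' Layout: `mouse_id`, `generation`, `sex`, `dam_id`, then one
#' REF/HET/VAR column per mutation site. Missing parent labels are
#' written as the literal `NA` token.
#'
#' @param path File path.
#' @return `read_genotype_table()` returns the validated tibble;
#'   `write_genotype_table()` returns `path` invisibly.
#' @export
read_genotype_table <- function(path) {
  tab <- read_tsv_strict(path, readr::cols(.default = readr::col_character()))
  check_columns(tab, c("mouse_id", "generation", "sex", "dam_id"), path)
  tab$dam_id[tab$dam_id == "NA"] <- NA_character_
  site_cols <- setdiff(names(tab), c("mouse_id", "generation", "sex", "dam_id"))
  if (length(site_cols) == 0L) {
    abort_data(sprintf("%s: no mutation-site columns.", path))
  }
  bad_gen <- which(!(tab$generation %in% c("G1", "G2", "G3")))
  if (length(bad_gen) > 0L) {
    abort_data(sprintf("%s: invalid generation '%s' in row %d.",
                       path, tab$generation[bad_gen[1]], bad_gen[1]))
  }
  check_genotype_cells(tab, site_cols, path)
  tab
}

#' @rdname read_genotype_table
#' @param x Table to write.
#' @export
write_genotype_table <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Read / write the mutation annotation table
#'
#' Layout: `site_id`, `chromosome`, `position_bp`, `gene`,
#' `effect_class`.
#'
#' @param path File path.
#' @return The validated tibble (reader) or `path` invisibly
#'   (writer).
#' @export
read_mutation_table <- function(path) {
  tab <- read_tsv_strict(path, readr::cols(
    site_id = readr::col_character(), chromosome = readr::col_character(),
    position_bp = readr::col_integer(), gene = readr::col_character(),
    effect_class = readr::col_character()
  ))
  check_columns(tab, c("site_id", "chromosome", "position_bp", "gene",
                       "effect_class"), path)
  bad <- which(!(tab$effect_class %in% EFFECT_CLASSES))
  if (length(bad) > 0L) {
    abort_data(sprintf("%s: invalid effect_class '%s' in row %d.",
                       path, tab$effect_class[bad[1]], bad[1]))
  }
  if (any(tab$position_bp <= 0)) {
    abort_data(sprintf("%s: positions must be strictly positive.", path))
  }
  tab
}

#' @rdname read_mutation_table
#' @param x Table to write.
#' @export
write_mutation_table <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Read / write the per-mouse phenotype table
#'
#' Layout: `mouse_id`, `age_months`, `od_score`, `os_score`,
#' `mouse_score`; the mouse score must equal the sum of the eye
#' scores.
#'
#' @param path File path.
#' @return The validated tibble (reader) or `path` invisibly
#'   (writer).
#' @export
read_phenotype_table <- function(path) {
  tab <- read_tsv_strict(path, readr::cols(
    mouse_id = readr::col_character(), age_months = readr::col_double(),
    od_score = readr::col_integer(), os_score = readr::col_integer(),
    mouse_score = readr::col_integer()
  ))
  check_columns(tab, c("mouse_id", "age_months", "od_score", "os_score",
                       "mouse_score"), path)
  bad <- which(!(tab$od_score %in% 0:4) | !(tab$os_score %in% 0:4) |
                 tab$mouse_score != tab$od_score + tab$os_score)
  if (length(bad) > 0L) {
    abort_data(sprintf("%s: inconsistent scores in row %d (mouse %s).",
                       path, bad[1], tab$mouse_id[bad[1]]))
  }
  tab
}

#' @rdname read_phenotype_table
#' @param x Table to write.
#' @export
write_phenotype_table <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Read / write raw per-eye quadrant spot counts
#'
#' Layout: `mouse_id`, `eye` (OD/OS), `q_superior`, `q_inferior`,
#' `q_nasal`, `q_temporal`, `age_months`.
#'
#' @param path File path.
#' @return The validated tibble (reader) or `path` invisibly
#'   (writer).
#' @export
read_exam_counts <- function(path) {
  tab <- read_tsv_strict(path, readr::cols(
    mouse_id = readr::col_character(), eye = readr::col_character(),
    q_superior = readr::col_integer(), q_inferior = readr::col_integer(),
    q_nasal = readr::col_integer(), q_temporal = readr::col_integer(),
    age_months = readr::col_double()
  ))
  check_columns(tab, c("mouse_id", "eye", "q_superior", "q_inferior",
                       "q_nasal", "q_temporal", "age_months"), path)
  bad <- which(!(tab$eye %in% c("OD", "OS")))
  if (length(bad) > 0L) {
    abort_data(sprintf("%s: invalid eye label '%s' in row %d.",
                       path, tab$eye[bad[1]], bad[1]))
  }
  qm <- as.matrix(tab[c("q_superior", "q_inferior", "q_nasal", "q_temporal")])
  if (anyNA(qm) || any(qm < 0)) {
    abort_data(sprintf("%s: quadrant counts must be non-negative integers.",
                       path))
  }
  tab
}

#' @rdname read_exam_counts
#' @param x Table to write.
#' @export
write_exam_counts <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Read / write a Manhattan scan table
#'
#' Layout: `site_id`, `chromosome`, `position_bp`, `gene`,
#' `best_model`, the per-model p columns present in the scan,
#' `best_p`, `neglog10p`, `n_var`, `two_var`, `status`.
#'
#' @param path File path.
#' @return The tibble (reader) or `path` invisibly (writer).
#' @export
read_manhattan_table <- function(path) {
  tab <- read_tsv_strict(path, readr::cols(
    site_id = readr::col_character(), chromosome = readr::col_character(),
    position_bp = readr::col_integer(), gene = readr::col_character(),
    best_model = readr::col_character(), status = readr::col_character(),
    n_var = readr::col_integer(), two_var = readr::col_logical(),
    .default = readr::col_double()
  ))
  check_columns(tab, c("site_id", "best_p", "neglog10p", "n_var", "status"),
                path)
  tab
}

#' @rdname read_manhattan_table
#' @param x Table to write.
#' @export
write_manhattan_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, na = "NA")
  invisible(path)
}

#' Read / write flat-mount region field counts
#'
#' Layout: `genotype`, `region`, `quadrant`, `field_count`.
#'
#' @param path File path.
#' @return The validated tibble (reader) or `path` invisibly
#'   (writer).
#' @export
read_region_counts <- function(path) {
  tab <- read_tsv_strict(path, readr::cols(
    genotype = readr::col_character(), region = readr::col_character(),
    quadrant = readr::col_character(), field_count = readr::col_integer()
  ))
  check_columns(tab, c("genotype", "region", "quadrant", "field_count"), path)
  tab
}

#' @rdname read_region_counts
#' @param x Table to write.
#' @export
write_region_counts <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Read / write a lipid-class abundance table
#'
#' Layout: `sample_id`, `tissue`, `TAG`, `DAG`, `Chl`, `CE`, and
#' optionally `group`.
#'
#' @param path File path.
#' @return The validated tibble (reader) or `path` invisibly
#'   (writer).
#' @export
read_lipid_table <- function(path) {
  tab <- read_tsv_strict(path, readr::cols(
    sample_id = readr::col_character(), tissue = readr::col_character(),
    .default = readr::col_double()
  ))
  check_columns(tab, c("sample_id", "tissue", "TAG", "DAG", "Chl", "CE"), path)
  tab
}

#' @rdname read_lipid_table
#' @param x Table to write.
#' @export
write_lipid_table <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Full screen-run configuration
#'
#' Every tunable of the end-to-end pipeline with its default; unknown
#' keys are rejected. Serialized as JSON alongside each run's
#' outputs.
#'
#' @param ... Named overrides of the defaults: `n_sites`, `n_g2_dams`,
#'   `n_g3_per_dam`, `effect_class_probs`, `baseline_mean`,
#'   `effect_size`, `inheritance`, `age_slope`, `dispersion`,
#'   `causal` (logical), `models`, `alpha`, `bonferroni_models`
#'   (count models in the Bonferroni divisor?),
#'   `quadrant_involvement_threshold`, `dichotomize_cut`, `seed`.
#' @return A named list of class `screen_config`.
#' @export
#' @examples
#' screen_config(effect_size = 0, seed = 7)
screen_config <- function(...) {
  defaults <- list(
    n_sites = 60L, n_g2_dams = 5L, n_g3_per_dam = 8L,
    effect_class_probs = c(0.08, 0.22, 0.25, 0.45),
    baseline_mean = 1, effect_size = 40, inheritance = "recessive",
    age_slope = 0, dispersion = 8,
    causal = TRUE, models = LINKAGE_MODELS, alpha = 0.05,
    bonferroni_models = TRUE, quadrant_involvement_threshold = 3L,
    dichotomize_cut = 6L, seed = 1L
  )
  overrides <- list(...)
  if (length(overrides) > 0L && (is.null(names(overrides)) ||
                                 any(names(overrides) == ""))) {
    abort_arg("all configuration overrides must be named.")
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    abort_arg(sprintf("unknown configuration key(s): %s.",
                      paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "screen_config")
}

#' @rdname screen_config
#' @param config A `screen_config` object.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname screen_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(screen_config, raw)
}

#' Run the complete simulated screen pipeline
#'
#' Breeds a pedigree, simulates and scores fundus exams, scans every
#' site under the configured inheritance models, calls candidates,
#' and writes the genotype, mutation, phenotype, Manhattan and
#' candidate tables plus the serialized configuration and a run log
#' into `out_dir`. Fully deterministic given the configured seed.
#'
#' @param config A [screen_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the `pedigree`, `causal_site`,
#'   `scan`, `threshold`, `candidates` and the written `paths`.
#' @export
run_screen <- function(config = screen_config(), out_dir) {
  if (!inherits(config, "screen_config")) {
    abort_arg("`config` must come from screen_config().")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort("cannot create output directory", class = "fundusmap_error_env")
  }
  ped_cfg <- pedigree_config(config$n_sites, config$n_g2_dams,
                             config$n_g3_per_dam, config$effect_class_probs)
  model <- phenotype_model(config$baseline_mean, config$effect_size,
                           config$inheritance, config$age_slope,
                           config$dispersion)
  res <- simulate_screen_rep(
    ped_cfg, model, causal = isTRUE(config$causal), seed = config$seed,
    alpha = config$alpha, models = config$models,
    bonferroni_models = isTRUE(config$bonferroni_models),
    quadrant_involvement_threshold = config$quadrant_involvement_threshold
  )
  paths <- list(
    config = file.path(out_dir, "config.json"),
    mutations = file.path(out_dir, "mutations.tsv"),
    genotypes = file.path(out_dir, "genotypes.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    manhattan = file.path(out_dir, "manhattan.tsv"),
    candidates = file.path(out_dir, "candidates.tsv"),
    log = file.path(out_dir, "run_log.txt")
  )
  write_config(config, paths$config)
  write_mutation_table(res$pedigree$sites, paths$mutations)
  write_genotype_table(genotype_table(res$pedigree), paths$genotypes)
  write_phenotype_table(res$phenotypes, paths$phenotypes)
  write_manhattan_table(res$scan, paths$manhattan)
  cand <- res$candidates[res$candidates$is_candidate, , drop = FALSE]
  readr::write_tsv(dplyr::select(cand, -dplyr::any_of("removed")),
                   paths$candidates, na = "NA")
  log_lines <- c(
    sprintf("[%s] fundusmap run", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %d", config$seed),
    sprintf("config md5: %s", unname(tools::md5sum(paths$config))),
    sprintf("sites: %d; G3 mice: %d", config$n_sites,
            config$n_g2_dams * config$n_g3_per_dam),
    sprintf("causal site: %s", res$causal_site %||% "none"),
    sprintf("bonferroni threshold: %.6g", res$threshold),
    sprintf("candidates: %s",
            if (nrow(cand) == 0L) "none" else
              paste(cand$site_id, collapse = ", "))
  )
  writeLines(log_lines, paths$log)
  invisible(list(pedigree = res$pedigree, causal_site = res$causal_site,
                 scan = res$scan, threshold = res$threshold,
                 candidates = res$candidates, paths = paths))
}
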