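#' Draw a pedigree-specific set of ENU-induced mutation sites
#'
#' Emulates the mutation load of a mutagenized G1 founder male: each
#' founder carries a private set of heterozygous coding/splice
#' mutations (around 60 in this screen design), scattered across the
#' autosomes, each annotated with a predicted effect class.
#'
#' Positions are drawn uniformly within the chromosome each site lands
#' on; chromosomes are drawn in proportion to their physical length.
#' Each site is assigned its own gene label (so in simulated data the
#' peak-dominance rule treats every site as an independent gene).
#'
#' @param n_sites Number of mutation sites (non-negative integer);
#'   default 60, the founder mutation load of this screen design.
#' @param effect_class_probs Probabilities for the four predicted
#'   effect classes, in the order probably_null, probably_damaging,
#'   possibly_damaging, probably_benign. Must sum to 1. The default
#'   reflects a typical ENU coding-variant spectrum: a small minority
#'   of outright nulls, roughly half damaging to possibly damaging,
#'   the rest likely benign.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `site_id`, `chromosome` (character,
#'   "1".."19"), `position_bp` (integer), `gene`, `effect_class`.
#' @export
#' @examples
#' mutation_sites(5, seed = 1)
mutation_sites <- function(n_sites = 60,
                           effect_class_probs = c(0.08, 0.22, 0.25, 0.45),
                           seed = NULL) {
  n_sites <- check_count(n_sites, "n_sites")
  effect_class_probs <- check_prob_vector(effect_class_probs,
                                          "effect_class_probs", 4L)
  draw <- function() {
    if (n_sites == 0L) {
      return(tibble(
        site_id = character(), chromosome = character(),
        position_bp = integer(), gene = character(),
        effect_class = character()
      ))
    }
    chrom <- sample(seq_along(MOUSE_AUTOSOME_MBP), n_sites,
                    replace = TRUE, prob = MOUSE_AUTOSOME_MBP)
    pos <- vapply(chrom, function(ch) {
      sample.int(MOUSE_AUTOSOME_MBP[ch] * 1e6L, 1L)
    }, integer(1))
    tibble(
      site_id = sprintf("site_%03d", seq_len(n_sites)),
      chromosome = as.character(chrom),
      position_bp = pos,
      gene = sprintf("gene_%03d", seq_len(n_sites)),
      effect_class = sample(EFFECT_CLASSES, n_sites,
                            replace = TRUE, prob = effect_class_probs)
    )
  }
  with_seed_maybe(seed, draw())
}

#' Breed a G1 -> G2 -> G3 pedigree with Mendelian genotypes
#'
#' Simulates the screen's backcross design: a G1 founder male,
#' heterozygous at every pedigree mutation site, is crossed to
#' wild-type females; his G2 daughters (each HET at a site with
#' probability 1/2, never VAR) are backcrossed to the G1 sire to
#' produce the screened G3 generation. Each G3 mouse receives one
#' allele from the sire (variant with probability 1/2 at every site)
#' and one from its dam (variant with probability 1/2 where the dam is
#' HET, never where she is REF): VAR means both alleles variant, HET
#' exactly one. The marginal G3 genotype distribution at any site is
#' therefore REF:HET:VAR = 3/8 : 1/2 : 1/8, and 1:2:1 conditional on a
#' HET dam.
#'
#' @param sites Tibble of mutation sites as from [mutation_sites()];
#'   must be non-empty with unique `site_id`s.
#' @param n_g2_dams Number of G2 dams (>= 1); default 5.
#' @param n_g3_per_dam G3 pups per dam (>= 1); default 8, giving the
#'   typical screened pedigree of ~40 G3 mice.
#' @param g3_age_range Ages (months) of G3 mice at screening, drawn
#'   uniformly; default c(4, 6), the screening window.
#' @param seed Optional integer seed; the same (sites, dams, pups,
#'   seed) always reproduces the identical pedigree.
#' @return An object of class `pedigree`: a list with elements
#'   `sites` (the input tibble), `mice` (tibble of mouse_id,
#'   generation, sex, sire_id, dam_id, age_months), `genotypes` (wide
#'   tibble, mouse_id plus one REF/HET/VAR column per site) and
#'   `seed`.
#' @export
#' @examples
#' ped <- breed_pedigree(mutation_sites(10, seed = 1), seed = 2)
#' ped
breed_pedigree <- function(sites, n_g2_dams = 5, n_g3_per_dam = 8,
                           g3_age_range = c(4, 6), seed = NULL) {
  if (!is.data.frame(sites) || nrow(sites) == 0L) {
    abort_arg("`sites` must be a non-empty data frame of mutation sites.")
  }
  if (!all(c("site_id", "chromosome", "position_bp") %in% names(sites))) {
    abort_arg("`sites` must have columns site_id, chromosome, position_bp.")
  }
  if (anyDuplicated(sites$site_id)) {
    abort_arg("`sites$site_id` must be unique within a pedigree.")
  }
  if (any(sites$position_bp <= 0)) {
    abort_arg("`sites$position_bp` must be strictly positive.")
  }
  n_g2_dams <- check_count(n_g2_dams, "n_g2_dams", min = 1L)
  n_g3_per_dam <- check_count(n_g3_per_dam, "n_g3_per_dam", min = 1L)
  k <- nrow(sites)
  n_g3 <- n_g2_dams * n_g3_per_dam

  draw <- function() {
    sire_id <- "G1_sire"
    dam_ids <- sprintf("G2_dam_%03d", seq_len(n_g2_dams))
    g3_dam_idx <- rep(seq_len(n_g2_dams), each = n_g3_per_dam)
    g3_ids <- sprintf("G3_%03d_%02d", g3_dam_idx,
                      rep(seq_len(n_g3_per_dam), times = n_g2_dams))

    # Dams: HET at each site independently w.p. 1/2 (one G1 allele).
    dam_het <- matrix(stats::runif(n_g2_dams * k) < 0.5,
                      nrow = n_g2_dams, ncol = k)
    # G3 allele transmissions: sire always HET, dam transmits a
    # variant only where she is HET.
    sire_allele <- matrix(stats::runif(n_g3 * k) < 0.5, nrow = n_g3)
    dam_allele <- matrix(stats::runif(n_g3 * k) < 0.5, nrow = n_g3) &
      dam_het[g3_dam_idx, , drop = FALSE]
    g3_code <- sire_allele + dam_allele # 0 = REF, 1 = HET, 2 = VAR

    to_calls <- function(code_mat) {
      m <- matrix(GENOTYPE_LEVELS[code_mat + 1L], nrow = nrow(code_mat))
      colnames(m) <- sites$site_id
      m
    }
    geno <- rbind(
      to_calls(matrix(1L, nrow = 1L, ncol = k)),       # G1 sire: HET everywhere
      to_calls(matrix(as.integer(dam_het), ncol = k)), # dams: REF/HET
      to_calls(g3_code)
    )
    mice <- tibble(
      mouse_id = c(sire_id, dam_ids, g3_ids),
      generation = c("G1", rep("G2", n_g2_dams), rep("G3", n_g3)),
      sex = c("M", rep("F", n_g2_dams),
              sample(c("M", "F"), n_g3, replace = TRUE)),
      sire_id = c(NA_character_, rep(sire_id, n_g2_dams + n_g3)),
      dam_id = c(NA_character_, rep(NA_character_, n_g2_dams),
                 dam_ids[g3_dam_idx]),
      age_months = c(15, rep(10, n_g2_dams),
                     stats::runif(n_g3, g3_age_range[1], g3_age_range[2]))
    )
    genotypes <- dplyr::bind_cols(
      tibble(mouse_id = mice$mouse_id),
      as_tibble(geno)
    )
    structure(
      list(sites = as_tibble(sites), mice = mice, genotypes = genotypes,
           seed = seed,
           params = list(n_g2_dams = n_g2_dams, n_g3_per_dam = n_g3_per_dam)),
      class = "pedigree"
    )
  }
  with_seed_maybe(seed, draw())
}

#' @export
print.pedigree <- function(x, ...) {
  n_gen <- table(x$mice$generation)
  cat(sprintf(
    "<pedigree> %d mutation sites; %d G1 sire, %d G2 dams, %d G3 mice\n",
    nrow(x$sites), n_gen[["G1"]], n_gen[["G2"]], n_gen[["G3"]]
  ))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Extract the rectangular genotype table of a pedigree
#'
#' One row per mouse, one column per site, no missing calls; the
#' layout round-trips losslessly through [write_genotype_table()] /
#' [read_genotype_table()].
#'
#' @param pedigree A `pedigree` object.
#' @param generation Optional generation filter, one of "G1", "G2",
#'   "G3".
#' @return A tibble with columns `mouse_id`, `generation`, `sex`,
#'   `dam_id`, then one REF/HET/VAR column per site.
#' @export
#' @examples
#' ped <- breed_pedigree(mutation_sites(3, seed = 1), seed = 2)
#' genotype_table(ped, "G3")
genotype_table <- function(pedigree, generation = NULL) {
  if (!inherits(pedigree, "pedigree")) {
    abort_arg("`pedigree` must be a pedigree object.")
  }
  tab <- dplyr::inner_join(
    dplyr::select(pedigree$mice, "mouse_id", "generation", "sex", "dam_id"),
    pedigree$genotypes,
    by = "mouse_id"
  )
  if (!is.null(generation)) {
    if (length(generation) != 1L || !generation %in% c("G1", "G2", "G3")) {
      abort_arg("`generation` must be one of G1, G2, G3.")
    }
    tab <- tab[tab$generation == generation, , drop = FALSE]
  }
  tab
}
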