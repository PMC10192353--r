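#' Manhattan plot of a genome scan
#'
#' -log10 p-values against cumulative genomic position, chromosomes
#' alternately shaded, with a horizontal line at the candidate
#' threshold.
#'
#' @param scan A `manhattan_scan` tibble from [scan_pedigree()].
#' @param threshold Optional p-value threshold to draw, e.g. from
#'   [bonferroni_threshold()].
#' @param label_candidates Label sites whose p falls below
#'   `threshold`? Default TRUE.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, threshold = NULL, label_candidates = TRUE) {
  if (!is.data.frame(scan) || !all(c("site_id", "neglog10p") %in% names(scan))) {
    abort_arg("`scan` must be a Manhattan table with site_id and neglog10p.")
  }
  dat <- as_tibble(scan)
  dat <- dat[!is.na(dat$neglog10p), , drop = FALSE]
  if (all(is.na(dat$chromosome))) {
    dat$chromosome <- "1"
    dat$position_bp <- seq_len(nrow(dat))
  }
  chrom_order <- as.character(sort(unique(as.integer(dat$chromosome))))
  offsets <- c(0, cumsum(MOUSE_AUTOSOME_MBP * 1e6))
  dat$genome_pos <- offsets[as.integer(dat$chromosome)] + dat$position_bp
  dat$chrom_parity <- factor(as.integer(dat$chromosome) %% 2)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$genome_pos / 1e6,
                                         y = .data$neglog10p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chrom_parity),
                        size = 2, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`0` = "grey40", `1` = "#2c7fb8")) +
    ggplot2::labs(x = "genomic position (Mb)",
                  y = expression(-log[10] * italic(P)),
                  title = "Single-locus linkage scan") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed", colour = "red")
    if (label_candidates) {
      hits <- dat[!is.na(dat$best_p) & dat$best_p < threshold, , drop = FALSE]
      if (nrow(hits) > 0L) {
        p <- p + ggplot2::geom_text(
          data = hits,
          ggplot2::aes(label = .data$gene),
          vjust = -0.6, size = 3
        )
      }
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.manhattan_scan <- function(object, threshold = NULL, ...) {
  plot_manhattan(object, threshold = threshold, ...)
}

#' Distribution of per-mouse fundus scores
#'
#' Histogram of the 0-8 per-mouse scores, optionally filled by the
#' genotype at a site of interest.
#'
#' @param phenotypes Per-mouse tibble from [phenotype_table()].
#' @param genotypes Optional wide genotype table; required with
#'   `site`.
#' @param site Optional `site_id` whose REF/HET/VAR calls colour the
#'   bars.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(phenotypes, genotypes = NULL,
                                    site = NULL) {
  if (!is.data.frame(phenotypes) ||
      !all(c("mouse_id", "mouse_score") %in% names(phenotypes))) {
    abort_arg("`phenotypes` must have mouse_id and mouse_score columns.")
  }
  dat <- as_tibble(phenotypes)
  if (!is.null(site)) {
    if (is.null(genotypes) || !site %in% names(genotypes)) {
      abort_arg("`genotypes` with the requested site column is required.")
    }
    dat$genotype <- factor(
      genotypes[[site]][match(dat$mouse_id, genotypes$mouse_id)],
      levels = GENOTYPE_LEVELS
    )
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$mouse_score,
                                           fill = .data$genotype))
  } else {
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$mouse_score))
  }
  p +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::scale_x_continuous(breaks = 0:8, limits = c(-0.5, 8.5)) +
    ggplot2::labs(x = "per-mouse fundus spot score (0-8)", y = "mice",
                  title = "Fundus spot score distribution") +
    ggplot2::theme_minimal()
}
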