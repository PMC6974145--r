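# ggplot2 views of the main result types.

#' Plot effect sizes of a multi-level eQTL scan
#'
#' One point per feature, `beta` with a 95% normal-approximation interval,
#' faceted by analysis level.
#'
#' @param object A `multilevel_eqtl` tibble from [run_multilevel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.multilevel_eqtl <- function(object, ...) {
  df <- filter(object, !is.na(.data$beta)) |>
    mutate(level = factor(.data$level, levels = eqtl_levels))
  ggplot(df, aes(x = .data$beta, y = .data$feature_id)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_errorbarh(aes(xmin = .data$beta - 1.96 * .data$se,
                       xmax = .data$beta + 1.96 * .data$se),
                   height = 0.2, colour = "grey40") +
    geom_point(aes(colour = .data$p < 0.05)) +
    facet_grid(rows = vars(.data$level), scales = "free_y", space = "free_y") +
    labs(x = "effect per minor-allele copy (phenotype units)",
         y = NULL, colour = "p < 0.05") +
    theme_bw()
}

#' Plot a direction-of-effect concordance report
#'
#' Observed t statistics coloured by agreement with the expected sign
#' pattern.
#'
#' @param object A `direction_report` from [direction_pattern()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.direction_report <- function(object, ...) {
  df <- object$table |>
    mutate(expected = factor(.data$expected_sign,
                             levels = c(-1, 0, 1),
                             labels = c("down", "null", "up")))
  ggplot(df, aes(x = .data$t, y = .data$feature_id,
                 colour = .data$concordant, shape = .data$expected)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_point(size = 3) +
    labs(x = "t statistic", y = NULL, colour = "concordant",
         shape = "expected") +
    theme_bw()
}

#' Exon-inclusion fraction by genotype
#'
#' Boxplots of the per-sample PSI (true or estimated) stratified by dosage
#' at a SNP.
#'
#' @param psi Numeric PSI vector.
#' @param dosage Integer dosage vector aligned with `psi`.
#' @param snp Label used in the x-axis title.
#' @return A ggplot object.
#' @export
plot_psi_by_genotype <- function(psi, dosage, snp = "SNP") {
  df <- tibble(psi = psi, dosage = factor(dosage)) |> filter(!is.na(.data$psi))
  ggplot(df, aes(x = .data$dosage, y = .data$psi)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    labs(x = sprintf("minor-allele dosage at %s", snp),
         y = "exon inclusion (PSI)") +
    theme_bw()
}
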