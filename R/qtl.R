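# Additive linear-model cis-eQTL fitting, conditional two-SNP analysis,
# multi-level scans and the direction-of-effect summary.

eqtl_row <- function(feature_id, level, beta = NA_real_, se = NA_real_,
                     t = NA_real_, p = NA_real_, n = NA_integer_,
                     note = NA_character_) {
  tibble(feature_id = feature_id, level = level, beta = beta, se = se,
         t = t, p = p, n = n, note = note)
}

# covariates -> numeric model matrix (no intercept column), with a
# rank-deficiency check that names the offending column
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = n, ncol = 0))
  covariates <- as.data.frame(covariates)
  C <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  qrX <- qr(cbind(1, C))
  if (qrX$rank < ncol(C) + 1L) {
    dropped <- colnames(C)[setdiff(seq_len(ncol(C)),
                                   qrX$pivot[seq_len(qrX$rank)] - 1L)]
    abort(sprintf("covariate column(s) rank-deficient: %s",
                  paste(dropped, collapse = ", ")))
  }
  C
}

#' Fit an additive cis-eQTL linear model for one feature
#'
#' Ordinary least squares `y = mu + beta * g + C gamma + e`, with a
#' two-sided t-test on `beta` (`n - k - 2` residual degrees of freedom for k
#' covariate columns). Samples with a missing phenotype, dosage or covariate
#' are dropped listwise. A genotype that is constant after filtering, or too
#' few complete cases, yields an untestable result (`NA` statistics with a
#' `note`) rather than an error. With a perfect fit the p-value is reported
#' at the smallest positive double rather than 0.
#'
#' @param y Numeric phenotype vector (one feature, one value per sample).
#' @param g Integer minor-allele dosage vector (0/1/2, `NA` allowed),
#'   aligned with `y`.
#' @param covariates Optional data frame of covariates aligned with `y`;
#'   factors are expanded via `model.matrix()`.
#' @param feature_id,level Labels copied into the result.
#' @param log1p_transform If `TRUE`, analyse `log1p(y)`.
#' @return A one-row tibble: `feature_id`, `level`, `beta`, `se`, `t`, `p`,
#'   `n`, `note`.
#' @export
fit_eqtl <- function(y, g, covariates = NULL, feature_id = NA_character_,
                     level = NA_character_, log1p_transform = FALSE) {
  stopifnot(length(y) == length(g))
  if (log1p_transform) y <- log1p(y)
  C <- covariate_matrix(covariates, length(y))
  ok <- complete.cases(y, g, if (ncol(C)) C else NULL)
  y <- y[ok]; g <- g[ok]
  C <- C[ok, , drop = FALSE]
  n <- length(y)
  k <- ncol(C)
  if (n < k + 3L) {
    return(eqtl_row(feature_id, level, n = n, note = "too few complete cases"))
  }
  if (length(unique(g)) < 2L) {
    return(eqtl_row(feature_id, level, n = n, note = "constant genotype"))
  }
  dat <- data.frame(.y = y, .g = g)
  if (k) {
    Cd <- as.data.frame(C)
    names(Cd) <- sprintf(".c%d", seq_len(k))  # avoid name collisions
    dat <- cbind(dat, Cd)
  }
  fit <- lm(.y ~ ., data = dat)
  # a perfect fit is a documented case (p floored below); silence only the
  # summary.lm warning it triggers
  cf <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- cf[".g", "Estimate"]
  se <- cf[".g", "Std. Error"]
  tval <- beta / se
  p <- 2 * pt(abs(tval), df = fit$df.residual, lower.tail = FALSE)
  p <- max(p, .Machine$double.xmin)  # numerical floor, p in (0, 1]
  eqtl_row(feature_id, level, beta = beta, se = se, t = tval, p = p, n = n)
}

#' Conditional eQTL test of one SNP given another
#'
#' Retests `g_test` with the dosage of `g_condition` appended to the
#' covariates, separating linkage-disequilibrium proxies from independent
#' effects: a pure proxy's signal collapses once the causal SNP is
#' conditioned on. If the two dosage vectors are (near-)collinear
#' (`|r| > 0.999` on complete cases) the test is flagged untestable.
#'
#' @param y,covariates As in [fit_eqtl()].
#' @param g_test Dosage vector to test.
#' @param g_condition Dosage vector to condition on (shared samples).
#' @inheritParams fit_eqtl
#' @return A one-row tibble as from [fit_eqtl()].
#' @export
conditional_eqtl <- function(y, g_test, g_condition, covariates = NULL,
                             feature_id = NA_character_,
                             level = NA_character_, log1p_transform = FALSE) {
  stopifnot(length(g_test) == length(g_condition))
  ok <- complete.cases(g_test, g_condition)
  r <- if (sum(ok) >= 3 && sd(g_test[ok]) > 0 && sd(g_condition[ok]) > 0) {
    cor(g_test[ok], g_condition[ok])
  } else 1
  if (abs(r) > 0.999) {
    return(eqtl_row(feature_id, level, n = sum(ok),
                    note = "collinear with conditioning SNP"))
  }
  covariates <- if (is.null(covariates)) {
    data.frame(.g_condition = g_condition)
  } else {
    cbind(as.data.frame(covariates), .g_condition = g_condition)
  }
  fit_eqtl(y, g_test, covariates, feature_id = feature_id, level = level,
           log1p_transform = log1p_transform)
}

eqtl_levels <- c("gene", "transcript", "exon", "junction", "splice_site",
                 "intron")

#' Run the eQTL model at every feature level
#'
#' Fits [fit_eqtl()] for each feature of a long phenotype table carrying the
#' five-level quantification (plus gene level), against one SNP's dosages.
#'
#' @param phenotypes Long tibble with columns `level`, `feature_id`,
#'   `sample_id`, `value` (normalized phenotype).
#' @param genotype Tibble with columns `sample_id` and `dosage`.
#' @param covariates Optional tibble with `sample_id` plus covariate
#'   columns.
#' @param condition_on Optional second genotype tibble (`sample_id`,
#'   `dosage`); when given, every test conditions on it via
#'   [conditional_eqtl()].
#' @param log1p_transform Passed through to [fit_eqtl()].
#' @return A tibble of class `multilevel_eqtl`, one row per feature,
#'   ordered by (level, feature_id) with levels in the order gene,
#'   transcript, exon, junction, splice_site, intron.
#' @export
run_multilevel <- function(phenotypes, genotype, covariates = NULL,
                           condition_on = NULL, log1p_transform = FALSE) {
  needed <- c("level", "feature_id", "sample_id", "value")
  if (!all(needed %in% names(phenotypes))) {
    abort("phenotypes must have columns level, feature_id, sample_id, value")
  }
  missing_ids <- setdiff(unique(phenotypes$sample_id), genotype$sample_id)
  if (length(missing_ids)) {
    abort(sprintf("sample id(s) missing from genotype: %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  samples <- genotype$sample_id
  g <- genotype$dosage
  cov_df <- NULL
  if (!is.null(covariates)) {
    if (!all(samples %in% covariates$sample_id)) {
      abort("sample id(s) missing from covariates")
    }
    cov_df <- as.data.frame(
      covariates[match(samples, covariates$sample_id), , drop = FALSE]
    )
    cov_df$sample_id <- NULL
  }
  g2 <- NULL
  if (!is.null(condition_on)) {
    if (!all(samples %in% condition_on$sample_id)) {
      abort("sample id(s) missing from conditioning genotype")
    }
    g2 <- condition_on$dosage[match(samples, condition_on$sample_id)]
  }
  res <- phenotypes |>
    tidyr::nest(.by = c("level", "feature_id")) |>
    pmap(function(level, feature_id, data) {
      y <- data$value[match(samples, data$sample_id)]
      if (is.null(g2)) {
        fit_eqtl(y, g, cov_df, feature_id = feature_id, level = level,
                 log1p_transform = log1p_transform)
      } else {
        conditional_eqtl(y, g, g2, cov_df, feature_id = feature_id,
                         level = level, log1p_transform = log1p_transform)
      }
    }) |>
    list_rbind() |>
    mutate(level = factor(.data$level, levels = eqtl_levels)) |>
    arrange(.data$level, .data$feature_id) |>
    mutate(level = as.character(.data$level))
  class(res) <- c("multilevel_eqtl", class(res))
  res
}

#' Benjamini-Hochberg adjustment helper
#'
#' Adds a `p_adj` column (BH across all testable features). The primary
#' analyses report raw per-feature p-values; this helper is provided for
#' users who scan many features and is off by default everywhere.
#'
#' @param results A tibble with a `p` column (e.g. from [run_multilevel()]).
#' @return The input with a `p_adj` column appended.
#' @export
adjust_fdr <- function(results) {
  mutate(results, p_adj = p.adjust(.data$p, method = "BH"))
}

#' Expected direction-of-effect pattern for a cassette-exon splice QTL
#'
#' The signed signature of a variant promoting cassette-exon inclusion, per
#' extra minor-allele copy: the exon-skipping transcript down, the two
#' inclusion junctions (e7-e8, e8-e9) up, the skipping junction (e7-e9)
#' down, the activities of the acceptor and donor sites flanking the
#' cassette up, the two neighbouring introns down, and no effect on total
#' gene expression (expected sign 0 = not significant). Feature ids match
#' the naming used by [simulate_splicing_study()].
#'
#' @return A tibble with columns `feature_id`, `level`, `expected_sign`
#'   (-1, 0 or +1).
#' @export
cassette_direction_expectation <- function() {
  tribble(
    ~feature_id,       ~level,        ~expected_sign,
    "skip_transcript", "transcript",  -1,
    "e7-e8",           "junction",     1,
    "e8-e9",           "junction",     1,
    "e7-e9",           "junction",    -1,
    "exon8_acceptor",  "splice_site",  1,
    "exon8_donor",     "splice_site",  1,
    "intron7",         "intron",      -1,
    "intron9",         "intron",      -1,
    "gene",            "gene",         0
  )
}

#' Compare fitted effect directions with an expected pattern
#'
#' For every expected feature with a nonzero expected sign, concordance
#' means `sign(beta)` matches; for an expected sign of 0 the feature counts
#' as concordant when it is not significant at `alpha`. The summary
#' concordance fraction is computed over the signed features only; the
#' null-expected features are reported separately.
#'
#' @param results Tibble of eQTL results (needs `feature_id`, `beta`, `p`).
#' @param expected Tibble with `feature_id` and `expected_sign`; defaults to
#'   [cassette_direction_expectation()].
#' @param alpha Significance level used for the sign-0 features.
#' @return An object of class `direction_report`: list with `table` (per
#'   feature), `concordance` (fraction of signed features matching),
#'   `n_signed`, `null_ok` (logical per sign-0 feature).
#' @export
direction_pattern <- function(results, expected = cassette_direction_expectation(),
                              alpha = 0.05) {
  unmapped <- setdiff(expected$feature_id, results$feature_id)
  if (length(unmapped)) {
    abort(sprintf("expected feature(s) not in results: %s",
                  paste(unmapped, collapse = ", ")))
  }
  tab <- expected |>
    select("feature_id", "expected_sign") |>
    left_join(results, by = "feature_id") |>
    mutate(
      observed_sign = sign(.data$beta),
      concordant = if_else(.data$expected_sign == 0,
                           .data$p > alpha,
                           .data$observed_sign == .data$expected_sign)
    )
  signed <- filter(tab, .data$expected_sign != 0)
  structure(
    list(table = tab,
         concordance = mean(signed$concordant),
         n_signed = nrow(signed),
         null_ok = setNames(tab$concordant[tab$expected_sign == 0],
                            tab$feature_id[tab$expected_sign == 0])),
    class = "direction_report"
  )
}

#' @export
print.direction_report <- function(x, ...) {
  cat(sprintf("<direction_report> %.0f/%d signed features concordant (%.2f)\n",
              x$concordance * x$n_signed, x$n_signed, x$concordance))
  if (length(x$null_ok)) {
    cat(sprintf("null-expected feature(s) non-significant: %s\n",
                paste(sprintf("%s=%s", names(x$null_ok), x$null_ok),
                      collapse = ", ")))
  }
  print(select(x$table, "feature_id", "expected_sign", "beta", "p",
               "concordant"))
  invisible(x)
}
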