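# Biometric group comparisons and the gene-expression-to-phenotype Pearson
# correlation screen within the insulin-treated group.

#' Pearson correlation with t-distribution p-value
#'
#' Product-moment correlation; the two-tailed p-value comes from the t
#' distribution with `n - 2` degrees of freedom ([stats::cor.test()]).
#' A zero-variance input raises an undefined-correlation error rather than
#' returning `NaN`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r`, `p`, `n`.
#' @examples
#' pearson_cor(c(1, 2, 3), c(1, 2, 4))  # r = 0.982
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate gene expression with metabolic phenotypes
#'
#' Screens each requested gene's normalized expression against each
#' requested phenotype by Pearson correlation within one experimental group
#' (by default the insulin-treated diabetic animals, where residual
#' dysregulation is the question of interest). Significance is flagged at
#' `p < alpha` with no multiplicity correction, as is conventional for this
#' small-panel screen.
#'
#' @param em A normalized [expression_matrix()].
#' @param phenotype `data.frame` from [simulate_phenotype()] or equivalent
#'   (columns `sample_id` plus phenotype variables).
#' @param design A [sample_design()].
#' @param genes Character vector of probe/gene ids (rows of `em`).
#' @param phenotypes Which phenotype columns to screen.
#' @param group Group restriction (`NULL` for all samples).
#' @param log2_expression Correlate log2 intensities instead of linear.
#' @param alpha Significance threshold.
#' @return `data.frame` with one row per (gene, phenotype): `r`, `p`, `n`,
#'   `significant`.
#' @export
correlate_genes <- function(em, phenotype, design, genes,
                            phenotypes = c("blood_glucose", "hba1c_pct"),
                            group = "DI", log2_expression = FALSE,
                            alpha = 0.05) {
  miss <- setdiff(genes, rownames(em$signal))
  if (length(miss))
    stop("integrity error: genes not in matrix: ", paste(miss, collapse = ", "))
  samples <- design$sample_id
  if (!is.null(group)) samples <- design$sample_id[design$group == group]
  samples <- intersect(samples, colnames(em$signal))
  pheno_idx <- match(samples, phenotype$sample_id)
  if (anyNA(pheno_idx))
    stop("integrity error: phenotype missing for samples: ",
         paste(samples[is.na(pheno_idx)], collapse = ", "))
  out <- expand.grid(gene = genes, phenotype = phenotypes,
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_; out$n <- length(samples)
  for (i in seq_len(nrow(out))) {
    e <- em$signal[out$gene[i], samples]
    if (log2_expression) e <- log2(e)
    ph <- phenotype[[out$phenotype[i]]][pheno_idx]
    if (anyNA(ph))
      stop("integrity error: missing ", out$phenotype[i], " values")
    pc <- pearson_cor(e, ph)
    out$r[i] <- pc$r; out$p[i] <- pc$p
  }
  out$significant <- out$p < alpha
  out
}

#' Biometric group summary and tests
#'
#' Per timepoint and phenotype variable: group means with SEM, then the
#' design-appropriate test — a two-tailed t-test for the two-group one-month
#' cohort, a one-way ANOVA with SNK post-hoc for the three-group three-month
#' cohort.
#'
#' @param phenotype Phenotype `data.frame` (`sample_id` + variables).
#' @param design A [sample_design()].
#' @param variables Phenotype columns to summarize.
#' @param alpha Significance level for the SNK post-hoc.
#' @return Nested list: `[[timepoint]][[variable]]` with `means`, `sem`,
#'   `n`, and either `t_p` or `anova_p` + `snk_pairs`.
#' @export
biometric_summary <- function(phenotype, design,
                              variables = c("blood_glucose", "hba1c_pct",
                                            "body_weight"),
                              alpha = 0.05) {
  idx <- match(design$sample_id, phenotype$sample_id)
  if (anyNA(idx))
    stop("integrity error: phenotype missing for samples: ",
         paste(design$sample_id[is.na(idx)], collapse = ", "))
  out <- list()
  for (tp in levels(droplevels(design$timepoint))) {
    sel <- design$timepoint == tp
    out[[tp]] <- list()
    for (v in variables) {
      vals <- phenotype[[v]][idx][sel]
      grp <- droplevels(design$group[sel])
      ok <- !is.na(vals)
      if (!any(ok)) next
      groups <- split(vals[ok], droplevels(grp[ok]))
      if (any(vapply(groups, length, 1L) < 2L)) next
      res <- list(
        means = vapply(groups, mean, 1),
        sem = vapply(groups, function(x) stats::sd(x) / sqrt(length(x)), 1),
        n = vapply(groups, length, 1L))
      if (length(groups) == 2L) {
        res$t_p <- probe_ttest(groups[[1L]], groups[[2L]])
      } else {
        an <- anova_oneway(groups)
        res$anova_p <- an$p
        if (an$p < alpha) {
          snk <- snk_posthoc(groups, alpha)
          res$snk_pairs <- with(snk[snk$significant, , drop = FALSE],
                                paste(group_i, group_j, sep = ":"))
        } else res$snk_pairs <- character(0)
      }
      out[[tp]][[v]] <- res
    }
  }
  out
}
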