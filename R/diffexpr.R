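# Per-probe pairwise differential-expression statistics: two-sample t-test
# p-values and signed fold changes on normalized linear-scale group means,
# with the joint significance rule (p < alpha AND |fold change| > cutoff,
# both strict).

#' Pairwise comparison specification
#'
#' @param group_a,group_b Group labels being compared (`b` relative to `a`).
#' @param alpha Two-tailed significance threshold (strict `<`).
#' @param fc_cutoff Absolute fold-change cutoff (strict `>`); `1.2` is the
#'   conventional value for this design.
#' @param test_variant `"pooled"` (pooled-variance t with
#'   `df = n_a + n_b - 2`, the default) or `"welch"`.
#' @return A list of class `"comparison_spec"`.
#' @export
comparison_spec <- function(group_a, group_b, alpha = 0.05, fc_cutoff = 1.2,
                            test_variant = c("pooled", "welch")) {
  if (!(alpha > 0 && alpha < 1)) stop("require 0 < alpha < 1")
  if (fc_cutoff < 1) stop("require fc_cutoff >= 1")
  structure(list(group_a = group_a, group_b = group_b, alpha = alpha,
                 fc_cutoff = fc_cutoff,
                 test_variant = match.arg(test_variant)),
            class = "comparison_spec")
}

#' Two-sample two-tailed t-test p-value for one probe
#'
#' Wraps [stats::t.test()] with the degenerate-data conventions a
#' probe-level screen needs: when both groups have zero variance, identical
#' means give `p = 1` and distinct means give `p = 0` (with a warning, since
#' no distributional statement is possible).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return Two-tailed p-value in `[0, 1]`.
#' @examples
#' probe_ttest(c(1, 2, 3), c(4, 5, 6))  # 0.0214 (pooled t, df = 4)
#' @export
probe_ttest <- function(values_a, values_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs >= 2 values")
  if (!all(is.finite(values_a)) || !all(is.finite(values_b)))
    stop("values must be finite")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) return(1)
    warning("zero variance in both groups with unequal means; p = 0 by convention")
    return(0)
  }
  stats::t.test(values_a, values_b,
                var.equal = (variant == "pooled"))$p.value
}

#' Signed fold change between two group means
#'
#' The ratio of group means reported with its direction of regulation:
#' `|signed_fc| = max(mean_b / mean_a, mean_a / mean_b)`, positive when
#' `mean_b > mean_a` (up in b relative to a) and negative when down, so that
#' downregulation reads as a negative reciprocal (-2 means halved). Equal
#' means give `+1` with direction `"none"`.
#'
#' @param mean_a,mean_b Positive group means (normalized intensity).
#' @return List with `signed_fc` and `direction` (`"up"`, `"down"`,
#'   `"none"`).
#' @examples
#' fold_change(10, 5)   # signed_fc -2, down
#' fold_change(10, 12)  # signed_fc +1.2, up
#' @export
fold_change <- function(mean_a, mean_b) {
  if (!is.finite(mean_a) || !is.finite(mean_b) || mean_a <= 0 || mean_b <= 0)
    stop("domain error: group means must be positive")
  if (mean_a == mean_b) return(list(signed_fc = 1, direction = "none"))
  if (mean_b > mean_a) list(signed_fc = mean_b / mean_a, direction = "up")
  else list(signed_fc = -mean_a / mean_b, direction = "down")
}

#' Joint differential-expression call
#'
#' A probe is called differentially expressed iff its p-value is strictly
#' below `alpha` and its absolute fold change strictly above `fc_cutoff`.
#' Both bounds are exclusive, so `p = 0.05` or `|fc| = 1.2` exactly fail.
#'
#' @param stats List/row with `p_value` and `signed_fc`.
#' @param spec A [comparison_spec()].
#' @return Logical.
#' @export
call_de <- function(stats, spec) {
  as.logical(stats$p_value < spec$alpha &
             abs(stats$signed_fc) > spec$fc_cutoff)
}

# Vectorized two-sample t-tests over the rows of two matrices.
# Returns p-values; pooled or Welch. Cross-checked against stats::t.test in
# the unit tests.
row_ttest_p <- function(mat_a, mat_b, variant = "pooled") {
  na <- ncol(mat_a); nb <- ncol(mat_b)
  ma <- rowMeans(mat_a); mb <- rowMeans(mat_b)
  va <- rowSums((mat_a - ma)^2) / (na - 1)
  vb <- rowSums((mat_b - mb)^2) / (nb - 1)
  if (variant == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep.int(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate rows: zero variance in both groups
  degen <- se == 0
  if (any(degen)) p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  p
}

# Vectorized signed fold change of b relative to a.
row_signed_fc <- function(mean_a, mean_b) {
  ifelse(mean_b >= mean_a, mean_b / pmax(mean_a, .Machine$double.xmin),
         -mean_a / pmax(mean_b, .Machine$double.xmin))
}

#' All three pairwise comparisons for every probe
#'
#' Computes, for each probe of a filtered matrix, the two-tailed t-test
#' p-value and signed fold change for ND vs D, ND vs DI and D vs DI
#' (second group relative to the first), on normalized linear-scale
#' intensities.
#'
#' @param em A filtered, normalized [expression_matrix()].
#' @param design A [sample_design()] containing all three groups.
#' @param alpha,fc_cutoff Thresholds recorded for the downstream DE call
#'   (ND vs D).
#' @param variant `"pooled"` or `"welch"` t-test.
#' @return `data.frame` with one row per probe: group means, `p_*` and
#'   `fc_*` for the three comparisons, the primary DE call `de_ND_D`, and
#'   any annotation columns.
#' @export
run_all_comparisons <- function(em, design, alpha = 0.05, fc_cutoff = 1.2,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  design <- check_design(em, design)
  gs <- group_samples(design)
  absent <- names(gs)[vapply(gs, length, 1L) == 0L]
  if (length(absent))
    stop("config error: groups absent from design: ",
         paste(absent, collapse = ", "))
  sub <- lapply(gs, function(s) em$signal[, s, drop = FALSE])
  means <- lapply(sub, rowMeans)

  comp <- list(ND_D = c("ND", "D"), ND_DI = c("ND", "DI"), D_DI = c("D", "DI"))
  out <- data.frame(probe_id = rownames(em$signal), stringsAsFactors = FALSE)
  out$mean_ND <- means$ND; out$mean_D <- means$D; out$mean_DI <- means$DI
  for (nm in names(comp)) {
    a <- comp[[nm]][1L]; b <- comp[[nm]][2L]
    out[[paste0("p_", nm)]] <- row_ttest_p(sub[[a]], sub[[b]], variant)
    out[[paste0("fc_", nm)]] <- row_signed_fc(means[[a]], means[[b]])
  }
  out$de_ND_D <- out$p_ND_D < alpha & abs(out$fc_ND_D) > fc_cutoff
  extra <- setdiff(names(em$annotation), "probe_id")
  if (length(extra)) out[, extra] <- em$annotation[, extra, drop = FALSE]
  attr(out, "alpha") <- alpha
  attr(out, "fc_cutoff") <- fc_cutoff
  attr(out, "variant") <- variant
  out
}
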