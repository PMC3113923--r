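# The core computation: partition diabetes-regulated probes into the four
# insulin-response categories from their three pairwise comparison
# statistics, and refine genes measured at two timepoints into the six
# Rescued/Prevented temporal categories.

#' Classify one differentially expressed probe by insulin response
#'
#' Decision tree over the three pairwise comparisons, applied to a probe
#' already called differentially expressed between non-diabetic and diabetic
#' groups: (1) if ND vs DI is significant with direction opposite to
#' ND vs D, the change is `Inverted`; (2) if ND vs DI is significant in the
#' same direction, the insulin-treated group remains different from control
#' in the same way — `NotNormalized`; (3) otherwise, if D vs DI is
#' significant, treatment moved expression away from the diabetic level —
#' `Normalized`; (4) otherwise `PartiallyNormalized` (no longer
#' distinguishable from control, yet not significantly different from the
#' untreated diabetic group either). Exactly one branch fires; the evidence
#' records the path for audit.
#'
#' Secondary comparisons (ND vs DI, D vs DI) use the p-value criterion only
#' by default; the fold-change cutoff applies to the primary ND vs D call.
#' Set `secondary_fc = TRUE` to require the cutoff everywhere.
#'
#' @param stats One-row list/data.frame with `p_ND_D`, `fc_ND_D`, `p_ND_DI`,
#'   `fc_ND_DI`, `p_D_DI`, `fc_D_DI` (as produced by
#'   [run_all_comparisons()]).
#' @param alpha Significance threshold for all comparisons (strict `<`).
#' @param fc_cutoff Fold-change cutoff of the primary DE call.
#' @param secondary_fc Apply the fold-change cutoff to the secondary
#'   comparisons too?
#' @return List with `category` (factor over the four response levels) and
#'   `evidence` (significance flags, directions and the ordered `rule_path`
#'   fired).
#' @export
classify_response <- function(stats, alpha = 0.05, fc_cutoff = 1.2,
                              secondary_fc = FALSE) {
  de <- stats$p_ND_D < alpha & abs(stats$fc_ND_D) > fc_cutoff
  if (!isTRUE(as.logical(de)))
    stop("contract error: classify_response called on a probe not differentially ",
         "expressed in ND vs D")
  sig2 <- function(p, fc) p < alpha && (!secondary_fc || abs(fc) > fc_cutoff)
  sig_nd_di <- sig2(stats$p_ND_DI, stats$fc_ND_DI)
  sig_d_di <- sig2(stats$p_D_DI, stats$fc_D_DI)
  same_dir <- sign(stats$fc_ND_DI) == sign(stats$fc_ND_D)
  path <- "de_ND_D"
  if (sig_nd_di && !same_dir) {
    category <- "Inverted"; path <- c(path, "sig_ND_DI", "opposite_direction")
  } else if (sig_nd_di) {
    category <- "NotNormalized"; path <- c(path, "sig_ND_DI", "same_direction")
  } else if (sig_d_di) {
    category <- "Normalized"; path <- c(path, "ns_ND_DI", "sig_D_DI")
  } else {
    category <- "PartiallyNormalized"; path <- c(path, "ns_ND_DI", "ns_D_DI")
  }
  list(category = factor(category, levels = RESPONSE_LEVELS),
       evidence = list(probe_id = stats$probe_id,
                       de_ND_D = TRUE,
                       de_direction = if (stats$fc_ND_D > 0) "up" else "down",
                       sig_ND_DI = sig_nd_di,
                       dir_ND_DI = if (stats$fc_ND_DI > 0) "up"
                                   else if (stats$fc_ND_DI < 0) "down"
                                   else "none",
                       sig_D_DI = sig_d_di,
                       rule_path = path))
}

#' Classify every differentially expressed probe of a comparison table
#'
#' Vectorized application of [classify_response()] to the DE subset of a
#' [run_all_comparisons()] table.
#'
#' @inheritParams classify_response
#' @param stats Full comparison table.
#' @return The DE rows of `stats` with an added `category` factor column.
#' @export
classify_probes <- function(stats, alpha = 0.05, fc_cutoff = 1.2,
                            secondary_fc = FALSE) {
  de <- stats$p_ND_D < alpha & abs(stats$fc_ND_D) > fc_cutoff
  out <- stats[de, , drop = FALSE]
  sig_nd_di <- out$p_ND_DI < alpha &
    (!secondary_fc | abs(out$fc_ND_DI) > fc_cutoff)
  sig_d_di <- out$p_D_DI < alpha &
    (!secondary_fc | abs(out$fc_D_DI) > fc_cutoff)
  same_dir <- sign(out$fc_ND_DI) == sign(out$fc_ND_D)
  category <- ifelse(sig_nd_di & !same_dir, "Inverted",
              ifelse(sig_nd_di, "NotNormalized",
              ifelse(sig_d_di, "Normalized", "PartiallyNormalized")))
  out$category <- factor(category, levels = RESPONSE_LEVELS)
  rownames(out) <- NULL
  out
}

#' Category counts, total and integer percentages
#'
#' Percentages are computed on the number of differentially expressed probes
#' and rounded half-up to whole percent (so 4.72% reports as 5%).
#'
#' @param categories Factor/character vector of response categories, or a
#'   named count vector.
#' @return List with `counts` (named, all four levels), `total` and
#'   `percent` (integer).
#' @examples
#' partition_counts(c(Normalized = 789, PartiallyNormalized = 514,
#'                    NotNormalized = 65, Inverted = 8))
#' @export
partition_counts <- function(categories) {
  if (is.numeric(categories)) {
    counts <- integer(length(RESPONSE_LEVELS))
    names(counts) <- RESPONSE_LEVELS
    counts[names(categories)] <- as.integer(categories)
  } else {
    counts <- table(factor(as.character(categories), levels = RESPONSE_LEVELS))
    counts <- stats::setNames(as.integer(counts), RESPONSE_LEVELS)
  }
  total <- sum(counts)
  percent <- if (total > 0) floor(100 * counts / total + 0.5) else counts * 0L
  list(counts = counts, total = total,
       percent = stats::setNames(as.integer(percent), RESPONSE_LEVELS))
}

#' Temporal (Rescued/Prevented) category of a gene
#'
#' Combines a gene's differential-expression status at one month of diabetes
#' (before insulin treatment starts) with its three-month insulin-response
#' category. Changes already manifest at one month map to the Rescued family
#' (`Normalized -> Rescued`, `PartiallyNormalized -> PartiallyRescued`,
#' `NotNormalized -> NotRescued`); changes absent at one month map to the
#' Prevented family (`Normalized -> Prevented`, etc.). A three-month
#' `Inverted` category has no defined temporal label and returns `NA`
#' (explicitly unmapped, not an error).
#'
#' @param de_m1 Logical: differentially expressed (ND vs D) at one month?
#' @param category_m3 Three-month [classify_response()] category.
#' @return Factor over the six temporal levels (`NA` for `Inverted`).
#' @examples
#' classify_temporal(TRUE, "Normalized")    # Rescued
#' classify_temporal(FALSE, "NotNormalized")  # NotPrevented
#' @export
classify_temporal <- function(de_m1, category_m3) {
  category_m3 <- as.character(category_m3)
  if (length(de_m1) != length(category_m3))
    stop("`de_m1` and `category_m3` must have equal length")
  if (!all(category_m3 %in% RESPONSE_LEVELS))
    stop("unknown three-month category: ",
         paste(setdiff(category_m3, RESPONSE_LEVELS), collapse = ", "))
  rescued <- c(Normalized = "Rescued", PartiallyNormalized = "PartiallyRescued",
               NotNormalized = "NotRescued")
  prevented <- c(Normalized = "Prevented",
                 PartiallyNormalized = "PartiallyPrevented",
                 NotNormalized = "NotPrevented")
  lab <- ifelse(category_m3 == "Inverted", NA_character_,
                ifelse(de_m1, rescued[category_m3], prevented[category_m3]))
  factor(lab, levels = TEMPORAL_LEVELS)
}

#' Build result rows from a classified comparison table
#'
#' Arranges a [classify_probes()] table into the column order used by
#' [write_result_rows()].
#'
#' @param classified Output of [classify_probes()].
#' @return `data.frame` of result rows.
#' @export
as_result_rows <- function(classified) {
  for (f in c("gene_symbol", "entrez_id", "gene_name"))
    if (!f %in% names(classified)) classified[[f]] <- NA_character_
  classified[, c(RESULT_COLUMNS, "category"), drop = FALSE]
}
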