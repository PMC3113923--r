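# Relative quantification by 2^-ddCt with an endogenous control, and the
# confirmation statistics: one-way ANOVA with Student-Newman-Keuls post-hoc
# tests at three months, a two-tailed t-test at one month.

#' 2^-ddCt relative quantification
#'
#' Per sample and target gene, `dCt = Ct(target) - Ct(control gene)`; the
#' calibrator is the mean dCt of the non-diabetic group at the same
#' timepoint, `ddCt = dCt - calibrator mean`, and relative expression
#' `rq = 2^-ddCt` (amplification efficiency fixed at 2, the method's
#' assumption). The calibrator group's geometric-mean rq is 1 by
#' construction.
#'
#' @param records qPCR record `data.frame` (see [read_qpcr_table()]).
#' @param design A [sample_design()] covering every sample in `records`.
#' @param calibrator_group Group whose mean dCt anchors `ddCt` (default the
#'   non-diabetic control group).
#' @return `data.frame` with `sample_id`, `gene`, `group`, `timepoint`,
#'   `delta_ct`, `ddct`, `rq`.
#' @examples
#' recs <- data.frame(sample_id = rep(c("a", "b"), each = 2),
#'                    gene = rep(c("Actb", "Tg"), 2),
#'                    ct = c(18, 26, 18, 24),
#'                    is_endogenous_control = rep(c(TRUE, FALSE), 2))
#' des <- sample_design(c("a", "b"), c("ND", "D"), "M3")
#' ddct(recs, des)
#' @export
ddct <- function(records, design, calibrator_group = "ND") {
  ctrl_gene <- validate_qpcr_records(records)
  miss <- setdiff(unique(records$sample_id), design$sample_id)
  if (length(miss))
    stop("integrity error: samples not in design: ", paste(miss, collapse = ", "))
  ctrl <- records[records$is_endogenous_control, , drop = FALSE]
  ctrl_ct <- stats::setNames(ctrl$ct, ctrl$sample_id)
  targets <- records[!records$is_endogenous_control, , drop = FALSE]
  if (!nrow(targets)) stop("integrity error: no target-gene rows")
  idx <- match(targets$sample_id, design$sample_id)
  out <- data.frame(sample_id = targets$sample_id, gene = targets$gene,
                    group = design$group[idx],
                    timepoint = design$timepoint[idx],
                    delta_ct = targets$ct - ctrl_ct[targets$sample_id],
                    stringsAsFactors = FALSE)
  out$ddct <- NA_real_
  for (tp in unique(out$timepoint)) {
    for (g in unique(out$gene)) {
      sel <- out$timepoint == tp & out$gene == g
      cal <- sel & out$group == calibrator_group
      if (!any(cal))
        stop("integrity error: no ", calibrator_group,
             " samples to calibrate gene ", g, " at ", tp)
      out$ddct[sel] <- out$delta_ct[sel] - mean(out$delta_ct[cal])
    }
  }
  out$rq <- 2^(-out$ddct)
  out
}

#' One-way fixed-effects ANOVA
#'
#' Standard one-way ANOVA (equal-variance F test) over a list of group
#' value vectors, with the degenerate convention `F = 0, p = 1` when all
#' values are identical.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List with `F`, `p`, `df` (between, within).
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3, p = 0.125
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs >= 2 values")
  values <- unlist(groups, use.names = FALSE)
  df1 <- length(groups) - 1L
  df2 <- length(values) - length(groups)
  if (stats::var(values) == 0)
    return(list(F = 0, p = 1, df = c(df1, df2)))
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Student-Newman-Keuls post-hoc test
#'
#' Stepwise multiple comparison of group means after a one-way ANOVA. Means
#' are ranked; each pair is tested with the studentized range statistic
#' `q = |mean_i - mean_j| / sqrt(MSE / n_h)` against the critical value
#' `q(alpha, span, df_error)` where `span` is the number of ranked means the
#' pair encloses; critical values come from the studentized range
#' distribution ([stats::qtukey()]). A non-significant span blocks every
#' pair it encloses (standard SNK stepdown logic). Unequal group sizes use
#' the harmonic-mean n, flagged in the output.
#'
#' @param groups Named list of numeric group value vectors.
#' @param alpha Familywise level per span.
#' @return `data.frame` with one row per group pair: `group_i`, `group_j`,
#'   `diff`, `q`, `span`, `q_crit`, `significant`; harmonic-n usage is
#'   recorded in `attr(, "harmonic_n")`.
#' @export
snk_posthoc <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  an <- anova_oneway(groups)
  n_i <- vapply(groups, length, 1L)
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1)) / an$df[2L]
  unbalanced <- length(unique(n_i)) > 1L
  n_h <- k / sum(1 / n_i)
  means <- sort(vapply(groups, mean, 1))   # ascending rank order
  ranks <- stats::setNames(seq_len(k), names(means))

  pairs <- utils::combn(names(means), 2L)
  res <- data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
                    stringsAsFactors = FALSE)
  res$diff <- means[res$group_j] - means[res$group_i]
  res$span <- abs(ranks[res$group_j] - ranks[res$group_i]) + 1L
  res$q <- if (mse > 0) abs(res$diff) / sqrt(mse / n_h) else 0
  res$q_crit <- stats::qtukey(1 - alpha, res$span, an$df[2L])
  res$significant <- res$q > res$q_crit
  # stepdown blocking: a pair is significant only if every wider span that
  # encloses it is significant; process spans from widest to narrowest.
  res <- res[order(-res$span), , drop = FALSE]
  for (i in seq_len(nrow(res))) {
    if (res$significant[i]) next
    lo <- ranks[res$group_i[i]]; hi <- ranks[res$group_j[i]]
    enclosed <- ranks[res$group_i] >= min(lo, hi) &
                ranks[res$group_j] <= max(lo, hi)
    res$significant[enclosed] <- FALSE
  }
  res <- res[order(res$group_i, res$group_j), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "harmonic_n") <- unbalanced
  attr(res, "anova") <- an
  res
}

snk_pair_significant <- function(snk, a, b) {
  hit <- (snk$group_i == a & snk$group_j == b) |
         (snk$group_i == b & snk$group_j == a)
  any(snk$significant[hit])
}

# Three-month response category from the SNK pairwise separation pattern of
# group mean rq values. Unlike the microarray decision tree (which only has
# p-values per comparison), SNK yields simultaneous pairwise separations, so
# a genuinely intermediate treated group typically separates from BOTH
# control and untreated groups; that pattern, or separation from neither, is
# the partially normalized outcome.
qpcr_m3_category <- function(means, snk) {
  nd_d <- snk_pair_significant(snk, "ND", "D")
  nd_di <- snk_pair_significant(snk, "ND", "DI")
  d_di <- snk_pair_significant(snk, "D", "DI")
  if (!nd_d) return(NA_character_)
  dir_d <- sign(means[["D"]] - means[["ND"]])
  dir_di <- sign(means[["DI"]] - means[["ND"]])
  if (nd_di && !d_di) {
    if (dir_di == dir_d) "NotNormalized" else "Inverted"
  } else if (!nd_di && d_di) {
    "Normalized"
  } else if (nd_di && d_di) {
    between <- (means[["DI"]] - means[["ND"]]) *
               (means[["DI"]] - means[["D"]]) < 0
    if (between) "PartiallyNormalized"
    else if (dir_di == dir_d) "NotNormalized" else "Inverted"
  } else {
    "PartiallyNormalized"
  }
}

#' qPCR group statistics for one gene
#'
#' Group mean rq with SEM, one-way ANOVA p, and the SNK significant pairs
#' (reported only when the ANOVA is significant, mirroring the usual gated
#' post-hoc behavior).
#'
#' @param rq [ddct()] rows for one gene at one timepoint.
#' @param alpha Significance level.
#' @return List with `means`, `sem`, `anova_p`, `snk` (`NULL` when the
#'   ANOVA gate fails), `snk_pairs` (significant pairs as "a:b" strings).
#' @export
qpcr_group_stats <- function(rq, alpha = 0.05) {
  groups <- split(rq$rq, droplevels(rq$group))
  means <- vapply(groups, mean, 1)
  sem <- vapply(groups, function(v) stats::sd(v) / sqrt(length(v)), 1)
  an <- anova_oneway(groups)
  snk <- NULL; pairs <- character(0)
  if (an$p < alpha) {
    snk <- snk_posthoc(groups, alpha)
    pairs <- with(snk[snk$significant, , drop = FALSE],
                  paste(group_i, group_j, sep = ":"))
  }
  list(means = means, sem = sem, anova_p = an$p, snk = snk,
       snk_pairs = pairs)
}

#' Confirm a gene and derive its temporal-classification inputs
#'
#' A gene is confirmed when the three-month one-way ANOVA over ND/D/DI rq
#' values is significant and the SNK post-hoc separates the non-diabetic
#' from the diabetic group. One-month differential expression comes from the
#' two-tailed t-test on rq (ND vs D); the direction from the group mean rq.
#' The three-month insulin-response category is read off the SNK separation
#' pattern, and the Rescued/Prevented label follows [classify_temporal()].
#'
#' @param rq_m3 [ddct()] rows for the gene at three months (ND, D, DI).
#' @param rq_m1 [ddct()] rows at one month (ND, D), or `NULL`.
#' @param alpha Significance level.
#' @param variant t-test variant for the one-month comparison.
#' @return List with `confirmed`, `anova_p`, `snk_pairs`, `category_m3`,
#'   `de_m1`, `t_p_m1`, `direction`, `temporal`.
#' @export
confirm_gene <- function(rq_m3, rq_m1 = NULL, alpha = 0.05,
                         variant = "pooled") {
  st <- qpcr_group_stats(rq_m3, alpha)
  snk <- if (is.null(st$snk)) snk_posthoc(split(rq_m3$rq,
                                                droplevels(rq_m3$group)),
                                          alpha) else st$snk
  confirmed <- st$anova_p < alpha && snk_pair_significant(snk, "ND", "D")
  category <- if (confirmed) qpcr_m3_category(st$means, snk) else NA_character_
  de_m1 <- NA; t_p <- NA_real_
  if (!is.null(rq_m1)) {
    a <- rq_m1$rq[rq_m1$group == "ND"]; b <- rq_m1$rq[rq_m1$group == "D"]
    t_p <- probe_ttest(a, b, variant)
    de_m1 <- t_p < alpha
  }
  temporal <- if (confirmed && !is.na(category) && !is.na(de_m1))
    classify_temporal(de_m1, category) else factor(NA, levels = TEMPORAL_LEVELS)
  list(confirmed = confirmed, anova_p = st$anova_p, snk_pairs = st$snk_pairs,
       category_m3 = category, de_m1 = de_m1, t_p_m1 = t_p,
       direction = unname(ifelse(st$means[["D"]] >= st$means[["ND"]],
                                 "up", "down")),
       temporal = temporal)
}

#' Run qPCR confirmation over every target gene of an experiment
#'
#' @param records qPCR records (both timepoints).
#' @param design Matching [sample_design()].
#' @param alpha Significance level.
#' @return `data.frame` with one row per target gene: confirmation status,
#'   three-month category, one-month DE status and temporal label.
#' @export
qpcr_confirmation <- function(records, design, alpha = 0.05) {
  rq <- ddct(records, design)
  out <- lapply(unique(rq$gene), function(g) {
    sub3 <- rq[rq$gene == g & rq$timepoint == "M3", , drop = FALSE]
    sub1 <- rq[rq$gene == g & rq$timepoint == "M1", , drop = FALSE]
    res <- confirm_gene(sub3, if (nrow(sub1)) sub1 else NULL, alpha)
    data.frame(gene = g, confirmed = res$confirmed, anova_p = res$anova_p,
               category_m3 = res$category_m3 %||% NA_character_,
               de_m1 = res$de_m1, t_p_m1 = res$t_p_m1,
               direction = res$direction,
               temporal = as.character(res$temporal),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
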