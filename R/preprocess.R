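# Average normalization with background subtraction, and the
# present/marginal detection filter that defines the analyzable probe set.

#' Detection-call rule
#'
#' A probe is retained when, in at least one experimental group, every
#' sample's detection p-value is at or below the marginal threshold (present
#' or marginal calls in 100% of the samples of that group). The present
#' threshold is carried as metadata — "present or marginal" is implemented
#' as `detection_p <= marginal_p`, since the marginal cutoff subsumes the
#' present one.
#'
#' @param present_p Present-call threshold (conventional Illumina cutpoint
#'   0.01).
#' @param marginal_p Marginal-call threshold (0.05).
#' @param required_fraction Fraction of samples within the qualifying group
#'   that must be called; fixed at 1 for this design.
#' @return A list of class `"detection_rule"`.
#' @export
detection_rule <- function(present_p = 0.01, marginal_p = 0.05,
                           required_fraction = 1) {
  if (!(present_p <= marginal_p && marginal_p <= 1))
    stop("require present_p <= marginal_p <= 1")
  structure(list(present_p = present_p, marginal_p = marginal_p,
                 required_fraction = required_fraction),
            class = "detection_rule")
}

#' Average normalization with background subtraction
#'
#' Per sample, a background estimate is subtracted from every intensity and
#' the result clamped at a positive floor (so downstream ratios stay
#' defined); each sample is then rescaled so that its mean equals the grand
#' mean of the per-sample backgrounded means. The background estimate is the
#' mean signal of the designated negative-control probes when provided,
#' otherwise the 5th percentile of the sample's own signals.
#'
#' @param em An [expression_matrix()] with raw provenance.
#' @param negative_controls Optional character vector of negative-control
#'   probe ids used for the background estimate.
#' @param floor Post-subtraction clamp, in raw signal units.
#' @param force Normalize even when the provenance flag says the values are
#'   already normalized (a re-run with zero background is then a no-op).
#' @return List with `matrix` (normalized [expression_matrix()], detection
#'   layer untouched) and `params` (`data.frame` with per-sample
#'   `background` and `scale_factor`, plus the `floor` as an attribute).
#' @examples
#' sig <- matrix(c(50, 150, 100, 300), 2,
#'               dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' nm <- normalize_average(expression_matrix(sig), floor = 1)
#' colMeans(nm$matrix$signal)  # equal sample means after normalization
#' @export
normalize_average <- function(em, negative_controls = NULL, floor = 1,
                              force = FALSE) {
  if (ncol(em$signal) < 2L) stop("need >= 2 samples to normalize")
  if (floor <= 0) stop("`floor` must be positive")
  if (em$normalized && !force)
    stop("matrix is flagged as already normalized; use force = TRUE to re-normalize")
  sig <- em$signal
  if (!is.null(negative_controls)) {
    idx <- rownames(sig) %in% negative_controls
    if (!any(idx)) stop("none of `negative_controls` found in the matrix")
    background <- colMeans(sig[idx, , drop = FALSE])
  } else {
    background <- apply(sig, 2L, stats::quantile, probs = 0.05, names = FALSE)
  }
  if (em$normalized && force) background <- background * 0
  sub <- pmax(sweep(sig, 2L, background, `-`), floor)
  sample_means <- colMeans(sub)
  grand_mean <- mean(sample_means)
  scale_factor <- grand_mean / sample_means
  norm <- sweep(sub, 2L, scale_factor, `*`)
  params <- data.frame(sample_id = colnames(sig), background = background,
                       scale_factor = scale_factor, row.names = NULL,
                       stringsAsFactors = FALSE)
  attr(params, "floor") <- floor
  list(matrix = expression_matrix(norm, em$detection, em$annotation,
                                  normalized = TRUE),
       params = params)
}

#' Present/marginal detection filter
#'
#' Keeps a probe iff there exists an experimental group in which every
#' sample's detection p-value is at or below the rule's marginal threshold.
#' This retains transcripts reliably detected in the whole experiment as
#' well as those potentially expressed in only one experimental group, and
#' excludes transcripts never reliably detected.
#'
#' @param em An [expression_matrix()] with a detection layer.
#' @param design A [sample_design()] covering the matrix samples.
#' @param rule A [detection_rule()].
#' @return List with `matrix` (the kept probes, order preserved),
#'   `kept_ids` and `dropped_ids` (together a partition of the input probes).
#' @export
detection_filter <- function(em, design, rule = detection_rule()) {
  if (is.null(em$detection))
    stop("integrity error: matrix has no detection p-value layer")
  design <- check_design(em, design)
  by_group <- group_samples(design)
  by_group <- by_group[vapply(by_group, length, 1L) > 0L]
  keep <- Reduce(`|`, lapply(by_group, function(samps) {
    det <- em$detection[, samps, drop = FALSE]
    rowSums(det <= rule$marginal_p) == length(samps)
  }))
  kept_ids <- rownames(em$signal)[keep]
  dropped_ids <- rownames(em$signal)[!keep]
  list(matrix = em[keep, ], kept_ids = kept_ids, dropped_ids = dropped_ids)
}
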