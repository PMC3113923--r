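#' @keywords internal
"_PACKAGE"

# Experimental-group and category levels used throughout the pipeline.
GROUP_LEVELS <- c("ND", "D", "DI")
TIMEPOINT_LEVELS <- c("M1", "M3")
RESPONSE_LEVELS <- c("Normalized", "PartiallyNormalized", "NotNormalized", "Inverted")
TRUTH_LEVELS <- c(RESPONSE_LEVELS, "Unchanged", "Undetected")
TEMPORAL_LEVELS <- c("Rescued", "PartiallyRescued", "NotRescued",
                     "Prevented", "PartiallyPrevented", "NotPrevented")

#' Probe-by-sample expression container
#'
#' Bundles a probe x sample intensity matrix with (optionally) a parallel
#' matrix of per-probe, per-sample detection p-values, probe annotation, and a
#' provenance flag recording whether the intensities have already been
#' normalized. This is the object every pipeline stage consumes and returns.
#'
#' @param signal Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). Non-negative fluorescence
#'   intensities in arbitrary units.
#' @param detection Numeric matrix of detection p-values in `[0, 1]` with the
#'   same dimnames as `signal`, or `NULL` when the source (e.g. a GEO series
#'   matrix) did not carry detection calls.
#' @param annotation `data.frame` with one row per probe; must contain a
#'   `probe_id` column matching `rownames(signal)`. Optional columns
#'   `gene_symbol`, `entrez_id`, `gene_name` are carried through to result
#'   tables.
#' @param normalized Logical provenance flag; `TRUE` means the values are
#'   already normalized and [normalize_average()] will refuse to run without
#'   `force = TRUE`.
#'
#' @return An object of class `"ExpressionMatrix"`: a list with elements
#'   `signal`, `detection`, `annotation`, `normalized`.
#' @examples
#' sig <- matrix(100, 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' em <- expression_matrix(sig, detection = matrix(0.001, 2, 2,
#'   dimnames = dimnames(sig)))
#' em
#' @export
expression_matrix <- function(signal, detection = NULL, annotation = NULL,
                              normalized = FALSE) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix")
  if ((nrow(signal) > 0L && is.null(rownames(signal))) ||
      (ncol(signal) > 0L && is.null(colnames(signal))))
    stop("`signal` must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(signal)))
    stop("integrity error: duplicate probe_id in signal matrix")
  if (anyDuplicated(colnames(signal)))
    stop("integrity error: duplicate sample_id in signal matrix")
  if (any(signal < 0, na.rm = TRUE))
    stop("`signal` must be non-negative")
  if (!is.null(detection)) {
    if (!is.matrix(detection) || !identical(dim(detection), dim(signal)))
      stop("`detection` must be a matrix with the same dimensions as `signal`")
    if (any(dim(signal) == 0L)) dimnames(detection) <- dimnames(signal)
    if (!identical(dimnames(detection), dimnames(signal)))
      stop("`detection` dimnames must match `signal` (same probes and samples)")
    if (any(detection < 0 | detection > 1, na.rm = TRUE))
      stop("detection p-values must lie in [0, 1]")
  }
  if (is.null(annotation)) {
    annotation <- data.frame(probe_id = rownames(signal),
                             stringsAsFactors = FALSE)
  }
  if (!"probe_id" %in% names(annotation))
    stop("`annotation` must contain a probe_id column")
  if (!identical(as.character(annotation$probe_id),
                 as.character(rownames(signal))))  # NULL rownames = no probes
    stop("`annotation$probe_id` must match rownames(signal) in order")
  structure(
    list(signal = signal, detection = detection, annotation = annotation,
         normalized = isTRUE(normalized)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples\n",
              nrow(x$signal), ncol(x$signal)))
  cat(sprintf("  detection p-values: %s\n",
              if (is.null(x$detection)) "absent" else "present"))
  cat(sprintf("  normalized: %s\n", x$normalized))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$signal)

#' Subset an ExpressionMatrix by probes and/or samples
#'
#' @param x An [expression_matrix()] object.
#' @param i,j Probe and sample indices (any form accepted by matrix
#'   subsetting).
#' @param ... Ignored.
#' @return An `ExpressionMatrix` restricted to the selected probes/samples.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$signal))
  if (missing(j)) j <- seq_len(ncol(x$signal))
  ii <- stats::setNames(seq_len(nrow(x$signal)), rownames(x$signal))[i]
  jj <- stats::setNames(seq_len(ncol(x$signal)), colnames(x$signal))[j]
  sig <- x$signal[ii, jj, drop = FALSE]
  # empty selections must keep their dimnames (base R drops them)
  dimnames(sig) <- list(rownames(x$signal)[ii], colnames(x$signal)[jj])
  det <- if (is.null(x$detection)) NULL else {
    d <- x$detection[ii, jj, drop = FALSE]
    dimnames(d) <- dimnames(sig)
    d
  }
  ann <- x$annotation[match(rownames(sig), x$annotation$probe_id), ,
                      drop = FALSE]
  rownames(ann) <- NULL
  expression_matrix(sig, det, ann, normalized = x$normalized)
}

#' Sample design table
#'
#' Validates and normalizes a sample -> (group, timepoint) assignment.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Character/factor vector with levels among `ND` (non-diabetic),
#'   `D` (diabetic), `DI` (insulin-treated diabetic).
#' @param timepoint Character/factor vector with levels `M1` (1 month) or
#'   `M3` (3 months).
#' @return A `data.frame` with columns `sample_id`, `group`, `timepoint`
#'   (factors with the canonical level order).
#' @examples
#' sample_design(c("a", "b"), c("ND", "D"), "M3")
#' @export
sample_design <- function(sample_id, group, timepoint = "M3") {
  n <- length(sample_id)
  d <- data.frame(sample_id = as.character(sample_id),
                  group = factor(as.character(group), levels = GROUP_LEVELS),
                  timepoint = factor(rep_len(as.character(timepoint), n),
                                     levels = TIMEPOINT_LEVELS),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample_id))
    stop("integrity error: duplicate sample_id in design")
  if (anyNA(d$group))
    stop("unknown group label; expected one of ", paste(GROUP_LEVELS, collapse = ", "))
  if (anyNA(d$timepoint))
    stop("unknown timepoint label; expected one of ", paste(TIMEPOINT_LEVELS, collapse = ", "))
  d
}

# Check that every matrix sample is assigned exactly once and that each
# (group, timepoint) cell used has at least two samples.
check_design <- function(em, design) {
  samples <- colnames(em$signal)
  miss <- setdiff(samples, design$sample_id)
  if (length(miss))
    stop("integrity error: samples missing from design: ",
         paste(miss, collapse = ", "))
  design <- design[design$sample_id %in% samples, , drop = FALSE]
  sizes <- table(droplevels(design$group), droplevels(design$timepoint))
  if (any(sizes > 0 & sizes < 2))
    stop("every (group, timepoint) used in an analysis needs >= 2 samples")
  design
}

# Split sample ids by group for one timepoint.
group_samples <- function(design, timepoint = NULL) {
  d <- design
  if (!is.null(timepoint)) d <- d[d$timepoint == timepoint, , drop = FALSE]
  split(d$sample_id, d$group, drop = FALSE)
}
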