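# Synthetic three-arm study generator. Emulates the structure of a
# streptozotocin-diabetes insulin-replacement experiment: a probe x sample
# intensity matrix with per-sample detection p-values and known
# insulin-response ground truth, two-timepoint qPCR Ct tables with a stable
# endogenous control, and biometric phenotype records. Everything is
# reproducible under a fixed seed so downstream stages can be tested by
# parameter recovery.

#' Simulation configuration
#'
#' Defaults mirror the study design this pipeline targets: a 22,523-probe
#' rat expression array of which 11,040 probes are reliably detected, group
#' sizes 8/5/7 (ND/D/DI) at three months after quality-control exclusions and
#' 8/8 (ND/D) at one month, and a 789/514/65/8 split of the 1,376
#' diabetes-regulated probes into Normalized / Partially Normalized /
#' Not Normalized / Inverted insulin-response archetypes.
#'
#' @param n_probes Number of probes on the simulated array.
#' @param group_sizes_m3 Named integer vector `c(ND=, D=, DI=)`: three-month
#'   array group sizes.
#' @param group_sizes_m1 Named integer vector `c(ND=, D=)`: one-month group
#'   sizes.
#' @param category_proportions Named probabilities over
#'   `Normalized, PartiallyNormalized, NotNormalized, Inverted, Unchanged,
#'   Undetected`; must sum to 1.
#' @param effect_size_fc True fold change (>1) of diabetes-affected probes.
#' @param cv Coefficient of variation of intensities on the natural scale;
#'   intensity noise is multiplicative (log-normal).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-probe
#'   baseline log2 intensities.
#' @param present_p,marginal_p Detection-call thresholds carried into the
#'   detection-p model (a probe is detected when its detection p-value is at
#'   or below `marginal_p`).
#' @param qpcr_group_sizes Per-timepoint qPCR group sizes.
#' @param qpcr_fc True qPCR fold change of an affected gene (2 = one Ct
#'   cycle).
#' @param sigma_ct Additive Gaussian noise SD on Ct, in cycles, per well.
#' @param phenotype Per-variable, per-(timepoint, group) means and SEMs used
#'   by [simulate_phenotype()]. Printed-value defaults: one-month blood
#'   glucose 321 +/- 16 (D) vs 114 +/- 12 (ND) mg/dL, body weight 264 +/- 16
#'   vs 391 +/- 9 g; dispersions are treated as SEM and converted to SD via
#'   sqrt(n).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_probes = 22523,
                       group_sizes_m3 = c(ND = 8, D = 5, DI = 7),
                       group_sizes_m1 = c(ND = 8, D = 8),
                       category_proportions = NULL,
                       effect_size_fc = 1.8,
                       cv = 0.15,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       present_p = 0.01,
                       marginal_p = 0.05,
                       qpcr_group_sizes = list(M1 = c(ND = 8, D = 8),
                                               M3 = c(ND = 8, D = 8, DI = 8)),
                       qpcr_fc = 2,
                       sigma_ct = 0.15,
                       phenotype = NULL,
                       seed = NULL) {
  if (is.null(category_proportions)) {
    counts <- c(Normalized = 789, PartiallyNormalized = 514,
                NotNormalized = 65, Inverted = 8,
                Unchanged = 11040 - 1376, Undetected = 22523 - 11040)
    category_proportions <- counts / 22523
  }
  if (abs(sum(category_proportions) - 1) > 1e-9)
    stop("config error: category_proportions must sum to 1")
  if (is.null(names(category_proportions)) ||
      !all(names(category_proportions) %in% TRUTH_LEVELS))
    stop("config error: category_proportions must be named with: ",
         paste(TRUTH_LEVELS, collapse = ", "))
  if (any(c(group_sizes_m3, group_sizes_m1) < 2))
    stop("config error: all group sizes must be >= 2")
  if (effect_size_fc <= 1) stop("config error: effect_size_fc must be > 1")
  if (cv < 0) stop("config error: cv must be >= 0")
  structure(list(
    n_probes = as.integer(n_probes),
    group_sizes_m3 = group_sizes_m3,
    group_sizes_m1 = group_sizes_m1,
    category_proportions = category_proportions,
    effect_size_fc = effect_size_fc,
    cv = cv,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    present_p = present_p,
    marginal_p = marginal_p,
    qpcr_group_sizes = qpcr_group_sizes,
    qpcr_fc = qpcr_fc,
    sigma_ct = sigma_ct,
    phenotype = phenotype %||% default_phenotype_params(),
    seed = seed
  ), class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean/sem per (variable, timepoint, group). Glucose and weight at one month
# are printed study values; the remaining cells are realistic values for an
# STZ rat cohort chosen once: untreated diabetics stay hyperglycemic and
# underweight at three months, insulin restores glycemia (with mildly
# elevated HbA1c) and most of the weight deficit.
default_phenotype_params <- function() {
  list(
    blood_glucose = list(
      M1 = list(ND = c(mean = 114, sem = 12), D = c(mean = 321, sem = 16)),
      M3 = list(ND = c(mean = 110, sem = 10), D = c(mean = 400, sem = 25),
                DI = c(mean = 125, sem = 12))),
    body_weight = list(
      M1 = list(ND = c(mean = 391, sem = 9), D = c(mean = 264, sem = 16)),
      M3 = list(ND = c(mean = 545, sem = 15), D = c(mean = 350, sem = 22),
                DI = c(mean = 470, sem = 15))),
    hba1c_pct = list(
      M3 = list(ND = c(mean = 4.5, sem = 0.15), D = c(mean = 11.5, sem = 0.4),
                DI = c(mean = 5.4, sem = 0.25)))
  )
}

# log2-scale noise SD implied by a natural-scale coefficient of variation of
# a log-normal intensity.
cv_to_sigma_log2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)

# Per-group log2 mean shifts for one probe, relative to the non-diabetic
# baseline. `delta` is the signed diabetes effect in log2 units.
archetype_shifts <- function(category, delta) {
  switch(category,
    Unchanged = ,
    Undetected = c(ND = 0, D = 0, DI = 0),
    Normalized = c(ND = 0, D = delta, DI = 0),
    PartiallyNormalized = c(ND = 0, D = delta, DI = delta / 2),
    NotNormalized = c(ND = 0, D = delta, DI = delta),
    Inverted = c(ND = 0, D = delta, DI = -delta),
    stop("config error: unknown archetype '", category, "'")
  )
}

#' Simulate a three-arm expression experiment with known ground truth
#'
#' Probes are assigned an archetype by multinomial draw from
#' `category_proportions`. Group log2 mean structure per archetype (with
#' `delta = log2(effect_size_fc)` and a random sign per probe):
#' `Unchanged` all equal; `Normalized` D shifted by `delta`, DI at the ND
#' level; `PartiallyNormalized` DI at the geometric midpoint of ND and D;
#' `NotNormalized` DI shifted like D; `Inverted` DI shifted by `-delta`.
#' Intensities are log-normal around the group mean with the configured
#' natural-scale CV. Detection p-values of detected probes are drawn from a
#' Beta(0.5, 20) truncated to `[0, marginal_p]` (every sample yields a
#' present/marginal call); `Undetected` probes draw from
#' Uniform(`marginal_p`, 1) and fail the detection filter in every group.
#'
#' @param config A [sim_config()].
#' @return List with elements `matrix` (an [expression_matrix()], raw
#'   provenance), `design` (a [sample_design()] at timepoint M3) and `truth`
#'   (`data.frame` with `probe_id`, `true_category`, `true_fc`).
#' @export
simulate_expression <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_probes
  sizes <- config$group_sizes_m3
  groups <- rep(names(sizes), sizes)
  sample_id <- unlist(lapply(names(sizes),
                             function(g) paste0(g, "_", seq_len(sizes[[g]]))))
  design <- sample_design(sample_id, groups, "M3")

  probe_id <- sprintf("probe_%05d", seq_len(n))
  category <- sample(names(config$category_proportions), n, replace = TRUE,
                     prob = config$category_proportions)
  sign <- sample(c(1, -1), n, replace = TRUE)
  delta <- ifelse(category %in% c("Unchanged", "Undetected"), 0,
                  sign * log2(config$effect_size_fc))
  baseline <- stats::rnorm(n, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  shift <- t(vapply(seq_len(n),
                    function(i) archetype_shifts(category[i], delta[i]),
                    numeric(3L)))  # n x 3, columns ND/D/DI
  colnames(shift) <- c("ND", "D", "DI")

  sigma <- cv_to_sigma_log2(config$cv)
  mu <- baseline + shift[, groups, drop = FALSE]      # n x n_samples log2 means
  noise <- matrix(stats::rnorm(n * length(groups), 0, sigma), n)
  signal <- 2^(mu + noise)
  dimnames(signal) <- list(probe_id, sample_id)

  detection <- matrix(NA_real_, n, length(groups),
                      dimnames = dimnames(signal))
  det_idx <- category != "Undetected"
  n_det <- sum(det_idx) * length(groups)
  # Beta(0.5, 20) truncated below the marginal threshold via inverse CDF
  pmax_beta <- stats::pbeta(config$marginal_p, 0.5, 20)
  detection[det_idx, ] <- stats::qbeta(stats::runif(n_det) * pmax_beta,
                                       0.5, 20)
  detection[!det_idx, ] <- stats::runif(sum(!det_idx) * length(groups),
                                        config$marginal_p, 1)

  truth <- data.frame(
    probe_id = probe_id,
    true_category = factor(category, levels = TRUTH_LEVELS),
    true_fc = ifelse(delta == 0, 1, ifelse(delta > 0, 2^abs(delta),
                                           -(2^abs(delta)))),
    stringsAsFactors = FALSE)

  ann <- data.frame(probe_id = probe_id,
                    gene_symbol = sprintf("Gene%05d", seq_len(n)),
                    entrez_id = as.character(100000L + seq_len(n)),
                    gene_name = sprintf("simulated gene %05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  list(matrix = expression_matrix(signal, detection, ann, normalized = FALSE),
       design = design, truth = truth)
}

# ddCt-scale (cycles) shifts of the target gene relative to the non-diabetic
# group, per temporal archetype, for a gene whose diabetes effect is
# `cycles` (> 0 means induced, i.e. Ct decreases). Order: M1 D, M3 D, M3 DI.
temporal_trajectory <- function(archetype, cycles) {
  traj <- switch(archetype,
    Rescued            = c(m1_d = 1, m3_d = 1, m3_di = 0),
    PartiallyRescued   = c(m1_d = 1, m3_d = 1, m3_di = 0.5),
    NotRescued         = c(m1_d = 1, m3_d = 1, m3_di = 1),
    Prevented          = c(m1_d = 0, m3_d = 1, m3_di = 0),
    PartiallyPrevented = c(m1_d = 0, m3_d = 1, m3_di = 0.5),
    NotPrevented       = c(m1_d = 0, m3_d = 1, m3_di = 1),
    stop("config error: unknown temporal archetype '", archetype, "'"))
  traj * cycles
}

#' Simulate two-timepoint qPCR Ct tables
#'
#' The endogenous-control gene has a group-independent Ct mean (stable
#' reference). Each target gene's delta-Ct encodes its temporal archetype's
#' fold-change trajectory across (M1: ND, D) and (M3: ND, D, DI); lower Ct
#' means higher expression, and a fold change of `qpcr_fc` corresponds to
#' `log2(qpcr_fc)` cycles. Noise is additive Gaussian on Ct per well.
#'
#' @param config A [sim_config()].
#' @param genes `data.frame` with columns `gene`, `archetype` (one of the six
#'   temporal categories) and optionally `direction` (+1 induced, -1
#'   suppressed; default +1).
#' @param control_gene Name of the endogenous-control gene.
#' @return List with `records` (qPCR rows as read by [read_qpcr_table()]),
#'   `design` (both timepoints) and `truth` (the input `genes`).
#' @export
simulate_qpcr <- function(config = sim_config(), genes, control_gene = "Actb") {
  if (!all(c("gene", "archetype") %in% names(genes)))
    stop("`genes` must have columns gene and archetype")
  bad <- setdiff(genes$archetype, TEMPORAL_LEVELS)
  if (length(bad))
    stop("config error: unknown temporal archetype '", bad[1L], "'")
  if (!is.null(config$seed)) set.seed(config$seed)
  direction <- if ("direction" %in% names(genes)) genes$direction
               else rep(1, nrow(genes))
  cycles <- log2(config$qpcr_fc)
  base_dct <- stats::rnorm(nrow(genes), 6, 1)  # target baseline above control
  ctrl_ct <- 18

  design <- do.call(rbind, lapply(names(config$qpcr_group_sizes), function(tp) {
    sizes <- config$qpcr_group_sizes[[tp]]
    sample_design(
      unlist(lapply(names(sizes),
                    function(g) paste0(tp, "_", g, "_", seq_len(sizes[[g]])))),
      rep(names(sizes), sizes), tp)
  }))
  rownames(design) <- NULL

  rows <- list()
  for (i in seq_len(nrow(design))) {
    s <- design$sample_id[i]
    g <- as.character(design$group[i])
    tp <- as.character(design$timepoint[i])
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s, gene = control_gene,
      ct = ctrl_ct + stats::rnorm(1, 0, config$sigma_ct),
      is_endogenous_control = TRUE, stringsAsFactors = FALSE)
    for (j in seq_len(nrow(genes))) {
      traj <- temporal_trajectory(genes$archetype[j], cycles * direction[j])
      shift <- if (g == "ND") 0
               else if (tp == "M1") traj[["m1_d"]]
               else if (g == "D") traj[["m3_d"]]
               else traj[["m3_di"]]
      # induced expression (positive shift) lowers the target Ct
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, gene = genes$gene[j],
        ct = ctrl_ct + base_dct[j] - shift +
          stats::rnorm(1, 0, config$sigma_ct),
        is_endogenous_control = FALSE, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  validate_qpcr_records(records)
  list(records = records, design = design, truth = genes)
}

#' Simulate biometric phenotype records
#'
#' Draws blood glucose, body weight and (three-month animals only) percent
#' glycosylated hemoglobin per sample from the per-(timepoint, group) means
#' and SEMs in the configuration; SEMs are converted to individual-animal
#' SDs via `sqrt(n)`. Optionally couples one phenotype to the expression of
#' one gene at a chosen population correlation, for correlation-recovery
#' testing.
#'
#' @param design A [sample_design()] table.
#' @param config A [sim_config()].
#' @param expression Optional named numeric vector of per-sample expression
#'   (required when `couple` is given).
#' @param couple Optional `list(phenotype =, r =)`: induce Pearson
#'   correlation `r` between `expression` and that phenotype, within each
#'   (group, timepoint) cell.
#' @return `data.frame` with `sample_id`, `blood_glucose`, `hba1c_pct`
#'   (`NA` at M1), `body_weight`.
#' @export
simulate_phenotype <- function(design, config = sim_config(),
                               expression = NULL, couple = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  params <- config$phenotype
  out <- data.frame(sample_id = design$sample_id,
                    blood_glucose = NA_real_, hba1c_pct = NA_real_,
                    body_weight = NA_real_, stringsAsFactors = FALSE)
  for (var in names(params)) {
    for (tp in names(params[[var]])) {
      for (g in names(params[[var]][[tp]])) {
        idx <- which(design$timepoint == tp & design$group == g)
        if (!length(idx)) next
        ms <- params[[var]][[tp]][[g]]
        sd_i <- ms[["sem"]] * sqrt(length(idx))
        vals <- stats::rnorm(length(idx), ms[["mean"]], sd_i)
        if (!is.null(couple) && couple$phenotype == var) {
          if (is.null(expression))
            stop("`expression` required when coupling a phenotype")
          e <- expression[design$sample_id[idx]]
          if (anyNA(e))
            stop("integrity error: expression missing for coupled samples")
          ze <- if (stats::sd(e) > 0) as.numeric(scale(e)) else rep(0, length(e))
          z <- couple$r * ze + sqrt(1 - couple$r^2) * stats::rnorm(length(e))
          vals <- ms[["mean"]] + sd_i * z
        }
        out[idx, var] <- pmax(vals, 1e-3)  # biometric values are positive
      }
    }
  }
  out
}
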