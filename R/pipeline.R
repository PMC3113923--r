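# End-to-end orchestration: simulation (or supplied data) -> normalization
# -> detection filter -> pairwise statistics -> insulin-response partition,
# with optional qPCR confirmation, temporal refinement and biometric
# summaries, plus a plain-text report renderer.

#' Run the full classification pipeline
#'
#' Sequences the stages in their standard order: (synthetic) data
#' generation, average normalization with background subtraction, the
#' present/marginal detection filter, the three pairwise comparisons, the
#' four-way insulin-response partition, and optionally qPCR confirmation
#' with temporal (Rescued/Prevented) refinement, phenotype simulation and
#' biometric summaries. All randomness derives from `config$seed`, so a
#' fixed configuration reproduces its bundle exactly.
#'
#' @param config A [sim_config()]; drives generation and carries the seed.
#' @param data Optional list with `matrix` ([expression_matrix()]) and
#'   `design`, to run on supplied rather than simulated expression data.
#' @param alpha,fc_cutoff,variant Differential-expression parameters.
#' @param secondary_fc Apply the fold-change cutoff to secondary
#'   comparisons (see [classify_response()]).
#' @param rule A [detection_rule()].
#' @param qpcr_genes Optional `data.frame(gene, archetype)` for the qPCR
#'   confirmation arm.
#' @param with_phenotype Simulate and summarize biometric phenotypes?
#' @param outdir Optional directory; when given, writes the result tables,
#'   counts JSON and a stage log.
#' @return A bundle: list with `config_hash`, `design`, `truth`,
#'   `n_input`, `n_detected`, `stats`, `classified`, `partition`, and when
#'   requested `qpcr`, `phenotype`, `biometrics`, `log`.
#' @export
run_pipeline <- function(config = sim_config(), data = NULL, alpha = 0.05,
                         fc_cutoff = 1.2, variant = "pooled",
                         secondary_fc = FALSE, rule = detection_rule(),
                         qpcr_genes = NULL, with_phenotype = FALSE,
                         outdir = NULL) {
  log <- character(0)
  say <- function(...) {
    log <<- c(log, sprintf(...))
  }
  hash <- config_hash(config)

  if (is.null(data)) {
    sim <- simulate_expression(config)
    em <- sim$matrix; design <- sim$design; truth <- sim$truth
    say("simulate: %d probes x %d samples", nrow(em$signal), ncol(em$signal))
  } else {
    em <- data$matrix; design <- data$design; truth <- data$truth %||% NULL
    say("input: %d probes x %d samples", nrow(em$signal), ncol(em$signal))
  }
  n_input <- nrow(em$signal)

  if (!em$normalized) {
    norm <- normalize_average(em)
    em <- norm$matrix
    say("normalize: %d samples, grand mean %.3f", ncol(em$signal),
        mean(colMeans(em$signal)))
  } else say("normalize: skipped (already-normalized provenance)")

  filt <- detection_filter(em, design, rule)
  say("detection_filter: kept %d / dropped %d (in = %d)",
      length(filt$kept_ids), length(filt$dropped_ids), n_input)
  stopifnot(length(filt$kept_ids) + length(filt$dropped_ids) == n_input)

  stats <- run_all_comparisons(filt$matrix, design, alpha, fc_cutoff, variant)
  classified <- classify_probes(stats, alpha, fc_cutoff, secondary_fc)
  partition <- partition_counts(classified$category)
  say("diffexpr: %d DE of %d detected (alpha=%g, fc>%g)",
      partition$total, length(filt$kept_ids), alpha, fc_cutoff)
  say("classify: %s",
      paste(sprintf("%s=%d", names(partition$counts), partition$counts),
            collapse = " "))

  bundle <- list(config_hash = hash, seed = config$seed, design = design,
                 truth = truth, n_input = n_input,
                 n_detected = length(filt$kept_ids),
                 kept_ids = filt$kept_ids, stats = stats,
                 classified = classified, partition = partition,
                 alpha = alpha, fc_cutoff = fc_cutoff)

  if (!is.null(qpcr_genes)) {
    qp <- simulate_qpcr(config, qpcr_genes)
    conf <- qpcr_confirmation(qp$records, qp$design, alpha)
    say("qpcr: %d/%d genes confirmed", sum(conf$confirmed), nrow(conf))
    bundle$qpcr <- list(records = qp$records, design = qp$design,
                        truth = qp$truth, confirmation = conf)
  }
  if (with_phenotype) {
    pdesign <- design
    if (!is.null(bundle$qpcr)) pdesign <- rbind(design, bundle$qpcr$design)
    pheno <- simulate_phenotype(pdesign, config)
    bundle$phenotype <- pheno
    bundle$biometrics <- biometric_summary(pheno, pdesign)
    say("phenotype: %d samples summarized", nrow(pheno))
  }
  bundle$log <- log

  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))],
                              auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  header <- sprintf("# config_hash: %s", bundle$config_hash)
  counts <- c(as.list(bundle$partition$counts),
              list(total = bundle$partition$total,
                   percent = as.list(bundle$partition$percent),
                   n_detected = bundle$n_detected,
                   n_input = bundle$n_input,
                   config_hash = bundle$config_hash))
  jsonlite::write_json(counts, file.path(outdir, "counts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (nrow(bundle$classified))
    write_result_rows(as_result_rows(bundle$classified),
                      file.path(outdir, "categories"))
  writeLines(c(header, bundle$kept_ids), file.path(outdir, "kept_probes.txt"))
  if (!is.null(bundle$qpcr))
    utils::write.table(bundle$qpcr$confirmation,
                       file.path(outdir, "qpcr_confirmation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(header, bundle$log), file.path(outdir, "pipeline.log"))
  invisible(outdir)
}

#' Render a pipeline bundle as a plain-text report
#'
#' Pure function of the bundle: regenerating the report from a saved bundle
#' reproduces it exactly. Shows the detection and DE totals, the partition
#' table with counts and integer percentages, and (when present) the qPCR
#' confirmation/temporal table and biometric summaries.
#'
#' @param bundle Output of [run_pipeline()].
#' @return Character vector of report lines, invisibly; also printed.
#' @export
render_report <- function(bundle) {
  lines <- c(
    sprintf("Insulin-response classification report (config %s)",
            bundle$config_hash),
    sprintf("Probes: %d input, %d detected, %d differentially expressed",
            bundle$n_input, bundle$n_detected, bundle$partition$total))
  if (bundle$partition$total == 0) {
    lines <- c(lines, "No probes were differentially expressed.")
  } else {
    pc <- bundle$partition
    lines <- c(lines, "Category              count  percent",
               sprintf("%-20s %6d  %6d%%", names(pc$counts), pc$counts,
                       pc$percent))
  }
  if (!is.null(bundle$qpcr)) {
    conf <- bundle$qpcr$confirmation
    lines <- c(lines,
               sprintf("qPCR confirmation: %d/%d genes (%d%%)",
                       sum(conf$confirmed), nrow(conf),
                       as.integer(floor(100 * sum(conf$confirmed) /
                                          nrow(conf) + 0.5))),
               sprintf("  %-10s %-12s %s", conf$gene, conf$category_m3,
                       conf$temporal))
  }
  if (!is.null(bundle$biometrics)) {
    for (tp in names(bundle$biometrics)) {
      for (v in names(bundle$biometrics[[tp]])) {
        b <- bundle$biometrics[[tp]][[v]]
        lines <- c(lines, sprintf(
          "%s %s: %s%s", tp, v,
          paste(sprintf("%s=%.1f+/-%.1f", names(b$means), b$means, b$sem),
                collapse = " "),
          if (!is.null(b$t_p)) sprintf(" (t-test p=%.3g)", b$t_p)
          else sprintf(" (ANOVA p=%.3g; SNK: %s)", b$anova_p,
                       paste(b$snk_pairs, collapse = ","))))
      }
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
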