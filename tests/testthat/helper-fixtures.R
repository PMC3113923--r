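# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

# Small ExpressionMatrix with explicit values.
make_em <- function(signal, detection = NULL, normalized = FALSE) {
  if (is.null(dimnames(signal)))
    dimnames(signal) <- list(sprintf("p%d", seq_len(nrow(signal))),
                             sprintf("s%d", seq_len(ncol(signal))))
  expression_matrix(signal, detection, normalized = normalized)
}

# Three-group design (2 samples per group by default, one timepoint).
make_design <- function(n = c(ND = 2, D = 2, DI = 2), timepoint = "M3") {
  sample_design(paste0("s", seq_len(sum(n))), rep(names(n), n), timepoint)
}

# Random probe-profile fixture with detection layer.
random_em <- function(n_probes = 10, n_samples = 6, seed = 1) {
  set.seed(seed)
  sig <- matrix(2^rnorm(n_probes * n_samples, 8, 1), n_probes,
                dimnames = list(sprintf("probe_%03d", seq_len(n_probes)),
                                sprintf("s%d", seq_len(n_samples))))
  det <- matrix(runif(n_probes * n_samples), n_probes,
                dimnames = dimnames(sig))
  expression_matrix(sig, det)
}

# The six temporal archetypes, one gene each.
six_archetype_genes <- function() {
  data.frame(gene = paste0("g", 1:6),
             archetype = c("Rescued", "PartiallyRescued", "NotRescued",
                           "Prevented", "PartiallyPrevented", "NotPrevented"),
             stringsAsFactors = FALSE)
}

# Comparison-stats row for classifier tests.
stats_row <- function(p_nd_d = 0.01, fc_nd_d = 2, p_nd_di = 0.5,
                      fc_nd_di = 1.1, p_d_di = 0.5, fc_d_di = -1.1) {
  data.frame(probe_id = "p1", p_ND_D = p_nd_d, fc_ND_D = fc_nd_d,
             p_ND_DI = p_nd_di, fc_ND_DI = fc_nd_di,
             p_D_DI = p_d_di, fc_D_DI = fc_d_di,
             stringsAsFactors = FALSE)
}

# Minimal qPCR record set: per sample one control and one target Ct chosen
# to produce the requested per-sample delta-Ct.
qpcr_records <- function(delta_ct, control_ct = 18, gene = "Tg") {
  do.call(rbind, lapply(names(delta_ct), function(s) {
    data.frame(sample_id = s, gene = c("Actb", gene),
               ct = c(control_ct, control_ct + delta_ct[[s]]),
               is_endogenous_control = c(TRUE, FALSE),
               stringsAsFactors = FALSE)
  }))
}

# column order of result tables (kept in sync with write_result_rows)
RESULT_COLS <- c("probe_id", "p_ND_D", "p_ND_DI", "p_D_DI",
                 "fc_ND_D", "fc_ND_DI", "fc_D_DI",
                 "gene_symbol", "entrez_id", "gene_name")

GROUPS3 <- c("ND", "D", "DI")
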