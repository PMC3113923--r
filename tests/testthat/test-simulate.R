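test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(category_proportions = c(Normalized = 0.5,
                                                   Unchanged = 0.4)),
               "sum to 1")
  expect_error(sim_config(group_sizes_m3 = c(ND = 8, D = 1, DI = 7)),
               ">= 2")
  expect_error(sim_config(effect_size_fc = 1), "> 1")
  expect_error(simulate_qpcr(sim_config(seed = 1),
                             data.frame(gene = "g", archetype = "Weird")),
               "unknown temporal archetype")
})

test_that("noise-free limit reproduces the configured fold change exactly", {
  cfg <- sim_config(n_probes = 50, cv = 0, effect_size_fc = 2,
                    category_proportions = c(Normalized = 1, Unchanged = 0,
                                             PartiallyNormalized = 0,
                                             NotNormalized = 0, Inverted = 0,
                                             Undetected = 0),
                    seed = 5)
  sim <- simulate_expression(cfg)
  gs <- split(sim$design$sample_id, sim$design$group)
  ratio <- unname(rowMeans(sim$matrix$signal[, gs$D]) /
                  rowMeans(sim$matrix$signal[, gs$ND]))
  # 2-fold up or down depending on each probe's drawn direction
  expect_equal(abs(log2(ratio)), rep(1, 50), tolerance = 1e-6)
  expect_equal(ifelse(ratio > 1, 2, -2), sim$truth$true_fc)
  # insulin-treated group fully normalized
  ratio_di <- unname(rowMeans(sim$matrix$signal[, gs$DI]) /
                     rowMeans(sim$matrix$signal[, gs$ND]))
  expect_equal(ratio_di, rep(1, 50), tolerance = 1e-6)
})

test_that("simulation is deterministic under a fixed seed and varies across seeds", {
  a <- simulate_expression(sim_config(n_probes = 100, seed = 42))
  b <- simulate_expression(sim_config(n_probes = 100, seed = 42))
  c <- simulate_expression(sim_config(n_probes = 100, seed = 43))
  expect_identical(a$matrix$signal, b$matrix$signal)
  expect_identical(a$matrix$detection, b$matrix$detection)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$matrix$signal, c$matrix$signal))
})

test_that("realized category counts stay within binomial 99% bounds", {
  n <- 2000
  sim <- simulate_expression(sim_config(n_probes = n, seed = 9))
  props <- sim_config()$category_proportions
  counts <- table(sim$truth$true_category)
  for (cat in names(props)) {
    lo <- qbinom(0.005, n, props[[cat]])
    hi <- qbinom(0.995, n, props[[cat]])
    expect_gte(counts[[cat]], lo)
    expect_lte(counts[[cat]], hi)
  }
})

test_that("detection p-values implement the threshold contract", {
  sim <- simulate_expression(sim_config(n_probes = 500, seed = 4))
  det <- sim$matrix$detection
  undet <- sim$truth$true_category == "Undetected"
  # undetected probes fail the marginal threshold in every sample
  expect_true(all(det[undet, ] > 0.05))
  # detected probes carry present/marginal calls in every sample
  expect_true(all(det[!undet, ] <= 0.05))
  filt <- detection_filter(sim$matrix, sim$design)
  expect_setequal(filt$kept_ids, sim$truth$probe_id[!undet])
})

test_that("noise-free qPCR encodes the archetype trajectories in ddCt", {
  cfg <- sim_config(sigma_ct = 0, qpcr_fc = 2, seed = 8)
  qp <- simulate_qpcr(cfg, six_archetype_genes())
  rq <- ddct(qp$records, qp$design)
  # Rescued gene: 2-fold up at one month (ddCt = -1), treated group back to
  # control at three months (ddCt = 0)
  m1 <- rq[rq$gene == "g1" & rq$timepoint == "M1" & rq$group == "D", ]
  expect_equal(unique(round(m1$ddct, 9)), -1)
  m3 <- rq[rq$gene == "g1" & rq$timepoint == "M3" & rq$group == "DI", ]
  expect_equal(unique(round(m3$ddct, 9)), 0)
  # NotPrevented gene: no one-month change, both arms 2-fold up at 3 months
  m1 <- rq[rq$gene == "g6" & rq$timepoint == "M1" & rq$group == "D", ]
  expect_equal(unique(round(m1$ddct, 9)), 0)
  m3 <- rq[rq$gene == "g6" & rq$timepoint == "M3" & rq$group != "ND", ]
  expect_equal(unique(round(m3$ddct, 9)), -1)
})

test_that("the endogenous control gene is stable across groups", {
  qp <- simulate_qpcr(sim_config(sigma_ct = 0.15, seed = 21),
                      six_archetype_genes())
  ctrl <- qp$records[qp$records$is_endogenous_control, ]
  idx <- match(ctrl$sample_id, qp$design$sample_id)
  means <- tapply(ctrl$ct, qp$design$group[idx], mean)
  # group means agree within a few SEM of the per-well noise
  expect_lt(max(means) - min(means), 5 * 0.15 / sqrt(8))
})

test_that("phenotypes reproduce the configured group means", {
  des <- make_design(c(ND = 8, D = 8), "M1")
  ph <- simulate_phenotype(des, sim_config(seed = 30))
  d_glu <- ph$blood_glucose[des$group == "D"]
  # D mean within 3 SEM of 321 (printed one-month value)
  expect_lt(abs(mean(d_glu) - 321), 3 * 16)
  nd_glu <- ph$blood_glucose[des$group == "ND"]
  expect_lt(abs(mean(nd_glu) - 114), 3 * 12)
  expect_true(all(is.na(ph$hba1c_pct)))  # HbA1c not measured at one month
  ph3 <- simulate_phenotype(make_design(), sim_config(seed = 31))
  expect_false(anyNA(ph3$hba1c_pct))
  expect_true(all(ph3$blood_glucose > 0 & ph3$body_weight > 0))
})

test_that("uncoupled phenotype shows no systematic expression correlation", {
  set.seed(77)
  des <- make_design(c(DI = 7), "M3")
  rs <- replicate(200, {
    expr <- setNames(2^rnorm(7, 8, 0.3), des$sample_id)
    ph <- simulate_phenotype(des, sim_config(seed = NULL))
    cor(expr, ph$hba1c_pct)
  })
  expect_lt(abs(mean(rs)), 0.1)  # centered on zero
})
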