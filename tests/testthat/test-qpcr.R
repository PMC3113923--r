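test_that("ddCt evaluates the worked example and calibrator identities", {
  # two calibrator samples at dCt 8; test sample dCt 6 -> ddCt -2, rq 4
  recs <- qpcr_records(c(n1 = 8, n2 = 8, d1 = 6))
  des <- sample_design(c("n1", "n2", "d1"), c("ND", "ND", "D"), "M3")
  rq <- ddct(recs, des)
  expect_equal(rq$ddct[rq$sample_id == "d1"], -2)
  expect_equal(rq$rq[rq$sample_id == "d1"], 4.0)
  # calibrator sample sitting at the calibrator mean has rq exactly 1
  expect_equal(rq$rq[rq$sample_id == "n1"], 1)
  # calibrator geometric-mean rq is 1 by construction
  recs <- qpcr_records(c(n1 = 7.3, n2 = 8.9, n3 = 8.1, d1 = 6))
  des <- sample_design(paste0(c("n1", "n2", "n3", "d1")),
                       c("ND", "ND", "ND", "D"), "M3")
  rq <- ddct(recs, des)
  expect_equal(exp(mean(log(rq$rq[rq$group == "ND"]))), 1, tolerance = 1e-12)
})

test_that("rq is invariant to a per-sample Ct offset (pipetting model)", {
  recs <- qpcr_records(c(n1 = 8, n2 = 7.5, d1 = 6))
  des <- sample_design(c("n1", "n2", "d1"), c("ND", "ND", "D"), "M3")
  rq1 <- ddct(recs, des)
  shifted <- recs
  shifted$ct[shifted$sample_id == "d1"] <-
    shifted$ct[shifted$sample_id == "d1"] + 1.7
  rq2 <- ddct(shifted, des)
  expect_equal(rq2$rq, rq1$rq, tolerance = 1e-12)
})

test_that("qPCR integrity errors name the offending sample", {
  recs <- qpcr_records(c(n1 = 8, d1 = 6))
  recs <- recs[!(recs$sample_id == "d1" & recs$is_endogenous_control), ]
  des <- sample_design(c("n1", "d1"), c("ND", "D"), "M3")
  expect_error(ddct(recs, des), "d1")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  an <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(an$F, 3.0, tolerance = 1e-12)
  expect_equal(unname(an$df), c(2, 6))
  expect_equal(an$p, 0.125, tolerance = 1e-9)  # (1 + 2F/6)^-3 for F(2,6)
  flat <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)
  ident <- anova_oneway(list(c(2, 2), c(2, 2)))
  expect_equal(ident, list(F = 0, p = 1, df = c(1, 2)))
  expect_error(anova_oneway(list(1:3)), ">= 2 groups")
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(6)
  a <- rnorm(8); b <- rnorm(6, 1)
  an <- anova_oneway(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(an$p, tt$p.value, tolerance = 1e-9)
})

test_that("SNK separates only the extreme group in a one-outlier layout", {
  set.seed(8)
  groups <- list(ND = rnorm(8, 10, 0.5), DI = rnorm(8, 10.2, 0.5),
                 D = rnorm(8, 16, 0.5))
  snk <- snk_posthoc(groups)
  sig <- snk[snk$significant, ]
  expect_setequal(paste(sig$group_i, sig$group_j),
                  c("ND D", "DI D"))
  # oracle: the studentized range statistic against qtukey at its span
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1)) / 21
  q_nd_d <- abs(mean(groups$D) - mean(groups$ND)) / sqrt(mse / 8)
  row <- snk[snk$group_i == "ND" & snk$group_j == "D", ]
  expect_equal(row$q, q_nd_d, tolerance = 1e-9)
  expect_equal(row$q_crit, qtukey(0.95, row$span, 21), tolerance = 1e-9)
  # identical group values produce no separations
  same <- snk_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_false(any(same$significant))
})

test_that("SNK stepdown blocking encloses non-significant spans", {
  set.seed(9)
  for (rep in 1:25) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(6, sample(0:3, 1)))
    names(groups) <- paste0("g", seq_len(k))
    snk <- snk_posthoc(groups)
    # if the full span is not significant nothing may be
    full <- snk[snk$span == k, ]
    if (!full$significant) expect_false(any(snk$significant))
    # any significant pair must have q above its own span critical value
    sig <- snk[snk$significant, ]
    if (nrow(sig)) expect_true(all(sig$q > sig$q_crit))
  }
})

test_that("harmonic-mean n is flagged for unbalanced layouts", {
  snk <- snk_posthoc(list(a = rnorm(8), b = rnorm(5), c = rnorm(7)))
  expect_true(attr(snk, "harmonic_n"))
  snk2 <- snk_posthoc(list(a = rnorm(6), b = rnorm(6)))
  expect_false(attr(snk2, "harmonic_n"))
})

test_that("confirm_gene maps hand-built rq patterns to their temporal labels", {
  # deterministic fixtures: fixed within-group spread around exact means
  j <- c(-0.08, -0.04, 0, 0.02, 0.04, 0.08, -0.02, 0.06)
  rq_groups <- function(nd, d, di = NULL) {
    g <- c(rep("ND", 8), rep("D", 8), if (!is.null(di)) rep("DI", 8))
    data.frame(group = factor(g, levels = GROUPS3),
               rq = c(nd * (1 + j), d * (1 + j), if (!is.null(di)) di * (1 + j)))
  }
  cases <- list(
    list(m1 = rq_groups(1, 2), m3 = rq_groups(1, 2, 1), want = "Rescued"),
    list(m1 = rq_groups(1, 2), m3 = rq_groups(1, 2, 1.5),
         want = "PartiallyRescued"),
    list(m1 = rq_groups(1, 2), m3 = rq_groups(1, 2, 2), want = "NotRescued"),
    list(m1 = rq_groups(1, 1), m3 = rq_groups(1, 2, 1), want = "Prevented"),
    list(m1 = rq_groups(1, 1), m3 = rq_groups(1, 2, 1.5),
         want = "PartiallyPrevented"),
    list(m1 = rq_groups(1, 1), m3 = rq_groups(1, 2, 2), want = "NotPrevented"))
  for (cs in cases) {
    res <- confirm_gene(cs$m3, cs$m1)
    expect_true(res$confirmed)
    expect_equal(as.character(res$temporal), cs$want)
    expect_equal(res$direction, "up")
  }
  # suppressed genes classify symmetrically
  res <- confirm_gene(rq_groups(1, 0.5, 1), rq_groups(1, 0.5))
  expect_equal(as.character(res$temporal), "Rescued")
  expect_equal(res$direction, "down")
  # unconfirmed when the diabetic group never separates
  res <- confirm_gene(rq_groups(1, 1.02, 1), rq_groups(1, 1))
  expect_false(res$confirmed)
  expect_true(is.na(res$temporal))
})

test_that("a simulated archetype panel feeds the temporal classifier", {
  cfg <- sim_config(sigma_ct = 0.1, seed = 23)
  qp <- simulate_qpcr(cfg, six_archetype_genes())
  conf <- qpcr_confirmation(qp$records, qp$design)
  expect_true(all(conf$confirmed))
  # at least five of six labels recovered (each label compounds several
  # alpha = 0.05 tests; see the vignette on the recovery ceiling)
  expect_gte(sum(conf$temporal == six_archetype_genes()$archetype), 5L)
  # Rescued gene: DE at one month; Prevented gene: quiet at one month
  expect_true(conf$de_m1[conf$gene == "g1"])
  expect_false(conf$de_m1[conf$gene == "g4"])
})

test_that("null genes are rarely confirmed", {
  set.seed(24)
  false_conf <- replicate(150, {
    groups <- split(rnorm(24, 0, 0.2), rep(GROUPS3, each = 8))
    rq <- data.frame(sample_id = paste0("s", 1:24),
                     gene = "null", group = factor(rep(GROUPS3, each = 8),
                                                   levels = GROUPS3),
                     timepoint = "M3", delta_ct = unlist(groups),
                     ddct = unlist(groups), rq = 2^-unlist(groups))
    confirm_gene(rq)$confirmed
  })
  expect_lte(mean(false_conf), 0.10)  # ANOVA gate + SNK keep type I low
})
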