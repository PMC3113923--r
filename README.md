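# irclass

Insulin-response classification of diabetes-induced transcriptome changes.

## The problem

In insulin-dependent (type 1) diabetes, insulin replacement normalizes blood
glucose but does not prevent long-term complications such as diabetic
retinopathy. At the molecular level this shows up as *metabolic memory*:
some diabetes-induced gene expression changes persist even after euglycemia
is restored. A standard way to characterize this is a three-arm rodent
study — non-diabetic controls (ND), untreated streptozotocin diabetics (D),
and diabetics receiving chronic insulin (D+I) — profiled on expression
arrays, with selected genes confirmed by qPCR at an earlier timepoint that
precedes the start of insulin treatment.

`irclass` implements that analysis as a tested, reusable R pipeline for
anyone running treatment-response expression studies of this design:

1. **Preprocessing** — average normalization with background subtraction,
   then a detection filter keeping probes with present/marginal calls
   (detection p ≤ 0.05) in 100% of the samples of at least one group.
2. **Differential expression** — per probe, pairwise two-tailed t-tests and
   signed fold changes; a probe is differentially expressed when
   *p* < 0.05 **and** |FC| > 1.2 between ND and D (both strict).
3. **Insulin-response partition** — each DE probe is classified from the
   ND-vs-D+I and D-vs-D+I comparisons:

   | category | ND vs D+I | D vs D+I |
   |---|---|---|
   | Inverted | significant, direction flipped | — |
   | Not Normalized | significant, same direction | — |
   | Normalized | not significant | significant |
   | Partially Normalized | not significant | not significant |

4. **Temporal refinement** — genes measured at one month (before insulin
   begins) and three months map to Rescued / Partially Rescued / Not
   Rescued (change already present at one month) or Prevented / Partially
   Prevented / Not Prevented (change arises later).
5. **qPCR confirmation** — 2^−ΔΔCt relative quantification against an
   endogenous control (β-actin), one-way ANOVA with Student–Newman–Keuls
   post-hoc tests at three months, t-test at one month.
6. **Phenotype screen** — Pearson correlation of expression with blood
   glucose / %HbA1c within the insulin-treated group, plus biometric group
   summaries.
7. **Synthetic data** — a generator producing expression matrices with
   per-sample detection p-values, two-timepoint qPCR Ct tables and
   phenotype records, all with known ground truth, so every stage is
   testable by parameter recovery without any download.

File formats covered: GenomeStudio-style sample probe profiles, GEO series
matrices, per-category result TSVs, qPCR CSV and sample-design CSV.

## Worked example

```r
library(irclass)

cfg <- sim_config(seed = 11)          # 22,523 probes, groups ND/D/DI = 8/5/7
bundle <- run_pipeline(cfg, qpcr_genes = data.frame(
  gene = paste0("g", 1:6),
  archetype = c("Rescued", "PartiallyRescued", "NotRescued",
                "Prevented", "PartiallyPrevented", "NotPrevented")))
render_report(bundle)
```

```
Insulin-response classification report (config c5782bb479d98b2a569f6f97679bb41d)
Probes: 22523 input, 11124 detected, 1740 differentially expressed
Category              count  percent
Normalized              836      48%
PartiallyNormalized     234      13%
NotNormalized           625      36%
Inverted                 45       3%
qPCR confirmation: 6/6 genes (100%)
  g1         Normalized   Rescued
  g2         PartiallyNormalized PartiallyRescued
  g3         NotNormalized NotRescued
  g4         Normalized   Prevented
  g5         PartiallyNormalized PartiallyPrevented
  g6         NotNormalized NotPrevented
```

Reading the report: 11,124 of 22,523 simulated probes pass the detection
filter and 1,740 are called differentially expressed between control and
diabetic arms. The partition splits those by behavior under insulin, and the
qPCR table shows each simulated archetype confirmed (ANOVA + SNK) and
assigned its temporal label. Note that the recovered *Partially Normalized*
share understates the simulated truth by design of the category — it is
defined by double non-significance, which genuinely intermediate probes
rarely achieve at these group sizes; the methods vignette quantifies this
recovery ceiling.

For published data rather than simulations, read a probe profile with
`read_probe_profile()` (GenomeStudio flat files or GEO series matrices) and
pass it via `run_pipeline(data = list(matrix = em, design = design))`.

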