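# emtscreen

Cross-cohort screening of metabolic pathway activity against the
epithelial-to-mesenchymal transition (EMT) in tumor expression data, with
median-split survival stratification.

## The problem

EMT — the loss of epithelial identity and gain of migratory, mesenchymal
traits — drives metastasis in solid tumors, and individual metabolic
pathways can promote or restrain it. Given several independent tumor
expression cohorts, an EMT gene signature and a catalogue of metabolic
gene-sets, the question is: **which metabolic processes are reproducibly
associated, positively or negatively, with EMT activation across cohorts,
and do the hits stratify patient survival?**

`emtscreen` implements that screen for computational biologists working
with bulk transcriptomes (normalized microarray series, RNA-seq summaries,
mRNA z-scores), plus a latent-factor simulator that generates multi-cohort
data with *planted* EMT–metabolic correlations so every stage can be
validated end to end without downloading patient data.

## The statistics

**Per-sample gene-set activation z-score.** For cohort expression matrix
`x` (log scale), fold values are computed per gene against the cohort
median, `f_gs = x_gs − median_s(x_g·)` (linear-scale input is
log2-ratioed instead). For a gene set *G* with *m* genes matched in the
matrix, the activation score of sample *s* is

```
z_Gs = sqrt(m) * ( mean_{g∈G} f_gs − mean_{all g} f_gs ) / sd_{all g}(f_·s)
```

i.e. the set's mean fold contrasted against the sample's whole-profile
mean and standard deviation (n−1 denominator), scaled by `sqrt(m)`.
Composite "up-minus-down" signature scores are differences of two such
rows. A rank-based alternative (`rank_set_score`, `emt_score`) rescales
the mean rank of set genes to [0, 1] and defines the EMT score as
mesenchymal-minus-epithelial, in [−1, 1].

**Meta-correlation.** Within each cohort, each set's activation is
Pearson-correlated with the EMT set's activation; per-cohort `r_i` (with
`n_i` samples) are pooled on the Fisher-z scale by DerSimonian–Laird
random effects: `z_i = atanh(r_i)`, `v_i = 1/(n_i − 3)`, Cochran's `Q`,
`tau² = max(0, (Q − (k−1))/C)`, random weights `1/(v_i + tau²)`, and
`meta_r = tanh(pooled_z)` with a two-sided normal p-value. Sets with
`meta_r > 0.3` (or `< −0.3`) and `meta_P < 0.05` are classified positive
(negative).

**Survival.** Samples are split at the median of a signature score;
groups are compared by Kaplan–Meier curves, the log-rank test, and a
single-covariate Cox model (Efron ties) reporting the high-vs-low hazard
ratio with a 95% Wald CI.

## Worked example

Six simulated cohorts (442, 293, 510, 85, 78 and 68 samples — 1,476 in
total), a 335-set metabolic catalogue with two modules planted at
ρ = −0.46 (propionate- and butanoate-like) and two at ρ = +0.45:

```r
library(emtscreen)

design  <- planted_screen_design(seed = 42)
cohorts <- generate_multi_cohort(design$specs)
tables  <- lapply(cohorts, function(co)
  activity_table(fold_matrix(co$expression), design$catalogue))
screen  <- meta_screen(tables, design$emt_set_name)
screen[screen$classification != "not_significant",
       c("set_name", "k", "meta_r", "p_value", "classification")]
#>                             set_name k meta_r  p_value classification
#> 1   CHONDROITIN_SULFATE_BIOSYNTHESIS 6  0.467 4.45e-83       positive
#> 2       HEPARAN_SULFATE_BIOSYNTHESIS 6  0.422 1.83e-58       positive
#> 334             BUTANOATE_METABOLISM 6 -0.471 3.69e-32       negative
#> 335            PROPIONATE_METABOLISM 6 -0.474 3.32e-86       negative
```

All four planted modules are recovered near their planted correlations,
with the 331 null sets left unclassified. A survival run on a cohort with
a planted protective hazard (HR = 0.5 for the high-score group):

```r
sp <- cohort_spec("LUAD_SIM", 1000, list(module_spec("EMT", 25, 1)),
                  n_background_genes = 50, noise_sd = 0.5,
                  survival = list(baseline_rate = 0.08, beta = log(0.5),
                                  censor_time_max = 40, link = "median"),
                  seed = 43)
co    <- generate_cohort(sp)
score <- activation_score(fold_matrix(co$expression),
                          module_gene_sets(sp)[["EMT"]])
compare_survival(co$survival, score)
#> survival_comparison: n_low = 500, n_high = 500
#>   log-rank chi-square = 84.543 (p = 3.76e-20)
#>   HR (high vs low) = 0.464 [0.393, 0.549]
```

High-score samples live longer (HR < 1) and the CI covers the planted 0.5.

Real cohorts enter the same way: `read_expression()` (genes × samples
TSV), `read_gmt()` (MSigDB GMT catalogues), `read_survival()`
(sample/time/event TSV), then the identical scoring, screening and
survival calls — or one YAML config driven through `run_screen()` /
`run_survival()` or the CLI at `inst/cli/emtscreen.R`
(`simulate`, `score`, `screen`, `survival` subcommands).

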