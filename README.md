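# mutaccum

Analysis of somatic mutation accumulation in clonally expanded stem-cell
genomes — for example intrahepatic cholangiocyte organoids (ICOs) grown
from single liver stem cells of healthy donors and of patients with
precancerous liver disease. Each sequenced clone exposes the somatic
mutation catalog of one founder cell; `mutaccum` turns per-clone somatic
VCFs into mutation-context spectra, signature attributions, age-regression
rate estimates and driver-gene tallies, and ships a ground-truth synthetic
cohort generator so the entire pipeline is testable without
controlled-access sequencing data.

It is written for genomics analysts and statisticians working with clonal
WGS designs (organoids, single-cell expansions, laser-capture clones).

## What it computes

**Mutation contexts.** Every PASS somatic variant is classified into its
catalog category: the 96 trinucleotide substitution contexts on the
pyrimidine strand (SBS96), the 78 canonical doublet substitutions (DBS78),
the 83 indel categories by size/repeat/microhomology (ID83), and a
16-category structural-variant schema — SV type (DEL/DUP/INV/TRA) crossed
with length bins 1–10 kb, 10–100 kb, 100 kb–1 Mb, 1–10 Mb, >10 Mb, with
translocations unbinned.

**Signature refitting.** Per-clone spectra are refit against a signature
definition matrix $D$ (contexts × signatures) by non-negative least
squares,

$$\hat x = \arg\min_{x \ge 0} \lVert D x - c \rVert_2,$$

with candidate signatures selected by prevalence (present in ≥10% of
samples of a requested cancer type in an exposure table, unioned over
types). Relative contributions are $\hat x / \sum_j \hat x_j$.

**Burden regression.** Per-clone mutation totals are regressed on donor
age with a zero intercept (no somatic mutations at birth) and patient as a
random effect (random slope on age, REML via `nlme`):

$$\mathrm{count}_{ij} = (m + b_i)\,\mathrm{age}_i + \varepsilon_{ij},
\qquad b_i \sim N(0, \sigma_p^2).$$

Groups are compared on rate with a Z-test,
$Z = (m_1 - m_2)/\sqrt{SE_1^2 + SE_2^2}$, $p = 2\,\Phi(-|Z|)$, and on
variability with a one-sided F-test,
$F = \mathrm{var}_{disease}/\mathrm{var}_{healthy}$,
$p = 1 - F_{df_1,df_2}(F)$. Per-context group differences use Wilcoxon
rank-sum tests with Bonferroni correction; normality is checked per group
with the Shapiro–Wilk test; `power_simulation()` estimates the design's
power and type-I error by forward simulation.

**Drivers.** Records are intersected with a user-supplied driver-gene
interval table and each sample × gene cell reports its most severe
category (`frameshift/nonsense > missense > promoter/UTR > none`).

## Worked example

Simulate a cohort at the default study design (healthy/ALC/NASH/PSC with
7/5/5/3 patients, two clones each, healthy rates 46 SBS and 9 indels per
year, all groups generated at the same rates), fit the healthy and
alcoholic-cirrhosis burden regressions, and compare them:

```r
library(mutaccum)
library(dplyr)

co <- simulate_cohort(sim_config(seed = 1))
cnt <- filter(co$truth$clone_counts, var_class == "SBS")
fit_h <- fit_burden_regression(cnt, co$meta, group = "healthy")
fit_a <- fit_burden_regression(cnt, co$meta, group = "ALC")
fit_h
#> <burden_fit> group: healthy ( lme )
#>   rate: 46.01 +/- 4.33 mutations/year (95% CI half-width)
#>   SE 1.771, residual var 1392.26, 14 clones / 7 patients
compare_groups(fit_a, fit_h)
#> # A tibble: 1 × 8
#>   group_a group_b     Z   p_z     F   p_f   df1   df2
#>   <chr>   <chr>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 ALC     healthy 0.567 0.571 0.356 0.937     9    13
```

The healthy fit recovers the generating 46 SBS/year (estimate 46.01 ±
4.33, the 95% CI half-width), and the ALC-vs-healthy comparison is null
(p_z = 0.57), as it should be — both groups were generated at the same
rate.

Refit a drawn spectrum against a 4-signature model:

```r
m  <- synthetic_signature_model(4, "SBS", seed = 1)
sp <- simulate_catalog(3000, c(0.5, 0.3, 0.15, 0.05), m, seed = 9)
fit_nnls(sp, m)
#> <signature_fit>   residual = 57.17
#>               SYN1     SYN2     SYN3     SYN4
#> absolute 1555.6590 856.8749 448.8155 149.1625
#> relative    0.5167   0.2846   0.1491   0.0495
```

The recovered relative contributions (0.52/0.28/0.15/0.05) sit on the
generating mixture (0.50/0.30/0.15/0.05) up to multinomial noise at
n = 3000.

The full pipeline — simulate (or read VCFs), classify, refit signatures,
run burden statistics and driver tallies, and write a checksummed run
manifest — runs from one config:

```r
cfg <- pipeline_config(
  outdir = "run1",
  simulate = list(n_patients = c(healthy = 7, ALC = 5)),
  reference_group = "healthy", seed = 11
)
run_pipeline(cfg)
```

## Scope

The package consumes caller output (Strelka/GRIDSS-style VCFs) and
annotation strings; it does not call variants, predict consequences, run
dN/dS selection models, or download signature/driver catalogs. See the
methods vignette (`vignettes/mutation-accumulation.Rmd`) for the models,
assumptions, parameter defaults and known limitations.
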