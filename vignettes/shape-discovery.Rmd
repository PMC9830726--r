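---
title: "Discovering U-shaped and line-shaped metabolites in paired maternal–cord metabolomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering U-shaped and line-shaped metabolites in paired maternal-cord metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadmet)
```

## The scientific problem

Both small-for-gestational-age (SGA) and large-for-gestational-age (LGA)
newborns carry elevated long-term metabolic risk, mirroring the well-known
U-shaped relation between birthweight and type-2-diabetes incidence. A
natural hypothesis is that some circulating metabolites deviate in the
*same* direction at both birthweight extremes ("U-shaped" metabolites),
while others track birthweight monotonically ("line-shaped" metabolites).
`dyadmet` implements the complete discovery pipeline for this question on
paired maternal and umbilical-cord plasma metabolomes from mother–offspring
dyads grouped as SGA / AGA / LGA:

1. per-comparison two-class **OPLS-DA** models (SGA vs AGA and LGA vs AGA,
   in each compartment), fit by NIPALS on unit-variance-scaled intensities;
2. **differential-metabolite (DM) selection** by variable importance in
   projection, VIP > 1;
3. **four-way intersection** of the DM sets — the candidate metabolites
   perturbed at both birthweight extremes in both compartments;
4. **fold-change shape classification** of the candidates on the raw
   intensity scale;
5. **association analyses**: Spearman correlation of maternal vs cord
   abundance, and crude (Model 1) or covariate-adjusted (Model 2)
   correlations between metabolites and clinical phenotypes;
6. **cohort summary machinery**: one-way ANOVA (from raw data or from
   printed mean/SD/n summaries) and the Fisher–Freeman–Halton exact r×c
   test.

Because raw cohort data of this kind are rarely deposited, the package
ships a synthetic dyad-cohort generator with planted ground truth, so that
every stage — and the pipeline end-to-end — is validated by parameter
recovery rather than by eyeballing.

## The models

### OPLS-DA and VIP

For a two-group comparison with centered, scaled matrix $X$ ($n \times p$)
and centered class code $y$, the orthogonal filter is estimated
component-wise: the predictive weight is $w \propto X^\top y$, an
orthogonal weight is the part of the loading not aligned with $w$,
$w_o \propto p - (w^\top p)\,w$, and $X$ is deflated by the corresponding
score/loading pair. After `n_orth` rounds a single predictive component
$(t, p, c)$ is fit on the filtered matrix. Because deflation makes every
column of the filtered matrix exactly orthogonal to the removed scores, the
predictive score is orthogonal to all orthogonal scores by construction —
the package asserts this to $10^{-8}$.

Variable importance is the standard projection formula
$$\mathrm{VIP}_j=\sqrt{p\,\frac{\sum_a \mathrm{SSY}_a\,(w_{ja}/\lVert w_a\rVert)^2}{\sum_a \mathrm{SSY}_a}},$$
computed over the predictive component(s). Its normalization identity,
$\operatorname{mean}(\mathrm{VIP}^2)=1$, makes VIP > 1 a
"more-than-average-contribution" rule. For OPLS-DA the default is the
predictive-only variant (`variant = "pred"`); a variant including the
orthogonal components is available behind a flag because chemometrics
software is not unanimous about which variant it reports.

Model quality is summarized by training $R^2Y$ and cross-validated
$Q^2 = 1 - \mathrm{PRESS}/\mathrm{SSY}$ with stratified venetian-blind
folds, `k_folds = 7` by default (the common default of commercial
chemometrics software; the choice is configurable and `k_folds = n` gives
leave-one-out). A negative $Q^2$ means the model predicts held-out samples
worse than the class mean. With tens of samples and hundreds of variables,
negative $Q^2$ alongside high $R^2Y$ is the expected regime; DM selection
by VIP still proceeds in that regime, which is deliberate — the selection
step is a screening device, and the downstream intersection-plus-
classification stages provide the error control (see the recovery results
below).

### Shape classification

Fold changes are ratios of arithmetic group means of **raw** intensities
("fold change of means"); Z scores are used only for ordering/heatmap
export. For each metabolite the four values
$FC^{m}_{SGA/AGA}, FC^{m}_{LGA/AGA}, FC^{c}_{SGA/AGA}, FC^{c}_{LGA/AGA}$
determine a per-compartment label:

| $FC_{SGA/AGA}$ | $FC_{LGA/AGA}$ | label |
|---|---|---|
| > 1 | > 1 | U_up |
| < 1 | < 1 | U_down |
| < 1 | > 1 | line_up |
| > 1 | < 1 | line_down |
| either exactly 1 | | none |

The final call requires the maternal and cord labels to agree
(`concordance = "both"`); discordant compartments yield `none`. A
maternal-only mode exists for sensitivity analysis. A fold change exactly
at 1 sits on the boundary of the strict inequalities and is classified
`none`; ties at exactly 1 have probability zero under continuous data, so
this convention only matters for degenerate inputs. The rule is total and
exhaustive: the test suite enumerates all $3^4 = 81$ sign patterns of the
two compartment pairs against an independent truth table.

### Association models

Maternal–cord "placental transfer" association is the per-metabolite
Spearman correlation across dyads. Metabolite–phenotype association uses
Spearman correlation (Model 1) or a nonparametric partial correlation
(Model 2): response, metabolite and all numeric covariates are
rank-transformed, the two rank vectors are residualized on the covariate
design by least squares, and the Pearson correlation of residuals is
tested on $n-2-k$ degrees of freedom. The rank-residual route was chosen
because the crude analyses are Spearman; a Pearson-partial option exists
for comparison. Two covariate presets ship — `"table"` (maternal age,
parity, GDM, gestational age, newborn sex) and `"methods"` (the same
without GDM) — because published descriptions of such models frequently
differ between a methods section and a table footnote; neither preset is
privileged, and `"table"` is the default only because it is the superset.
No multiple-testing correction is applied by default (each record is a
per-test $\alpha = 0.05$ decision); a Benjamini–Hochberg FDR column is
emitted for users who want it.

### Exact r×c test

The Fisher–Freeman–Halton test enumerates all tables with the observed
margins, accumulating multivariate-hypergeometric probabilities with
log-factorials; the two-sided p value sums the probabilities of tables no
more probable than the observed one, with a relative tie tolerance of
$10^{-12}$. Enumeration is budgeted (default $10^7$ candidate tables);
beyond the budget a seeded Monte-Carlo mode (Patefield sampling) is
offered instead of silently switching methods.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a birthweight-stratified
dyad cohort. Defaults are fixed once and define the package's validation
conditions:

* **Design**: 16 / 28 / 23 dyads (SGA / AGA / LGA), paired maternal and
  cord samples, positive and negative ionization modes.
* **Intensity model**: log-normal abundances,
  $\log I_{ijc} = b_j + e_j(g_i) + \lambda u_{ij} + \varepsilon_{ijc}$,
  with baseline $b_j \sim N(12, 1)$ (arbitrary instrument units). An
  additive effect on the log scale directly parameterizes the
  ratio-of-means fold change: a planted class with effect $\delta$ has
  population fold change $e^{\delta}$.
* **Planted classes**: 30 metabolites in each of U_up, U_down, line_up,
  line_down and 200 nulls; $\delta_U = \delta_{line} = \ln 2$ and
  within-group log-SD $\sigma = 0.4$. U classes deviate by $\pm\delta_U$
  in SGA and LGA; line classes step by $\pm\delta_{line}$ per group
  ordinal (SGA, AGA, LGA) = (0, 1, 2) — group ordinal rather than
  continuous birthweight, matching the three-group analysis the pipeline
  implements.
* **Placental transfer**: a per-dyad, per-metabolite latent shared between
  compartments with loading $\lambda = \sigma\sqrt{\rho}$ and residual SD
  $\sigma\sqrt{1-\rho}$, so the maternal–cord Pearson correlation of log
  intensities is exactly $\rho$ (default 0.5) while the marginal log-SD
  stays at $\sigma$. Note that the *Spearman* correlation of the
  exponentiated values is slightly attenuated
  ($\tfrac{6}{\pi}\arcsin(\rho/2) \approx 0.68$ at $\rho = 0.7$), which is
  why recovery checks use a ±0.08 band.
* **Effects concordant across compartments** by default; a configurable
  discordance fraction flips cord effects to exercise the classifier's
  `none` branch.
* **Phenotypes**: per-group normal draws whose means/SDs (and categorical
  proportions) default to the demographic table of the motivating cohort;
  clinical panel entries that the source table does not print (HbA1c,
  HDL-C, LDL-C, FFA, homocysteine) carry synthetic third-trimester
  reference values and are documented as such. Phenotypes are independent
  of the metabolome unless an explicit `pheno_links` entry plants a linear
  link on the log scale — needed to validate association recovery.
* **Missingness** is MCAR only (rate 0 by default); real intensity data
  are left-censored rather than MCAR, so imputation behavior under
  intensity-dependent missingness is *not* validated here.

What passing tests show — and what they do not: recovery at these defaults
demonstrates that the pipeline's logic is correct and well-calibrated under
log-normal, homoscedastic, batch-free data with moderate effects. Real
UPLC–TOF data add drift, batch structure, heteroscedastic noise,
correlated features and annotation ambiguity, none of which the generator
emulates; QC-based drift correction and annotation are explicitly out of
scope.

## Numerical choices

* NIPALS: convergence tolerance $10^{-10}$ on the score vector, at most
  500 iterations, initialized from the response column of maximal
  variance. Sign convention: the largest-magnitude loading element of each
  component is positive, making every fit bit-for-bit reproducible.
* Z normalization uses sample SD (denominator $n-1$), the common
  chemometrics convention; constant or all-missing columns are dropped
  with a warning since their Z score is undefined. Normalization is
  applied within compartment by default.
* Unit-variance scaling is the model default; Pareto scaling is available
  (`scaling = "pareto"`) since the originating software family defaults
  differ.
* `n_orth = 1` orthogonal component by default — the most common choice
  for two-class OPLS-DA — configurable upward.
* Fold change: `NA` (flagged, never silently dropped) when the
  denominator-group mean is zero; missing intensities excluded pairwise.
* Random-number state: every generator and fold assignment consumes an
  explicit seed and restores the caller's RNG state on exit.

## Validation at a glance

The test suite validates each stage against an independent oracle (SVD-
based PLS, spreadsheet-style VIP evaluation, closed-form first-order
partial correlation, explicit leave-one-out loops, reference exact-test
enumeration) and the pipeline end-to-end by parameter recovery. At the
default study conditions (16/28/23 dyads, 120 planted + 200 null
metabolites, $\delta = \ln 2$, $\sigma = 0.4$, $\rho = 0.5$, ten seeds)
the full chain recovers planted shapes with sensitivity ≈ 0.97 and assigns
a U/line label to ≈ 0% of null metabolites; the transfer correlation
$\rho = 0.7$ is recovered within ±0.08 (Spearman attenuation included);
Model-1/Model-2 type-I error sits inside the binomial 95% band of the
nominal 5% over 1000 null metabolites; and the mean cross-validated $Q^2$
over 100 label permutations of null data is negative. Problem sizes were
chosen so the whole suite runs in well under a minute of CPU; they are the
package's validation conditions, not tuning knobs.

## Known limitations

* Multi-class OPLS, kernel variants and permutation-based validation plots
  are not implemented.
* The exact test's full enumeration is practical for the small tables of
  demographic summaries; large sparse tables need the Monte-Carlo mode.
* The generator's MCAR missingness and feature independence understate the
  difficulty of real data (see above).
* Fold-change shape calls inherit the instability of ratios of small
  means when intensities approach zero; the flagging mechanism surfaces
  but does not repair such metabolites.
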