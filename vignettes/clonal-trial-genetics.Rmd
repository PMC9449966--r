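---
title: "Methods: quantitative genetics of clonal trials and oil quality indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative genetics of clonal trials and oil quality indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrial)
```

## The model

A clonally replicated randomized block trial observes trait $t$ on clone
$i$ in block $j$ as

$$ y_{ijt} = \mu_t + g_{it} + b_{jt} + e_{ijt}, $$

with clone effects $g_i \sim N_T(0, \Sigma_g)$ drawn **once per clone**
and shared across its replications (vegetative propagation means replicate
plants carry the whole genotype), block effects
$b_{jt} \sim N(0, \sigma^2_{b,t})$, and plot errors
$e_{ij} \sim N_T(0, \Sigma_e)$. All effects are additive and mutually
independent; there is no genotype-by-block or genotype-by-year term.

The balanced two-way ANOVA of one trait gives expected mean squares
$E[\mathrm{MS}_G] = \sigma^2_e + r\,\sigma^2_g$ and
$E[\mathrm{MS}_E] = \sigma^2_e$, so

$$ \hat\sigma^2_g = \frac{\mathrm{MS}_G - \mathrm{MS}_E}{r}, \qquad
   \hat\sigma^2_e = \mathrm{MS}_E, \qquad
   \hat\sigma^2_p = \hat\sigma^2_g + \hat\sigma^2_e .$$

Because clones are whole-genotype replicates, $h^2 =
\sigma^2_g/\sigma^2_p$ is broad-sense heritability — operationally, the
repeatability of clone performance on a plot basis. The derived chain is

$$ \mathrm{PCV} = 100\,\sigma_p/\bar x,\quad
   \mathrm{GCV} = 100\,\sigma_g/\bar x,\quad
   h^2 = (\mathrm{GCV}/\mathrm{PCV})^2,\quad
   \mathrm{GA\%} = k\,h^2\,\mathrm{PCV}. $$

These identities are asserted (`1e-9`/`1e-12` relative) on every fitted
row, and they are what makes published tables auditable: heritability and
GA% are fully determined by the printed PCV/GCV columns.

Trait-pair association uses the mean cross-product decomposition, the
covariance analogue of the ANOVA computed by the same engine, with
$\widehat{\mathrm{cov}}_g = (\mathrm{MP}_G - \mathrm{MP}_E)/r$ and
$r_g = \widehat{\mathrm{cov}}_g / \sqrt{\hat\sigma^2_{gX}\hat\sigma^2_{gY}}$.
Path analysis solves the correlation normal equations $R\,p = r_y$ for
direct effects and reports indirect effects $r_{ij} p_j$ and the residual
effect $\sqrt{1 - \sum_i p_i r_{iy}}$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 2.06 | standardized selection differential; 2.06 retains the best 5%. Configurable in `rbd_genetics()` and `genetic_advance()`. |
| `alpha` | 0.05 | level for correlation flags and Duncan's test. |
| CV / GA% bands | <10 / 10–20 / >20 | conventional low/moderate/high cutoffs, left-closed at the boundary. |
| h² bands | <30 / 30–60 / >60 (%) | likewise conventional. |
| `max_condition` | 1e8 | path analysis refuses predictor matrices with a 2-norm condition number beyond this; no pseudo-inverse fallback. |
| standards registry | IS 15607 (CN ≥ 51, AV ≤ 0.5), ASTM D6751 (CN ≥ 47), EN 14214 (IV ≤ 115) | editable CSV; boundary values pass. |

The default `k = 2.06` is not arbitrary: across the packaged reference
estimate table, `GA% = 2.06 · GCV²/PCV` reproduces every printed GA% cell
to within 0.03, which pins down both the constant and the fact that the
chain was computed with the *unrounded* heritability rather than the
printed (capped) column. `verify_reference_tables()` recomputes this.

## Design decisions

**Two-way RBD, not one-way.** The reference analysis is described as
one-way ANOVA yet the trial is an RBD with four replications. The package
fits the two-way decomposition by default because the variance-component
chain requires an error term with block effects removed; a `"oneway"`
mode is kept for exact mimicry of a completely randomized analysis.

**Phenotypic variance on a plot basis.** $\sigma^2_p = \sigma^2_g +
\sigma^2_e$ (the Burton–DeVane convention), not $\sigma^2_g +
\sigma^2_e/r$. This is the convention that reproduces the reference
PCV–GCV gaps and sub-95 heritability cells (e.g. fruit aspect ratio 31%).

**Negative estimates.** $\hat\sigma^2_g < 0$ is truncated to zero with a
`truncated` flag, keeping downstream ratios defined while preserving the
information that $\mathrm{MS}_G < \mathrm{MS}_E$.

**Out-of-range genotypic correlations.** The $r_g$ estimator is a ratio
of independent noisy estimates and routinely leaves $[-1, 1]$ at small
clone counts. Such cells are reported raw with an `out_of_range` flag;
path analysis refuses matrices containing them unless the user opts into
clamping (`clamp = TRUE`). Truncating silently would hide estimator
breakdown.

**Significance of correlations.** The two-tailed t-test
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df (equivalent to $F(1, n-2)$), with
$n$ the number of clones. At $n = 6$ the critical $|r|$ is about 0.811;
one printed flag in the reference correlation table (0.771) cannot be
reproduced under any standard convention at this $n$, so fixtures retain
the printed flags while computations produce their own.

**Duncan's test.** Critical ranges come from the studentized-range
distribution at protection level $1-(1-\alpha)^{p-1}$ rather than from
transcribed tables (spot-checked against published two-decimal values,
e.g. 2.95 at $p=2$, 20 df). Ties in means are ordered by clone label so
letter displays are deterministic. The compact letter display uses the
insert-and-absorb construction, whose output is checked against the
pairwise matrix by definition on every run.

**Heritability cap anomaly.** Every reference row whose implied
$(\mathrm{GCV}/\mathrm{PCV})^2$ exceeds ~95% is printed as exactly 95.00
(while the abstract quotes 99% for one of them). Whether this is a cap or
a typesetting artifact cannot be decided from the printed record; the
package reports the unrounded value and flags these rows (`"cap"`), and
flags two further rows (male flowers, bunches per branch) whose printed
heritability disagrees with the implied value by >1 point
(`"inconsistent"`). One printed genotypic correlation (+0.523 for primary
branches × male flowers, where the phenotypic value is −0.517) is almost
surely a dropped sign; the fixture keeps it verbatim.

**Oil chemistry.** Formulas and units are fixed to the wet-chemistry
conventions (mg KOH/g, % oleic, g I₂/100 g); FFA/AV is the constant
28.2/56.1 whenever both derive from one titration. Compliance is reported
per row per standard with no aggregate verdict, because the reference
discussion's own aggregate claims are internally inconsistent (an iodine
value of 116.64 cannot be "below" a limit of 115).

## What the simulator does and does not emulate

`demo_trial_spec()` mirrors the reference trial's scale: 6 clones × 4
replications × 22 traits, trait means near the third-year clone means,
genotypic and error variances back-calculated from the reference GCV and
heritability columns (true $h^2$ from 0.31 to 0.99), block SD set to 2%
of each trait mean (a modest replication effect, chosen once as a
realistic field value; the reference tables contain no information about
block variance), and a genotypic correlation block linking female
flowers, fruits per bunch and seed yield at the printed genotypic
correlations.

The generator draws everything multivariate normal on the continuous
scale (counts included), keeps block effects independent across traits,
and produces one year per call — separate years are independent draws
with distinct labels, so there is no genotype-by-year correlation.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to non-normality,
spatial trend, missing plots, or genotype-by-environment interaction, all
of which real trials have.

Recovery checks run at two scales: the null calibration of the genotype
F-test (6 clones × 4 reps, 1000 seeds, rejection rate ≈ 5%) and
parameter recovery (50 clones × 4 reps, 200 seeds, mean $\hat h^2$ within
±0.03 of truth at $h^2 \in \{0.2, 0.5, 0.8, 0.95\}$ and mean $\hat r_g$
within ±0.05 of 0.6). The flag-rate calibration for genotypic
correlations is run at $h^2 = 0.95$, 20 clones: the $n-2$ df t-test is
exact only in the limit where clone means are dominated by genotype, so
high heritability is the regime where the calibration claim is
well-posed; at low heritability the test is approximate, which is a
property of the estimator, not of this implementation. These problem
sizes are the package's standing test conditions.

## Numerical notes and degenerate inputs

- Balanced-case SS partition is exact to 1e-9 relative tolerance and is
  tested against definitional loops and `stats::aov`/`stats::manova`.
- All-equal observations give zero SS everywhere; F and $h^2$ are
  reported `NA`, never 0/0.
- CVs are undefined at non-positive grand means (error), matching their
  percent-of-mean meaning.
- Multivariate normal draws use an eigendecomposition with negative
  rounding eigenvalues clamped at zero, so exactly singular PSD
  $\Sigma_g$ (including the all-zero null) is supported; $\Sigma_e$ must
  be positive definite.
- Unbalanced layouts are refused by the ANOVA layer (no silent
  approximation); the container warns at load time, or errors in strict
  mode.

## Limitations

No narrow-sense heritability (clonal data cannot separate additive from
non-additive variance), no pooled multi-year or multi-location analysis,
no spatial row–column modelling, no multicollinearity remediation in path
analysis beyond refusal, and no fatty-acid-profile-based fuel property
prediction. The packaged reference tables are verification fixtures: the
raw plot data behind them were never deposited, so their means, SEs and
letter groups are inputs, not recomputable outputs.
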