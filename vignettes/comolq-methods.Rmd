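---
title: "Methods: joint cis-QTL mapping, co-localization, and mediation with comolq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint cis-QTL mapping, co-localization, and mediation with comolq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comolq)
```

`comolq` analyses the joint genetic architecture of gene expression and
DNA methylation in *cis*. This vignette documents the statistical models,
the tunable parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reasonable choice existed.

## Study design assumed by the package

The workflow assumes the two molecular traits were profiled in two
*disjoint* genotyped panels of one cohort — an expression panel and a
methylation panel — because the co-localization model treats the two sets
of summary statistics as independent. A third, smaller *overlap* panel
(members of the methylation panel that also have expression data not used
in the eQTL scan) supports the individual-level causal analyses. The
synthetic-data defaults, 992 expression samples, 337 methylation samples
and an overlap of 316, mirror this design at the sample sizes typical of
a two-platform population cohort.

## cis-QTL scans

For each SNP–probe pair on the same chromosome with
$|\text{pos}_{SNP} - \text{pos}_{probe}| < w$ (default $w = 500$ kb,
strict inequality, so a SNP exactly 500 kb away is excluded), the scan
fits

$$ y_i = \mu + \beta g_i + \gamma^\top c_i + \varepsilon_i $$

on complete cases, where $g_i$ is the imputed dosage in $[0,2]$ and $c_i$
the covariates (age, sex, and phenotype principal components; PCs are
computed per trait with `compute_phenotype_pcs()` and the count is chosen
to maximize discoveries). Expression enters on the $\log_2$ scale and
methylation as logit-transformed beta values,
$\mathrm{logit}(b) = \ln(b/(1-b))$, clipped to $[10^{-6}, 1-10^{-6}]$
before the transform so boundary values remain finite. Two-sided P-values
use the $t$ distribution with $n - p$ residual degrees of freedom; the
implementation residualizes both phenotype and dosage on the covariates
(Frisch–Waugh), which is algebraically identical to the full fit. The
probe anchor is the TSS for expression probes and the CpG coordinate for
methylation; when only a probe start is annotated it is used as the
anchor.

**Permutation-adjusted empirical P.** Per probe, the phenotype is
residualized on the covariates once, the residuals are permuted, and the
minimum nominal P across the probe's cis-SNPs is recorded per
permutation; permutation regressions omit the covariates, the standard
fast approximation (a full re-fit per permutation changes nothing
materially when covariates are residualized out first). Permutation is
adaptive between 1000 and 10000 rounds: after the first 1000, sampling
stops if at least 100 permutation minima beat the observed best P (the
adjusted P is then already well resolved). A beta distribution is fitted
to the permutation minima by maximum likelihood (Nelder–Mead on
$(\log a, \log b)$ from a moment-matched start, parameters bounded to
$(10^{-3}, 10^{6})$), and the adjusted P is
$F_{\mathrm{Beta}(a,b)}(p_{\min})$. If the permutation minima are
degenerate the plain $(r+1)/(N+1)$ empirical P is returned with a
warning. Adjusted P-values are uniform under the null (tested by KS) and
track 10000-permutation direct empirical P-values with Spearman
$\rho > 0.99$ in the acceptance suite.

**FDR.** Probe-level q-values use Storey's estimator with $\pi_0$
estimated on the grid $\lambda = 0.05, 0.10, \dots, 0.95$, smoothed by a
cubic spline and evaluated at $\lambda = 0.95$; with fewer than 100 tests
$\pi_0$ is fixed at 1 (Benjamini–Hochberg). Scans use a probe-level FDR
of 0.01; causal analyses use 0.05. The lead SNP is the probe's
minimum-P SNP, with exact ties broken by smaller distance and then lower
coordinate — a deterministic rule the data rarely exercise.

## LD utilities

`ld_r2()` is the squared Pearson correlation of dosages (composite LD on
imputed dosages, not phased haplotypes — appropriate because dosages are
what the scans use). `ld_score()` sums r² between a lead SNP and all SNPs
within 500 kb *including the self term*, following the LD-score
literature convention; an isolated SNP therefore scores 1. `ld_prune()`
visits SNPs in ascending P order and keeps a SNP only if its r² with
every kept SNP is ≤ 0.3 (strict `>` removes), so the more significant
member of a violating pair survives.

## Candidate eProbe–CpG pairs

A CpG qualifies for pairing with an eProbe when the probe's lead eSNP is
a genome-wide-significant meSNP for that CpG. Significance is extended
from the probe to the SNP level the way permutation-calibrated mappers
do: the CpG must pass probe-level q < 0.01, and the pair's nominal P must
fall below the CpG-specific nominal threshold obtained by inverting the
CpG's fitted beta null at the genome-wide adjusted-P cutoff. Because CpG
clusters are correlated, the raw combinations are pruned in two steps:
among CpGs sharing a SNP, keep the CpG whose own lead meSNP has the
highest r² with a lead eSNP; then force each eProbe into exactly one pair
— the CpG whose lead meSNP is in strongest LD with the probe's lead eSNP.
Exact r² ties (common when both leads coincide) are broken by smaller
meQTL P, then lower CpG coordinate.

## Co-localization

Per SNP and trait, the Wakefield approximate Bayes factor compares a
normal effect prior $N(0, W^2)$ with the point null: with $V =
\mathrm{SE}^2$, $z = \hat\beta/\mathrm{SE}$ and $r = W^2/(W^2+V)$,

$$ \log \mathrm{ABF} = \tfrac12 \log(1-r) + \tfrac12 z^2 r . $$

$W = 0.15$ on the standardized-phenotype scale is the default for
quantitative traits and is exposed as configuration. Raw-scale effects
are rescaled to that scale preserving $z$, with
$\mathrm{SE}_{std} = \sqrt{1/(2 n \cdot \mathrm{maf}(1-\mathrm{maf}))}$;
the same approximation reconstructs effects from external summary
statistics carrying only P, MAF and n (`effects_from_p()`). Whether a
study standardized its effects before ABF computation is rarely
reported; the rescaling used here leaves $z$ — the dominant term —
unchanged, so posteriors are insensitive to that choice at the effect
sizes that matter.

The five-hypothesis posterior (H0 none, H1/H2 one trait, H3 distinct
variants, H4 common variant) enumerates single-causal-variant
configurations over the SNPs shared by the two summary sets: $S_1 =
\sum_i e^{L_{1i}}$, $S_2 = \sum_i e^{L_{2i}}$, $S_4 = \sum_i
e^{L_{1i}+L_{2i}}$, $S_3 = S_1 S_2 - S_4$, with unnormalized weights
$(1,\, p_1 S_1,\, p_2 S_2,\, p_1 p_2 S_3,\, p_{12} S_4)$. All sums run in
log space (log-sum-exp); $S_3$ is computed via `expm1` on the log scale
and is exactly zero — not merely small — for a single-SNP region, where
no distinct-variant configuration exists; a materially negative value
from cancellation is clamped to zero with a warning. The tested region is
the intersection of SNPs within 250 kb of the lead eSNP, SNPs within
500 kb of the CpG (others were never scanned for methylation), and SNPs
present in both sets.

**Priors from QTL counts.** With $P_e$ and $P_m$ the fractions of tested
SNPs that are independent eSNPs and meSNPs, and $f$ the prior probability
that a causal eSNP is also a causal meSNP:
$p_{12} = f P_e$, $p_1 = P_e - p_{12}$, $p_2 = P_m - p_{12}$. The default
grid is $f \in \{0.75, 0.5, 0.25, 0.1, 0.05\}$. The calibrated $f$
minimizes $|\sum_{\text{pairs}} PP_4(f) - f \cdot n_{\text{pairs}}|$
(posterior vs prior expectation of co-localization). The published
description of this internal empirical calibration does not pin down the
statistic; the sum of PP4 is used for selection and the count of pairs
with PP4 > 0.8 is reported alongside. Pairs with PP4 above 0.8 (config)
are designated co-localized; the relative CCV support $PP_4/(PP_3+PP_4)$
is reported for all pairs but flagged interpretable only when
$PP_3 + PP_4 > 0.8$.

## Causal analyses on the overlap panel

Phenotypes are covariate/PC-adjusted once; the lead SNP is then the only
additional regressor. `partial_correlation()` reports the Pearson
correlation of the pair before and after residualizing both phenotypes on
the lead eSNP dosage (by default the lead eSNP alone, matching the named
adjustment variable; a dosage matrix supports the multi-SNP adjustment
used after a secondary signal is found). `mediation_test()` fits the
total-effect, direct-effect and mediator regressions and evaluates the
Sobel statistic

$$ t = \frac{\beta_1 \beta_2}{\sqrt{\beta_1^2 \sigma_{\beta_2}^2 +
\beta_2^2 \sigma_{\beta_1}^2}} $$

against the standard normal; the mediation proportion is
$(\beta_{unadj} - \beta_{adj})/\beta_{unadj}$, undefined when the total
effect vanishes. `run_both_models()` evaluates SME (methylation mediates)
and SEM (expression mediates) per pair; evidence of mediation requires
the per-model q-value below 0.05 *and* a positive mediation proportion.
Fixed nominal cutoffs sometimes quoted for such analyses (e.g. Sobel
P < 0.0035) are realizations of an FDR rule on a particular pair set, not
constants, so the package applies the FDR rule itself. All effect signs
are reported relative to the expression-increasing allele, which makes
"opposite direction" well defined in `direction_summary()` and drives the
opposite-sign secondary-CpG search (`find_opposite_cpgs()`; search window
500 kb, the meQTL testing window, since secondary CpGs are simply other
meQTL targets of the same SNP). `conditional_secondary_scan()` re-runs a
probe's cis scan with the primary lead dosage appended to the covariates
and reports a new lead only below a configurable threshold (default
1e-5); a dosage collinear with the primary is skipped.

## The synthetic-data generator

`simulate_trio()` implements the canonical mediation simulation: dosages
$g_i$ as sums of two Hardy–Weinberg Bernoulli haplotypes, then

$$ x_i = \beta_{GX} g_i + \varepsilon_{Xi}, \qquad
   y_i = \beta_{XY} x_i + \rho_{Yi}, \qquad
   \varepsilon, \rho \sim N(0,1) . $$

The published description of this design states the variance in the
mediator explained by the SNP, not $\beta_{GX}$, and does not say whether
$g$ was standardized; the package uses $g$ on its raw dosage scale and
sets $\beta_{GX} = \sqrt{v/\bigl((1-v)\, 2\,\mathrm{maf}(1-\mathrm{maf})\bigr)}$
so that the population fraction of $\mathrm{var}(x)$ explained equals $v$
exactly with unit noise variance. Grids for $v$ and $\beta_{XY}$ span
0.01–0.75. Measurement error, when requested, is added to the designated
mediator *after* the causal chain is generated, so it attenuates
estimated mediation without changing the truth; the magnitudes of such
error are not published, so tests use an SD grid of 0, 0.75, 1.5 (noise
comparable to none, moderate, and strong relative to the unit residual).

`simulate_region()` generates a multi-SNP cis window. Within an LD block,
each haplotype's alleles are thresholded from a shared latent Gaussian;
the latent correlation is calibrated numerically (bivariate-normal
orthant probability + root finding) so that the realized allele
correlation matches the requested block correlation — a naive threshold
model would attenuate it. Five causal models generate the phenotypes:
NULL (noise), PLEIOTROPY ($E$ and $M_j$ each receive independent SNP
effects), SME ($M_j$ from the SNP, $E = \beta_{path} M_1 + \varepsilon$),
SEM (reversed), DISTINCT (different causal SNPs). CpG effect signs
alternate by default, creating the anti-correlated CpG clusters that the
secondary-CpG search expects. Methylation is generated on the logit scale
(the analysis scale) and exposed both ways. One cohort is simulated and
split into the disjoint panels; the overlap panel is the leading subset
of the methylation panel.

**What the generator does not emulate:** realistic allele-frequency
spectra and recombination maps, haplotype phasing, imputation error,
array probe artifacts and batch effects, trans effects, and cellular
heterogeneity. Passing tests therefore demonstrate the statistical
machinery is correct and calibrated under the stated models, not that
real data meet those models.

## Reproducibility and problem sizes

Every stochastic stage derives its own seed from the root seed and a
stage tag (`derive_seed()`), so stages are individually reproducible and
results do not depend on evaluation order. Output TSVs carry the
configuration hash and seed. Test-suite problem sizes were chosen so each
statistical claim has adequate resolution while the whole suite stays
desk-scale: 200 probes against the 10000-permutation oracle, 100
replicates for shared/distinct co-localization recovery, 1000 replicates
for partial-correlation type-I error at $n = 316$, 200 replicates per
point of the measurement-error and model-comparison grids.

One qualitative claim deserves a note: the negative relationship between
a lead SNP's LD score and PP4. In a pure shared-causal simulation the
distinct-variant hypothesis is strongly prior-suppressed
($p_1 p_2 / p_{12} \sim 10^{-6}$), so LD affects PP4 only through the
power channel and the effect is weak; quartile means of PP4 are
noise-dominated at a few hundred desk-scale replicates, while the rank
correlation between LD score and PP4 is reliably negative. The suite
therefore asserts the trend as a negative Spearman correlation over 300
replicates in a power-limited regime (variance explained 0.03).

## Known limitations

- The co-localization model assumes at most one causal variant per trait
  in the region; allelic series violate it.
- Sobel's normal approximation is conservative for small indirect
  effects; the package reports the test as defined rather than a
  bootstrap alternative.
- The mediation proportion is unstable when the total effect is near
  zero; results with $|\beta_{unadj}|$ close to machine noise are flagged
  undefined rather than reported.
- The partial-correlation adjustment uses the lead eSNP (optionally plus
  a secondary lead); when the lead meSNP differs and is in imperfect LD,
  residual confounding by the meSNP is possible.
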