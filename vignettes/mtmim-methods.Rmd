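---
title: "Multi-environment QTL mapping for biparental RIL populations: models and methods"
author: "mtmim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-environment QTL mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mtmim` implements the analysis chain used to map quantitative trait loci
(QTLs) for quantitative traits in a biparental recombinant inbred line (RIL)
population evaluated in several field trials: linkage-map construction from
genotyping-by-sequencing (GBS) SNP calls, REML mixed-model analysis of
lattice-design trials, and multitrait multiple interval mapping (MT-MIM)
across trials. This vignette describes the models, the tunable parameters
and their defaults, the synthetic-data generator the tests rely on, and the
numerical and design choices made where several reasonable options existed.

## Population and genotype model

The population is a set of RILs derived from a cross of two inbred parents
(in the motivating material, the sweet sorghum lines Brandes and Wray) by
single-seed descent to F2:6. Marker calls are recoded against the parental
lines: `+1` for the first-parent (Brandes-like) homozygote, `-1` for the
second-parent (Wray-like) homozygote. Residual heterozygous calls are set to
missing rather than resolved — the same handling applied to heterozygous GBS
calls upstream — because at F2:6 they are rare (expected fraction
$2^{-5} \approx 3\%$ per locus) and GBS heterozygote calls are unreliable.

Marker filtering runs in three ordered stages, each with its count reported:
missing fraction above 25%; redundancy (two markers are redundant iff their
call vectors are identical *including* the positions of missing values — a
conservative definition that never imputes); and segregation distortion,
a 1-df chi-square test of the 1:1 parental ratio at a Bonferroni-corrected
5% level whose denominator is the number of markers entering the stage.

Two-point linkage between markers uses the selfed-RIL correction: with $n$
complete pairs and observed recombinant fraction $\hat R = k/n$, the gametic
recombination fraction is $\hat r = \hat R / (2(1-\hat R))$
(Haldane–Waddington), and the LOD is the base-10 binomial likelihood ratio
against $R = 0.5$. Markers are grouped transitively at $\hat r < 0.35$ and
LOD $> 8$; each group's minority-chromosome members (by physical annotation)
are removed as false positives, a 50/50 tie discarding the group since its
origin cannot be identified. Within groups, markers are ordered by reference
physical position; de-novo ordering is out of scope.

## Hidden Markov model

Multipoint distances and genotype probabilities come from a two-state HMM
over the final inbred genome (states: the two parental homozygotes). The
transition probability across an interval with gametic recombination
fraction $r$ is the selfed-RIL recombinant probability $R = 2r/(1+2r)$; the
chain deliberately models the finished RIL genome, not per-generation
meioses. Emissions tolerate a fixed genotyping error: an observed call
matches the underlying state with probability $1-\varepsilon$
($\varepsilon = 0.01$ by default, chosen to absorb GBS-scale error), and
missing calls emit 1. Per-interval $r$ is re-estimated by EM
(Baum–Welch with the constrained symmetric transition matrix) to a
log-likelihood change below $10^{-6}$ or 1000 iterations. Distances in cM
use the Kosambi map function by default
($d = 25\,\ln\!\frac{1+2r}{1-2r}$), with Haldane
($d = -50\,\ln(1-2r)$) selectable; the choice is exposed because the
original tooling's default is not documented, and Kosambi is the common
default of linkage-mapping software for these populations.

Conditional genotype probabilities are computed by forward–backward
smoothing on a grid augmenting the markers with pseudomarkers every 1 cM
(grid positions are cM offsets from the first marker of the group, both ends
included; pseudomarkers carry the physical position of the nearest left
marker for reporting). Each probability pair sums to one within $10^{-9}$;
the tests verify the smoother against brute-force enumeration over all
hidden paths on small instances.

## Phenotype mixed models

Each trial is a square lattice (15 × 15 with three replicates in the
motivating design; 223 RILs plus the two parents as checks). The single-trial
model is

$$y_{ijk} = \mu + r_k + b_{j(k)} + t_i + s_{i(jk)} + \epsilon_{ijk},$$

with replicates and the plant-count (stand) covariate fixed, incomplete
blocks random within replicates, and the genotype term either fixed (BLUE
adjusted means) or split into random RIL effects
$g_i \sim N(0, \sigma_g^2)$ plus fixed check effects (BLUP adjusted means).
The stand covariate is centered within trial to keep intercepts
interpretable. REML estimation runs on dense Henderson mixed-model
equations: the restricted likelihood is evaluated through the MME
coefficient matrix ($-2\ell_R = (N-p)\log 2\pi + \log|R| + \log|G| +
\log|C| + y'Py$, identical to the V-based form), and maximized over
log-variance parameters with `nlminb` to a relative tolerance of $10^{-8}$.
This in-package engine exists because the multitrial genotype covariance
structures below, the per-trial residual variances, and the exact genotype
prediction-error-variance (PEV) block of $C^{-1}$ are not all available from
general mixed-model packages; tests check it against independent direct
V-matrix likelihood maximization and PEV formulas.

Summaries follow the standard definitions:
$\mathrm{CV} = \sqrt{\sigma^2}/\bar y \times 100$ (the square root of the
residual variance over the trait mean — the form consistent with published
values; $\bar y$ defaults to the mean of the adjusted means) and the Cullis
generalized heritability $h^2 = 1 - \bar v_{\mathrm{BLUP}} / (2\sigma_g^2)$,
where $\bar v_{\mathrm{BLUP}}$ is the exact average over all RIL pairs of
the PEV of a BLUP difference, computed from the MME inverse (cheap and exact
at a few hundred genotypes; no sampling approximation).

The multitrial model adds trial, replicate-in-trial, check and
check-by-trial fixed effects, per-trial block variances, per-trial residual
variances (always heterogeneous; structure selection applies to the genetic
part only), and RIL effects with covariance $G_L \otimes I$ across the $L$
trials. $G_L$ structures: ID (1 parameter), DIAG ($L$), CS (2),
CSH ($L+1$), US ($L(L+1)/2$), parameterized to stay positive (semi)definite
(log variances; the common correlation mapped onto $(-1/(L-1), 1)$; US via
Cholesky). AIC $= -2\ell_R + 2q$ and BIC uses the residual-contrast sample
size $N - \mathrm{rank}(X)$; ranking is by BIC with ties broken toward fewer
parameters and any AIC/BIC disagreement flagged. Because a richer structure
can never lower the restricted likelihood, nesting is a test invariant.

GGE biplots summarize genotype-by-environment pattern: columns of the
genotype × trial mean matrix are centered and (by default) SD-scaled, then
decomposed by SVD with symmetric singular-value partitioning. With full
singular-value weighting on the column side the loading angles reproduce the
Pearson correlations of the columns; with symmetric partitioning (the
default display convention) the angles are an approximation, which is why
the result object carries the correlation matrix alongside.

## MT-MIM

QTL mapping regresses the per-trial adjusted means on expected genotype
scores (Haley–Knott):

$$y_{ei} = \mu_e + \sum_{r=1}^{R} a_{er} x_{ir} + \epsilon_{ei},
\qquad \epsilon_i \sim N(0, \Sigma_E),$$

with $x = P(\mathrm{AA}) - P(\mathrm{BB}) \in [-1, 1]$ (+1 = Brandes-like
homozygote). Maximum likelihood with environment-specific regressor sets is
computed by iterated GLS (coefficients given $\Sigma_E$, then
$\Sigma_E$ = residual crossproduct / I) to a log-likelihood change below
$10^{-10}$; with a common regressor set the first step is already the exact
solution (SUR = OLS identity).

The model search is forward–backward on score statistics. At each candidate
position the multivariate score statistic for $H_0: a_e = 0\ \forall e$ is
$U' \hat\Sigma^{-1} U / \tilde x'\tilde x$ with
$U_e = \tilde x' \hat e_e$, where $\tilde x$ is the candidate score
residualized against the current design — asymptotically $\chi^2_E$ under
the null. Genome-wide thresholds come from multiplier (wild) resampling:
per-individual score contributions are reweighted by i.i.d. standard normal
draws, statistics recomputed everywhere, and the genome-wide maximum
collected over 1000 resamples (default); the threshold is the empirical
$(1-\alpha)$ quantile. A per-individual multiplier scheme was chosen over
permutation because it preserves the fitted covariate structure under the
current model; the tests verify the implied family-wise error rate by
simulation. Forward selection adds the argmax position while it exceeds the
genome-wide 5% threshold, recomputing the threshold under the updated model
each round (a conditional scan); backward elimination then re-tests each QTL
against the 1% threshold under the model without it. Positions within the
exclusion window of a model QTL — 10 cM in genetic-map mode, 100 or 200 kb
in physical-map mode (observed marker scores, no pseudomarkers) — are
ineligible, as they sit in high-LD neighborhoods of QTLs already fitted.

After the search, per-environment effects are pruned in the seemingly
unrelated regression sense: the least significant effect with Wald
$p > 0.05$ is removed and the model refitted with unequal regressor sets,
iterating until all retained effects are significant (the per-effect level
and the iterative variant are package choices; neither is pinned by the
motivating analysis). Pruned effects are reported as the literal token
`sur`; a QTL losing every environment is dropped.

Reporting: the LOD of a QTL is the base-10 likelihood ratio of the model
with and without it; ~95% support intervals are the widest contiguous
region around the profile peak within 1.5 LOD (profile computed by moving
the focal QTL along its group with the others fixed); and
$\mathrm{PVE}_{er} = 100\, \hat a_{er}^2 \mathrm{Var}_i(x_{ir}) /
\mathrm{Var}_i(y_{ei})$ — the marginal variance-ratio form, chosen (and
recorded in output metadata) because the published tables do not state
their convention; a sequential decomposition would differ for linked QTLs.
QTLs are named `TRAIT-{T1|T2|T3|MT}.k` in genome order within each
trait-analysis combination.

## The synthetic-data generator

The generator exists so the whole chain runs and is testable with no
external data; its defaults are the study conditions: 10 chromosomes
(~137 cM each), 223 RILs at F2:6, GBS-like missingness with 1% genotyping
error, three trials in a 15-block lattice with three replicates, five QTLs
with environment-specific effects (one simulated as null in trial 1,
exercising the `sur` path) and a correlated residual covariance
$\Sigma_E$ across trials. Where the motivating material states no value,
one realistic choice was made once: 15% missingness after upstream
filtering, 40 markers per chromosome, block variance 0.25 and plot residual
variance 1 in trait units, stand simulated as truncated Poisson with a
zero coefficient by default, and a fixed synthetic physical scale of
250 kb/cM recorded in the map object.

Two RIL engines are provided. `"ssd"` (default) simulates the F1 and
`generations - 1` rounds of single-seed descent explicitly, with Poisson
(no-interference) crossovers — crossover interference is deliberately out of
scope, Haldane being the standard null model. `"markov"` draws finished
inbred genomes directly from the $R = 2r/(1+2r)$ interval process, the
single-seed-descent limit; it is orders of magnitude faster and is used for
the large replicated calibration simulations, having been cross-checked
against the explicit engine (heterozygosity decay, recombinant-pair
fractions). All randomness flows from one master seed through named
per-operation sub-streams, so any artifact is reproducible from the
resolved configuration alone.

What passing tests on synthetic data do *not* show: the generator has no
crossover interference, no epistasis or dominance, no segregation-distortion
mechanism, no linkage between missingness and genotype (GBS missingness is
not independent in real data), and its lattice randomization is a simple
permutation rather than a resolvable alpha design. Results on real data can
therefore differ, particularly the distortion-filter counts and the LD
structure the exclusion windows lean on.

## Numerical choices and degenerate inputs

Variance parameters are optimized on the log scale, so exact zeros are
reached only in the limit; noise-free data return components at numerical
zero (below $10^{-4}$). Probabilities are normalized pairwise and asserted
to $10^{-9}$. The score statistic at a position collinear with the current
design is undefined and skipped. Two-point estimates with no informative
pairs raise an error the caller must handle by exclusion; groups with fewer
than two markers are skipped with a warning during map estimation. The EM
initialization uses adjacent-pair observed fractions; with two markers the
HMM likelihood reduces to the binomial two-point likelihood, which the tests
exploit as an oracle. The simulation sizes used by the test suite (e.g.
200-replicate calibrations at n = 223 with 500-position grids and 1000
resamples) were chosen as the smallest sizes at which the binomial/Monte
Carlo error of each check is comfortably below the tolerance being
asserted.

## Known limitations

Only selfed-RIL biparental populations are supported (no F2, backcross,
dominance, or X chromosome); marker order is taken from the physical
reference rather than estimated; the multitrial model fits one trait at a
time (multi-trait mixed models are out of scope); spatial row-column models
and outlier handling are not implemented; and the physical-map scan mode
inherits the flat-peak behavior of single-marker tests in long high-LD
regions — support intervals are therefore only reported in genetic-map mode.
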