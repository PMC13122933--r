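---
title: "Methods: two-sample MR for genetic liability with mrliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for genetic liability with mrliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrliability)
library(dplyr)
```

## The model

For a binary condition, a GWAS on the case/control scale estimates per-allele
effects on the log-odds of *liability* — the latent propensity to the
condition. With instruments $j = 1, \dots, k$ (independent, genome-wide
significant variants), the two-sample MR model assumes

$$\hat\beta_{Yj} = \theta\,\beta_{Xj} + \alpha_j + \varepsilon_j,$$

where $\theta$ is the causal effect of exposure liability on the outcome
(log-odds per unit log-odds), $\alpha_j$ is a direct ("horizontally
pleiotropic") effect of the variant on the outcome, and $\varepsilon_j$ is
estimation noise with known standard error $se_{Yj}$. Valid instruments have
$\alpha_j = 0$; the estimator suite differs in what it assumes about the
$\alpha_j$:

* **IVW** pools per-instrument Wald ratios
  $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order weights
  $w_j = \hat\beta_{Xj}^2/se_{Yj}^2$ and is consistent when pleiotropy is
  absent (or balanced with mean zero and independent of instrument
  strength). Algebraically it is the zero-intercept weighted regression of
  outcome on exposure effects; the tests exploit that identity as an oracle.
* **MR-Egger** frees the intercept of that regression (after orienting all
  instruments to a positive exposure effect): the slope is consistent under
  the InSIDE assumption (pleiotropy independent of instrument strength) even
  when the mean pleiotropic effect $\mu_\alpha$ is non-zero, and the
  intercept estimates $\mu_\alpha$ — the *intercept test* for unbalanced
  pleiotropy.
* The **weighted median** of the $\hat\theta_j$ is consistent whenever
  instruments carrying at least half the total weight are valid, whatever
  the invalid ones do.

Heterogeneity between the $\hat\theta_j$ is summarised by Cochran's
$Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ on $k-1$ (IVW) or $k-2$
(Egger, as the weighted residual sum of squares) degrees of freedom.

### Random-effects inference

"Random effects" here is the multiplicative overdispersion model: the
fixed-effect standard error $(\sum_j w_j)^{-1/2}$ is inflated by
$\max\{1, \sqrt{Q/\mathrm{df}}\}$. The factor is floored at one so that
under-dispersed sets are not rewarded with spuriously tight intervals. Egger
inference uses the $t$ distribution on $k-2$ degrees of freedom; IVW and the
Wald ratio use the normal. All 95% intervals use the 1.96 quantile. The
weighted-median standard error comes from a parametric bootstrap (default
1000 draws) that redraws both effect vectors from their reported sampling
distributions; the seed is a required argument, making results exactly
reproducible.

### The per-doubling scale

A one-unit increase in log-odds of liability (an $e$-fold change in odds) is
an awkwardly large unit for rare conditions. Estimates and standard errors
are therefore multiplied by $\ln 2 \approx 0.693$, re-expressing effects per
*doubling* of liability odds, before intervals are formed
(`scale_to_doubling()`). The z-statistic, hence the p-value, is invariant.
For binary outcomes the odds-ratio surface is the exponential of the scaled
estimate; odds and risks are treated as interchangeable, which is adequate
for outcomes with prevalence of a few percent and is the convention the
selection rule below is phrased in. Effect magnitudes on the liability scale
have no direct clinical interpretation; direction and robustness are the
meaningful outputs.

## Instrument processing

**Selection.** Candidates below $p = 5\times10^{-8}$ are clumped greedily:
sort ascending by p-value (ties broken lexicographically by rsid for
determinism), accept the best remaining candidate, discard every candidate
within 10,000 kb of it on the same chromosome with $r^2 \ge 0.001$, repeat.
The LD source is a pluggable matrix; without one, same-chromosome
neighbours inside the window are conservatively treated as linked (and a
warning says so). Externally curated instrument lists can bypass selection
entirely.

**Harmonization.** Outcome rows are aligned to the exposure's effect
allele: same pair kept, swapped pair sign-flipped (and frequency
complemented), strand-complemented pairs corrected first. Palindromic
pairs (A/T, C/G) are strand-ambiguous by construction, so allele labels
carry no orientation information; orientation is inferred from allele
frequencies when both sides' minor-allele frequencies are below the
informativeness threshold (default 0.42, configurable): same side of 0.5
keeps, opposite sides flips, anything else drops the variant. All removals
are recorded dispositions, never silent; instruments absent from the
outcome dataset are recorded as `missing` — no proxy substitution is
attempted, matching the analysis design this package operationalises.

**HLA region.** chr6:28,477,797–33,448,354 (GRCh37, 1-based inclusive)
hosts dense immune genes with long-range LD and pervasive pleiotropy across
autoimmune conditions; `rerun_without_hla()` re-estimates without variants
in the window as a standard sensitivity check.

## Sensitivity analyses

* **Steiger filtering** guards against reverse causation: per variant, each
  side's association is converted to a correlation proxy
  $r = z/\sqrt{z^2 + n}$ ($z = \hat\beta/se$), and a variant is removed only
  if it explains more outcome than exposure variance *and* the Fisher-z
  two-sample comparison is significant (one-sided, default $\alpha=0.05$).
  The same proxy is used on both sides so binary exposure and binary outcome
  GWAS are compared on a common footing; the proxy is a configuration point
  should an allele-frequency-aware variant be preferred. Variants whose
  sample sizes are missing or $\le 3$ are retained and flagged unevaluable.
* **Leave-one-SNP-out** recomputes IVW dropping each instrument in turn.
  "Influential" has no canonical numeric definition, so the default flag —
  omission flips the estimate's sign or moves it by more than half its
  magnitude — is explicit configuration, and all deltas are always returned
  so users can apply their own rule.
* **Leave-one-study-out** re-meta-analyses per-study outcome GWAS
  (fixed-effect inverse variance) with each study omitted, then reruns IVW.
  Variants covered by no remaining study drop out of that replicate.
* **Fetal-genotype adjustment.** A maternal variant transmitted to the
  fetus can act on a pregnancy outcome through the fetal genome. With
  marginal maternal ($M$) and fetal ($F$) GWAS effects, the transmission
  model $M = a + b/2$, $F = b + a/2$ (direct maternal effect $a$, direct
  fetal effect $b$; the factor ½ is the transmission probability) solves to
  $a = (4M - 2F)/3$, with
  $\mathrm{var}(a) = (16\,se_M^2 + 4\,se_F^2 - 16\,\mathrm{cov}_{MF})/9$.
  The estimate covariance defaults to zero (independent samples) and is
  accepted per variant where maternal and fetal GWAS overlap. The
  coefficient set sits behind this single function so an alternative
  weighting can be swapped in.

## Triage and multiplicity

Main per-doubling IVW estimates across the condition-by-outcome grid are
selected for sensitivity follow-up when either (i) $p < 0.05$, or (ii) the
odds ratio exceeds 1.05 or falls below 0.95 with $p < 0.10$ (strict
inequalities; criterion (ii) applies to binary outcomes only). Selection on
significance alone is deliberately avoided: the outcomes are rare but
clinically important, priors from observational studies are strong, and
modest effects matter. Alongside, Benjamini–Yekutieli adjusted p-values
(valid under arbitrary dependence — conditions share risk loci and outcomes
are correlated) are reported at $\alpha = 0.05$. The FDR family defaults to
the supplied grid and can be fixed (e.g. at a 90-test
10-condition × 9-outcome grid) via `family_size`; absent tests are padded as
uninformative ($p = 1$).

Each selected result gets a robustness tier: **robust** when every
evaluable sensitivity estimate is directionally concordant with the main
estimate and no single-variant omission flips the direction, **uncertain**
otherwise. Analyses that could not run count as unevaluable, never as
discordant. The tier is advisory — published adjudications of influential
variants typically also weigh phenome-scan evidence, which is human
judgment outside this package's scope (a local annotation join is the
supported hook).

## The synthetic-data generator

`simulate_pair()` generates matched exposure/outcome summary statistics at
the summary level directly — the analysis consumes nothing else, and this
keeps full recovery grids cheap enough to run routinely. Per variant:
minor-allele frequency uniform on (0.05, 0.45); GWAS precision
$se = (2\,\mathrm{maf}(1-\mathrm{maf})\,n\,\phi(1-\phi))^{-1/2}$ for a
binary trait with case fraction $\phi$; true exposure effects drawn from a
normal with SD 0.08 and rejection-sampled until $|\gamma|/se > 5.45$, so
every instrument is genome-wide significant at the configured sample size.
The retained effect is oriented positive: the effect allele is *defined* as
the liability-increasing allele, as in curated instrument lists. This
orientation matters — with sign-symmetric true effects, Egger's internal
re-orientation would flip planted pleiotropy into symmetry and no
directional-pleiotropy signal could exist in the generated data.

Defaults describe a well-powered liability GWAS against a large binary
outcome GWAS ($n_{exp} = 2.5\times10^5$ at 10% cases,
$n_{out} = 5\times10^5$ at 5% cases), consistent with the sample-size range
of the study designs this package targets. Pleiotropy
($\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ for a configured invalid
fraction, independent of $\gamma_j$ — InSIDE holds by construction), allele
corruption (effect/other swaps with sign negation, strand flips,
palindromic allele pairs), fetal direct effects, and multi-study splits are
all off by default and switched on per experiment. The same seed always
reproduces bit-identical datasets.

What the generator does **not** emulate: LD between instruments,
winner's-curse bias in the exposure effects (the conditioning is on the
*true* effect, the idealisation of a replication-based instrument list),
sample overlap between exposure and outcome GWAS, InSIDE violations, and
individual-level covariate structure. Passing recovery tests therefore
demonstrates correctness of the estimators under their stated assumptions,
not robustness to these real-data pathologies.

## Numerical choices and degenerate inputs

* Ties in clumping are broken by rsid so output is order-invariant.
* A single retained instrument routes to the Wald ratio; zero retained
  instruments yield an absent-result marker (pipelines skip and report,
  never abort on one pair).
* Instruments with exactly zero exposure effect are excluded from IVW with
  a warning (the ratio is undefined).
* The weighted median interpolates the sorted ratios at cumulative weight
  0.5 and clamps to the extreme ratios outside the grid.
* Significance conditioning in the generator abandons after $10^6$
  proposals per variant with an error naming the cure (larger sample size
  or effect SD).
* `by_fdr()` delegates to `stats::p.adjust(method = "BY")`; its tests
  compare against a longhand step-up implementation.

## Test problem sizes

The recovery grids used by the test suite and the acceptance script were
sized so Monte-Carlo error is small relative to the tolerances while the
whole suite stays desk-scale: 150–200 replicates of $k = 100$ instruments
for bias/coverage at $\theta \in \{0, 0.1\}$, 120–150 replicates for
Egger-intercept recovery of $\mu_\alpha = 0.01$, 80 replicates of a 30%
contaminated grid for the weighted-median comparison, 400–500 simulated
90-test families for FDR control. One caveat is folded into the bias
tolerance (±0.005): with first-order weights, ratio estimators carry a
finite-sample attenuation of order $1/\bar F$, a couple of percent relative
at realistic instrument strength ($\bar F$ around 50–100). That attenuation
is a property of IVW itself, not a bug, and is why the bias band is wider
than pure Monte-Carlo error.

## Known limitations

* No proxy-variant lookup for instruments missing from the outcome data.
* No conditional/joint re-analysis of externally supplied instrument lists;
  they are taken as given.
* The Steiger correlation proxy ignores allele frequency; for binary traits
  it is a monotone transform of the z-statistic rather than a
  variance-explained estimate on the observed scale.
* Sample overlap between exposure and outcome GWAS is neither estimated nor
  corrected; leave-one-study-out is the supported probe.
* Odds/risk interchangeability is assumed for binary outcomes (no
  rare-disease correction).
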