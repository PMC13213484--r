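---
title: "Methods: morphological profiling with cellpaintr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphological profiling with cellpaintr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellpaintr)
```

This vignette documents the statistical model behind `cellpaintr`: how the
synthetic screen generator works, why its parameters default to the values
they do, how each pipeline quantity is defined numerically, and where the
approach stops being realistic.

## 1. The pipeline in one paragraph

Per-site image features are collapsed to **well medians**, replicate
plates are collapsed to one **compound-level profile** by a second median,
features that do not reproduce between two biological repeats are
discarded, each profile is expressed as a robust **Z-score fingerprint**
against the vehicle wells of the same screen, and fingerprints are
compared by clipped Pearson correlation (**biosimilarity**). An
**induction** value (percent of features with |Z| ≥ 3) gates all
comparisons: > 5% calls a compound biologically active, > 30% admits it
into cross-biosimilarity matrices. Mechanism-of-action hypotheses come
from matching a fingerprint against **cluster subprofiles** at an 85%
biosimilarity threshold.

## 2. Generative model of the simulator

`simulate_screen()` produces per-site feature tables with full ground
truth. For feature $j$ with screen-level location $\mu_j \sim N(10, 3^2)$
and scale $\sigma_j \sim \text{LogNormal}(0, 0.4^2)$, the value at plate
$p$, well $w$, site $s$ is

$$
x_{pwsj} = \mu_j + o_{pj} + \delta_{wj}\,u_j + \varepsilon_{pwsj},
\qquad \varepsilon_{pwsj} \sim N(0, (\tau\sigma_j)^2),
$$

where $o_{pj} \sim N(0, (0.2\,\sigma_j)^2)$ is an additive per-plate
offset (the batch effect that shifted layouts are designed to average
out), $\tau$ = `site_noise_sd` = 1 is the per-site noise in units of the
feature scale, and $\delta_{wj}$ is the programmed effect of the
compound in well $w$ (zero for vehicle and inert filler compounds).

**Effect-size units.** A `phenotype_signature()` states effects in units
of the *robust SD of DMSO well medians within one plate*. The median of
$n$ sites has SD $k_n \tau \sigma_j$ where $k_n$ is the Gaussian
median-of-$n$ factor, so the simulator uses the per-well shift
$u_j = \tau\, k_{n_\text{sites}}\, \sigma_j$. The factor $k_n$
(`median_sd_factor()`) is computed by exact numerical integration of the
order-statistic density for odd $n$ and by the asymptotic
$\sqrt{\pi/(2n)}$ for even $n$; $k_9 \approx 0.3596$.

This unit choice makes effect sizes commute cleanly with the pipeline:
after the second median over $m$ replicate plates, the compound-level
profile has noise $k_m$ times the well-median SD, so a programmed effect
of $e$ appears in the fingerprint as an expected Z-score of $e / k_m$
($k_3 \approx 0.6698$, hence $e = 5 \rightarrow E[Z] \approx 7.5$). The
simulator records exactly this in `truth$expected_z`. Anchoring effects
at the *well-median* level — rather than, say, the replicate-profile
level — keeps the stated effect a property of the plate, independent of
how many replicates the analyst later runs.

**Layouts.** All replicate plates share one compound assignment, cyclically
permuted by $(p-1)\,\lfloor n_\text{wells}/n_\text{plates}\rfloor$
positions, so each compound sits in a different well on every plate and
per-plate offsets cannot masquerade as compound effects. Vehicle wells
(fraction 0.1 of the plate, ≈ 38 wells at 384) carry unique pseudo-labels
so replicate matching keeps them as independent null profiles — this
matters because the MAD of the vehicle profiles is the denominator of
every Z-score.

**Cell counts.** Per-site counts are Gaussian around
`baseline_cells_per_site` = 180 with CV 0.1, multiplied by a per-compound
`toxicity` factor, feeding the relative-cell-count classes (≥ 80%
normal, 50–80% reduced, < 50% growth arrest / dead).

**Irreproducible features.** With `irreproducible_fraction` > 0, selected
features receive an extra per-(plate, well) noise of 3 $\sigma_j$,
destroying the between-repeat correlation; these exercise robust-feature
selection. For programmed correlations, `simulate_feature_repeats()`
instead constructs two repeats as shared + independent Gaussians with
shared variance $r/(1-r)$, giving expected Pearson $r$ exactly.

## 3. Numerical definitions

* **Aggregation** is the plain median (site → well, then across replicate
  plates matched by compound and concentration); medians rather than
  means limit the influence of out-of-focus or segmentation-failure
  sites.
* **Robust features**: similarity of feature $j$ is
  $\max(0, \text{cor}(m^{(1)}_{\cdot j}, m^{(2)}_{\cdot j}))$ between the
  two repeats' well-median vectors; keep if ≥ 0.8. Constant features are
  rejected and logged. Selection happens on raw medians, before any
  Z-scoring.
* **Fingerprint**: $z_j = (x_j - \text{med}_v)/(1.4826\cdot\text{MAD}_v)$
  over the vehicle profiles $v$; 1.4826 makes the MAD a consistent SD
  estimate under normality. A configuration switch (`scale_method =
  "sd"`) substitutes mean/SD. Features with zero vehicle dispersion are
  excluded and reported rather than yielding infinities.
* **Induction** = $100\,|\{j: |z_j| \ge 3\}| / n$; **activity** is the
  strict comparison induction > 5.
* **Biosimilarity** = $100 \max(0, r)$, i.e. $1 - \text{CD}$ with the
  correlation distance $\text{CD} = 1 - r$, clipped so anti-correlation
  scores 0 rather than negative. Constant profiles give `NA` with a
  warning instead of a silent 0.
* **Regions**: the canonical 579-feature robust set splits cell 1–229,
  cytoplasm 230–461, nuclei 462–579; other lengths split proportionally
  to those block sizes.
* **Subprofiles**: a cluster is the element-wise median of its members'
  Z-scores restricted to the cluster's dominant features; a query is
  assigned wherever its biosimilarity to the subprofile (on the dominant
  features) strictly exceeds 85%.
* **qPCR**: $\Delta Ct$ = Ct(target) − mean(Ct(references));
  $\Delta\Delta Ct$ is taken against the control-group mean $\Delta Ct$;
  fold change = $2^{-\Delta\Delta Ct}$. Group summaries are geometric
  (mean/SD of $\log$ fold changes), since $2^{-\Delta\Delta Ct}$ is
  log-normal under Gaussian Ct noise. Testing is one-way ANOVA on
  $\Delta Ct$ followed by Dunnett's many-to-one comparisons
  (`multcomp::glht`, multivariate-*t* adjustment); testing on the Ct
  scale, not the fold-change scale, keeps the errors approximately
  Gaussian.

## 4. Default problem sizes

The package's validation suite runs on sizes chosen to be large enough
for stable statistics and small enough for fast, deterministic tests:
1716 features / 384 wells / 9 sites / 3 plates as the headline format
(matching common practice for cell painting), scaled-down screens of
96–384 wells with 120–400 features for repeated-simulation checks, and
signature widths of 20% of the feature set with effects of ±5 robust SDs
— strong but not saturating, so recovery is a real test rather than a
formality. These sizes are the package's own validation choices, not
constraints of the implementation.

## 5. Limitations and realism

The generator is deliberately simple where simplicity does not affect
what the pipeline must get right:

* Features are **independent** Gaussians; real morphology features are
  heavily correlated in blocks. Biosimilarity values between unrelated
  real compounds therefore scatter more widely than the near-zero values
  seen here.
* Plate effects are **additive and feature-wise**; real screens show
  spatial gradients (edge effects) within plates, which layout shifting
  alone does not remove.
* Per-site noise is homoscedastic Gaussian; real features are often
  skewed or heavy-tailed — one reason the pipeline defaults to
  median/MAD everywhere.
* Cytotoxicity affects only the cell count, not the morphology features,
  whereas in reality dying cells change shape dramatically. The
  cell-count class is therefore reported alongside, never folded into,
  the fingerprint.
* The qPCR model treats amplification efficiency as exactly 2 per cycle
  for all genes; the $2^{-\Delta\Delta Ct}$ method inherits this
  assumption.

## 6. A minimal end-to-end run

```{r, eval = FALSE}
sig <- phenotype_signature("S1", 1:24, rep(c(-5, 5), 12))
cmp <- data.frame(compound = c("A1", "A2"), concentration_uM = 10,
                  signature = "S1", toxicity = 1)
scr <- simulate_screen(simulation_config(n_features = 120, n_wells = 96,
                                         signatures = list(sig),
                                         compounds = cmp, seed = 7))
run <- run_screen_pipeline(scr$tables, scr$layouts)
run$summary[run$summary$compound %in% c("A1", "A2"), ]
biosimilarity(run$fingerprints[["A1@10"]], run$fingerprints[["A2@10"]])
```

With this seed the two compounds recover ~24–25% induction (20%
programmed plus a false-positive tail), both are called active, and the
shared signature yields ~93% biosimilarity while disjoint compounds in
the same screen sit near zero.
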