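---
title: "Methods: ddPCR quantification of meat-species adulteration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ddPCR quantification of meat-species adulteration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddpcrquant)
library(dplyr)
```

This vignette is the package's account of the statistics it implements: the
Poisson partition model, the transfer-coefficient calibration that turns DNA
copy ratios into meat mass ratios, the decision rules of the validation
battery, the generative model behind the simulator, and the numerical
conventions and limitations a user should know about.

## 1. Poisson partition statistics

A ddPCR reaction is atomized into roughly 20,000 droplets of ~0.85 nL and
each droplet is read positive or negative at end point. If template
molecules land in droplets independently at rate $\lambda$ copies per
droplet, the probability a droplet stays negative is $e^{-\lambda}$, so
from $P$ positive droplets out of $N$ accepted:

$$\hat\lambda = -\ln\!\left(1 - \frac{P}{N}\right), \qquad
  \text{copies/µL} = \frac{\hat\lambda}{v \times 10^{-3}}$$

with $v$ the droplet volume in nanoliters. Three numerical conventions:

* **Saturation.** $P = N$ makes $\hat\lambda$ unbounded.
  `estimate_cpd()` raises a distinct `ddq_error_saturated` condition rather
  than returning `Inf`, so batch pipelines (`estimate_concentrations()`)
  can flag the well and keep going instead of propagating non-finite
  values.
* **Droplet volume.** $v$ is an instrument constant that the vendor
  software applies internally; published concentration tables never state
  it. The package default is 0.85 nL, the conventional partition volume for
  this instrument class, and it is configurable everywhere. Crucially, $v$
  cancels in every concentration *ratio*, so the calibrated $K$ and all
  mass fractions are independent of it.
* **Uncertainty.** `concentration_interval()` is a normal-approximation
  binomial interval on $P/N$ pushed through the $-\ln(1-\cdot)$ link and
  scaled by volume. It is a per-well reporting aid — replicate spread
  remains the primary uncertainty measure — but its empirical coverage is
  close to nominal at routine droplet counts (checked by simulation in the
  test suite: 95% ± 2 points at $\lambda = 0.1$, $N = 20{,}000$).

## 2. The transfer coefficient

Copy number is not mass. Species differ in genome size and in copies of a
single-copy nuclear gene per gram of tissue, so the copy ratio
$Q_T/Q_B$ of adulterant to beef assays mis-states the mass ratio by a
species-pair-specific factor. Writing $C_T$, $C_B$ for the (latent) copy
densities per unit mass, which are stable constants for single-copy nuclear
targets under a fixed extraction protocol:

$$\frac{M_T}{M_B} \;=\; \frac{Q_T / C_T}{Q_B / C_B}
   \;=\; \underbrace{\frac{C_B}{C_T}}_{K} \cdot \frac{Q_T}{Q_B}.$$

$K$ is calibrated from gravimetric binary mixtures with known adulterant
fraction $w$ (percent w/w): for each mixture
$K = \frac{w}{100 - w}\cdot\frac{\bar Q_B}{\bar Q_T}$, pooled by the
arithmetic mean across the series. Three conventions are fixed in
`estimate_k()` because they are the ones under which published replicate
tables reproduce their printed per-mixture and pooled values exactly:

1. **Ratio of means.** Replicate concentrations are averaged per channel
   *before* the ratio is taken (not a mean of per-replicate ratios).
2. **Round, then pool.** Per-mixture $K$ values are rounded to 2 decimals
   before the pooled mean and RSD are computed. Unrounded values are kept
   in the result (`k_raw`, `k_mean_raw`) for transparency.
3. **Sample RSD.** The spread across mixtures is reported as
   $100 \cdot s / \bar K$ with the $n-1$ standard deviation.

The pooled constant the package carries forward (`$k`) is the 2-decimal
working value — the form in which a quantification formula like
$M_{pork}/M_{beef} = 1.19 \cdot Q_{pork}/Q_{beef}$ is shipped and audited.

A calibration is only trustworthy if $K$ is composition-stable, which is
why `estimate_k()` refuses fewer than two mixtures and reports the
across-mixture RSD, and why `verify_k()` exists: it quantifies independent
check mixtures of known composition with the calibrated constant and
summarises the signed relative deviations. Deviations are reported to two
decimals (`deviation()`), matching assay-report convention; the sign is
always computed from the definition $100(m - a)/a$.

## 3. From copy ratio to mass fraction

`mass_ratio()` applies $K Q_T / Q_B$; `mass_fraction()` maps a ratio $r$ to
$100\,r/(1+r)$, the adulterant's share of total meat mass under the
**binary-mixture assumption**: the sample is adulterant plus beef and
nothing else. Every supported measurement design satisfies this; for
multi-species products the pairwise ratio is still well defined but the
fraction-of-total interpretation is not, and results should then be read as
target-to-beef ratios only.

A sample whose reference (beef) channel is empty is refused with a
dedicated condition class: with no beef background the "fraction of beef
mixture" question is ill-posed, and silently returning 100% would be
misleading. Measured-vs-declared screening (`screen_products()`) flags a
product when the measured fraction exceeds the declared one by more than a
tolerance, default 5 percentage points — deliberately conservative, since
genuine adulteration cases in market surveys exceed labels by 10–60 points,
while honest products sit within a couple of points. Labels lacking a
defined content are reported with status `"LC"` and no verdict.

## 4. The validation battery

**LOD.** The lowest level at which *all* replicates give a positive
qualitative result, where "positive" means at least one positive droplet in
the target channel of a well passing the accepted-droplet QC (default
≥ 10,000 droplets). Because a dilution series can be non-monotone by
sampling accident, `determine_lod()` additionally requires every *higher*
tested level to be fully detected ("stably detected"); the lowest level of
the fully-passing tail is returned. With no such level the LOD is undefined
and returned as `NA` with a warning, not an error — an undefined limit is a
reportable validation outcome.

**LOQ.** `determine_loq()` requires, per level and again stably over all
higher levels: 100% detection, replicate RSD ≤ 25%, *and* absolute relative
bias ≤ 25%. Precision alone is not sufficient: near the detection limit a
series can be precise yet biased high by 50–100% (few-copy wells that do
fire overstate the concentration), and an RSD-only rule would admit levels
no analyst would call quantifiable. The 25% thresholds are the standard
acceptance criteria for DNA-based food quantification methods and are both
configurable.

**Precision.** `rsd()` is the sample RSD; `repeatability_reproducibility()`
computes within-run RSDs (repeatability) and the RSD of run means per level
(reproducibility) from a tidy `level × run × replicate` table, each judged
against the ≤ 25% criterion.

**Linearity.** `fit_linearity()` regresses measured on actual mass fraction
by OLS and reports slope, intercept and $r^2$ (squared Pearson correlation,
identical to OLS $R^2$ in the simple regression and numerically quiet on an
exact fit). On noiseless pipeline output the fit is exact
($r^2 = 1$ to machine precision); at the default 5% replicate noise a
1–90% series still yields $r^2 > 0.99$ — both are asserted in the test
suite rather than claimed here.

## 5. The simulator as a testing oracle

`sim_config()` fixes a generative model with the statistical structure the
analysis assumes:

* a mixture at fraction $w$ contributes $\frac{w}{100} C_T$ copies/µL to
  the target channel and $(1 - \frac{w}{100}) C_B$ to the reference
  channel;
* each well's concentration is jittered by **lognormal multiplicative
  noise** with a configurable CV (default 5%), chosen because replicate
  spreads in real calibration tables scale with magnitude — additive noise
  would not reproduce that;
* concentration maps to copies per droplet via the droplet volume, and the
  positive count is drawn $\mathrm{Binomial}(N, 1 - e^{-\lambda})$;
* an optional multiplicative copy-retention factor emulates thermal
  degradation; by default it hits both channels equally (which is exactly
  why ratio-based quantification survives cooking), and a channel-specific
  override lets tests produce the directional drift expected when target
  and reference amplicons degrade at different rates.

Defaults are anchored so fixtures look like real data: $C_T = 300$
copies/µL per unit mass fraction and $K = 1.19$ (pork-like) put a 10%
mixture at ≈ 30 target and ≈ 320 reference copies/µL; a chicken-like run
uses $C_T = 2300$, $K = 0.38$. The anchors only set magnitudes — every
recovery property holds at any reasonable values.

Two modes matter for testing. With `sampling = "expected"` and
`replicate_cv = 0` the simulator returns each well's *expected* (possibly
fractional) positive count, making the entire pipeline a closed-form
deterministic oracle: the estimated $K$ equals the configured truth and the
recovered mass fraction equals $w$ to machine precision. With the default
stochastic mode, seeded Monte-Carlo studies quantify estimator behaviour.
The problem sizes used in the shipped studies are: 500 wells per rate for
estimator consistency (within 2% at $\lambda \in \{0.01, 0.1, 1\}$,
$N = 20{,}000$); 20 seeded calibration series (5 levels × 6 replicates) per
$K \in \{0.38, 1.19\}$ for coefficient recovery within 5%; 200 seeded runs
per composition for mass-fraction bias below 2 percentage points at 10, 50
and 90%; and 30-replicate dilution series for the droplet-count/LOD
monotonicity property.

What the simulator deliberately does **not** model: droplet-volume
variability, "rain" (intermediate-amplitude droplets) and misclassification
at the gating step, cross-channel leakage, background false positives in
blank matrices, and inhibition. Passing tests therefore demonstrate the
statistical machinery is correct under the Poisson-lognormal model, not
that a particular wet-lab assay meets its specifications — that is what the
bundled reference measurements and a lab's own validation runs are for.

## 6. Representation and rounding

Mass fractions are carried in percent end to end (`*_pct` columns),
matching how every assay table, label claim and validation criterion is
expressed; there is no internal fraction/percent conversion layer.
Full double precision is kept through all intermediate computation, and
rounding to two decimals happens only at defined reporting boundaries:
per-mixture $K$ (by the calibration convention above), `deviation()`, and
the JSON report writer. Readers never round: `read_droplet_table()`
preserves numeric fields exactly and flags — rather than drops — QC
failures, and `write_k_config()`/`read_k_config()` round-trip a calibration
with its provenance so a quantification run is auditable from its report
alone.

## 7. Known limitations

* $K$ is protocol-specific: it absorbs extraction efficiency and genome
  properties, so a coefficient calibrated under one extraction/instrument
  protocol does not transfer to another without re-verification.
* The binary-mixture assumption (Section 3) limits fraction-of-total
  reporting to two-species products.
* No correction model for thermal degradation is fitted; the package
  measures deviations under treatment (and can simulate differential copy
  loss) but does not attempt to reverse it.
* The LOD/LOQ rules operate on whatever dilution levels were tested; they
  return a *tested* level, not an interpolated limit, so the grid's
  resolution bounds the answer.
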