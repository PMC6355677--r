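---
title: "Digital biovolume and water-use-efficiency phenotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital biovolume and water-use-efficiency phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenovol)
```

## The traits

High-throughput greenhouse phenotyping platforms image every pot from three
orthogonal vantage points (two side views 90° apart and one top view) and
weigh it between irrigations. phenovol turns those two data streams into two
plant-level traits and their treatment contrasts.

**Digital Biovolume (DB).** For one plant at one time point, with
$\Sigma_{s0}$, $\Sigma_{s90}$ and $\Sigma_{top}$ the foreground pixel counts
of the three views,

$$DB = \Sigma_{s0} + \Sigma_{s90} + \log\!\left(\Sigma_{top}/3\right).$$

DB is a pixel-count proxy proportional to above-ground fresh mass. The log
term contributes at most a dozen units against side sums in the tens of
thousands, so it is numerically negligible for any grown plant; it is kept
because it is part of the published trait definition. `DBConfig()` exposes
the log base (natural or 10), the top-view divisor, and the policy for a
zero top count (pre-emergence plants): by default the log term is dropped
and the record flagged, keeping early time series finite. The **Digital
Biovolume Ratio (DBR)** is the ratio of treated to control cell-mean DB per
genotype (or arm) per day. It is computed on cell means, not paired
replicates, because the factorial design carries no replicate pairing.

**Water Use Efficiency (WUE).** Between two weighings the pot loses water to
soil evaporation and transpiration; the loss attributed to the interval
ending at weighing $i$ is the previous post-irrigation weight minus the
current pre-irrigation weight (consecutive-weighing bookkeeping, which
conserves mass under partial refills). Plant-free bare pots estimate the
evaporation component, so per-interval transpiration is
$\max(\text{loss} - \text{evaporation}, 0)$; where a trial carries no bare
pots (the wheat screen), whole-pot evapotranspiration is used instead, and
both behaviours sit behind the `mode` argument of
`cumulativeTranspiration()`. Then

$$WUE(t) = \frac{DB_t - DB_{t_0}}{\sum_{t_0}^{t} Tr},$$

in pixels per gram of water. Negative values (biovolume shrinking late in a
drought) are reported as-is. The **WUE ratio** divides stressed by control
WUE per genotype; ratios at or above 1 classify green (efficiency
maintained), below 1 red — the boundary is closed on the green side.

**Choice of the reference day $t_0$.** For the tomato trial $t_0 = 0$ DAT is
natural. For the wheat screen we use the imaging start (55 DAS) rather than
the stress-imposition day (104 DAS). The reason is numerical: under the
logistic growth model the control panel is within a few percent of its
asymptote by 104 DAS, so a stress-day reference leaves the control WUE a
near-zero, noise-dominated denominator and the drought/control ratio loses
both sign and rank stability. Anchoring at 55 DAS gives both arms a genuine
growth window; end-of-run ratios then span roughly 0.5–1 across a panel
whose stress factors span 0.5–1, and the ranking they induce matches the
simulated tolerance ordering. `t0` remains a configuration field.

## Segmentation

The upstream platform's segmentation is proprietary, so the imaging module
uses the standard greenhouse baseline: the excess-green index
$ExG = 2G - R - B$, a histogram threshold, a morphological opening
(radius-1 square structuring element by default), and removal of connected
components below 25 px. Components are *not* reduced to the largest one:
wheat canopies fragment into tillers and leaves in side view, and all
fragments above the size floor are plant.

The adaptive threshold is Otsu's criterion with *neighborhood valley
emphasis*: the between-class variance is weighted by one minus the
histogram mass within ±25 index units of the candidate threshold. Classic
Otsu drifts into the majority mode when the foreground occupies only a few
percent of the frame and noise has broadened the background — exactly the
small-seedling case — while the valley weight steers the optimum into the
empty region between modes; on a cleanly bimodal histogram the two criteria
coincide. A fixed-threshold mode is available for strict reproducibility,
and thresholds are monotone: lowering a fixed threshold never shrinks the
mask. An image whose index map is constant returns an empty mask (there is
no contrast to split on); all-foreground and all-background results are
valid, not errors.

## The synthetic-experiment generator

No raw imagery is distributed with the published trials, so validation runs
on a seeded generator that emulates their statistical structure.

**Designs.** The wheat preset is 36 single-seed-descent genotypes plus three
reference varieties × {control, drought} × 3 replicates, imaged every other
day from 55 to 147 DAS with drought imposed at 104 DAS by holding pots at
50% field capacity (controls near capacity; 1200 g pots). The tomato preset
is an untreated control plus six biostimulant arms × 5 replicates at 70%
field capacity over 22 days, with ten bare-soil pots (1800 g pots).

**Growth.** Projected area follows a logistic curve
$A(t) = K/(1+e^{-r(t - t_{mid})})$; wheat defaults $K \approx 150\,000$ px
(±15% across genotypes), $r = 0.12$/day, $t_{mid} = 70$ DAS. At stress
onset $s$ the logistic dynamics are re-initialised at the onset value $A_s$
under the stressed carrying capacity $K f$ and rate $r f$
($f$ = per-genotype treatment factor in $(0,1]$):

$$A(t) = \frac{Kf}{1 + \frac{Kf - A_s}{A_s}\, e^{-rf\,(t-s)}}, \quad t \ge s.$$

The branch is continuous at $s$, reduces exactly to the unstressed curve at
$f = 1$, and — because the panel has outgrown the stressed capacity by 104
DAS — *declines* toward $Kf$, reproducing the characteristic post-onset
divergence and decay of drought-stressed canopies. A pure amplitude-rescaled
logistic cannot decline and would let late-stressed plants overshoot their
controls, which is why the changeover is modelled as an ODE re-start rather
than a rescaling. The wheat preset's per-genotype factors are taken from
the published end-of-run drought-to-control biovolume ratios, spanning
0.52–0.97 from susceptible to tolerant; the tomato arms instead carry
growth boosts of 1.05–1.30 over the control, the strongest for prototype
2148.

**Noise.** Observation noise is mean-one multiplicative lognormal on area
(default coefficient of variation 0.05) and additive Gaussian on recorded
weights (grams; zero by default in simulations meant for exact-recovery
checks). Noise streams are keyed by (genotype, replicate) and *shared
between the control and stressed series of the same replicate*: the
stressed trajectory is the exact counterfactual of its control partner.
Replicate-to-replicate and genotype-to-genotype variation is preserved,
while treatment contrasts before stress onset are exactly zero — so
pre-stress per-day treatment F statistics are identically null rather than
merely small, and any post-onset significance is attributable to the
imposed effect. Real trials, with independent biological noise per plant,
would instead show uniformly distributed pre-stress p-values.

**Water.** Per interval the pot loses `evapRate * dt` g of evaporation plus
`transpCoeff * meanArea * dt` g of transpiration (trapezoidal area mean;
wheat default 3e-4 g/px/day, tomato 5e-4, evaporation 5 and 8 g/day);
weighings restore the target fraction of field capacity. Losses that would
push a pot below the dry-soil floor (default 40% of field capacity) are
truncated proportionally across both components and flagged, never
silently. True per-interval evaporation and transpiration are stored so the
water-budget reconstruction can be checked to rounding error.

**Rendering.** Views are drawn as a 3-px stem with 3-px leaf rectangles
branching alternately, plus a 4-row base absorbing the area residue modulo
3 — so every side-view mask holds *exactly* the requested pixel count, and,
being a union of rectangles at least 3 px thick, is invariant under the
default 3×3 opening. The top view carries 30% of the side area (erect
habit). Foreground colour jitter keeps $ExG$ in [160, 240] and backgrounds
(gray with a slight blue cast) in [−30, 0]; the ~6.5-sd valley on either
side of a σ=10 channel noise keeps per-pixel misclassification negligible,
which is what makes the clean-recovery and 2%-noisy-recovery checks
meaningful statements about the segmentation rather than about luck.
Requested areas below 30 px fall back to a compact disc (exact but not
opening-invariant; real seedlings that small also defeat morphological
cleanup). What the generator does **not** emulate: perspective, occlusion
and overlap between organs, senescent or yellowing tissue, specular pot and
carrier surfaces, illumination drift, and soil texture — so exact recovery
here bounds segmentation behaviour on rendered geometry only, not
performance on real greenhouse imagery.

## Statistics

One two-way fixed-effects ANOVA (treatment, genotype, interaction) is
fitted per imaging day, matching the day-wise reporting of the original
analyses; no repeated-measures structure is assumed because none was
reported. Only balanced layouts with ≥2 replicates per cell are accepted —
the published designs are balanced, and this sidesteps the Type I/II/III
sums-of-squares ambiguity entirely. Model fitting is delegated to `aov()`;
the test suite cross-checks the decomposition against brute-force
mean-based sums of squares.

Duncan's new multiple range test ranks arm means after a one-way ANOVA.
Critical ranges use studentized-range quantiles at Duncan's protection
level $1-(1-\alpha)^{p-1}$ for a span of $p$ means; `qtukey()`'s own
inversion can fail to converge for many means at these low levels, in which
case the quantile is obtained by bisecting `ptukey()` (tolerance 1e-6).
Letters are assigned by the standard underlining procedure — maximal
non-significant stretches of the descending means share a letter — which
makes letter groups contiguous and transitive by construction. Unequal
group sizes use the harmonic-mean n and are flagged. Linear correlation
(DB against harvested fresh weight, or against WUE) is ordinary least
squares via `lm()`, reporting the squared Pearson correlation and the
two-sided slope test; a constant response returns $r^2 = 0$ by convention.

In the generator, fresh weight is proportional to realised projected area
(default 2e-4 g/px), so the DB–fresh-weight relation is linear by
construction and its $r^2$ checks the pipeline's bookkeeping, not a
biological discovery.

## Pipeline and reproducibility

`runPipeline()` executes segment → traits → water → stats from a validated
input directory and writes CSV outputs whose header comment records the
configuration hash and seed; reruns on identical inputs are byte-identical.
Warnings (missing views, no bare pots, unequal n) are logged and never
abort; schema violations always abort with file, row and column. Every
stochastic entry point takes an integer seed, and a bundle is fully
determined by its seed and configuration.

Validation problem sizes were chosen to keep the full suite inside a few
minutes on one core: day-wise F-pattern checks run 100 seeded replicates of
an 8-genotype × 2-treatment × 3-replicate panel; ranking checks use 20
seeds of the same scale plus 20 tomato runs; segmentation checks use 100
clean and 50 noisy rendered fixtures (480² and 320² canvases). The full
39-genotype presets are exercised once end-to-end.

## Known limitations

* The segmentation baseline is a stand-in for the platform's undisclosed
  pipeline; senescent (yellow) tissue would be dropped by a greenness
  index, biasing late-season DB low on real imagery. A configurable hue
  window is future work.
* The additive printed form of the DB formula is implemented as printed; a
  multiplicative side×top construction cannot be ruled out from the
  published material, and the configuration object localises the ambiguity.
* Logistic growth cannot represent control-plant senescence, so late-season
  control decline (visible in the published panel means) is not emulated;
  consequences for the WUE reference day are discussed above.
* WUE is left in pixels per gram; no absolute biomass conversion is
  applied, so only ratios and rankings are comparable across platforms.
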