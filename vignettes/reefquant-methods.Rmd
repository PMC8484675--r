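---
title: "Methods: spike-in calibrated eDNA metabarcoding around artificial reefs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in calibrated eDNA metabarcoding around artificial reefs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefquant)
```

## The problem

Artificial reefs aggregate fish, and managers want to know which species,
how strongly, and over what spatial footprint. Metabarcoding of
environmental DNA (eDNA) filtered from seawater identifies many species at
once, but raw read counts are not comparable between samples: each library
amplifies with its own efficiency. The fix implemented here is an internal
standard: every library is spiked with the same ladder of synthetic DNA
fragments — sequences that amplify with the marker primers but match no real
fish — at known concentrations. Within a sample, reads are then proportional
to input copies, and the proportionality constant is estimated per sample.

## The calibration model

For sample $s$ with standard concentrations $x_k$ (copies/µl) and observed
standard reads $y_{sk}$, the model is a regression through the origin,

$$ y_{sk} = b_s\, x_k + \varepsilon_{sk}, \qquad
   \hat b_s = \frac{\sum_k x_k y_{sk}}{\sum_k x_k^2}, $$

the least-squares estimator with the intercept fixed at zero: a library with
no template yields no reads, so a free intercept would only absorb noise.
Fit quality is reported as the *uncentered* $R^2 = 1 - \mathrm{RSS}/\sum_k
y_{sk}^2$. The centered version can go negative when the line is forced
through the origin and does not correspond to any variance decomposition
here; the uncentered form is the standard zero-intercept convention. A fish
OTU with reads $r$ then has $\hat c = r/\hat b_s$ copies/µl of extract, and
$\hat c \cdot V_\mathrm{elution}/V_\mathrm{filtered}$ copies/ml of seawater
(defaults: 100 µl elution, 2000 ml filtered; both are sample metadata, not
constants, since the effective filtered volume is a survey choice).

Samples whose standards all read zero cannot be calibrated: they are flagged
and excluded from quantification rather than raising an error, so one failed
library does not kill a run. Calibrations with $R^2$ below a QC floor
(default 0.7, about the worst seen in practice on real runs) are marked but
retained — the floor is a report, not a filter. Field negative controls are
calibrated like any sample (they receive standards) but never quantified;
their fish reads feed a contamination metric instead (copies as a percentage
of the mean field-positive sample).

A deliberate limitation, inherited from the method itself: one slope per
sample corrects between-sample efficiency, not between-species efficiency.
Comparisons across species assume similar primer compatibility.

## OTU filtering rules

Filtering runs in a fixed order, and the pipeline enforces it:

1. **Assignment-quality filters.** Drop OTUs assigned to anything but bony
   fishes, sharks and rays; drop top-hit identity < 98.5% (the boundary is
   kept); drop alignment length ≤ 150 bp. The marker amplicon is ~172 bp, so
   genuine amplicons clear the length rule comfortably either way the
   boundary is read; ≤ 150 is used.
2. **Taxonomy collapsing.** Multi-species hits within one genus become
   "Genus spp." — unless the regional checklist holds exactly one species of
   that genus, in which case species rank is restored (the congener simply
   does not occur locally). Hits spanning genera fall back to a higher rank.
3. **Noise filter.** Within each sample, fish OTUs with reads strictly below
   0.05% of that sample's total fish reads are zeroed. The total is computed
   once, before any zeroing; because zeroing only shrinks the total and
   hence the cut, a second pass changes nothing (the filter is idempotent; an
   iterative variant exists behind a flag for sensitivity checks). Standards
   are excluded from the denominator by default — they are not biological
   signal — with an option to include them, since published totals do not
   always say. At a 100,000-read sample the cut is 50 reads: 49 is noise, 50
   survives, and singletons never survive.
4. **Contaminant removal.** Labelled taxa on a blocklist are removed
   entirely; the default names three cold-water/market species implausible
   in a warm-temperate bay and common as human food — the classic signature
   of contamination.

Zeros are retained (columns are never silently dropped) so that sample and
OTU id sets stay stable through the pipeline.

## Catch comparison

The detection rate against a set-net record excludes, in order: records
identified only above species rank; species belonging to a pair the marker
cannot separate; then, optionally, species under a biomass floor. The floor
is applied last and only changes the denominator's membership — whether a
species was detected is decided once, by name or by a covering "Genus spp."
label. An empty denominator yields a flagged, not failing, report.

## Acoustics

Echograms are time × depth grids of volume backscattering strength $S_V$
(dB re 1 m⁻¹). Cells in the bottom dead zone (deeper than 1 m above the
bottom) and under instrument/bubble masks are invalidated, never deleted.
A −70 dB threshold separates fish echo from background: valid cells below
it are set to linear zero, cells at the boundary are kept. Station summaries
are arithmetic means of *linear* $s_v = 10^{S_V/10}$ over the half-open
10-minute window starting at the sampling time. Three choices matter:

- **Zeros count.** Thresholded cells enter the mean as zero; that is the
  only way a station mean can fall below the linear threshold equivalent
  (10⁻⁷), which observed per-station minima do.
- **Linear domain.** Averaging decibels would understate patchy backscatter;
  a test asserts the two averages provably differ.
- **Depth band.** Whether the mean covers the whole water column or only the
  sampled layer's band is exposed as a parameter (`depth_band`), since
  published summaries rarely say; the default is the full valid column.

## Spatial models

Strictly positive copy-number responses use a gamma GLM with log link;
counts (OTU richness) use Poisson; responses with exact zeros use a gamma
hurdle — a binomial logit model for presence plus a gamma log-link model for
the positive magnitudes, with the joint log-likelihood the sum of the two
parts and the parameter count summed likewise (gamma shape included), so
BIC $= k\ln n - 2\ell$ holds for the composite. Coefficients come from IRLS
(`stats::glm`); the gamma shape is re-estimated by full maximum likelihood
(`MASS::gamma.shape`) because the gamma coefficient MLE does not depend on
the shape but the likelihood does, and BIC comparisons need true ML values.

The distance covariate is $\log(\mathrm{distance} + 0.1)$ in metres, natural
log, so the reef station (0 m) maps to $\log 0.1$ and anchors the intercept.
Echo intensity enters as $\log_{10}$ of linear $s_v$ by default — it spans
three orders of magnitude across stations — with a raw-linear option. Depth
layer is coded with *bottom* as the reference level, so "middle" effects are
reported. BIC selection always fits the same five hierarchical candidates
{1; cov; depth; cov+depth; cov+depth+cov:depth}; for hurdle fits the
candidates vary the gamma component while the binomial component stays
intercept-only by default (mirroring how sparse presence models are usually
reported), with a flag to mirror the gamma terms.

Station effects are tested by likelihood-ratio against chi-square with
(levels − 1) df, followed — when significant — by all-pairs contrasts on the
link scale with single-step max-|z| adjustment computed from the contrasts'
joint normal law (`mvtnorm::pmvnorm`, seeded randomized quasi-Monte-Carlo);
Holm adjustment is the deterministic fallback. The reported pseudo-$R^2$ is
the squared Pearson correlation between observed and fitted responses — a
deliberately simple definition, chosen because GLM $R^2$ conventions vary
and this one is transparent and monotone in fit quality.

## Community structure

Bray–Curtis dissimilarity is computed on the copy-number table as-is: the
concentrations are the quantity of interest, so no relative-abundance
standardisation is applied by default (a square-root option exists). A pair
of all-zero samples has an undefined ratio and is set to 0 with a warning.
NMDS minimises Kruskal stress-1 over 50 random starts (best-of), and
PERMANOVA uses free permutation of sample labels with
$p = (\#\{F^* \ge F\} + 1)/(n_\mathrm{perm} + 1)$. The two factors — reefs
vs surrounding stations, middle vs bottom layer — are tested separately as
two one-factor analyses; a two-factor run is possible but the separate tests
match how such results are conventionally reported.

One property worth noting: for *rank-based* NMDS a regular simplex (all
dissimilarities tied) is not an impossibility witness — with primary tie
treatment any equidistant layout reaches stress 0. The test suite therefore
uses a higher-dimensional point cloud with distinct distances to verify that
non-planar structure yields positive stress.

## The synthetic survey world

`generate_survey()` emulates the survey design the analysis assumes: eight
stations (a focal high-rise reef at 0 m, a second reef at 220 m, and
150/500/750 m stations on both sides), two depth layers, two replicates
(32 samples) plus one spiked field negative control — hence 33 calibrations
per run. Per species $i$ and sample $s$:

$$ \mu_{si} = \mathrm{baseline}_i \cdot
   e^{-\delta\, a_i \log(d_s + 0.1)} \cdot m_{si} \cdot
   \mathrm{lognormal}(\sigma_\mathrm{bio}), $$

with decay $\delta = 0.3$ per log-metre (the order of magnitude observed for
total fish eDNA around reefs), reef association $a_i \in \{0, 1\}$ (60% of
species associated), and a depth-preference multiplier $m_{si}$ of 2 in the
preferred layer and 0.5 in the other. Baselines are log-normal with median
0.8 copies/ml across a 40-species pool, giving mean totals of a few tens of
copies/ml — the magnitude seen in coastal surveys. Reads are Poisson,
$r_{si} \sim \mathrm{Pois}(b_s\, \mu_{si}\, V_f/V_e)$ with per-sample slopes
$b_s$ log-normal (median 15 reads per copy/µl, log-sd 0.5, matching the
strictly positive, sample-varying slopes of real calibration plots), and
standards $r_{sk} \sim \mathrm{Pois}(b_s x_k)$. Poisson-per-OTU is the
default because it keeps the standards' linearity assumption exactly true; a
multinomial option conditions on a target total (~65,000 reads, a figure
inferred from run totals since per-sample depth targets are rarely printed)
to stress compositional distortion, and a "none" option emits rounded
expected reads for exact round-trip tests. One congeneric species pair
shares a single OTU to emulate marker-indistinguishable taxa; the catch
generator keeps that pair as two species records and adds a configurable
number of genus/family-rank records, with biomass proportional to mean
density under log-normal error. Echogram cells carry fish echo with
probability 0.3 at a dB level tracking summed station density (gain 2×10⁻⁹
m⁻¹ per copy/ml, 2 dB cell noise), background at −85 dB; the resulting
station means span roughly 10⁻⁸–10⁻⁷ m⁻¹, inside the observed range.

What a green test on this world does establish: the estimators are unbiased
where they should be, the filters implement their stated rules, model
selection finds generating structures, and the whole pipeline composes.
What it does not establish: robustness to features the generator omits —
PCR chimeras and index hopping, species-specific amplification bias,
overdispersed (non-Poisson) read noise, eDNA transport between stations, and
tag-jumping contamination. Real calibration $R^2$ values (0.7–1.0) are lower
than this generator's (~0.999 at default depth) for exactly these reasons.

## Numerical choices and degenerate inputs

- Zero-intercept slope and uncentered $R^2$ are closed-form; a grid-search
  RSS oracle verifies equality to 10⁻⁶ relative.
- Gamma fits on a (near-)constant response have no finite shape MLE and stop
  with an explicit error rather than returning infinities.
- Hurdle fits with no zeros fall back to the plain gamma fit (warning); with
  no positives they stop.
- `linear_to_db(0)` returns −Inf as a sentinel; downstream averaging happens
  in the linear domain where the value is exactly 0.
- Thresholding keeps the boundary cell (−70 dB itself is fish); the noise
  filter drops the boundary read count (strictly below 0.05%); the identity
  filter keeps the boundary (98.5% itself passes). Each boundary follows the
  stated rule's inequality.
- All stochastic components (generator, NMDS restarts, PERMANOVA, contrast
  integration) take explicit seeds and are bitwise reproducible.

## Known limitations

- Between-species amplification-efficiency differences are not corrected;
  copy numbers are comparable across samples, cautiously across species.
- The hurdle binomial component defaults to intercept-only; presence
  processes with strong covariate structure need the `binom_policy = "full"`
  flag.
- PERMANOVA uses free permutations; no strata/restricted permutation for the
  paired replicate structure.
- The acoustic module summarises backscatter; it does not apportion it to
  species or convert it to absolute biomass.
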