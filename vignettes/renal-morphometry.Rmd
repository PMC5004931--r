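---
title: "Compartmental morphometry of renal fibrosis, epithelial mass and microvascularity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental morphometry of renal fibrosis, epithelial mass and microvascularity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renomorph)
```

## The measurement problem

Chronic kidney injury scars the tubulointerstitium: collagen accumulates in
the interstitium (interstitial fibrosis), tubular epithelium is lost (tubular
atrophy), and the peritubular microvasculature rarefies.  Renal biopsies are
conventionally scored in the cortex, yet much of a biopsy is medulla — outer
stripe and inner stripe of the outer medulla — and medullary scarring carries
its own information about the nephron as a whole.  This package implements an
objective, whole-slide-image style morphometry of these processes on plain
RGB region exports of stained sections, stratified by anatomic compartment,
together with the cohort-level correlation analysis used to ask whether
cortical and medullary injury move together.

Four histochemical signals are quantified:

* **Fibrosis** — the aniline-blue collagen of a Masson trichrome, and DAB
  immunohistochemistry for collagen III.
* **Basement-membrane mass** — the magenta of a periodic acid–Schiff (PAS)
  stain, confined by a narrow hue band to basement-membrane pink.
* **Epithelial cell mass (EPCM)** — the Biebrich-scarlet red of the
  trichrome, and DAB cytokeratin immunohistochemistry.
* **Microvascularity** — CD34-stained endothelium, segmented into discrete
  vessel profiles.

## Positive pixel counting in HSI space

Every classifier in the package works per pixel in hue–saturation–intensity
space.  For an 8-bit pixel $(R,G,B)$:

* intensity $I = (R+G+B)/3$ on $[0,255]$;
* saturation $S = 1 - \min(R,G,B)/I$ (0 for achromatic pixels, whose hue is
  undefined);
* hue $H \in [0,1)$ is the hexcone hue as a fraction of the color circle,
  red at 0, so 0 and 1 are identified.

A `stain_profile` holds a hue centre $h_0$, a circular tolerance $w$, a
saturation floor $s_{\min}$, three intensity thresholds splitting positives
into weak/medium/strong (strong = darkest), and a background cutoff
$I_{\max}$ above which a pixel is glass.  A pixel inside the analysis region
is

* **background** if $I > I_{\max}$ (default 240);
* **positive** if $d(H, h_0) \le w$ (circular distance, boundary inclusive),
  $S \ge s_{\min}$, and $I$ is at most the weak-bin bound;
* **negative tissue** otherwise.

Percent positivity is $100 \cdot P / (P + N)$ over positive and negative
tissue pixels; glass never enters the denominator, so positivity is a
fraction of tissue, not of the slide.  When a region contains no tissue the
value is `NA`, never silently zero.

The shipped profiles carry the panel's tuned hue parameters: trichrome blue
0.60 with the default width 0.50, PAS 0.86 with a deliberately narrow width
of 0.05 (so that only basement-membrane pink passes), trichrome red 0.96
with width 0.20, and the DAB brown chromogen at 0.10 with width 0.50 for
collagen III, cytokeratin and CD34.  Hue centres can be recalibrated from
slides with `calibrate_hue()`, a circular mean over a sampled dye region —
circular because pinks and reds straddle the hue wrap (hues 0.98 and 0.02
average to 0.00, not 0.50).

Two consequences of these conventions are worth stating plainly:

* A width of 0.5 is the maximal circular distance, so wide-band profiles
  (trichrome blue, DAB) accept *every* sufficiently saturated tissue pixel;
  their selectivity on real slides comes from the saturation floor and the
  intensity bins, and on multichrome sections the classes overlap (trichrome
  "blue" positivity includes red-stained epithelium).  This is why the
  derived statistics below, not raw positivity, carry the fibrosis signal.
* No vendor values are published for the intensity bins or the saturation
  floor.  The defaults (strong $<$ 100 $\le$ medium $<$ 175 $\le$ weak
  $\le$ 220; $s_{\min} = 0.04$) are package choices, exposed both in
  `stain_profile()` and in the YAML profile format, and every shipped result
  is conditional on them.

### The T–P fibrosis statistic

Trichrome blue counts collagen but also basement membranes and proteinaceous
casts; PAS counts basement membranes and the same casts.  The derived
statistic

$$\mathrm{T\!-\!P} = \mathrm{Tri}\% - \mathrm{PAS}\%$$

subtracts the shared signal per compartment.  It is computed as a difference
of the two compartment percentages (not a pixel-wise set difference), may
legitimately be negative, and the package preserves negative values — cohort
tables show negative minima where PAS positivity exceeds trichrome
positivity.  No cast detector is implemented; the subtraction is the cast
correction.  When a case has several cytokeratin stains, EPCM is their
arithmetic mean (`average_cytokeratin()`).

## Compartments and the digital ruler

All metrics are stratified over a pixel-aligned label raster
(`compartment_mask`) with codes for cortex, outer stripe, inner stripe,
other medulla, background, and *excluded* regions.  Exclusions are a
first-class label because glomeruli are deliberately kept out of microvessel
analysis; excluded pixels never enter any denominator.  "Medulla" is always
the union of the three medullary labels and "all" tissue the union of cortex
and medulla.  Annotations are ingested, not inferred: compartment
delineation on real slides is a manual act, and the package's job is to
honor it.  Label PNGs and polygon JSON are both accepted; polygons are
rasterized by an even–odd test on pixel centres with no anti-aliasing, so an
axis-aligned 100 × 100 px square yields exactly 10,000 labelled pixels.

Stripe widths are measured with a geometric ruler (`stripe_width()`): the
first boundary polyline is resampled every 20 px of arc length, a
perpendicular is cast at each sample from the direction of the *original*
polyline segment under it (tangents from coarsely resampled points visibly
tilt the perpendiculars on curved annotations), and the reported width is
the **median** of the sample distances, converted to millimetres.  A manual
ruler placement is a single sample; the median over many perpendiculars is a
robust version of the same act, and the per-sample spread is returned so the
choice can be audited.  Boundaries that cross each other, or that a majority
of perpendiculars miss, are rejected as geometry errors rather than
averaged over.

## Microvessel segmentation

CD34 outlines endothelium as brown rings with open lumens.  The vendor
algorithm that inspired the output schema is proprietary, so the package
uses an explicit, fully parameterised reconstruction (`detect_vessels()`):

1. chromogen-positive mask from `classify_pixels()` under the CD34 profile;
2. morphological closing with a disc (default radius 2 px) to seal small
   gaps in the ring;
3. hole filling, so lumens join their vessel profile;
4. connected components (8-connectivity);
5. an area filter, default 10–10,000 µm², to drop chromogen specks and
   confluent sheets;
6. per-component geometry: area (lumen included), crack-length perimeter,
   wall thickness, and the majority compartment label.  Components touching
   an excluded region are dropped entirely.

Vessel area includes the lumen — whole-profile areas are what mean-vessel-
area magnitudes of tens to ~200 µm² refer to.  The perimeter estimator is
the crack length (count of exposed pixel edges), which overestimates a
smooth contour by up to $4/\pi$; it is documented as such so tolerances on
annulus fixtures are meaningful.  Wall thickness is estimated from the
Euclidean distance transform of the wall mask: for a digitized strip of
width $w$ the mean distance to background is $(w+2)/4$, so the package
reports the calibrated $4(\bar d - \tfrac12)$, exact for straight even-width
walls, within ~10% for thin odd widths, and mildly biased by ring curvature.
(The naive $2\bar d$ under-reports a strip's width by roughly half and was
rejected on that ground.)

Region statistics (`microvessel_stats()`) define microvessel density as
vessels per µm² of the compartment's analysable tissue area — exclusions
subtracted — so `mvd = n / area` holds to machine precision, and doubling
the µm/px doubles perimeters and quadruples areas on the same raster.

## Cohort statistics

`summarize_cohort()` reports per-metric N, mean, sample SD ($n-1$), min and
max, dropping missing values per column: real biopsy panels have very
heterogeneous per-metric Ns (a stain applied to a third of cases is normal),
and that is also why `pearson_matrix()` uses **pairwise-complete** deletion
— listwise deletion would discard most of such a cohort.  Each pair gets a
Pearson r, a two-sided t-test P ($t = r\sqrt{(n-2)/(1-r^2)}$), and its
complete-case n; pairs below three complete cases or with a constant member
are `NA` and flagged.  Raw P values are reported by default, matching common
practice for exploratory correlation panels; Benjamini–Hochberg adjustment
is available but off by default.

Correlations are verbalised with the conventional bands on $|r|$: 0.90–1.0
"very high", 0.70–0.90 "high", 0.50–0.70 "moderate", 0.30–0.50 "low",
0.00–0.30 "negligible".  The published band endpoints overlap, which forces
a tie rule: boundaries belong to the upper band (0.70 is "high").  The sign
is reported separately from the band.

For the clustered colour map, variables are ordered by average-linkage
agglomerative clustering on the dissimilarity $d = 1 - r$.  The distance is
$1-r$, not $1-|r|$: the display groups measures that rise together, and an
anti-correlated pair (EPCM against fibrosis, say) should land far apart, not
adjacent.  No published linkage or distance exists for the display this
emulates, so the exact leaf order is a package convention, not a
reproduction.  `rank_compartment_correlations()` builds the cortex-versus-
medulla ranking table from named column pairs, sorted by descending r and
grouped by band.

## The synthetic verification substrate

No biopsy images or per-case tables are deposited with the study this
package operationalises, so its verification surface is synthetic and
ground-truth-exact.

`render_tissue()` draws a rectangular region export: cortical band over
outer- and inner-stripe bands (defaults 127 / 56 / 97 px at 1 µm/px, a
45.4% / 54.6% cortex/medulla split matching the cohort-mean tissue
composition of native biopsies with medulla), a glass margin, excluded
glomerular discs in the cortex, tubule profiles (pink basement-membrane
rings around red epithelium), and DAB vessel annuli with open lumens, placed
by rejection sampling with a separation halo wider than the closing radius
so vessels cannot merge.  Each compartment is then topped up with scattered
single pixels per stain class to hit `round(fraction × tissue px)` exactly;
infeasible targets abort before rendering.  Nothing is anti-aliased —
realism is deliberately sacrificed so that every class count is exact and
recovery tests can demand equality rather than tolerance.  An optional hue
jitter (SD in hue fraction) exists for robustness experiments and voids the
exactness contract when switched on.

The palette holds one exact RGB triplet per class, derived by inverting the
hexcone hue formula so each triplet's hue lands exactly on its profile
centre (e.g. (40, 104, 200) has hue 0.60).  Ground truth stores the exact
recount of the emitted rasters *and* the expected classifier output per
shipped profile, obtained by classifying the palette colours under the same
per-pixel rule — so overlap between wide-band profiles is part of the
ground truth, not an error source.  Because a real slide carries one stain,
the renderer also emits a CD34-style view in which only vessel rings are
stained; vessel detection is validated on that view, while the all-class
panel raster validates the positive-pixel counts.

What the generator does **not** emulate: anti-aliased edges, stain
batch-to-batch variation, out-of-focus regions, proteinaceous casts,
interstitial CD34 staining, and anatomy more realistic than banded
compartments.  Tests passing on these fixtures therefore certify the
*computational* contract (counting, geometry, statistics), not performance
on real histology.

`simulate_cohort()` draws per-case metric vectors from a multivariate
normal: paired cortical/medullary measures with means and SDs taken from the
67-case panel summary (e.g. cortical trichrome 31.7 ± 10.3%, medullary
47.0 ± 12.0%), cortex/medulla correlation per measure from the published
ranking (trichrome 0.68, cytokeratin 0.85, PAS 0.87, …), independence
across measures — which makes the target correlation matrix block-diagonal
and provably positive semi-definite — then clips to each metric's domain
and applies per-metric missingness matching the panel's Ns.  Clipping
biases metrics whose mean sits within ~2 SD of a domain edge (microvessel
density, collagen III, the visual scores), attenuating their recovered
correlations by up to ~0.02 at $n = 10{,}000$; parameter-recovery tests
therefore assert elementwise recovery on interior-mean metrics and
order-recovery only for target pairs separated beyond the sampling scale.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run, by choice, at desk scale:
rendered fixtures of roughly 270 × 290 px (400 × 380 for dense vessel
fields), 8–20 seeded renders per property, 3–30 vessels per field, cohorts
of $n = 10{,}000$ for correlation recovery and a few hundred for
missingness bookkeeping.  These sizes put Monte-Carlo noise well inside the
asserted tolerances (Fisher-z SD at $n = 10{,}000$ is about 0.005 for the
targets used) while keeping a full run in tens of seconds.

Other numerical conventions, collected in one place: raster coordinates are
row-major with pixel-centre semantics and 0-based centres at half-integers;
masks must be pixel-aligned to images; boundary pixels at exactly the hue
tolerance or an intensity threshold follow the inclusive rules stated above;
the circular mean maps the float artefact $-\varepsilon \bmod 1 = 1.0$ back
to 0; undefined quantities (empty compartments, constant columns,
no-qualifying-pixel calibrations) are `NA` or errors, never silent zeros;
and every seeded operation is bit-reproducible given its seed.

## Known limitations

* The classifier is a hue gate, not stain unmixing; co-localised dyes and
  counterstain bleed-through are folded into the class a pixel's hue lands
  in.  Colour deconvolution is out of scope by design.
* Wide-band profiles are not hue-selective at all (see above); on
  multichrome material the raw positivity of such profiles must be read as
  "saturated tissue", and the derived statistics used instead.
* The ruler measures width between *annotated* boundaries; it does not find
  the corticomedullary junction.
* The vessel pipeline is a reconstruction, not the proprietary original;
  its parameters are exposed precisely because no reference values exist.
* The cohort generator's independence-across-measures default is a
  deliberately minimal correlation structure: it reproduces the paired
  cortex/medulla correlations it is told, and nothing else, so cross-measure
  correlations in simulated cohorts hover near zero.
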