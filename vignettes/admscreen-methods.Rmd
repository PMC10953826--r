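---
title: "Methods: morphology-based ADM screening analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphology-based ADM screening analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay this package models

Pancreatic acinar cells exposed to oncogenic stress transdifferentiate into
duct-like cells (acinar-to-ductal metaplasia, ADM), one of the earliest
events on the road to pancreatic ductal adenocarcinoma. In a 3D organoid
culture, this transition is visible as a morphology switch: compact,
berry-like *acinar clusters* become ring-shaped, lumen-bearing *duct-like*
organoids. A phenotypic drug screen can therefore read compound activity
straight off well images: a compound that blocks ADM (inhibition mode, on
wild-type organoids) or reverts formed ducts (reversal mode, on organoids
that have already undergone ADM) raises the fraction of acinar clusters
among live objects relative to the DMSO vehicle.

`admscreen` implements the full analysis chain for such a screen:

1. **simulation** of every input (compound library with designed
   ground-truth effects, object-level well truth, rendered two-channel
   images, qPCR CT tables, DE tables),
2. **imaging**: segmentation, shape features, duct/cluster classification,
   calcein-style viability scoring,
3. **screen statistics**: per-well summaries, Welch tests against vehicle,
   Z'-factor QC, three-criterion hit selection,
4. **dose-response**: 4PL fitting with IC50 reporting, and
5. **molecular endpoints**: 2^-ddCT fold changes, the ADM Reversal Index
   (ADMRI) and volcano-style panel annotation.

# Readouts and statistics

**Well summary.** For each well, the percent of live objects that are ducts
and clusters (these sum to 100 by construction — morphology is strictly
binary here), the percent of *all* objects that are clusters (viable plus
nonviable), and the viability fraction. Wells with no live objects cannot
define the live percentages and are flagged and excluded from group means
with a warning, never imputed.

**Hit selection.** A compound (tested at 1 uM, quadruplicate wells) is a
hit when all three gates pass:

* *criterion i* — higher mean percent live clusters than vehicle, with a
  two-tailed Welch t-test p <= 0.05, direction-gated (significance is only
  declared when the treated mean exceeds the vehicle mean);
* *criterion ii* — the same on percent total clusters of all objects;
* *criterion iii* — at most 50% cytotoxicity, operationalized within-well
  as mean viability fraction >= 0.5. A vehicle-relative viability column is
  reported alongside as a diagnostic only.

P-values are deliberately raw: the screen it reproduces used unadjusted
p <= 0.05 across 144 compounds, and the direction-gated two-tailed test
implies a per-compound null pass rate of about 2.5%. An optional
Benjamini–Hochberg flag (`bhCorrect`) is available but off by default,
as a faithful-reproduction choice. Whether criterion ii should use percent
of all objects or raw counts is not derivable from the assay description;
percent-of-all-objects was chosen (it is plate-density invariant) and the
column naming makes this explicit.

**Plate QC.** The Z'-factor
$Z' = 1 - 3(\sigma_{pos}+\sigma_{neg})/|\mu_{pos}-\mu_{neg}|$ is computed
from vehicle wells and a TSA-like positive control. Note that with
quadruplicate control wells the *sample* SDs are noisy: single-plate Z'
values scatter around their design value with an SD near 0.1, exactly as in
real screening practice, so individual simulated plates occasionally fall
below the 0.5 screen-quality bound even though the assay design sits near
0.6.

# The synthetic-data generator

The generator *is* the study-condition definition, not a tuning knob. Its
defaults:

| parameter | default | unit | rationale |
|---|---|---|---|
| objects per well | Poisson(50) | organoids | seeding density of the modeled assay |
| vehicle % clusters, inhibition | 10 | % | untreated wild-type organoids mostly complete ADM |
| vehicle % clusters, reversal | 5 | % | ducts already formed before treatment |
| replicate SD of % clusters | 3 | points | plate-to-plate technical noise |
| wells per group | 4 | wells | quadruplicate technical replicates, incl. n = 4 vehicle |
| positive-control shift | +80 | points | positive control defined as acting on >80% of organoids |
| qPCR technical noise | 0.15 | cycles | typical replicate CT scatter |
| per-sample CT offset SD | 0.3 | cycles | loading differences; cancels in delta-CT |

Well-level percent-cluster noise is drawn from a Beta distribution with
mean equal to the designed expectation, so boundary designs (e.g. an
expected 100% clusters) are honored exactly without clamping bias; the
object classes are then Bernoulli draws, adding the binomial component
(about 4 points at 50 objects/well) that dominates well-to-well spread.

Designed compound effects are parameterized directly on the readout scale
(percentage points of % live clusters) rather than mechanistically, which
makes recovery testable by construction. Effect sizes follow a power rule:
every designed effect is sized to Cohen's d >= 4 *given that compound's
cytotoxicity* — cytotoxic compounds retain only ~15 live objects per well,
inflating the readout SD to ~13 points, so their designed shifts are +55 to
+60 points while the non-cytotoxic hits use +50 to +60 over a 10-point
baseline. Likewise the four cytotoxicity-excluded compounds carry dead
fractions of 0.65–0.70, placing them >= 4 SDs beyond the 50% viability
floor. With these choices the designed screen structure (6 significant in
inhibition, 4 cytotoxicity-excluded, 2 hits; 2 reversal hits) is recovered
with power ~ 1, while null compounds pass criterion i at <= 2.5%.

Rendering draws ducts as annuli (lumen radius 0.5 x outer radius, outer
radius ~13 px) and clusters as unions of seven lobes around a core disk
(~9 px envelope), placed one per cell of a shuffled 56-px grid so rendered
objects never merge; images are 16-bit, two channels (morphology, green
viability), with Gaussian blur (sigma 1 px) and read noise (SD 40 counts).
Only live objects carry green signal.

**What the generator does not emulate:** real brightfield optics and
Matrigel texture, touching/overlapping organoids, the cyst-like morphology
seen in Kras-mutant organoids (scored manually in the modeled assay, and
explicitly out of scope here), field-of-view stitching artifacts (wells are
single stitched frames), plate-edge effects, and amplification-efficiency
deviations in qPCR. Passing tests therefore demonstrate correctness of the
*analysis* under a faithful noise model, not segmentation robustness on
real micrographs.

# Imaging choices

Segmentation is Otsu thresholding after Gaussian smoothing, connected
components, small-object removal (>= 50 px^2 kept) and small-hole filling
(<= 25 px^2; duct lumens are far larger and survive). There is no
declumping/watershed — touching objects stay merged, a documented
limitation consistent with the rendering guarantee that objects do not
touch. Coordinates are 0-based, row-major, origin top-left; thresholds
apply as >=.

Features follow the CellProfiler conventions: area, perimeter, form factor
$4\pi A/P^2$, solidity, eccentricity, plus a `lumen_ratio`
$(A_{filled}-A)/A_{filled}$ that directly encodes "has a lumen". The
perimeter uses the crack-length estimator with the $\pi/4$ isotropic
correction — the raw boundary-pixel count underestimates smooth perimeters
enough to push a disk's form factor to ~1.26, while the corrected estimator
is exact for disks (form factor 0.97 for a radius-30 raster disk).
Solidity is area over convex-hull area (hull of pixel centers, shoelace
formula), clamped to 1 against discretization.

Classification defaults to a transparent rule — duct iff
`lumen_ratio >= 0.08`, or large (`area >= 380 px^2`) and non-solid
(`solidity <= 0.85`) — because rendered annuli and berry clusters separate
almost perfectly on the lumen feature alone; an rpart tree trained on
synthetic labeled objects is available for parity with
machine-learning-classifier workflows. Viability is binary per object: live
iff >= 50% of its pixels exceed a green cut of 2000 counts (between the
rendered green background of 200 and live signal of 8000).

# Dose-response fitting

The 4PL model $y = bottom + (top-bottom)/(1+(x/IC_{50})^{hill})$ is fit by
unweighted least squares (Levenberg–Marquardt on a log-IC50
parameterization), with multi-start initialization over a 7-point log-grid
of IC50 values spanning the dose range crossed with slopes
{±0.5, ±1, ±2}; the lowest-RSS candidate wins, making the fit invariant to
input order and equivariant under dose-unit changes. Hill slopes are
bounded to magnitude [0.1, 10]; fits ending on a bound, outside a 10^4-fold
extrapolation window, or on flat data are flagged `converged = FALSE`
(flat data short-circuit to an intercept-only fallback). Fits are
canonicalized to `bottom <= top` using the exact symmetry
$(top, bottom, hill) \to (bottom, top, -hill)$.

The default dilution factor is 3.162 (half-log): a "3-fold" series from
10 uM cannot land on 32 nM in five steps (3^5 = 243-fold vs the ~312-fold
span), so the half-log factor honors both stated endpoints; factor 3 is one
argument away. For the low-nanomolar IC50 recovery study (16 nM), doses are
a relevant range topping at 1 uM so the series brackets the IC50 — screens
validate each compound over "a relevant concentration range", and a
32 nM–10 uM series would leave a 16 nM IC50 below its lowest dose.

# Molecular endpoints

Fold changes use the standard 2^-ddCT presentation: per sample
$\Delta CT = CT_{gene} - CT_{18S}$; per gene
$\Delta\Delta CT = \overline{\Delta CT}_{treated} -
\overline{\Delta CT}_{vehicle}$; $FC = 2^{-\Delta\Delta CT}$. Averaging
delta-CTs before exponentiation is the default (the conventional
presentation); per-replicate averaging of linear fold changes is available
behind `perReplicate`. Per-sample loading offsets cancel exactly in the
within-sample delta-CT, a property the generator reproduces and the tests
assert.

The ADM Reversal Index is
$\mathrm{ADMRI} = \overline{FC}_{acinar} / \overline{FC}_{ductal}$ with
acinar genes (Amy2a, Cela1, Cpa2) and ductal genes (Krt19, Krt7, Sox9) —
arithmetic means on the linear scale, all six genes required (missing genes
are an error, never silently dropped). "Cela" appears in some write-ups
where the canonical mouse symbol is *Cela1*; the canonical symbol is used
throughout. Note the index is driven by both directions at once: a large
denominator drop can dominate the ratio without any acinar re-expression,
so the per-gene means are always reported beside it. Ranking within a dose
group is dense and descending, ties broken lexicographically by compound
id. The index is timepoint-agnostic: it ranks whatever fold-change table it
is given.

The packaged volcano panel keeps the documented sizes (27 acinar, 23
ductal/PDAC, including the six qPCR genes); beyond those six the symbols
are representative and user-replaceable — the sizes are contractual, the
identities are not published. Significance cut-offs for annotation are
linear |FC| > 1.5 (two-sided) and FDR < 0.05.

# Reproducibility and problem sizes

Every stochastic function takes an explicit seed and restores the caller's
RNG state. A run-level seed expands to per-well substreams via
`wellSeed(seed, index) = (seed + 1000003 * index) mod (2^31 - 1)`, so
extending a layout never perturbs existing wells. Table writers format
numerics to 6 significant digits, making identical runs byte-identical.

The shipped studies use desk-scale sizes chosen to keep every check
decisive at interactive runtimes: full screens of 144 compounds x 4 wells
(plus controls) at object level; 20 rendered 512 x 512 wells for the
imaging round-trip; 200 replicate simulations for error-control, power and
IC50-recovery studies; 1000 replicates for Monte-Carlo mean-recovery
checks.

# Known limitations

* Binary morphology only; no third (cyst-like) class.
* No declumping; accuracy contracts hold for non-touching objects.
* No plate-effect or edge-effect normalization, no robust (B-score) variants.
* qPCR model assumes perfect amplification efficiency.
* DE tables are simulated at the summary level (log2FC + FDR), not from
  read counts.
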