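---
title: "Methods: high-resolution retinal thickness phenotyping and spatial multi-omics association"
author: "retinagrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retinal thickness phenotyping and association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`retinagrid` implements a desk-scale pipeline for spatially resolved
analysis of macular retinal thickness (RT) from optical coherence
tomography (OCT), together with the mass-association machinery needed to
relate a fine pixel grid of thickness phenotypes to genetic variants,
metabolites, blood traits, disease codes and genetic scores. RT here is
the distance between the inner limiting membrane (ILM) and the retinal
pigment epithelium (RPE), measured in axial pixels (about 3.5 um per
pixel on the emulated device). The macular geometry the package assumes
throughout is the canonical one: thickness peaks in a perifoveal ring and
dips to its minimum at the central foveal pit.

Because the motivating data (population-biobank OCT volumes, genotypes
and phenomes) are access-controlled, every input is produced by a
first-class synthetic-data generator with recorded ground truth. The
generator is not a test fixture: it defines the study conditions under
which the pipeline's statistical behaviour is demonstrated, and all
parameter-recovery and calibration results in the test suite refer to
those conditions.

## Pipeline stages and their models

### Boundary segmentation

`track_boundaries()` recovers the ILM and RPE on each B-scan as
minimum-cost left-to-right paths over the bright bands. The per-cell cost
is `max(intensity) - intensity` plus a step penalty of 0.1 x the
intensity range per row of vertical movement, with the row jump per
column bounded at 3. The path problem is solved exactly by dynamic
programming; an exhaustive path-enumeration oracle in the test suite
confirms exactness on small images. The ILM is searched first with a
small depth bias (1% of the intensity range per row index) that prefers
the upper of two equally bright bands; the RPE is then searched strictly
below the ILM. Because costs and penalties are all proportional to the
intensity range, the tracked boundaries are invariant to affine
rescalings of image intensity.

The smoothness constraint that makes the path robust to noise also makes
it blind to genuine single-location band displacements, so a per-column
snap-to-peak refinement (window 45 axial px, bounded away from the other
boundary) follows the path stage. This mimics the behaviour of
segmentation methods that localise each boundary column-wise, and it is
what makes spikes and wobble visible to quality control. The refinement
can be disabled (`snap = 0`), which is how the oracle-equality tests run.

### Location quality control

`qc_locations()` applies six per-location criteria; a location's
thickness survives only if all six pass:

1. whole-B-scan faintness — the mean of per-column peak intensities must
   reach a threshold;
2. local faintness — the column's own peak intensity must reach it;
3. thickness range — 30 to 165 axial px (105-577.5 um at 3.5 um/px);
4. cut-off — the boundary must not sit within 2 px of a faint region or
   the image edge;
5. discontinuity — no boundary row jump above 10 px between neighbouring
   locations;
6. local disturbance — the SD of the 10-location window enclosing the
   location (5 left, 4 right, self; truncated at edges) must not exceed
   20 px (70 um).

Faintness thresholds are expressed as a fraction (default 0.15) of the
volume's 99th intensity percentile, which keeps them invariant to global
intensity scaling. The faintness statistic is the per-column peak rather
than the mean because OCT background is dark: the presence of a bright
band, not the average brightness, is what distinguishes a usable A-scan.

A note on criterion 6: a solitary spike of +40 px in a 10-location
window shifts the window SD to `sqrt(40^2/10) = 12.6` px, below the
20 px limit — single spikes are criterion-5 events. Criterion 6 responds
to disturbances that are both large and extended (for example +-25 px
wobble across a run of locations), and that is how its sensitivity is
exercised. Sensitivity is assessed per injected artifact instance: an
artifact counts as detected when its targeted criterion fires somewhere
in the affected span, since windows straddling the edge of a disturbed
run are diluted by design.

`accept_training_mask()` reproduces the acceptance rule used when
auto-generated segmentations are screened as training material: mean
thickness in [30, 80] px and SD at most 10 px, all bounds inclusive.

### Fovea alignment and grid construction

The fovea is located as the centroid of the k = 25 thinnest observed
pixels ("centre of the thinnest area" rather than a single argmin, which
is noise-sensitive); ties at the k-th value break lexicographically by
(row, col) so detection is deterministic. Left-eye grids are
column-mirrored before detection so that left/right rounding is
identical, then every grid is translated — integer shifts only, no
resampling, so measured values are never interpolated — to put the fovea
at the central grid index. Cells shifted in from outside the scan are
missing. The choice of the grid centre as the common reference, and
missing fill for out-of-frame cells, is ours; any fixed reference would
do, and the centre maximises retained overlap for approximately centred
scans.

Grid trimming is two-stage: pixels missing in more than 10% of scans are
removed, then whole rows or columns in which more than 50% of pixels
were removed in stage 1. Scan selection excludes scans with more than
10% missingness on the trimmed grid or missing refractive error, keeps
the lowest-missingness scan per eye and instance (seeded random
tie-break), prefers the instance with both eyes and the fewest total
missing pixels, and otherwise takes the single best eye.

Remaining holes in each selected scan are imputed with the model
`Z = b0 + f(x, y) + e`, where `f` is a penalized tensor-product spline
with 12 x 12 marginal bases, fitted to the observed pixels of that scan
(fast REML smoothing via `mgcv::bam`); missing pixels take fitted
values, observed pixels are untouched. Imputation assumes missingness at
random; the fraction imputed per pixel is available from the missingness
masks for sensitivity checks. Finally, left and right imputed scans are
averaged per pixel where both exist, and individuals are dropped if any
final pixel lies below 30 or above 150 px or the scan-wise SD exceeds 15
px (strict inequalities).

### Functional principal component analysis

`fit_fpca()` represents each centred surface in the same 12 x 12
tensor-product basis (mean surface estimated by a penalized smooth of
the pixel means; individual surfaces by least squares in the basis,
which for 144 basis functions against ~2,000 pixels is already a strong
smoother) and eigen-decomposes the coefficient covariance in the metric
induced by grid quadrature. Quadrature weights are relative pixel areas
normalised to sum to one — for the uniform grids used here, `1/npix` —
so that eigenfunctions have RMS 1 over the grid, scores carry
axial-pixel units, and "variance explained" refers to the mean per-pixel
variance. Eigenfunction signs are fixed so the largest-magnitude loading
is positive. The default of 100 components is truncated to the basis
rank with a warning; the number of components retained downstream is the
smallest reaching 95% cumulative variance.

Because the basis has 144 dimensions while the grid has thousands of
pixels, eigenvalues estimated through the basis carry a small smoothing
bias relative to the raw pixel covariance; the test suite bounds this at
2% on a grid small enough for the direct decomposition.

### Mass association engine

For a factor of interest, `design_spec()` builds one model matrix: the
factor and all quantitative covariates (age, age squared, height,
spherical equivalent, 10 ancestry PCs) standardised to mean 0, SD 1 —
which also defuses the age/age-squared collinearity — plus sex, device
and eye code (left/right/mean) as categoricals. Rows with any missing
design value are dropped and counted. `fit_mass_linear()` then fits
every pixel by OLS through a single shared QR decomposition.

`moderate_variances()` implements empirical-Bayes variance moderation:
residual variances are modelled as draws from a scaled inverse-chi-square
prior whose hyperparameters (prior df `d0`, prior variance `s0^2`) are
estimated by matching the first two moments of `log s^2` through the
digamma/trigamma equations; each pixel's variance is shrunk to
`(d0 s0^2 + d s^2)/(d0 + d)` and the t-statistic gets `d + d0` degrees
of freedom. When the log-variances show no excess dispersion the prior
df is infinite (full pooling); when they are exactly constant the
shrunken variances equal the observed ones. The implementation is checked
against the reference empirical-Bayes implementation in `limma` to
6 decimal places, and recovers planted (d0, s0^2) within 10% from 20,000
simulated variances. Moderation is fitted per factor across pixels — one
engine run per factor — not across factors.

Three multiple-testing schemes are always available: global Bonferroni,
global Benjamini-Hochberg (the default reporting scheme), and BH across
pixels within each factor. Per-factor summaries are the number of
significant pixels, mean beta over significant pixels (missing when there
are none), mean beta over all pixels, and the median -log10 p. The
factor x age interaction scan reports the proportion of significant
interactions whose sign matches the main effect. FPC associations run
the same engine with scores as outcomes at a more lenient 1% FDR; with
fewer than 10 components there is nothing to pool across, so the
ordinary t is reported there.

### GWAS and loci consolidation

`gwas_scan()` residualises the phenotype matrix and dosage matrix on the
covariates once and computes every (SNP, phenotype) slope, SE and p-value
from the residual cross-products — algebraically identical to the joint
regression (Frisch-Waugh-Lovell), verified against `lm` at 1e-10.
Chromosome X uses hemizygous males coded as homozygous (dosage 0/2),
which the generator produces and the scan consumes unchanged.
Monomorphic SNPs are skipped and logged.

Clumping follows the permissive membership semantics: every SNP with
p < 5e-8 indexes a clump containing all SNPs with p < 5e-5, r^2 > 0.001
with the index, and within 5,000 kb; SNPs may belong to several clumps.
The r^2 bound is deliberately read literally — it is unusually low and
acts as a near-distance filter rather than an LD filter.

`consolidate_loci()` iterates: take the most significant remaining
(SNP, phenotype) pair (ties broken by p, chromosome, position, phenotype
— reproducibility demands a total order); if the SNP indexes a clump for
that phenotype, found a locus with the full clump membership as
supporting SNPs, allocate every phenotype nominally associated
(p < 5e-5) with any locus SNP, and remove the (locus SNP x allocated
phenotype) pairs; otherwise the SNP must be a member of a clump whose
index already founded a locus — anything else is a hard error signalling
inconsistent clump bookkeeping — and that clump's remaining pairs for
the current phenotype are removed. Iteration runs at the conventional
5e-8; reporting applies the per-arm Bonferroni threshold (5e-8 divided
by the number of pixels or FPCs in use) to the sentinel, after removing
loci with fewer than 5 assigned SNPs. Where the loop's prose admits two
readings (what exactly is removed on allocation; whether supporting SNPs
are the full clump or only still-live pairs) we chose the reading stated
above, and an independently coded implementation of the same reading
must agree exactly on randomized instances in the test suite. Iterating
at 5e-8 and filtering afterwards (rather than iterating at the Bonferroni
threshold) is the default; the alternative only reallocates
sub-threshold pairs and is available by setting `p_iter`.

Secondary signals are found by exact conditional OLS on individual-level
data: the scan is refit for the locus's top phenotype with the sentinel
dosage as a covariate, and locus SNPs meeting the arm threshold
conditionally are secondary (candidates with r^2 > 0.99 to the sentinel
are skipped). Summary-statistics-based stepwise selection is unnecessary
when individual-level data exist, as they do for every synthetic cohort.

### Spatial summaries

Pixel over-representation analysis treats the pixel-factor significance
grid as a sampling problem: with N = pixels x factors pairs, K of them
significant, each pixel holds n = #factors pairs of which k are
significant, and the upper hypergeometric tail of k is the pixel's
enrichment p-value (BH across pixels). The set phrasing this formalises
is terse, so the parameterisation is documented as an interpretation; a
binomial-tail alternative is available by flag, and exact enumeration
validates the hypergeometric tail on small instances. Display smoothing
uses local quadratic (loess) regression over the grid with span 0.3 —
display-only, never inferential. Hierarchical clustering of factors or
pixels uses correlation distance with average linkage; the cluster count
is a configuration choice. ETDRS sectors are assigned from physical
distances: central subfield (1 mm diameter), inner ring (1-3 mm), outer
ring (3-6 mm), quadrants split by the +-45 degree diagonals, with top =
superior and right = nasal (right-eye orientation; all writers emit this
orientation).

### Phenome preparation

Blood traits are log- (counts) or logit- (proportions, clipped to
(1e-6, 1-1e-6)) transformed; a technical model (cubic smooth in
acquisition time with 8 knots, plus instrument, route and day
categoricals) is fitted on measurements within 3.5 MAD of the median,
all values are adjusted by the predicted technical effect, and outliers
beyond 6 MAD of the adjusted trait are excluded. MAD-based rules make
the exclusion set invariant to affine rescaling of the raw trait. The
four systemic inflammation indices are NLR = N/L, PLR = P/L, LMR = L/M,
SII = N x P / L.

Metabolites are square-root transformed for symmetry. Missing values are
filled by a deliberately simple chained conditional-mean imputer — each
incomplete metabolite regressed on the others, a few sweeps, five
seeded noise-perturbed repeats averaged — which keeps the multiple-
imputation flavour (five averaged imputations) without the full MICE
machinery, which would be out of proportion for synthetic data that is
usually complete. Derived ratios are recomputed on the raw scale and
then square-root transformed (our documented choice; the alternative of
recomputation on the transformed scale changes only the ratio's
labelling). Genetic scores are weighted dosage sums with allele-aware
flipping (2 - d when the effect allele is the reference), unmatched SNPs
dropped with a warning, and metabolic scores rejected below 3 matched
SNPs. PheCode mapping binarises ICD records through a map table;
multiple ICD codes mapping to one PheCode still give a single 1.

## The synthetic-data generator

`generate_cohort()` composes, per individual and eye:

* the deterministic macular surface — baseline 65 axial px (~228 um),
  foveal pit depth 22 px with lateral SD 400 um, perifoveal ring height
  6 px at radius 1,800 um with SD 700 um — values chosen to sit inside
  the typical adult thickness range with a pit minimum near 150 um;
* six orthonormal eigenmodes of individual variation (perifoveal ring,
  two tilts, parafoveal annulus, foveal disc, saddle) with score SDs
  `sqrt(10, 6, 4, 2, 1, 0.5)` px. Modes are projected into the 12 x 12
  tensor-spline span before orthonormalisation so that the FPCA basis
  can represent them exactly, and the annulus/disc widths are broad
  enough that individual variation never undercuts the pit — the fovea
  must remain the global minimum for detection to be well-posed;
* covariate effects: a quadratic age profile peaking at 54 years, a male
  thickness excess concentrated in fovea/parafovea (2 px), a height
  effect on the parafoveal annulus (0.8 px per SD) and a spherical-
  equivalent effect on the perifovea (0.6 px per dioptre);
* optional causal-SNP and factor effects on named spatial supports
  (parafoveal annulus, foveal disc, nasal crescent);
* i.i.d. pixel noise (SD 1 px), 2% MCAR missingness plus extra
  missingness (15%) on the outermost two rows/columns to emulate
  non-random edge QC failures.

Genotypes use a shared-founder block model: within a block all SNPs
share one MAF and each haplotype copies a block-wide founder allele with
probability r, giving pairwise dosage correlation exactly r within the
block and independence across blocks (r = 0.9 yields mean r^2 ~ 0.81).
Chromosome X males carry one haplotype doubled. Factors come in
correlated clusters through shared Gaussian cluster factors; binary
factors use a liability threshold, which gives exact control of
prevalence and effect size. Blood counts are log-normal with injected
instrument offsets and a smooth time drift. One master seed spawns named
child seeds per component (`child_seed()`), so any component can be
regenerated alone and whole cohorts are byte-reproducible.

What the generator does **not** emulate: OCT speckle statistics,
realistic population LD (no recombination gradients, no allele-frequency
spectrum), NMR spectral artifacts, or informative missingness tied to
extreme thickness. Passing tests therefore demonstrate correctness of
the algorithms and calibration under a known, well-behaved
data-generating process — not robustness to every pathology of real
biobank data.

## Problem sizes and study conditions

The grid default is 32 x 64 pixels (the full-scale convention is
128 x 256; all geometry is parameterised in um, so ETDRS radii are
meaningful at either scale, with defaults 46.88 um/row and 23.44 um/col
and 3.5 um per axial pixel). The test suite and the acceptance script
use: FPCA recovery at n = 500 on 32 x 64 with spectrum
(10, 6, 4, 2, 1, 0.5) and residual noise below 5% of total variance;
variance-prior recovery at 20,000 pixels; a null-calibration experiment
with 2,000 heteroskedastic null pixels at n = 400; and an end-to-end
cohort of n = 600 with twelve 12-SNP LD blocks (r = 0.9) of which six
carry causal variants at MAF 0.3. Planted allele effects are 3.5 px for
annulus/fovea supports and 5 px for the nasal crescent: the nasal region
overlaps the generator's high-variance tilt modes, which are residual
noise for the GWAS, so a larger raw effect is required there to plant a
comparable standardized effect. These sizes were fixed as the package's
reference experiment; they are deliberately small enough to run on a
laptop in minutes.

## Numerical choices and degenerate inputs

* Boundary-path ties break toward the predecessor found first in the
  fixed step order; only path cost is contract-stable under ties.
* All-missing grids, empty factor tables, metabolic scores with < 3
  matched SNPs, constant-age interaction designs and rank-deficient
  design matrices raise immediate errors naming the offending input.
* Fully masked image columns mark locations invalid rather than raising.
* `trigamma` inversion uses Newton iteration on the standard recurrence
  with a closed-form start, converging to 1e-10 relative tolerance.
* p-values are floored at the smallest positive double before -log10.
* BH and Bonferroni go through `stats::p.adjust`; the hypergeometric
  tail through `stats::phyper`; smooths through `mgcv`; loess through
  `stats::loess` with direct surface evaluation so predictions are exact
  at grid nodes.

## Known limitations

Alignment is integer-translation only; sub-pixel foveal offsets survive
as (small) registration noise and inflate the apparent score SDs of
sharp modes. The basis least-squares step of FPCA ignores the penalty
when representing individual surfaces, which is harmless at 144 basis
functions against thousands of pixels but would undersmooth on very
small grids. The loci-consolidation loop's removal semantics follow one
documented reading of an ambiguous prose description; both our
implementation and the independent oracle encode the same reading, so
the equality tests validate internal consistency of that reading, not
the prose itself. Secondary-signal detection requires individual-level
data and does not implement summary-based conditional analysis.
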