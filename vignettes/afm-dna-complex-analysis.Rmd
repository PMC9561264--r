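---
title: "Quantifying protein-DNA complexes in AFM topographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein-DNA complexes in AFM topographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmdna)
```

# The measurement problem

Atomic force microscopy (AFM) of protein-DNA samples deposited on mica
yields topographic height maps (nm) in which individual DNA molecules appear
as ~0.5 nm ridges and bound proteins as brighter blobs. From such images,
single-molecule studies of lesion-recognition proteins such as hOGG1 (human
oxoguanine glycosylase 1), alone or with the transcription factor Myc,
derive four quantities per bound complex:

* **fractional binding position** along the DNA, folded to the nearer end
  (the two ends of the substrate are indistinguishable, so positions live on
  0-50% of the DNA length). On a 505 bp substrate with an oxoG lesion at
  49.8% of the contour (and optionally an E-box at 51.8%), specific binding
  shows up as a peak near the 50% position;
* **DNA bend angle** at the complex - the deflection of the DNA axis from
  collinearity, with 0° meaning straight DNA. hOGG1 populates discrete bend
  states near 0°, 35° and 70°; hOGG1/Myc complexes at the lesion show a
  single ~20° state;
* **complex volume** (nm³), which reports stoichiometry: ~100 nm³ for an
  hOGG1 monomer, ~160 nm³ for the dimer, ~240 nm³ with Myc bound;
* **maximum height**, used to classify quantum-dot (QD) labelled complexes:
  plain protein complexes image at ~1.5 nm, QD-labelled ones at ~4.5 nm,
  separated by an inclusive ≥3 nm criterion.

Aggregated over many molecules, these give the headline statistics: the
position histogram normalised per DNA, its Gaussian fit, the binding
specificity $S = N\,(A_{sp}/A_{nsp}) + 1$ (with $N = 505$ available sites,
$A_{sp}$ the area under the specific-site Gaussian and $A_{nsp}$ the
background area over 0-50% of the DNA length), the occupancy per DNA in the
45-50% bin, bend-state mixtures, and volume modes. Fluorescence polarisation
titrations fitted with single Hill equations complement the imaging with
solution affinities.

The package implements this entire pipeline, together with a synthetic
scene generator that takes the place of raw microscope data so every stage
can be tested against known ground truth.

# The synthetic data generator

## DNA conformations

Deposited DNA is modelled as a discrete 2D worm-like chain (WLC)
equilibrated on the surface, the standard regime for DNA on mica at low
ionic strength: per-step turning angles are independent Gaussians with
variance $\ell/P$ ($\ell$ the segment length, default 1 nm; $P$ the
persistence length, default 50 nm), giving tangent correlation
$e^{-s/2P}$ and the closed-form mean squared end-to-end distance

$$\langle R^2 \rangle = 4PL\left(1 - \frac{2P}{L}\left(1 - e^{-L/2P}\right)\right),$$

which serves as an exact test oracle. The contour is discretised so that
$L = n_{\text{seg}}\,\ell$ holds exactly; 505 bp at 0.34 nm/bp gives
$L = 171.7$ nm (the helical rise is a textbook constant, not something the
imaging can calibrate). A kinetically-trapped (projected 3D) deposition
regime is not implemented; only the equilibrated regime is generated and
tested.

## Binding events and bend states

Each molecule receives a specific-site event with probability
`occupancy_specific` (Bernoulli), positioned at `site_fraction` (0.498)
with Gaussian jitter of sd 1.5% of the contour - emulating the finite
localisation precision that makes the measured position peak a fittable
Gaussian - plus a Poisson(`nonspecific_rate`) number of uniformly placed
nonspecific events. Each event draws a bend state from the configured
mixture (defaults 0/35/70°, weights 0.3/0.4/0.3, within-state sd 8°).

Before the bend is imposed, the chain is straightened over ±15 nm around
the binding node. This emulates local stiffening of the DNA by the bound
protein; without it, thermal WLC curvature alone contributes ~15-20° of
apparent deflection over ±10 nm measurement arms at $P = 50$ nm and would
swamp the 8° state width. Passing bend-state tests therefore demonstrates
recovery of protein-imposed bends on locally clamped DNA, not on freely
fluctuating DNA.

## Rendering

Chains are rasterised as constant-height ridges (0.5 nm, Gaussian
cross-section sd 1.6 nm) by max-composition of point stamps; complexes as
2D Gaussian blobs **added on top of the ridge** (a protein sits on the
DNA). The blob amplitude is the configured composite height minus the ridge
height, and its width follows from the configured volume via
$V = 2\pi\sigma^2 h$, so both the rendered maxima (~1.5 nm protein, ~4.5 nm
QD) and the integrated volumes are honoured. QD blobs carry their own
volume (default 700 nm³ - a QD-antibody sandwich is far larger than the
protein), which keeps their rendered height above the 3 nm criterion even
after tip broadening.

Tip broadening is applied as an isotropic Gaussian blur (sd
`tip_sigma_nm`, default 3 nm), then white Gaussian pixel noise (sd 0.1 nm)
is added. Gaussian blur conserves integrated volume (the property the
volume measurement relies on) but attenuates peak heights, whereas a
physical AFM tip acts more like grey-scale dilation, which widens features
at preserved height. This is a known simplification: absolute heights in
rendered images are lower than the nominal values (a 4.5 nm QD blob images
at ~3.2 nm after default blur), and the height-based QD classifier on
image-mode data operates closer to its cutoff than it would on real data.
Defaults: 2 nm pixels on a 512 px field (~1 µm²), 10 molecules per scene -
deposition densities and scan settings typical of such experiments.

The fast **tabular mode** (`simulate_measurements()`) bypasses rendering
and samples the per-complex measurement table directly from the configured
distributions, in exactly the schema the imaging pipeline emits. It is the
route of choice for statistics-level studies (occupancy calibration,
specificity recovery) where imaging errors are not the question.

## What the generator does not emulate

Real AFM data contain scanner drift and line artefacts beyond a per-line
polynomial, tip asymmetry and double-tip artefacts, salt deposits,
fragmented DNA, and molecule-surface interactions that perturb chain
statistics. Chains are not self-avoiding. Passing tests on synthetic scenes
shows the measurement chain is correct under the stated forward model; it
does not certify performance on any particular instrument's data.

# The image analysis

**Flattening.** Per-scanline polynomial background (order 0-3, default 1)
is fit on pixels below a molecule-exclusion threshold (median + 3 robust
sd) and subtracted; fully masked lines fall back to the pooled fit with a
warning.

**Segmentation.** The flattened map is smoothed with a small matched
filter (Gaussian sd 2 nm): pixel noise is white while molecules are already
tip-broadened, so smoothing buys ~5x noise reduction at a few percent
signal cost - without it the 0.23 nm tip-attenuated DNA ridge would sit
below a 3-sigma threshold on 0.1 nm noise. Connected regions above
background + max(3 robust sd, 0.05 nm) are labelled (8-connectivity);
border-touching regions are flagged `edge_touching`, specks below 20 px
dropped.

**Tracing.** Regions are skeletonised by Zhang-Suen thinning. Endpoints and
branch points are identified by the crossing number (connected neighbour
groups around the 8-ring) - plain 8-neighbour degree miscounts on the
staircase patterns thinning produces. Spurs shorter than 6 nm are pruned;
remaining topology classifies the molecule (`closed_loop` without
endpoints, `branched` with more than two or with residual junctions). The
ordered skeleton is smoothed to subpixel resolution by Gaussian-weighted
local quadratic fits (window 7 points, weight sd 1.5): an unweighted
window-5 quadratic left enough staircase zigzag to bias contour length by
up to +3% at unfavourable orientations, while the weighted window-7 fit
holds the orientation dependence below 1% without shortening straight
runs. Ends are extended along the terminal tangent to the point where the
height falls to half the ridge level - the 50% crossing of a blurred ridge
end marks the true end, while the raw skeleton stops about half a ribbon
width short. Contour length is the polyline length of this subpixel path;
ok traces outside ±20% of the expected 171.7 nm are re-flagged
`off_length`. Residual length bias is below +2% (within the QC band), with
about 1% orientation dependence.

**Complex detection.** The height profile along the contour (bilinear
interpolation at 0.5 nm steps, on the smoothed map) is compared with its
median - the bare-DNA ridge level; local maxima exceeding it by
`min_peak_height_nm` (default 0.4 nm) survive non-maximum suppression in a
10 nm window (the width of a tip-broadened blob).

**Positions** are folded per definition: $100 \cdot \min(s, L - s)/L$.
Because both $s$ and $L$ come from the same traced path, small length
biases largely cancel in the ratio.

**Bend angles.** Principal directions are fit to the contour over two arm
windows of 10 nm per side, starting 4 nm away from the peak: the skeleton
through the blob itself is corner-rounded, and starting the arms at the
apex biased imposed 70° bends ~10° low in calibration scans. The angle is
180° minus the angle between the outward arm directions, so collinear arms
give 0°. Peaks within one arm reach of a DNA end are excluded from angle
statistics (the angle is undefined there) but retained for positions.
Calibration on rendered single-molecule ensembles recovers imposed
0/20/35/70° states within ~2-3° of the mean; the measurement itself
contributes ~6-8° of spread, so fitted state widths exceed the generative
8° somewhat. A folded-at-zero floor of ~6-9° is inherent to angle
magnitudes: straight DNA never measures exactly 0°.

**Volumes.** The half-prominence footprint around a peak sets the blob
scale ($\sigma = \sqrt{A/(2\pi\ln 2)}$ from its area $A$); the volume is
the integral of height above local background over the disk of radius
$3\sigma$, which holds 98.9% of a Gaussian blob. The background is the
median of a ring just outside that disk, with pixels near the traced DNA
path excluded (ridge pixels in the ring would shift the median by a
noticeable fraction of the noise sd). The DNA ridge crossing the disk is
subtracted as $\lambda \cdot 2r$, where the ridge line density $\lambda$
(nm³ per nm of contour) is measured on bare stretches of the same molecule
by perpendicular profile integration. On isolated rendered blobs the
estimator is accurate to ~1%; on DNA-bound blobs under the default imaging
model it runs 2-4% low with ~10% per-complex spread. Footprints reaching
another detected peak are flagged `ambiguous`. No tip-shape deconvolution
is attempted, and volumes are reported in nm³ without molecular-weight
calibration.

**QD classification** is the inclusive height criterion
`max_height_nm >= 3`, evaluated on the *unsmoothed* flattened map so the
1.5 vs 4.5 nm contrast is not attenuated by the matched filter.

# The statistics layer

**Histograms and fits.** Folded positions are binned on fixed edges
(default 2% bins for fitting; the 45-50% bin alone defines the occupancy
statistic) and normalised per DNA. The position model is a constant
background plus one Gaussian centred near the nominal site, fitted by
bounded nonlinear least squares on the bin counts (mirroring histogram-fit
practice; the centre is constrained to ±5% of the site and the component is
reflected at the 0 and 50% folding boundaries - folding piles the upper
tail of a 49.8% peak back below 50%, and an unreflected Gaussian would bias
the fitted centre). $A_{sp}$ is the fitted Gaussian area in events;
$A_{nsp}$ is the background level times the number of bins, i.e. the total
background area over 0-50% of the DNA length. Whether the original
histogram fits used a constant or Gaussian background is not documented;
the constant-background model is this package's declared choice.

**Specificity and occupancy.** $S = N (A_{sp}/A_{nsp}) + 1$ with
$N = 505$; $A_{nsp} \le 0$ raises an undefined-specificity error rather
than returning a number. Occupancy is events in the 45-50% bin per DNA,
per replicate, averaged with SD across replicates (SD is reported as
missing, not zero, for a single replicate). Events-per-DNA is the
implemented definition; counting molecules-with-an-event instead is
available via `count = "molecules"`.

**Bend states.** Angle magnitudes are histogrammed in 5° bins and fitted
with up to three Gaussian components by bounded least squares, components
reflected at 0°. A component initialised at 0° is a half-Gaussian with its
centre *fixed* at zero - on half-normal data a free centre trades against
the width and is not identifiable. Free centres are bounded to ±15° of
their initialisation. Fewer than 30 angles raises a small-sample error.
When the least-squares gradient is singular at the start (a component over
an empty histogram region), the fit falls back to bounded L-BFGS-B on the
same objective.

**Replicate comparison** is the two-tailed pooled-variance Student t-test;
with triplicates per group this has 4 degrees of freedom. Stars follow
* P < 0.05, ** P < 0.01, *** P < 0.005, with no multiple-testing
correction (stated in the output metadata by this design). Zero pooled
variance with equal means returns t = 0, P = 1; with unequal means the
infinite-t case is flagged explicitly.

**Hill fits.** $P(c) = P_0 + \Delta P \, c^n/(K_D^n + c^n)$ by bounded
least squares, initialised from the data (baseline = minimum, amplitude =
range, $K_D$ = concentration at half range, $n = 1$). The Hill coefficient
is fitted within [0.5, 4] by default - "single Hill equation" does not
pin $n$ - with `fix_n = TRUE` available. A fit is accepted only when
$R^2 \ge 0.95$ and the fitted $K_D$ lies within the titrated range scaled
by [0.1, 10]; replicate affinities are arithmetic means ± SD over accepted
fits. Concentrations are treated as total ligand; with a 5 nM probe,
depletion near tight $K_D$s is a recognised caveat, not modelled.

# Pipeline, reproducibility and problem sizes

`run_all()` executes simulate → trace → measure → stats per condition and
replicate, with replicates realised as independent generator seeds
(independent depositions). Every random stage receives a seed derived
deterministically from the master seed (`derive_seed()`, a Lehmer-style
mixer kept below $2^{31}$), so a fixed master seed reproduces every output
byte for byte. Stages exchange one documented CSV schema
(`molecule_id, position_pct_folded, bend_angle_deg, volume_nm3,
max_height_nm, is_qd, condition, replicate`), validated at each boundary;
QC rejects are logged one line per molecule with their status. Height maps
are written both as 32-bit float TIFF (values affinely mapped into [0, 1];
the YAML sidecar records `height_scale_nm`, `height_offset_nm`,
`pixel_size_nm` and the seed) and as plain-text matrices in nm.

The packaged studies run at deliberately modest sizes chosen to estimate
each quantity to a few percent: 10,000 chains for the WLC oracle, 200
noiseless molecules for tracing yield, ~170 molecules for position
recovery, 3,000 tabular molecules for specificity, 3 × 600 DNA per regime
for occupancy, 300 angles for bend decomposition, ~110 measured complexes
per volume condition, 10⁶ draws per population for the QD error, and 100
noisy titrations for the Hill recovery. `scripts/acceptance.R` re-runs all
of them from scratch under a supplied seed.

# Known limitations

* Tip convolution as Gaussian blur attenuates absolute heights; real tips
  dilate. Image-mode QD classification is correspondingly conservative.
* Rendered molecule ends extend slightly beyond the backbone (the ridge
  cap), so traced lengths carry a small positive bias (<2%) that the ±20%
  full-length QC band absorbs.
* Volumes on DNA-bound complexes are 2-4% low under the default model, and
  merged footprints of nearby complexes are flagged rather than resolved.
* Bend angles below ~10° are not resolvable individually (angle magnitudes
  fold at zero); they are handled distributionally by the half-Gaussian
  component.
* Chains are not self-avoiding; self-contacting conformations and molecule
  overlaps below the imaging resolution limit are generated, imaged as
  loops/branches, and rejected by QC - they exercise the reject paths
  rather than being avoided.
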