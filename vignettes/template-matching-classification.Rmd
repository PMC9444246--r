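---
title: "Locating and classifying related complexes in 2D cryo-EM images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating and classifying related complexes in 2D cryo-EM images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(tm2d)
```

## The problem

A cryo-EM image of a thinned cell section contains projections of every
macromolecule in the ice, superimposed on each other and on strong noise.
High-resolution 2D template matching (2DTM) locates copies of a *known*
complex by exhaustively correlating projections of a 3D template — over
orientations and defocus — against the image, and standardising the
correlations so that pure noise follows a standard normal distribution.
The standardised score is the 2DTM signal-to-noise ratio (SNR); a
per-pixel maximum over the search (the MIP) peaks wherever a copy of the
complex sits.

Because structurally related complexes (for example, a mature large
ribosomal subunit and its late nuclear precursor) share most of their
structure, each template also detects the other's particles. The quantity
that separates them is the *ratio* of the SNRs a physical particle achieves
under the competing templates, summarised per target as
$x_i = \log_2(\mathrm{SNR}_{i,1} / \mathrm{SNR}_{i,k})$ for templates
$k = 2, \dots, K$. A $K$-component Gaussian mixture over these ratio
vectors, fitted by maximum likelihood (EM), then assigns each particle a
class and a Bayes-rule posterior confidence.

This package implements the whole chain at desk scale: image formation
(projection, CTF, spectral whitening), the exhaustive search with its
extreme-value detection threshold, multi-template bookkeeping and the
overfitting noise-bias model, the mixture classifier, template-truncation
occupancy probing, and a synthetic phantom simulator that makes every
stage testable without any external data.

## The matched filter and its noise model

`whiten_image()` estimates the rotationally averaged power spectrum in at
least 32 radial bins, multiplies each Fourier component by
$1/\sqrt{\text{power}}$, and rescales to unit sample variance. Template
projections are CTF-modulated, filtered with the *same* radial gain, and
L2-normalised. The correlation of a unit-norm template with a
unit-variance, spectrally flat image is then standard normal under the
noise-only hypothesis — this is the package's operational definition of
the 2DTM SNR, and it is tested directly (mean $0 \pm 0.01$, variance
$1 \pm 0.02$ over $10^6$ noise correlations).

The detection threshold solves $N \cdot Q(t) = n_{\mathrm{fp}}$, with $Q$
the standard normal survival function, $N$ the number of correlations
searched (pixels × orientations × defocus planes) and $n_{\mathrm{fp}}$
the tolerated expected false positives per image (default 1). The
assumption of independent correlations deserves a caveat that our
simulations make concrete: the exceedance count has expectation
$N \cdot Q(t)$ *regardless* of correlations, but exceedances cluster when
the whitened template's autocorrelation is wide, so the count of distinct
*peaks* falls below the nominal rate. A smooth, blob-like template
clusters severely (we measure a mean peak count of ~0.05 instead of 1); a
template with fine pseudo-atomic texture under a realistic CTF
decorrelates within about a pixel and calibrates to ~1 peak per image.
Real macromolecular templates live in the second regime, which is why the
published threshold formula works in practice; the package's
`pseudo_atomic_phantom()` reproduces it.

## Why SNR ratios, and the overfitting bias

A template with $\pm 1$ pixel of positional freedom and $\pm 1$ step in
each of three Euler angles has $3^5 = 243$ ways to align to a target, and
the expected maximum of that many standard normal noise contributions is
$\sqrt{2 \ln 243} \approx 3.31$ SNR units. An observed SNR therefore
decomposes as $\mathrm{SNR_o} = \mathrm{SNR_s} + \mathrm{SNR_n}$: at the
detection threshold of 7.85 the genuine signal may be only 4.54. The
ratio of two templates' SNRs cancels this bias *only if both scores carry
it equally*. This has a practical consequence that we verified on
simulations: scoring the alternate template at the reference's fixed pose
(no maximisation) leaves the reference's bias uncancelled and shifts every
log2 ratio toward the reference template. The pipeline therefore searches
*every* template exhaustively by default and reconciles detections by
coordinate matching (`alt_search = "full"`); the faster fixed-pose mode
remains available (`alt_search = "fixed"`) with its bias documented by a
regression test. Near the detection limit the ratios also shrink toward 0
and their variance grows — both reproduced as property tests across
planted-SNR tiers.

## The mixture classifier

`fit_mixture()` is a from-scratch EM for $K$ multivariate Gaussians over
the $(K-1)$-dimensional ratio vectors: responsibilities by Bayes rule in
log space (log-sum-exp throughout), then responsibility-weighted updates
of proportions, means and covariances. `prior_mode = "fixed"` pins the
mixing proportions at user priors (for instance compartment frequencies);
`"updated"` runs the full EM. Convergence is
$|\Delta \log L| < 10^{-8} N$ or 500 iterations; covariance diagonals
carry a ridge of $10^{-6}$ times the pooled variance.

Initialisation matters more than it first appears. A single
quantile-based initialisation reliably *splits the dominant mode* when one
component is rare (11% of the data) and sits in a tail, converging to an
inferior local optimum. The package therefore runs EM from a small,
deterministic set of starts — marginal quantiles, plus prior-mass
quantiles with the component order both as given and reversed — and keeps
the best final likelihood. On 100 synthetic datasets of 1532 targets drawn
from two components with means 0.336 and −0.026 (proportions 0.89/0.11,
common σ 0.12 — σ is a fixture choice, not an estimated quantity), the
recovered means average within three single-fit standard errors of the
generating values. The independent cross-check in the test suite fits the
same data with `mclust` and agrees to $10^{-3}$ on well-separated
fixtures.

`classify()` labels a target only when its maximum posterior reaches the
confidence threshold (default 0.5, at which the two-class rule reduces to
the equal-posterior boundary); `fit_quality_r2()` scores the fitted
mixture against the 0.05-wide ratio histogram. `tidy()`, `glance()` and
`autoplot()` follow the usual broom/ggplot2 conventions.

## The phantom simulator: what it does and does not emulate

`two_class_phantom_spec()` builds two aligned templates sharing an
identical core — a deterministic cloud of 60 small Gaussian atoms placed
on a spherical Fibonacci lattice — with class-distinguishing additions:
three "appendage" clusters on the precursor-like class (several bound
biogenesis factors) and a smaller private "stalk" on the mature-like
class. The atom texture is essential, not cosmetic: with smooth
three-blob phantoms the *wrong* template recovers ~94% of the right
template's score by overfitting its core to the particle at some other
orientation, and the class separation observed at matched orientations
(log2 gap ≈ 0.47) collapses to ≈ 0.07 after the search. Fine texture
makes mismatched orientations decorrelate, as they do for real
macromolecules.

`simulate_micrograph()` plants particles at uniform random orientations
(uniform on the sphere via $\cos\theta \sim U[-1,1]$) and non-overlapping
positions in white Gaussian noise, with "planted signal SNR $s$" defined
so the noiseless particle's whitened unit-template correlation at its true
pose is $s$; a recovery test confirms planted 10 is recovered at
$10.5 \pm 0.5$ (the residual deviation comes from estimating the
whitening filter on an image that contains the particle). Compartment
masks are simple half-planes or ellipses standing in for a nuclear
envelope. The simulator deliberately omits structured cellular background
(membranes, neighbouring complexes), detector MTF, radiation damage and
thickness-dependent scattering — dose, thickness and detector effects are
all absorbed into a single `noise_sd`. Passing tests on these phantoms
therefore validate the *algorithms* (standardisation, thresholds, ratio
statistics, EM), not robustness to structured cellular clutter.

## Study-scale choices

The shipped configurations keep every test within a desk-scale budget
while preserving the statistical contracts being tested:

* False-positive calibration: 20 pure-noise 512×512 images, a
  150-atom pseudo-atomic template under a 15,000 Å defocus CTF, ~860
  orientations (20°/45° steps); mean peak count measured 1.15.
* End-to-end classification: two 440×440 images, 10 + 10 particles of two
  classes at planted SNR 15, appendage mass 70% of the core (the real
  precursor/mature difference spans several bound factors plus
  conformational changes), coarse search at 30°/40° followed by 6°/8°
  refinement of both templates' detections — the coarse-then-refine
  pattern the method itself prescribes. Accuracy at confidence 0.5
  measures ≥ 95%.
* Parameter recovery: 100 seeds × 1532 draws of the two-population ratio
  fixture.

Other defaults: search grid 2.5° out-of-plane / 1.5° in-plane with no
defocus search (the conventional full-resolution defaults; the test
configurations above override them); `defocus_range` is a full span, so a
200 Å range at a 10 Å step gives 21 planes; coordinate-matching tolerance
5 px (well under a template radius); peak exclusion radius defaults to
the template radius, and peaks within a template radius of the image
border are discarded.

## Numerical and format choices

* ZYZ intrinsic Euler angles $(\phi, \theta, \psi)$ rotate the template
  before projection along $+z$; rotation origin is the voxel
  $\lfloor n/2 \rfloor$; resampling is trilinear. 0-based pixel
  coordinates, x = column, origin top-left.
* CTF: positive defocus means underfocus; the value at zero frequency is
  $-w$ (dark-atom contrast); astigmatism enters through
  $\Delta f(\alpha)$.
* Correlation is circular (FFT); `snr_at_pose()` reproduces MIP values to
  $10^{-6}$ because both paths share one template-preparation routine.
  The heavy inner loop (padding, FFTs, conjugate multiply, MIP update) is
  compiled C++ against FFTW, with two orientations packed per complex
  transform.
* Whitening bins with zero or missing power are floored at $10^{-12}$ of
  the median bin power before inversion.
* Tables are TSV (header row, '.' decimal); models serialise to JSON; run
  configurations to YAML; volumes and micrographs to MRC2014 mode 2 with
  the voxel size in `cella/mx`.

## Known limitations

* The whitening filter is estimated from the full image including its
  particles; at high particle density this slightly attenuates genuine
  signal (self-whitening). Large fields of view make the effect small.
* The detection threshold's independence assumption is conservative for
  smooth or heavily oversampled orientation grids; thresholds are exact
  only in the fine-texture regime described above.
* No astigmatism search, per-particle B-factors, dose weighting, tilted
  CTF or 3D reconstruction; `K` is user-specified (no model selection).
* The simulator's noise is white; conclusions about structured cellular
  background require real data.
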