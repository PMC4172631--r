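---
title: "Simulating low-dose CT scans by sinogram noise insertion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating low-dose CT scans by sinogram noise insertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lodosim)
```

## The problem

Optimizing CT protocols means finding the lowest tube current–time product
(mAs) that still yields diagnostic images — but scanning the same subject
repeatedly across a dose ladder is exactly what radiation protection
forbids. A *low-dose simulator* sidesteps this: one acquisition at high
dose is converted, in the raw count domain, into a scan that is
statistically indistinguishable from a genuine acquisition at a lower mAs.
Protocol designers can then explore the dose–quality trade-off on a single
exposure, following the ALARA principle.

`lodosim` implements such a simulator end to end at desk scale: a
tissue-labeled digital phantom, a parallel-beam forward model with Poisson
photon statistics and non-Gaussian electronic detector noise, the
dose-reduction transform itself, filtered back projection with a smooth
kernel, and the statistical toolkit used to validate simulated against
directly acquired scans.

## The noise model

A detector bin behind attenuation line integral $p$ at tube load $m$ mAs
detects

$$X \;=\; \mathrm{Poisson}(\lambda) + e, \qquad
  \lambda = N_0\, m\, e^{-p},$$

where $N_0$ is the mean incident count per bin per mAs and $e$ is additive,
signal-independent electronic readout noise with standard deviation
$\sigma_e$. Electronic noise in energy-integrating detectors is markedly
non-Gaussian, so `lodosim` never draws $e$ from a normal law: it resamples
values from an `electronic_noise_pool()`, which can hold measured samples
loaded from a one-column CSV, or a synthetic default — a mixture of a
centered normal (90%) and a zero-mean shifted exponential (10%), centered
exactly and rescaled to $\sigma_e$ exactly. The pool's skewness is what a
Gaussian model would miss; it matters most at low photon flux, where the
electronic floor dominates.

## The dose-reduction transform

Given a measured high-dose sinogram $X$ at $m_0$ mAs and a target
$m_t = a\,m_0$ with dose fraction $0 < a \le 1$, `simulate_low_dose()`
draws, per bin,

$$Y \;=\; aX \;+\; \sqrt{a(1-a)\max(X,0)}\; g \;+\; \sqrt{1-a^2}\; e',$$

with $g$ a zero-mean unit-variance photonic increment and $e'$ resampled
from the electronic pool. The coefficients come from the law of total
variance (the conditional-variance identity): conditioning on the *noisy*
measured $X$,

$$\mathrm{Var}(Y) = \mathbb{E}[\mathrm{Var}(Y \mid X)] +
  \mathrm{Var}(\mathbb{E}[Y \mid X])
  = \big(a(1-a)\lambda + (1-a^2)\sigma_e^2\big) + a^2(\lambda + \sigma_e^2)
  = a\lambda + \sigma_e^2,$$

exactly the variance of a genuine acquisition at $a\,m_0$, and
$\mathbb{E}[Y] = a\lambda$. Two properties follow that distinguish this
construction from simulators that pretend the source scan is noiseless:

* **No source-noise approximation.** The variance already present in $X$
  is accounted for through the $a^2$ term; nothing assumes $X \approx
  \lambda$.
* **Source-dose independence.** The target moments depend only on
  $a\lambda = \lambda_t$ and $\sigma_e$, not on the source dose: simulating
  10 mAs from 100 mAs or from 200 mAs lands on the same distribution, as
  the package's Monte-Carlo tests verify.

The electronic coefficient is $\sqrt{1-a^2}$ (not $\sqrt{1-a}$) because the
carried-over source electronic noise arrives scaled by $a$, contributing
$a^2\sigma_e^2$; the injected term tops this up to $\sigma_e^2$ exactly.
At $a = 1$ both noise coefficients vanish and $Y = X$ bit for bit.

**Low-count branch.** The Gaussian increment is a good photon model only
for expected counts above a few tens. Where $a\,\max(X,0)$ falls below a
configurable threshold (default 20 counts), the photonic part switches to
binomial thinning, $\mathrm{Binomial}(\mathrm{round}(\max(X,0)),\,a)$,
which keeps counts integer and nonnegative and satisfies the same first
and second moments (thinning a Poisson variable is again Poisson). Both
branches are held to the same Monte-Carlo moment oracle in the test suite.
Negative measured counts (possible after electronic noise) contribute zero
photonic variance via the $\max(X,0)$ clamp, and their expectation is
preserved through the $aX$ term.

## Forward model and reconstruction

The projector is a Joseph-style interpolating ray driver: bilinear sampling
of the attenuation grid at pixel-size steps along each ray, over a
parallel-beam geometry (default 180 views over 180°, detector bins 1.5×
the matrix size, pitch chosen so the detector covers the FOV diagonal).
The linear-interpolation kernel forms a partition of unity along the ray,
so axis-aligned single-pixel integrals are exact and per-view mass is
conserved to a fraction of a percent — the two analytic oracles the tests
use.

Reconstruction is standard frequency-domain filtered back projection:
projections are zero-padded to the next power of two past twice the
detector length, multiplied by a ramp $|f|$ (zero at DC), optionally
apodized by a Hann window rolling off to zero at the detector Nyquist
frequency, and backprojected with linear interpolation. Clinical "smooth"
kernel responses are proprietary; the Hann-apodized ramp is this package's
declared stand-in, and — what actually matters for validation — the *same*
kernel is applied to the original and the simulated arm, so the comparison
between arms remains fair regardless of the stand-in's exact shape.

HU calibration is the monoenergetic textbook mapping
$\mu = \mu_w (1 + \mathrm{HU}/1000)$ with $\mu_w = 0.0203\,\mathrm{mm}^{-1}$,
an effective-beam value of roughly 60 keV for a 100 kV spectrum.
Polychromatic effects (beam hardening, bowtie filtration, scatter) are out
of scope; they cancel between arms for the same reason the kernel does.

## What the synthetic phantom emulates — and what it does not

`default_swine_phantom()` is a deterministic 2D stand-in for a scanned
juvenile pig: an elliptical fat-sheathed soft-tissue body with two lungs
(−800 HU), a fluid-filled gallbladder (0 HU), a back-muscle block (50 HU)
and a vertebral body (700 HU) on air. Tissue HU are conventional textbook
values, configurable through `build_phantom()`. Ten 50 mm² circular ROIs
per tissue are placed by farthest-point sampling inside each labeled
region, mirroring the "representative ROIs" methodology of swine
validation studies; ROI masks take the $k$ pixel centers nearest the ROI
center with $k = \mathrm{round}(50\,\mathrm{mm^2}/A_{px})$, so the
rasterized area matches the nominal area to within one pixel.

The phantom does **not** emulate: helical/cone-beam 3D geometry and
multi-slice averaging (a single 2D slice stands in for a 3 mm slice),
anatomical texture within organs (regions are piecewise-constant, so ROI
standard deviation is pure reconstruction noise), contrast-agent kinetics,
tube-current modulation, or scanner raw-data formats. Passing tests
therefore demonstrate the statistical correctness of the noise insertion
and the measurement pipeline — not that any particular clinical image
would look identical.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n0_per_mas` | 2×10³ | counts/bin/mAs | 2×10⁵ counts at the 100 mAs reference — realistic relative noise behind a body-sized object |
| `sigma_e` | 15 | counts | electronic floor visible below ~20 mAs but not dominating at 100 mAs |
| `mu_water` | 0.0203 | mm⁻¹ | ~60 keV effective beam at 100 kV |
| log clip `eps` | 0.1 | counts | keeps $-\log$ finite for non-positive measured counts |
| thinning threshold | 20 | counts | Gaussian increment adequate above; binomial thinning below |
| matrix / FOV | 256 / 380 | px / mm | desk-scale default; 512 matches the clinical matrix and is a config knob |
| angles / bins | 180 / 1.5×matrix | — | keeps a projection+FBP cycle in fractions of a second |
| ROIs per tissue | 10 (`run_experiment`) | — | the validation-study design; `default_swine_phantom()` returns 1 unless asked |

All randomness fans out from one master seed through per-stage derived
streams (pool, parent acquisition, then acquisition/simulation pairs per
dose, in that order), so an entire experiment is reproducible bit for bit
and arms never share a stream.

## Measurement precision at desk scale

ROI noise is the sample ($n-1$) standard deviation over a 50 mm² ROI. At
the 256-pixel desk scale a ROI holds ~23 pixels, and smooth-kernel FBP
noise is spatially correlated over a few pixels, leaving roughly 5–8
effective degrees of freedom per ROI. A single ROI's noise estimate
therefore carries a relative standard error of ~30–40%; averaged over ten
ROIs a tissue value still fluctuates by ~8–12%, and a per-dose mean
discrepancy over five tissues by ~5%. Two further effects are worth
knowing when reading single-run tables:

* all simulated arms derive from one parent scan, so at high dose
  fractions ($a$ near 1) their ROI statistics inherit the parent's local
  noise realization — an unlucky parent shifts several tissues coherently;
* the relative HU discrepancy is ill-conditioned for the fluid tissue,
  whose true value sits at 0 HU: tiny absolute HU differences produce
  huge percentages. Absolute differences with confidence intervals (also
  reported per cell) are the meaningful quantity there.

At the clinical 512 matrix each ROI holds four times as many pixels and
the same estimators tighten correspondingly; published swine validations
additionally spread their ten ROIs across independent slices of a 3D
animal. Single-slice desk-scale runs should be interpreted with these
sampling errors in mind — or averaged over seeds, which `run_experiment`
makes cheap.

The package's own test suite runs the full chain at 256×256 with the
five-dose ladder (a ~20 s computation), the Monte-Carlo moment oracles at
10⁵ draws, and the physics checks (1/√a noise scaling, water-disk
recovery, filter DC response) on replicated 256-pixel reconstructions.

## Numerical and design choices

* **Coordinates:** pixel centers at $(i+0.5)\,\Delta x$ from the grid
  edge, row-major; the image center is the rotation center.
* **Log transform:** $\hat p = -\log(\max(c,\varepsilon)/N_0 m)$, applied
  identically to both arms, so the (rare) clip events are commensurable.
* **ROI masks:** nearest-$k$ rasterization (above); ties at the disk
  boundary resolve in array order, deterministically.
* **ROI placement:** farthest-point sampling inside the eroded tissue
  label — ROIs are distinct measurement sites, overlapping only when a
  region is physically too small to hold ten disjoint disks (the
  desk-scale gallbladder and vertebra are).
* **Paired statistics:** Student-$t$ intervals (not normal) because
  tissue-level $n$ is ten; per-dose tests pool the fifty ROI pairs; no
  multiplicity correction, matching the per-comparison 0.05 convention of
  the validation literature.
* **Observer analytics:** Cohen's $\kappa$ is computed from rating
  vectors. Published studies print only per-observer 2×2 tables;
  `observer_rating_vectors()` fabricates vectors whose marginals match
  those tables exactly — useful for exercising the code path, but pairwise
  agreement is *not* recoverable from marginals, so such $\kappa$ values
  are synthetic by construction and labeled as such.
* **File formats:** images travel as single-slice NIfTI with JSON
  sidecars; sinograms as headerless CSV matrices with JSON sidecars
  (mAs, $N_0$, $\sigma_e$, geometry); noise pools as one-column CSV. All
  formats are plain text or standard neuroimaging containers readable
  outside R.

## Known limitations

Beyond the phantom simplifications above: dose increase ($a > 1$) is
rejected by design; kV changes are out of scope (the calibration is
monoenergetic); detector crosstalk is ignored (bins are independent); and
the electronic pool is applied with signal-independent scaling — variance
bookkeeping only — whereas real detector electronics may couple gain to
signal level.
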