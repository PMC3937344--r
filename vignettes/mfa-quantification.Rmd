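---
title: "Methods: force-based quantification of protein-DNA binding with mfaq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-based quantification of protein-DNA binding with mfaq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfaq)
```

## The measurement model

The Molecular Force Assay loads a protein–DNA complex (the *sample*
bond) in series with a DNA duplex of known length (the *reference*
bond). Separating the two surfaces at constant velocity ramps the force
linearly, `F(t) = r t`, through both bonds at once, until one of them
ruptures. The read-out is binary per construct — did the reference break
(label transferred) or the sample — and the per-pad fraction of
transferred labels, the Normalized Fluorescence

$$\mathrm{NF} = \frac{F_\mathrm{transfer}}{F_\mathrm{intact\ protein}},$$

estimates the probability that the reference bond is the weaker of the
two under this loading. Varying the reference length moves that
probability, which is what makes the base-pair calibration possible.

### Rupture kinetics

`mfaq` models each bond with the Bell law, the standard single-barrier
description in force spectroscopy: the off-rate under force is
$k(F) = k_0 e^{F/F_\beta}$, with $k_0$ the zero-force off-rate (1/s)
and $F_\beta$ the force scale (pN). Under the linear ramp, the chance
that the reference breaks first is the competing-hazards integral

$$P_\mathrm{ref} = \int_0^{F_{max}} \frac{h_\mathrm{ref}(F)}{r}
  \exp\!\Big(-\frac{1}{r}\int_0^{F}\big[h_\mathrm{ref}+h_s\big]\,dF'\Big)\,dF ,$$

which `reference_rupture_probability()` evaluates by adaptive
quadrature, and `simulate_rupture()` samples by kinetic Monte Carlo
(invert the combined cumulative hazard at $-\log U$, then split the
event by the hazard ratio at the rupture force). The two routes are
checked against each other — and against the closed form
$P_\mathrm{ref} = k_{0,\mathrm{ref}}/(k_{0,\mathrm{ref}}+k_{0,s})$
that holds when both force scales are equal — throughout the test
suite. Identical bonds give $P_\mathrm{ref} = 1/2$ exactly: NF = 0.5 is
the matched-stability point.

Assumptions worth stating: both bonds feel the identical force at all
times (linker elasticity is ignored — the read-out depends only on
*which* bond breaks, not when); no rebinding after rupture; and a
single-exponential hazard with no inner barriers. Shear-geometry
sequence-level models and zipper-mode references are out of scope.

### Reference duplexes in Bell terms

A shear duplex of $n$ base pairs maps to a Bell bond through a monotone
per-bp rule,

$$k_0(n) = k_{0,1}\, e^{-\Delta g\, n}, \qquad
  F_\beta(n) = F_{\beta,1} + \beta\,(n-1),$$

with defaults $k_{0,1} = 0.01$/s, $\Delta g = 0.07$ per bp,
$F_{\beta,1} = 10$ pN, $\beta = 0$ (`default_per_bp_params()`).
$\Delta g$ is an *effective*, loading-rate-dependent stability
increment, deliberately much smaller than a thermodynamic base-pairing
free energy: it is chosen so that doubling the reference from 20 to
40 bp moves the transfer probability across the experimentally observed
NF range (0.65 → 0.32) rather than saturating it. More base pairs
always means a strictly lower rupture probability against any fixed
sample bond.

### Calibrated default sample bonds

The generator's default conditions are the reference experiment's six:
{no, low, high affinity} × {20, 40 bp shear}. The high- and
low-affinity sample bonds shipped in `default_config()` were obtained
once with `calibrate_sample_bond()`, which inverts the competition
integral so that the model's transfer probabilities equal the measured
condition NFs:

| motif | $k_0$ (1/s) | $F_\beta$ (pN) | P at 20 bp | P at 40 bp |
|-------|------------:|---------------:|-----------:|-----------:|
| high  | 1.763e-3    | 10.41          | 0.650      | 0.320      |
| low   | 0.1410      | 22.77          | 0.390      | 0.200      |
| no    | —           | —              | 0          | 0          |

(the no-binding motif forms no complex, so nothing can transfer). Two
targets per motif determine the two Bell parameters; the fit residual
is below $10^{-4}$. This makes the synthetic study a closed loop: the
full pipeline must hand the generating NF table back.

### Loading rate

The ramp rate is not part of the package's claims — the NF compares two
bonds under the *same* ramp — so its default, 100 pN/s, is simply a
rate typical of soft-stamp retraction experiments; it is configurable
(`rupture.loading_rate`). An optional force cap `f_max` truncates the
ramp, leaving survivor constructs with neither bond broken.

## The synthetic imaging model

`render_image_set()` renders both channels of one field of view:

    saturation = B + D · field · (1 + cv·ε₁) + read noise
    transfer   = B + D · field · p · (1 + cv·ε₂) + read noise

where `D` is the pad's protein density (counts), `p` its transfer
probability, and `field` a smooth multiplicative inhomogeneity of mean
exactly 1 (`make_inhomogeneity_field()`: white noise smoothed at a
configurable correlation length, scaled to a maximum relative deviation
`amplitude`). The field is **shared** between the channels, because the
transfer and saturation images show the same immobilised proteins; all
other noise terms are drawn independently per pixel and channel. This
shared/independent split is the crux of the design: the NF ratio
cancels the shared field exactly (a property the tests verify to
machine precision) while per-channel noise propagates into the NF
histogram width.

Default scales are instrument-realistic: background 1500 counts
(within the typical 1000–2000 band), density 15500 counts so a fully
transferring pad reads 17000 counts, 16-bit dynamic range. These
absolute counts are *generator inputs only* — the pipeline's outputs
(NF, Δbp) are dimensionless and invariant to rescaling both channels,
which the acceptance suite asserts explicitly.

The multiplicative noise CV defaults to 0.1. It is anchored to the
widths of measured per-pad NF histograms (Gaussian fit SDs of
0.07–0.15 at 20 bp, i.e. relative widths of 10–40%): a pixel NF spread
of $\approx p\cdot cv\sqrt{2} \approx 0.05$–$0.09$ reproduces that
regime. This matters beyond realism — the matched-pair calibration
argument ("equal within errors") is only exercisable if the synthetic
errors resemble the experimental ones; with much sharper noise no pair
of distinct conditions could ever be declared equal. Photon noise is
approximated as Gaussian (counts ≫ 1); Poisson sampling is not
implemented.

What the generator does *not* emulate: optical blur (pads have sharp
edges), channel misregistration, bleaching between the two
acquisitions, spatially varying background, partial protein
functionality. Passing tests therefore demonstrate the correctness of
the estimators under the stated noise model, not robustness to every
optical artefact of a real microscope.

## The NF pipeline and its numerical choices

* **Background**: median and MAD-sigma (1.4826·MAD) of the inter-pad
  pixels. Robust location/scale so pad bleed-through and hot pixels
  have no leverage; one global scalar per channel by default (the
  spatial structure of real backgrounds is not modelled, and the pad
  read-out subtracts a constant anyway).
* **Subtraction** clips at zero — negative counts are unphysical.
* **Ratio validity**: pixels are divided only where the corrected
  saturation signal is at least `min_denominator`, default
  `max(5·background SD, 1e-6)` counts. This keeps ratio blow-ups out of
  the histograms; raising the threshold can only remove valid pixels,
  never add them. NF values above 1 are *kept*: clipping would skew the
  histogram and bias the Gaussian fit.
* **Pad masks** are the known stamp rectangles (0-based, half-open),
  eroded by `margin_px = 2` to drop edge pixels. A margin of half the
  pad size empties the mask and the pad is reported `failed`.
* **Histogram fit**: 100 uniform bins over the pad's value range,
  three-parameter Gaussian (amplitude, mean, sd) by Levenberg–Marquardt
  least squares, initialised at the sample moments. At least 500 valid
  pixels are required; non-convergence or sparsity gives `failed`, not
  an exception. A degenerate all-equal pad reports its value with a
  bin-width-limited sd.
* **Zero rule**: a pad whose *median raw transfer* signal is at or
  below background mean + 3·SD is assigned NF = 0 without fitting
  (`k_sigma = 3`; the criterion in the literature is qualitative —
  "hardly exceeds the background"). The threshold is inclusive, and
  zeroing is monotone in `k_sigma`.
* **Errors**: the reported per-pad uncertainty is the fitted Gaussian
  SD of the pixel histogram (the width of the NF distribution), not a
  standard error of the mean. Published per-condition "±" values are
  read the same way.

## Calibration in base-pair units

Within the probed range the mean NF is linear in the reference length,
so each motif gets an ordinary least-squares line NF(L) (exact
interpolation for two lengths), and

* `matched_reference_length()` solves NF(L) = 0.5 — the length of the
  reference duplex with the same stability as the protein–DNA bond;
  solutions outside the fitted range are flagged as extrapolation and
  never silently trusted (linearity is only asserted *within* the
  probed 20–40 bp window);
* `equivalent_bp_difference()` compares two motifs either by the
  **matched pair** route (find a cross-motif pair of conditions that is
  equal within errors — |ΔNF| ≤ sum of the two SDs, the most permissive
  reading consistent with calling 0.39±0.15 and 0.32±0.01 equal — and
  take the bp difference of their references; ties resolved toward the
  smallest |ΔNF|, and a same-length pair legitimately yields Δbp = 0)
  or by the **linear model** route (difference of the two matched
  lengths). Matched-pair is the default because it is the assay's own
  argument; the model route generalises to more than two reference
  lengths. On the reference table the two routes give 20 and 20.7 bp.
  Zeroed conditions are excluded from fits but reported with NF 0.

## Problem sizes and determinism

All simulations in the tests and the acceptance script are sized to be
informative yet quick: 256×256 px single-pad fields (≈24k valid pixels
per fit, comfortably above the 500-pixel minimum), the full 4×4 field
at 304×304 px, kinetic Monte Carlo at 10⁵ replicates (Monte-Carlo SE
≈ 0.0016 on a fraction near 0.5), and randomized property checks at
2×10⁴ replicates per parameter set with 4-SE bands. Every stochastic
step takes an explicit integer seed; identical seeds reproduce images,
tables and reports byte for byte, which the workflow tests assert via
checksums.

## Known limitations

* The Bell model has no inner-barrier structure; catch bonds or
  multi-state unbinding would need a different hazard.
* The per-bp rule is an effective parametrisation for shear duplexes
  only; zipper-geometry references are represented but not
  parametrised.
* One background scalar per channel; fields of view with strong
  background gradients would need the field-based estimator extension.
* The fitted Gaussian SD understates nothing about pixel correlation:
  neighbouring pixels share the density field, so the *effective*
  number of independent measurements per pad is smaller than the pixel
  count. Since the pipeline reports distribution width rather than a
  standard error, this does not bias the stated results.
* Conversion of base-pair equivalents to free energies or dissociation
  constants is intentionally out of scope.
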