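# mfaq — quantification pipeline for the Molecular Force Assay

The Molecular Force Assay (MFA) measures how strongly a protein binds a
DNA sequence by force, not by equilibrium binding: each protein–DNA
complex is clamped in series with a DNA reference duplex between two
surfaces, the surfaces are pulled apart at constant velocity, and the
weaker of the two bonds ruptures. A fluorophore on the linker between
the bonds reports which one broke — if the reference ruptured, the label
is transferred to the protein surface. Because every construct carries
its own reference, millions of single-molecule competitions run in
parallel on each pad of a 4×4 stamp, one (DNA motif, reference length)
condition per pad.

`mfaq` implements the complete quantification workflow for this assay,
plus a physics-based synthetic data generator so that every stage can be
validated against known ground truth:

* **Rupture competition** (`bell_bond`, `reference_rupture_probability`,
  `simulate_rupture`): both bonds feel the same linearly ramped force
  *F = rt* and rupture with Bell-model hazards *k(F) = k₀·exp(F/F_β)*.
  The probability that the reference breaks first is

      P(ref) = ∫₀^∞ (h_ref(F)/r) · exp( −(1/r) ∫₀^F [h_ref + h_s] dF' ) dF,

  computed by adaptive quadrature and, independently, by kinetic Monte
  Carlo (inverse-CDF sampling of the combined hazard, then a Bernoulli
  split by hazard ratio at the rupture force).
* **Synthetic imaging** (`render_image_set`): seeded 16-bit
  transfer/saturation image pairs on the pad layout, with realistic
  backgrounds (~1500 counts), per-pixel noise, and a smooth
  protein-density inhomogeneity field shared between the two channels —
  the same immobilised molecules are imaged twice.
* **Normalized Fluorescence** (`estimate_background`,
  `subtract_background`, `compute_nf_image`): NF =
  F_transfer / F_intact-protein, computed pixel-by-pixel after
  background subtraction. Shared inhomogeneities cancel exactly in the
  ratio.
* **Per-pad statistics** (`fit_nf_histogram`, `apply_zero_rule`):
  each pad's NF histogram is fitted by a Gaussian; the fitted mean ± SD
  is the pad's read-out. Pads whose transfer signal sits at the
  background (no-binding sequences) are assigned NF = 0 without fitting.
* **Base-pair calibration** (`fit_linear_nf_model`,
  `matched_reference_length`, `equivalent_bp_difference`): within the
  probed range the mean NF falls linearly with reference length, so the
  length at which NF = 0.5 expresses the protein–DNA bond strength in
  equivalent DNA base pairs, and two motifs can be compared as a Δbp.

## Worked example

Simulate a full 4×4 experiment, quantify it, and calibrate it, all from
one config:

```r
library(mfaq)
res <- run_all(default_config(seed = 7), "mfa-demo")
res$calibrate$conditions
```

```
  motif_label reference_n_bp   nf_mean      nf_sd n_pixels n_pads status
1        high             20 0.6463557 0.08926022     5808      3 fitted
4        high             40 0.3176910 0.04629857     5808      3 fitted
2         low             20 0.3896470 0.05481452     5808      3 fitted
5         low             40 0.1999988 0.02952774     3872      2 fitted
3          no             20 0.0000000         NA     5808      3 zeroed
6          no             40 0.0000000         NA     3872      2 zeroed
```

The high-affinity motif transfers 65% of its labels against a 20 bp
reference and 32% against a 40 bp reference (the NF roughly halves when
the reference length doubles — the linear regime); the low-affinity
motif gives 0.39 and 0.20; the no-binding pads are zeroed. The
low-affinity/20 bp and high-affinity/40 bp conditions are equal within
errors, so swapping motifs is worth exactly the 20 bp reference-length
difference:

```r
res$calibrate$matched_pair$delta_bp   # 20  (bp, matched-pair route)
res$calibrate$linear_model$delta_bp   # 20.54374  (bp, linear-model route)
```

The linear-model route solves each motif's NF-vs-length line for
NF = 0.5:

```r
m <- fit_linear_nf_model(data.frame(reference_n_bp = c(20, 40),
                                    nf_mean = c(0.65, 0.32)), "high")
m                              # NF(L) = 0.9800 -0.01650 * L
matched_reference_length(m)    # 29.09 bp, inside the fitted range
```

i.e. the high-affinity protein–DNA bond is as stable as a 29 bp shear
duplex under this loading.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mfa",package="mfaq"))')" \
    run-all --outdir mfa-run --seed 7
```

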