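# dscaif

Automated arterial input function (AIF) selection and cerebral blood
flow (CBF) quantification for dynamic susceptibility contrast MRI
(DSC-MRI), for perfusion researchers and methodologists who need a
reproducible, testable alternative to hand-drawn arterial ROIs.

In bolus-tracking perfusion imaging the tissue concentration curve is
the convolution of the arterial input with the flow-scaled residue
function,

    C_t(t) = F · ∫ C_a(τ) R(t−τ) dτ ,

so CBF is obtained by deconvolving the AIF from each tissue curve.
The package implements a complete workflow around that model:

* **Digital phantom** (`build_phantom`): three 9×9 blocks — artery,
  artery-surrounding tissue, tissue — with 0.5 partial-volume mixing
  strips, contrast physics in the static-dephasing (SDR, linear) and
  diffusional-narrowing (DNR, quadratic) relaxation regimes, a
  gamma-variate input bolus (C_max = 3 mM), dilution-theory dispersion
  (MTT 2.6 s), 80 frames at 1.5 s, and noise set by a target
  contrast-to-noise ratio (CNR) of the arterial curve.
* **Spatial ICA segmentation** (`decompose`, `zscore_map`,
  `top_k_voxels`): PCA reduction then FastICA over the voxel domain;
  each component map is standardised into a z-map and the 50
  highest-z voxels form a candidate ROI.
* **Hemodynamic component selection** (`rank_components`,
  `select_aif_components`): candidate ROI curves are log-converted
  (C = −(K/TE)·ln(S/S0), K = 7.62 at 1.5 T) and gamma-fitted; an
  artery is *early, narrow, high* and spatially compact; the
  surrounding tissue — the preferred AIF source — is the narrowest
  compact component hugging it.
* **z-weighted AIF** (`weighted_aif`): AIF = Σ Q_i S_i / n with
  weights Q_i taken from the z-map and normalised to mean 1.
* **Quantification** (`svd_deconvolve`, `cbf_map`): truncated-SVD
  deconvolution with an adaptive truncation threshold chosen per
  curve by an oscillation-index criterion; flow in mL/100 g/min via
  the standard hematocrit/density scale.
* **Evaluation** (`segmentation_accuracy`, `segmentation_sweep`,
  `region_stats`): top-k accuracy against phantom truth (with and
  without partial-volume strips), CNR sweeps, regional CBF tables and
  gray/white ratios.

## Worked example

Simulate a phantom at CNR 50, decompose it, select the artery and
surrounding-tissue components automatically, and extract the weighted
AIF:

```r
library(dscaif)

ph <- build_phantom(phantom_spec(cnr = 50, seed = 7))
ic <- decompose(ph$series, n_components = 10, seed = 7)
rk <- rank_components(ic, ph$series)
head(rk, 3)
#>   component score coherence arrival_s ttp_s onset_s fwhm_s peak_height fit_ok
#> 1         1 0.911      0.70       9.0  19.3    10.5   31.4         789   TRUE
#> 2         2 0.910      0.86      10.5  18.9    10.5   20.0         400   TRUE
#> 3         3 0.546      1.00      10.5  24.1    12.0   61.3         808   TRUE

sel <- select_aif_components(ic, rk)
segmentation_accuracy(sel$artery$voxels, ph$truth, "artery")
#> <segmentation_score> artery (+PV strips): true rate 92.0% (46/50)
segmentation_accuracy(sel$surround$voxels, ph$truth, "surround")
#> <segmentation_score> surround (+PV strips): true rate 100.0% (50/50)

z   <- zscore_map(ic, component = sel$surround$component)
aif <- weighted_aif(ph$series, sel$surround$map_positions, z, "surround")
conv <- conversion_params(te = ph$series$te,
                          baseline_window = ph$series$baseline)
aif$curve <- curve_to_concentration(aif$curve, conv)
aif_features(aif$curve, fit_gamma_variate(aif$curve, dt = 1.5), dt = 1.5)
#> <aif_features> TTP 18.448 s | onset 10.500 s | FWHM 19.900 s | peak 405.6
```

Reading the output: component 1 is the artery (highest peak, earliest
arrival — its broad FWHM reflects signal-void clipping at the bolus
peak), component 2 is the surrounding tissue (narrowest bolus,
adjacent region); 46/50 arterial and 50/50 peri-arterial top-z voxels
fall inside the true regions when the 0.5 partial-volume strips are
counted. The extracted surround AIF peaks ~9 s after injection with a
~20 s first-pass width.

The whole pipeline (simulation or NIfTI input → ICA → selection →
AIF → gamma features → CBF map → artifacts on disk) runs from a
single YAML-configured call, `run_pipeline(config, out_dir)`, or from
the command line:

```sh
dscaif=$(Rscript -e 'cat(system.file("exec", "dscaif", package = "dscaif"))')
Rscript "$dscaif" simulate --cnr 30 --seed 7 --out phantom.nii.gz --truth truth.json
Rscript "$dscaif" quantify --config run.yaml --out results/
Rscript "$dscaif" sweep --cnrs 30,40,50,60,70 --seeds 1:20 --out sweep.csv
```

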