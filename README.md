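# verdictmri

Microstructural modelling of renal diffusion-weighted MRI with the VERDICT
(Vascular, Extracellular and Restricted Diffusion for Cytometry in Tumours)
framework, in plain R.

Renal cell carcinoma subtypes are hard to tell apart on conventional imaging,
and the apparent diffusion coefficient conflates cellularity, extracellular
water and perfusion into a single number. VERDICT instead models the
normalised PGSE diffusion signal as a three-compartment mixture

    S(b, delta, Delta) = f_VASC * S_stick(d_VASC; b)
                       + f_IC   * S_sphere(R, d_IC; b, delta, Delta)
                       + f_EES  * S_ball(d_EES; b)

with intracellular water restricted in impermeable spheres of radius `R`
(Gaussian-phase-distribution / Murday–Cotts signal, d_IC = 2 um^2/ms),
vascular water in randomly oriented sticks with pseudo-diffusivity
d_VASC = 50 um^2/ms, and extracellular-extravascular water as free Gaussian
diffusion with d_EES = 2 um^2/ms. The free parameters are f_IC, f_EES and R;
f_VASC = 1 − f_IC − f_EES. The package is aimed at quantitative-MRI
researchers who want to fit these models, test protocol economisation, or
benchmark fitting engines on fully synthetic renal phantoms — no patient data
are included or required.

What is implemented:

* the nine b-value kidney acquisition (b = 70–2500 s/mm^2, three orthogonal
  directions per b, matched b0 per echo time) and a plain-text scheme format
  (`kidney_full_protocol()`, `load_scheme()`, `expand_measurements()`);
* closed-form compartment signals validated against independent oracles: a
  Monte-Carlo random-walk simulator for the sphere (`mc_sphere_oracle()`,
  compiled) and numerical quadrature for the stick spherical mean;
* classical multi-start bound-constrained least squares for VERDICT, IVIM
  and ADC (`fit_nlls()`), and the self-supervised network fit
  (`fit_selfsupervised()`): a three-hidden-layer, 18-neuron fully connected
  network mapping each voxel's 18-volume measurement vector to clamped model
  parameters, trained by reconstruction MSE through the forward model — no
  labels, training and inference on the same dataset;
* the dual-network protocol selector (`train_dual_network()`,
  `select_protocol()`, `reduce_scheme()`): a scoring network ranks the 27
  direction-resolved measurements, a prediction network reconstructs all 27
  from the retained 12, and cohort-averaged importance scores yield a
  4 b-value protocol;
* a synthetic renal phantom/cohort generator with per-class tissue contrasts,
  Rician noise, spherical averaging and matched-b0 normalisation
  (`make_phantom()`, `simulate_signals()`, `make_cohort()`);
* NIfTI map I/O, ROI summaries, rank-based group comparison with star-coded
  p-values (`read_dwi()`, `write_maps()`, `roi_summary()`,
  `compare_groups()`), and a small CLI (`inst/cli/verdictmri.R`).

## Worked example

```r
library(verdictmri)

scheme <- kidney_full_protocol()
y <- model_signal("verdict", tissue_params(f_ic = 0.3, f_ees = 0.5, R = 7),
                  scheme)
fit <- verdict_fit(y, scheme, model = "verdict")
print(fit)
#> VERDICT fit (nlls)
#>   f_ic  f_ees f_vasc      R
#>    0.3    0.5    0.2    7.0
#> MSE: 2.482e-33
```

A noiseless signal from a tumour-like voxel (30% intracellular water in 7 um
cells, 20% vascular) is recovered exactly by the classical fit. The same
entry point fits whole phantoms with the network engine:

```r
spec <- phantom_spec(grid = c(16, 16, 2), snr = 50, seed = 7)
ds   <- simulate_signals(make_phantom(spec), scheme, spec)
maps <- verdict_fit(ds)            # self-supervised network fit
summary(maps)
#> VERDICT fit (selfsupervised), 512 voxel(s)
#>  parameter   mean     sd
#>       f_ic 0.2495 0.1629
#>      f_ees 0.5616 0.2024
#>     f_vasc 0.1889 0.1080
#>          R 8.0603 0.1615
#> mean MSE: 0.0003036
#> early stopping at epoch 602
plot(maps, parameter = "f_ic", slice = 1)
```

The phantom mixes seven tissue classes (normal parenchyma, four RCC
subtypes, oncocytoma, cyst) whose intracellular and vascular fractions
follow the group-level contrasts reported for renal tumours, so the fitted
means reflect the mixture of classes on the grid.

Protocol economisation on a synthetic cohort:

```r
cohort <- make_cohort(spec, n_subjects = 3, seed = 1)
scores <- train_dual_network(cohort, selection_config(seed = 1))
reduced <- reduce_scheme(scheme, select_protocol(scores, scheme))
nrow(reduced)   # 4 b-values, 12 DW measurements, matched b0s re-attached
```

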