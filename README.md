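# eegnetdx

Diagnostic modelling from multichannel resting-state EEG functional
networks. Interictal EEG in children with suspected partial epilepsy is
often unremarkable to visual inspection, and no single spectral or network
quantity reliably separates patients from controls. `eegnetdx` implements
the alternative: estimate a weighted functional network per subject with
the synchronization likelihood (SL), summarize it into 18 network
characteristics, and evaluate a multivariable random-forest classifier
with bootstrap-corrected internal validation.

## The method

For channels *x*, *y* with delay-embedded state vectors, SL is the
conditional probability that *y* recurs at a time pair where *x* recurs,
with each reference time's critical distance calibrated so its recurrence
fraction equals p_ref (default 0.05); independent channels give
SL ≈ p_ref, identical channels SL = 1. Per-epoch SL matrices are averaged
into one symmetric weighted graph **W** per subject (w_ii = 0,
w_ij ∈ [0, 1], no thresholding).

From **W**, 18 features: min/mean/max of strength s_i = Σ_j w_ij, shortest
path length (edge length 1/w), closeness cc_i = (N−1)/Σ_j d_ij,
eigenvector centrality (Perron vector of **W**), and Onnela weighted
clustering; mean/max of betweenness (ordered-pair transit counts); and the
power-law index α = 1 + n/Σ log(d_i/d_min) of the strength distribution.

A random forest (500 trees, 5 features per split) scores subjects by case
vote fraction. Because same-data evaluation is optimistic, performance is
reported only after bootstrap correction: refit on stratified resamples,
score out-of-bag subjects, average replicate ROC/AUC and Youden-threshold
sensitivity/specificity/PPV/NPV, with percentile 95% CIs.

A synthetic cohort generator (alpha-band AR(2) oscillators coupled through
shared latent drivers, with a planted focal coupling increment in the case
group) makes the whole pipeline testable and calibratable without clinical
data.

## Worked example

```r
library(eegnetdx)

spec <- cohort_spec(n_per_group = 15, n_channels = 17, fs = 512,
                    epoch_seconds = 4, n_epochs = 2,
                    effect_size = 0.6, seed = 21)
cohort  <- generate_cohort(spec)
features <- cohort_features(cohort, params = sl_params(fs = 512))
report  <- bootstrap_validate(features, B = 50, seed = 9)
report
#> <validation_report> oob bootstrap, B = 50 (50 used, 0 skipped), seed 9
#>   auc          0.934 [95% CI 0.694-1.000]
#>   sensitivity  0.932 [95% CI 0.600-1.000]
#>   specificity  0.908 [95% CI 0.625-1.000]
#>   ppv          0.908 [95% CI 0.600-1.000]
#>   npv          0.944 [95% CI 0.667-1.000]
```

The corrected AUC of 0.93 says the forest separates the two synthetic
groups — whose only difference is a 0.6-amplitude shared driver on a block
of 5 channels — nearly perfectly even when every replicate is scored on
subjects left out of its resample; the CIs reflect the small out-of-bag
sets. With `effect_size = 0` the same pipeline returns AUC ≈ 0.5: the
bootstrap correction removes the optimism a same-data evaluation would
show. Univariate structure is available too:

```r
per_feature_ttest(features)     # pooled-variance Student t per feature
feature_correlation(features)   # 18 x 18 Pearson matrix
autoplot(report)                # averaged ROC curve
```

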