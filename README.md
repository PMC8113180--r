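# sabl — specific amyloid load from amyloid PET with deep-learning nonspecific-uptake correction

Amyloid-PET quantification with the standardized uptake value ratio
(SUVr = PET / mean uptake of an amyloid-free reference region) is
contaminated by the tracer's *nonspecific* (NS) binding to myelin: white
matter is the brightest tissue in an amyloid-negative scan, it spills into
cortical grey matter (GM) through the scanner point-spread function, and
its level varies between subjects — globally with myelin content and
diffuse cerebrovascular disease (CeVD), and locally inside white-matter
hyperintensities, lacunes and cortical infarcts. SUVr therefore carries a
CeVD-driven variance component unrelated to amyloid.

`sabl` implements a subtraction-based alternative for researchers working
on amyloid-PET quantification in mixed AD/CeVD cohorts:

* a trainable multi-scale 3D convolutional model translates structural MRI
  (T1-weighted and T2-FLAIR) into the subject's NS uptake map in SUVr
  units, trained on the cohort's lowest-SUVr scans (which exhibit mainly
  NS uptake) with a 34 train / 6 evaluation split;
* the **specific amyloid load**
  `SAbL = mean over cortical GM of (SUVr − NS_estimate)`
  is obtained by voxel-wise subtraction in native space;
* comparison biomarkers: global SUVr, and the two-template amyloid load
  `AbL` — ordinary least squares of the SUVr image on an NS template and a
  PCA-derived amyloid-deposition template
  (`SUVr ≈ AbL · T_deposition + ns · T_NS`);
* the four evaluation metrics used for image-translation quality, computed
  over region masks (whole brain, GM, eroded WM, reference): MSE, a global
  SSIM statistic, the signed mean relative error
  `MRE(%) = 100 (mean Y − mean X)/mean Y` (cohort-summarized as the mean
  of absolute values), and histogram intersection;
* a Spearman rank association analysis of every biomarker against
  cognition, atrophy, hippocampal volume and CeVD lesion counts;
* a synthetic 3D brain-phantom generator (co-registered T1/FLAIR/PET with
  GM/WM/CSF anatomy, WM-dominant NS binding with global and lesion-driven
  variability, cortical deposition scaled by a per-subject burden, PET
  point-spread blur and noise, and covariates with known dependencies), so
  the whole pipeline is testable end to end with exact ground truth and no
  data download.

## Worked example

Simulate a 40-phantom cohort, train the translator on the lowest-SUVr
subset, quantify every subject and run the association analysis:

```r
library(sabl)

res <- run_pipeline(demo_config(seed = 5), "demo_out")

head(res$biomarkers[, c("subject_id", "burden", "suvr_global", "sabl", "abl", "ns_gm")])
```

```
  subject_id      burden suvr_global          sabl          abl     ns_gm
1    sub-001 0.042710400   1.2311120  0.0063086108  0.042107019 1.2248034
2    sub-002 0.663933871   1.9978407  0.6585277872  0.611822125 1.3393129
3    sub-003 0.005743598   1.0727487 -0.0868086522 -0.073377628 1.1595573
4    sub-004 0.021595876   0.9680457  0.0002549021 -0.054368493 0.9677908
5    sub-005 0.030438751   1.2430015 -0.0375968933  0.005011812 1.2805984
6    sub-006 0.059064916   1.3329579  0.0186941909  0.119381950 1.3142637
```

`suvr_global` is the GM mean of the SUVr image; `ns_gm` the GM mean of the
model's NS estimate; `sabl` their difference — note how the near-zero
burdens map to near-zero `sabl` while `suvr_global` stays at its 1.0–1.3
nonspecific baseline, and the one high-burden subject (`sub-002`) stands
out in both.

```r
subset(res$assoc, covariate == "n_lesions_total")
```

```
        marker       covariate        rho           p stars
4  suvr_global n_lesions_total -0.3810748 0.015264950     *
9         sabl n_lesions_total -0.1327318 0.414230312
14         abl n_lesions_total -0.1855988 0.251545502
19       ns_gm n_lesions_total -0.4532260 0.003314926    **
```

SUVr and the NS estimate are significantly (negatively) associated with
the CeVD lesion count; after subtraction `sabl` is not — the design
property that makes the subtracted biomarker a cleaner amyloid readout.

A command-line interface wrapping the same functions ships in
`inst/cli/sabl` (subcommands `simulate`, `train`, `estimate-ns`,
`quantify`, `templates`, `fit-abl`, `evaluate`, `associate`, `run`).

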