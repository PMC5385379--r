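# endoprofile

In-vivo endothelial profiling from MRI and plasma panels, as a reproducible
desk-scale R pipeline — built for researchers quantifying endothelial
dysfunction and vasoprotective treatment effects in mouse models of
atherosclerosis (ApoE/LDLR-deficient animals, MNA or ACE-inhibitor
treatment), and for methodologists who need a fully synthetic, ground-truth
test bed for such analyses.

The package implements the three analysis chains such studies combine, plus
the phantom/cohort generator that stands in for the animals:

* **Vasomotor response.** Acetylcholine constricts the brachiocephalic
  artery (BCA) when the endothelium is dysfunctional and dilates it when
  treatment restores NO-dependent signalling. From pre/post-acetylcholine
  cine gradient-echo stacks the pipeline picks the end-diastolic frame,
  selects five slices ending just before the bifurcation, segments the
  lumen by thresholding, reconstructs volumes slice-wise and reports
  `100 · (V_post − V_pre) / V_pre`.
* **Endothelial permeability (Npx50).** Per-pixel T1 maps are fitted before
  and after an albumin-binding gadolinium agent with the variable flip
  angle method on the spoiled gradient-echo signal
  `S = M0 sin α (1 − E)/(1 − E cos α)`, `E = exp(−TR/T1)` (linear DESPOT1
  solve plus Levenberg–Marquardt refinement). **Npx50** is the count of
  perivascular pixels whose T1 dropped by strictly more than 50% — an
  operator-independent permeability statistic.
* **Plasma biochemistry.** Renin–angiotensin peptide and
  L-arginine/ADMA panels, per-animal protective-axis ratios
  (Ang-(1–7)/Ang II, L-Arg/ADMA), group comparisons (Kruskal–Wallis with
  Dunn/Holm post-hoc, or ANOVA with Tukey HSD), and Spearman correlation of
  functional against biochemical readouts.

## Worked example

Simulate the untreated 6-month condition (ground-truth volume response
−7.18%, SNR 30) at the full acquisition size and run the vasomotor
analysis; then build a noiseless permeability phantom with 15 leaking rim
voxels and count them back; finally profile a full synthetic cohort:

```r
library(endoprofile)

proto  <- protocol_function()                 # 256 x 256 x 30, 7 frames
tissue <- tissue_params()
tissue$noise_sigma <- tissue$cine_intensity[["blood"]] / 30   # SNR 30
geom   <- default_geometry(proto, dilation_factor = 0.9282)   # -7.18% truth
cines  <- simulate_cine(geom, tissue, proto, seed = 1)
measure_vasomotion(cines$pre, cines$post, seed_point = c(132, 130))
#> <vasomotion_result>
#>   end-diastolic BCA volume: pre 2.9022 mm^3, post 2.6848 mm^3
#>   response: -7.49% (vasoconstriction)
#>   diastolic frame 4 (pre) / 4 (post); slices 7-11

tis0 <- tissue_params(); tis0$noise_sigma <- 0
ph   <- simulate_permeability_phantom(n_leak = 15, tis0, seed = 3)
compute_npx50(fit_t1_map(ph$pre), fit_t1_map(ph$post), ph$rim_mask)
#> <permeability_result> Npx50 = 15 of 759 evaluable ROI pixels (threshold 0.50, decrease)

cohort <- simulate_study_cohort("2-month", seed = 7)
profile_cohort(cohort$imaging, cohort$panel)
#> <cohort_profile>
#>   21 animals, reference group: Untreated_6m
#>   function-biochemistry correlations (Spearman):
#>                                          pair r_spearman      p_value  n
#>                   BCA volume change and Npx50 -0.8883413 7.596947e-08 21
#>        BCA volume change and L-Arg/ADMA ratio  0.7337662 1.532404e-04 21
#>  BCA volume change and Ang-(1-7)/Ang II ratio  0.7779221 3.305456e-05 21
#>                    Npx50 and L-Arg/ADMA ratio -0.5830559 5.535204e-03 21
#>              Npx50 and Ang-(1-7)/Ang II ratio -0.6629804 1.054498e-03 21
```

Reading the output: the single noisy phantom recovers the encoded −7.18%
response to within a few tenths of a percentage point (the acceptance
script averages 20 noise seeds); the permeability phantom returns exactly
the planted leak count; and the cohort correlations show the expected sign
pattern — vasoconstriction goes with high permeability and low protective
ratios.

A complete per-animal pipeline (simulate → segment → T1-fit → Npx50 →
biochemistry → report) runs from one seeded YAML configuration:

```r
res <- run_pipeline(system.file("extdata", "demo_config.yaml",
                                package = "endoprofile"))
```

A thin command-line wrapper with `run`, `simulate`, `vasomotion`, `t1fit`
and `permeability` verbs lives at `inst/cli/endoprofile.R`.

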