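# gazewin

Offline analysis of **gaze-contingent moving-window** experiments on basic
facial-expression recognition.

In this paradigm an observer inspects an emotional face (happiness, sadness,
neutrality, fear, anger) while the display is masked except for a circular
aperture locked to their gaze: unrestricted viewing (NVR), a 5° window
admitting parafoveal + foveal input (PFFV), or a 2° foveal-only window (FV).
gazewin turns the raw outputs of such an experiment — 60 Hz gaze logs and
per-trial judgment records — into the full set of behavioral results:

* **Geometry** — visual-angle ↔ pixel conversion from a screen model
  (`pixels_per_degree()`, `aperture_diameter_px()`, `within_window()`), using
  the exact projection `2 d tan(θ/2)` and the horizontal pixel density.
* **Fixation detection** — dispersion-based spatiotemporal clustering
  (I-DT/EyeMMV style) with a running-centroid membership rule, spatial
  tolerance (default 40 px ≈ 1°), minimum duration (80 ms) and blink-gap
  handling, with a compiled core for million-sample logs
  (`detect_fixations()`, `segment_trials()`, `merge_binocular()`).
* **Judgment metrics** — accuracy at any grouping, row-stochastic confusion
  matrices, and ordinal-confidence analytics on the 5-point scale
  X = (1, 0.5, 0, −0.5, −1): mean μ = Σ pᵢXᵢ, Shannon entropy
  −Σ pᵢ log₂ pᵢ, and the Tastle–Wierman consensus
  Cns = 1 + Σ pᵢ log₂(1 − |Xᵢ − μ|/d_X), which is 1 under unanimity and 0
  under an even split between the scale extremes.
* **Inference** — Kruskal–Wallis with adjusted η² = (H − k + 1)/(n − k),
  Dunn's Bonferroni-corrected post hocs, paired Wilcoxon with matched-pairs
  rank-biserial ρ, and an a-priori noncentral-F power search
  (`required_sample_size()`).
* **Synthetic data** — a seeded generator (`simulate_study()`) that emulates
  the full three-arm study (54/59/50 participants, 30 balanced trials,
  binocular 60 Hz streams with planted fixations, condition-dependent
  log-normal timing, confusion and confidence templates), so the entire
  pipeline is testable end to end with known ground truth.

## Worked example

```r
library(gazewin)

scr <- screen_model_from_diagonal(1920, 1080, 23, 57)
scr
#> <screen_model> 1920 x 1080 px, 50.92 x 28.64 cm, viewed at 57.0 cm (37.51 px/deg)
aperture_diameter_px(scr, c(2, 5))   # FV and PFFV window diameters, px
#> [1]  75.03449 187.68631

required_sample_size(k = 3, effect_size_f = 0.25)
#> A-priori power: N = 159 (3 x 53), f = 0.25, alpha = 0.05 -> power 0.8049 (target 0.80)

# a reduced synthetic study: 10 participants per condition
cfg <- simulation_config(n_per_condition = c(NVR = 10, PFFV = 10, FV = 10))
sim <- simulate_study(cfg, seed = 1)
fx  <- pipeline_fixations(sim$gaze)      # merge eyes, detect fixations
an  <- pipeline_analyze(fx, sim$records) # tables + confusion + consensus + tests

an$accuracy_table                        # median % (IQR) per condition
#> # A tibble: 6 × 4
#>   scope      FV            NVR           PFFV
#>   <chr>      <chr>         <chr>         <chr>
#> 1 happiness  100 (100-100) 100 (83-100)  100 (100-100)
#> 2 sadness    67 (50-67)    100 (88-100)  83 (67-96)
#> 3 neutrality 83 (67-83)    100 (83-100)  83 (83-100)
#> 4 fear       100 (88-100)  100 (100-100) 83 (67-96)
#> 5 anger      100 (71-100)  92 (71-100)   100 (88-100)
#> 6 overall    83 (78-87)    92 (90-96)    90 (84-92)

dplyr::filter(an$stats$kruskal, scope == "overall", face_gender == "all")
#> # A tibble: 4 × 8
#>   scope   face_gender measure                  H    df    p_value eta_sq     n
#> 1 overall all         accuracy              9.07     2 0.0107      0.262    30
#> 2 overall all         inspection_time_s    25.8      2 0.00000249  0.882    30
#> 3 overall all         fixation_count       24.1      2 0.00000577  0.819    30
#> 4 overall all         fixation_duration_ms 25.8      2 0.00000249  0.882    30
```

Reading this output: accuracy drops under the foveal-only window (overall
median 83% vs 92% without restriction, driven by sadness), and all three
oculomotor measures separate the conditions strongly (Kruskal–Wallis
p ≪ 0.001 with large η²) — the planted FV > PFFV > NVR ordering. The
confidence report (`an$consensus`) gives per-expression mean, entropy, Cns
and the semantic label of the mean; `pipeline_report(an, "out/")` writes all
tables, confusion matrices and a JSON statistics report to disk.

A thin command-line wrapper over the same functions lives at
`inst/cli/gazewin.R` (`simulate | fixations | analyze`), configured by a
YAML/JSON file (example in `inst/extdata/run_config.yaml`).

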