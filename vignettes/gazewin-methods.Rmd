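---
title: "Methods: gaze-contingent moving-window analysis with gazewin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-contingent moving-window analysis with gazewin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazewin)
```

## The problem

In a gaze-contingent moving-window experiment, an observer inspects an
emotional face while the display is masked everywhere except a circular
aperture centered on their current gaze position. Shrinking the aperture from
unrestricted viewing (NVR) to the parafovea+fovea (PFFV, a 5° window) and to
the fovea alone (FV, a 2° window) controls how much facial information enters
per fixation. The behavioral questions are how this restriction changes
recognition accuracy, judgment confidence, and oculomotor effort (inspection
time, number of fixations, fixation duration) for the five basic expressions
happiness, sadness, neutrality, fear and anger.

gazewin implements the complete *offline* analysis for such an experiment:
aperture geometry, fixation detection from raw 60 Hz gaze logs, judgment and
confidence metrics, the non-parametric inferential layer, and a seeded
synthetic-data generator that makes the whole pipeline testable end to end
without access to any recorded dataset.

## Viewing geometry

All conversions between visual angle and screen pixels go through a
`screen_model` (resolution, physical panel size, viewing distance). A
centrally viewed angle $\theta$ projects to

$$\mathrm{px}(\theta) = 2\,d\,\tan(\theta/2)\cdot\frac{W_{px}}{W_{cm}},$$

with $d$ the viewing distance and $W_{px}/W_{cm}$ the *horizontal* pixel
density. Design choices:

* **Horizontal density as the reference.** On square-pixel panels the axis
  choice is immaterial; the constructor rejects panels whose horizontal and
  vertical densities differ by more than 20% unless explicitly overridden.
* **Full tangent, no small-angle approximation.** Exactness at 5° costs
  nothing.
* **Inclusive window boundary.** `within_window()` treats a sample exactly on
  the aperture rim as visible, with a sub-nanopixel slack so the convention
  survives floating-point rounding.

On a 23-inch 16:9 panel at 1920 × 1080 viewed from 57 cm, one degree spans
about 37.5 px and the 2° foveal aperture about 75 px. Note that the default
*detector* tolerance below is 40 px — a rounded operational value for "one
degree" on this class of hardware — and is deliberately not tied to the
geometry module: the spatial threshold of a dispersion detector is a tuning
parameter, not a derived quantity.

## Fixation detection

`detect_fixations()` implements sequential dispersion clustering with
spatiotemporal thresholds (the I-DT family, in the style of the EyeMMV
toolkit):

1. Invalid samples (tracking dropouts, non-finite coordinates) are skipped.
2. A valid sample joins the open cluster iff its Euclidean distance to the
   cluster's **running centroid** (recomputed after every accepted sample) is
   at most `tolerance_px` *and* the gap since the last valid member is at
   most `max_gap_ms`; otherwise the cluster closes and a new one starts at
   that sample.
3. On close, an optional secondary radius `secondary_tolerance_px` (≥ the
   primary; off by default) drops members farther than it from the final
   centroid and recomputes the centroid once.
4. Clusters whose span (last − first member timestamp) reaches
   `min_duration_ms` are emitted as fixations.

Parameter defaults and rationale:

| parameter | default | rationale |
|---|---|---|
| `tolerance_px` | 40 px | ≈ 1° on the target hardware; standard dispersion threshold |
| `min_duration_ms` | 80 ms | conventional lower bound for a true fixation |
| `max_gap_ms` | 100 ms | tolerates single-sample dropouts and short blinks at 60 Hz without splitting a fixation; configurable |
| `membership` | `"centroid"` | mean-point clustering; a `"first"`-point rule is available since dispersion implementations differ on this detail |

Duration is defined as last − first member timestamp with no half-sample
padding — a simple, stated, testable convention. Binocular logs are merged
before detection: per timestamp, the mean of the valid eyes, invalid only
when both eyes are invalid. Streams with fewer than two valid samples yield
an empty result rather than an error.

The detector core is compiled (Rcpp) because study-scale logs run to
millions of samples; its behavior is pinned, sample for sample, to an
independent pure-R greedy re-clustering oracle in the test suite.

## Judgment and confidence metrics

**Accuracy** is the proportion of trials whose judged emotion matches the
presented one, computed at any grouping (participant, condition, expression,
face gender). **Confusion matrices** are row-normalized counts with rows the
expected class and columns the judgment, so each presented row sums to 1.

Confidence ratings arrive on a 5-point scale and are mapped to the symmetric
numeric coding SA = 1, A = 0.5, N = 0, D = −0.5, SD = −1. For a response
distribution $p_i$ over scale values $X_i$:

* mean: $\mu_X = \sum_i p_i X_i$, mapped back to a semantic label through
  the intervals $(0.75, 1] \to$ SA, $(0.25, 0.75] \to$ A,
  $[-0.25, 0.25] \to$ N, $[-0.75, -0.25) \to$ D, $[-1, -0.75) \to$ SD
  (upper bounds inclusive exactly as stated, so $\mu_X = 0.75$ is "A");
* Shannon entropy: $\mathrm{Ent} = -\sum_i p_i \log_2 p_i$ (bits, with
  $0 \log 0 \equiv 0$);
* Tastle–Wierman consensus:
  $\mathrm{Cns} = 1 + \sum_i p_i \log_2\!\big(1 - |X_i - \mu_X|/d_X\big)$
  with $d_X = X_{max} - X_{min} = 2$.

Cns is 1 under unanimity and 0 when the mass splits evenly between the two
scale extremes; over this scale the formula is bounded in $[0, 1]$ (prose
descriptions of "−1 for complete disagreement" that circulate for this
measure do not follow from the formula, and the package follows the
formula). Consensus and entropy are complementary: within unimodal families
the ranks move in opposite directions, which the suite checks as rank
anticorrelation rather than as a universal theorem (it is not one — the mean
shifts too).

Likert distributions are pooled per condition × expression by default,
since per-trial group consensus is the target quantity; a per-participant
mode exists for robustness checks.

**Eye-movement aggregates** per participant × expression divide by the
number of presentations of that expression (6 in the standard 30-trial
design). For fixation duration two conventions exist and are both
implemented:

* `mean_per_fixation` (default): total duration / number of fixations;
* `total_per_presentation`: total duration / number of presentations.

The default is `mean_per_fixation` because reported per-condition magnitudes
of a few hundred ms alongside ~9–21 fixations over multi-second inspections
are only dimensionally consistent with a per-fixation average; the
per-presentation total is a dwell-time measure an analyst may prefer, hence
the switch.

## Inferential layer

Throughout, per-participant values are the units of analysis and all data
are treated as non-normal (these measures are typically right-skewed):

* **Kruskal–Wallis** (via `stats::kruskal.test`, midranks with tie
  correction) with the adjusted eta-squared effect size
  $\eta^2 = (H - k + 1)/(n - k)$, clipped at 0, anchors 0.01/0.06/0.14 for
  small/moderate/large. Fully tied inputs are reported as $H = 0$, $p = 1$.
* **Dunn's post hoc** on mean midrank differences with tie-corrected pooled
  variance; two-sided z tests, Bonferroni-adjusted
  $p_{adj} = \min(1, m\,p)$ with $m = k(k-1)/2$ (so per-test α ≈ 0.0167 at
  α = 0.05 for three groups).
* **Paired Wilcoxon signed-rank** for male-vs-female faces within condition:
  zeros dropped, exact null for ≤ 25 untied pairs, tie-corrected normal
  approximation otherwise; effect size is the matched-pairs rank-biserial
  correlation $\rho = (W^+ - W^-)/(W^+ + W^-)$ (the literature rarely states
  which "ρ" it reports; this choice is documented rather than asserted
  against any external value).
* **A-priori power**: the smallest total $N$, *balanced over k groups* (N a
  multiple of k, the G*Power convention for the one-way omnibus test), such
  that the noncentral-F power with $\lambda = f^2 N$, df $(k-1, N-k)$
  reaches the target. For $k=3$, $f=0.25$, $\alpha=0.05$, power 0.80 this
  gives $N = 159$; without the balanced constraint the crossing happens at
  158, which is why the constraint matters. (Effect sizes for this design
  are on the ANOVA $f$ scale; a "medium effect 0.25" quoted as Cohen's d in
  some reports corresponds to the $f$ computation here.)

`analyze_all()` crosses each measure (accuracy, inspection time, fixation
count, fixation duration) with each scope (overall, per expression, per face
gender), skipping — with a warning — any scope that lacks two conditions.

## The synthetic generator

`simulate_study()` emulates the three-arm design so that every pipeline
stage has planted ground truth:

* arm sizes 54/59/50 (NVR/PFFV/FV), 30 trials each over a balanced catalog
  (6 per emotion, 3 per gender × emotion);
* **inspection times** log-normal per condition, medians 4.51/10.90/19.64 s —
  log-normal because these are positive, right-skewed durations; `sdlog`
  0.55 was set once from the reported IQR-to-median ratios of such data;
* **fixation durations** log-normal, medians 356/520/794 ms, `sdlog` 0.18,
  snapped to the 60 Hz sample grid; fixations fill the drawn inspection time
  (the recorded time is the actual span, which slightly exceeds the draw —
  at most by one fixation plus one gap);
* **fixation positions** uniform over a central face-region box with
  consecutive centers ≥ 120 px apart (beyond twice the detector tolerance),
  per-sample Gaussian jitter of 3 px per axis — the precision class of a
  chin-rest 60 Hz tracker — and saccade gaps of 20–80 ms without samples;
* **judgments** drawn from per-condition 5 × 5 confusion templates,
  diagonal-dominant with foveal-only viewing degraded mainly for sadness
  (misread as neutrality 18% and fear 12% of the time) and anger;
* **confidence** drawn from per-expression Likert templates concentrated on
  the confident end, least so for sadness and neutrality;
* 2% of samples are flagged invalid; both eyes are emitted (the merged
  stream is what the detector sees).

Every participant draws from a seeded substream derived from the master
seed, so datasets are bit-reproducible and individual sessions can be
regenerated in isolation.

**What the generator does not emulate** — and what passing tests therefore
do not establish about real data: no between-participant trait variability
beyond sampling noise (real participant distributions are wider than the
simulated ones), no drift or calibration error, no smooth pursuit or
realistic saccade kinematics (gaps are simply sample-free), no
area-of-interest structure on the face (AOI analysis is out of scope), and
no dependence of confidence on correctness. The generator validates the
*machinery* — detection, aggregation, inference — not any behavioral claim.

## Numerical and testing choices

* Trial segmentation uses closed-open windows $[on, off)$; a sample exactly
  at an onset belongs to that trial.
* The power search floors at $N = k$ and reports an error above $N = 10^6$.
* Degenerate inputs are defined, not exceptional: all-tied Kruskal–Wallis
  gives $H=0$; all-zero Wilcoxon differences return a flagged undefined
  result; sub-threshold streams yield zero fixations.
* Test problem sizes: oracle equivalence on 500 random streams of ≤ 200
  samples; planted-fixation recovery over 1,000 seeded streams (expecting
  ≥ 99% exact count recovery and mean centroid error < 1 px at 3 px jitter);
  Kruskal–Wallis type-I calibration over 5,000 null replicates of 3 × 20
  observations (empirical rejection in [0.04, 0.06] at α = 0.05); exact
  Wilcoxon against full $2^n$ enumeration for n ≤ 10; and one full-size
  default study for the end-to-end condition-ordering check. These sizes
  balance statistical resolution against a test suite that runs in a few
  minutes.

## Limitations

The pipeline is strictly offline: it replays and analyzes logs, it does not
present stimuli or drive a tracker. Velocity-based (I-VT) detection, saccade
kinematics and AOI-based spatial analyses are out of scope. The consensus
measure is computed on pooled trials, which treats repeated trials of a
participant as exchangeable with trials of different participants; the
per-participant mode exists precisely to check sensitivity to that
assumption.
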