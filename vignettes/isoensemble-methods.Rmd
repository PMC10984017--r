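---
title: "Methods: models, parameters and design choices in isoensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in isoensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`isoensemble` implements the quantitative chain of a social-isolation
drinking study: dominance ranking, lick microstructure, pose-based social
contact detection, peri-event calcium analysis, pseudo-population decoding,
and cross-session ensemble overlap. This vignette documents the models and
the choices behind them: what is assumed, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open.

## Rank scoring

The tube dominance test yields, for each mouse, percent wins = 100 ×
(trials won) / (trials received against any cage mate), pooled over three
daily round-robin sessions. Rank 1 is the most dominant (highest percent
wins). Ties are resolved deterministically: first by head-to-head wins among
the tied mice, then by lexicographic mouse id. Ranks are therefore always a
permutation of 1..N, non-increasing in percent wins, and reproducible from
the trial list alone.

## Lick microstructure

A *bout* is a run of consecutive licks whose inter-lick interval never
exceeds `iliThresholdS`, kept only if it has at least `minLicks` licks.
Neither parameter has a single canonical value in the rodent licking
literature; the defaults — 1.0 s and 3 licks — are conventional, and both
are explicit arguments everywhere so the criterion is never hidden. Licks
are conserved by construction: every lick belongs to exactly one run, and
runs are either reported as bouts or discarded whole.

The condition contrast fits `value ~ condition * rank`. When every mouse is
measured under both conditions (the isolation-challenge design), the fit
uses a repeated-measures error structure, `Error(mouse/condition)` with
sum-to-zero contrasts: the condition and interaction terms are then tested
against the mouse-by-condition stratum, which is the error structure that
produces the small denominator degrees of freedom typical of within-subject
drinking studies, and with one rank level the condition F reduces exactly to
the squared paired t statistic. In the balanced designs the synthetic
cohorts produce, these tests coincide with Type III tests; for unbalanced
between-subject data the function falls back to a between-subjects fit.
Post-hoc condition comparisons within rank use Sidak adjustment by default.
Correlations against rank use the integer rank as regressor (configurable
to percent wins).

## Pose-based social contact

A frame counts as interaction when **both** hold: resident-head to
intruder-body distance ≤ 60 px, and approach angle ≤ 135°, where the angle
is measured at the resident's head between the heading vector (body → head)
and the head → intruder vector. Both comparisons are inclusive, which makes
boundary behavior deterministic. The 135° bound is read as an upper bound
on the approach cone — interaction requires the resident to be oriented
toward the intruder within a wide cone; the opposite reading (a
facing-away criterion) would label a resident walking away from a nearby
intruder as interacting, which contradicts the construct being measured.
The angle's vertex is placed at the head because the distance criterion is
also head-referenced.

Frames with missing keypoints never count as contact (tracking dropouts
must not fabricate interaction); they break runs unless bridged by
`mergeGapS` (default 0.2 s). Runs shorter than `minDurS` (default 0.5 s)
are dropped after merging. With both set to zero, the interval output
reproduces the raw per-frame rule exactly, which is how the implementation
is audited. Detection is monotone in both thresholds and invariant to
global rotation and translation of all keypoints.

## Peri-event calcium analysis

Activity is excerpted around events into fixed bins: baseline −5…0 s,
response 0…5 s, bin width 0.25 s (all configurable; these spans suit
trial-structured drinking with roughly one-minute access periods and
transients lasting a few seconds). Trials extending past the recording
edges are dropped and counted. Z-scoring is per neuron against the pooled
baseline across trials, with the sample SD: per-trial SDs over 20 baseline
bins are too unstable to normalize by. Baselines with SD below 1e-6 mark a
degenerate (constant) neuron, which is excluded rather than silently
producing infinities. The Z transform is invariant to per-neuron affine
transformations of the raw traces.

A neuron is *excited* by an event class when two criteria agree: a Wilcoxon
signed-rank test of the per-trial response-minus-baseline differences at
α = 0.05, and a standardized mean response `mean(d) / (sd(d)/√n)` of at
least +1.98 (inhibited: at most −1.98). The threshold 1.98 is the two-sided
5% normal critical value, so the magnitude criterion is itself a calibrated
test; the conjunction of the two correlated tests is slightly conservative
(measured ≈ 0.042 flagged on null populations at α = 0.05, within two
binomial standard errors of nominal). Reading the ±1.98 bound against the
*raw* mean response Z instead would make the criterion scale with trial and
bin counts and flag essentially nothing on null data, which would leave the
rule uncalibratable; the raw mean is still reported alongside. Event
alignment for drinking responses uses bout onset (first lick of a bout),
the event whose count the drinking analyses correlate against.

Functional clustering standardizes each neuron's trial-averaged time
course, computes correlation distance, and applies Ward linkage
(`ward.D2`), with k = 9 by default and a mean silhouette width reported so
the choice of k can be audited. Cluster ids are relabeled by descending
peak of the cluster-mean time course, which makes labels stable under
neuron permutation. Enrichment of groups within clusters is normalized by
group size — `(n_cg/N_g) / Σ_g'(n_cg'/N_g')` — so a group that contributed
more neurons overall is not spuriously "enriched" everywhere; the
accompanying chi-square tests cluster × group independence.

## Pseudo-population decoding

Neurons recorded in different animals are combined into pseudo-simultaneous
populations: per resample and class, every neuron contributes
`nTrialsPerClass` of its own trials drawn with replacement, stacked into a
balanced pseudo-trial × neuron matrix. A pseudo-trial is an artificial
conjunction — trial-to-trial noise correlations between neurons are
destroyed by construction, which is a known property of this design, not a
bug.

Two leakage pitfalls shaped the implementation, and both are worth knowing
about when decoding real recordings:

1. **Fold leakage.** If pseudo-trials are resampled freely and folds are
   drawn at the pseudo-trial level, held-out pseudo-trials reuse real
   trials seen in training, and null data decodes far above chance
   (≈ 0.7 in our measurements). Folds are therefore fixed at build time at
   the *real-trial* level: each neuron's trials are partitioned into
   `folds` subsets, and a pseudo-trial assigned to fold f draws only from
   fold-f trials.
2. **Normalization leakage.** Z-scoring each event class against its own
   pooled baseline gives each neuron a small class-specific offset (all of
   a class's trials share the same baseline estimate), which is decodable
   on otherwise chance-level data (≈ 0.55). Decoding features therefore
   use class-agnostic normalization: whole-trace per-neuron Z
   (`zscoreTraces`) with per-trial baseline subtraction
   (`tensorFeatures(..., baselineSubtract = TRUE)`). Per-class baseline
   Z-scoring remains the right normalization for classification and
   population contrasts, where no classifier sits downstream.

The decoder is a linear SVM with C = 1 (the conventional choice for this
design), features standardized with training-fold statistics only.
Defaults: 20 pseudo-trials per class, 100 resamples, 5 folds. The shuffle
control permutes labels within folds (stratified permutation): permuting
across folds leaves folds class-imbalanced in complementary train/test
directions and biases the null measurably below chance.

One further property matters for interpretation: even with fold separation,
the mean cross-validated accuracy of *one* finite null recording is not
exactly 0.5 — the recording's realized per-neuron class differences are
genuinely decodable structure. Chance calibration is therefore a statement
about the ensemble of recordings, and the package's calibration checks
marginalize over independent synthetic recordings (25 recordings × 4
resamples), comparing the grand mean against 0.5 with the standard error
computed across recordings. Group comparisons of decoding accuracy use
Kruskal–Wallis with pairwise rank-sum post-hocs (reducing to the unpaired
rank-sum test for two groups).

## Cross-session ensembles

The identity map records which within-session neuron corresponds to which
global identity. The co-registration rate divides the number of identities
present in *every* listed session by the mean per-session neuron count.
Ensemble overlap between two conditions is computed over neurons
co-registered across the two sessions being compared (not across all
sessions) — this maximizes usable cells and the denominator is recorded in
the output. Excited and inhibited ensembles are analyzed separately, with
direction an explicit parameter. The overlap comparison is a 2×2
chi-square on (overlapping, non-overlapping) counts, without Yates
correction by default (matching large-sample usage; the flag is recorded in
the output), and equals the textbook Σ(O−E)²/E to 1e-9.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions for every calibration and recovery check.

* **Tournaments** follow a Bradley–Terry model: mouse i has latent skill
  −s·(i−1) with skill gap s = 3 by default, at which adjacent ranks are
  separated with ≈ 95% win probability and assigned ranks almost always
  recover the latent order.
* **Lick streams** place a Poisson number of bouts into the session with
  between-bout gaps guaranteed ≥ 2 s — twice the default segmentation
  threshold — so ground-truth bouts are unambiguous to any criterion
  between the within-bout interval (0.15 s) and the gap floor. Lick counts
  per bout are `minLicks + Poisson`.
* **Cohorts** plant expected total alcohol licks
  `600 + mouseIntercept + 60·(rank−1) + SI·(150 + 80·(rank−1))` with a
  between-mouse intercept SD of 100 licks (≈ 15% CV, typical inter-animal
  variability); the subordinate escalation is carried by +1 lick per bout
  per rank step under isolation and the dominant escalation by bout rate,
  with sessions of 60 min. These magnitudes mirror the strong
  rank-dependent escalation the assay is known for; at 16 mice they put
  the single-cohort rank correlation around r² ≈ 0.25 before isolation,
  and water streams carry no planted effect. All effect sizes are exposed
  in `cohortConfig()`, since lick-rate distributions for any particular
  cohort are not canonical.
* **Pose sessions** plant episodes with margin: inside an episode the
  intruder sits 18–50 px ahead within a ±100° cone; outside, it is either
  far (≥ 75 px) or behind (≥ 160°). Keypoint jitter (SD 0.5 px, truncated
  at 2.5 SD) cannot flip the 60 px / 135° rule across these margins, so
  detector output can be compared to ground truth exactly.
* **Calcium populations** add an instantaneous-rise, exponential-decay
  transient (τ = 1 s) at each event on a Gaussian noise floor — the
  simplest model with the timescale structure the peri-event analysis
  assumes. Amplitude is expressed in Z units of the noise floor. Response
  ensembles for different event classes are disjoint.
* **Identity maps** mark each of one session's worth of identities as
  fully tracked with probability `coregistrationRate`; remaining
  per-session slots are filled by identities spanning strict session
  subsets, so every session has exactly the requested neuron count.

What the generator does **not** emulate: photobleaching and motion
artifacts, calcium indicator nonlinearity, correlated noise across neurons,
within-session drinking dynamics (satiety), pose identity swaps, or
imperfect cell registration (the identity map is error-free). Passing the
recovery checks therefore demonstrates that the estimators are correct and
calibrated under their stated assumptions — not that those assumptions hold
in any particular recording.

## Numerical choices and degenerate inputs

Seeds: every generator draws from a local RNG seeded per call and restores
global RNG state; identical config + seed gives bit-identical output
through the whole chain, including the command-line interface. Degenerate
cases are explicit: empty lick streams give zero bouts and a missing
licks-per-bout; constant-baseline neurons are excluded with their ids
recorded; degenerate headings (head coincident with body) give missing
angles; zero-F ANOVA cells (identical values) report F = 0 rather than
0/0; empty contrast cells raise a degrees-of-freedom error.

Problem sizes used by the test suite and the acceptance script — 1000-neuron
null populations, 200-neuron planted populations with 20 trials, 25 × 4
decoder resamples, 100 seeded cohorts of 16 mice — were chosen to put
binomial standard errors well inside the tolerances being checked.

## Known limitations

The ANOVA machinery targets the balanced or nearly balanced designs the
assay produces; heavily unbalanced within-subject data would need a
mixed-model treatment. The bout criterion and the peri-event windows are
conventions, not estimates; conclusions that depend on them should be
checked across a range (both are plain arguments). Pseudo-population
decoding destroys noise correlations, so its accuracies quantify the
information in trial-averaged single-neuron statistics, not in the joint
population response.
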