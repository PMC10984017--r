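# isoensemble

Social factors shape alcohol drinking: in group-housed mice, social rank
predicts how much alcohol an animal drinks, and social isolation escalates
drinking most strongly in subordinates. Studies of this phenomenon combine
tube-test dominance ranking, lick-by-lick analysis of two-bottle-choice
drinking, pose-tracking of resident–intruder interactions, cellular-resolution
calcium imaging of amygdala–cortical populations, and population decoding.
`isoensemble` implements that full quantitative chain as a tested, reusable R
package, together with a seeded synthetic-cohort generator that plants ground
truth for every stage — so each estimator can be audited against what was
actually put in.

## What the package computes

**Behavior**

- *Rank scoring*: percent wins = 100 × (trials won) / (trials received),
  pooled over 3 days of round-robin tube tests; rank 1 = dominant
  (`percentWins`, `assignRanks`).
- *Lick microstructure*: bouts are runs of licks whose inter-lick interval
  stays within a threshold (default 1 s) with a minimum run length
  (default 3 licks); summaries report total licks, bout count and licks per
  bout (`segmentBouts`, `microstructureSummary`).
- *Condition contrasts*: condition × rank ANOVA (repeated-measures when each
  mouse is measured under both conditions), Sidak post-hocs, and rank–drinking
  correlations (`conditionContrast`).

**Pose geometry** — a frame counts as social interaction when the
resident-head-to-intruder-body distance is ≤ 60 px *and* the approach angle
(between the resident's heading and the head→intruder vector) is ≤ 135°
(`headBodyDistance`, `approachAngle`, `detectInteraction`).

**Neural** — peri-event alignment into fixed time bins (baseline −5…0 s,
response 0…5 s, 0.25 s bins), baseline Z-scoring per neuron
(Z = (x − μ_baseline)/σ_baseline), responsive-neuron classification
(Wilcoxon signed-rank on per-trial response−baseline differences at α = 0.05
*and* a standardized mean response beyond ±1.98), population time-course
contrasts, Ward/correlation-distance functional clustering, and
group-enrichment chi-square tests (`alignEvents`, `zscoreBaseline`,
`classifyResponses`, `populationMeanResponse`, `clusterFunctional`,
`clusterEnrichment`).

**Decoding** — pseudo-simultaneous populations: per resample, each neuron
contributes trials drawn with replacement independently per class; a linear
SVM (C = 1) is cross-validated with folds fixed at the real-trial level so
held-out pseudo-trials never reuse trials seen in training
(`buildPseudopopulation`, `decodePopulation`, `shuffleControl`,
`compareDecoders`).

**Ensembles** — cross-session identity bookkeeping, co-registration rates,
overlap of event-responsive ensembles, and 2×2 chi-square comparisons of
overlap proportions (`coregistrationRate`, `ensembleOverlap`, `overlapChi2`).

## Worked example

```r
library(isoensemble)

cfg    <- cohortConfig(nCages = 4, seed = 7001)   # 16 mice, 1 h sessions
cohort <- genCohort(cfg)                          # tournaments + lick streams
summ   <- cohortSummaries(cohort)                 # ranks, bouts, licks/bout

alc <- subset(summ, spout == "alcohol")
mouseMean <- aggregate(totalLicks ~ mouse + rank, alc, mean)
cor.test(mouseMean$rank, mouseMean$totalLicks)
```

```
	Pearson's product-moment correlation
data:  mouseMean$rank and mouseMean$totalLicks
t = 1.895, df = 14, p-value = 0.07894
sample estimates:
      cor
0.4518135
```

Lower-ranked mice drink more (the planted structure; at n = 16 a single
cohort's correlation is noisy — across 100 seeded cohorts the mean
pre-isolation r² is ≈ 0.26, which `scripts/acceptance.R` recomputes). The
isolation contrast on licks per bout shows the planted rank × isolation
interaction clearly even in one cohort:

```r
alc$rankGroup <- ifelse(alc$rank <= 2, "dominant", "subordinate")
d <- data.frame(mouse = alc$mouse, condition = alc$condition,
                rank = alc$rankGroup, meanLicksPerBout = alc$meanLicksPerBout)
conditionContrast(d, value = "meanLicksPerBout")$anova
```

```
            term df     sumSq        F            p
1           rank  1  7.884994 50.79274 5.116611e-06
2      condition  1 16.397716 53.72784 3.733356e-06
3 condition:rank  1  6.930434 22.70787 3.016401e-04
```

Subordinates escalate their drinking through more licks per bout
(interaction p = 3e-4), the microstructural signature that distinguishes
them from dominants, who escalate through bout number.

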