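# egoflow

Simulation and analysis of wide-field optic-flow fMRI experiments, entirely
on synthetic data with known ground truth.

Human visual cortex contains a set of motion-sensitive areas (V6, MT, MST+,
V3A, CSv, an intraparietal motion region) that differ in how strongly they
prefer *coherent* optic flow — the globally structured motion produced by
self-motion (egomotion) — over spatially incoherent motion. Experiments
probing this use wide-field "star field" stimuli (translational, circular,
radial, spiral, random and static dot fields), event-related fMRI with a
first-level GLM, functional localizers (including the ipsilateral-response
criterion that separates MST+ from MT), and a simple summary statistic per
region: the motion-coherence coefficient

```
MC / MI  =  mean(beta_translational, beta_circular, beta_radial, beta_spiral) / beta_random
```

computed per hemisphere and averaged (mean ± SEM across hemispheres). A
coefficient of 1 means coherent and random motion drive a region equally;
values near 3 indicate strong egomotion selectivity; negative values arise
when random motion suppresses a region below its fixation baseline.

Raw data for such experiments are typically not public, so `egoflow` is
built around *parameter recovery*: it simulates the stimuli, the designs and
the BOLD data with planted condition amplitudes, then runs the full analysis
chain — HRF convolution, discrete-cosine high-pass, AR(1) prewhitening, F
contrasts, FDR/cluster-extent thresholding, ROI definition and the MT/MST+
split, regional profiling, MC/MI, repeated-measures ANOVA, and phase-encoded
retinotopy (stimulus-frequency F ratio, response phase, visual field sign) —
and checks that the planted truth comes back out.

## Worked example

Simulate a 3-s radial flow clip at the low speed tier and summarize it:

```r
library(egoflow)

p <- speedTierProfile("low")          # 1-20 deg/s, calibrated mean 18
clip <- simulateFlowClip("radial", duration = 3, profile = p, seed = 7)
s <- summarizeStimulus(clip)
sprintf("density %.4f speed %.2f maxAge %.3f", s$meanDensity, s$meanSpeed, s$maxAge)
#> [1] "density 0.0401 speed 17.87 maxAge 0.350"
s$reversalTimes
#> [1] 0.5 1.0 1.5 2.0 2.5
```

The realized density sits on the 0.04 dots/deg² target, the mean dot speed
is within 1% of the calibrated 18 deg/s, no dot outlives 350 ms, and the
global direction reverses exactly every 500 ms.

Recover a planted V6-like coherence coefficient (coherent amplitude 0.70,
random 0.25, ratio 2.8) from 26 simulated hemispheres, six runs each, with
AR(1) noise:

```r
cp <- recoverCoherence(0.70, 0.25, nHemispheres = 26, seed = 11)
cp
#> CoherenceProfile: MC/MI = 2.795 +/- 0.021 over 26 hemispheres
head(hemisphereTable(cp), 3)
#>   hemisphere        mc        mi    ratio
#> 1       left 0.6999200 0.2488673 2.812422
#> 2      right 0.7087219 0.2624232 2.700683
#> 3       left 0.7180661 0.2671021 2.688359
```

The across-hemisphere mean lands on the planted 2.8 to within its SEM: the
whole estimation chain (design, convolution, whitening, regional profiling,
ratio statistics) is unbiased at this noise level.

`runFullPipeline(seed = 1, outputDir = "out")` chains everything — stimulus
summaries, design checks, the noiseless identity, the three-area recovery
study and a planted retinotopy map — and writes event tables, a sample clip
and a JSON report.

## Package layout

| Area | Functions |
|---|---|
| Stimuli | `makeFieldGeometry`, `speedTierProfile`, `dotSpeed`, `dotSize`, `velocityField`, `stepFlow`, `simulateFlowClip`, `summarizeStimulus` |
| Designs | `buildFF3DDesign`, `buildLocalizerDesign`, `buildRetinotopyDesign`, `writeEventTable` |
| Synthetic BOLD | `makeHRF`, `canonicalHRF`, `makeROISpec`, `makeNoiseModel`, `simulateROITimeseries`, `simulateVolume`, `writeSyntheticVolume` |
| GLM | `buildDesignMatrix`, `fitGLM`, `fContrast`, `motionVsStaticContrast`, `fdrClusterThreshold`, `percentSignalChange` |
| ROIs | `defineROIsFromPeaks`, `splitMtMst`, `regionalProfile` |
| Coherence | `mcMiCoefficient`, `rmAnovaOneway`, `rmAnovaRegionByCondition`, `pairwiseHolmPosthoc` |
| Retinotopy | `periodicFRatio`, `responsePhase`, `phaseMap`, `fieldSign`, `circularSlope` |
| Orchestration | `recoverCoherence`, `runFullPipeline`, `plantedCoherenceTable` |

The methods vignette (`vignettes/egoflow-methods.Rmd`) documents the models,
the calibration of the speed law, the whitening approximation, all numerical
conventions, and what the synthetic studies can and cannot show about real
data.
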