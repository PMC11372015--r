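# petidif

Automated image-derived input function (IDIF) extraction and kinetic
modelling for dynamic brain ^18^F-FDG PET, in R.

## The problem

Quantitative FDG kinetic modelling needs the arterial input function (AIF)
— the tracer concentration in arterial blood over the scan. Arterial
sampling is invasive; reading the blood signal from the images is the
alternative, but in a brain-only field of view the available blood pools
(carotid arteries, venous sinuses) are small enough that partial volume
effects bias any naive vessel VOI. `petidif` implements a fully automated
extraction that sidesteps explicit partial-volume correction:

1. every brain voxel's time-activity curve is screened with a Morlet
   continuous wavelet transform (integer scales 1–100, per-curve relative
   coefficient threshold 0.5) to locate its peak;
2. curves survive only if their peak exceeds `(1 - a1) * meanPeak` and
   their 55–65 min tail is below `((1 - a2) * meanTail) + meanTail`, where
   `meanPeak`/`meanTail` average the cohort's 10 largest peaks and 10
   smallest tails;
3. survivors are split by Ward hierarchical clustering into an arterial
   (early-peaking) and a venous (late-peaking) family, at threshold levels
   `a1 = 0.4, 0.5, 0.6` whose cluster averages are combined;
4. the automatic IDIF concatenates the arterial bolus peak with the venous
   tail on a 2 s grid, after advancing the venous curve by the measured
   arterio-venous delay and smoothing 4 s around the junction.

Thin arteries preserve bolus timing but lose amplitude; large venous
sinuses preserve amplitude but lag by ~6 s. The hybrid keeps the best of
both.

The package also provides the irreversible two-tissue compartment model
(`C_T = (1-v_b)[(K1k2/(k2+k3)) e^{-(k2+k3)t} + K1k3/(k2+k3)] ⊗ C_p + v_b C_b`)
with bounded Levenberg–Marquardt fitting, the net influx rate
`Ki = K1*k3/(k2+k3)`, Patlak graphical analysis (40–65 min window),
voxel-wise parametric maps, evaluation metrics (AUC error, NRMSE, peak
delays, FWHM quadrature, resolution-degradation studies, map regression),
and a synthetic dynamic head phantom with ground truth for validation.

## Worked example

```r
library(petidif)

# the clinical 65-min protocol: 62 frames
sched <- buildFrameSchedule(list(
  c(2, 10), c(30, 2), c(4, 10), c(8, 30), c(4, 60), c(5, 120), c(9, 300)))
nFrames(sched)        # 62
totalTime(sched) / 60 # 65

# simulate a dynamic head phantom at 3.83 mm FWHM and extract the IDIF
ph <- buildPhantom(phantomSpec(seed = 101), sched)
ex <- extractIdifAuto(ph$image)
ex$levels[["a1=0.5"]]
#> ClusterResult: 15 arterial rows (TTP 39.4 s), 59 venous rows (TTP 45.7 s)

aucError(ex$idif,   ph$truth@trueAif)  # -0.99  (hybrid IDIF vs truth, %)
aucError(ex$artery, ph$truth@trueAif)  # -23.9  (artery-only: partial volume)
aucError(ex$vein,   ph$truth@trueAif)  # -0.48  (vein-only: full recovery)
peakDelay(ex$vein, ex$artery)          #  4     (arterio-venous delay, s,
                                       #         on the 2 s analysis grid)

# reference blood pool and kinetics
da <- referenceDaIdif(ph$image, ph$truth@daCenter)   # 10 mm cylinder VOI
round(kiMacro(0.173, 0.137, 0.053), 3)               # 0.048 mL/cm3/min
```

The numbers read as follows: the artery-only input function underestimates
the true AUC by ~24% (its 5 mm vessels sit at ~1.3× the image FWHM), the
vein-only curve is essentially unbiased but delayed, and the hybrid
automatic IDIF lands within 1% of the ground-truth AUC while keeping the
arterial peak timing.

A command-line interface wrapping these functions is installed as
`exec/autoaif` (`autoaif simulate | extract-tacs | peaks | cluster | idif |
da-idif | evaluate`).

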