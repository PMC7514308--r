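# chorusentropy

Detection of fish choruses in marine passive acoustic recordings with
the complexity-entropy (C-H) method, alongside the three classical
ecoacoustic indices it is usually compared against.

## The problem

Long-term hydrophone deployments in shallow coastal waters record massed
nocturnal calling of sciaenid fishes ("choruses") concentrated around
500-2500 Hz, with activity peaks near dawn (01:00-05:00) and dusk
(17:00-21:00).  Detecting those choruses automatically is hard because
the same band and the bands below it also carry vessel noise
(tonal stacks plus broadband cavitation at ~10-200 Hz and above),
impulsive sediment-transport noise (~10-70 Hz), and colored background
noise.  Energy-based acoustic indices (ACI, ADI, BI) confuse these
sources with biophony; the C-H method instead measures the *temporal
structure* of the waveform and is largely blind to unstructured noise,
whatever its loudness.

## The method

A time series is symbolized with Bandt-Pompe ordinal patterns: each
window of `d` samples (delay `tau`) is mapped to the permutation that
sorts its values in descending order (ties resolved towards the earlier
sample), giving a probability distribution `P` over the `d!` patterns.
Two quantifiers are computed from `P` (natural logarithms throughout):

- normalized permutation entropy
  `H = S[P] / ln(d!)`, with `S` the Shannon entropy — the randomness of
  the fluctuations, in [0, 1];
- statistical complexity
  `C = Q_J[P, P_e] * H`, where `Q_J` is the Jensen-Shannon divergence
  to the uniform distribution `P_e`, normalized by its maximum (attained
  at a point mass) — the amount of correlation structure.

On the C-H plane, white noise sits at the far right (H near 1, small C)
and periodic signals at the far left (small H, high C); all reachable
points lie between two boundary curves `C_min(H)` and `C_max(H)`.
Chorusing adds quasi-periodic pulse trains to the waveform, so chorus
hours move left and up — towards the position of a pure sine — while
vessel or sediment noise leaves H and C almost unchanged.  Per-hour
values of H, C, ACI, ADI, BI are min-max normalized over a deployment
and thresholded at 0.5 (above for C/ACI/ADI/BI, below for H) to declare
detections, which are scored against annotated truth with a confusion
matrix (accuracy = (TP+TN)/n, error rate = (FP+FN)/n).

The package implements all of this plus: calibrated Welch power spectral
densities and band SPLs (dB re 1 µPa) for the 50-200 Hz noise band and
the 500-2500 Hz chorus band, Pearson correlation of indices against
chorus-masked band SPL by diel group, a plain PCM WAV reader/writer, and
a seeded synthetic soundscape generator that renders labeled 24-h scenes
(compressed to 10 s per hour) so the whole pipeline is testable without
field recordings.

## Worked example

Render the "intense dawn and dusk chorusing with sediment noise" preset,
analyze each hour, and evaluate detection against the generator's truth:

```r
library(chorusentropy)
sc  <- render_scene(scene_presets(seed = 1)$a)
res <- analyze_scene(sc)
head(round(res, 3), 8)
#>   hour     H     C     ACI   ADI       BI spl_50_200 spl_500_2500
#> 1    0 0.971 0.064 515.811 2.833 5700.693    110.019      107.084
#> 2    1 0.846 0.269 512.224 2.833 8055.081    110.439      115.143
#> 3    2 0.806 0.316 509.594 2.833 9087.291    108.928      117.401
#> 4    3 0.798 0.322 514.587 2.833 8830.266    110.848      117.417
#> 5    4 0.802 0.320 515.390 2.833 8943.154    111.197      117.359
#> 6    5 0.841 0.276 507.955 2.832 8167.527    111.541      115.227
#> 7    6 0.970 0.065 519.467 2.833 6093.073    110.635      107.044
#> 8    7 0.970 0.065 512.816 2.833 6140.999    111.119      107.016

evaluate_run(res, sc$truth, chorus_hours = c(1:5, 17:21))
#> chorus_evaluation
#>   H   accuracy 1.000 (TP 10 FP 0 TN 14 FN 0)
#>   C   accuracy 1.000 (TP 10 FP 0 TN 14 FN 0)
#>   ACI accuracy 0.250 (TP 4 FP 12 TN 2 FN 6)
#>   ADI accuracy 0.500 (TP 10 FP 12 TN 2 FN 0)
#>   BI  accuracy 1.000 (TP 10 FP 0 TN 14 FN 0)
#>   CH  accuracy 1.000 (TP 10 FP 0 TN 14 FN 0)
#>   r vs masked chorus-band SPL: H -1.00, C 1.00, ACI -0.47, ADI 0.21, BI 1.00
#>   C-H plane containment: 24/24 inside
```

Reading the hourly table: during chorus hours (01:00-05:00 here) H drops
from ~0.97 to ~0.80 and C rises from ~0.06 to ~0.32 — the hours move
left on the C-H plane — while the chorus-band SPL rises by ~10 dB.  ACI
barely moves (the dense chorus is quasi-steady in each bin) and ADI is
pinned near its ceiling `ln 17 = 2.833`; both misdetect.  On this quiet
preset BI also detects perfectly; its failures appear once vessel noise
enters the 10-3500 Hz band it integrates (preset `b`).

A shell front end wraps the same functions:

```sh
Rscript scripts/chorus-tool.R simulate --preset a --seed 1 --out scenes/
Rscript scripts/chorus-tool.R analyze  --wav 'scenes/*.wav' --out results.csv
Rscript scripts/chorus-tool.R plane    --d 6 --out curves.csv
```

## Layout

- `R/` — ordinal symbolization, complexity quantifiers and limit
  curves, Welch SPL, acoustic indices, detection/evaluation, synthetic
  soundscapes, WAV I/O
- `tests/testthat/` — unit, property and end-to-end suites with
  brute-force oracles
- `vignettes/chorus-detection.Rmd` — the methods vignette
- `scripts/` — `chorus-tool.R` (CLI) and `acceptance.R`
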