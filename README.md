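# circacp

Unsupervised detection of sleep and wake onset times (S/WOTs) from
unlabelled actigraphy. The package is aimed at sleep and circadian-rhythm
researchers who have days-to-weeks of wrist- or hip-worn accelerometer
counts — possibly from devices with incompatible count scales — and no
polysomnography or diary labels to train a classifier on.

## Method

Detection is a two-stage procedure:

1. **Cosinor rhythm fit.** The series is summarised by
   `r(t) = mes + amp·cos((t − φ)·2π/T)` with the period fixed at
   `T = 1440` min, solved exactly as a harmonic regression. The fitted
   curve's lower 18% of range is dichotomized as nocturnal, giving one
   rough wake→sleep and sleep→wake transition per circadian cycle.
2. **Gamma change-point search.** Within a search window around each
   rough transition, counts are modelled as `y_k ~ Gamma(θ_k, ξ)` with a
   common shape and a scale that switches once. The onset is the index
   minimising the modified information criterion

   `MIC(k) = −2 log L1(θ̂₁, θ̂₂) + 2 log n + λ(2k/n − 1)² log n`,  λ = 50,

   whose quadratic penalty discourages solutions near window edges. A
   second round rebuilds the windows from midpoints between first-round
   change points and re-searches once.

Because the change-point statistic depends on the counts only through
scale ratios, the detector transfers across devices without retuning.
Supporting machinery: non-wear screening (4-day minimum, 120-min zero-run
rule), Calinski–Harabasz error flagging (`ch_pro − ch_cos < 100`),
marker-based Bland–Altman validation, and a zero-inflated-Gamma cohort
simulator with known ground truth.

## Worked example

```r
library(circacp)

sim <- simulate_cohort(n_subjects = 5, seed = 11)   # 7 days per subject
events <- detect_sw(sim$activity)
head(events[, 1:5], 4)
#> # A tibble: 4 × 5
#>   subject_id kind  timestamp           minutes_since_midnight source
#>   <chr>      <chr> <dttm>                               <dbl> <chr>
#> 1 S01        WOT   2024-01-01 06:18:00                    378 circacp
#> 2 S01        SOT   2024-01-01 22:48:00                   1368 circacp
#> 3 S01        WOT   2024-01-02 06:01:00                    361 circacp
#> 4 S01        SOT   2024-01-02 21:53:00                   1313 circacp
```

Each row is one detected onset: `minutes_since_midnight` is the event
time on the analysis scale (SOTs between midnight and noon get +1440 so
one night's bedtimes stay contiguous). The per-subject QC table shows the
Calinski–Harabasz comparison; subject S05's refined segmentation barely
improves on the raw cosinor dichotomy (`ch_delta` 14 < 100), so it is
flagged as likely containing detection errors:

```r
attr(events, "qc")
#> # A tibble: 5 × 8
#>   subject_id passed reason n_events ch_cos ch_pro ch_delta flagged
#> 1 S01        TRUE   ""           14  1788.  2182.    394.  FALSE
#> 2 S02        TRUE   ""           14  1535.  2621.   1086.  FALSE
#> 3 S03        TRUE   ""           14  1506.  2694.   1188.  FALSE
#> 4 S04        TRUE   ""           14  1621.  2696.   1075.  FALSE
#> 5 S05        TRUE   ""           14  1902.  1916.     14.2 TRUE
```

Agreement with the (noisy, incomplete) self-report markers, per event
kind — bias is the mean estimate−marker difference in minutes, `loa_*`
the 95% limits of agreement, `mae` the median absolute error:

```r
matches <- match_markers(events, sim$markers)
summarize_agreement(matches)
#> # A tibble: 2 × 9
#>   kind  n_events n_pairs match_rate   bias sd_diff loa_low loa_high   mae
#> 1 SOT         35      29      0.829 -1.66     8.87   -19.0     15.7     7
#> 2 WOT         35      32      0.914  0.375   10.7    -20.7     21.4     8
```

`plot_bland_altman(matches)` draws the corresponding agreement plot, and
`autoplot(detect_subject(...))` shows one subject's activity trace with
shaded detected sleep periods.

A command-line front end is installed with the package
(`exec/circacp`): `circacp simulate | detect | validate --help`.

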