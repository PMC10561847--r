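# kuratap

Beat perception is usually studied with metronomes, but natural sound
rarely ticks. `kuratap` generates *quasi-periodic* auditory beat stimuli
from an ensemble of phase-coupled Kuramoto oscillators and provides the
complete analysis chain for sensorimotor-synchronization (finger-tapping)
experiments against them. It is aimed at auditory psychophysicists and
timing researchers who want a reproducible stimulus generator, a
principled beat-window segmentation, and the tapping metrics needed to
phenotype how people extract beats from onset-density cues.

## The model in brief

Forty oscillators advance as

    dphi_i/dt = omega_i + k R sin(psi - phi_i)

where `R exp(i psi) = mean_j exp(i phi_j)` are the complex order
parameters (phase coherence `R` in [0, 1], mean angle `psi`), intrinsic
frequencies `omega_i` are Gaussian around the base tempo, and `k` is the
coupling. Integration is forward Euler at `dt = 0.016` s; each wrapped-phase
cycle completion of an oscillator emits a sound onset. Coupling can be
constant (calibrated strong/medium/weak presets) or steered by a bang-bang
feedback controller toward a target coherence. The analysis chain then:

1. segments each stimulus into beat windows from cycle completions of the
   mean angle `psi` (with a 2x-mean-period gap constraint for uncoupled
   stimuli);
2. computes inter-tap intervals (ITI) and normalized ITIs (nITI = ITI /
   design beat period, so beat tapping has mean 1), tap-section adaptation
   curves with `A exp(B t)` fits, and a practice-trial screening rule;
3. maps taps and onsets to within-beat phases and compares them with
   circular statistics (mean phasors, Rayleigh uniformity test,
   Watson-Wheeler two-sample test);
4. phenotypes participants by k-means (k = 5) on per-trial
   (log10 coherence, mean nITI) points into Regular / Hybrid / Fast
   tapping groups, splits frequent-tapping trials into dense vs sparse by
   phase-portrait RMS dispersion (threshold 0.1065 s), and fits a
   factorial regression of mean raw ITI on coherence x tempo x group;
5. ships a synthetic tapper cohort (17 Regular / 24 Hybrid / 9 Fast by
   default) so the full pipeline is testable end to end without human
   data.

See `vignettes/kuratap-methods.Rmd` for the methods in detail.

## Worked example

```r
library(kuratap)

cfg <- sim_config(coupling_mode = "feedback", r_target = 0.97, k_init = 2.5,
                  base_tempo = 92, duration_beats = 22, seed = 1)
sq <- simulate_sequence(cfg, condition_label = "strong")
sq
#> <stimulus_sequence> (unnamed): strong, 92 BPM, 880 onsets over 14.35 s, mean |R| = 0.895

grid <- segment_sequence(sq)
grid
#> <beat_grid> 22 beat centers spanning [0.02641, 14.33) s, mean period 0.6522 s

trial <- tap_trial("demo", "stim", grid$centers, base_period = 60 / 92,
                   condition_label = "strong")
trial
#> <tap_trial> demo x stim: 22 taps, mean nITI = 0.997

order_parameters(grid_phases(sq$onsets$onset_time_s, grid))
#> <phasor> R = 0.8978, phi = -0.07858 rad, n = 878
```

A strongly coupled 22-beat sequence at 92 BPM produces 880 onsets whose
time-mean coherence is 0.895 (the controller spends the first beats
locking the ensemble, then holds |R| near 0.97). Segmentation recovers 22
beat centers ~0.652 s apart; an ideal tapper placed at every center has
mean nITI 0.997 — within half a percent of 1, the normalization identity.
The pooled onset phasor (R = 0.90) shows how tightly onsets concentrate
within beat windows under strong coupling.

The full pipeline — stimulus batch, segmentation, synthetic cohort,
metrics, phasors, clustering, groups, dense/sparse, regression, with all
artifacts and a JSON manifest — is one call:

```r
res <- run_pipeline("out", seed = 1)
table(res$groups$group)
```

A command-line wrapper with `generate`, `segment` and `run` subcommands
lives at `inst/cli/kuratap.R`.

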