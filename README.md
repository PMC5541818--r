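# multirsvp

EEG target detection with multi-stream rapid serial visual presentation
(RSVP), for brain–computer interface researchers and for anyone who needs a
fully simulatable, testable P300 detection pipeline.

In an RSVP experiment, images flash at 4 Hz while EEG is recorded; a rare
target image elicits a P300 deflection ~300–500 ms after onset, and a
single-trial classifier scores each 1000 ms epoch. The multi-stream paradigm
presents two or three copies of the image sequence simultaneously, the
copies delayed by 750 ms steps (three frames), so an attended target is
viewed and scored multiple times. Per-image *interest scores* are fused by
averaging across streams:

- **HDCA** (hierarchical discriminant component analysis) cuts the epoch
  into K = 40 windows of T = 25 ms (N = T·f_s samples) and scores
  `y_k = (1/N) Σ_n Σ_i w_ki · x_i[(k−1)N + n]`, with per-window spatial
  filters `w_k` from Fisher's linear discriminant and a logistic temporal
  combination `y_IS = Σ_k v_k y_k`.
- **SWLDA** (stepwise linear discriminant analysis) decimates each channel
  to 60 points (14 channels → an 840-point feature vector) and selects
  features by forward entry (p < 0.10) with backward removal (p > 0.15)
  on a least-squares discriminant.
- Evaluation is threshold-free AUC under image-grouped, stratified tenfold
  cross-validation, with exact paired Wilcoxon signed-rank comparisons.
- The gaze model and the analytic miss probability
  `P_miss = 1 − (1 − P_target)^N` quantify the paradigm's cost: while the
  gaze travels between streams, N ≈ 5–6 (dual) or 8–9 (triple) base images
  go unattended.

A bundled synthetic EEG generator (AR(1) background, 50 Hz mains component,
planted P300s whose amplitude shrinks and latency grows across repetitions)
makes the entire chain testable without recorded data. Recordings can also
be written/read as EDF plus a BIDS-style events TSV.

## Worked example

```r
library(multirsvp)

# triple-RSVP session: 5 blocks x 200 images, 20 targets/block, 4 Hz,
# streams delayed by 0 / 750 / 1500 ms
sched <- generate_schedule(n_streams = 3, n_blocks = 5, images_per_block = 200,
                           targets_per_block = 20, seed = 1)
gz  <- derive_gaze(sched)                        # deterministic attention shifts
rec <- simulate_recording(sched, gz, fs_hz = 600, seed = 1)
ep  <- preprocess(rec, sched)                    # 0.5-60 Hz, epoch, baseline
cv  <- kfold_cv(ep, method = "hdca", k = 10, seed = 1)
cv
#> <rsvp_cv> hdca, 10-fold (seed 1, grouped by image)
#>   single mean AUC 0.8102 (sd 0.0552)
#>   dual   mean AUC 0.8469 (sd 0.0333)
#>   triple mean AUC 0.8326 (sd 0.0406)

paired_wilcoxon(cv$fold_aucs[, "dual"], cv$fold_aucs[, "single"])$p.value
#> [1] 0.02734375
```

Reading the numbers: fusing the left and right streams raises the mean
cross-validated AUC from 0.81 to 0.85 (exact signed-rank p = 0.027 across
folds). Adding the third stream does *not* help here — the default template
attenuates and delays the third P300 (4 µV at 400 ms versus 6 µV at
300 ms), the physiological effect of the observer anticipating the
reappearance, and at that strength the third score adds as much noise as
signal. With equal-strength repetitions the single < dual < triple ordering
is essentially deterministic; see the methods vignette
(`vignettes/multirsvp-methods.Rmd`) for the full analysis.

The miss-probability side of the trade-off:

```r
miss_probability(0.1, c(6, 9))   # dual, triple geometry at P_target = 0.1
#> [1] 0.4685590 0.6125795
```

An end-to-end run from a single config (writes scores, per-fold AUCs and a
JSON summary):

```r
res <- run_pipeline(rsvp_config("dual", n_blocks = 2L, seed = 7L), out_dir = "run1")
```

A thin command-line wrapper with `run`, `simulate` and `miss-curve`
subcommands is installed at `inst/cli/multirsvp`.

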