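# depthbreathe

Non-contact breathing analysis and sleep apnea detection from depth-camera
recordings.

Consumer depth sensors (MS Kinect v2, Intel RealSense SR300 / R200 / D415 /
D435) can watch a sleeper's chest instead of the belts, thermistors and
cannulas of clinical polysomnography (PSG). `depthbreathe` implements the
full signal chain that turns a stack of depth frames into an apnea report,
and a synthetic-data generator so the whole chain is testable without any
recording hardware:

1. **ROI frame differencing.** Over a rectangular chest region of interest
   with *R* rows and *S* columns, each pair of consecutive depth frames
   yields one motion sample

   d(n) = (1 / RS) · Σᵢ Σⱼ ( D₍ₙ₊₁₎(i,j) − Dₙ(i,j) ),  n = 0 … N−2.

2. **Band-pass filtering.** A zero-DC windowed-sinc FIR filter
   y(n) = Σₖ b(k) d(n−k) with cut-offs f₁ = 0.01 Hz and f₂ = 1 Hz keeps the
   breathing band and rejects the mean level and high-frequency sensor
   noise; optional second-order Savitzky–Golay smoothing follows.

3. **Resampling.** Depth sensors deliver 3–45 FPS with jitter; a cubic
   spline through the timestamped samples is evaluated on a uniform 10 Hz
   grid (the PSG respiration rate).

4. **Window features.** Overlapping 10 s windows advancing by 0.1 s give,
   per window, the dominant in-band frequency of the Hann-windowed spectrum
   and the sample standard deviation.

5. **Unsupervised classification.** A two-neuron competitive (winner-take-
   all / Kohonen) network is trained on z-scored features: for each
   presented vector xₙ the nearest weight vector w_l moves by
   w_l ← w_l + η (xₙ − w_l) with a linearly decaying learning rate. The
   cluster whose centroid has the smaller standard-deviation feature is
   labelled *apnea* — breathing cessation collapses the signal's local
   variance. A K-means baseline (`train_kmeans()`) is provided for
   comparison.

6. **Evaluation.** Per-sample confusion-matrix metrics — sensitivity
   TPR = TP/(TP+FN), specificity TNR = TN/(TN+FP), precision
   PPV = TP/(TP+FP), accuracy ACC = (TP+TN)/(TP+TN+FP+FN), and
   F1 = 2·PPV·TPR/(PPV+TPR) = 2TP/(2TP+FP+FN) — plus event-level detection
   (merged apnea runs ≥ 5 s, any-overlap rule) and events-per-hour, the
   clinical severity index. Repeated random 70/30 splits over training
   segments give cross-validated summaries.

## Worked example

```r
library(depthbreathe)

# simulate a 10-minute recording with three apnea events (R200 profile)
events <- sample_apnea_schedule(600, n_events = 3, seed = 2)
rec <- simulate_recording(600, breathing_profile(rate = 0.27, amplitude = 6,
                                                 noise_sd = 1.2),
                          events, sensor = sensor_profile("r200"), seed = 2)

sig <- extract_breathing_signal(rec$sequence)   # 10 Hz breathing signal
dominant_frequency(amplitude_spectrum(sig))
#> [1] 0.269928

fit <- apnea_workflow(sig, rec$annotations, seed = 2)
fit$events
#> <event_report> 3/3 annotated events detected; 18.0 predicted events/hour
fit$metrics
#> Sensitivity (TPR): 86.5%
#> Specificity (TNR): 100.0%
#> Precision   (PPV): 100.0%
#> Accuracy    (ACC): 95.6%
#> F1 score        : 92.8%
```

The dominant frequency recovers the simulated 0.27 Hz breathing rate
(16 breaths/min). All three simulated events are found; the per-sample
metrics are computed over the training segments (each event plus 25 s of
surrounding normal breathing), where the F1 score summarises how closely
the 10 Hz label track matches the annotated event spans.

`autoplot(sig, rec$annotations)`, `plot_features()` and
`plot_classification()` visualise the signal, the feature plane and the
label track; `tidy()` / `glance()` methods return model and report
summaries as tibbles. A command-line front end over the same functions is
installed at `system.file("cli", "depthbreathe", package = "depthbreathe")`
with subcommands `simulate`, `extract`, `features`, `train`, `classify`,
`evaluate`, `crossval` and `run`.

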