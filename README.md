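# emdetect

Segment-wise detection of narrowband marine mammal calls (blue-whale-style
"A"/"B" calls) in passive acoustic monitoring recordings, by empirical mode
decomposition (EMD) and energy-spectrum-entropy features.

## The method

A mono recording is cut into fixed windows (200 ms by default). Each window
`X(t)` is decomposed by EMD,

    X(t) = Σᵢ IMFᵢ(t) + rf(t),

and the total energy `E_total = Σᵢ Σₜ IMFᵢ²(t) + Σₜ rf²(t)` distributes over
the modes as energy ratios `E_IMFᵢ = 100 · Σₜ IMFᵢ²(t) / E_total`. The mode
with the highest average ratio over all windows — the competent IMF (CIMF) —
is the analysis channel. Hilbert analysis of that mode gives its
instantaneous frequency `F(t) = (1/2π) dθ/dt` and, by accumulating each
sample's energy at its frequency bin, a marginal frequency distribution
`MF(f)` (percent of `E_total` per 1 Hz bin), from which an averaged main
frequency band and main domain are derived.

Four per-window detector features are computed on the CIMF:

| Feature | Definition | Units |
|---|---|---|
| ERD  | energy ratio `E_IMFᵢ` | % |
| ESD  | max marginal bin within the main domain | % |
| ESED | entropy of `P_j = E_ij / E_total` over a frequency range | nats |
| CESED | entropy of the min–max scaled, renormalized in-domain energies | nats |

Thresholding a feature series (median, median + M·MAD, or the ROC-optimal
cutoff closest to the (0,1) corner) yields binary detections, evaluated
against labels with confusion counts, TPR/FPR, ROC curves, trapezoidal AUC
and accuracy/precision/recall/F1. A labeled synthetic two-zone recording
generator provides ground-truthed test data; see the methods vignette
(`vignettes/emdetect-methods.Rmd`) for the model, parameter and polarity
details.

## Worked example

```r
library(emdetect)

lr <- synth_generate(synth_config(seed = 1))  # 100 s, A zone 39 Hz / B zone 13 Hz
lr
#> <labeled_recording> 100.0 s @ 4800 Hz, 500 segments (176 positive)

run <- detect_calls(lr, polarity = "auto")    # EMD -> CIMF -> features -> ROC
run
#> <detection_run> 500 segments, CIMF 1, domain 1~50 Hz
#>   avg IMF energy ratios (%): 57.36 23.34 7.16 1.65 0.10 ...
#>   ERD   threshold    70.06  AUC 0.5530  acc 67.00%  prec 53.46%  rec 48.30%  F1 50.75%
#>   ESD   threshold    8.556  AUC 0.5735  acc 66.40%  prec 52.13%  rec 55.68%  F1 53.85%
#>   ESED  threshold     1.66  AUC 0.5654  acc 65.40%  prec 51.18%  rec 36.93%  F1 42.90%
#>   CESED threshold    2.959  AUC 0.6798  acc 65.40%  prec 50.70%  rec 61.36%  F1 55.53%
```

Reading the output: the first mode carries 57% of the average energy and is
selected as the CIMF; its averaged marginal spectrum concentrates below
50 Hz (the main domain), where both call types live. Each detector is then
thresholded at its ROC-optimal cutoff in its informative direction
(`polarity = "auto"`). On these moderate-noise conditions the
concentrated-entropy detector (CESED) separates call from no-call windows
best by AUC — the shape of the in-domain spectrum is more informative than
raw energy (ERD/ESD) or unnormalized entropy (ESED).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "emdetect", package = "emdetect"))')
Rscript $CLI simulate --outdir out --seed 1
Rscript $CLI detect   --input out/recording.wav --labels out/labels.csv --outdir out
Rscript $CLI evaluate --features out/features.csv --labels out/labels.csv --outdir out
```

`simulate` writes a float32 WAV plus a `segment,label` CSV; `detect` writes
feature, detection and metric CSVs plus a run log; `evaluate` recomputes
ROC points and metrics (median and ROC-optimal thresholds) from saved
features.

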