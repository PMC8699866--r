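# pcgLVDD

Heart-sound (phonocardiogram, PCG) analysis for screening left-ventricular
diastolic dysfunction (LVDD). LVDD changes the spectral content of the
second heart sound: in log-spectrograms the S2 energy of affected hearts
stops near 150 Hz while healthy controls extend to about 200 Hz. The
package implements the full screening pipeline around that signature, for
biomedical signal-processing researchers who want a tested, self-contained
reference implementation:

* **synthetic PCG simulation** with exact four-state ground truth
  (S1 → systole → S2 → diastole), class-dependent S2 spectral ceilings and
  cohort generation (the emulated study shape is 30 vs 41 subjects,
  five-minute recordings at 8000 Hz);
* **preprocessing**: anti-aliased resampling to 1000 Hz, translation-
  invariant wavelet denoising (Daubechies-6, level-dependent universal
  threshold), peak normalisation `S_n / max |S_n|`;
* **segmentation**: a logistic-regression hidden semi-Markov model
  (multinomial emissions over four envelope features at 50 Hz, Gaussian
  state durations, exact duration-constrained Viterbi in C++), followed by
  1.6 s S1-onset-aligned framing with two-period spacing;
* **spectrogram imaging**: STFT with a 256-sample Hanning window
  (`S(t,f) = sum_tau s(tau) w(tau - t) e^{-j 2 pi tau f}`), log power,
  128×128×3 images in [0, 1];
* **augmentation**: five audio-domain transforms (pitch up/down, stretch
  slow/fast, trim silence; 5 images per frame) and a per-class DCGAN
  (generator: dense latent projection to 8×8×512 then stride-2 5×5
  transposed convolutions to 128×128×3 with Tanh; discriminator mirrored
  with Leaky ReLU and a sigmoid scalar; Adam lr 2e-4, beta1 0.5, batch 64);
* **classification**: a compact CNN (3×3 convs 64/32/16 with ReLU and 2×2
  max-pooling, FC 128 → 100 with dropout 0.5, softmax; Adam lr 1e-4) with
  subject-wise 10-fold cross-validation and Acc/Se/Sp metrics
  (`Acc = (TP+TN)/(TP+TN+FP+FN)`, `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
  LVDD positive);
* **evaluation**: the train-on-generated/test-on-real (TSTR) similarity
  protocol, the expansion-coefficient sweep, and a pooled two-sample
  t-test from printed summary statistics.

The neural-network primitives (im2col/GEMM convolutions, transposed
convolutions, max-pooling, batch-norm, Adam) are implemented in
C++/RcppArmadillo with R orchestration and are gradient-checked in the
test suite.

## Worked example

Simulate a small two-class cohort, segment it, image the frames and train
the classifier with subject-wise cross-validation:

```r
library(pcgLVDD)

cfg  <- pcgSimConfig(duration = 30, noiseSnr = 25)
rec  <- simulateRecording(cfg, subjectId = "demo")
rec
#> SimulatedPCG: 240000 samples @ 8000 Hz (30.0 s), subject demo, label control

pp     <- preprocessRecording(rec)          # 1000 Hz, denoised, normalised
seg    <- trainSegmenter(lapply(simulateCohort(2, 2, cfg, seed = 77),
                                preprocessRecording))
states <- segmentStates(pp, seg)
states
#> StateSequence: 140 runs, 30000 samples @ 1000 Hz (35 cycles)
segmentationAccuracy(states, pp@trueStates)
#> [1] 0.9643667

frames <- extractFrames(pp, states)         # 1.6 s, S1-onset aligned
images <- framesToSpectrograms(frames)
dim(imageData(images, 1))
#> [1] 128 128   3
```

The per-sample segmentation accuracy (~0.96 here) is measured against the
simulator's exact ground truth; each image is a 128×128×3 log-spectrogram
in [0, 1]. `runPipeline(pipelineConfig(smoke = TRUE), "runs/001")` chains
every stage — simulation through DCGAN augmentation, cross-validation and
TSTR — at desk scale and writes `report.json`;
`inst/cli/pcg-lvdd.R` is a thin command-line wrapper around it.

The summary t-test utility reproduces cohort-table p-values from printed
summaries, e.g. peak E-wave velocity, 73.81 ± 26.60 (n = 30) vs
63.25 ± 14.07 (n = 41):

```r
r <- summaryTTest(73.81, 26.60, 30, 63.25, 14.07, 41)
round(c(t = r$t, df = r$df, p = r$p), 3)
#>      t     df      p
#>  2.165 69.000  0.034
```

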