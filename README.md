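# hfdeeg — Higuchi fractal dimension analysis of multichannel EEG

`hfdeeg` analyses group differences in EEG signal complexity with the
Higuchi fractal dimension (HFD), for studies that compare two groups of
subjects — the motivating design is mathematics experts versus novices
watching long, naturalistic math demonstrations — on a high-density
montage. Because raw EEG of such studies is rarely redistributable, the
package includes a calibrated synthetic cohort generator, so the whole
chain is reproducible and testable from a single seed:

1. **Synthetic cohort** — power-law (fractional-Brownian-motion-like)
   signals per channel with a controllable fractal dimension, a group
   effect localized to configurable channels during task (absent at
   rest), subject-level random variation, and a 129-channel montage
   (124 EEG + 5 ocular/cardiac auxiliaries).
2. **HFD features** — whole-signal or windowed HFD per channel
   (optimized C++ core, validated against a naive reference
   implementation to 1e-10).
3. **k_max tuning** — sweep of the estimator's key hyperparameter with
   the channel max-minus-min spread criterion and plateau rule.
4. **Channel statistics** — expert−novice ΔHFD per channel (double mean
   over presentations, then subjects), one-sided Welch t-tests on
   subject means, top-k ranking, resting-state and
   algebraic-vs-geometric null controls, topographic value export.
5. **Classification** — expert/novice prediction under three
   cross-validation schemes (pooled subject-presentation pairs,
   subject-specific, presentation-specific) with a fixed classifier grid
   (kNN, linear SVM, decision tree, AdaBoost), ten-fold CV over three
   seeds, and a full-montage vs standard-10/20-subset comparison.

## The estimator

For a series of length $N$, interval $k$ and phase $m \le k$:

$$L_m(k) = \frac{N-1}{M k^2} \sum_{i=1}^{M}\left|x(m+ik)-x(m+(i-1)k)\right|,
\quad M=\lfloor (N-m)/k \rfloor,$$

$L(k)$ is the mean over phases, and HFD is the slope of $\log L(k)$
versus $\log(1/k)$ for $k = 1..k_{\max}$: about 1 for smooth signals, 2
for uncorrelated noise. See `vignettes/hfd-eeg-methods.Rmd` for the full
methods account.

## Worked example

The numbered scripts under `analysis/` run a desk-scale study (12 + 12
subjects, 2 presentation pairs, 24 EEG channels, 256 Hz; the group
effect, +0.15 FD for novices, sits on channels X1–X4, outside the
standard montage subset):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_tune_kmax.R
Rscript analysis/03_extract_features.R
Rscript analysis/04_group_contrasts.R
Rscript analysis/05_classification.R
```

Stage 4 prints the channel contrast (abridged):

```
top 10 channels by |expert - novice| mean HFD:
 channel       delta      p_value significant
      X4 -0.12250029 4.857675e-08        TRUE
      X3 -0.10762040 1.722733e-07        TRUE
      X2 -0.09333688 7.578749e-06        TRUE
      X1 -0.09274653 2.329884e-05        TRUE
      S6  0.02666643 9.246200e-01       FALSE
 ...
4 of 24 channels significant at p < 0.05 (effect sits on X1, X2, X3, X4)
resting-state control: 0 of 24 channels significant
```

Exactly the four configured effect channels are recovered (delta is
expert − novice, so the novice-positive effect appears negative), and
the resting recordings — which carry no group effect by construction —
show none. Stage 5 then reports:

```
                scheme presentation     algorithm mean_accuracy
  subject_presentation         <NA>    linear_svm     0.9825926
      subject_specific         <NA>    linear_svm     0.9750000
montage comparison: full 24-channel 0.915 vs standard subset 0.629
```

With this strong, localized effect the classifier generalizes well even
to unseen subjects; dropping the high-density channels (where the effect
lives) costs nearly thirty accuracy points — the mechanism by which a
standard low-density montage underperforms.

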