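# jdnet — joint-distribution-entropy functional networks from epoched EEG

`jdnet` builds functional connectivity networks from short, epoched,
multichannel EEG — the kind of recording produced by rapid cognitive
tasks, where each subject contributes a second or so of post-stimulus
signal per epoch. Classical nonlinear coupling estimators need long
stationary series; joint distribution entropy (JDistEn) does not, which
makes it attractive for comparing patient and control groups (e.g. mild
cognitive impairment vs healthy ageing) on task EEG. The package provides
the complete analysis chain plus a synthetic cohort generator for
validation when clinical recordings cannot be shared.

## The method

Per subject, channels × samples × epochs at sampling rate $f_s$:

1. **Preprocess** — drop the pre-stimulus samples, average across epochs,
   band-filter with a zero-phase (two-pass) Butterworth cascade
   (high-pass order 4 at 9 Hz, low-pass order 8 at 34 Hz), and rescale
   each channel to $[0,1]$.
2. **Couple** — for every channel pair: delay-embed each channel
   ($m = 2$, $\tau = 1$), form intra-channel distance matrices
   $D_\varphi$ with the max-spread norm, combine them into the joint
   distance matrix $JD = J - \sqrt{(J-D_1)\circ(J-D_2)}$, histogram its
   off-diagonal entries with Doane's bin count, and take the normalized
   Shannon entropy
   $\mathrm{JDistEn} = -\tfrac{1}{\log_2 B}\sum_t \rho_t\log_2\rho_t
   \in [0,1]$ as the coupling weight.
3. **Network** — keep the strongest 10% of node pairs as edges (fixed
   density, so every subject has the same edge count; 813 edges at 128
   channels), then summarize: clustering coefficient $C$, characteristic
   path length $L$, mean eccentricity, and the small-world quotient
   $Q = (C/C_{\mathrm{rand}})/(L/L_{\mathrm{rand}})$ against ten
   uniform-random reference graphs of identical size.
4. **Compare** — per metric, a Jarque–Bera normality gate chooses between
   the pooled-variance t-test and an exact Wilcoxon rank-sum test
   (permutation-exact, ties handled via midranks); Chauvenet and IQR
   outlier screens are reported. Significance at 5%, no multiple-testing
   correction across the four metrics.

The methods vignette (`vignettes/jdisten-networks.Rmd`) documents every
formula, default and numerical convention, and what the synthetic
generator does and does not emulate.

## Worked example

```r
library(jdnet)

# a synthetic two-group cohort: 13 weakly vs 14 strongly coupled subjects
spec <- cohort_spec(channels = 16L, epoch_len = 110L, prestim = 16L,
                    between_a = 0.0, between_b = 0.6, seed = 20240L)
res  <- run_cohort(generate_cohort(spec), pipeline_config(seed = spec$seed))

head(res$metrics[, c("id", "group", "clustering", "path_length", "q")], 3)
#>    id group clustering path_length         q
#> 1 S01     A  0.1458333    1.666667 25.362626
#> 2 S02     A  0.2625000    1.533333  4.628983
#> 3 S03     A  0.2291667    1.666667  7.273345

res$comparisons[, c("metric", "mean_a", "mean_b", "test", "p")]
#>         metric    mean_a    mean_b    test            p
#> 1   clustering 0.2076923  0.406994       t 1.118694e-06
#> 2  path_length 1.7505495  1.194728 ranksum 6.381398e-06
#> 3 eccentricity 2.6250000  1.464286       t 5.807535e-06
#> 4            q 9.6201537 51.521836 ranksum 3.301376e-04
```

Each metrics row is one subject's network summary (component size and the
random-reference means are also returned). In the comparison table the
weakly coupled group A shows markedly lower clustering and small-world
quotient: its strongest couplings fall on scattered, noise-chosen pairs,
while group B's between-module mixing concentrates the top-density edges
into connected, triangle-rich blocks. That is the coupling structure
injected by the generator, recovered through the full chain of entropy
coupling, fixed-density thresholding and gated testing.

The numbered drivers under `analysis/` run the same study as a
reproducible workflow (simulate → couple/graph → compare → null
calibration) and leave their tables under `results/`.

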