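# orthopop

Linear population decoding of orthographic stimuli from visual neural
responses.

## What this package is for

When a primate looks at printed letter strings, does a high-level visual
cortical population (such as inferior temporal cortex) already contain an
*explicit* — that is, linearly decodable — representation of orthographic
content, before any reading experience?  `orthopop` implements the complete
analysis chain for that question, for neuroscientists who have (or want to
simulate) site x stimulus x repetition firing-rate tensors:

* **Stimuli** — four-letter words and one-vowel pseudowords rendered as
  binary glyph images under size/case/position variations, with per-string
  mean bigram frequency and pixel-level letter reflectivity
  (R_H, R_V, ΔR = R_H − R_V over all 325 letter pairs).
* **Synthetic populations** — a seeded generator of response tensors with
  letter-by-position tuning, Poisson repetition noise, two response windows
  (70–170 / 170–270 ms), a small planted weakly word-selective
  subpopulation (|d′| < 0.5), and optional mirror-symmetric tuning, so every
  analysis is testable without recorded data.
* **Decoding** — a 30-task battery (20 invariant letter, 8 invariant bigram,
  2 word-classification tasks) of ridge-logistic readouts with stratified
  ten-fold cross-validation, site-count sweeps, and support for external
  feature matrices on identical fold plans.
* **Behavioral metrics** — balanced accuracy (HR + (1 − FAR))/2, sensitivity
  d′ = Z(HR) − Z(FAR), ten-bin bigram-frequency behavioral signatures, and
  the noise-adjusted consistency
  ρ̃(m, p) = ρ(m, p) / √(ρ(m, m) ρ(p, p)) with split-half reliabilities,
  including leave-one-subject-out ceilings.
* **Single sites** — selectivity d′ with a bootstrap significance test,
  exact binomial tests for selective fractions and hemispheric bias, the
  sparsity index SI(x) = (1 − A(x))/(1 − 1/N) with A(x) = E[x]²/E[x²] plus
  noise-preserving uniform and one-hot null simulations, and Moran's I
  spatial autocorrelation on 10x10 electrode grids with permutation tests.
* **Encoding models** — cross-validated reconstruction of string responses
  from single-letter responses (full four-slot, best-substring, and
  bag-of-letters models) with noise-adjusted fit.
* **Mirror symmetry** — a cross-position-validated 26-way letter decoder,
  pairwise decoder similarity r_IT, and its dependence on ΔR.

The methods vignette (`vignettes/orthopop-methods.Rmd`) documents every
model, formula, default and numerical choice.

## Worked example

An end-to-end run on a synthetic population (120 sites, 10 repetitions,
100 words + 100 pseudowords and the full 624-image letter set; a few
minutes on one CPU):

```r
library(orthopop)
cfg <- run_config(out_dir = "demo_run", seed = 42)
run_pipeline(cfg)
report("demo_run")
```

```
== orthopop run report ==
stimuli: 1824 images (1200 strings, 624 letter images)
screens: 120/120 visually driven, 120 reliable letter tuning
decoding battery: 30 tasks
  letter_A                         0.998
  letter_L                         1.000
  ...                                   (18 more letter tasks, 0.92-1.00)
  bigram_AN                        0.986
  ...                                   (7 more bigram tasks, 0.89-1.00)
  word_classification_base         0.830
  word_classification_invariant    0.938
consistency: decoder-pool rho~ = 0.431 (ceiling median 1.035)
single sites: 13/120 selective (binomial p = 0.0072), Moran's I = -0.070 (p = 0.68), median SI letters 0.14 positions 0.09
encoding: median rho~ full_4 0.93, best_3 0.90, bag 0.49 (full>bag p = 0.000999)
mirror symmetry: right-vs-left bin p = 0.00155
```

Reading the numbers: the linear readout classifies held-out words versus
pseudowords at 0.83 balanced accuracy, and its pattern of per-bin errors
correlates positively (ρ̃ = 0.43) with the simulated reference behavior,
below the subject-to-pool ceiling (≈1.0) — on synthetic data the decoder
shares the frequency-linked error structure only partially, since the
generator's conjunctive terms are random rather than corpus-shaped.  About
11% of sites are weakly word-selective (close to the 10% planted fraction;
binomial p = 0.0072 against a 5% false-positive rate), with no spatial
clustering on the electrode grids (Moran's I = −0.07, permutation
p = 0.68).  String responses reconstruct from position-correct letter
responses (median noise-adjusted ρ̃ = 0.93) far better than from
position-shuffled ones (0.49).  Letter pairs with high
horizontal-versus-vertical reflectivity (like b/d) are more confusable for
the 26-way decoder than low-ΔR pairs (one-tailed p = 0.00155).

Smaller building blocks work standalone:

```r
si <- sparsity_index(c(3, 1))          # 0.4: A = 0.8, N = 2
b  <- render_string("b", "lower", "medium")
d  <- render_string("d", "lower", "medium")
reflectivity(b, d, "horizontal")       # 1: exact mirror pair in this font
```

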