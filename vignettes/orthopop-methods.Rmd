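---
title: "Linear readout of orthographic information from visual neural populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthopop methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

A high-level visual cortical population (such as the inferior temporal
cortex, IT) can be asked a precise computational question: does a *linear*
readout of its firing rates suffice to support orthographic tasks —
recognizing letters and bigrams invariantly, and classifying four-letter
strings as English words versus pseudowords?  `orthopop` implements the full
analysis chain for that question: orthographic stimulus construction, a
battery of cross-validated linear decoders, signal-detection behavioral
metrics with a noise-adjusted consistency statistic, single-site
selectivity/sparsity/topography statistics, letter-to-string encoding
reconstruction, and a mirror-symmetry analysis relating pixel-level letter
reflectivity to decoder confusions.

Because recorded data cannot ship with a package, every analysis is
exercised end-to-end on a synthetic population generator
(`simulate_population()`) whose sole contract is to realize the statistical
structures the analyses assume.  The generator is first-class, tested code,
not a fixture.

# Stimuli

Strings are four-letter words and pseudowords (exactly one vowel and three
consonants; "y" counts as a consonant).  Each string is rendered under six
variations — sizes 0.8/1.2/1.6 degrees of visual angle per letter and
upper/lower case — on a square canvas (default 32 px/degree, 8-degree
canvas).  Inter-letter spacing is proportional to letter size, so four-letter
strings span 3.2/4.8/6.4 degrees.  Single letters are rendered at the four
string slots (26 letters x 4 positions x 6 variations = 624 images).  The
default base set of 308 + 308 strings yields 3696 images.

Rendering uses an embedded 5x7 monospaced bitmap font defined in code, which
makes every mask bit-exact and deterministic; resizing uses pixel-centre
sampling so that it commutes with reflections.  A second face
(`ortho_font("mirror")`) constructs `d`, `p`, `q` as exact reflections of
`b`, giving the mirror-symmetry analysis a pair that is a perfect horizontal
mirror by construction.

Orthographic typicality is indexed by mean bigram frequency: the mean of the
three adjacent ordered-bigram counts-per-million of a string.  The bigram
table is computed once from the packaged 750-entry four-letter word list and
frozen as a TSV in the package; it stands in for corpus-derived statistics so
that no download is ever needed.  Absolute frequencies therefore differ from
any published corpus, but the induced *ordering* of strings — the only thing
the analyses use — behaves the same way.

Pixel reflectivity between letters a and b along an axis is the
intersection-over-union of foreground pixels after reflecting one glyph
about the centre of its own bounding box and aligning the two bounding-box
centres.  Coordinates are kept in centred half-pixel units, which makes the
measure exactly symmetric in its arguments and parity-safe.  The identity
pair is excluded everywhere (alphabets are biased towards horizontal
self-symmetry); 26 letters give 325 pairs with
$\Delta R = R_H - R_V$.

# The synthetic population

Each simulated site responds to a string as

$$\mu = b + g\,\Big[\sum_{k=1}^{4} w_k(\ell_k)\,p_k \;+\;
  \lambda \sum_{k=1}^{3} c(\ell_k, \ell_{k+1}, k)\Big]$$

where $b$ is the baseline rate (10 spikes/s), $g$ the gain (20 spikes/s,
with lognormal site-to-site heterogeneity), $w_k(\ell)$ the site's letter
tuning at slot $k$, $p_k$ a position envelope with a contralateral gain
(1.5 for slots contralateral to the site's hemisphere), and $c(\cdot)$
fixed random conjunctive terms for adjacent letter pairs with weight
$\lambda$ (`nonlinearity_weight`, default 0.2).  Letter responses use the
single corresponding term, so with $\lambda = 0$ a string's expected rate
equals the sum of its four letter-at-slot rates minus three baselines — an
exact identity used as a test oracle.

Two modelling choices deserve comment:

* **Letter tuning comes from glyph shape.**  $w_k(\ell)$ is a positively
  rectified random projection of the letter's bitmap embedding.  Tuning
  across slots mixes a shared component (weight = `position_tolerance`,
  default 0.5) with slot-specific components, so tuning is
  position-tolerant but *not* separable into letter x position factors.
  Separable tuning would be a degenerate world: a fixed permutation of slots
  could be absorbed by regression coefficients and the "bag of letters"
  reconstruction model would spuriously match the position-specific model.
  Mirror-symmetric sites (fraction `mirror_symmetric_fraction`, default 0.1)
  project the *symmetrized* glyph (average of the bitmap and its left-right
  flip), so horizontally mirrored letters like b/d drive them identically in
  expectation — the planted mechanism behind the $\Delta R$ analysis.

* **Letter statistics are matched between classes.**  By default words are
  restricted to one-vowel words and pseudoword letters are drawn from the
  words' position-specific letter pools.  Without this, words carry more
  vowels than pseudowords and ordinary letter-tuned sites become genuinely
  word-selective, contradicting the weak-selectivity regime the analyses
  assume (every site |d'| < 0.5, ~10% weakly selective).  With matching,
  class information lives in letter *combinations*, carried by the
  conjunctive terms and by a small planted subpopulation
  (`frac_word_selective`, default 0.10) whose additive class offset is
  calibrated per site by a one-dimensional root search so that the
  *realized* d' (including noise shrinkage) lands in
  `word_dprime_range` (default 0.15–0.45).

Noise is Poisson on spike counts in a 100 ms window by default
(variance of the count equal to its mean; a variance-matched gaussian model
is available for analytic tests).  Two response windows are drawn (70–170 ms
carrying the full signal; 170–270 ms a damped copy with independent noise),
plus per-trial baseline rates for the visual-drive screen.  Everything is
reproducible from the config seed.

What the generator does **not** emulate: temporal dynamics beyond the two
windows, correlated noise across sites, receptive-field geometry, adaptation
or attentional state, and any relationship between a site's tuning and its
electrode position (topography is null by construction, so the Moran's I
analysis has a true negative to calibrate against).  Passing tests therefore
demonstrate correctness of the *analysis machinery* and recoverability of
*planted* structure, not claims about real cortex.

# Site screens and features

Decoding uses repetition-averaged rates with the two windows concatenated
site-wise (each site contributes two features); single-site analyses use the
early window only.  The visual-drive screen is a two-sided Wilcoxon
signed-rank test of trial-wise evoked minus baseline rates (p < 0.001); the
test statistic is a package choice since rates are non-normal.  The letter
reliability screen split-halves repetitions, correlates the two half-mean
response patterns over the letter set, and averages over 20 random resplits;
the p-value uses the first split only, because averaging correlations before
the t-transform shrinks the null distribution and would overstate
significance (the reported reliability is still the resplit average).

# The decoding battery

The default battery has 30 binary tasks: 20 invariant letter-identification
and 8 invariant bigram-identification tasks ("token present anywhere in the
string", over an invariant set of 40 + 40 strings x 5 variations = 400
stimuli), plus two word-classification variants (canonical views of the base
set; the invariant set).  Which letters/bigrams: the tokens with the most
label-balanced splits, chosen deterministically with an alphabetical
tie-break (a seed can randomize among near-balanced candidates).

The readout is L2-regularized binary logistic regression with stratified
ten-fold cross-validation over stimuli: weights learned on 90% of stimuli,
class probabilities produced for the held-out 10%, every stimulus tested
exactly once.  Features are standardized per feature using training folds
only.  The whole procedure repeats over random site samples; site-count
sweeps report mean ± SD of balanced accuracy over samples.  The ridge
strength is frozen at $\lambda = 0.05$ (binary) after a one-off scan on
synthetic data; the 26-way multinomial letter decoder uses $\lambda = 5$,
because weak regularization lets it memorize slot-specific tuning components
and destroys cross-position generalization.  A probability of exactly 0.5
resolves to the negative class, deterministically.

External feature matrices (pixels, artificial-network layers) run through
`decode_external_features()` on the identical fold plans, so comparisons
with neural features are seed-for-seed matched.

# Behavioral metrics and consistency

Balanced accuracy is $(HR + (1 - FAR))/2$.  Sensitivity is
$d' = Z(HR) - Z(FAR)$; extreme rates are clipped to
$[1/(2N), 1 - 1/(2N)]$ with $N$ the trial count behind the rate, the
standard correction keeping $d'$ finite.

The behavioral signature bins strings into ten equal-sized bins by mean
bigram frequency, separately for words and pseudowords, rank-matching
word-decile i with pseudoword-decile i, and computes per-bin d' over all
trials in the bin.  The alternative reading (2x10 unpaired bins) was
rejected because the signature must be a single ten-vector with one HR and
one FAR per element.

Consistency between systems m and p is the noise-adjusted correlation
$$\tilde\rho(m,p) = \frac{\rho(m,p)}{\sqrt{\rho(m,m)\,\rho(p,p)}},$$
computed on split-half signature estimates (trials split within each
subject x stimulus cell), with the raw cross-correlation averaged over the
four cross-half pairings and the denominators the within-system split-half
reliabilities; all correlations use the same number of trials, so no
extrapolation formula is needed.  Ten resplits are averaged.  When a
reliability is non-positive the estimate is reported as undefined rather
than coerced.  The estimator is a ratio and carries a small positive bias at
low trial counts (~+0.1 at 30 trials/stimulus in our simulations, gone by
80); the tests use trial counts where it is unbiased within Monte-Carlo
error.  Decoder "trials" for splitting are independent cross-validation
repeats under different fold seeds, which restores trial-like variability
for a deterministic readout.  The behavioral ceiling is the
leave-one-subject-out distribution of subject-versus-pool consistencies.

# Single-site statistics

Selectivity is $d'_{x,y} = (\mu_x - \mu_y)/\sqrt{(\sigma_x^2 +
\sigma_y^2)/2}$ across repetition-averaged stimulus responses.
Significance uses a two-tailed bootstrap test: resample stimuli with
replacement within class and compare the observed d' to zero in units of
the bootstrap distribution's spread, $p = 2\Phi(-|d'|/\mathrm{sd}(d'_b))$.
The alternative realization that counts bootstrap mass across zero was
measured to be anticonservative for this statistic (false-positive rate
about 0.06 at a nominal 0.05 under exchangeable nulls, stable across
stimulus counts), while the spread-based form recovers the nominal level;
calibration is asserted in the test suite at 1000 null sites.  The
population-level claims use an exact binomial tail test (fraction of
selective sites against the nominal level) and a two-sided binomial test of
hemispheric composition against the sampling fraction.

The sparsity index is $A(x) = E[x]^2/E[x^2]$,
$SI(x) = (1 - A)/(1 - 1/N)$: 0 for uniform, 1 for one-hot vectors in the
noise-free limit.  Negative repetition averages (possible under the gaussian
noise model) are rectified at zero first.  Because noise inflates SI, the
package simulates both reference hypotheses while preserving repetition
noise: the *uniform* null shuffles stimulus categories independently within
each repetition before averaging; the *one-hot* null infers the top category
from half the repetitions and rebuilds the held-out half as top-category
responses plus minimum-category level with resampled trial residuals for the
rest.  Across sites, medians are compared to the null-median distributions
by permutation.

Topography uses Moran's I on the 10x10 electrode grid with rook adjacency
and row-standardized weights (the adjacency is configurable; the 400 µm
electrode pitch is metadata only), a permutation p-value from shuffling
values across occupied electrodes (at least 100 shuffles), and averaging
over arrays with within-array shuffling for the multi-array null.  With
row-standardized rook weights a 10x10 checkerboard gives exactly $I = -1$,
a closed-form oracle used in the tests alongside an independent
implementation.

# Encoding reconstruction

For each site, canonical-view string responses are regressed (with
intercept) on the site's own responses to the constituent letters at the
corresponding slots, cross-validating over strings.  Substring models
(best 1/2/3 slots) search all slot subsets on training folds only, with ties
broken towards the lowest slot indices; the bag-of-letters model looks
letters up at the wrong slot through one fixed random derangement shared by
all strings.  The held-out prediction-measurement correlation is divided by
the square root of the Spearman-Brown-corrected split-half reliability of
the measured string responses, so that a fully predictive model scores
around 1 regardless of repetition count — without the Spearman-Brown step a
perfect model would plateau at the square root of the half-data
reliability.  Model medians are compared across sites by one-tailed
bootstrap of the median difference.

# Mirror symmetry

A 26-way multinomial ridge decoder maps the population response of each
letter image to class probabilities.  Cross-validation is
leave-one-position-out — the embedding of a letter at slot p comes from a
decoder that never saw slot p — preventing memorization of the embedded
stimuli (cross-validating over stimuli within position was the rejected
alternative; it leaves position-specific information in the training set).
Pairwise similarity $r_{IT}$ is the Pearson correlation of two letters'
26-vectors at one position, averaged over the four positions.  Pairs are
sorted by $\Delta R$, smoothed with a five-pair boxcar, and binned into
three equal-$\Delta R$-range bins; the extreme bins are tested against zero
(one-tailed one-sample t) and against each other (one-tailed Welch t,
rightmost greater).  With a fully mirror-symmetric simulated population the
rightmost bin's mean $r_{IT}$ exceeds the leftmost decisively; note that
even plain glyph-shape tuning produces some positive dependence, because
high-$\Delta R$ pairs also share plain pixel structure in a blocky bitmap
font.

# Problem sizes, tolerances, degenerate inputs

The test-suite simulations use 25–200 sites, 4–24 repetitions, and 40–160
strings — sizes chosen so the whole suite runs in a few minutes on one CPU
while every stochastic check keeps comfortable Monte-Carlo margins; the
pipeline demo (`run_config()`) defaults to 120 sites, 10 repetitions and
100 + 100 strings for the same reason.  Calibration checks use binomial
95% bands at their simulation sizes.  Degenerate inputs are errors, not
silent values: zero pooled variance in d', all-zero vectors in SI, constant
fields in Moran's I, single-class inputs to balanced accuracy, non-positive
reliabilities in consistency (reported as undefined with diagnostics).
Glyph rendering refuses rasters below the 7-pixel glyph grid
(px_per_degree below about 9 at the small letter size).

# Known limitations

* The generator's conjunctive terms are random adjacent-pair effects; they
  make lexical class decodable through letter combinations but encode no
  English bigram statistics, so the decoder-versus-reference consistency on
  synthetic data is positive yet well below the subject ceiling.
* The frozen bigram table is list-derived, not corpus-derived; only rank
  structure should be interpreted.
* The embedded bitmap font is coarse (5x7); reflectivity values are
  font-specific, and only their ordering across pairs is meaningful.
* The tensor container is a plain-text sidecar directory; it is
  schema-versioned and lossless but not a community container format.
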