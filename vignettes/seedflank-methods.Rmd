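---
title: "Designing promoter flanking sequences around fixed motif seeds"
author: "seedflank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing promoter flanking sequences around fixed motif seeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most synthetic promoters are designed by placing well-characterised
transcription-factor binding sites -- the sigma-70 −10/−35 hexamers,
operator sites such as lacO or tetO, a minimal core promoter -- into a
backbone, and treating everything between the sites as filler. The filler
is not neutral: flanking sequence shifts local DNA shape, carries weak
secondary binding sites, and biases the k-mer composition that
transcription machinery reads. seedflank treats promoter design as a
constrained optimisation over exactly that flanking sequence.

The design window of length $L$ is split by a *seed specification* $m^*$
(motifs with fixed content and position) into seed positions and flanking
positions $f$. Writing $T$ for the target property (here: expression
level), the design goal is to maximise $P(f \mid m^*, T) \propto
P(f \mid m^*)\, P(T \mid f, m^*)$. The two factors are modelled
separately:

* $P(f \mid m^*)$ -- a conditional adversarial generator $G(m^*, z)$ that
  fills flanking rows compatible with the seeds, trained against a critic
  $D(m, s)$ under the Wasserstein objective with gradient penalty, plus an
  L1 reconstruction term over flanking positions (weight $\lambda$,
  default 10, the image-translation convention);
* $P(T \mid f, m^*)$ -- a sequence-to-activity regressor $F$
  (convolution, bidirectional LSTM, DenseNet trunk, dense head).

Design then maximises $F(G(m^*, z), m^*)$ over the latent variable $z$
with a genetic algorithm; the seeds are restored exactly in every emitted
sequence, so the search can only move the flanks.

## Encodings and the latent variable

Sequences are one-hot encoded over channels A, C, G, T (0-based
coordinates, half-open intervals). `N` encodes as the uniform row and is
never emitted on decode; argmax decoding breaks ties lexicographically.
The generator's input carries hard one-hot rows at seed positions and an
independent random probability row (softmax of four standard normals) at
every flanking position: these random rows *are* the realisation of $z$.
The generator is a residual refinement of that input -- its trunk
(per-position linear embedding into $d_k$ channels, one multi-head
self-attention layer with residual connection, two channel-preserving
convolutional residual blocks, projection back to 4 channels) emits logit
adjustments added to the log of the input rows before a row softmax. At
initialisation the map is close to the identity on the latent rows, so
outputs are diverse from the first step and the latent search space is
well-behaved; training reshapes the output distribution toward the data.
Head count and width default to $o = 4$, $d_k = 64$ (configurable; the
attention scale is $1/\sqrt{d_k}$).

## Adversarial training

The critic receives the channel-concatenation of the motif conditioning
(hard one-hot at seed rows, zeros elsewhere) and the sequence encoding,
and shares the generator's trunk family, ending in global average pooling
and a scalar head. The default objective is the Wasserstein loss with
gradient penalty (weight 10, interpolates drawn uniformly per sample
between real and generated encodings, 5 critic steps per generator step);
the saturating log-loss is available behind `loss = "logistic"` for
comparison. Training uses Adam with learning rate $10^{-4}$,
$\beta_1 = 0.5$, $\beta_2 = 0.9$, batch size 32; full-scale runs are
50,000 batches, and the package's own experiments scale this down (see
below). The L1 term is computed over flanking positions only: seed rows
are overwritten by the hard constraint, so their residual is identically
zero and including them would only dilute the term.

All networks are implemented in base R matrix code with hand-derived
backward passes; every layer's gradient is verified against central
finite differences in the test suite. One consequence worth documenting:
the parameter gradient of the gradient penalty needs second-order
information. It is computed with the directional-derivative identity
$\nabla_\theta (g \cdot v) \approx [\nabla_\theta D(\hat x + \epsilon v)
- \nabla_\theta D(\hat x - \epsilon v)] / (2\epsilon)$, where $g$ is the
input gradient at the interpolate and $v$ its scaled copy -- two extra
ordinary backward passes, exact to $O(\epsilon^2)$ and also verified
against finite differences.

## The activity predictor

`predictor_config()` defaults follow the full-scale architecture: a 1-D
convolution with 64 output channels, stride-2 average pooling, a
bidirectional LSTM (hidden 64 per direction -- directionality, width and
the pooling that follows the DenseNet are this package's choices, as is
global average pooling before the one-unit dense head), and four dense
blocks of 2, 2, 4 and 2 layers with growth rate 32 and per-layer kernels
1 and 3, linked by channel-halving transitions with stride-2 pooling.
Training minimises mean squared error on z-scored activities (the z-score
is optional; predictions return on the original scale) with early
stopping (patience 10 by default) because deep regressors on modest
sequence sets overfit readily. Saliency maps are input gradients, by
default masked by the one-hot input so each position reports the
contribution of the observed base; the raw gradient is also available.
The penultimate embedding is the global-average-pooled feature vector
feeding the head.

## Genetic-algorithm search

Each latent coordinate (four per flanking row) is binary-encoded at 8
bits over $[-3, 3]$ (about the support of a standard normal); variation
is single-point crossover (probability 0.9) and per-bit mutation at
0.005; selection is tournament of size 3 with elitism 1, which makes the
best-fitness trace non-decreasing by construction. Full-scale defaults
are population $5 \times 1024$ and 100 generations; fitness is evaluated
on whole populations at once so the generator and predictor run batched.
The desk-scale experiments in this package use population 256 and 30
generations, which is enough for the synthetic landscape below. Decoded
designs are deduplicated by exact string, filtered (motif library scan
and/or second-promoter check), and returned top-$k$ by predicted
activity.

## The synthetic landscape

`simulate_dataset()` emulates the structure of a bacterial
promoter-activity corpus: 165 bp windows, uniform background, a −35/−10
seed pair (TTGACA at 120, TATAAT at 143; 17 bp spacer, TSS at 155)
planted with per-position consensus probability 0.85 so motif quality
varies, and activity

$$a(s) = w_m \sum_i \mathrm{logodds}_i(s) + w_f\,\big[(\mathrm{GC}(f) -
0.5) + 0.1\,\#\mathrm{GCCA}(f)\big] + \mathcal N(0, \sigma^2)$$

with defaults $w_m = 1$, $w_f = 20$, $\sigma = 0.1$. The flank weight is
chosen so the flanking term carries roughly a quarter of the activity
variance: the landscape is meant to emulate promoters whose activity
depends materially on *both* the core elements and their flanks -- a
simulation in which flanks are negligible would make the flank-design
problem vacuous. What the simulator does not emulate: positional
dependence of flank effects, epistasis between flank and motif,
heavy-tailed expression noise, or any chromatin context; passing the
synthetic benchmarks therefore demonstrates that the machinery recovers a
known landscape of this additive form, not that it captures real
promoter biology.

## Analysis battery

* **k-mer spectra** are pooled overlapping counts normalised to
  probability vectors; the distal/proximal split defaults to the window
  halves (the split coordinate is configurable).
* **Edit distance** is unit-cost Levenshtein (via the C implementation
  underlying `utils::adist`); diversity profiles enumerate all
  cross-group pairs. Template difference divides by the flanking length;
  both a flanking-only and a full-sequence mode exist because indels can
  couple seed and flank regions -- the flanking-only mode is the default
  and is what the random-flank control recomputation uses.
* **DNA shape** uses a pluggable pentamer table. The packaged table is
  synthetic (deterministic, reverse-complement symmetric, with an
  AT-content trend so that embeddings have signal); a loader accepts
  published-format TSV tables for real analyses. MGW/ProT sit at pentamer
  centres; Roll/HelT are assigned per step, overlaps averaged, and
  reported at pentamer centres as the mean of the two adjacent steps, so
  all four tracks share the $L - 4$ defined span.
* **Shape embedding** standardises the concatenated tracks, reduces to 10
  principal components and embeds with Sammon nonlinear MDS initialised
  from classical MDS (deterministic); duplicate rows are collapsed first
  so identical inputs land at identical coordinates. This replaces the
  stochastic t-SNE a GPU-era pipeline would use; for two-group separation
  questions the conclusions are equivalent.
* **PWM scanning** scores log2-odds against the background. P-values are
  exact: for widths up to 8 the DP runs over the exact set of attainable
  score sums (merged at 1e-9), matching exhaustive enumeration to 1e-6;
  wider motifs use a 1e-3-binned DP with floor rounding and a
  `width x granularity` threshold slack, making the reported p-value
  conservative (never smaller than exact).
* **Second-promoter detection** builds a combined −35 / 17 bp
  information-free spacer / −10 motif and scans every offset (forward
  strand by default -- promoters are directional; both strands behind a
  flag). Offsets overlapping the original seed are excluded from
  flagging so a design does not flag its own promoter.

## Numerical and design choices

* Noise rows use softmax-of-normals rather than a Dirichlet draw: it is
  seedable, smooth in the latent coordinates (which the GA encodes
  directly), and row-stochastic by construction.
* Argmax ties decode as A < C < G < T; `N` never appears in output.
* Adam state is keyed per parameter path; training is bitwise
  reproducible for a fixed seed and single-threaded BLAS.
* Degenerate inputs error early and descriptively: overlapping motifs
  report the offending interval, non-finite activations name the layer,
  all-identical activities refuse to train.
* The geometry filter reads "more than 75 bp distal of the TSS" as a
  strict inequality and applies rules in the fixed order (a) distal
  span, (b) −10 placement 1-21 bp upstream, (c) −35 placement 25-45 bp
  upstream, (d) spacer 10-24 bp, tagging each rejection with the first
  failed rule; element positions come from annotations when present and
  otherwise from maximal PWM log-odds placement inside the allowed
  windows.

## Scaled experiment sizes

The package's own validation experiments are sized for a single CPU:
predictor parameter recovery uses the n = 2000 synthetic corpus with a
reduced-width predictor (32 conv channels, LSTM 16, blocks 1-1-2-1,
growth 16, 35 epochs); the adversarial distribution-matching experiment
uses 200 sequences of length 32 for 300 batches; the design-benefit
experiment uses population 256 for 30 generations with a compact
($d_k = 16$) generator. These sizes are the package's reference
conditions; the full-scale defaults remain available through the
configuration objects.

## Known limitations

* The networks run on CPU in base R: full-scale (50,000-batch, $5 \times
  1024$-population) runs are out of desk range by design.
* The generator in the design-benefit experiment is freshly initialised
  (an identity-like latent map) rather than adversarially converged; the
  experiment isolates the GA + predictor loop.
* The synthetic shape table supports method development and symmetry
  tests only; biological shape analyses need a published pentamer table
  via `load_shape_table()`.
* Activities are modelled as a single scalar; multi-objective design
  (e.g. jointly minimising leaky expression) is out of scope.
* The predictor sees the sequence only: the motif mask is constant
  within a design task, so feeding it as an extra channel would add no
  usable information. The predictor is regression-only; binary
  high/low datasets should be recoded to a numeric label, and any
  activity transform (e.g. log) is applied by the caller before
  building the dataset.

## A worked example

```{r example}
library(seedflank)

spec <- read_seed_spec(system.file("extdata", "sigma70_seed_spec.yaml",
                                   package = "seedflank"))
cfg <- sim_config(n = 2000, rng_seed = 42,
                  activity_weights = list(w_motif = 1, w_flank = 20,
                                          noise_sd = 0.1))
ds <- simulate_dataset(cfg)

pred <- train_predictor(ds, predictor_config(conv1_channels = 32,
                                             lstm_hidden = 16,
                                             dense_blocks = c(1, 1, 2, 1),
                                             growth_rate = 16,
                                             epochs = 35, patience = 8,
                                             rng_seed = 7))
gen <- generator_model(spec, d_k = 16, heads = 2, rng_seed = 3)
res <- design_promoters(gen, pred, spec,
                        ga_config(population = 256, generations = 30,
                                  rng_seed = 9),
                        n_out = 16)
head(res$designs)
```
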