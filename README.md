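# seedflank

Seed-constrained design and analysis of promoter flanking sequences.

## The problem

Synthetic promoters are usually assembled by placing well-characterised
motifs — the bacterial sigma-70 −10/−35 hexamers, operator sites such as
lacO or tetO, a minimal core promoter — into a backbone and improvising
everything in between. That flanking sequence is not neutral: it shifts
local DNA shape, carries weak secondary binding sites, and sets the
k-mer composition around the motifs, all of which move expression.
seedflank is for synthetic biologists and regulatory genomicists who
want to **keep their expert-chosen motifs fixed and optimise the
flanking sequence around them**.

## The method

A design window of length *L* is split by a seed specification *m\** into
fixed motif positions and free flanking positions *f*. The design goal is

> max over *z* of *F*( *G*(*m\**, *z*), *m\** )

with three cooperating parts:

* **Generator** *G*: a conditional adversarial network (per-position
  embedding → multi-head self-attention → two convolutional residual
  blocks → row softmax) that fills flanking rows compatible with the
  seeds. It trains against a critic under the Wasserstein objective with
  gradient penalty plus an L1 reconstruction term over flanking
  positions (Pix2Pix convention, weight 10). Seed rows are hard-restored
  in every emitted sequence.
* **Predictor** *F*: a sequence-to-activity regressor (1-D convolution,
  64 channels → bidirectional LSTM → DenseNet with blocks 2-2-4-2 and
  growth rate 32 → dense head), with input-gradient saliency maps and
  penultimate-layer embeddings.
* **Genetic algorithm**: searches the generator's latent input (the
  random flanking rows), binary-encoded at 8 bits per coordinate, with
  tournament selection, single-point crossover, bit-flip mutation and
  elitism, evaluating fitness on whole populations at once.

An analysis battery rounds the pipeline out: k-mer spectra and their
correlations, Levenshtein diversity profiles and template differences
(normalised by flanking length), pentamer-based DNA shape tracks and a
deterministic 2-D shape embedding, PWM scanning with exact p-values, and
second-promoter detection with a combined −35/spacer/−10 motif.

All networks are implemented in base R matrix code with hand-derived,
finite-difference-verified backward passes; a synthetic promoter
simulator with a known activity oracle makes the whole pipeline testable
offline.

## A worked example

```r
library(seedflank)

# a canonical sigma-70 seed: TTGACA at 120, TATAAT at 143, 165 bp window
spec <- read_seed_spec(system.file("extdata", "sigma70_seed_spec.yaml",
                                   package = "seedflank"))
flanking_length(spec)
#> [1] 153

# synthetic training corpus with a known activity oracle
cfg <- sim_config(n = 2000, rng_seed = 42,
                  activity_weights = list(w_motif = 1, w_flank = 20,
                                          noise_sd = 0.1))
ds <- simulate_dataset(cfg)

# activity predictor (reduced widths for a single CPU)
pred <- train_predictor(ds, predictor_config(
  conv1_channels = 32, lstm_hidden = 16, dense_blocks = c(1, 1, 2, 1),
  growth_rate = 16, epochs = 35, patience = 8, rng_seed = 7))
print(pred)
#> Activity predictor: 165 bp window
#>   held-out (n=400): Pearson 0.875, Spearman 0.898, MSE 7.118

# GA search over the generator's latent space
gen <- generator_model(spec, d_k = 16, heads = 2, rng_seed = 3)
res <- ga_optimize(gen, pred, spec,
                   ga_config(population = 256, generations = 30,
                             rng_seed = 9))

# score designs and matched random-flank controls with the oracle
designs <- head(res$designs$seq, 64)
mean(vapply(designs, activity_oracle, numeric(1), config = cfg))
#> [1] 30.82633
set.seed(10)
mean(vapply(random_sequences(64, 165, spec = spec), activity_oracle,
            numeric(1), config = cfg))
#> [1] 22.17171
```

The designed sequences keep the seed hexamers exactly, and their mean
oracle activity beats random-flank controls carrying the same seeds by
about 8.7 activity units (Cohen's d ≈ 4.8): the search moved only the
flanks, and the flanks alone produced the gain.

A thin command-line wrapper over the same functions ships at
`inst/cli/seedflank.R` (subcommands `simulate`, `train-predictor`,
`train-generator`, `design`, `analyze`).

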