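# Shared fixtures, memoised per test session: the expensive model fits are
# built once and reused by every file that needs them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Canonical sigma-70 toy spec on a short window.
toy_spec <- function(window = 40L) {
  seed_spec(window, list(list(seq = "TTGACA", start = 5L),
                         list(seq = "TATAAT", start = 25L)),
            label = "toy sigma70")
}

# The synthetic study conditions: 165 bp, canonical seeds, n = 2000.
sim_study <- function() {
  fixture("sim_study", function() {
    cfg <- sim_config(n = 2000L, rng_seed = 42L,
                      activity_weights = list(w_motif = 1, w_flank = 20,
                                              noise_sd = 0.1))
    list(config = cfg, dataset = simulate_dataset(cfg))
  })
}

# Desk-scale predictor configuration used for the parameter-recovery
# experiments (reduced widths and epochs; architecture family unchanged).
study_predictor_config <- function(rng_seed = 7L, epochs = 35L) {
  predictor_config(conv1_channels = 32L, conv1_kernel = 7L,
                   lstm_hidden = 16L, dense_blocks = c(1L, 1L, 2L, 1L),
                   growth_rate = 16L, learning_rate = 1e-3,
                   batch_size = 64L, epochs = epochs, patience = 8L,
                   rng_seed = rng_seed)
}

study_predictor <- function() {
  fixture("study_predictor", function() {
    train_predictor(sim_study()$dataset, study_predictor_config())
  })
}

# A very small trained predictor on a 30 bp window for interface-level
# tests (saliency, embeddings, prediction mechanics).
tiny_sim <- function() {
  fixture("tiny_sim", function() {
    spec <- seed_spec(30L, list(list(seq = "TTGACA", start = 4L),
                                list(seq = "TATAAT", start = 18L)))
    cfg <- sim_config(n = 150L, window_length = 30L, planted_spec = spec,
                      rng_seed = 5L,
                      activity_weights = list(w_motif = 1, w_flank = 20,
                                              noise_sd = 0.1))
    list(config = cfg, dataset = simulate_dataset(cfg))
  })
}

tiny_predictor <- function() {
  fixture("tiny_predictor", function() {
    cfg <- predictor_config(conv1_channels = 8L, conv1_kernel = 5L,
                            lstm_hidden = 4L, dense_blocks = c(1L, 1L, 1L, 1L),
                            growth_rate = 4L, epochs = 4L, batch_size = 32L,
                            rng_seed = 3L)
    train_predictor(tiny_sim()$dataset, cfg)
  })
}

# The scaled distribution-matching experiment: 200 sequences of length 32
# with a composition-biased flank, 300 total batches.
toy_corpus_32 <- function() {
  fixture("toy_corpus_32", function() {
    spec <- seed_spec(32L, list(list(seq = "TATAAT", start = 13L)),
                      label = "toy")
    mask <- seed_mask(spec)
    tmpl <- strsplit(seed_template(spec), "")[[1]]
    set.seed(11L)
    seqs <- vapply(seq_len(200L), function(i) {
      ch <- sample(c("A", "C", "G", "T"), 32L, replace = TRUE,
                   prob = c(0.15, 0.2, 0.45, 0.2))
      ch[mask] <- tmpl[mask]
      paste(ch, collapse = "")
    }, character(1))
    list(spec = spec,
         dataset = promoter_dataset(seqs, rnorm(200L),
                                    provenance = "toy corpus"))
  })
}

toy_cgan_fit <- function() {
  fixture("toy_cgan_fit", function() {
    tc <- toy_corpus_32()
    train_cgan(tc$dataset, tc$spec,
               cgan_config(batch_size = 32L, total_batches = 300L,
                           checkpoint_every = 10L, rng_seed = 5L))
  })
}

# Independent brute-force Levenshtein by plain recursion (memoised on the
# suffix pair), used as the oracle against the package implementation.
lev_recursive <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste0(i, ",", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- if (substr(a, i, i) == substr(b, j, j)) 0L else 1L
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

# Plain silhouette coefficient for a 2-group labelling (no extra deps).
silhouette_mean <- function(coords, labels) {
  D <- as.matrix(dist(coords))
  s <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(nrow(D)) != i])
    b <- mean(D[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}
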