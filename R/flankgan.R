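#' Generator network for flanking sequences
#'
#' The generator maps a seed-constrained input (hard one-hot rows at motif
#' positions, random probability rows elsewhere -- the latent variable)
#' to a relaxed one-hot matrix over the whole window. Architecture:
#' per-position linear embedding into `d_k` channels, one multi-head
#' self-attention layer (with residual connection), two convolutional
#' residual blocks, a per-position projection back to 4 channels and a row
#' softmax. Seed rows of the emitted matrix are always overwritten with the
#' hard motif rows.
#'
#' The trunk emits per-position logit adjustments that are added to the
#' log-probabilities of the input rows before the softmax, so the
#' generator is a residual refinement of its latent input: at
#' initialisation it is close to an identity map on the random rows
#' (diverse outputs), and training reshapes their distribution. This keeps
#' the output sensitive to the latent variable, which the downstream
#' genetic-algorithm search relies on.
#'
#' @param spec A [seed_spec()] fixing the window and motifs.
#' @param d_k Embedding channels (default 64).
#' @param heads Attention heads (default 4; must divide `d_k`).
#' @param kernel Convolution kernel size in the residual blocks (default 3).
#' @param rng_seed Seed for weight initialisation.
#' @return Object of class `generator_model`.
#' @export
generator_model <- function(spec, d_k = 64L, heads = 4L, kernel = 3L,
                            rng_seed = 1L) {
  stopifnot(inherits(spec, "seed_spec"))
  set.seed(as.integer(rng_seed))
  layers <- list(
    list(type = "pointwise", W = glorot(4L, d_k), b = numeric(d_k)),
    list(type = "act", slope = 0.2),
    list(type = "attention", params = make_attention_params(d_k, heads),
         residual = TRUE),
    make_resblock(d_k, kernel),
    make_resblock(d_k, kernel),
    list(type = "pointwise", W = glorot(d_k, 4L) * 0.1, b = numeric(4L))
  )
  structure(list(layers = layers, spec = spec,
                 config = list(d_k = d_k, heads = heads, kernel = kernel,
                               rng_seed = rng_seed)),
            class = "generator_model")
}

# Full generator pass on a [B, L, 4] input batch: trunk logits plus the
# input log-probabilities, then a row softmax. Returns the trunk forward
# (for backprop), the softmax cache and the output array.
generator_pass <- function(gen, X) {
  trunk <- net_forward(gen$layers, X)
  logits <- trunk$out + log(X + 1e-6)
  sm <- rowsoftmax_fwd(logits)
  list(trunk = trunk, sm = sm, out = sm$out)
}

# Backprop dOut (w.r.t. the softmax output) into trunk parameter grads.
generator_pass_bwd <- function(gen, pass, dOut) {
  dLogits <- rowsoftmax_bwd(pass$sm$cache, dOut)
  net_backward(gen$layers, pass$trunk, dLogits)$grads
}

#' @export
print.generator_model <- function(x, ...) {
  cat("Flanking-sequence generator:", x$spec$window_length, "bp window,",
      x$config$d_k, "channels,", x$config$heads, "attention heads\n")
  invisible(x)
}

#' Run the generator on one or more inputs
#'
#' @param model A [generator_model()].
#' @param input A `generator_input` (from [build_generator_input()]) or a
#'   list of them.
#' @return For a single input, an L x 4 row-stochastic matrix whose seed
#'   rows are hard one-hot motif rows; for a list, a list of such matrices.
#' @export
generator_forward <- function(model, input) {
  single <- inherits(input, "generator_input")
  inputs <- if (single) list(input) else input
  L <- model$spec$window_length
  for (gi in inputs) {
    if (nrow(gi$matrix) != L) {
      stop("input window ", nrow(gi$matrix), " != model window ", L)
    }
  }
  X <- array(0, c(length(inputs), L, 4L))
  for (b in seq_along(inputs)) X[b, , ] <- inputs[[b]]$matrix
  out <- generator_pass(model, X)$out
  res <- lapply(seq_along(inputs), function(b) {
    m <- matrix(out[b, , ], L, 4L, dimnames = list(NULL, DNA_BASES))
    impose_seeds(m, model$spec)
  })
  if (single) res[[1]] else res
}

#' Decode generator outputs into sequences
#' @param model A [generator_model()].
#' @param input As in [generator_forward()].
#' @return Character vector of designed sequences (seed motifs guaranteed).
#' @export
generator_sequences <- function(model, input) {
  out <- generator_forward(model, input)
  if (is.matrix(out)) out <- list(out)
  vapply(out, decode_onehot, character(1))
}

#' Critic (discriminator) network
#'
#' Scores (motif encoding, sequence encoding) pairs with a single scalar.
#' The two L x 4 encodings are concatenated channel-wise into an L x 8
#' input; the trunk mirrors the generator (embedding, attention, two
#' residual blocks) and ends in global average pooling plus a dense scalar
#' head. Under the Wasserstein objective the scalar is an unconstrained
#' score, not a probability.
#'
#' @inheritParams generator_model
#' @return Object of class `critic_model`.
#' @export
critic_model <- function(spec, d_k = 64L, heads = 4L, kernel = 3L,
                         rng_seed = 2L) {
  stopifnot(inherits(spec, "seed_spec"))
  set.seed(as.integer(rng_seed))
  layers <- list(
    list(type = "pointwise", W = glorot(8L, d_k), b = numeric(d_k)),
    list(type = "act", slope = 0.2),
    list(type = "attention", params = make_attention_params(d_k, heads),
         residual = TRUE),
    make_resblock(d_k, kernel),
    make_resblock(d_k, kernel),
    list(type = "gap"),
    list(type = "dense", W = glorot(d_k, 1L), b = numeric(1L))
  )
  structure(list(layers = layers, spec = spec,
                 config = list(d_k = d_k, heads = heads, kernel = kernel,
                               rng_seed = rng_seed)),
            class = "critic_model")
}

#' @export
print.critic_model <- function(x, ...) {
  cat("Critic:", x$spec$window_length, "bp window,", x$config$d_k,
      "channels\n")
  invisible(x)
}

# The motif-conditioning encoding: hard one-hot at seed rows, zeros at
# flanking rows.
motif_encoding <- function(spec) {
  m <- matrix(0, spec$window_length, 4L, dimnames = list(NULL, DNA_BASES))
  impose_seeds(m, spec) * seed_mask(spec)
}

# Stack motif + sequence encodings into the critic's [B, L, 8] input.
critic_input <- function(motif_mats, seq_mats) {
  B <- length(seq_mats)
  L <- nrow(seq_mats[[1]])
  X <- array(0, c(B, L, 8L))
  for (b in seq_len(B)) {
    X[b, , 1:4] <- motif_mats[[b]]
    X[b, , 5:8] <- seq_mats[[b]]
  }
  X
}

#' Score a (motif, sequence) pair with the critic
#'
#' @param model A [critic_model()].
#' @param motif_encoding L x 4 motif conditioning matrix (hard one-hot at
#'   seed rows, zero elsewhere); see [seed_spec()].
#' @param seq_encoding L x 4 (relaxed) one-hot sequence matrix.
#' @return Finite scalar score.
#' @export
critic_forward <- function(model, motif_encoding, seq_encoding) {
  L <- model$spec$window_length
  if (!is.matrix(motif_encoding) || !all(dim(motif_encoding) == c(L, 4L)) ||
      !is.matrix(seq_encoding) || !all(dim(seq_encoding) == c(L, 4L))) {
    stop("encodings must both be ", L, " x 4 matrices")
  }
  X <- critic_input(list(motif_encoding), list(seq_encoding))
  as.numeric(net_forward(model$layers, X)$out)
}

# Batched critic forward returning the full pass (for training).
critic_forward_batch <- function(model, X) {
  net_forward(model$layers, X)
}

# Gradient of the summed critic score with respect to its input batch.
critic_input_grad <- function(model, X) {
  fwd <- net_forward(model$layers, X)
  d <- dim(fwd$out)
  dOut <- matrix(1, d[1], 1L)
  net_backward(model$layers, fwd, dOut)$dX
}

# Gradient penalty E[(||grad_xhat D||_2 - 1)^2] on interpolates, plus the
# parameter gradient of the penalty computed with a directional-derivative
# scheme: grad_theta(g . v) ~ [grad_theta D(x + eps v) -
# grad_theta D(x - eps v)] / (2 eps), with v the appropriately scaled input
# gradient. Returns list(value, grads).
gradient_penalty <- function(critic, Xhat, eps_scale = 1e-3,
                             want_grads = TRUE) {
  if (is.list(critic) && !inherits(critic, "critic_model")) {
    # test hook: plain list with score_fn / grad_fn
    g <- critic$grad_fn(Xhat)
  } else {
    g <- critic_input_grad(critic, Xhat)
  }
  B <- dim(Xhat)[1]
  norms <- sqrt(apply(g^2, 1L, sum))
  value <- mean((norms - 1)^2)
  if (!want_grads || (is.list(critic) && !inherits(critic, "critic_model"))) {
    return(list(value = value, grads = NULL))
  }
  # v_b = 2 (n_b - 1) / (B n_b) * g_b  (coefficient of dD/dx in d penalty)
  coef <- 2 * (norms - 1) / (B * pmax(norms, 1e-12))
  v <- g * array(rep(coef, prod(dim(g)[2:3])), dim(g))
  vmax <- max(abs(v))
  if (vmax == 0) return(list(value = value, grads = NULL))
  eps <- eps_scale / vmax
  fp <- net_forward(critic$layers, Xhat + eps * v)
  fm <- net_forward(critic$layers, Xhat - eps * v)
  ones <- matrix(1, B, 1L)
  gp <- net_backward(critic$layers, fp, ones)$grads
  gm <- net_backward(critic$layers, fm, ones)$grads
  grads <- scale_grads(sub_grads(gp, gm), 1 / (2 * eps))
  list(value = value, grads = grads)
}

# elementwise arithmetic on parallel grad structures
map_grads <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (i in seq_along(a)) out[[i]] <- map_grads(a[[i]], b[[i]], f)
  out
}
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  map_grads(a, b, `+`)
}
sub_grads <- function(a, b) map_grads(a, b, `-`)
scale_grads <- function(a, s) map_grads(a, NULL, function(x, ...) x * s)

#' Training configuration for the conditional GAN
#'
#' Defaults follow the training protocol of the framework this package
#' implements: batch size 32, Adam with learning rate 1e-4, beta1 0.5,
#' beta2 0.9; the full-scale runs use 50,000 batches (scale `total_batches`
#' down for desk-size experiments). `l1_weight` is the weight of the L1
#' reconstruction term over flanking positions (Pix2Pix convention, 10);
#' `gp_weight` the WGAN-GP gradient-penalty weight (10);
#' `critic_steps_per_gen_step` the usual 5.
#'
#' @param batch_size,total_batches Positive counts.
#' @param learning_rate,beta1,beta2 Adam settings.
#' @param l1_weight,gp_weight Non-negative loss weights.
#' @param critic_steps_per_gen_step Critic updates per generator update.
#' @param loss `"wasserstein"` (default) or `"logistic"` (the vanilla
#'   saturating log-loss, kept for comparison).
#' @param checkpoint_every Log a distribution-matching checkpoint every
#'   this many generator steps (0 = off).
#' @param rng_seed Integer seed fixing data order, latent draws and
#'   interpolation noise.
#' @return Object of class `cgan_config`.
#' @export
cgan_config <- function(batch_size = 32L, total_batches = 50000L,
                        learning_rate = 1e-4, beta1 = 0.5, beta2 = 0.9,
                        l1_weight = 10, gp_weight = 10,
                        critic_steps_per_gen_step = 5L,
                        loss = c("wasserstein", "logistic"),
                        checkpoint_every = 0L, rng_seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(batch_size > 0, total_batches > 0, l1_weight >= 0,
            gp_weight >= 0, critic_steps_per_gen_step > 0)
  structure(list(batch_size = as.integer(batch_size),
                 total_batches = as.integer(total_batches),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, l1_weight = l1_weight,
                 gp_weight = gp_weight,
                 critic_steps_per_gen_step =
                   as.integer(critic_steps_per_gen_step),
                 loss = loss, checkpoint_every = as.integer(checkpoint_every),
                 rng_seed = as.integer(rng_seed)),
            class = "cgan_config")
}

#' Evaluate the conditional-GAN loss terms on one batch
#'
#' Under the Wasserstein objective:
#' `critic_loss = mean D(m, G(m,z)) - mean D(m, f) + gp_weight * GP`,
#' `gen_loss = -mean D(m, G(m,z)) + l1_weight * L1`, where `L1` is the
#' mean absolute difference between real and generated encodings over
#' flanking positions (seed rows are constrained and contribute zero), and
#' `GP` the gradient penalty on real/generated interpolates.
#'
#' @param gen A [generator_model()].
#' @param critic A [critic_model()].
#' @param real_seqs Character vector of real promoter sequences.
#' @param inputs List of `generator_input`s, one per real sequence.
#' @param config A [cgan_config()].
#' @return List with `critic_loss`, `gen_loss`, `l1_term`, `gp_term`.
#' @export
cgan_losses <- function(gen, critic, real_seqs, inputs, config = cgan_config()) {
  if (!length(real_seqs)) stop("empty batch")
  stopifnot(length(real_seqs) == length(inputs))
  spec <- gen$spec
  B <- length(real_seqs)
  fake <- generator_forward(gen, inputs)
  real <- lapply(real_seqs, encode_onehot)
  mot <- replicate(B, motif_encoding(spec), simplify = FALSE)
  Xf <- critic_input(mot, fake)
  Xr <- critic_input(mot, real)
  Df <- as.numeric(net_forward(critic$layers, Xf)$out)
  Dr <- as.numeric(net_forward(critic$layers, Xr)$out)
  mask <- seed_mask(spec)
  l1 <- mean(vapply(seq_len(B), function(b) {
    mean(abs(real[[b]][!mask, ] - fake[[b]][!mask, ]))
  }, numeric(1)))
  alpha <- runif(B)
  Xhat <- Xr
  for (b in seq_len(B)) {
    Xhat[b, , ] <- alpha[b] * Xr[b, , ] + (1 - alpha[b]) * Xf[b, , ]
  }
  gp <- gradient_penalty(critic, Xhat, want_grads = FALSE)$value
  if (config$loss == "wasserstein") {
    critic_loss <- mean(Df) - mean(Dr) + config$gp_weight * gp
    gen_loss <- -mean(Df) + config$l1_weight * l1
  } else {
    critic_loss <- -mean(log(sigm(Dr) + 1e-12)) -
      mean(log(1 - sigm(Df) + 1e-12)) + config$gp_weight * gp
    gen_loss <- -mean(log(sigm(Df) + 1e-12)) + config$l1_weight * l1
  }
  list(critic_loss = critic_loss, gen_loss = gen_loss, l1_term = l1,
       gp_term = gp)
}

# One critic update on a batch. Returns new critic layers + loss pieces.
critic_step <- function(gen, critic, real, inputs, config, state) {
  spec <- gen$spec
  B <- length(real)
  fake <- generator_forward(gen, inputs)
  mot <- replicate(B, motif_encoding(spec), simplify = FALSE)
  Xf <- critic_input(mot, fake)
  Xr <- critic_input(mot, lapply(real, encode_onehot))
  ff <- net_forward(critic$layers, Xf)
  fr <- net_forward(critic$layers, Xr)
  ones <- matrix(1 / B, B, 1L)
  if (config$loss == "wasserstein") {
    gf <- net_backward(critic$layers, ff, ones)$grads
    gr <- net_backward(critic$layers, fr, -ones)$grads
    loss <- mean(ff$out) - mean(fr$out)
  } else {
    sf <- sigm(as.numeric(ff$out)); sr <- sigm(as.numeric(fr$out))
    gf <- net_backward(critic$layers, ff, matrix(sf / B, B, 1L))$grads
    gr <- net_backward(critic$layers, fr, matrix(-(1 - sr) / B, B, 1L))$grads
    loss <- -mean(log(sr + 1e-12)) - mean(log(1 - sf + 1e-12))
  }
  grads <- add_grads(gf, gr)
  gp_val <- 0
  if (config$gp_weight > 0) {
    alpha <- runif(B)
    Xhat <- Xr
    for (b in seq_len(B)) {
      Xhat[b, , ] <- alpha[b] * Xr[b, , ] + (1 - alpha[b]) * Xf[b, , ]
    }
    gp <- gradient_penalty(critic, Xhat)
    gp_val <- gp$value
    if (!is.null(gp$grads)) {
      grads <- add_grads(grads, scale_grads(gp$grads, config$gp_weight))
    }
  }
  critic$layers <- adam_update_layers(critic$layers, grads, state,
                                      config$learning_rate, config$beta1,
                                      config$beta2)
  list(critic = critic, loss = loss + config$gp_weight * gp_val,
       gp = gp_val)
}

# One generator update. Backprops the critic score and L1 term through the
# generator (seed rows carry no gradient: they are overwritten).
generator_step <- function(gen, critic, real, inputs, config, state) {
  spec <- gen$spec
  B <- length(real)
  L <- spec$window_length
  mask <- seed_mask(spec)
  X <- array(0, c(B, L, 4L))
  for (b in seq_len(B)) X[b, , ] <- inputs[[b]]$matrix
  gfwd <- generator_pass(gen, X)
  # emitted sequences: seed rows overwritten
  fake <- lapply(seq_len(B), function(b) {
    impose_seeds(matrix(gfwd$out[b, , ], L, 4L), spec)
  })
  mot <- replicate(B, motif_encoding(spec), simplify = FALSE)
  Xf <- critic_input(mot, fake)
  cf <- net_forward(critic$layers, Xf)
  if (config$loss == "wasserstein") {
    dscore <- matrix(-1 / B, B, 1L)
    adv_loss <- -mean(cf$out)
  } else {
    s <- sigm(as.numeric(cf$out))
    dscore <- matrix(-(1 - s) / B, B, 1L)
    adv_loss <- -mean(log(s + 1e-12))
  }
  dXf <- net_backward(critic$layers, cf, dscore)$dX
  dFake <- dXf[, , 5:8, drop = FALSE] # channels 1:4 are the conditioning
  # L1 term over flanking rows
  realm <- lapply(real, encode_onehot)
  nflank <- sum(!mask) * 4L
  l1 <- 0
  for (b in seq_len(B)) {
    diff <- fake[[b]] - realm[[b]]
    l1 <- l1 + mean(abs(diff[!mask, ]))
    dL1 <- matrix(0, L, 4L)
    dL1[!mask, ] <- sign(diff[!mask, ]) / (nflank * B)
    dFake[b, , ] <- dFake[b, , ] + config$l1_weight * dL1
  }
  l1 <- l1 / B
  # seed rows of the emitted matrix do not depend on generator output
  for (b in seq_len(B)) dFake[b, mask, ] <- 0
  grads <- generator_pass_bwd(gen, gfwd, dFake)
  gen$layers <- adam_update_layers(gen$layers, grads, state,
                                   config$learning_rate, config$beta1,
                                   config$beta2)
  list(gen = gen, loss = adv_loss + config$l1_weight * l1, l1 = l1)
}

#' Train the conditional GAN on a promoter dataset
#'
#' Alternates `critic_steps_per_gen_step` critic updates with one generator
#' update, Adam throughout, for `config$total_batches` total batches.
#' Real batches are (motif encoding, real sequence) pairs; generator inputs
#' re-draw fresh latent rows each batch. The log records the four loss
#' terms at every generator step; checkpoints record the mononucleotide
#' composition gap between generated and real flanks.
#'
#' @param dataset A [promoter_dataset()].
#' @param spec A [seed_spec()] describing the seed motifs shared by the
#'   training windows (per-record specs are supported by passing a list of
#'   specs of equal geometry; the common case is one shared spec).
#' @param config A [cgan_config()].
#' @param d_k,heads,kernel Architecture sizes passed to
#'   [generator_model()] and [critic_model()].
#' @return List of class `cgan_fit`: `generator`, `critic`, `log` (data
#'   frame per generator step: `step`, `critic_loss`, `gen_loss`,
#'   `l1_term`, `gp_term`), `checkpoints` (data frame: `step`,
#'   `flank_comp_gap`).
#' @export
train_cgan <- function(dataset, spec, config = cgan_config(), d_k = 64L,
                       heads = 4L, kernel = 3L) {
  stopifnot(inherits(dataset, "promoter_dataset"), length(dataset) > 0)
  set.seed(config$rng_seed)
  gen <- generator_model(spec, d_k = d_k, heads = heads, kernel = kernel,
                         rng_seed = config$rng_seed)
  critic <- critic_model(spec, d_k = d_k, heads = heads, kernel = kernel,
                         rng_seed = config$rng_seed + 1L)
  cstate <- adam_state_new()
  gstate <- adam_state_new()
  seqs <- dataset$records$seq
  n <- length(seqs)
  cycle <- config$critic_steps_per_gen_step + 1L
  n_gen_steps <- max(1L, config$total_batches %/% cycle)
  log <- vector("list", n_gen_steps)
  ckpts <- list()
  draw_batch <- function() {
    idx <- sample.int(n, config$batch_size, replace = n < config$batch_size)
    list(real = seqs[idx],
         inputs = lapply(idx, function(i) build_generator_input(spec)))
  }
  for (step in seq_len(n_gen_steps)) {
    closs <- gp <- NA_real_
    for (k in seq_len(config$critic_steps_per_gen_step)) {
      b <- draw_batch()
      r <- critic_step(gen, critic, b$real, b$inputs, config, cstate)
      critic <- r$critic; closs <- r$loss; gp <- r$gp
    }
    b <- draw_batch()
    r <- generator_step(gen, critic, b$real, b$inputs, config, gstate)
    gen <- r$gen
    log[[step]] <- data.frame(step = step, critic_loss = closs,
                              gen_loss = r$loss, l1_term = r$l1,
                              gp_term = gp)
    if (!all(is.finite(c(closs, r$loss)))) {
      warning("non-finite loss at generator step ", step,
              "; stopping early with last finite model")
      log <- log[seq_len(step)]
      break
    }
    if (config$checkpoint_every > 0 &&
        step %% config$checkpoint_every == 0L) {
      gap <- flank_composition_gap(gen, seqs, spec, n_sample = 32L)
      ckpts[[length(ckpts) + 1L]] <- data.frame(step = step,
                                                flank_comp_gap = gap)
    }
  }
  structure(list(generator = gen, critic = critic,
                 log = do.call(rbind, log),
                 checkpoints = if (length(ckpts)) do.call(rbind, ckpts)
                               else NULL,
                 config = config),
            class = "cgan_fit")
}

#' @export
print.cgan_fit <- function(x, ...) {
  cat("Conditional GAN fit:", nrow(x$log), "generator steps\n")
  cat("  final losses: critic", signif(x$log$critic_loss[nrow(x$log)], 4),
      "generator", signif(x$log$gen_loss[nrow(x$log)], 4), "l1",
      signif(x$log$l1_term[nrow(x$log)], 4), "\n")
  invisible(x)
}

# L1 gap between mononucleotide composition of generated vs real flanks.
flank_composition_gap <- function(gen, real_seqs, spec, n_sample = 32L) {
  mask <- seed_mask(spec)
  gen_seqs <- generator_sequences(
    gen, lapply(seq_len(n_sample), function(i) build_generator_input(spec)))
  comp <- function(ss) {
    ch <- unlist(lapply(ss, function(s) strsplit(s, "")[[1]][!mask]))
    tab <- table(factor(ch, levels = DNA_BASES))
    as.numeric(tab) / sum(tab)
  }
  sum(abs(comp(gen_seqs) - comp(sample(real_seqs,
                                       min(length(real_seqs), 200L)))))
}
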