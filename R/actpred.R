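#' Configuration of the sequence-to-activity predictor
#'
#' The predictor is a 1-D convolution (64 output channels by default)
#' followed by a stride-2 average pooling, a bidirectional LSTM, a DenseNet
#' trunk (4 dense blocks of 2, 2, 4 and 2 layers by default, growth rate
#' 32, dense-layer kernels 1 and 3, channel-halving transitions with
#' stride-2 pooling between blocks), global average pooling, and one fully
#' connected unit that predicts the activity. The defaults are the
#' full-scale architecture; every width is configurable so desk-scale
#' experiments can run quickly.
#'
#' @param conv1_channels First-conv output channels (default 64).
#' @param conv1_kernel First-conv kernel (default 7).
#' @param lstm_hidden Per-direction LSTM width (default 64).
#' @param dense_blocks Integer vector of layer counts, one per block
#'   (default `c(2, 2, 4, 2)`).
#' @param growth_rate DenseNet growth rate (default 32).
#' @param dense_layer_kernels Kernels of the two convs in each dense layer
#'   (default `c(1, 3)`).
#' @param learning_rate,beta1,beta2 Adam settings (defaults 1e-3, 0.9,
#'   0.999).
#' @param batch_size Minibatch size (default 32).
#' @param epochs Maximum training epochs (default 50).
#' @param patience Early-stopping patience on held-out loss (default 10).
#' @param early_stopping Keep the best-validation-loss weights (default
#'   TRUE). With FALSE the final epoch's weights are returned -- the right
#'   choice when the training labels carry no signal by construction
#'   (e.g. shuffled-label controls), where best-validation selection
#'   would return a near-initialisation model.
#' @param val_fraction Held-out fraction (default 0.2).
#' @param standardize Z-score activities before fitting (default TRUE;
#'   predictions are returned on the original scale).
#' @param rng_seed Integer seed (weights, split, batch order).
#' @return Object of class `predictor_config`.
#' @export
predictor_config <- function(conv1_channels = 64L, conv1_kernel = 7L,
                             lstm_hidden = 64L,
                             dense_blocks = c(2L, 2L, 4L, 2L),
                             growth_rate = 32L,
                             dense_layer_kernels = c(1L, 3L),
                             learning_rate = 1e-3, beta1 = 0.9,
                             beta2 = 0.999, batch_size = 32L,
                             epochs = 50L, patience = 10L,
                             early_stopping = TRUE,
                             val_fraction = 0.2, standardize = TRUE,
                             rng_seed = 1L) {
  stopifnot(length(dense_blocks) == 4L, growth_rate > 0,
            length(dense_layer_kernels) == 2L)
  structure(as.list(environment()), class = "predictor_config")
}

build_predictor_layers <- function(config) {
  ch <- config$conv1_channels
  H <- config$lstm_hidden
  layers <- list(
    list(type = "conv", k = config$conv1_kernel,
         W = glorot(config$conv1_kernel * 4L, ch), b = numeric(ch)),
    list(type = "act", slope = 0),
    list(type = "avgpool2"),
    list(type = "bilstm",
         params = list(Wx_f = glorot(ch, 4L * H), Wh_f = glorot(H, 4L * H),
                       b_f = numeric(4L * H), Wx_b = glorot(ch, 4L * H),
                       Wh_b = glorot(H, 4L * H), b_b = numeric(4L * H)))
  )
  cur <- 2L * H
  for (b in seq_along(config$dense_blocks)) {
    blk <- make_denseblock(cur, config$dense_blocks[b], config$growth_rate,
                           config$dense_layer_kernels)
    layers[[length(layers) + 1L]] <- blk
    cur <- blk$out_channels
    if (b < length(config$dense_blocks)) {
      half <- max(1L, cur %/% 2L)
      layers[[length(layers) + 1L]] <-
        list(type = "pointwise", W = glorot(cur, half), b = numeric(half))
      layers[[length(layers) + 1L]] <- list(type = "avgpool2")
      cur <- half
    }
  }
  layers[[length(layers) + 1L]] <- list(type = "gap")
  layers[[length(layers) + 1L]] <- list(type = "dense",
                                        W = glorot(cur, 1L),
                                        b = numeric(1L))
  layers
}

#' Train the activity predictor
#'
#' Minimises mean squared error on (optionally z-scored) activities with
#' Adam, early-stopping on held-out loss. The validation report carries
#' held-out Pearson and Spearman correlations.
#'
#' @param dataset A [promoter_dataset()] with at least 50 records.
#' @param config A [predictor_config()].
#' @param quiet Suppress per-epoch progress (default TRUE).
#' @return Object of class `predictor_model` with elements `layers`,
#'   `config`, `window_length`, `activity_center`/`activity_scale`, and
#'   `validation` (list: `pearson`, `spearman`, `mse`, `n_val`,
#'   `epochs_run`).
#' @export
train_predictor <- function(dataset, config = predictor_config(),
                            quiet = TRUE) {
  stopifnot(inherits(dataset, "promoter_dataset"))
  if (length(dataset) < 50L) stop("need at least 50 records")
  y <- dataset$records$activity
  if (stats::sd(y) == 0) stop("degenerate target: all activities identical")
  set.seed(config$rng_seed)
  center <- if (config$standardize) mean(y) else 0
  scl <- if (config$standardize) stats::sd(y) else 1
  ys <- (y - center) / scl
  seqs <- dataset$records$seq
  n <- length(seqs)
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  layers <- build_predictor_layers(config)
  state <- adam_state_new()
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  wait <- 0L
  mse_of <- function(lys, idx) {
    preds <- numeric(length(idx))
    bs <- 128L
    for (s in seq(1L, length(idx), bs)) {
      ii <- idx[s:min(s + bs - 1L, length(idx))]
      preds[s:(s + length(ii) - 1L)] <-
        as.numeric(net_forward(lys, encode_batch(seqs[ii]))$out)
    }
    mean((preds - ys[idx])^2)
  }
  epochs_run <- 0L
  for (epoch in seq_len(config$epochs)) {
    epochs_run <- epoch
    ord <- sample(tr_idx)
    for (s in seq(1L, length(ord), config$batch_size)) {
      ii <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      X <- encode_batch(seqs[ii])
      fwd <- net_forward(layers, X)
      resid <- as.numeric(fwd$out) - ys[ii]
      dOut <- matrix(2 * resid / length(ii), length(ii), 1L)
      grads <- net_backward(layers, fwd, dOut)$grads
      layers <- adam_update_layers(layers, grads, state,
                                   config$learning_rate, config$beta1,
                                   config$beta2)
    }
    vloss <- mse_of(layers, val_idx)
    if (!quiet) message("epoch ", epoch, " val mse ", signif(vloss, 4))
    if (vloss < best$loss - 1e-8) {
      best <- list(loss = vloss, layers = layers, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (config$early_stopping && wait >= config$patience) break
    }
  }
  if (config$early_stopping) layers <- best$layers
  # validation report on the original activity scale
  vp <- numeric(n_val)
  bs <- 128L
  for (s in seq(1L, n_val, bs)) {
    ii <- val_idx[s:min(s + bs - 1L, n_val)]
    vp[s:(s + length(ii) - 1L)] <-
      as.numeric(net_forward(layers, encode_batch(seqs[ii]))$out)
  }
  vp <- vp * scl + center
  validation <- list(
    pearson = stats::cor(vp, y[val_idx]),
    spearman = stats::cor(vp, y[val_idx], method = "spearman"),
    mse = mean((vp - y[val_idx])^2), n_val = n_val,
    epochs_run = epochs_run, best_epoch = best$epoch)
  structure(list(layers = layers, config = config,
                 window_length = dataset$window_length,
                 activity_center = center, activity_scale = scl,
                 validation = validation),
            class = "predictor_model")
}

#' @export
print.predictor_model <- function(x, ...) {
  cat("Activity predictor:", x$window_length, "bp window\n")
  v <- x$validation
  cat(sprintf("  held-out (n=%d): Pearson %.3f, Spearman %.3f, MSE %.4g\n",
              v$n_val, v$pearson, v$spearman, v$mse))
  invisible(x)
}

#' Predict activities for sequences
#'
#' @param model A trained `predictor_model`.
#' @param seqs Character vector of sequences of the model's window length.
#' @return Numeric vector of predicted activities (original scale).
#' @export
predict_activity <- function(model, seqs) {
  if (!all(nchar(seqs) == model$window_length)) {
    stop("sequence length(s) must equal model window ", model$window_length)
  }
  out <- numeric(length(seqs))
  bs <- 256L
  for (s in seq(1L, length(seqs), bs)) {
    ii <- s:min(s + bs - 1L, length(seqs))
    out[ii] <- as.numeric(net_forward(model$layers,
                                      encode_batch(seqs[ii]))$out)
  }
  out * model$activity_scale + model$activity_center
}

#' @export
predict.predictor_model <- function(object, newdata, ...) {
  predict_activity(object, newdata)
}

#' Saliency map of a sequence under the predictor
#'
#' The gradient of the (standardised-scale) predicted activity with respect
#' to the one-hot input. By default the gradient is masked by the input
#' (gradient x one-hot), giving one contribution per observed nucleotide;
#' `masked = FALSE` returns the raw L x 4 gradient.
#'
#' @param model A trained `predictor_model`.
#' @param seq A sequence of the model's window length.
#' @param masked Multiply the gradient by the one-hot input? (default TRUE)
#' @return Object of class `saliency_map`: list with `values` (L x 4
#'   matrix) and `seq`.
#' @export
saliency_map <- function(model, seq, masked = TRUE) {
  stopifnot(nchar(seq) == model$window_length)
  X <- encode_batch(seq)
  fwd <- net_forward(model$layers, X)
  g <- net_backward(model$layers, fwd, matrix(1, 1L, 1L))$dX
  values <- matrix(g[1, , ], model$window_length, 4L,
                   dimnames = list(NULL, DNA_BASES))
  if (masked) values <- values * encode_onehot(seq)
  structure(list(values = values, seq = seq), class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat("Saliency map,", nrow(x$values), "positions; strongest at position",
      which.max(rowSums(abs(x$values))), "\n")
  invisible(x)
}

#' Write saliency maps as TSV (position x channel)
#' @param maps List of `saliency_map`s (or one).
#' @param path Output TSV.
#' @export
write_saliency_tsv <- function(maps, path) {
  if (inherits(maps, "saliency_map")) maps <- list(maps)
  rows <- do.call(rbind, lapply(seq_along(maps), function(i) {
    v <- maps[[i]]$values
    data.frame(map = i, position = seq_len(nrow(v)) - 1L, A = v[, 1],
               C = v[, 2], G = v[, 3], T = v[, 4])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Cluster saliency maps with k-means
#'
#' Flattens each map to a vector, runs seeded k-means, and randomly samples
#' up to 30 members per cluster as representatives.
#'
#' @param maps List of `saliency_map`s with equal shapes.
#' @param k Number of clusters (default 7).
#' @param rng_seed Seed for initialisation and the per-cluster subsample.
#' @param n_representatives Members sampled per cluster (default 30).
#' @return List: `labels` (integer vector), `centroids` (list of k mean
#'   maps, L x 4), `representatives` (list of k index vectors),
#'   `kmeans_fit`.
#' @export
cluster_saliency <- function(maps, k = 7L, rng_seed = 1L,
                             n_representatives = 30L) {
  n <- length(maps)
  if (k > n) stop("k = ", k, " exceeds number of maps ", n)
  dims <- dim(maps[[1]]$values)
  M <- t(vapply(maps, function(m) as.numeric(m$values),
                numeric(prod(dims))))
  set.seed(rng_seed)
  fit <- stats::kmeans(M, centers = k, nstart = 5L, iter.max = 50L)
  centroids <- lapply(seq_len(k), function(j) {
    matrix(fit$centers[j, ], dims[1], dims[2],
           dimnames = list(NULL, DNA_BASES))
  })
  reps <- lapply(seq_len(k), function(j) {
    members <- which(fit$cluster == j)
    if (length(members) <= n_representatives) members
    else sort(sample(members, n_representatives))
  })
  list(labels = fit$cluster, centroids = centroids,
       representatives = reps, kmeans_fit = fit)
}

#' Penultimate-layer embedding of sequences
#'
#' Activations feeding the final dense unit (the output of the global
#' average pooling), one row per sequence. This embedding is the package's
#' "functional space": nearby sequences are treated similarly by the
#' predictor.
#'
#' @param model A trained `predictor_model`.
#' @param seqs Character vector of sequences.
#' @return `n x d` numeric matrix, `d` the final dense layer's input width.
#' @export
penultimate_embedding <- function(model, seqs) {
  if (!all(nchar(seqs) == model$window_length)) {
    stop("sequence length(s) must equal model window ", model$window_length)
  }
  d_final <- nrow(model$layers[[length(model$layers)]]$W)
  out <- matrix(0, length(seqs), d_final)
  bs <- 256L
  for (s in seq(1L, length(seqs), bs)) {
    ii <- s:min(s + bs - 1L, length(seqs))
    fwd <- net_forward(model$layers, encode_batch(seqs[ii]))
    out[ii, ] <- fwd$inputs[[length(model$layers)]]
  }
  out
}
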