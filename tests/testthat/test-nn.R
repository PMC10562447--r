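# The layer kernels are hand-derived; every backward pass is checked
# against central finite differences on small instances.

fd_input_grad <- function(layers, X, coord, eps = 1e-5) {
  E <- array(0, dim(X)); E[coord[1], coord[2], coord[3]] <- 1
  up <- sum(seedflank:::net_forward(layers, X + eps * E)$out)
  dn <- sum(seedflank:::net_forward(layers, X - eps * E)$out)
  (up - dn) / (2 * eps)
}

test_that("generator trunk backward matches finite differences", {
  set.seed(21)
  spec <- seed_spec(20L, list(list(seq = "TATAAT", start = 7L)))
  gen <- generator_model(spec, d_k = 8L, heads = 2L, rng_seed = 3L)
  X <- array(rnorm(2 * 20 * 4), c(2, 20, 4))
  fwd <- seedflank:::net_forward(gen$layers, X)
  bk <- seedflank:::net_backward(gen$layers, fwd, array(1, dim(fwd$out)))
  for (co in list(c(1, 1, 1), c(2, 11, 3), c(1, 20, 4))) {
    num <- fd_input_grad(gen$layers, X, co)
    expect_equal(bk$dX[co[1], co[2], co[3]], num, tolerance = 1e-4)
  }
})

test_that("predictor stack backward matches finite differences", {
  set.seed(22)
  cfg <- predictor_config(conv1_channels = 6L, conv1_kernel = 3L,
                          lstm_hidden = 4L, dense_blocks = c(1L, 1L, 1L, 1L),
                          growth_rate = 3L, rng_seed = 9L)
  layers <- seedflank:::build_predictor_layers(cfg)
  X <- array(rnorm(3 * 24 * 4), c(3, 24, 4))
  fwd <- seedflank:::net_forward(layers, X)
  bk <- seedflank:::net_backward(layers, fwd, matrix(1, 3, 1))
  for (co in list(c(1, 1, 1), c(2, 10, 3), c(3, 24, 4))) {
    num <- fd_input_grad(layers, X, co)
    expect_equal(bk$dX[co[1], co[2], co[3]], num, tolerance = 1e-4)
  }
  # parameter gradients: first conv, LSTM recurrences, dense head
  pert_loss <- function(mod) sum(seedflank:::net_forward(mod, X)$out)
  eps <- 1e-5
  check_param <- function(getter, setter, analytic) {
    up <- setter(layers, getter(layers) + eps)
    dn <- setter(layers, getter(layers) - eps)
    expect_equal(analytic, (pert_loss(up) - pert_loss(dn)) / (2 * eps),
                 tolerance = 1e-4)
  }
  check_param(function(l) l[[1]]$W[2, 3],
              function(l, v) { l[[1]]$W[2, 3] <- v; l },
              bk$grads[[1]]$W[2, 3])
  check_param(function(l) l[[4]]$params$Wh_b[2, 5],
              function(l, v) { l[[4]]$params$Wh_b[2, 5] <- v; l },
              bk$grads[[4]]$Wh_b[2, 5])
  check_param(function(l) l[[5]]$sub[[1]]$conv2$W[2, 1],
              function(l, v) { l[[5]]$sub[[1]]$conv2$W[2, 1] <- v; l },
              bk$grads[[5]][[1]]$conv2$W[2, 1])
  nl <- length(layers)
  check_param(function(l) l[[nl]]$W[3, 1],
              function(l, v) { l[[nl]]$W[3, 1] <- v; l },
              bk$grads[[nl]]$W[3, 1])
})

test_that("DenseNet connectivity is assertable from the weight shapes", {
  cfg <- predictor_config(conv1_channels = 10L, lstm_hidden = 6L,
                          dense_blocks = c(2L, 2L, 4L, 2L),
                          growth_rate = 5L)
  layers <- seedflank:::build_predictor_layers(cfg)
  blocks <- Filter(function(l) l$type == "denseblock", layers)
  expect_length(blocks, 4L)
  for (blk in blocks) {
    in_ch <- nrow(blk$sub[[1]]$conv1$W) / blk$sub[[1]]$conv1$k
    for (j in seq_along(blk$sub)) {
      # channels into layer j = block input + (j-1) * growth_rate
      expect_equal(nrow(blk$sub[[j]]$conv1$W) / blk$sub[[j]]$conv1$k,
                   in_ch + (j - 1L) * cfg$growth_rate)
    }
    expect_equal(blk$out_channels, in_ch + length(blk$sub) * cfg$growth_rate)
  }
})

test_that("gradient-penalty parameter gradients match finite differences", {
  set.seed(23)
  spec <- seed_spec(16L, list(list(seq = "TATAAT", start = 5L)))
  critic <- critic_model(spec, d_k = 8L, heads = 2L, rng_seed = 7L)
  Xhat <- array(rnorm(3 * 16 * 8), c(3, 16, 8))
  gp <- seedflank:::gradient_penalty(critic, Xhat)
  penalty_of <- function(cr) {
    g <- seedflank:::critic_input_grad(cr, Xhat)
    norms <- sqrt(apply(g^2, 1, sum))
    mean((norms - 1)^2)
  }
  eps <- 1e-4
  for (probe in list(list(l = 1, i = 3, j = 2), list(l = 7, i = 5, j = 1))) {
    up <- critic; up$layers[[probe$l]]$W[probe$i, probe$j] <-
      up$layers[[probe$l]]$W[probe$i, probe$j] + eps
    dn <- critic; dn$layers[[probe$l]]$W[probe$i, probe$j] <-
      dn$layers[[probe$l]]$W[probe$i, probe$j] - eps
    num <- (penalty_of(up) - penalty_of(dn)) / (2 * eps)
    expect_equal(gp$grads[[probe$l]]$W[probe$i, probe$j], num,
                 tolerance = 2e-3)
  }
})
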