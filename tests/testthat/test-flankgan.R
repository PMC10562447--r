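make_heads <- function(d_k, heads, seed = 1) {
  set.seed(seed)
  seedflank:::make_attention_params(d_k, heads)
}

test_that("multi-head attention matches a dense-loop recomputation", {
  params <- make_heads(8L, 2L, seed = 31)
  set.seed(32)
  X <- matrix(rnorm(5 * 8), 5, 8)
  got <- multi_head_attention(X, params)
  # straight-line re-computation: explicit loops, no batched tricks
  dh <- 4L
  ref <- matrix(0, 5, 8)
  for (h in 1:2) {
    Q <- X %*% params$Aq[[h]]; K <- X %*% params$Ak[[h]]
    V <- X %*% params$Av[[h]]
    for (i in 1:5) {
      sc <- numeric(5)
      for (j in 1:5) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(8)
      w <- exp(sc - max(sc)); w <- w / sum(w)
      for (c in 1:dh) {
        ref[i, (h - 1) * dh + c] <- sum(w * V[, c])
      }
    }
  }
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("attention degenerates correctly on single positions and ties", {
  params <- make_heads(4L, 1L, seed = 33)
  X1 <- matrix(rnorm(4), 1, 4)
  # n = 1: softmax over a scalar is 1, output = X Av
  expect_equal(multi_head_attention(X1, params), X1 %*% params$Av[[1]],
               tolerance = 1e-12)
  # two identical rows give identical outputs
  X2 <- rbind(X1, X1)
  out <- multi_head_attention(X2, params)
  expect_equal(out[1, ], out[2, ])
  expect_error(multi_head_attention(matrix(0, 2, 6), params), "d_k")
})

test_that("generator output is row-stochastic with hard seed rows", {
  spec <- toy_spec(40L)
  gen <- generator_model(spec, d_k = 8L, heads = 2L, rng_seed = 4L)
  set.seed(41)
  for (i in 1:20) {
    out <- generator_forward(gen, build_generator_input(spec))
    expect_true(all(abs(rowSums(out) - 1) < 1e-6))
    s <- decode_onehot(out)
    expect_equal(substr(s, 6, 11), "TTGACA")
    expect_equal(substr(s, 26, 31), "TATAAT")
  }
})

test_that("critic is deterministic and zero-headed critics score zero", {
  spec <- seed_spec(20L, list(list(seq = "TATAAT", start = 7L)))
  critic <- critic_model(spec, d_k = 8L, heads = 2L, rng_seed = 5L)
  m <- seedflank:::motif_encoding(spec)
  x <- encode_onehot(random_dna(1, 20, seed = 51))
  expect_identical(critic_forward(critic, m, x),
                   critic_forward(critic, m, x))
  critic$layers[[7]]$W[] <- 0
  critic$layers[[7]]$b[] <- 0
  expect_equal(critic_forward(critic, m, x), 0)
  expect_error(critic_forward(critic, m, encode_onehot("ACGT")), "20")
})

test_that("loss terms behave as the objective dictates", {
  spec <- seed_spec(20L, list(list(seq = "TATAAT", start = 7L)))
  gen <- generator_model(spec, d_k = 8L, heads = 2L, rng_seed = 6L)
  critic <- critic_model(spec, d_k = 8L, heads = 2L, rng_seed = 7L)
  set.seed(61)
  inputs <- lapply(1:4, function(i) build_generator_input(spec))
  real <- generator_sequences(gen, inputs) # G reproduces these exactly
  # relaxed outputs differ from hard encodings, so compute L1 on the
  # emitted matrices: feeding the generator's own decoded output as real
  # keeps the decoded argmax equal, not the relaxed rows; the exact-zero
  # case is the matrix identity, checked directly:
  fake <- generator_forward(gen, inputs)
  mask <- seed_mask(spec)
  l1_self <- mean(vapply(fake, function(f) mean(abs(f - f)[!mask, ]),
                         numeric(1)))
  expect_equal(l1_self, 0)
  losses <- cgan_losses(gen, critic, real, inputs)
  expect_true(all(vapply(losses, is.finite, logical(1))))
  expect_gte(losses$gp_term, 0)
  expect_error(cgan_losses(gen, critic, character(0), list()), "empty")
})

test_that("a linear critic with unit-norm gradient has zero penalty", {
  # analytic: D(x) = <u, x> with ||u|| = 1 has grad u everywhere
  L <- 6L
  u <- array(rnorm(1 * L * 8), c(1, L, 8))
  u <- u / sqrt(sum(u^2))
  hook <- list(grad_fn = function(X) {
    out <- X
    for (b in seq_len(dim(X)[1])) out[b, , ] <- u[1, , ]
    out
  })
  Xhat <- array(rnorm(3 * L * 8), c(3, L, 8))
  gp <- seedflank:::gradient_penalty(hook, Xhat, want_grads = FALSE)
  expect_equal(gp$value, 0, tolerance = 1e-12)
})

test_that("scaled training reduces reconstruction error deterministically", {
  spec <- seed_spec(20L, list(list(seq = "TATAAT", start = 7L)))
  set.seed(71)
  mask <- seed_mask(spec)
  tmpl <- strsplit(seed_template(spec), "")[[1]]
  seqs <- vapply(1:80, function(i) {
    ch <- sample(c("A", "C", "G", "T"), 20, replace = TRUE,
                 prob = c(0.1, 0.2, 0.5, 0.2))
    ch[mask] <- tmpl[mask]
    paste(ch, collapse = "")
  }, character(1))
  ds <- promoter_dataset(seqs, rnorm(80))
  cfg <- cgan_config(batch_size = 16L, total_batches = 240L, rng_seed = 8L)
  fit <- train_cgan(ds, spec, cfg, d_k = 8L, heads = 2L)
  expect_lt(fit$log$l1_term[nrow(fit$log)], fit$log$l1_term[1])
  # identical config and seed reproduce the loss trajectory bitwise
  fit2 <- train_cgan(ds, spec, cfg, d_k = 8L, heads = 2L)
  expect_identical(fit$log, fit2$log)
})
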