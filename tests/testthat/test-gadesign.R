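test_that("GA climbs a toy landscape with non-decreasing elite fitness", {
  spec <- toy_spec(40L)
  gen <- generator_model(spec, d_k = 16L, heads = 2L, rng_seed = 3L)
  mask <- seed_mask(spec)
  g_count <- function(seqs) {
    vapply(seqs, function(s) sum(strsplit(s, "")[[1]][!mask] == "G"),
           numeric(1))
  }
  cfg <- ga_config(population = 64L, generations = 20L, rng_seed = 4L)
  res <- ga_optimize(gen, g_count, spec, cfg)
  expect_false(is.unsorted(res$trace$best))
  expect_gt(res$trace$best[20], res$trace$mean[1])
  # all designs keep the seed motifs
  expect_true(all(substr(res$designs$seq, 6, 11) == "TTGACA"))
  expect_true(all(substr(res$designs$seq, 26, 31) == "TATAAT"))
  # ranking is non-increasing
  expect_false(is.unsorted(rev(res$designs$predicted_activity)))
  # identical seed reproduces the whole result
  res2 <- ga_optimize(gen, g_count, spec, cfg)
  expect_identical(res$designs, res2$designs)
  expect_identical(res$trace, res2$trace)
})

test_that("without variation operators the population never changes", {
  spec <- seed_spec(24L, list(list(seq = "TATAAT", start = 9L)))
  gen <- generator_model(spec, d_k = 8L, heads = 2L, rng_seed = 5L)
  fitness <- function(seqs) nchar(gsub("[^G]", "", seqs))
  cfg <- ga_config(population = 8L, generations = 6L, mutation_prob = 0,
                   crossover_prob = 0, rng_seed = 6L)
  res <- ga_optimize(gen, fitness, spec, cfg)
  expect_equal(length(unique(res$trace$best)), 1L)
  expect_error(ga_config(population = 2L, elitism = 5L), "elitism")
})

test_that("motif filter rejects exactly what a sliding recount rejects", {
  set.seed(61)
  motif <- pwm_from_consensus("GGATCC", certainty = 0.95, name = "bamhi")
  seqs <- random_dna(100, 40)
  thr <- 8
  got <- motif_filter(seqs, list(motif), threshold = thr,
                      mode = "logodds")
  # brute-force recount on both strands
  sm <- log2(sweep(motif$matrix, 2, motif$background, "/"))
  score_window <- function(w) {
    idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    sum(sm[cbind(1:6, idx)])
  }
  hit <- vapply(seqs, function(s) {
    for (st in 1:(40 - 5)) {
      if (score_window(substr(s, st, st + 5)) >= thr) return(TRUE)
    }
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (st in 1:(40 - 5)) {
      if (score_window(substr(rc, st, st + 5)) >= thr) return(TRUE)
    }
    FALSE
  }, logical(1))
  expect_setequal(got$rejected, seqs[hit])
  expect_equal(length(got$retained), sum(!hit))
})

test_that("motif filter annotates consensus hits and passes empty libraries", {
  motif <- pwm_from_consensus("TGCAGT", certainty = 0.9, name = "m")
  s <- paste0(strrep("A", 10), "TGCAGT", strrep("A", 10))
  got <- motif_filter(s, list(motif), threshold = 1e-3)
  expect_equal(got$rejected, s)
  expect_true(any(got$hits$start == 10 & got$hits$strand == "+"))
  expect_warning(out <- motif_filter(s, list()), "empty")
  expect_equal(out$retained, s)
})

test_that("the design pipeline filters, deduplicates and warns sanely", {
  ts <- tiny_sim()
  spec <- ts$config$planted_spec
  gen <- generator_model(spec, d_k = 8L, heads = 2L, rng_seed = 7L)
  mod <- tiny_predictor()
  cfg <- ga_config(population = 24L, generations = 5L, rng_seed = 8L)
  res <- design_promoters(gen, mod, spec, cfg, n_out = 10L)
  expect_true(all(nchar(res$designs$seq) == 30L))
  expect_true(all(substr(res$designs$seq, 5, 10) == "TTGACA"))
  expect_false(any(duplicated(res$designs$seq)))
  tally <- attr(res$designs, "filter_tally")
  survivors <- tally["candidates"] - tally["deduplicated"] -
    tally["motif_rejected"] - tally["second_promoter_rejected"]
  expect_gte(unname(survivors), unname(tally["returned"]))
  expect_equal(unname(tally["returned"]), nrow(res$designs))
  # a library matching every base rejects everything, with a warning
  everything <- lapply(c("A", "C", "G", "T"), function(b) {
    pwm_from_consensus(b, certainty = 0.97, name = paste0("any", b))
  })
  expect_warning(
    res2 <- design_promoters(gen, mod, spec, cfg, n_out = 5L,
                             filters = list(motif_library = everything,
                                            motif_threshold = 0,
                                            motif_mode = "logodds")),
    "filtered out")
  tally2 <- attr(res2$designs, "filter_tally")
  expect_equal(unname(tally2["returned"]), 0L)
  expect_equal(nrow(res2$designs), 0L)
  expect_equal(unname(tally2["motif_rejected"] + tally2["deduplicated"]),
               unname(tally2["candidates"]))
})

test_that("design reports serialise to FASTA and JSON", {
  ts <- tiny_sim()
  spec <- ts$config$planted_spec
  gen <- generator_model(spec, d_k = 8L, heads = 2L, rng_seed = 9L)
  res <- ga_optimize(gen, function(s) nchar(gsub("[^G]", "", s)), spec,
                     ga_config(population = 8L, generations = 3L,
                               rng_seed = 10L))
  fa <- file.path(tempdir(), "designs.fa")
  js <- file.path(tempdir(), "designs.json")
  write_design_report(res, fa, js)
  back <- read_fasta(fa)
  expect_equal(length(back), nrow(res$designs))
  expect_equal(attr(back, "activity"), res$designs$predicted_activity,
               tolerance = 1e-5)
  rep <- jsonlite::fromJSON(js)
  expect_equal(nrow(rep$trace), 3L)
})
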