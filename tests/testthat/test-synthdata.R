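test_that("activity tables load with exclusions counted", {
  p <- file.path(tempdir(), "tab.tsv")
  writeLines(c("sequence\tactivity", "ACGTACGT\t1.0", "TTTTTTTT\t2.5",
               "GGGGCCCC\tNA", "ACGTACGT\t1.0"), p)
  ds <- load_activity_table(p)
  expect_equal(length(ds), 3L) # NA row dropped, duplicate kept
  expect_equal(attr(ds, "excluded")[["bad_activity"]], 1L)
  dd <- load_activity_table(p, dedupe = TRUE)
  expect_equal(length(dd), length(unique(dd$records$seq)))
  expect_equal(attr(dd, "excluded")[["duplicate"]], 1L)
  expect_error(load_activity_table(p, seq_column = "nope"), "nope")
})

test_that("geometry filter applies the four rules in order", {
  # construct a 120 bp record with known geometry: TSS at 110,
  # -10 end 8 bp upstream (start 96), -35 end 27 bp upstream (start 77),
  # spacer 96 - 83 = 13
  L <- 120L; tss <- 110L
  ch <- rep("C", L)
  ch[(77 + 1):(77 + 6)] <- strsplit("TTGACA", "")[[1]]
  ch[(96 + 1):(96 + 6)] <- strsplit("TATAAT", "")[[1]]
  good <- paste(ch, collapse = "")
  ds <- promoter_dataset(good, 1,
                         meta = data.frame(minus10_start = 96L,
                                           minus35_start = 77L))
  kept <- filter_promoters(ds, tss)
  expect_equal(length(kept), 1L)
  # -35 end 49 bp upstream violates rule (c), which precedes rule (d)
  ds2 <- promoter_dataset(good, 1,
                          meta = data.frame(minus10_start = 96L,
                                            minus35_start = 55L))
  rej <- filter_promoters(ds2, tss)
  expect_equal(length(rej), 0L)
  expect_equal(attr(rej, "rejections")$rule, "c")
  # -35 placement fine (39 bp upstream) but spacer 25 violates rule (d)
  ds3 <- promoter_dataset(good, 1,
                          meta = data.frame(minus10_start = 96L,
                                            minus35_start = 65L))
  expect_equal(attr(filter_promoters(ds3, tss), "rejections")$rule, "d")
  expect_error(filter_promoters(ds, 200L), "outside window")
})

test_that("filter retains exactly the records a rule-by-rule recount keeps", {
  set.seed(77)
  L <- 120L; tss <- 100L
  n <- 200L
  m10 <- sample(60:95, n, replace = TRUE)
  m35 <- sample(40:80, n, replace = TRUE)
  seqs <- random_dna(n, L)
  ds <- promoter_dataset(seqs, rnorm(n),
                         meta = data.frame(minus10_start = m10,
                                           minus35_start = m35))
  kept <- filter_promoters(ds, tss)
  # independent re-implementation of the four inequalities
  d10 <- tss - (m10 + 6L)
  d35 <- tss - (m35 + 6L)
  spacer <- m10 - (m35 + 6L)
  ok <- (tss > 75L) & (d10 >= 1L & d10 <= 21L) &
    (d35 >= 25L & d35 <= 45L) & (spacer >= 10L & spacer <= 24L)
  expect_equal(length(kept), sum(ok))
  # idempotence: filtering the filtered set changes nothing
  again <- filter_promoters(kept, tss)
  expect_equal(again$records$seq, kept$records$seq)
})

test_that("simulated datasets are reproducible and respect planted seeds", {
  spec <- seed_spec(30L, list(list(seq = "TTGACA", start = 4L),
                              list(seq = "TATAAT", start = 18L)))
  cfg <- sim_config(50L, window_length = 30L, planted_spec = spec,
                    motif_certainty = 1, rng_seed = 7L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$records, b$records)
  # exact-consensus planting: every record carries the motifs in place
  expect_true(all(substr(a$records$seq, 5, 10) == "TTGACA"))
  expect_true(all(substr(a$records$seq, 19, 24) == "TATAAT"))
})

test_that("stored activity equals the oracle when noise is off", {
  cfg <- sim_config(60L, window_length = 30L,
                    planted_spec = seed_spec(30L, list(
                      list(seq = "TATAAT", start = 10L))),
                    activity_weights = list(w_motif = 1, w_flank = 20,
                                            noise_sd = 0),
                    rng_seed = 9L)
  ds <- simulate_dataset(cfg)
  oracle <- vapply(ds$records$seq, activity_oracle, numeric(1),
                   config = cfg, USE.NAMES = FALSE)
  expect_equal(ds$records$activity, oracle)
  expect_equal(ds$records$oracle, oracle)
})

test_that("the oracle matches an independent recomputation", {
  spec <- seed_spec(30L, list(list(seq = "TATAAT", start = 12L)))
  cfg <- sim_config(10L, window_length = 30L, planted_spec = spec,
                    rng_seed = 3L)
  set.seed(15)
  for (s in random_dna(100, 30)) {
    # plant the motif so the window is a legal design
    substr(s, 13, 18) <- "TATAAT"
    w <- cfg$activity_weights
    motif <- pwm_log_odds("TATAAT", cfg$motif_pwms[[1]])
    flank <- paste0(substr(s, 1, 12), substr(s, 19, 30))
    gc <- mean(strsplit(flank, "")[[1]] %in% c("G", "C"))
    hits <- sum(gregexpr("GCCA", substr(s, 1, 12), fixed = TRUE)[[1]] > 0) +
      sum(gregexpr("GCCA", substr(s, 19, 30), fixed = TRUE)[[1]] > 0)
    expected <- w$w_motif * motif +
      w$w_flank * ((gc - 0.5) + cfg$bonus_per_hit * hits)
    expect_equal(activity_oracle(s, cfg), expected, tolerance = 1e-12)
  }
  expect_error(activity_oracle("ACGT", cfg), "length")
})

test_that("oracle is monotone in flanking GC and maximal at consensus", {
  spec <- seed_spec(20L, list(list(seq = "TATAAT", start = 7L)))
  cfg <- sim_config(10L, window_length = 20L, planted_spec = spec,
                    activity_weights = list(w_motif = 1, w_flank = 20,
                                            noise_sd = 0))
  lowgc <- paste0(strrep("A", 7), "TATAAT", strrep("A", 7))
  higc <- paste0(strrep("G", 7), "TATAAT", strrep("G", 7))
  expect_lt(activity_oracle(lowgc, cfg), activity_oracle(higc, cfg))
  # consensus motif scores at least as high as any single mismatch
  base <- activity_oracle(lowgc, cfg)
  for (pos in 8:13) {
    for (b in c("A", "C", "G", "T")) {
      mut <- lowgc
      substr(mut, pos, pos) <- b
      expect_lte(activity_oracle(mut, cfg), base + 1e-9)
    }
  }
})

test_that("dataset writers round-trip through TSV and FASTA", {
  ds <- tiny_sim()$dataset
  p1 <- file.path(tempdir(), "ds.tsv")
  write_dataset(ds, p1)
  back <- load_activity_table(p1)
  expect_equal(back$records$seq, ds$records$seq)
  expect_equal(back$records$activity, ds$records$activity,
               tolerance = 1e-6)
  p2 <- file.path(tempdir(), "ds.fa")
  write_dataset(ds, p2)
  back2 <- as_promoter_dataset(p2)
  expect_equal(back2$records$seq, ds$records$seq)
})
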