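test_that("k-mer spectra are probability vectors matching a hash recount", {
  f <- kmer_frequencies("AAAA", 4)
  expect_equal(unname(f["AAAA"]), 1)
  expect_equal(sum(f), 1)
  set.seed(201)
  seqs <- random_dna(50, 165)
  f4 <- kmer_frequencies(seqs, 4)
  expect_equal(sum(f4), 1)
  expect_true(all(f4 >= 0))
  # independent hash-map recount
  counts <- new.env(parent = emptyenv())
  for (s in seqs) {
    for (i in 1:(nchar(s) - 3)) {
      w <- substr(s, i, i + 3)
      counts[[w]] <- (counts[[w]] %||% 0) + 1
    }
  }
  tot <- sum(unlist(as.list(counts)))
  for (w in ls(counts)) {
    expect_equal(unname(f4[w]), counts[[w]] / tot, tolerance = 1e-12)
  }
  expect_warning(kmer_frequencies(c("ACGTACGT", "AC"), 4), "skipped")
})

test_that("k-mer correlation behaves at the extremes", {
  set.seed(202)
  seqs <- random_dna(30, 60)
  expect_equal(kmer_correlation(seqs, seqs, 4), 1)
  # disjoint single-k-mer sets anticorrelate
  expect_lt(kmer_correlation(strrep("A", 20), strrep("C", 20), 4), 0)
  # two independent samples of the same composition-biased population
  # estimate the same non-uniform spectrum
  biased <- function(n) vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 100, TRUE,
                 prob = c(0.15, 0.2, 0.45, 0.2)), collapse = "")
  }, character(1))
  expect_gt(kmer_correlation(biased(500), biased(500), 4), 0.9)
})

test_that("edit distance matches brute-force recursion and the axioms", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("", "ACGT"), 4L)
  set.seed(203)
  for (rep in 1:50) {
    a <- random_dna(1, sample(0:8, 1))
    b <- random_dna(1, sample(0:8, 1))
    expect_equal(edit_distance(a, b), lev_recursive(a, b))
  }
  # metric axioms on random triples
  for (rep in 1:20) {
    x <- random_dna(3, sample(4:10, 1))
    expect_equal(edit_distance(x[1], x[2]), edit_distance(x[2], x[1]))
    expect_lte(edit_distance(x[1], x[3]),
               edit_distance(x[1], x[2]) + edit_distance(x[2], x[3]))
  }
})

test_that("diversity profiles enumerate all cross-group pairs", {
  p <- diversity_profile("ACGT", list(g = "ACGT"))
  expect_equal(p$distance, 0L)
  p2 <- diversity_profile(random_dna(3, 10, seed = 204),
                          list(g = random_dna(4, 10)))
  expect_equal(nrow(p2), 12L)
  # histogram equals a pairwise recount
  A <- random_dna(10, 12, seed = 205)
  B <- random_dna(10, 12)
  p3 <- diversity_profile(A, list(n = B))
  manual <- as.vector(vapply(B, function(b) {
    vapply(A, function(a) lev_recursive(a, b), numeric(1))
  }, numeric(10)))
  expect_equal(sort(p3$distance), sort(as.integer(manual)))
})

test_that("template difference normalises by flanking length", {
  # window 16, one 6 bp seed; designed differs from template at all 10
  # flanking positions
  spec <- seed_spec(16L, list(list(seq = "TTGACA", start = 5L)))
  template <- paste0("AAAAA", "TTGACA", "AAAAA")
  designed <- paste0("CCCCC", "TTGACA", "CCCCC")
  td <- template_difference(designed, template, spec, mode = "flanking")
  expect_equal(td$scores, 1.0)
  expect_equal(td$flanking_length, 10L)
  expect_equal(template_difference(template, template, spec)$scores, 0)
  expect_equal(td$sd, 0) # single design
  expect_error(template_difference("ACGT", template, spec), "length")
})

test_that("levenshtein template scores never exceed hamming scores", {
  spec <- seed_spec(40L, list(list(seq = "TTGACA", start = 6L),
                              list(seq = "TATAAT", start = 26L)))
  tm <- paste0(strrep("A", 6), "TTGACA", strrep("A", 14), "TATAAT",
               strrep("A", 8))
  set.seed(206)
  designs <- random_sequences(30, 40, spec = spec)
  td <- template_difference(designs, tm, spec, mode = "flanking")
  mask <- seed_mask(spec)
  hamming <- vapply(designs, function(s) {
    sum(strsplit(s, "")[[1]][!mask] != strsplit(tm, "")[[1]][!mask])
  }, numeric(1)) / flanking_length(spec)
  expect_true(all(td$scores <= hamming + 1e-12))
  # expected mismatch fraction of uniform flanks is at most 0.75
  expect_lte(mean(hamming), 0.75 + 3 * sd(hamming) / sqrt(30))
})

test_that("full-sequence mode can differ from flanking-only mode", {
  spec <- seed_spec(16L, list(list(seq = "TTGACA", start = 5L)))
  template <- paste0("AAAAA", "TTGACA", "AAAAA")
  designed <- paste0("CCCCC", "TTGACA", "CCCCC")
  td_full <- template_difference(designed, template, spec, mode = "full")
  expect_equal(td_full$scores, 1.0) # seeds align, 10 substitutions / 10
})

test_that("shape tracks follow the pentamer windowing conventions", {
  tab <- synthetic_shape_table()
  tr <- dna_shape("AAAAAAA", tab)
  aa <- tab$MGW[tab$pentamer == "AAAAA"]
  expect_equal(tr$mgw[3:5], rep(aa, 3))
  expect_true(all(is.na(tr$mgw[c(1, 2, 6, 7)])))
  expect_equal(sum(tr$defined), 7L - 4L)
  expect_equal(sum(!is.na(tr$roll)), 7L - 4L)
  expect_error(dna_shape("ACG", tab), "at least 5")
  # missing pentamer is a completeness error
  bad <- tab[tab$pentamer != "ACGTA", ]
  expect_error(dna_shape("TACGTAC", bad), "ACGTA")
})

test_that("MGW and ProT tracks are reverse-complement symmetric", {
  tab <- synthetic_shape_table()
  set.seed(207)
  for (s in random_dna(50, 30)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    a <- dna_shape(s, tab)
    b <- dna_shape(rc, tab)
    expect_equal(a$mgw, rev(b$mgw))
    expect_equal(a$prot, rev(b$prot))
    # step parameters mirror too under the symmetric synthetic table
    expect_equal(a$roll, rev(b$roll))
    expect_equal(a$helt, rev(b$helt))
  }
})

test_that("shape tables round-trip and complete canonical halves", {
  tab <- synthetic_shape_table()
  p <- file.path(tempdir(), "shape.tsv")
  write_shape_table(tab, p)
  back <- load_shape_table(p)
  expect_equal(back$MGW, tab$MGW)
  # drop all pentamers lexicographically above their reverse complement
  canon <- tab[tab$pentamer <= seedflank:::revcomp(tab$pentamer), ]
  write_shape_table(canon, p)
  completed <- load_shape_table(p)
  expect_equal(nrow(completed), 1024L)
  expect_equal(completed$MGW, tab$MGW)
})

test_that("shape embedding is deterministic and respects duplicates", {
  set.seed(208)
  seqs <- c(random_dna(12, 20), random_dna(1, 20))
  seqs[13] <- seqs[1] # exact duplicate
  emb <- shape_embedding(seqs, reduction_seed = 3)
  emb2 <- shape_embedding(seqs, reduction_seed = 3)
  expect_identical(emb$coords, emb2$coords)
  expect_equal(emb$coords[13, ], emb$coords[1, ])
  expect_error(shape_embedding(random_dna(5, 20)), "at least 10")
})

test_that("AT-shifted populations separate in the shape embedding", {
  set.seed(209)
  at_rich <- vapply(1:15, function(i) {
    paste(sample(c("A", "T", "C", "G"), 30, TRUE,
                 prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
  }, character(1))
  gc_rich <- vapply(1:15, function(i) {
    paste(sample(c("A", "T", "C", "G"), 30, TRUE,
                 prob = c(0.1, 0.1, 0.4, 0.4)), collapse = "")
  }, character(1))
  emb <- shape_embedding(c(at_rich, gc_rich))
  sil <- silhouette_mean(emb$coords, rep(1:2, each = 15))
  expect_gt(sil, 0.2)
})

test_that("PWM log-odds scoring matches a straight-loop recomputation", {
  u <- pwm(matrix(0.25, 6, 4))
  expect_equal(pwm_log_odds("ACGTAC", u), 0)
  set.seed(210)
  for (rep in 1:20) {
    m <- matrix(runif(32), 8, 4); m <- m / rowSums(m)
    p <- pwm(m)
    w <- random_dna(1, 8)
    idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
    manual <- sum(log2(m[cbind(1:8, idx)] / 0.25))
    expect_equal(pwm_log_odds(w, p), manual, tolerance = 1e-12)
  }
  # consensus attains the column-wise maximum
  p <- pwm_from_consensus("TTGACA", certainty = 0.7)
  cons <- pwm_log_odds("TTGACA", p)
  for (s in random_dna(20, 6, seed = 211)) {
    expect_lte(pwm_log_odds(s, p), cons + 1e-12)
  }
  expect_error(pwm_log_odds("ACGT", p), "width")
})

test_that("exact p-values agree with exhaustive enumeration", {
  set.seed(212)
  mers4 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4))[, 4:1],
                 1, paste, collapse = "")
  for (rep in 1:5) {
    m <- matrix(runif(16), 4, 4); m <- m / rowSums(m)
    p <- pwm(m)
    sc <- vapply(mers4, pwm_log_odds, numeric(1), pwm = p)
    for (q in unname(quantile(sc, c(0, 0.3, 0.7, 1)))) {
      exact <- mean(sc >= q - 1e-9)
      expect_equal(pwm_pvalue(p, q), exact, tolerance = 1e-6)
    }
  }
  p <- pwm_from_consensus("TTGACA", certainty = 0.8)
  expect_equal(pwm_pvalue(p, -Inf), 1)
  expect_equal(pwm_pvalue(p, pwm_log_odds("TTGACA", p) + 0.1), 0)
  # monotone non-increasing in score
  ss <- seq(-8, 8, length.out = 30)
  ps <- vapply(ss, function(s) pwm_pvalue(p, s), numeric(1))
  expect_false(is.unsorted(rev(ps)))
  expect_error(pwm_pvalue(p, NA), "finite")
})

test_that("second-promoter scan localises a planted promoter structure", {
  p35 <- pwm_from_consensus("TTGACA", certainty = 0.9)
  p10 <- pwm_from_consensus("TATAAT", certainty = 0.9)
  core <- paste0("TTGACA", strrep("A", 17), "TATAAT")
  set.seed(213)
  s <- random_dna(1, 120)
  substr(s, 41, 40 + nchar(core)) <- core
  scan <- second_promoter_scan(s, p10, p35)
  expect_equal(scan$track$start[which.min(scan$track$pvalue)], 40)
  expect_true(scan$flagged)
  # a fixed random sequence has no hit at a stringent threshold
  s2 <- random_dna(1, 120, seed = 214)
  scan2 <- second_promoter_scan(s2, p10, p35, alpha = 1e-6)
  expect_false(scan2$flagged)
  # the original seed region is excluded from flagging but still scored
  spec <- seed_spec(120L, list(list(seq = "TTGACA", start = 40L),
                               list(seq = "TATAAT", start = 63L)))
  scan3 <- second_promoter_scan(s, p10, p35, spec = spec)
  expect_false(scan3$flagged)
  expect_true(scan3$track$in_seed_region[scan3$track$start == 40])
  expect_error(second_promoter_scan("ACGT", p10, p35), "width")
})

test_that("PWM files in MEME, JASPAR and plain layouts parse", {
  # minimal MEME block
  meme <- file.path(tempdir(), "m.meme")
  writeLines(c("MEME version 4", "", "MOTIF crp",
               "letter-probability matrix: alength= 4 w= 3",
               " 0.7 0.1 0.1 0.1", " 0.1 0.7 0.1 0.1", " 0.1 0.1 0.1 0.7"),
             meme)
  got <- read_pwms(meme)
  expect_equal(names(got), "crp")
  expect_equal(pwm_consensus(got$crp), "ACT")
  # JASPAR counts
  jas <- file.path(tempdir(), "m.jaspar")
  writeLines(c(">MA0001 test", "A [ 10  1  1 ]", "C [  1 10  1 ]",
               "G [  1  1  1 ]", "T [  1  1 10 ]"), jas)
  gj <- read_pwms(jas)
  expect_equal(pwm_consensus(gj$MA0001), "ACT")
  expect_true(all(abs(rowSums(gj$MA0001$matrix) - 1) < 1e-9))
  # plain 4-column probabilities
  plain <- file.path(tempdir(), "m.txt")
  writeLines(c("0.97 0.01 0.01 0.01", "0.01 0.01 0.97 0.01"), plain)
  gp <- read_pwms(plain)
  expect_equal(pwm_consensus(gp[[1]]), "AG")
})

test_that("scan hits export as BED-like intervals", {
  motif <- pwm_from_consensus("GGATCC", certainty = 0.95)
  s <- paste0(strrep("A", 12), "GGATCC", strrep("A", 12))
  hits <- pwm_scan(s, motif)
  hits <- hits[hits$score > 5, ]
  p <- file.path(tempdir(), "hits.bed.tsv")
  write_scan_bed(hits, motif, p)
  df <- read.delim(p)
  expect_equal(df$start, 12L)
  expect_equal(df$end, 18L)
})
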