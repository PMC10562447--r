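#' Genetic-algorithm configuration
#'
#' Defaults follow the full-scale search settings of the framework:
#' population 5*1024, mutation probability 0.005, 100 generations. Each
#' latent coordinate (one of the four pre-softmax values of every flanking
#' row) is binary-encoded at `precision_bits` bits over `latent_range`;
#' variation is single-point crossover plus bit-flip mutation; selection is
#' tournament (size 3) with elitism.
#'
#' @param population Population size (default 5120).
#' @param mutation_prob Per-bit flip probability (default 0.005).
#' @param generations Number of generations (default 100).
#' @param elitism Number of top genomes copied unchanged (default 1).
#' @param precision_bits Bits per latent coordinate (default 8).
#' @param latent_range Half-width of the latent interval; coordinates
#'   decode into `[-latent_range, latent_range]` (default 3, roughly the
#'   support of a standard normal).
#' @param crossover_prob Probability a mating pair recombines (default 0.9;
#'   0 disables crossover).
#' @param tournament_size Tournament size (default 3).
#' @param rng_seed Integer seed.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population = 5120L, mutation_prob = 0.005,
                      generations = 100L, elitism = 1L,
                      precision_bits = 8L, latent_range = 3,
                      crossover_prob = 0.9, tournament_size = 3L,
                      rng_seed = 1L) {
  stopifnot(population > 0, mutation_prob >= 0, mutation_prob <= 1,
            generations > 0, elitism >= 0, precision_bits >= 1)
  if (population < elitism) stop("population smaller than elitism")
  structure(list(population = as.integer(population),
                 mutation_prob = mutation_prob,
                 generations = as.integer(generations),
                 elitism = as.integer(elitism),
                 precision_bits = as.integer(precision_bits),
                 latent_range = latent_range,
                 crossover_prob = crossover_prob,
                 tournament_size = as.integer(tournament_size),
                 rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

#' Read a GA configuration from YAML
#' @param path YAML file with [ga_config()] fields.
#' @export
read_ga_config <- function(path) {
  do.call(ga_config, yaml::read_yaml(path))
}

# Decode a logical genome matrix [P x nbits] into latent matrices
# (n_flank x 4 each), mapping each precision_bits group to
# [-range, range].
decode_genomes <- function(pop, n_flank, config) {
  P <- nrow(pop)
  bits <- config$precision_bits
  n_coord <- n_flank * 4L
  weights <- 2^((bits - 1L):0L)
  denom <- 2^bits - 1L
  ints <- matrix(0, P, n_coord)
  for (j in seq_len(bits)) {
    ints <- ints + pop[, seq(j, n_coord * bits, by = bits), drop = FALSE] *
      weights[j]
  }
  vals <- (ints / denom * 2 - 1) * config$latent_range
  lapply(seq_len(P), function(p) matrix(vals[p, ], n_flank, 4L))
}

# Vectorised fitness: decode latents -> generator inputs -> sequences ->
# predictor scores, whole population at once.
population_fitness <- function(pop, generator, predictor, spec, config) {
  n_flank <- flanking_length(spec)
  latents <- decode_genomes(pop, n_flank, config)
  inputs <- lapply(latents, function(z) {
    build_generator_input(spec, latent = z)
  })
  seqs <- generator_sequences(generator, inputs)
  list(fitness = predict_activity(predictor, seqs), seqs = seqs)
}

#' Optimise the generator's latent input with a genetic algorithm
#'
#' Maximises the predictor's score of the generated sequence over
#' binary-encoded latent genomes. Fitness is evaluated on whole
#' populations at once (the generator and predictor run batched). With
#' `elitism >= 1` the best-fitness trace is non-decreasing.
#'
#' @param generator A [generator_model()].
#' @param predictor A trained `predictor_model`, or a function
#'   `f(seqs) -> numeric` used directly as the fitness (handy for toy
#'   landscapes).
#' @param spec A [seed_spec()]; must match both models' window length.
#' @param config A [ga_config()].
#' @return Object of class `design_result`: `designs` (data frame `seq`,
#'   `predicted_activity`, `latent_id`, ranked non-increasing), `trace`
#'   (data frame `generation`, `best`, `mean`), `latents` (list of latent
#'   matrices for the final population, named by `latent_id`).
#' @export
ga_optimize <- function(generator, predictor, spec, config = ga_config()) {
  stopifnot(inherits(spec, "seed_spec"))
  if (generator$spec$window_length != spec$window_length) {
    stop("generator window != spec window")
  }
  if (inherits(predictor, "predictor_model") &&
      predictor$window_length != spec$window_length) {
    stop("predictor window != spec window")
  }
  score <- if (is.function(predictor)) {
    function(seqs) predictor(seqs)
  } else {
    function(seqs) predict_activity(predictor, seqs)
  }
  set.seed(config$rng_seed)
  n_flank <- flanking_length(spec)
  nbits <- n_flank * 4L * config$precision_bits
  P <- config$population
  pop <- matrix(runif(P * nbits) < 0.5, P, nbits)
  eval_pop <- function(pop) {
    latents <- decode_genomes(pop, n_flank, config)
    inputs <- lapply(latents, function(z) {
      build_generator_input(spec, latent = z)
    })
    seqs <- generator_sequences(generator, inputs)
    list(fitness = score(seqs), seqs = seqs, latents = latents)
  }
  trace <- data.frame(generation = integer(), best = numeric(),
                      mean = numeric())
  ev <- eval_pop(pop)
  for (gener in seq_len(config$generations)) {
    fit <- ev$fitness
    trace <- rbind(trace, data.frame(generation = gener, best = max(fit),
                                     mean = mean(fit)))
    if (gener == config$generations) break
    ord <- order(fit, decreasing = TRUE)
    newpop <- matrix(FALSE, P, nbits)
    n_elite <- min(config$elitism, P)
    if (n_elite > 0L) newpop[seq_len(n_elite), ] <-
        pop[ord[seq_len(n_elite)], , drop = FALSE]
    # tournament selection of parents
    pick <- function() {
      cand <- sample.int(P, config$tournament_size, replace = TRUE)
      cand[which.max(fit[cand])]
    }
    i <- n_elite + 1L
    while (i <= P) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (config$crossover_prob > 0 &&
          runif(1) < config$crossover_prob && nbits > 1L) {
        cx <- sample.int(nbits - 1L, 1L)
        c1 <- c(p1[1:cx], p2[(cx + 1L):nbits])
        c2 <- c(p2[1:cx], p1[(cx + 1L):nbits])
      } else {
        c1 <- p1; c2 <- p2
      }
      if (config$mutation_prob > 0) {
        flip <- runif(nbits) < config$mutation_prob
        c1 <- xor(c1, flip)
        flip <- runif(nbits) < config$mutation_prob
        c2 <- xor(c2, flip)
      }
      newpop[i, ] <- c1
      if (i + 1L <= P) newpop[i + 1L, ] <- c2
      i <- i + 2L
    }
    pop <- newpop
    ev <- eval_pop(pop)
  }
  fit <- ev$fitness
  ord <- order(fit, decreasing = TRUE)
  designs <- data.frame(seq = ev$seqs[ord], predicted_activity = fit[ord],
                        latent_id = ord, stringsAsFactors = FALSE)
  structure(list(designs = designs, trace = trace,
                 latents = stats::setNames(ev$latents[ord],
                                           as.character(ord)),
                 spec = spec, config = config),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("Design result:", nrow(x$designs), "candidates,",
      max(x$trace$generation), "generations\n")
  cat("  best predicted activity:", signif(x$designs$predicted_activity[1], 4),
      "\n")
  invisible(x)
}

#' @export
plot.design_result <- function(x, ...) {
  graphics::plot(x$trace$generation, x$trace$best, type = "l",
                 xlab = "generation", ylab = "fitness",
                 ylim = range(c(x$trace$best, x$trace$mean)), ...)
  graphics::lines(x$trace$generation, x$trace$mean, lty = 2)
  graphics::legend("bottomright", legend = c("best", "mean"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Filter sequences by a PWM motif library
#'
#' Rejects any sequence in which some library motif attains a significant
#' hit on either strand outside the seed positions -- used to strip
#' designs that acquired unintended transcription-factor binding sites.
#' `mode = "pvalue"` rejects hits with exact scan p-value <= `threshold`;
#' `mode = "logodds"` rejects hits with log2-odds >= `threshold`.
#'
#' @param seqs Character vector of sequences.
#' @param motif_library List of [pwm()] objects (possibly empty).
#' @param threshold Numeric threshold (see `mode`).
#' @param mode `"pvalue"` (default) or `"logodds"`.
#' @param spec Optional [seed_spec()]; hits overlapping seed positions are
#'   ignored.
#' @return List: `retained` (character vector), `rejected` (character
#'   vector), `hits` (data frame: `seq_index`, `motif`, `start`, `strand`,
#'   `score`, `pvalue` for every rejecting hit).
#' @export
motif_filter <- function(seqs, motif_library, threshold = 1e-4,
                         mode = c("pvalue", "logodds"), spec = NULL) {
  mode <- match.arg(mode)
  if (!length(motif_library)) {
    warning("empty motif library: all sequences retained")
    return(list(retained = seqs, rejected = character(0),
                hits = data.frame()))
  }
  mask <- if (!is.null(spec)) seed_mask(spec) else NULL
  hits <- list()
  reject <- rep(FALSE, length(seqs))
  for (m in motif_library) {
    sc <- pwm_scan(seqs, m, both_strands = TRUE)
    if (is.null(sc) || !nrow(sc)) next
    w <- pwm_width(m)
    if (!is.null(mask)) {
      outside <- vapply(seq_len(nrow(sc)), function(i) {
        idx <- (sc$start[i] + 1L):(sc$start[i] + w)
        idx <- idx[idx >= 1L & idx <= length(mask)]
        !any(mask[idx])
      }, logical(1))
      sc <- sc[outside, , drop = FALSE]
    }
    if (!nrow(sc)) next
    if (mode == "logodds") {
      sig <- sc$score >= threshold
      sc$pvalue <- NA_real_
    } else {
      sc$pvalue <- vapply(sc$score, function(s) pwm_pvalue(m, s),
                          numeric(1))
      sig <- sc$pvalue <= threshold
    }
    if (any(sig)) {
      sc <- sc[sig, , drop = FALSE]
      sc$motif <- m$name
      hits[[length(hits) + 1L]] <- sc
      reject[unique(sc$seq_index)] <- TRUE
    }
  }
  hits <- if (length(hits)) {
    do.call(rbind, hits)[, c("seq_index", "motif", "start", "strand",
                             "score", "pvalue")]
  } else data.frame()
  list(retained = seqs[!reject], rejected = seqs[reject], hits = hits)
}

#' End-to-end promoter design pipeline
#'
#' Runs the GA latent search, decodes and deduplicates candidate
#' sequences, applies the configured filter chain (motif library filter
#' and/or second-promoter check), and returns the top `n_out` designs with
#' full provenance.
#'
#' @param generator A trained [generator_model()].
#' @param predictor A trained `predictor_model`.
#' @param spec A [seed_spec()].
#' @param ga_config A [ga_config()].
#' @param n_out Number of designs to return (default 16).
#' @param filters Optional list with any of: `motif_library` (list of
#'   [pwm()]), `motif_threshold`, `motif_mode`, `second_promoter` (list
#'   with `pwm_minus10`, `pwm_minus35`, optional `spacer_bp`, `alpha`).
#' @return A `design_result` whose `designs` also records `filter_tally`
#'   as an attribute (named counts: candidates, deduplicated,
#'   motif_rejected, second_promoter_rejected, returned).
#' @export
design_promoters <- function(generator, predictor, spec,
                             ga_config = ga_config(), n_out = 16L,
                             filters = list()) {
  res <- ga_optimize(generator, predictor, spec, ga_config)
  designs <- res$designs
  tally <- c(candidates = nrow(designs))
  dup <- duplicated(designs$seq)
  designs <- designs[!dup, , drop = FALSE]
  tally["deduplicated"] <- sum(dup)
  tally["motif_rejected"] <- 0L
  if (!is.null(filters$motif_library) && length(filters$motif_library)) {
    mf <- motif_filter(designs$seq, filters$motif_library,
                       threshold = filters$motif_threshold %||% 1e-4,
                       mode = filters$motif_mode %||% "pvalue",
                       spec = spec)
    tally["motif_rejected"] <- length(mf$rejected)
    designs <- designs[designs$seq %in% mf$retained, , drop = FALSE]
  }
  tally["second_promoter_rejected"] <- 0L
  if (!is.null(filters$second_promoter)) {
    sp <- filters$second_promoter
    keep <- vapply(designs$seq, function(s) {
      !second_promoter_scan(s, sp$pwm_minus10, sp$pwm_minus35,
                            spacer_bp = sp$spacer_bp %||% 17L,
                            spec = spec,
                            alpha = sp$alpha %||% 1e-6)$flagged
    }, logical(1))
    tally["second_promoter_rejected"] <- sum(!keep)
    designs <- designs[keep, , drop = FALSE]
  }
  if (nrow(designs) == 0L) {
    warning("all candidates filtered out; tally: ",
            paste(names(tally), tally, sep = "=", collapse = ", "))
  } else if (nrow(designs) < n_out) {
    warning("only ", nrow(designs), " designs survive filtering (asked ",
            n_out, ")")
  }
  designs <- utils::head(designs, n_out)
  tally["returned"] <- nrow(designs)
  rownames(designs) <- NULL
  attr(designs, "filter_tally") <- tally
  out <- res
  out$designs <- designs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a design report (FASTA + JSON)
#'
#' @param result A `design_result` from [design_promoters()].
#' @param fasta_path FASTA output (predicted activity in headers).
#' @param report_path Optional JSON report with the fitness trace and
#'   filter tally.
#' @export
write_design_report <- function(result, fasta_path, report_path = NULL) {
  d <- result$designs
  write_fasta(stats::setNames(d$seq, sprintf("design_%d", seq_len(nrow(d)))),
              fasta_path, activity = d$predicted_activity)
  if (!is.null(report_path)) {
    jsonlite::write_json(list(
      trace = result$trace,
      filter_tally = as.list(attr(d, "filter_tally")),
      n_designs = nrow(d)
    ), report_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(fasta_path)
}
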