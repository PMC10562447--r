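#' Promoter dataset container
#'
#' A fixed-window set of promoter records: sequence, scalar activity and
#' optional per-record metadata. All sequences share `window_length`.
#'
#' @param seqs Character vector of DNA sequences (uppercased).
#' @param activity Numeric vector of finite activities.
#' @param window_length Window length in bp; defaults to the common
#'   sequence length.
#' @param provenance Free-text origin note.
#' @param meta Optional data frame of per-record metadata.
#' @param allow_duplicates Keep duplicate sequences? (default TRUE).
#' @return Object of class `promoter_dataset`: a list with a `records`
#'   data frame (`seq`, `activity`, meta columns), `window_length`,
#'   `provenance`.
#' @export
promoter_dataset <- function(seqs, activity, window_length = NULL,
                             provenance = "", meta = NULL,
                             allow_duplicates = TRUE) {
  seqs <- toupper(as.character(seqs))
  activity <- as.numeric(activity)
  stopifnot(length(seqs) == length(activity))
  if (!all(is.finite(activity))) stop("activities must be finite")
  lens <- unique(nchar(seqs))
  if (is.null(window_length)) {
    if (length(lens) != 1L) stop("sequences have mixed lengths: ",
                                 paste(lens, collapse = ", "))
    window_length <- lens
  } else if (!all(lens == window_length)) {
    stop("sequence length(s) ", paste(lens, collapse = ","),
         " != declared window_length ", window_length)
  }
  records <- data.frame(seq = seqs, activity = activity,
                        stringsAsFactors = FALSE)
  if (!is.null(meta)) records <- cbind(records, meta)
  if (!allow_duplicates) {
    records <- records[!duplicated(records$seq), , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(records = records,
                 window_length = as.integer(window_length),
                 provenance = provenance),
            class = "promoter_dataset")
}

#' @export
print.promoter_dataset <- function(x, ...) {
  cat("Promoter dataset:", nrow(x$records), "records,",
      x$window_length, "bp window\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  cat("  activity range: [", signif(min(x$records$activity), 4), ", ",
      signif(max(x$records$activity), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
length.promoter_dataset <- function(x) nrow(x$records)

#' Load a delimited sequence/activity table
#'
#' Reads a delimited text file with a header, keeps the named sequence and
#' activity columns, uppercases sequences, drops rows whose activity is
#' missing/non-numeric or whose sequence contains non-ACGT characters, and
#' reports the exclusion count as an attribute.
#'
#' @param path Delimited text file with a header row.
#' @param seq_column,activity_column Column names.
#' @param sep Field separator (default tab).
#' @param dedupe Drop duplicate sequences (first kept)?
#' @param window_length Optional declared window; rows of other lengths are
#'   excluded (counted) rather than erroring.
#' @return A [promoter_dataset()] with attribute `excluded` (named integer
#'   vector of exclusion counts by reason).
#' @export
load_activity_table <- function(path, seq_column = "sequence",
                                activity_column = "activity", sep = "\t",
                                dedupe = FALSE, window_length = NULL) {
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path)
  for (col in c(seq_column, activity_column)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path, "; available: ",
           paste(names(df), collapse = ", "))
    }
  }
  seqs <- toupper(as.character(df[[seq_column]]))
  act <- suppressWarnings(as.numeric(df[[activity_column]]))
  excl <- c(bad_activity = 0L, bad_sequence = 0L, bad_length = 0L,
            duplicate = 0L)
  keep <- is.finite(act)
  excl["bad_activity"] <- sum(!keep)
  ok_seq <- grepl("^[ACGT]+$", seqs)
  excl["bad_sequence"] <- sum(keep & !ok_seq)
  keep <- keep & ok_seq
  if (!is.null(window_length)) {
    ok_len <- nchar(seqs) == window_length
    excl["bad_length"] <- sum(keep & !ok_len)
    keep <- keep & ok_len
  }
  seqs <- seqs[keep]; act <- act[keep]
  if (dedupe) {
    dup <- duplicated(seqs)
    excl["duplicate"] <- sum(dup)
    seqs <- seqs[!dup]; act <- act[!dup]
  }
  if (!length(seqs)) stop("no usable records in ", path)
  ds <- promoter_dataset(seqs, act, window_length = window_length,
                         provenance = paste("loaded from", basename(path)))
  attr(ds, "excluded") <- excl
  ds
}

#' Write a dataset as TSV or FASTA-with-activities
#'
#' @param dataset A [promoter_dataset()].
#' @param path Output path; `.fa`/`.fasta` writes FASTA with `|activity=`
#'   headers, anything else a two-column TSV.
#' @export
write_dataset <- function(dataset, path) {
  if (grepl("\\.fa(sta)?$", path, ignore.case = TRUE)) {
    write_fasta(stats::setNames(dataset$records$seq,
                                sprintf("seq_%d",
                                        seq_len(nrow(dataset$records)))),
                path, activity = dataset$records$activity)
  } else {
    utils::write.table(dataset$records[, c("seq", "activity")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = c("sequence", "activity"))
  }
  invisible(path)
}

#' Convert FASTA-with-activities to a dataset
#' @param path FASTA file whose headers carry `|activity=` tags.
#' @return A [promoter_dataset()].
#' @export
as_promoter_dataset <- function(path) {
  seqs <- read_fasta(path)
  act <- attr(seqs, "activity")
  keep <- is.finite(act)
  promoter_dataset(seqs[keep], act[keep],
                   provenance = paste("loaded from", basename(path)))
}

# Default core-element PWMs used for annotation and simulation: sigma-70
# -35 (TTGACA) and -10 (TATAAT) consensus models.
default_core_pwms <- function(certainty = 0.85) {
  list(minus35 = pwm_from_consensus("TTGACA", certainty, name = "minus35"),
       minus10 = pwm_from_consensus("TATAAT", certainty, name = "minus10"))
}

# Locate the maximal-scoring window for a PWM inside allowed start range
# [lo, hi] (0-based, inclusive). Returns 0-based start.
locate_element <- function(seq, pwm, lo, hi) {
  sc <- pwm_scan(seq, pwm)$score
  lo <- max(lo, 0L); hi <- min(hi, nchar(seq) - pwm_width(pwm))
  if (hi < lo) return(NA_integer_)
  window <- sc[(lo + 1L):(hi + 1L)]
  lo + which.max(window) - 1L
}

#' Filter promoters by core-element geometry around the TSS
#'
#' Keeps records whose -10/-35 elements sit in the canonical sigma-70
#' geometry relative to the transcription start site: (a) more than 75 bp
#' of sequence between the distal window start and the TSS; (b) the -10
#' element ends 1-21 bp upstream of the TSS; (c) the -35 element ends
#' 25-45 bp upstream of the TSS; (d) the spacer between the elements is
#' 10-24 bp. Rejections are tagged with the first failed rule (a-d).
#'
#' Element positions are taken from record metadata columns
#' `minus10_start` / `minus35_start` (0-based) when present; otherwise they
#' are located as the maximal PWM log-odds placement inside the allowed
#' search windows.
#'
#' @param dataset A [promoter_dataset()].
#' @param tss_index 0-based TSS position inside the window.
#' @param pwms Named list with elements `minus10`, `minus35` (defaults to
#'   the consensus models).
#' @return The retained [promoter_dataset()], with metadata columns
#'   `minus10_start`, `minus35_start` and attribute `rejections` (data
#'   frame of rejected indices and the first failed rule).
#' @export
filter_promoters <- function(dataset, tss_index,
                             pwms = default_core_pwms()) {
  L <- dataset$window_length
  tss_index <- as.integer(tss_index)
  if (tss_index < 0L || tss_index >= L) {
    stop("TSS index ", tss_index, " outside window [0, ", L, ")")
  }
  rec <- dataset$records
  n <- nrow(rec)
  has10 <- "minus10_start" %in% names(rec)
  has35 <- "minus35_start" %in% names(rec)
  w10 <- pwm_width(pwms$minus10); w35 <- pwm_width(pwms$minus35)
  m10 <- m35 <- integer(n)
  for (i in seq_len(n)) {
    s <- rec$seq[i]
    m10[i] <- if (has10 && is.finite(rec$minus10_start[i])) {
      rec$minus10_start[i]
    } else {
      # -10 end must fall 1-21 bp upstream of TSS: end e = start + w10,
      # distance tss - e in [1,21] -> start in [tss-21-w10, tss-1-w10]
      locate_element(s, pwms$minus10, tss_index - 21L - w10,
                     tss_index - 1L - w10)
    }
    m35[i] <- if (has35 && is.finite(rec$minus35_start[i])) {
      rec$minus35_start[i]
    } else {
      locate_element(s, pwms$minus35, tss_index - 45L - w35,
                     tss_index - 25L - w35)
    }
  }
  # rule evaluation (first failed rule tags the rejection)
  rule <- rep(NA_character_, n)
  d10 <- tss_index - (m10 + w10) # bp between -10 end and TSS
  d35 <- tss_index - (m35 + w35)
  spacer <- m10 - (m35 + w35)
  fail_a <- tss_index <= 75L
  fail_b <- is.na(m10) | d10 < 1L | d10 > 21L
  fail_c <- is.na(m35) | d35 < 25L | d35 > 45L
  fail_d <- is.na(spacer) | spacer < 10L | spacer > 24L
  rule[fail_d] <- "d"; rule[fail_c] <- "c"; rule[fail_b] <- "b"
  if (fail_a) rule[] <- "a"
  keep <- is.na(rule)
  meta <- data.frame(minus10_start = m10, minus35_start = m35)
  extra <- setdiff(names(rec), c("seq", "activity", "minus10_start",
                                 "minus35_start"))
  if (length(extra)) meta <- cbind(meta, rec[, extra, drop = FALSE])
  out <- promoter_dataset(rec$seq[keep], rec$activity[keep],
                          window_length = L,
                          provenance = paste(dataset$provenance,
                                             "| geometry-filtered"),
                          meta = meta[keep, , drop = FALSE])
  attr(out, "rejections") <- data.frame(index = which(!keep),
                                        rule = rule[!keep])
  out
}

#' Simulation configuration for the synthetic promoter generator
#'
#' The simulator emulates the structure of a bacterial MPRA training set:
#' fixed-length windows, planted -35/-10 (and optionally operator) motifs,
#' and an activity that depends on both the motif matches and the flanking
#' composition, plus Gaussian noise. Defaults mirror the study conditions
#' this package targets: 165 bp windows with sigma-70 consensus elements
#' planted in canonical geometry.
#'
#' @param n Number of records.
#' @param window_length Window length in bp (default 165).
#' @param planted_spec A [seed_spec()] giving motif consensus strings and
#'   positions (default: TTGACA at 120, TATAAT at 143 -- canonical 17 bp
#'   spacer, TSS at 155).
#' @param motif_certainty Per-position consensus probability of the PWMs
#'   used both to mutate the planted motifs and to score them (default
#'   0.85; set 1 for exact consensus planting).
#' @param activity_weights List with `w_motif`, `w_flank`, `noise_sd`
#'   (defaults 1, 20, 0.1). The default flank weight is chosen so the
#'   flanking-composition term carries a substantial share (roughly a
#'   quarter) of the activity variance next to the motif log-odds term:
#'   the landscape is meant to emulate promoters whose activity depends
#'   materially on both the core elements and their flanks.
#' @param background Length-4 background base probabilities (default
#'   uniform).
#' @param bonus_kmer Fixed 4-mer whose flanking occurrences earn an
#'   activity bonus (default "GCCA").
#' @param bonus_per_hit Activity bonus per occurrence (default 0.1).
#' @param rng_seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n, window_length = 165L,
                       planted_spec = NULL, motif_certainty = 0.85,
                       activity_weights = list(w_motif = 1, w_flank = 20,
                                               noise_sd = 0.1),
                       background = rep(0.25, 4), bonus_kmer = "GCCA",
                       bonus_per_hit = 0.1, rng_seed = 1L) {
  stopifnot(n > 0, activity_weights$noise_sd >= 0)
  if (is.null(planted_spec)) {
    planted_spec <- seed_spec(window_length, list(
      list(seq = "TTGACA", start = 120L),
      list(seq = "TATAAT", start = 143L)
    ), label = "sigma70 canonical")
  }
  stopifnot(inherits(planted_spec, "seed_spec"),
            planted_spec$window_length == window_length)
  pwms <- lapply(planted_spec$motifs, function(m) {
    pwm_from_consensus(m$seq, motif_certainty, background = background)
  })
  structure(list(n = as.integer(n), window_length = as.integer(window_length),
                 planted_spec = planted_spec, motif_pwms = pwms,
                 motif_certainty = motif_certainty,
                 activity_weights = activity_weights,
                 background = background, bonus_kmer = bonus_kmer,
                 bonus_per_hit = bonus_per_hit,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#' @param path YAML file with the fields of [sim_config()];
#'   `planted_spec` given as `{window_length, motifs: [{seq, start}]}`.
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  spec <- if (!is.null(x$planted_spec)) {
    seed_spec(x$planted_spec$window_length, x$planted_spec$motifs)
  } else NULL
  args <- x[setdiff(names(x), "planted_spec")]
  do.call(sim_config, c(args, list(planted_spec = spec)))
}

# GC fraction of a character vector of sequences.
gc_fraction <- function(seqs) {
  vapply(strsplit(toupper(seqs), ""), function(ch) {
    mean(ch %in% c("G", "C"))
  }, numeric(1))
}

count_kmer_hits <- function(seq, kmer) {
  length(gregexpr(kmer, seq, fixed = TRUE)[[1]] |>
           (\(v) v[v > 0])())
}

#' Noise-free activity oracle of the simulator
#'
#' The documented ground-truth activity:
#' `w_motif * sum(motif PWM log2-odds at the planted positions)`
#' `+ w_flank * ((GC fraction of flanking) - 0.5`
#' `              + bonus_per_hit * (occurrences of bonus_kmer in flanking))`.
#' Flanking occurrences of the bonus 4-mer are counted within the
#' concatenated flanking segments (motif-spanning occurrences do not
#' count).
#'
#' @param seq DNA string of the configured window length.
#' @param config A [sim_config()].
#' @return Numeric activity.
#' @export
activity_oracle <- function(seq, config) {
  if (nchar(seq) != config$window_length) {
    stop("sequence length ", nchar(seq), " != window ",
         config$window_length)
  }
  w <- config$activity_weights
  motif_score <- 0
  for (i in seq_along(config$planted_spec$motifs)) {
    m <- config$planted_spec$motifs[[i]]
    win <- substr(seq, m$start + 1L, m$start + nchar(m$seq))
    motif_score <- motif_score + pwm_log_odds(win, config$motif_pwms[[i]])
  }
  mask <- seed_mask(config$planted_spec)
  chars <- strsplit(seq, "")[[1]]
  # concatenated flanking segments, split at motif boundaries
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  flank_segs <- vapply(which(!runs$values), function(j) {
    paste(chars[starts[j]:ends[j]], collapse = "")
  }, character(1))
  flank_all <- paste(chars[!mask], collapse = "")
  bonus_hits <- sum(vapply(flank_segs, count_kmer_hits, numeric(1),
                           kmer = config$bonus_kmer))
  g <- (gc_fraction(flank_all) - 0.5) + config$bonus_per_hit * bonus_hits
  w$w_motif * motif_score + w$w_flank * g
}

#' Simulate a synthetic promoter dataset with a known activity oracle
#'
#' Background positions are drawn iid from the configured base
#' composition; planted motifs are written at their seed positions,
#' sampled from the corresponding consensus PWMs (so motif quality
#' varies); the stored activity is [activity_oracle()] plus
#' `Normal(0, noise_sd)` noise. The same `rng_seed` yields a bitwise
#' identical dataset.
#'
#' @param config A [sim_config()].
#' @return A [promoter_dataset()] with metadata column `oracle` (the
#'   noise-free activity).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  L <- config$window_length
  n <- config$n
  mask <- seed_mask(config$planted_spec)
  seqs <- character(n)
  for (i in seq_len(n)) {
    chars <- sample(DNA_BASES, L, replace = TRUE, prob = config$background)
    for (j in seq_along(config$planted_spec$motifs)) {
      m <- config$planted_spec$motifs[[j]]
      planted <- pwm_sample(config$motif_pwms[[j]])
      chars[(m$start + 1L):(m$start + nchar(m$seq))] <-
        strsplit(planted, "")[[1]]
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  oracle <- vapply(seqs, activity_oracle, numeric(1), config = config,
                   USE.NAMES = FALSE)
  noise <- if (config$activity_weights$noise_sd > 0) {
    rnorm(n, 0, config$activity_weights$noise_sd)
  } else rep(0, n)
  promoter_dataset(seqs, oracle + noise, window_length = L,
                   provenance = sprintf("simulated (n=%d, seed=%d)", n,
                                        config$rng_seed),
                   meta = data.frame(oracle = oracle))
}
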