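#' Position weight matrix
#'
#' A PWM is stored as a width x 4 matrix of per-position base probabilities
#' (channels A, C, G, T), together with a background distribution and the
#' pseudocount that was folded in when normalising counts. Scoring is
#' log2-odds against the background.
#'
#' @param matrix width x 4 matrix of probabilities (rows sum to 1) or of
#'   non-negative counts (normalised after adding `pseudocount`).
#' @param background Length-4 base probabilities (default uniform).
#' @param pseudocount Added to every cell before normalising count input
#'   (default 0.01).
#' @param name Motif identifier.
#' @return Object of class `pwm`.
#' @examples
#' minus10 <- pwm_from_consensus("TATAAT", certainty = 0.85)
#' pwm_log_odds("TATAAT", minus10) # maximal score
#' @export
pwm <- function(matrix, background = rep(0.25, 4), pseudocount = 0.01,
                name = "motif") {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4L, all(matrix >= 0), all(is.finite(matrix)))
  rs <- rowSums(matrix)
  if (any(abs(rs - 1) > 1e-9)) { # treat as counts
    matrix <- matrix + pseudocount
    matrix <- matrix / rowSums(matrix)
  }
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-9)
  colnames(matrix) <- DNA_BASES
  structure(list(matrix = matrix, background = as.numeric(background),
                 pseudocount = pseudocount, name = name),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$name, "' width ", nrow(x$matrix), ", consensus ",
      pwm_consensus(x), "\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' @rdname pwm
#' @param consensus Consensus string (A/C/G/T).
#' @param certainty Probability assigned to the consensus base at each
#'   position; the remainder is split evenly over the other three bases.
#' @export
pwm_from_consensus <- function(consensus, certainty = 0.85,
                               background = rep(0.25, 4),
                               name = consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  idx <- match(chars, DNA_BASES)
  stopifnot(!anyNA(idx))
  m <- matrix((1 - certainty) / 3, nrow = length(chars), ncol = 4L)
  m[cbind(seq_along(idx), idx)] <- certainty
  pwm(m, background = background, name = name)
}

#' @rdname pwm
#' @param x A `pwm`.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[max.col(x$matrix, ties.method = "first")], collapse = "")
}

#' Width of a PWM
#' @param x A `pwm`.
#' @export
pwm_width <- function(x) nrow(x$matrix)

#' Reverse-complement a PWM
#' @param x A `pwm`.
#' @export
pwm_revcomp <- function(x) {
  m <- x$matrix[rev(seq_len(nrow(x$matrix))), c("T", "G", "C", "A"),
                drop = FALSE]
  colnames(m) <- DNA_BASES
  pwm(m, background = x$background, pseudocount = x$pseudocount,
      name = paste0(x$name, "_rc"))
}

# Per-position log2-odds lookup table (width x 4).
pwm_score_matrix <- function(x) {
  log2(sweep(x$matrix, 2L, x$background, "/"))
}

#' Log-odds score of one window under a PWM
#'
#' Sum over positions of `log2(p_i(base) / background(base))`. The window
#' must have exactly the PWM's width.
#'
#' @param seq_window DNA string of length `pwm_width(pwm)`.
#' @param pwm A [pwm()].
#' @return Numeric log2-odds score.
#' @export
pwm_log_odds <- function(seq_window, pwm) {
  w <- pwm_width(pwm)
  if (nchar(seq_window) != w) {
    stop("window length ", nchar(seq_window), " != PWM width ", w)
  }
  idx <- match(strsplit(toupper(seq_window), "")[[1]], DNA_BASES)
  if (anyNA(idx)) stop("window contains non-ACGT characters")
  sm <- pwm_score_matrix(pwm)
  sum(sm[cbind(seq_len(w), idx)])
}

#' Scan all windows of sequences with a PWM
#'
#' Vectorised sliding-window log-odds scan; optionally on both strands.
#'
#' @param seqs Character vector of DNA sequences.
#' @param pwm A [pwm()].
#' @param both_strands Scan the reverse strand too?
#' @return A data frame with columns `seq_index`, `start` (0-based),
#'   `strand` (`+`/`-`), `score`.
#' @export
pwm_scan <- function(seqs, pwm, both_strands = FALSE) {
  sm <- pwm_score_matrix(pwm)
  w <- nrow(sm)
  scan_one <- function(s, strand, i) {
    L <- nchar(s)
    if (L < w) return(NULL)
    idx <- match(strsplit(s, "")[[1]], DNA_BASES)
    n <- L - w + 1L
    sc <- numeric(n)
    for (j in seq_len(w)) {
      b <- idx[j:(j + n - 1L)]
      col <- sm[j, ]
      v <- col[b]
      v[is.na(v)] <- 0 # N scores as background
      sc <- sc + v
    }
    data.frame(seq_index = i, start = seq_len(n) - 1L, strand = strand,
               score = sc)
  }
  out <- list()
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[[i]])
    out[[length(out) + 1L]] <- scan_one(s, "+", i)
    if (both_strands) {
      rc <- scan_one(revcomp(s), "-", i)
      if (!is.null(rc)) {
        # report minus-strand hits in plus-strand coordinates
        rc$start <- nchar(s) - w - rc$start
        out[[length(out) + 1L]] <- rc
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Exact p-value of a PWM log-odds score
#'
#' Computes `P(score(W) >= score)` for a width-mer `W` drawn from the PWM's
#' background, by dynamic programming over the score distribution. For
#' widths up to 8 the DP runs over the exact set of attainable score sums
#' (scores merged at 1e-9 resolution), so the p-value agrees with
#' exhaustive enumeration of all `4^w` words to floating-point accuracy.
#' For wider motifs, scores are binned at `granularity` (default 1e-3)
#' with rounding toward negative infinity, which makes the reported
#' p-value conservative (never smaller than the exact one).
#'
#' @param pwm A [pwm()] of width <= 30.
#' @param score Log2-odds score; `-Inf` gives p = 1, a score above the
#'   attainable maximum gives 0.
#' @param granularity Score bin width for the wide-motif path.
#' @return P-value in `[0, 1]`.
#' @export
pwm_pvalue <- function(pwm, score, granularity = 1e-3) {
  if (is.na(score)) stop("score must be finite or -Inf/+Inf")
  w <- pwm_width(pwm)
  if (w > 30L) stop("exact DP supported for widths <= 30, got ", w)
  if (score == -Inf) return(1)
  sm <- pwm_score_matrix(pwm)
  if (w <= 8L) {
    # sparse exact DP over distinct attainable sums
    vals <- 0; probs <- 1
    for (i in seq_len(w)) {
      nv <- rep(vals, each = 4L) + rep(sm[i, ], length(vals))
      np <- rep(probs, each = 4L) * rep(pwm$background, length(vals))
      key <- round(nv, 9)
      agg <- rowsum(np, key)
      vals <- as.numeric(rownames(agg))
      probs <- as.numeric(agg)
    }
    # merge rounding accumulates ~5e-10 per position; compare with a
    # 1e-6 slack (scores this close are ties at the supported accuracy)
    return(sum(probs[vals >= score - 1e-6]))
  }
  bins <- floor(sm / granularity) # integer bins, toward -Inf
  cur_lo <- 0L
  dist <- 1
  for (i in seq_len(w)) {
    b <- bins[i, ]
    new_lo <- cur_lo + min(b)
    new_hi <- (cur_lo + length(dist) - 1L) + max(b)
    nd <- numeric(new_hi - new_lo + 1L)
    for (base in 1:4) {
      sh <- (cur_lo + b[base]) - new_lo
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + dist * pwm$background[base]
    }
    dist <- nd
    cur_lo <- new_lo
  }
  # Binned score of any word undershoots its true score by at most
  # w * granularity (one floor per column), so threshold with that slack
  # to stay conservative: p_reported >= p_exact always.
  target <- floor(score / granularity) - w
  hi_bin <- cur_lo + length(dist) - 1L
  if (target > hi_bin) return(0)
  if (target <= cur_lo) return(1)
  sum(dist[(target - cur_lo + 1L):length(dist)])
}

#' Build the combined "promoter structure" motif
#'
#' Concatenates the -35 motif, `spacer_bp` information-free (background)
#' columns, and the -10 motif into one wide PWM. Under its own background
#' the spacer columns contribute exactly zero log-odds.
#'
#' @param pwm_minus35,pwm_minus10 [pwm()] objects.
#' @param spacer_bp Spacer length in bp (default 17).
#' @return A [pwm()] of width `w35 + spacer_bp + w10`.
#' @export
combined_promoter_pwm <- function(pwm_minus35, pwm_minus10, spacer_bp = 17L) {
  stopifnot(spacer_bp >= 0L)
  bg <- pwm_minus35$background
  spacer <- matrix(rep(bg, each = spacer_bp), ncol = 4L)
  m <- rbind(pwm_minus35$matrix, spacer, pwm_minus10$matrix)
  pwm(m, background = bg,
      name = sprintf("%s+%dbp+%s", pwm_minus35$name, spacer_bp,
                     pwm_minus10$name))
}

#' Scan a sequence for secondary promoter structures
#'
#' Slides the combined -35/spacer/-10 motif along the sequence and reports
#' an exact p-value per offset. Positions overlapping the original seed
#' region (if a spec is given) are excluded from flagging, so the original
#' promoter does not flag itself: the question is whether the *flanking*
#' sequence has grown an alternative promoter.
#'
#' @param seq DNA string.
#' @param pwm_minus10,pwm_minus35 [pwm()] objects for the core elements.
#' @param spacer_bp Spacer length used to build the combined motif
#'   (default 17).
#' @param spec Optional [seed_spec()]; offsets whose window overlaps seed
#'   positions are excluded from flagging (still scored).
#' @param alpha Significance threshold on the p-value (default 1e-4).
#' @param both_strands Scan the reverse strand too (default FALSE:
#'   promoters are directional).
#' @return List with `track` (data frame: `start`, `strand`, `score`,
#'   `pvalue`, `in_seed_region`), `flagged` (logical: any non-seed offset
#'   with p <= alpha) and `best` (row of the track with the smallest
#'   p-value).
#' @export
second_promoter_scan <- function(seq, pwm_minus10, pwm_minus35,
                                 spacer_bp = 17L, spec = NULL,
                                 alpha = 1e-4, both_strands = FALSE) {
  comb <- combined_promoter_pwm(pwm_minus35, pwm_minus10, spacer_bp)
  w <- pwm_width(comb)
  if (nchar(seq) < w) {
    stop("combined motif width ", w, " exceeds sequence length ",
         nchar(seq))
  }
  track <- pwm_scan(seq, comb, both_strands = both_strands)
  track$seq_index <- NULL
  # exact p-value per offset via the score distribution (computed once)
  track$pvalue <- vapply(track$score, function(s) pwm_pvalue(comb, s),
                         numeric(1))
  in_seed <- rep(FALSE, nrow(track))
  if (!is.null(spec)) {
    mask <- seed_mask(spec)
    in_seed <- vapply(seq_len(nrow(track)), function(i) {
      idx <- (track$start[i] + 1L):(track$start[i] + w)
      idx <- idx[idx <= length(mask)]
      any(mask[idx])
    }, logical(1))
  }
  track$in_seed_region <- in_seed
  hits <- !in_seed & track$pvalue <= alpha
  best <- track[which.min(track$pvalue), , drop = FALSE]
  list(track = track, flagged = any(hits), best = best)
}

#' Read PWMs from MEME, JASPAR or plain 4-column text
#'
#' Supports: minimal MEME motif format (`MOTIF` blocks with a
#' `letter-probability matrix` section), JASPAR PFM blocks
#' (`>name` followed by `A [ ... ]` count rows), and headerless 4-column
#' probability text (one PWM per file, columns A C G T).
#'
#' @param path Motif file.
#' @param background Background distribution applied to all motifs.
#' @param pseudocount Pseudocount for count matrices.
#' @return Named list of [pwm()] objects.
#' @export
read_pwms <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  if (any(grepl("^MOTIF", lines))) {
    starts <- grep("^MOTIF", lines)
    for (s in seq_along(starts)) {
      name <- strsplit(trimws(lines[starts[s]]), "\\s+")[[1]][2]
      from <- starts[s]
      to <- if (s < length(starts)) starts[s + 1] - 1L else length(lines)
      block <- lines[from:to]
      lp <- grep("letter-probability", block)
      if (!length(lp)) next
      rows <- block[(lp + 1L):length(block)]
      rows <- rows[grepl("^\\s*[0-9.eE+-]", rows)]
      m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"),
                                 as.numeric))
      out[[name]] <- pwm(m[, 1:4, drop = FALSE], background = background,
                         pseudocount = pseudocount, name = name)
    }
  } else if (any(grepl("^>", lines))) {
    starts <- grep("^>", lines)
    for (s in seq_along(starts)) {
      name <- sub("^>\\s*", "", lines[starts[s]])
      name <- strsplit(name, "\\s+")[[1]][1]
      rows <- lines[(starts[s] + 1L):min(starts[s] + 4L, length(lines))]
      vals <- lapply(rows, function(r) {
        v <- strsplit(gsub("[^0-9.eE+-]", " ", r), "\\s+")[[1]]
        v <- suppressWarnings(as.numeric(v[nzchar(v)]))
        v[!is.na(v)]
      })
      m <- t(do.call(rbind, vals)) # rows were A,C,G,T -> transpose
      out[[name]] <- pwm(m, background = background,
                         pseudocount = pseudocount, name = name)
    }
  } else {
    rows <- lines[grepl("^\\s*[0-9.eE+-]", lines)]
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    nm <- sub("\\.[^.]*$", "", basename(path))
    out[[nm]] <- pwm(m[, 1:4, drop = FALSE], background = background,
                     pseudocount = pseudocount, name = nm)
  }
  out
}

#' Write PWM scan hits as BED-like TSV
#'
#' 0-based half-open intervals, one row per hit, with the motif name,
#' score and strand.
#'
#' @param hits Data frame from [pwm_scan()] (optionally with a `pvalue`
#'   column).
#' @param pwm The [pwm()] that produced the hits (for the interval width
#'   and name).
#' @param path Output TSV path.
#' @param seq_names Optional names for `seq_index` values.
#' @export
write_scan_bed <- function(hits, pwm, path, seq_names = NULL) {
  chrom <- if (!is.null(seq_names)) seq_names[hits$seq_index] else
    paste0("seq_", hits$seq_index)
  df <- data.frame(chrom = chrom, start = hits$start,
                   end = hits$start + pwm_width(pwm), name = pwm$name,
                   score = hits$score, strand = hits$strand)
  if (!is.null(hits$pvalue)) df$pvalue <- hits$pvalue
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Sample a sequence from a PWM
#'
#' @param pwm A [pwm()].
#' @param n Number of sequences.
#' @return Character vector of length `n`.
#' @export
pwm_sample <- function(pwm, n = 1L) {
  w <- pwm_width(pwm)
  vapply(seq_len(n), function(i) {
    idx <- vapply(seq_len(w), function(j) {
      sample.int(4L, 1L, prob = pwm$matrix[j, ])
    }, integer(1))
    paste(DNA_BASES[idx], collapse = "")
  }, character(1))
}
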