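#' Pooled k-mer frequency spectrum of a sequence set
#'
#' Counts all overlapping k-mers across the set and normalises to a
#' probability vector over all `4^k` k-mers (lexicographic order).
#' Sequences shorter than `k` are skipped and counted in the `skipped`
#' attribute. `region` restricts counting to the distal (first) or
#' proximal (second) half of each window.
#'
#' @param seqs Character vector of ACGT sequences.
#' @param k K-mer size, 1..8.
#' @param region `"entire"` (default), `"distal"` or `"proximal"`.
#' @return Named numeric vector of length `4^k` summing to 1, with
#'   attribute `skipped`.
#' @export
kmer_frequencies <- function(seqs, k, region = c("entire", "distal",
                                                 "proximal")) {
  stopifnot(k >= 1L, k <= 8L)
  region <- match.arg(region)
  if (region != "entire") {
    half <- nchar(seqs) %/% 2L
    seqs <- if (region == "distal") substr(seqs, 1L, half) else
      substr(seqs, half + 1L, nchar(seqs))
  }
  short <- nchar(seqs) < k
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than k skipped")
    seqs <- seqs[!short]
  }
  if (!length(seqs)) stop("no sequences of length >= k")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k)
  total <- colSums(counts)
  if (sum(total) == 0) stop("no countable k-mers")
  out <- total / sum(total)
  attr(out, "skipped") <- sum(short)
  out
}

#' Pearson correlation of two k-mer spectra
#'
#' @param setA,setB Character vectors of sequences.
#' @param k K-mer size.
#' @param region Passed to [kmer_frequencies()].
#' @return Pearson correlation of the two `4^k` frequency vectors.
#' @export
kmer_correlation <- function(setA, setB, k = 4L, region = "entire") {
  fa <- kmer_frequencies(setA, k, region)
  fb <- kmer_frequencies(setB, k, region)
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0) {
    stop("zero-variance k-mer spectrum: correlation undefined")
  }
  stats::cor(fa, fb)
}

#' Levenshtein edit distance
#'
#' Unit-cost substitution/insertion/deletion distance (dynamic
#' programming, via the C implementation underlying [utils::adist()]).
#' Vectorised over pairs.
#'
#' @param a,b Character vectors (recycled to equal length).
#' @return Integer vector of distances.
#' @examples
#' edit_distance("TTGACA", "TTGTCA") # 1
#' @export
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- utils::adist(a[i], b[i])[1, 1]
  out
}

#' Cross-group edit-distance diversity profile
#'
#' All pairwise distances between a reference group and one or more
#' comparison groups -- the "sequence similar diversity" statistic: the
#' distribution of `ed(seq_i, seq_j)` for `i` in the reference group and
#' `j` in each comparison group.
#'
#' @param groupA Character vector (reference group, e.g. random
#'   sequences).
#' @param groupB_list Named list of character vectors (e.g.
#'   `list(g = generated, n = natural)`).
#' @return Object of class `diversity_profile`: data frame with columns
#'   `group`, `i`, `j`, `distance`; plus summary quantiles per group in
#'   attribute `summary`.
#' @export
diversity_profile <- function(groupA, groupB_list) {
  if (!is.list(groupB_list)) groupB_list <- list(B = groupB_list)
  if (is.null(names(groupB_list))) {
    names(groupB_list) <- paste0("group", seq_along(groupB_list))
  }
  stopifnot(length(groupA) > 0, all(lengths(groupB_list) > 0))
  rows <- list()
  for (g in names(groupB_list)) {
    B <- groupB_list[[g]]
    d <- utils::adist(groupA, B) # |A| x |B| matrix in one C call
    rows[[g]] <- data.frame(group = g,
                            i = rep(seq_along(groupA), times = length(B)),
                            j = rep(seq_along(B), each = length(groupA)),
                            distance = as.integer(d))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  smry <- do.call(rbind, lapply(names(groupB_list), function(g) {
    d <- out$distance[out$group == g]
    data.frame(group = g, n = length(d), mean = mean(d),
               q25 = stats::quantile(d, 0.25), median = stats::median(d),
               q75 = stats::quantile(d, 0.75), row.names = NULL)
  }))
  attr(out, "summary") <- smry
  class(out) <- c("diversity_profile", class(out))
  out
}

#' Edit-distance difference between designs and their template
#'
#' Per-design difference score `s = ed(design, template) / flanking_length`
#' where `flanking_length` is the number of non-seed positions in the
#' window. `mode = "flanking"` (default) computes the edit distance on the
#' concatenated flanking regions only (seed regions are identical by
#' construction); `mode = "full"` uses the whole sequences. Both modes
#' normalise by the flanking length.
#'
#' @param designed_seqs Character vector of designed sequences.
#' @param template_seq Template sequence of the same length.
#' @param spec A [seed_spec()] defining the seed/flanking split.
#' @param mode `"flanking"` or `"full"`.
#' @return Object of class `template_difference`: list with `scores`
#'   (numeric per design), `mean`, `sd`, `mode`, `flanking_length`.
#' @export
template_difference <- function(designed_seqs, template_seq, spec,
                                mode = c("flanking", "full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "seed_spec"))
  L <- spec$window_length
  if (nchar(template_seq) != L || !all(nchar(designed_seqs) == L)) {
    stop("designed and template sequences must all have length ", L)
  }
  fl <- flanking_length(spec)
  if (fl == 0L) stop("spec has no flanking positions")
  extract_flank <- function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(chars[!seed_mask(spec)], collapse = "")
  }
  if (mode == "flanking") {
    d <- edit_distance(vapply(designed_seqs, extract_flank, character(1),
                              USE.NAMES = FALSE),
                       extract_flank(template_seq))
  } else {
    d <- edit_distance(designed_seqs, template_seq)
  }
  s <- d / fl
  structure(list(scores = s, mean = mean(s),
                 sd = if (length(s) > 1L) stats::sd(s) else 0,
                 mode = mode, flanking_length = fl),
            class = "template_difference")
}

#' @export
print.template_difference <- function(x, ...) {
  cat(sprintf(
    "Template difference (%s mode): %.2f%% +- %.2f%% over %d design(s)\n",
    x$mode, 100 * x$mean, 100 * x$sd, length(x$scores)))
  invisible(x)
}

# ---- DNA shape -------------------------------------------------------------

all_pentamers <- function() {
  g <- expand.grid(p5 = DNA_BASES, p4 = DNA_BASES, p3 = DNA_BASES,
                   p2 = DNA_BASES, p1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3, g$p4, g$p5))
}

# Deterministic hash of a string into [0, 1) (linear congruential over the
# base-4 index; exact in double arithmetic).
pent_unit <- function(pent, salt) {
  idx <- vapply(strsplit(pent, ""), function(ch) {
    sum((match(ch, DNA_BASES) - 1) * 4^(4:0))
  }, numeric(1))
  ((idx + 1) * 137 + salt * 263) %% 1021 / 1021
}

#' Synthetic pentamer DNA-shape table
#'
#' A fully deterministic stand-in for a published pentamer shape table,
#' covering all 1024 pentamers with four parameters: minor groove width
#' (MGW, Angstrom), propeller twist (ProT, degrees), roll and helix twist
#' (Roll/HelT, degrees). Values are a smooth function of AT content (AT
#' tracts get narrower MGW and more negative ProT, a qualitative property
#' of real B-DNA) plus a reproducible pentamer-specific component, and are
#' strand-symmetric: a pentamer and its reverse complement share all four
#' values, which gives the reverse-complement track symmetry real tables
#' have. Synthetic: suitable for method development and tests, not for
#' biological interpretation.
#'
#' @return Data frame with columns `pentamer`, `MGW`, `ProT`, `Roll`,
#'   `HelT`.
#' @export
synthetic_shape_table <- function() {
  pents <- all_pentamers()
  canon <- pmin(pents, revcomp(pents))
  at <- 1 - gc_fraction(pents)
  data.frame(
    pentamer = pents,
    MGW = 5.0 - 1.2 * at + 1.0 * (pent_unit(canon, 1) - 0.5),
    ProT = -7.0 - 6.0 * at + 4.0 * (pent_unit(canon, 2) - 0.5),
    Roll = 1.0 + 4.0 * (pent_unit(canon, 3) - 0.5) + 2.0 * (at - 0.5),
    HelT = 34.5 + 2.0 * (pent_unit(canon, 4) - 0.5) + 1.0 * (0.5 - at)
  )
}

#' Load a pentamer shape table from TSV
#'
#' Accepts a tab-separated table keyed by pentamer with columns
#' `pentamer`, `MGW`, `ProT`, `Roll`, `HelT` (the layout written by
#' [write_shape_table()], and the common export format of pentamer-model
#' shape tables). Tables with only the 512 canonical pentamers are
#' completed by reverse-complement symmetry.
#'
#' @param path TSV file.
#' @return Data frame with the five columns, 1024 rows.
#' @export
load_shape_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pentamer", "MGW", "ProT", "Roll", "HelT")
  if (!all(need %in% names(df))) {
    stop("shape table must have columns: ", paste(need, collapse = ", "))
  }
  df$pentamer <- toupper(df$pentamer)
  missing <- setdiff(all_pentamers(), df$pentamer)
  if (length(missing)) {
    rc <- revcomp(missing)
    have <- match(rc, df$pentamer)
    if (anyNA(have)) {
      stop("shape table incomplete: missing pentamer(s) e.g. ",
           missing[which(is.na(have))[1]])
    }
    add <- df[have, ]
    add$pentamer <- missing
    df <- rbind(df, add)
  }
  df[order(df$pentamer), need]
}

#' @rdname load_shape_table
#' @param table Shape table data frame.
#' @export
write_shape_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pentamer-based DNA shape tracks of a sequence
#'
#' Slides a pentamer window along the sequence and looks each pentamer up
#' in the shape table. MGW and ProT are assigned to the pentamer's centre
#' base. Roll and HelT are step parameters: each pentamer assigns its
#' value to its two central steps, overlapping assignments from adjacent
#' pentamers are averaged, and the track reports each pentamer centre as
#' the mean of the averaged steps on either side of it -- so all four
#' tracks are per-position vectors of length L whose defined span is
#' `L - 4` (the two boundary positions on each side are `NA` and flagged
#' undefined).
#'
#' @param seq DNA string of length >= 5 (A/C/G/T).
#' @param table Shape table (default [synthetic_shape_table()]).
#' @return Object of class `shape_tracks`: list with `mgw`, `prot`,
#'   `roll`, `helt` (length-L numeric, NA outside the defined span) and
#'   `defined` (logical length L).
#' @export
dna_shape <- function(seq, table = synthetic_shape_table()) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 5L) stop("sequence must be at least 5 bp")
  if (!grepl("^[ACGT]+$", seq)) stop("sequence must be ACGT only")
  pents <- substring(seq, 1:(L - 4L), 5:L)
  hit <- match(pents, table$pentamer)
  if (anyNA(hit)) {
    stop("pentamer missing from shape table: ", pents[which(is.na(hit))[1]])
  }
  mgw <- prot <- rep(NA_real_, L)
  centers <- 3:(L - 2L)
  mgw[centers] <- table$MGW[hit]
  prot[centers] <- table$ProT[hit]
  # steps: j is the step between bases j and j+1; pentamer starting at i
  # (centre i+2) covers steps i+1 and i+2; overlaps averaged
  roll_sum <- helt_sum <- cover <- numeric(L - 1L)
  for (i in seq_len(L - 4L)) {
    for (st in c(i + 1L, i + 2L)) {
      roll_sum[st] <- roll_sum[st] + table$Roll[hit[i]]
      helt_sum[st] <- helt_sum[st] + table$HelT[hit[i]]
      cover[st] <- cover[st] + 1
    }
  }
  step_roll <- ifelse(cover > 0, roll_sum / pmax(cover, 1), NA_real_)
  step_helt <- ifelse(cover > 0, helt_sum / pmax(cover, 1), NA_real_)
  # centre-of-pentamer track: mean of the steps flanking each centre
  roll <- helt <- rep(NA_real_, L)
  roll[centers] <- (step_roll[centers - 1L] + step_roll[centers]) / 2
  helt[centers] <- (step_helt[centers - 1L] + step_helt[centers]) / 2
  structure(list(mgw = mgw, prot = prot, roll = roll, helt = helt,
                 defined = !is.na(mgw), seq = seq),
            class = "shape_tracks")
}

#' @export
print.shape_tracks <- function(x, ...) {
  cat("DNA shape tracks,", length(x$mgw), "bp;",
      sum(x$defined), "defined MGW positions\n")
  invisible(x)
}

#' Concatenated, standardised shape feature vectors
#'
#' One feature vector per sequence: the four defined shape tracks
#' concatenated, then each feature standardised across sequences.
#'
#' @param seqs Equal-length sequences.
#' @param table Shape table.
#' @return n x d matrix.
#' @export
shape_features <- function(seqs, table = synthetic_shape_table()) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  feats <- t(vapply(seqs, function(s) {
    tr <- dna_shape(s, table)
    c(tr$mgw[tr$defined], tr$prot[tr$defined],
      tr$roll[!is.na(tr$roll)], tr$helt[!is.na(tr$helt)])
  }, numeric(4L * (nchar(seqs[1]) - 4L)), USE.NAMES = FALSE))
  sds <- apply(feats, 2L, stats::sd)
  sds[sds == 0] <- 1
  scale(feats, scale = sds)
}

#' Two-dimensional embedding of DNA shape features
#'
#' Concatenates the four shape tracks of each sequence into one feature
#' vector, standardises, reduces to `n_pc` principal components and embeds
#' into 2-D with Sammon nonlinear multidimensional scaling (deterministic:
#' classical MDS initialisation). Duplicate feature rows are collapsed
#' before the MDS and re-expanded afterwards, so identical inputs land at
#' identical coordinates.
#'
#' @param seqs At least 10 equal-length sequences.
#' @param table Shape table.
#' @param activity Optional numeric vector carried through for colouring.
#' @param n_pc Principal components kept before the MDS (default 10).
#' @param reduction_seed Seed (kept for interface stability; the embedding
#'   is deterministic).
#' @return Object of class `shape_embedding`: list with `coords` (n x 2),
#'   `activity`, `stress` (Sammon stress, 0 when the PCA plane already
#'   reproduces the distances).
#' @export
shape_embedding <- function(seqs, table = synthetic_shape_table(),
                            activity = NULL, n_pc = 10L,
                            reduction_seed = 1L) {
  if (length(seqs) < 10L) stop("need at least 10 sequences")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must have equal length")
  }
  feats <- shape_features(seqs, table)
  set.seed(reduction_seed)
  pc <- stats::prcomp(feats, rank. = min(n_pc, ncol(feats),
                                         nrow(feats) - 1L))
  Z <- pc$x
  key <- apply(round(Z, 10), 1L, paste, collapse = ",")
  uniq <- !duplicated(key)
  Zu <- Z[uniq, , drop = FALSE]
  stress <- 0
  if (nrow(Zu) <= 3L) {
    coords_u <- Zu[, 1:2, drop = FALSE]
  } else {
    D <- stats::dist(Zu)
    init <- stats::cmdscale(D, k = 2L)
    # jitter-free Sammon: distances are positive off-diagonal by uniqueness
    sm <- MASS::sammon(D, y = init, trace = FALSE)
    coords_u <- sm$points
    stress <- sm$stress
  }
  coords <- coords_u[match(key, key[uniq]), , drop = FALSE]
  dimnames(coords) <- list(NULL, c("dim1", "dim2"))
  structure(list(coords = coords, activity = activity, stress = stress),
            class = "shape_embedding")
}

#' @export
plot.shape_embedding <- function(x, ...) {
  col <- if (!is.null(x$activity)) {
    grDevices::hcl.colors(100, "Viridis")[
      cut(x$activity, 100, labels = FALSE)]
  } else "grey30"
  graphics::plot(x$coords, col = col, pch = 19, xlab = "dim 1",
                 ylab = "dim 2", ...)
  invisible(x)
}

#' Write shape tracks as TSV
#' @param tracks A `shape_tracks` object.
#' @param path Output TSV (0-based `position`).
#' @export
write_shape_tsv <- function(tracks, path) {
  L <- length(tracks$mgw)
  df <- data.frame(position = 0:(L - 1L), MGW = tracks$mgw,
                   ProT = tracks$prot,
                   Roll = tracks$roll, HelT = tracks$helt)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Uniform-random DNA sequences
#'
#' @param n Number of sequences.
#' @param length Sequence length.
#' @param prob Base probabilities A,C,G,T (default uniform).
#' @param spec Optional [seed_spec()]; when given, seed motifs are written
#'   over the random background (the "random flanks, fixed seeds" control
#'   construction).
#' @return Character vector.
#' @export
random_sequences <- function(n, length, prob = rep(0.25, 4), spec = NULL) {
  if (!is.null(spec)) length <- spec$window_length
  out <- vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
  if (!is.null(spec)) {
    mask <- seed_mask(spec)
    tmpl <- strsplit(seed_template(spec), "")[[1]]
    out <- vapply(out, function(s) {
      ch <- strsplit(s, "")[[1]]
      ch[mask] <- tmpl[mask]
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  out
}
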