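#' @importFrom stats rnorm runif predict sd cor quantile
#' @importFrom utils adist head
NULL

# Channel order is fixed package-wide: A, C, G, T. Coordinates are 0-based,
# intervals half-open, matching the conventions of BED-style genomics tooling.
DNA_BASES <- c("A", "C", "G", "T")

#' Seed specification: fixed motifs inside a design window
#'
#' A seed specification pins down the expert-chosen sequence elements of a
#' promoter design -- e.g. the sigma-70 -10/-35 elements, operator sites such
#' as lacO or tetO, or a minimal core promoter -- as exact substrings at exact
#' 0-based positions inside a fixed-length window. Everything outside the
#' motifs is "flanking" sequence, the part the generator is free to fill.
#'
#' @param window_length Window length in bp (single positive integer).
#' @param motifs List of motifs, each a list with elements `seq` (a DNA string
#'   over A/C/G/T) and `start` (0-based offset of its first base). May be
#'   empty.
#' @param label Optional free-text label.
#' @return An object of class `seed_spec`.
#' @examples
#' spec <- seed_spec(165, list(
#'   list(seq = "TTGACA", start = 120),
#'   list(seq = "TATAAT", start = 143)
#' ), label = "sigma70 consensus")
#' flanking_length(spec)
#' @export
seed_spec <- function(window_length, motifs = list(), label = "") {
  window_length <- as.integer(window_length)
  stopifnot(length(window_length) == 1L, window_length > 0L)
  motifs <- lapply(motifs, function(m) {
    m$seq <- toupper(as.character(m$seq))
    if (!grepl("^[ACGT]+$", m$seq)) {
      stop("seed motif contains characters outside A/C/G/T: ", m$seq)
    }
    m$start <- as.integer(m$start)
    if (m$start < 0L || m$start + nchar(m$seq) > window_length) {
      stop("motif '", m$seq, "' at start ", m$start,
           " does not fit inside [0, ", window_length, ")")
    }
    m[c("seq", "start")]
  })
  if (length(motifs) > 1L) {
    iv <- t(vapply(motifs, function(m) c(m$start, m$start + nchar(m$seq)),
                   numeric(2)))
    ord <- order(iv[, 1])
    iv <- iv[ord, , drop = FALSE]
    bad <- which(iv[-1, 1] < iv[-nrow(iv), 2])
    if (length(bad)) {
      stop(sprintf("overlapping motifs in [%d, %d) and [%d, %d)",
                   iv[bad[1], 1], iv[bad[1], 2], iv[bad[1] + 1, 1],
                   iv[bad[1] + 1, 2]))
    }
    motifs <- motifs[ord]
  }
  structure(list(window_length = window_length, motifs = motifs,
                 label = as.character(label)),
            class = "seed_spec")
}

#' @export
print.seed_spec <- function(x, ...) {
  cat("Seed specification", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "\n  window:", x$window_length, "bp\n")
  for (m in x$motifs) {
    cat(sprintf("  motif %-12s at [%d, %d)\n", m$seq, m$start,
                m$start + nchar(m$seq)))
  }
  cat("  flanking:", flanking_length(x), "bp\n")
  invisible(x)
}

#' Logical mask of seed positions
#'
#' @param spec A [seed_spec()].
#' @return Logical vector of length `window_length`, `TRUE` at positions
#'   covered by a motif.
#' @export
seed_mask <- function(spec) {
  stopifnot(inherits(spec, "seed_spec"))
  mask <- rep(FALSE, spec$window_length)
  for (m in spec$motifs) {
    mask[(m$start + 1L):(m$start + nchar(m$seq))] <- TRUE
  }
  mask
}

#' Total flanking length of a seed specification
#'
#' The number of positions in the window not covered by any seed motif; this
#' is the normaliser used by [template_difference()].
#'
#' @inheritParams seed_mask
#' @return Integer number of flanking bp.
#' @export
flanking_length <- function(spec) {
  sum(!seed_mask(spec))
}

#' The sequence a seed spec implies, with flanks filled by a placeholder
#'
#' @param spec A [seed_spec()].
#' @param fill Single character used at flanking positions (default `"N"`).
#' @return A character string of length `window_length`.
#' @export
seed_template <- function(spec, fill = "N") {
  chars <- rep(fill, spec$window_length)
  for (m in spec$motifs) {
    chars[(m$start + 1L):(m$start + nchar(m$seq))] <-
      strsplit(m$seq, "")[[1]]
  }
  paste(chars, collapse = "")
}

#' One-hot encode a DNA sequence
#'
#' Encodes over the fixed channel order A, C, G, T. `N` becomes the uniform
#' row (0.25 in every channel); any other character is an error naming the
#' offending position.
#'
#' @param seq A non-empty DNA string (A/C/G/T/N, case-insensitive).
#' @return An L x 4 numeric matrix with `colnames` A, C, G, T.
#' @examples
#' encode_onehot("ACGT")
#' @export
encode_onehot <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, c(DNA_BASES, "N"))
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop("illegal character '", chars[p], "' at position ", p,
         " (1-based); alphabet is A/C/G/T/N")
  }
  m <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  hard <- idx <= 4L
  m[cbind(which(hard), idx[hard])] <- 1
  m[!hard, ] <- 0.25
  m
}

#' Decode a one-hot (or relaxed) matrix back to a DNA string
#'
#' Takes the per-row argmax; ties break lexicographically (A < C < G < T),
#' so the uniform row decodes to `"A"`.
#'
#' @param matrix An L x 4 numeric matrix with finite entries, channels
#'   A, C, G, T.
#' @return A DNA string of length L.
#' @export
decode_onehot <- function(matrix) {
  if (!is.matrix(matrix) || ncol(matrix) != 4L) {
    stop("expected an L x 4 matrix (channels A,C,G,T), got ",
         paste(dim(matrix), collapse = " x "))
  }
  if (!all(is.finite(matrix))) stop("non-finite entries in one-hot matrix")
  paste(DNA_BASES[max.col(matrix, ties.method = "first")], collapse = "")
}

# Draw one relaxed random row per flanking position: softmax of 4 iid
# standard normals. This is the documented realisation of the generator's
# latent variable z -- the random rows ARE z.
random_rows <- function(n) {
  z <- matrix(rnorm(4L * n), nrow = n, ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

#' Build a generator input: hard seed rows plus random flanking rows
#'
#' Seed positions carry the exact one-hot rows of the motifs; every other
#' position is an independent random probability vector (softmax of four
#' standard normals), which realises the generator's latent variable.
#'
#' @param spec A [seed_spec()].
#' @param rng_seed Integer seed; the same seed yields an identical input.
#' @param latent Optional numeric matrix (`n_flank` x 4) of pre-softmax
#'   normals to use instead of drawing fresh ones (used by the GA, which
#'   optimises these numbers directly).
#' @return A list of class `generator_input` with elements `matrix`
#'   (L x 4), `seed_mask` (logical L) and `spec`.
#' @export
build_generator_input <- function(spec, rng_seed = NULL, latent = NULL) {
  stopifnot(inherits(spec, "seed_spec"))
  mask <- seed_mask(spec)
  L <- spec$window_length
  m <- matrix(0.25, nrow = L, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  if (any(mask)) {
    m[mask, ] <- encode_onehot(gsub("N", "", seed_template(spec)))
  }
  nf <- sum(!mask)
  if (nf > 0L) {
    if (is.null(latent)) {
      if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
      m[!mask, ] <- random_rows(nf)
    } else {
      stopifnot(is.matrix(latent), nrow(latent) == nf, ncol(latent) == 4L)
      e <- exp(latent - apply(latent, 1L, max))
      m[!mask, ] <- e / rowSums(e)
    }
  }
  structure(list(matrix = m, seed_mask = mask, spec = spec),
            class = "generator_input")
}

#' Overwrite seed positions of a relaxed matrix with hard motif rows
#'
#' The hard constraint of the design framework: whatever the generator
#' emits, the seed motifs are restored exactly before a sequence leaves the
#' pipeline.
#'
#' @param matrix L x 4 numeric matrix.
#' @param spec A [seed_spec()] with `window_length == nrow(matrix)`.
#' @return The matrix with seed rows replaced by hard one-hot motif rows.
#' @export
impose_seeds <- function(matrix, spec) {
  stopifnot(nrow(matrix) == spec$window_length)
  mask <- seed_mask(spec)
  if (any(mask)) {
    matrix[mask, ] <- encode_onehot(gsub("N", "", seed_template(spec)))
  }
  matrix
}

#' Read / write seed specifications as YAML or JSON
#'
#' The on-disk form is `{window_length, motifs: [{seq, start}], label}` with
#' 0-based starts. Format is chosen by file extension (`.yaml`/`.yml` vs
#' `.json`).
#'
#' @param path File path.
#' @return `read_seed_spec()` returns a [seed_spec()]; `write_seed_spec()`
#'   returns `path` invisibly.
#' @export
read_seed_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  seed_spec(x$window_length, x$motifs,
            label = if (is.null(x$label)) "" else x$label)
}

#' @rdname read_seed_spec
#' @param spec A [seed_spec()].
#' @export
write_seed_spec <- function(spec, path) {
  x <- list(window_length = spec$window_length, motifs = spec$motifs,
            label = spec$label)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read / write plain FASTA sequence sets
#'
#' Thin wrappers around Biostrings. `read_fasta()` returns a character
#' vector named by record id; if headers carry `|activity=<x>` tags (the
#' package's convention for scored sequence sets) the activities are parsed
#' into an attribute and by [as_promoter_dataset()] into a dataset.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences, with attribute
#'   `activity` (numeric, `NA` where absent).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  ids <- names(seqs)
  act <- rep(NA_real_, length(seqs))
  hit <- grepl("\\|activity=", ids)
  act[hit] <- as.numeric(sub(".*\\|activity=([-0-9.eE+]+).*", "\\1", ids[hit]))
  names(seqs) <- sub("\\|activity=.*$", "", ids)
  attr(seqs, "activity") <- act
  seqs
}

#' @rdname read_fasta
#' @param seqs Character vector of sequences (names used as ids).
#' @param activity Optional numeric vector written as `|activity=` header
#'   tags.
#' @export
write_fasta <- function(seqs, path, activity = NULL) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(seqs))
  if (!is.null(activity)) {
    ids <- sprintf("%s|activity=%.6g", ids, activity)
  }
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Reverse complement for plain character vectors.
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}
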