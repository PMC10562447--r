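# Constitutive sigma-70 promoter templates from the iGEM Anderson (J23)
# collection: 35 bp parts with the -35 element at offset 0 and the -10
# element at offset 24 (17 bp spacer). These are standard public parts,
# embedded here as the templates for the random-flank control analysis.
J23_PROMOTERS <- c(
  J23119 = "TTGACAGCTAGCTCAGTCCTAGGTATAATGCTAGC",
  J23118 = "TTGACGGCTAGCTCAGTCCTAGGTATTGTGCTAGC",
  J23114 = "TTTATGGCTAGCTCAGTCCTAGGTACAATGCTAGC"
)

#' Anderson-collection promoter template and its seed specification
#'
#' Returns one of the 35 bp J23 constitutive promoter parts, extended to a
#' design window by placing the part at the 3' end of the window over a
#' deterministic neutral background, together with the [seed_spec()] that
#' fixes its -35 and -10 hexamers (offsets 0 and 24 within the part).
#' This is the "keep the seeds, randomise the rest" template used by the
#' random-flank control construction.
#'
#' @param name One of `"J23119"`, `"J23118"`, `"J23114"`.
#' @param window_length Design window (default 165 bp).
#' @return List with `template` (window-length string: the part at the 3'
#'   end, alternating-base filler upstream), `part` (the 35 bp part),
#'   `spec` (a [seed_spec()] over the window fixing the two hexamers).
#' @export
j23_template <- function(name = c("J23119", "J23118", "J23114"),
                         window_length = 165L) {
  name <- match.arg(name)
  part <- J23_PROMOTERS[[name]]
  stopifnot(window_length >= nchar(part))
  off <- window_length - nchar(part) # part sits at the 3' end
  filler <- paste(rep(c("A", "C", "G", "T"), length.out = off),
                  collapse = "")
  template <- paste0(filler, part)
  spec <- seed_spec(window_length, list(
    list(seq = substr(part, 1L, 6L), start = off),
    list(seq = substr(part, 25L, 30L), start = off + 24L)
  ), label = name)
  list(template = template, part = part, spec = spec)
}

#' Random-flank control statistics against a template
#'
#' The computational analogue of a "fixed seeds, random flanks" control
#' group: draws `n` uniform-random windows, writes the template's seed
#' motifs over them, and summarises the normalised edit distance to the
#' template with [template_difference()].
#'
#' @param name J23 part name (see [j23_template()]).
#' @param n Group size (default 16, the in-vivo group size this mirrors).
#' @param window_length Design window (default 165).
#' @param mode Passed to [template_difference()] (default `"flanking"`).
#' @param rng_seed Seed.
#' @return The [template_difference()] object for the control group.
#' @export
control2_template_difference <- function(name, n = 16L,
                                         window_length = 165L,
                                         mode = "flanking",
                                         rng_seed = 1L) {
  tm <- j23_template(name, window_length)
  set.seed(rng_seed)
  ctrl <- random_sequences(n, window_length, spec = tm$spec)
  template_difference(ctrl, tm$template, tm$spec, mode = mode)
}
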