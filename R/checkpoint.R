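#' Save and load model checkpoints
#'
#' One-file checkpoints for the generator, critic and predictor: an RDS
#' archive holding the weights, the configuration and the RNG state at
#' save time, with a schema version so old checkpoints stay readable.
#'
#' @param model A `generator_model`, `critic_model`, `predictor_model` or
#'   `cgan_fit`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the restored object.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("generator_model", "critic_model",
                              "predictor_model", "cgan_fit")))
  rng <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  saveRDS(list(schema = 1L, class = class(model), model = model,
               rng_state = rng, saved = as.character(Sys.time())),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (is.null(x$schema) || x$schema != 1L) {
    stop("unsupported checkpoint schema in ", path)
  }
  x$model
}
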