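#' Save and load model checkpoints
#'
#' A checkpoint is a single file holding the model class, its architecture
#' specification and its parameter arrays. The companion YAML helpers
#' serialise a specification alone, for config files consumed by the
#' command-line interface.
#'
#' @param model a `TransformerModel` or `MLPModel`
#' @param path checkpoint file path
#' @return `readCheckpoint` returns the model object.
#' @export
writeCheckpoint <- function(model, path) {
  saveRDS(list(class = class(model)[1L], spec = model@spec,
               params = model@params), path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  x <- readRDS(path)
  new(x$class, spec = x$spec, params = x$params)
}

#' @rdname writeCheckpoint
#' @param spec a model specification list
#' @export
specToYaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
specFromYaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$inputDim))
    mlpSpec(x$inputDim, unlist(x$hiddenWidths), x$dropout %||% 0)
  else
    transformerSpec(x$tokenDim, x$embedWidth %||% 32L, x$nBlocks %||% 1L,
                    x$nHeads %||% 4L,
                    lapply(x$headHidden, unlist),
                    x$dropout %||% 0, x$context %||% 31L,
                    x$maskPad %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
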