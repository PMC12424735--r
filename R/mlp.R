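#' MLP specification and initialisation
#'
#' A dense ReLU stack with dropout over pooled site embeddings, ending in a
#' single sigmoid output. This is the per-site baseline model; the input is
#' the embedding row of the lysine itself (see [poolSiteEmbedding()]),
#' optionally a concatenation of several embedders' rows.
#'
#' @param inputDim input vector length
#' @param hiddenWidths integer vector of hidden-layer widths (non-empty)
#' @param dropout dropout rate in \[0, 1)
#' @return An `MLPSpec` list.
#' @export
mlpSpec <- function(inputDim, hiddenWidths = c(64L, 32L), dropout = 0) {
  if (!length(hiddenWidths)) stop("hiddenWidths must be non-empty")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(inputDim = as.integer(inputDim),
                 hiddenWidths = as.integer(hiddenWidths),
                 dropout = dropout),
            class = "MLPSpec")
}

#' @rdname mlpSpec
#' @param spec an `MLPSpec`
#' @param seed integer RNG seed
#' @return `initMLP` returns an [MLPModel-class].
#' @export
initMLP <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  new("MLPModel", spec = unclass(spec),
      params = list(layers = .headInit(spec$inputDim, spec$hiddenWidths)))
}

.mlpForward <- function(model, x, train = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model@spec$inputDim)
    stop("input has ", ncol(x), " columns; spec inputDim is ",
         model@spec$inputDim)
  head <- .headForward(model@params$layers, x, model@spec$dropout, train)
  list(prob = .sigmoid(head$logit), logit = head$logit, head = head)
}

.mlpGrad <- function(model, x, labels, train = TRUE) {
  fw <- .mlpForward(model, x, train = train)
  n <- length(labels)
  prob <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  loss <- -mean(labels * log(prob) + (1 - labels) * log(1 - prob))
  dlogit <- (prob - labels) / n
  hb <- .headBackward(model@params$layers, fw$head$caches, dlogit)
  list(loss = loss, prob = fw$prob, grads = list(layers = hb$grads))
}
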