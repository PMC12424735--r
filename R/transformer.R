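#' Transformer specification
#'
#' Encoder-style architecture over a lysine-centred window of per-residue
#' embeddings: a per-token dense layer (tokenDim -> embedWidth), sinusoidal
#' positional encoding, `nBlocks` pre-norm self-attention blocks (multi-head
#' attention plus a GELU feed-forward of width 4 x embedWidth, residual
#' connections, layer normalisation), a flattening layer concatenating the
#' `context` post-attention token vectors, and one ReLU classification head
#' per task ending in a sigmoid. Pad positions are masked out of attention by
#' default and their token rows zeroed, so scores are invariant to pad
#' content.
#'
#' The shipped production-scale default mirrors the best published
#' configuration (2 blocks, 4 heads, embed width 1,600, head widths
#' 1,797/1,803/338/493 in [ptmTasks()] order, dropout 0.15); reduced specs
#' are used everywhere speed matters.
#'
#' @param tokenDim input embedding dimension d
#' @param embedWidth width of the pre-attention dense layer; must be even and
#'   divisible by `nHeads`
#' @param nBlocks number of attention blocks (>= 1)
#' @param nHeads attention heads per block
#' @param headHidden named list mapping task -> integer vector of hidden
#'   widths for that task's classification head (a single unnamed vector is
#'   taken as a methylation-only head)
#' @param dropout dropout rate in \[0, 1), applied uniformly (attention
#'   output, feed-forward output, head hidden layers) during training
#' @param context window length (odd)
#' @param maskPad mask pad positions out of attention and zero their rows
#' @return A `TransformerSpec` list.
#' @export
transformerSpec <- function(tokenDim, embedWidth = 32L, nBlocks = 1L,
                            nHeads = 4L, headHidden = list(methylation = 32L),
                            dropout = 0, context = 31L, maskPad = TRUE) {
  if (!is.list(headHidden)) headHidden <- list(methylation = headHidden)
  if (is.null(names(headHidden)))
    stop("headHidden must be named by task")
  for (t in names(headHidden)) .assertTask(t)
  embedWidth <- as.integer(embedWidth)
  if (embedWidth %% as.integer(nHeads) != 0L)
    stop("nHeads (", nHeads, ") must divide embedWidth (", embedWidth, ")")
  if (embedWidth %% 2L != 0L)
    stop("embedWidth must be even for the positional encoding")
  if (nBlocks < 1L) stop("nBlocks must be >= 1")
  if (context %% 2L == 0L) stop("context must be odd")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(tokenDim = as.integer(tokenDim), embedWidth = embedWidth,
                 nBlocks = as.integer(nBlocks), nHeads = as.integer(nHeads),
                 headHidden = lapply(headHidden, as.integer),
                 dropout = dropout, context = as.integer(context),
                 maskPad = isTRUE(maskPad)),
            class = "TransformerSpec")
}

#' Production-scale default transformer specification
#'
#' @param tokenDim input embedding dimension (default 1024)
#' @return A `TransformerSpec` with the shipped default hyperparameters.
#' @export
defaultTransformerSpec <- function(tokenDim = 1024L) {
  transformerSpec(tokenDim, embedWidth = 1600L, nBlocks = 2L, nHeads = 4L,
                  headHidden = list(methylation = 1797L,
                                    ubiquitination = 1803L,
                                    acetylation = 338L,
                                    sumoylation = 493L),
                  dropout = 0.15, context = 31L)
}

#' Fitted site-classifier models
#'
#' `TransformerModel` and `MLPModel` couple an architecture specification
#' with a parameter set; both predict per-site modification probabilities.
#'
#' @slot spec architecture specification list
#' @slot params nested list of parameter arrays
#' @name TransformerModel-class
#' @aliases TransformerModel MLPModel-class MLPModel
#' @exportClass TransformerModel
setClass("TransformerModel",
         representation(spec = "list", params = "list"))

#' @exportClass MLPModel
setClass("MLPModel", representation(spec = "list", params = "list"))

setMethod("show", "TransformerModel", function(object) {
  s <- object@spec
  cat(sprintf(paste0("TransformerModel: d=%d, embed=%d, %d block(s), ",
                     "%d heads, context %d\n  tasks: %s\n  parameters: %s\n"),
              s$tokenDim, s$embedWidth, s$nBlocks, s$nHeads, s$context,
              paste(names(s$headHidden), collapse = ", "),
              format(nParameters(object), big.mark = ",")))
})
setMethod("show", "MLPModel", function(object) {
  s <- object@spec
  cat(sprintf("MLPModel: input %d, hidden %s, dropout %.2f, parameters %s\n",
              s$inputDim, paste(s$hiddenWidths, collapse = "/"), s$dropout,
              format(nParameters(object), big.mark = ",")))
})

#' Model accessors
#'
#' @param model a `TransformerModel` or `MLPModel`
#' @return `modelSpec` the architecture spec; `modelParameters` the parameter
#'   list; `modelTasks` the tasks the model can score; `nParameters` the
#'   total parameter count.
#' @export
modelSpec <- function(model) model@spec

#' @rdname modelSpec
#' @export
modelParameters <- function(model) model@params

#' @rdname modelSpec
#' @export
modelTasks <- function(model) {
  if (is(model, "TransformerModel")) names(model@spec$headHidden)
  else "methylation"
}

#' @rdname modelSpec
#' @export
nParameters <- function(model) {
  sum(vapply(.flattenParams(model@params), length, integer(1)))
}

#' Closed-form parameter count for a transformer spec
#'
#' Asserted against the instantiated model in the test suite to catch silent
#' architecture drift.
#'
#' @param spec a [transformerSpec()]
#' @return Integer parameter count.
#' @export
nParametersFormula <- function(spec) {
  d <- spec$tokenDim; E <- spec$embedWidth; C <- spec$context
  perBlock <- 2L * E +                 # ln1
    4L * (E * E + E) +                 # q, k, v, o projections
    2L * E +                           # ln2
    (E * 4L * E + 4L * E) +            # ffn in
    (4L * E * E + E)                   # ffn out
  headCount <- function(widths) {
    dims <- c(C * E, widths, 1L)
    sum(dims[-length(dims)] * dims[-1L] + dims[-1L])
  }
  d * E + E + spec$nBlocks * perBlock +
    sum(vapply(spec$headHidden, headCount, numeric(1)))
}

.denseInit <- function(nin, nout, zero = FALSE) {
  w <- if (zero) matrix(0, nin, nout)
       else matrix(rnorm(nin * nout, sd = 1 / sqrt(nin)), nin, nout)
  list(W = w, b = numeric(nout))
}

.headInit <- function(inDim, widths) {
  dims <- c(inDim, widths)
  layers <- lapply(seq_along(widths), function(l)
    .denseInit(dims[l], dims[l + 1L]))
  # zero-initialised output layer: an untrained model scores exactly 0.5
  c(layers, list(.denseInit(dims[length(dims)], 1L, zero = TRUE)))
}

#' Initialise a transformer model
#'
#' Weights are Gaussian with 1/sqrt(fan-in) scale; biases and the final head
#' layer are zero (so an untrained model scores 0.5 everywhere); layer-norm
#' gains start at 1.
#'
#' @param spec a [transformerSpec()]
#' @param seed integer RNG seed
#' @return A [TransformerModel-class].
#' @export
initTransformer <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  E <- spec$embedWidth
  input <- .denseInit(spec$tokenDim, E)
  blocks <- lapply(seq_len(spec$nBlocks), function(b) {
    att <- list(ln1g = rep(1, E), ln1b = numeric(E))
    for (nm in c("q", "k", "v", "o")) {
      dn <- .denseInit(E, E)
      att[[paste0("W", nm)]] <- dn$W
      att[[paste0("b", nm)]] <- dn$b
    }
    ffn1 <- .denseInit(E, 4L * E)
    ffn2 <- .denseInit(4L * E, E)
    c(att, list(ln2g = rep(1, E), ln2b = numeric(E),
                W1 = ffn1$W, b1 = ffn1$b, W2 = ffn2$W, b2 = ffn2$b))
  })
  heads <- lapply(spec$headHidden, function(w)
    .headInit(spec$context * E, w))
  new("TransformerModel", spec = unclass(spec),
      params = list(input = input, blocks = blocks, heads = heads))
}

# ---- forward --------------------------------------------------------------

.trunkForward <- function(spec, params, tokens, mask, train = FALSE) {
  C <- spec$context; E <- spec$embedWidth
  N <- nrow(mask); nH <- spec$nHeads; dh <- E %/% nH
  if (ncol(tokens) != spec$tokenDim)
    stop("token dimension ", ncol(tokens), " does not match spec tokenDim ",
         spec$tokenDim)
  if (nrow(tokens) != N * C)
    stop("tokens has ", nrow(tokens), " rows; expected n * context = ",
         N * C)
  maskVec <- as.integer(t(mask))
  if (spec$maskPad && any(maskVec == 0L))
    tokens[maskVec == 0L, ] <- 0
  H <- tokens %*% params$input$W
  H <- sweep(H, 2L, params$input$b, "+")
  pe <- sinusoidalPositionalEncoding(C, E)
  H <- H + pe[rep(seq_len(C), N), ]
  dr <- if (train) spec$dropout else 0
  headCols <- lapply(seq_len(nH), function(h) ((h - 1L) * dh + 1L):(h * dh))
  blockCaches <- vector("list", spec$nBlocks)
  for (b in seq_len(spec$nBlocks)) {
    p <- params$blocks[[b]]
    Hin <- H
    ln1 <- .layernormForward(Hin, p$ln1g, p$ln1b)
    L1 <- ln1$y
    Q <- sweep(L1 %*% p$Wq, 2L, p$bq, "+")
    K <- sweep(L1 %*% p$Wk, 2L, p$bk, "+")
    V <- sweep(L1 %*% p$Wv, 2L, p$bv, "+")
    P <- array(0, c(C, C, nH, N))
    O <- matrix(0, N * C, E)
    for (i in seq_len(N)) {
      ri <- ((i - 1L) * C + 1L):(i * C)
      padKeys <- spec$maskPad && any(mask[i, ] == 0L)
      for (h in seq_len(nH)) {
        ch <- headCols[[h]]
        S <- tcrossprod(Q[ri, ch, drop = FALSE],
                        K[ri, ch, drop = FALSE]) / sqrt(dh)
        if (padKeys) S[, mask[i, ] == 0L] <- -Inf
        Pi <- .softmaxRows(S)
        P[, , h, i] <- Pi
        O[ri, ch] <- Pi %*% V[ri, ch, drop = FALSE]
      }
    }
    A <- sweep(O %*% p$Wo, 2L, p$bo, "+")
    dropA <- .dropoutMask(nrow(A), ncol(A), dr)
    A <- .applyMask(A, dropA)
    H2 <- Hin + A
    ln2 <- .layernormForward(H2, p$ln2g, p$ln2b)
    L2 <- ln2$y
    F1 <- sweep(L2 %*% p$W1, 2L, p$b1, "+")
    Phi <- pnorm(F1)
    G <- F1 * Phi
    F2 <- sweep(G %*% p$W2, 2L, p$b2, "+")
    dropF <- .dropoutMask(nrow(F2), ncol(F2), dr)
    F2 <- .applyMask(F2, dropF)
    H <- H2 + F2
    blockCaches[[b]] <- list(Hin = Hin, ln1 = ln1, L1 = L1, Q = Q, K = K,
                             V = V, P = P, O = O, dropA = dropA, H2 = H2,
                             ln2 = ln2, L2 = L2, F1 = F1, Phi = Phi, G = G,
                             dropF = dropF)
  }
  Z <- matrix(as.vector(t(H)), N, C * E, byrow = TRUE)
  list(Z = Z, cache = list(tokens = tokens, mask = mask, blocks = blockCaches,
                           headCols = headCols, N = N))
}

.headForward <- function(layers, Z, dropout = 0, train = FALSE) {
  U <- Z
  dr <- if (train) dropout else 0
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    pre <- sweep(U %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    if (l < length(layers)) {
      act <- .relu(pre)
      dm <- .dropoutMask(nrow(act), ncol(act), dr)
      out <- .applyMask(act, dm)
      caches[[l]] <- list(input = U, pre = pre, dm = dm)
      U <- out
    } else {
      caches[[l]] <- list(input = U)
      U <- pre
    }
  }
  list(logit = drop(U), caches = caches)
}

.transformerForward <- function(model, data, task, train = FALSE) {
  spec <- model@spec
  task <- .assertTask(task)
  if (!task %in% names(spec$headHidden))
    stop("model has no head for task '", task, "'")
  trunk <- .trunkForward(spec, model@params, data$tokens, data$mask, train)
  head <- .headForward(model@params$heads[[task]], trunk$Z, spec$dropout,
                       train)
  list(prob = .sigmoid(head$logit), logit = head$logit,
       trunk = trunk, head = head, task = task)
}

# ---- backward -------------------------------------------------------------

.headBackward <- function(layers, caches, dlogit) {
  grads <- vector("list", length(layers))
  dU <- matrix(dlogit, ncol = 1L)
  for (l in rev(seq_along(layers))) {
    cc <- caches[[l]]
    if (l < length(layers)) {
      dOut <- .applyMask(dU, cc$dm)
      dPre <- dOut * (cc$pre > 0)
    } else dPre <- dU
    grads[[l]] <- list(W = crossprod(cc$input, dPre), b = colSums(dPre))
    dU <- dPre %*% t(layers[[l]]$W)
  }
  list(grads = grads, dZ = dU)
}

.trunkBackward <- function(spec, params, cache, dZ) {
  C <- spec$context; E <- spec$embedWidth
  N <- cache$N; nH <- spec$nHeads; dh <- E %/% nH
  headCols <- cache$headCols
  dH <- matrix(as.vector(t(dZ)), ncol = E, byrow = TRUE)
  blockGrads <- vector("list", spec$nBlocks)
  for (b in rev(seq_len(spec$nBlocks))) {
    p <- params$blocks[[b]]
    cc <- cache$blocks[[b]]
    # feed-forward sub-layer (H = H2 + F2)
    dF2 <- .applyMask(dH, cc$dropF)
    dG <- dF2 %*% t(p$W2)
    gW2 <- crossprod(cc$G, dF2); gb2 <- colSums(dF2)
    dF1 <- dG * (cc$Phi + cc$F1 * dnorm(cc$F1))
    gW1 <- crossprod(cc$L2, dF1); gb1 <- colSums(dF1)
    dL2 <- dF1 %*% t(p$W1)
    ln2b <- .layernormBackward(dL2, cc$ln2, p$ln2g)
    dH2 <- dH + ln2b$dx
    # attention sub-layer (H2 = Hin + A)
    dA <- .applyMask(dH2, cc$dropA)
    dO <- dA %*% t(p$Wo)
    gWo <- crossprod(cc$O, dA); gbo <- colSums(dA)
    dQ <- matrix(0, N * C, E); dK <- dQ; dV <- dQ
    for (i in seq_len(N)) {
      ri <- ((i - 1L) * C + 1L):(i * C)
      for (h in seq_len(nH)) {
        ch <- headCols[[h]]
        Pi <- cc$P[, , h, i]
        dOih <- dO[ri, ch, drop = FALSE]
        dV[ri, ch] <- crossprod(Pi, dOih)
        dP <- tcrossprod(dOih, cc$V[ri, ch, drop = FALSE])
        dS <- Pi * (dP - rowSums(dP * Pi))
        dQ[ri, ch] <- dS %*% cc$K[ri, ch, drop = FALSE] / sqrt(dh)
        dK[ri, ch] <- crossprod(dS, cc$Q[ri, ch, drop = FALSE]) / sqrt(dh)
      }
    }
    gWq <- crossprod(cc$L1, dQ); gbq <- colSums(dQ)
    gWk <- crossprod(cc$L1, dK); gbk <- colSums(dK)
    gWv <- crossprod(cc$L1, dV); gbv <- colSums(dV)
    dL1 <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    ln1b <- .layernormBackward(dL1, cc$ln1, p$ln1g)
    dH <- dH2 + ln1b$dx
    blockGrads[[b]] <- list(ln1g = ln1b$dg, ln1b = ln1b$db,
                            Wq = gWq, bq = gbq, Wk = gWk, bk = gbk,
                            Wv = gWv, bv = gbv, Wo = gWo, bo = gbo,
                            ln2g = ln2b$dg, ln2b = ln2b$db,
                            W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }
  list(input = list(W = crossprod(cache$tokens, dH), b = colSums(dH)),
       blocks = blockGrads)
}

# full forward + backward for one task-homogeneous batch; returns mean BCE
# (times lossScale) and gradients for the trunk and the active head only
.transformerGrad <- function(model, data, task, labels, lossScale = 1,
                             train = TRUE) {
  fw <- .transformerForward(model, data, task, train = train)
  n <- length(labels)
  prob <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  loss <- -mean(labels * log(prob) + (1 - labels) * log(1 - prob)) *
    lossScale
  dlogit <- (prob - labels) / n * lossScale
  hb <- .headBackward(model@params$heads[[task]], fw$head$caches, dlogit)
  tg <- .trunkBackward(model@spec, model@params, fw$trunk$cache, hb$dZ)
  heads <- setNames(vector("list", length(model@params$heads)),
                    names(model@params$heads))
  heads[[task]] <- hb$grads
  list(loss = loss, prob = fw$prob,
       grads = list(input = tg$input, blocks = tg$blocks, heads = heads))
}

#' Score sites with a single-task model
#'
#' Deterministic evaluation-mode forward pass. For a `TransformerModel`,
#' `data` is an embedded dataset (see [embedDataset()]); for an `MLPModel` a
#' numeric matrix of pooled site embeddings (one row per site).
#'
#' @param model a `TransformerModel` or `MLPModel`
#' @param data model input
#' @param task PTM task to score (must have a head); defaults to the model's
#'   first task
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predictSites <- function(model, data, task = NULL) {
  if (is(model, "MLPModel")) return(.mlpForward(model, data)$prob)
  if (is.null(task)) task <- names(model@spec$headHidden)[1L]
  as.vector(.transformerForward(model, data, task, train = FALSE)$prob)
}

#' Score one input under every head of a multitask model
#'
#' The shared trunk is evaluated once; each head is applied to the same
#' flattened trunk output.
#'
#' @param model a multitask `TransformerModel`
#' @param data embedded dataset
#' @return Matrix of probabilities, one column per task.
#' @export
predictAllTasks <- function(model, data) {
  trunk <- .trunkForward(model@spec, model@params, data$tokens, data$mask,
                         train = FALSE)
  vapply(names(model@spec$headHidden), function(t)
    as.vector(.sigmoid(.headForward(model@params$heads[[t]],
                                    trunk$Z)$logit)),
    numeric(data$n))
}
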