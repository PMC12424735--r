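# Independent oracles and fixture builders used across the test files.

# --- brute-force curve oracle: enumerate every distinct threshold ----------
bruteCurveMetrics <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  Nn <- sum(labels == 0)
  prec <- rec <- fpr <- numeric(length(th))
  tp <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- scores >= th[i]
    tp[i] <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    prec[i] <- tp[i] / (tp[i] + fp)
    rec[i] <- tp[i] / P
    fpr[i] <- fp / Nn
  }
  auprc <- sum(prec * diff(c(0, tp))) / P
  tpr2 <- c(0, rec); fpr2 <- c(0, fpr)
  auroc <- sum(diff(fpr2) * (tpr2[-length(tpr2)] + tpr2[-1]) / 2)
  list(auprc = auprc, auroc = auroc)
}

# Mann-Whitney AUROC by exhaustive pair counting (ties count 1/2)
pairCountAUROC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# --- independently hand-coded transformer forward pass ---------------------
# Plain scalar/loop implementation of the same architecture, written without
# reference to the package internals; used as the dual-implementation oracle.
naiveForward <- function(spec, params, tokens, mask, task) {
  C <- spec$context; E <- spec$embedWidth; nH <- spec$nHeads
  dh <- E / nH
  ln <- function(x, g, b) {
    t(apply(x, 1, function(r) {
      mu <- mean(r); v <- mean((r - mu)^2)
      g * (r - mu) / sqrt(v + 1e-5) + b
    }))
  }
  X <- tokens
  if (spec$maskPad) X[mask == 0, ] <- 0
  H <- matrix(0, C, E)
  for (i in 1:C) H[i, ] <- as.vector(X[i, ] %*% params$input$W) +
    params$input$b
  pe <- matrix(0, C, E)
  for (p in 0:(C - 1)) for (k in 0:(E / 2 - 1)) {
    pe[p + 1, 2 * k + 1] <- sin(p / 10000^(2 * k / E))
    pe[p + 1, 2 * k + 2] <- cos(p / 10000^(2 * k / E))
  }
  H <- H + pe
  for (blk in params$blocks) {
    L1 <- ln(H, blk$ln1g, blk$ln1b)
    Q <- sweep(L1 %*% blk$Wq, 2, blk$bq, "+")
    K <- sweep(L1 %*% blk$Wk, 2, blk$bk, "+")
    V <- sweep(L1 %*% blk$Wv, 2, blk$bv, "+")
    O <- matrix(0, C, E)
    for (h in 1:nH) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      for (q in 1:C) {
        s <- numeric(C)
        for (k in 1:C)
          s[k] <- sum(Q[q, cols] * K[k, cols]) / sqrt(dh)
        if (spec$maskPad) s[mask == 0] <- -Inf
        w <- exp(s - max(s)); w <- w / sum(w)
        O[q, cols] <- colSums(w * V[, cols, drop = FALSE])
      }
    }
    A <- sweep(O %*% blk$Wo, 2, blk$bo, "+")
    H2 <- H + A
    L2 <- ln(H2, blk$ln2g, blk$ln2b)
    F1 <- sweep(L2 %*% blk$W1, 2, blk$b1, "+")
    G <- F1 * pnorm(F1)
    H <- H2 + sweep(G %*% blk$W2, 2, blk$b2, "+")
  }
  z <- as.vector(t(H))
  layers <- params$heads[[task]]
  for (l in seq_along(layers)) {
    z <- as.vector(z %*% layers[[l]]$W) + layers[[l]]$b
    if (l < length(layers)) z <- pmax(z, 0)
  }
  1 / (1 + exp(-z))
}

# --- small fixture builders ------------------------------------------------
reducedSpec <- function(tasks = "methylation", context = 31L, d = 32L,
                        embed = 16L, hidden = 16L) {
  transformerSpec(d, embedWidth = embed, nBlocks = 1L, nHeads = 4L,
                  headHidden = setNames(as.list(rep(hidden, length(tasks))),
                                        tasks),
                  dropout = 0, context = context)
}

randomEmbeddedBatch <- function(n, context = 5L, d = 5L, seed = 1L) {
  set.seed(seed)
  mask <- t(vapply(seq_len(n), function(i) {
    padL <- sample(0:2, 1); padR <- sample(0:2, 1)
    m <- rep(1L, context)
    if (padL > 0) m[seq_len(padL)] <- 0L
    if (padR > 0) m[(context - padR + 1):context] <- 0L
    m
  }, integer(context)))
  tokens <- matrix(rnorm(n * context * d), n * context, d)
  for (i in seq_len(n))
    tokens[(i - 1) * context + which(mask[i, ] == 0L), ] <- 0
  list(tokens = tokens, mask = mask, windowSize = context, d = d, n = n)
}

randomWindows <- function(n, L = 31L, alphabet = c("A", "C", "D", "K"),
                          seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    w <- sample(alphabet, L, replace = TRUE)
    w[(L + 1) %/% 2] <- "K"
    paste(w, collapse = "")
  }, character(1))
}

# tiny labelled study used by several files (cheap to embed)
tinyStudy <- function(nPerTask = 120L, seed = 5L, d = 16L,
                      sharedEffect = 3, taskEffect = 1) {
  sim <- simulateSiteDataset(nPerTask = nPerTask, seed = seed)
  prov <- syntheticEmbeddingProvider(sim$proteins, sim$records, d = d,
                                     sharedEffect = sharedEffect,
                                     taskEffect = taskEffect,
                                     seed = seed + 1L)
  list(sim = sim, prov = prov)
}
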