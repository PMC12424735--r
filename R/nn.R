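# Low-level neural network primitives shared by the MLP and transformer.
# All forward functions return caches sufficient for the hand-derived
# backward passes; gradients are verified against finite differences in the
# test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.gelu <- function(x) x * pnorm(x)
.geluGrad <- function(x) pnorm(x) + x * dnorm(x)

.relu <- function(x) pmax(x, 0)

# row-wise softmax, -Inf entries allowed (masked keys)
.softmaxRows <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / rowSums(e)
}

.LN_EPS <- 1e-5

# layer normalization across features (columns), per row
.layernormForward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

.layernormBackward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# inverted dropout; returns the scaled keep mask (identity when p == 0)
.dropoutMask <- function(dimr, dimc, p) {
  if (p <= 0) return(NULL)
  matrix(rbinom(dimr * dimc, 1L, 1 - p) / (1 - p), dimr, dimc)
}

.applyMask <- function(x, m) if (is.null(m)) x else x * m

#' Sinusoidal positional encoding
#'
#' Canonical transformer positional encoding: with 0-based position `pos` and
#' column pair index `i`, `PE[pos, 2i] = sin(pos / 10000^(2i/width))` and
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/width))` (returned 1-based).
#'
#' @param context number of positions (rows)
#' @param width encoding width (columns); must be even
#' @return context x width matrix with entries in \[-1, 1\].
#' @examples
#' sinusoidalPositionalEncoding(31, 8)[1, ]
#' @export
sinusoidalPositionalEncoding <- function(context, width) {
  if (width %% 2L != 0L) stop("width must be even, got ", width)
  pos <- seq_len(context) - 1L
  i <- seq_len(width %/% 2L) - 1L
  angle <- outer(pos, 1 / 10000^(2 * i / width))
  pe <- matrix(0, context, width)
  pe[, 2L * i + 1L] <- sin(angle)
  pe[, 2L * i + 2L] <- cos(angle)
  pe
}

# ---- Adam with per-parameter lazy state -----------------------------------
# Parameters and gradients are nested lists of numeric arrays addressed by a
# flat path; a parameter is stepped only when a gradient for it exists, so
# untouched classification heads stay bitwise identical after a step on
# another task's batch.

.flattenParams <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- list()
    nm <- names(x)
    for (i in seq_along(x)) {
      key <- if (is.null(nm) || nm[i] == "") as.character(i) else nm[i]
      out <- c(out, .flattenParams(x[[i]], paste0(prefix, key, "/")))
    }
    out
  } else {
    setNames(list(x), substr(prefix, 1L, nchar(prefix) - 1L))
  }
}

.adamInit <- function() new.env(parent = emptyenv())

.adamStep <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  fg <- .flattenParams(grads)
  fp <- .flattenParams(params)
  for (key in names(fg)) {
    g <- fg[[key]]
    if (is.null(g)) next
    s <- state[[key]]
    if (is.null(s)) s <- list(m = g * 0, v = g * 0, t = 0L)
    s$t <- s$t + 1L
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mhat <- s$m / (1 - beta1^s$t)
    vhat <- s$v / (1 - beta2^s$t)
    fp[[key]] <- fp[[key]] - lr * mhat / (sqrt(vhat) + eps)
    state[[key]] <- s
  }
  .unflattenParams(fp, params)
}

.unflattenParams <- function(flat, skeleton, prefix = "") {
  if (is.list(skeleton)) {
    nm <- names(skeleton)
    for (i in seq_along(skeleton)) {
      key <- if (is.null(nm) || nm[i] == "") as.character(i) else nm[i]
      skeleton[[i]] <- .unflattenParams(flat, skeleton[[i]],
                                        paste0(prefix, key, "/"))
    }
    skeleton
  } else {
    flat[[substr(prefix, 1L, nchar(prefix) - 1L)]]
  }
}

# elementwise sum of two gradient trees with identical shape (NULLs allowed)
.addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- .addGrads(a[[i]], b[[i]])
    a
  } else a + b
}

.gradNorm <- function(g) {
  sqrt(sum(vapply(.flattenParams(g), function(x) sum(x * x), numeric(1))))
}
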