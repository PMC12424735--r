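#' @include kmethyl-package.R
NULL

#' Embedding providers
#'
#' An `EmbeddingProvider` supplies one L x d matrix of per-residue embeddings
#' per protein. Model code consumes only embedded windows or pooled site
#' vectors and is agnostic to the provider's origin (precomputed files vs the
#' synthetic generator).
#'
#' @slot dim embedding dimension d
#' @name EmbeddingProvider-class
#' @aliases EmbeddingProvider
#' @exportClass EmbeddingProvider
setClass("EmbeddingProvider", representation("VIRTUAL", dim = "integer"))

#' In-memory embedding provider
#'
#' Wraps a named list of L x d matrices (one per accession).
#'
#' @slot matrices named list of numeric matrices
#' @name MatrixEmbeddingProvider-class
#' @aliases MatrixEmbeddingProvider
#' @exportClass MatrixEmbeddingProvider
setClass("MatrixEmbeddingProvider", contains = "EmbeddingProvider",
         representation(matrices = "list"),
         validity = function(object) {
           d <- unique(vapply(object@matrices, ncol, integer(1)))
           if (length(d) > 1L)
             return("all embedding matrices must share one dimension d")
           if (length(d) == 1L && d != object@dim)
             return("matrix columns disagree with provider dim")
           if (is.null(names(object@matrices)) &&
               length(object@matrices))
             return("matrices must be named by accession")
           TRUE
         })

#' Directory-container embedding provider
#'
#' On-disk container: a directory holding `index.tsv` (columns `accession`,
#' `length`, `file`) plus one whitespace-delimited L x d matrix file per
#' accession. Matrices are read lazily, one protein at a time, so a proteome
#' of embeddings never has to fit in memory at once.
#'
#' @slot path container directory
#' @slot index data.frame index
#' @name DirectoryEmbeddingProvider-class
#' @aliases DirectoryEmbeddingProvider
#' @exportClass DirectoryEmbeddingProvider
setClass("DirectoryEmbeddingProvider", contains = "EmbeddingProvider",
         representation(path = "character", index = "data.frame"))

#' Synthetic class-conditional embedding provider
#'
#' Emulates protein-language-model output at desk scale: every residue row is
#' isotropic Gaussian noise keyed deterministically by (seed, position,
#' residue identity), and rows at labelled positive sites additionally
#' receive a planted signal `sharedEffect * u + taskEffect * v_t` along
#' unit directions that are mutually orthogonal: `u` is common to all four
#' PTM tasks and `v_t` is private to task t. Because the noise is keyed by
#' residue identity and position, the provider is a deterministic function of
#' sequence content: mutating one residue changes exactly that row, which is
#' what makes mutation delta-scores well-defined under this provider.
#'
#' @slot sequences named character vector of protein sequences
#' @slot positives data.frame of positive sites (accession, position, task)
#' @slot config list with d, sharedEffect, taskEffect, noiseSd, seed
#' @slot directions d x 5 matrix: column 1 the shared direction, then one
#'   task-private direction per task in [ptmTasks()] order
#' @name SyntheticEmbeddingProvider-class
#' @aliases SyntheticEmbeddingProvider
#' @exportClass SyntheticEmbeddingProvider
setClass("SyntheticEmbeddingProvider", contains = "EmbeddingProvider",
         representation(sequences = "character", positives = "data.frame",
                        config = "list", directions = "matrix"))

setMethod("show", "MatrixEmbeddingProvider", function(object) {
  cat(sprintf("MatrixEmbeddingProvider: %d proteins, d = %d\n",
              length(object@matrices), object@dim))
})
setMethod("show", "DirectoryEmbeddingProvider", function(object) {
  cat(sprintf("DirectoryEmbeddingProvider at %s: %d proteins, d = %d\n",
              object@path, nrow(object@index), object@dim))
})
setMethod("show", "SyntheticEmbeddingProvider", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("SyntheticEmbeddingProvider: %d proteins, d = %d, ",
                     "shared %.3g, task %.3g, noise sd %.3g, seed %d\n"),
              length(object@sequences), object@dim, cfg$sharedEffect,
              cfg$taskEffect, cfg$noiseSd, cfg$seed))
})

#' Embedding dimension of a provider
#' @param provider an `EmbeddingProvider`
#' @return Integer embedding dimension d.
#' @export
embeddingDim <- function(provider) provider@dim

#' Per-residue embedding matrix for one protein
#'
#' @param provider an `EmbeddingProvider`
#' @param accession protein accession
#' @param sequence optional amino-acid string; required by providers that
#'   compute embeddings from sequence content (the synthetic provider uses it
#'   to embed mutant sequences), ignored by file-backed providers
#' @return L x d numeric matrix.
#' @export
setGeneric("residueEmbeddings",
           function(provider, accession, sequence = NULL)
             standardGeneric("residueEmbeddings"))

#' @rdname residueEmbeddings
setMethod("residueEmbeddings", "MatrixEmbeddingProvider",
          function(provider, accession, sequence = NULL) {
  m <- provider@matrices[[accession]]
  if (is.null(m)) stop("no embeddings for accession ", accession)
  m
})

#' @rdname residueEmbeddings
setMethod("residueEmbeddings", "DirectoryEmbeddingProvider",
          function(provider, accession, sequence = NULL) {
  i <- match(accession, provider@index$accession)
  if (is.na(i)) stop("no embeddings for accession ", accession)
  f <- file.path(provider@path, provider@index$file[i])
  m <- as.matrix(read.table(f))
  dimnames(m) <- NULL
  if (nrow(m) != provider@index$length[i])
    stop("embedding file for ", accession, " has ", nrow(m),
         " rows, index says ", provider@index$length[i])
  m
})

# deterministic Gaussian row keyed by (seed, position, residue identity);
# collisions across keys are harmless (rows need only be label-independent)
.residueNoiseRow <- function(d, seed, position, residueCode, noiseSd) {
  key <- (seed * 2654435761 + position * 97003 + residueCode * 7919) %%
    2147483647
  set.seed(as.integer(key))
  rnorm(d, sd = noiseSd)
}

#' @rdname residueEmbeddings
setMethod("residueEmbeddings", "SyntheticEmbeddingProvider",
          function(provider, accession, sequence = NULL) {
  if (is.null(sequence)) {
    if (!accession %in% names(provider@sequences))
      stop("no sequence known for accession ", accession,
           "; pass `sequence` explicitly")
    sequence <- provider@sequences[[accession]]
  }
  cfg <- provider@config
  res <- utf8ToInt(sequence)
  L <- length(res)
  m <- matrix(0, L, cfg$d)
  for (i in seq_len(L))
    m[i, ] <- .residueNoiseRow(cfg$d, cfg$seed, i, res[i], cfg$noiseSd)
  pos <- provider@positives
  mine <- pos[pos$accession == accession & pos$position <= L, , drop = FALSE]
  if (nrow(mine)) {
    u <- provider@directions[, 1L]
    for (j in seq_len(nrow(mine))) {
      p <- mine$position[j]
      # the mutant-sequence contract: the signal belongs to a lysine site
      if (substr(sequence, p, p) != "K") next
      t <- match(mine$task[j], ptmTasks())
      m[p, ] <- m[p, ] + cfg$sharedEffect * u +
        cfg$taskEffect * provider@directions[, 1L + t]
    }
  }
  m
})

#' Construct a synthetic embedding provider
#'
#' @param proteins data.frame with `accession`, `sequence`
#' @param labels window record data.frame; rows with `label == 1` plant the
#'   class-conditional signal at (accession, position) for their `task`
#' @param d embedding dimension (default 32)
#' @param sharedEffect,taskEffect signal magnitudes along the shared and
#'   task-private directions (defaults 3 and 1, in units of `noiseSd`
#'   when `noiseSd = 1`)
#' @param noiseSd isotropic noise standard deviation (default 1)
#' @param seed integer seed; the provider is fully deterministic given it
#' @return A [SyntheticEmbeddingProvider-class] object.
#' @export
syntheticEmbeddingProvider <- function(proteins, labels, d = 32L,
                                       sharedEffect = 3, taskEffect = 1,
                                       noiseSd = 1, seed = 1L) {
  d <- as.integer(d)
  if (d < 2L) stop("d must be >= 2")
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  if (sharedEffect < 0 || taskEffect < 0)
    stop("effect sizes must be >= 0")
  set.seed(as.integer(seed))
  q <- qr.Q(qr(matrix(rnorm(d * 5L), d, 5L)))
  pos <- labels[labels$label == 1L, c("accession", "position", "task")]
  bad <- setdiff(pos$accession, proteins$accession)
  if (length(bad))
    stop("labelled sites reference unknown accessions: ",
         paste(unique(bad), collapse = ", "))
  new("SyntheticEmbeddingProvider",
      dim = d,
      sequences = setNames(proteins$sequence, proteins$accession),
      positives = pos,
      config = list(d = d, sharedEffect = sharedEffect,
                    taskEffect = taskEffect, noiseSd = noiseSd,
                    seed = as.integer(seed)),
      directions = q)
}

#' Materialise synthetic embedding matrices
#'
#' Runs the synthetic provider over every protein and returns the matrices;
#' mostly useful for writing a container with [writeEmbeddingStore()].
#'
#' @inheritParams syntheticEmbeddingProvider
#' @param ... passed to [syntheticEmbeddingProvider()]
#' @return Named list of L x d matrices.
#' @export
generateSyntheticEmbeddings <- function(proteins, labels, ...) {
  provider <- syntheticEmbeddingProvider(proteins, labels, ...)
  setNames(lapply(proteins$accession,
                  function(a) residueEmbeddings(provider, a)),
           proteins$accession)
}

#' Write / open a directory embedding container
#'
#' @param matrices named list of L x d matrices
#' @param path container directory (created if absent)
#' @param model free-text tag recording which embedder produced the matrices
#' @return `writeEmbeddingStore` returns `path`; `openEmbeddingStore` returns
#'   a [DirectoryEmbeddingProvider-class].
#' @export
writeEmbeddingStore <- function(matrices, path, model = "synthetic") {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(make.names(names(matrices)), ".txt")
  for (i in seq_along(matrices))
    write.table(matrices[[i]], file.path(path, files[i]),
                row.names = FALSE, col.names = FALSE)
  idx <- data.frame(accession = names(matrices),
                    length = vapply(matrices, nrow, integer(1)),
                    file = files)
  write.table(idx, file.path(path, "index.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(model, file.path(path, "model.txt"))
  invisible(path)
}

#' @rdname writeEmbeddingStore
#' @export
openEmbeddingStore <- function(path) {
  idx <- read.delim(file.path(path, "index.tsv"), stringsAsFactors = FALSE)
  d <- if (nrow(idx)) {
    ncol(as.matrix(read.table(file.path(path, idx$file[1L]), nrows = 1L)))
  } else 0L
  new("DirectoryEmbeddingProvider", dim = as.integer(d), path = path,
      index = idx)
}

#' Embed one lysine-centred window
#'
#' Copies rows `position - h .. position + h` (h = (windowSize-1)/2) of the
#' per-residue matrix; rows falling outside the protein are zero-filled with
#' mask 0, mirroring the zero-vector padding used when a site sits near a
#' terminus.
#'
#' @param embeddings L x d matrix of per-residue embeddings
#' @param position 1-based centre position
#' @param windowSize odd context length (default 31)
#' @return list with `tokens` (windowSize x d), `mask` (binary length
#'   windowSize).
#' @export
embedWindow <- function(embeddings, position, windowSize = 31L) {
  L <- nrow(embeddings)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > L)
    stop("position ", position, " out of range 1..", L)
  h <- (as.integer(windowSize) - 1L) %/% 2L
  idx <- (position - h):(position + h)
  ok <- idx >= 1L & idx <= L
  tokens <- matrix(0, windowSize, ncol(embeddings))
  tokens[ok, ] <- embeddings[idx[ok], , drop = FALSE]
  list(tokens = tokens, mask = as.integer(ok))
}

#' Pooled site embedding (the MLP input)
#'
#' Returns the embedding row of the site residue itself; with
#' `pool = "mean"` instead averages the rows of the window around it.
#'
#' @param embeddings L x d matrix
#' @param position 1-based site position
#' @param pool "site" (default: the residue row) or "mean"
#' @param windowSize window used when `pool = "mean"`
#' @return Numeric d-vector.
#' @export
poolSiteEmbedding <- function(embeddings, position, pool = c("site", "mean"),
                              windowSize = 31L) {
  pool <- match.arg(pool)
  L <- nrow(embeddings)
  if (position < 1L || position > L)
    stop("position ", position, " out of range 1..", L)
  if (pool == "site") return(embeddings[position, ])
  w <- embedWindow(embeddings, position, windowSize)
  colSums(w$tokens) / sum(w$mask)
}

#' Embed a set of window records as one batch tensor
#'
#' Builds the flat token matrix consumed by the models: instance i occupies
#' rows `(i-1)*windowSize + 1 .. i*windowSize` of `tokens`.
#'
#' @param records window record data.frame (accession, position, label, task)
#' @param provider an `EmbeddingProvider`
#' @param windowSize odd context length
#' @return list with `tokens` ((n*windowSize) x d), `mask` (n x windowSize),
#'   `label`, `task`, `windowSize`, `d`, `n`.
#' @export
embedDataset <- function(records, provider, windowSize = 31L) {
  n <- nrow(records)
  d <- embeddingDim(provider)
  tokens <- matrix(0, n * windowSize, d)
  mask <- matrix(0L, n, windowSize)
  for (acc in unique(records$accession)) {
    emb <- residueEmbeddings(provider, acc)
    for (i in which(records$accession == acc)) {
      w <- embedWindow(emb, records$position[i], windowSize)
      tokens[((i - 1L) * windowSize + 1L):(i * windowSize), ] <- w$tokens
      mask[i, ] <- w$mask
    }
  }
  list(tokens = tokens, mask = mask, label = as.integer(records$label),
       task = as.character(records$task), windowSize = as.integer(windowSize),
       d = d, n = n)
}

# row subset of the flat token matrix for instances `idx`
.tensorRows <- function(idx, windowSize) {
  as.vector(vapply(idx, function(i)
    ((i - 1L) * windowSize + 1L):(i * windowSize), integer(windowSize)))
}

#' Subset an embedded dataset by instance index
#'
#' @param data result of [embedDataset()]
#' @param idx integer vector of instance indices
#' @return An embedded dataset restricted to `idx`.
#' @export
subsetDataset <- function(data, idx) {
  list(tokens = data$tokens[.tensorRows(idx, data$windowSize), ,
                            drop = FALSE],
       mask = data$mask[idx, , drop = FALSE],
       label = data$label[idx], task = data$task[idx],
       windowSize = data$windowSize, d = data$d, n = length(idx))
}
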