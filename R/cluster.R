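#' Ungapped pairwise identity between two equal-length windows
#'
#' Column-wise identity over the fixed-length window: positions where both
#' strings carry the same symbol count toward the numerator, including
#' pad-pad matches; a pad position never matches a residue.
#'
#' @param a,b window strings of equal length
#' @return Fraction of matching columns in \[0, 1\].
#' @examples
#' pairwiseIdentity("AKA", "AKV")
#' @export
pairwiseIdentity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("windows have unequal lengths: ", nchar(a), " vs ", nchar(b))
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(ca == cb)
}

# windows as an n x L character matrix for vectorised identity sweeps
.windowMatrix <- function(windows) {
  L <- unique(nchar(windows))
  if (length(L) != 1L)
    stop("all windows must share one length; saw lengths ",
         paste(L, collapse = ", "))
  matrix(unlist(strsplit(windows, "", fixed = TRUE)),
         nrow = length(windows), ncol = L, byrow = TRUE)
}

#' Greedy incremental identity clustering of windows
#'
#' CD-HIT-style greedy pass: records are visited in a deterministic order
#' (positives first, then lexicographic by accession and position); each
#' record joins the first existing cluster whose representative has identity
#' at or above the threshold, otherwise founds a new cluster. The founding
#' record is the cluster's comparison representative.
#'
#' @param records window record data.frame (columns `accession`, `position`,
#'   `window`, `label`)
#' @param threshold identity threshold in (0, 1\] (default 0.70)
#' @return list with `cluster` (integer cluster id per input row, in input
#'   order) and `founder` (row index of each cluster's representative).
#' @export
greedyCluster <- function(records, threshold = 0.70) {
  n <- nrow(records)
  if (!n) return(list(cluster = integer(0), founder = integer(0)))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  ord <- order(-records$label, records$accession, records$position)
  wm <- .windowMatrix(records$window)
  L <- ncol(wm)
  cluster <- integer(n)
  founder <- integer(0)
  repMat <- matrix(character(0), nrow = 0L, ncol = L)
  for (i in ord) {
    assigned <- 0L
    if (nrow(repMat)) {
      idn <- rowMeans(repMat == matrix(wm[i, ], nrow = nrow(repMat),
                                       ncol = L, byrow = TRUE))
      hit <- which(idn >= threshold)
      if (length(hit)) assigned <- hit[1L]
    }
    if (assigned == 0L) {
      repMat <- rbind(repMat, wm[i, , drop = FALSE])
      founder <- c(founder, i)
      assigned <- length(founder)
    }
    cluster[i] <- assigned
  }
  list(cluster = cluster, founder = founder)
}

#' Select one representative record per cluster
#'
#' If a cluster contains at least one positive, the representative is drawn
#' uniformly at random from its positives; otherwise uniformly from all its
#' members. Reproducible under `seed`.
#'
#' @param records window record data.frame
#' @param clustering result of [greedyCluster()] over the same records
#' @param seed integer RNG seed
#' @return data.frame of selected representative records (one per cluster).
#' @export
selectRepresentatives <- function(records, clustering, seed = 1L) {
  set.seed(seed)
  ids <- sort(unique(clustering$cluster))
  pick <- vapply(ids, function(cl) {
    members <- which(clustering$cluster == cl)
    pos <- members[records$label[members] == 1L]
    pool <- if (length(pos)) pos else members
    pool[sample.int(length(pool), 1L)]
  }, integer(1))
  out <- records[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label-stratified train/validation/test partition
#'
#' The test partition receives `testFraction` of each class; the validation
#' partition receives `validationFraction` of each class's remainder; the
#' rest is training. Counts per class deviate from the exact proportions by
#' at most one (rounding).
#'
#' @param records window record data.frame with a binary `label` column
#' @param testFraction,validationFraction fractions in (0, 1) summing to < 1
#' @param seed integer RNG seed
#' @return the records with an added `partition` factor column
#'   (train / validation / test).
#' @export
partitionHoldout <- function(records, testFraction = 0.2,
                             validationFraction = 0.2, seed = 1L) {
  if (testFraction <= 0 || testFraction >= 1 ||
      validationFraction <= 0 || validationFraction >= 1 ||
      testFraction + validationFraction >= 1)
    stop("fractions must lie in (0, 1) with testFraction + ",
         "validationFraction < 1")
  set.seed(seed)
  partition <- character(nrow(records))
  for (lab in unique(records$label)) {
    idx <- which(records$label == lab)
    if (length(idx) < 3L)
      stop("class ", lab, " has only ", length(idx),
           " records; cannot fill three partitions")
    idx <- idx[sample.int(length(idx))]
    nTest <- round(testFraction * length(idx))
    nVal <- round(validationFraction * (length(idx) - nTest))
    partition[idx[seq_len(nTest)]] <- "test"
    partition[idx[nTest + seq_len(nVal)]] <- "validation"
    partition[idx[-seq_len(nTest + nVal)]] <- "train"
  }
  records$partition <- factor(partition,
                              levels = c("train", "validation", "test"))
  records
}

#' Non-redundant, partitioned dataset for one task
#'
#' Convenience wrapper chaining [greedyCluster()], [selectRepresentatives()]
#' and, for the methylation task only, [partitionHoldout()]; auxiliary tasks
#' are train-only.
#'
#' @param records labelled window records for one task
#' @param threshold clustering identity threshold
#' @param testFraction,validationFraction split fractions (methylation only)
#' @param seed integer RNG seed
#' @return representative records with a `partition` column.
#' @export
reduceAndSplit <- function(records, threshold = 0.70, testFraction = 0.2,
                           validationFraction = 0.2, seed = 1L) {
  cl <- greedyCluster(records, threshold)
  reps <- selectRepresentatives(records, cl, seed = seed)
  task <- unique(reps$task)
  if (length(task) == 1L && task != "methylation") {
    reps$partition <- factor("train",
                             levels = c("train", "validation", "test"))
    return(reps)
  }
  partitionHoldout(reps, testFraction, validationFraction, seed = seed + 1L)
}
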