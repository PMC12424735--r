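#' Proteome scan result
#'
#' @slot records data.frame of (accession, position, score) for every scored
#'   lysine
#' @slot threshold decision threshold used for the summary counts
#' @slot nPredicted number of lysines scoring at or above the threshold
#' @slot nProteinsHit number of distinct proteins with at least one
#'   predicted site
#' @slot skipped accessions skipped for missing embeddings
#' @name ProteomeScanResult-class
#' @aliases ProteomeScanResult
#' @exportClass ProteomeScanResult
setClass("ProteomeScanResult",
         representation(records = "data.frame", threshold = "numeric",
                        nPredicted = "integer", nProteinsHit = "integer",
                        skipped = "character"))

setMethod("show", "ProteomeScanResult", function(object) {
  cat(sprintf(paste0("ProteomeScanResult: %d lysines scored, %d predicted ",
                     "at threshold %.3f in %d proteins (%d accession(s) ",
                     "skipped)\n"),
              nrow(object@records), object@nPredicted, object@threshold,
              object@nProteinsHit, length(object@skipped)))
})

#' @rdname ProteomeScanResult-class
#' @param object a `ProteomeScanResult`
#' @return `scanRecords` the per-lysine score table; `nPredicted` the count
#'   of sites at or above the threshold.
#' @export
scanRecords <- function(object) object@records

#' @rdname ProteomeScanResult-class
#' @export
nPredicted <- function(object) object@nPredicted

#' Score every lysine of a proteome
#'
#' Embeds a window around each lysine via the provider, scores it with the
#' model's methylation head, and summarises the count of sites at or above
#' the threshold. Accessions the provider cannot embed are skipped and
#' reported, not silently dropped.
#'
#' @param proteins data.frame from [readProteome()]
#' @param provider an `EmbeddingProvider`
#' @param model a fitted model
#' @param threshold decision threshold (e.g. the conservative
#'   `PCPr >= 0.75` operating threshold)
#' @param windowSize context length
#' @param task head to score with (default methylation)
#' @return A [ProteomeScanResult-class].
#' @export
scanProteome <- function(proteins, provider, model, threshold = 0.5,
                         windowSize = 31L, task = "methylation") {
  recs <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(proteins))) {
    acc <- proteins$accession[i]
    s <- proteins$sequence[i]
    kpos <- which(strsplit(s, "", fixed = TRUE)[[1]] == "K")
    if (!length(kpos)) next
    emb <- tryCatch(residueEmbeddings(provider, acc, s),
                    error = function(e) NULL)
    if (is.null(emb)) {
      skipped <- c(skipped, acc)
      next
    }
    data <- .embedPositions(emb, kpos, windowSize)
    recs[[length(recs) + 1L]] <- data.frame(
      accession = acc, position = kpos,
      score = predictSites(model, data, task = task))
  }
  records <- if (length(recs)) do.call(rbind, recs)
             else data.frame(accession = character(), position = integer(),
                             score = numeric())
  hit <- records$score >= threshold
  new("ProteomeScanResult", records = records, threshold = threshold,
      nPredicted = sum(hit),
      nProteinsHit = length(unique(records$accession[hit])),
      skipped = skipped)
}

# embedded dataset for a set of positions within one protein
.embedPositions <- function(emb, positions, windowSize) {
  n <- length(positions)
  tokens <- matrix(0, n * windowSize, ncol(emb))
  mask <- matrix(0L, n, windowSize)
  for (j in seq_len(n)) {
    w <- embedWindow(emb, positions[j], windowSize)
    tokens[((j - 1L) * windowSize + 1L):(j * windowSize), ] <- w$tokens
    mask[j, ] <- w$mask
  }
  list(tokens = tokens, mask = mask, windowSize = as.integer(windowSize),
       d = ncol(emb), n = n)
}

#' Extrapolate the methylome size from a proteome scan
#'
#' The number of predicted sites times the precision at the operating
#' threshold gives the expected number of true sites found; dividing by the
#' recall at the same threshold extrapolates to the total:
#' `round(nPredicted * precision / recall)`.
#'
#' @param nPredicted predicted site count at the operating threshold
#' @param precision,recall estimated precision and recall at that threshold
#'   (fractions in (0, 1\])
#' @return Estimated total number of sites (rounded).
#' @examples
#' estimateMethylomeSize(62567, 0.75, 0.30)
#' @export
estimateMethylomeSize <- function(nPredicted, precision, recall) {
  if (precision <= 0 || precision > 1 || recall < 0 || recall > 1)
    stop("precision and recall must lie in (0, 1]")
  if (recall == 0) stop("recall of 0 cannot be extrapolated")
  round(nPredicted * precision / recall)
}

#' Sample two score-matched candidate sets for wet-lab validation
#'
#' Eligible sites score at or above the threshold, are exposed
#' (RSA >= `rsaThreshold`) and are not known methylation sites. Set 1 draws
#' from sites carrying another known PTM (acetylation, ubiquitination
#' and/or sumoylation); Set 2 from sites with no known modification.
#' Sampling is stratified over score bins with matched per-bin counts, so
#' the two samples' score distributions are similar; the maximum CDF
#' distance between them is reported. If the binned pools cannot fill the
#' request the bins are widened with a warning; a globally insufficient
#' pool is an error.
#'
#' @param scores data.frame (accession, position, score), e.g.
#'   [scanRecords()]
#' @param annotations PTM annotation data.frame (all four PTMs)
#' @param rsa RSA data.frame
#' @param threshold minimum score for eligibility
#' @param rsaThreshold exposure cut-off (default 0.2, the curation burial
#'   threshold)
#' @param perSetN sites per set (default 50)
#' @param binWidth score-bin width over \[threshold, 1\] (default 0.05)
#' @param seed integer RNG seed
#' @return list with `set1`, `set2` (data.frames) and `cdfDistance`.
#' @export
sampleMatchedCandidates <- function(scores, annotations, rsa,
                                    threshold = 0.5, rsaThreshold = 0.2,
                                    perSetN = 50L, binWidth = 0.05,
                                    seed = 1L) {
  key <- function(a, p) paste(a, p)
  annKey <- key(annotations$accession, annotations$position)
  methKey <- unique(annKey[annotations$ptm == "methylation"])
  otherKey <- unique(annKey[annotations$ptm != "methylation"])
  rsaMap <- setNames(rsa$rsa, key(rsa$accession, rsa$position))
  k <- key(scores$accession, scores$position)
  exposed <- !is.na(rsaMap[k]) & rsaMap[k] >= rsaThreshold
  eligible <- scores$score >= threshold & exposed & !(k %in% methKey)
  pool1 <- which(eligible & k %in% otherKey)
  pool2 <- which(eligible & !(k %in% otherKey))
  if (length(pool1) < perSetN || length(pool2) < perSetN)
    stop("eligible pools too small: ", length(pool1), " / ", length(pool2),
         " for perSetN = ", perSetN)
  set.seed(as.integer(seed))
  bw <- binWidth
  repeat {
    breaks <- unique(c(seq(threshold, 1, by = bw), 1))
    bin1 <- cut(scores$score[pool1], breaks, include.lowest = TRUE)
    bin2 <- cut(scores$score[pool2], breaks, include.lowest = TRUE)
    cap <- pmin(table(bin1), table(bin2))
    if (sum(cap) >= perSetN) break
    bw <- bw * 2
    warning("score bins too sparse; widening bin width to ", bw)
    if (bw > 1) stop("cannot match score distributions: joint bin ",
                     "capacity ", sum(cap), " < ", perSetN)
  }
  # largest-remainder allocation proportional to joint bin capacity
  quota <- as.numeric(cap) * perSetN / sum(cap)
  take <- floor(quota)
  rem <- perSetN - sum(take)
  if (rem > 0) {
    ord <- order(quota - take, decreasing = TRUE)
    room <- which(take[ord] < as.numeric(cap)[ord])
    take[ord[room[seq_len(rem)]]] <- take[ord[room[seq_len(rem)]]] + 1L
  }
  draw <- function(pool, bins) {
    sel <- integer(0)
    for (bidx in seq_along(take)) {
      if (take[bidx] == 0L) next
      inBin <- pool[as.integer(bins) == bidx]
      sel <- c(sel, sample(inBin, take[bidx]))
    }
    sel
  }
  s1 <- draw(pool1, bin1)
  s2 <- draw(pool2, bin2)
  ks <- .maxCdfDistance(scores$score[s1], scores$score[s2])
  list(set1 = scores[s1, , drop = FALSE], set2 = scores[s2, , drop = FALSE],
       cdfDistance = ks)
}

.maxCdfDistance <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g),
                 numeric(1))))
}

#' Methylation-score impact of missense mutations
#'
#' For every lysine whose window overlaps a mutated position, scores the
#' wild-type and mutant sequences (the provider embeds the mutant sequence)
#' and reports the score drop `delta = wild - mutant`, flagging sites whose
#' prediction is lost (wild at or above the threshold, mutant below).
#' Mutations whose reference residue does not match the sequence yield an
#' error record and processing continues.
#'
#' @param mutations data.frame with columns `accession`, `position`, `ref`,
#'   `alt`
#' @param proteins data.frame from [readProteome()]
#' @param provider an `EmbeddingProvider` able to embed mutant sequences
#' @param model a fitted model
#' @param threshold prediction threshold for the `lost` flag
#' @param minDelta smallest absolute score change to report (default 0.02);
#'   `relative = TRUE` interprets it as a fraction of the wild score
#' @param windowSize context length
#' @param relative interpret `minDelta` relative to the wild-type score
#' @return list with `impacts` (data.frame: accession, mutation fields,
#'   lysine position, wild/mutant scores, delta, lost) and `errors`
#'   (data.frame of reference mismatches).
#' @export
mutationDeltaScores <- function(mutations, proteins, provider, model,
                                threshold = 0.5, minDelta = 0.02,
                                windowSize = 31L, relative = FALSE) {
  half <- (windowSize - 1L) %/% 2L
  seqs <- setNames(proteins$sequence, proteins$accession)
  impacts <- list()
  errors <- list()
  for (i in seq_len(nrow(mutations))) {
    acc <- mutations$accession[i]
    mpos <- mutations$position[i]
    s <- if (acc %in% names(seqs)) seqs[[acc]] else NA_character_
    if (is.na(s)) {
      errors[[length(errors) + 1L]] <- data.frame(
        accession = acc, position = mpos, reason = "unknown accession")
      next
    }
    refHave <- substr(s, mpos, mpos)
    if (refHave != mutations$ref[i]) {
      errors[[length(errors) + 1L]] <- data.frame(
        accession = acc, position = mpos,
        reason = sprintf("ref mismatch: sequence has %s, mutation says %s",
                         refHave, mutations$ref[i]))
      next
    }
    mut <- s
    substr(mut, mpos, mpos) <- mutations$alt[i]
    kpos <- which(strsplit(s, "", fixed = TRUE)[[1]] == "K")
    kpos <- kpos[abs(kpos - mpos) <= half & kpos != mpos]
    if (!length(kpos)) next
    wildEmb <- residueEmbeddings(provider, acc, s)
    mutEmb <- residueEmbeddings(provider, acc, mut)
    wild <- predictSites(model, .embedPositions(wildEmb, kpos, windowSize))
    mutant <- predictSites(model, .embedPositions(mutEmb, kpos, windowSize))
    delta <- wild - mutant
    minAbs <- if (relative) minDelta * wild else rep(minDelta, length(wild))
    keep <- abs(delta) >= minAbs
    if (!any(keep)) next
    impacts[[length(impacts) + 1L]] <- data.frame(
      accession = acc, mutationPosition = mpos,
      ref = mutations$ref[i], alt = mutations$alt[i],
      lysinePosition = kpos[keep], wildScore = wild[keep],
      mutantScore = mutant[keep], delta = delta[keep],
      lost = wild[keep] >= threshold & mutant[keep] < threshold)
  }
  list(impacts = if (length(impacts)) do.call(rbind, impacts)
                 else data.frame(),
       errors = if (length(errors)) do.call(rbind, errors)
                else data.frame())
}
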