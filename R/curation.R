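#' Read a proteome FASTA into a protein table
#'
#' The accession is the first whitespace-delimited token of the header line.
#' Sequences may contain the 20 standard residues plus `X`.
#'
#' @param path path to a (possibly line-wrapped) FASTA file
#' @return data.frame with columns `accession`, `sequence`.
#' @export
readProteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(acc))
    stop("duplicate accessions in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  data.frame(accession = acc, sequence = as.character(aa),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a PTM annotation table
#'
#' Tab-separated with header columns `accession`, `position` (1-based),
#' `ptm` (one of the four lysine PTM tasks).
#'
#' @param path path to the TSV file
#' @return data.frame of annotations.
#' @export
readPTMTable <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "position", "ptm")
  if (!all(need %in% names(x)))
    stop("PTM table must have columns: ", paste(need, collapse = ", "))
  x$position <- as.integer(x$position)
  bad <- setdiff(unique(x$ptm), ptmTasks())
  if (length(bad))
    stop("unknown PTM types in table: ", paste(bad, collapse = ", "))
  if (any(is.na(x$position) | x$position < 1L))
    stop("PTM positions must be integers >= 1")
  x[need]
}

#' Read a relative solvent accessibility table
#'
#' Tab-separated with header columns `accession`, `position`, `rsa`
#' (fraction in \[0, 1\]).
#'
#' @param path path to the TSV file
#' @return data.frame of per-residue RSA values.
#' @export
readRSATable <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "position", "rsa")
  if (!all(need %in% names(x)))
    stop("RSA table must have columns: ", paste(need, collapse = ", "))
  x$position <- as.integer(x$position)
  x$rsa <- as.numeric(x$rsa)
  if (any(is.na(x$rsa) | x$rsa < 0 | x$rsa > 1))
    stop("rsa values must lie in [0, 1]")
  x[need]
}

#' Extract a fixed-length window centred on a lysine
#'
#' Flanks that run past a protein terminus are filled with the pad symbol, so
#' the centre residue always sits at position `(windowSize + 1) / 2` of the
#' returned string.
#'
#' @param sequence amino-acid string
#' @param position 1-based index of the centre lysine
#' @param config a [curationConfig()]
#' @param accession accession used in error messages
#' @return A window string of length `config$windowSize`.
#' @examples
#' extractWindow("MKAV", 2)
#' @export
extractWindow <- function(sequence, position, config = curationConfig(),
                          accession = "?") {
  n <- nchar(sequence)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > n)
    stop(sprintf("position %s out of range 1..%d for %s", position, n,
                 accession))
  if (substr(sequence, position, position) != "K")
    stop(sprintf("residue at %s:%d is '%s', expected K", accession, position,
                 substr(sequence, position, position)))
  half <- (config$windowSize - 1L) %/% 2L
  lo <- position - half
  hi <- position + half
  core <- substr(sequence, max(1L, lo), min(n, hi))
  padL <- max(0L, 1L - lo)
  padR <- max(0L, hi - n)
  paste0(strrep(config$padSymbol, padL), core, strrep(config$padSymbol, padR))
}

#' Label lysine sites for one PTM task
#'
#' Positives are every lysine annotated with `targetPtm`. Negatives are drawn
#' only from proteins that carry at least one `targetPtm` site: a lysine with
#' no annotation for any of the four PTMs and a relative solvent accessibility
#' below the burial threshold (a high-confidence "buried, never observed
#' modified" site). All other lysines are of unknown status and discarded.
#' Candidate negatives lacking an RSA value are skipped and tallied.
#'
#' @param proteins data.frame from [readProteome()]
#' @param annotations data.frame from [readPTMTable()] (all four PTMs)
#' @param rsa data.frame from [readRSATable()]
#' @param targetPtm one of [ptmTasks()]
#' @param config a [curationConfig()]
#' @return data.frame of window records (`accession`, `position`, `window`,
#'   `label`, `task`) with attribute `skipped` counting candidate negatives
#'   dropped for missing RSA.
#' @export
labelSites <- function(proteins, annotations, rsa, targetPtm,
                       config = curationConfig()) {
  .assertTask(targetPtm)
  seqs <- setNames(proteins$sequence, proteins$accession)
  missing <- setdiff(annotations$accession, names(seqs))
  if (length(missing))
    stop("annotations reference unknown accessions: ",
         paste(unique(missing), collapse = ", "))
  # surface coordinate mismatches loudly rather than skipping
  res <- substr(seqs[annotations$accession], annotations$position,
                annotations$position)
  bad <- which(res != "K")
  if (length(bad))
    stop("annotation residue is not K at ",
         paste(sprintf("%s:%d(%s)", annotations$accession[bad],
                       annotations$position[bad], res[bad]),
               collapse = ", "))

  annKey <- paste(annotations$accession, annotations$position)
  targetKey <- unique(annKey[annotations$ptm == targetPtm])
  anyKey <- unique(annKey)
  rsaMap <- setNames(rsa$rsa, paste(rsa$accession, rsa$position))

  keep <- unique(annotations$accession[annotations$ptm == targetPtm])
  out <- vector("list", length(keep))
  skipped <- 0L
  for (j in seq_along(keep)) {
    acc <- keep[j]
    s <- seqs[[acc]]
    kpos <- which(strsplit(s, "", fixed = TRUE)[[1]] == "K")
    if (!length(kpos)) next
    key <- paste(acc, kpos)
    isPos <- key %in% targetKey
    unannotated <- !(key %in% anyKey)
    rsaVal <- rsaMap[key]
    noRSA <- unannotated & is.na(rsaVal)
    skipped <- skipped + sum(noRSA)
    isNeg <- unannotated & !is.na(rsaVal) &
      rsaVal < config$rsaBurialThreshold
    sel <- isPos | isNeg
    if (!any(sel)) next
    pos <- kpos[sel]
    out[[j]] <- data.frame(
      accession = acc, position = pos,
      window = vapply(pos, function(p) extractWindow(s, p, config, acc),
                      character(1)),
      label = as.integer(isPos[sel]), task = targetPtm,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(accession = character(), position = integer(),
                      window = character(), label = integer(),
                      task = character(), stringsAsFactors = FALSE)
  out <- out[order(out$accession, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Summarise PTM co-occurrence at lysine sites
#'
#' Counts, over unique (accession, position) keys, how many sites carry each
#' PTM, how many carry two or more, and for each PTM the number and fraction
#' of its sites that carry at least one other PTM.
#'
#' @param annotations data.frame with columns `accession`, `position`, `ptm`
#' @return list with `perPtm` (named counts), `multiPtmSites`,
#'   and `overlap` (data.frame: ptm, total, withOther, percent -- percent to
#'   one decimal, `NA` for a PTM with no sites).
#' @examples
#' ann <- data.frame(accession = "P1", position = c(5, 5, 9),
#'                   ptm = c("methylation", "acetylation", "methylation"))
#' countPTMCooccurrence(ann)
#' @export
countPTMCooccurrence <- function(annotations) {
  if (!nrow(annotations)) {
    return(list(perPtm = setNames(integer(4), ptmTasks()),
                multiPtmSites = 0L,
                overlap = data.frame(ptm = ptmTasks(), total = 0L,
                                     withOther = 0L, percent = NA_real_)))
  }
  key <- paste(annotations$accession, annotations$position)
  byKey <- split(annotations$ptm, key)
  nPtm <- vapply(byKey, function(p) length(unique(p)), integer(1))
  perPtm <- vapply(ptmTasks(), function(t)
    length(unique(key[annotations$ptm == t])), integer(1))
  overlap <- do.call(rbind, lapply(ptmTasks(), function(t) {
    keys <- unique(key[annotations$ptm == t])
    withOther <- sum(nPtm[keys] >= 2L)
    data.frame(ptm = t, total = length(keys), withOther = withOther,
               percent = if (length(keys)) round(100 * withOther /
                                                   length(keys), 1)
                         else NA_real_)
  }))
  list(perPtm = perPtm, multiPtmSites = sum(nPtm >= 2L), overlap = overlap)
}

#' Write / read window record tables
#'
#' Plain TSV round-trip for the labelled window tables produced by
#' [labelSites()] and consumed downstream.
#'
#' @param records window record data.frame
#' @param path file path
#' @return `readWindowRecords` returns the data.frame.
#' @export
writeWindowRecords <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWindowRecords
#' @export
readWindowRecords <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  x$position <- as.integer(x$position)
  x$label <- as.integer(x$label)
  x
}
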