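#' Simulate a desk-scale multitask site-labelling study
#'
#' Generates a random proteome and labelled lysine window records for the
#' four PTM tasks, sized and class-balanced like the high-confidence
#' training data the method was built on: per-task positive fractions
#' default to the published training-set composition (methylation 0.133,
#' ubiquitination 0.540, acetylation 0.235, sumoylation 0.266 — a roughly
#' 1:6.5 methylation imbalance). Pair the result with
#' [syntheticEmbeddingProvider()] to obtain embeddings carrying a planted,
#' partially task-shared signal at the positive sites.
#'
#' @param nPerTask instances per task (scalar or named vector over
#'   [ptmTasks()])
#' @param posFraction positive fraction per task (named vector; defaults
#'   above)
#' @param proteinLength protein length (default 120)
#' @param lysinesPerProtein expected lysines per protein (default 10)
#' @param seed integer RNG seed
#' @return list with `proteins` (data.frame) and `records` (window record
#'   data.frame over all four tasks).
#' @export
simulateSiteDataset <- function(nPerTask = 500L,
                                posFraction = c(methylation = 0.133,
                                                ubiquitination = 0.540,
                                                acetylation = 0.235,
                                                sumoylation = 0.266),
                                proteinLength = 120L,
                                lysinesPerProtein = 10L, seed = 1L) {
  set.seed(as.integer(seed))
  tasks <- ptmTasks()
  if (length(nPerTask) == 1L)
    nPerTask <- setNames(rep(as.integer(nPerTask), 4L), tasks)
  nPerTask <- nPerTask[tasks]
  posFraction <- posFraction[tasks]
  nSites <- sum(nPerTask)
  nProteins <- ceiling(nSites / (lysinesPerProtein * 0.8))
  aa <- setdiff(strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]], "")
  proteins <- data.frame(
    accession = sprintf("SYN%05d", seq_len(nProteins)),
    sequence = vapply(seq_len(nProteins), function(i) {
      s <- sample(aa, proteinLength, replace = TRUE)
      kpos <- sample(proteinLength, lysinesPerProtein)
      s[kpos] <- "K"
      paste(s, collapse = "")
    }, character(1)))
  # enumerate all lysine sites once; tasks draw disjoint subsets, so each
  # instance's class is identifiable from its own planted signal
  siteList <- do.call(rbind, lapply(seq_len(nProteins), function(i) {
    kpos <- which(strsplit(proteins$sequence[i], "")[[1]] == "K")
    data.frame(accession = proteins$accession[i], position = kpos)
  }))
  cfg <- curationConfig()
  seqs <- setNames(proteins$sequence, proteins$accession)
  unassigned <- sample(nrow(siteList))
  records <- do.call(rbind, lapply(tasks, function(t) {
    n <- nPerTask[[t]]
    idx <- unassigned[seq_len(n)]
    unassigned <<- unassigned[-seq_len(n)]
    lab <- as.integer(seq_len(n) <= round(posFraction[[t]] * n))
    lab <- sample(lab)
    data.frame(accession = siteList$accession[idx],
               position = siteList$position[idx],
               window = vapply(seq_len(n), function(j)
                 extractWindow(seqs[[siteList$accession[idx[j]]]],
                               siteList$position[idx[j]], cfg),
                 character(1)),
               label = lab, task = t)
  }))
  rownames(records) <- NULL
  list(proteins = proteins, records = records)
}
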