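# Monoisotopic residue masses (Da), standard 20 amino acids.
.RESIDUE_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)

.MASS_WATER <- 18.0105646
.MASS_PROTON <- 1.0072765
.MASS_METHYL <- 14.0156500

.residueMassSum <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(res, names(.RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(unique(bad), collapse = ", "))
  sum(.RESIDUE_MASS[res])
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to every K or R not followed by proline, with zero
#' missed cleavages; the emitted peptides tile the protein exactly.
#'
#' @param sequence protein amino-acid string
#' @param accession accession carried into the output
#' @param missedCleavages also enumerate peptides spanning up to this many
#'   internal cleavage sites (default 0; the extra peptides are appended,
#'   the zero-missed set always tiles the protein)
#' @return data.frame with `accession`, `start`, `end` (1-based inclusive),
#'   `sequence`.
#' @examples
#' digest("AKRPGK")$sequence
#' @export
digest <- function(sequence, accession = "?", missedCleavages = 0L) {
  n <- nchar(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut == n | res[pmin(cut + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut, n))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  out <- data.frame(accession = accession, start = starts, end = ends,
                    sequence = substring(sequence, starts, ends),
                    stringsAsFactors = FALSE)
  if (missedCleavages > 0L) {
    extra <- list()
    for (m in seq_len(missedCleavages)) {
      i <- seq_len(length(starts) - m)
      if (!length(i)) break
      extra[[m]] <- data.frame(accession = accession, start = starts[i],
                               end = ends[i + m],
                               sequence = substring(sequence, starts[i],
                                                    ends[i + m]),
                               stringsAsFactors = FALSE)
    }
    out <- rbind(out, do.call(rbind, extra))
  }
  out
}

#' Tryptic peptide containing a lysine site
#'
#' Returns the unique zero-missed-cleavage peptide containing the site; when
#' the site lysine is itself a cleavage site, the peptide ends at it.
#'
#' @param sequence protein amino-acid string
#' @param position 1-based position of the target K
#' @param accession accession for error messages and output
#' @return One-row data.frame with `accession`, `start`, `end`, `sequence`,
#'   `siteOffset` (1-based position of the site within the peptide).
#' @export
sitePeptide <- function(sequence, position, accession = "?") {
  if (substr(sequence, position, position) != "K")
    stop(sprintf("residue at %s:%d is '%s', expected K", accession,
                 position, substr(sequence, position, position)))
  pep <- digest(sequence, accession)
  row <- pep[pep$start <= position & pep$end >= position, , drop = FALSE]
  row$siteOffset <- position - row$start + 1L
  rownames(row) <- NULL
  row
}

#' Precursor mass-to-charge ratio
#'
#' Neutral monoisotopic mass = residue masses + water + methylState x CH2;
#' `mz = (M + charge x proton) / charge`.
#'
#' @param sequence peptide string
#' @param methylState number of methyl groups on the site lysine (0-3)
#' @param charge precursor charge (>= 1)
#' @return m/z in Thomson.
#' @examples
#' precursorMz("GK", 0, 1)
#' @export
precursorMz <- function(sequence, methylState = 0L, charge = 2L) {
  if (!methylState %in% 0:3)
    stop("methylState must be 0 (null) through 3 (tri)")
  if (charge < 1L) stop("charge must be >= 1")
  M <- .residueMassSum(sequence) + .MASS_WATER +
    methylState * .MASS_METHYL
  (M + charge * .MASS_PROTON) / charge
}

#' Fragment ion mass-to-charge ratio
#'
#' b ions are the N-terminal `index` residues plus proton(s); y ions the
#' C-terminal `index` residues plus water and proton(s). The methyl mass is
#' carried by the site residue and included iff that residue lies inside
#' the fragment.
#'
#' @param sequence peptide string
#' @param siteOffset 1-based position of the modified K within the peptide
#' @param methylState methyl count on the site (0-3)
#' @param series "b" or "y"
#' @param index fragment length (1 <= index < peptide length)
#' @param charge fragment charge (default 1)
#' @return m/z in Thomson.
#' @export
fragmentMz <- function(sequence, siteOffset = NA_integer_, methylState = 0L,
                       series = c("y", "b"), index, charge = 1L) {
  series <- match.arg(series)
  n <- nchar(sequence)
  if (index < 1L || index >= n)
    stop("fragment index must lie in 1..", n - 1L)
  if (methylState > 0L && (is.na(siteOffset) || siteOffset < 1L ||
                           siteOffset > n))
    stop("siteOffset required (1..", n, ") when methylState > 0")
  if (series == "y") {
    frag <- substr(sequence, n - index + 1L, n)
    hasSite <- !is.na(siteOffset) && siteOffset > n - index
    M <- .residueMassSum(frag) + .MASS_WATER
  } else {
    frag <- substr(sequence, 1L, index)
    hasSite <- !is.na(siteOffset) && siteOffset <= index
    M <- .residueMassSum(frag)
  }
  if (hasSite) M <- M + methylState * .MASS_METHYL
  (M + charge * .MASS_PROTON) / charge
}

#' Build a PRM isolation list
#'
#' One precursor entry per (site, methylation state, charge): for the
#' reference protocol of 100 sites, charges \{2, 3, 4\} and the four methyl
#' states (null through tri) this is 1,200 rows. Duplicate input sites are
#' deduplicated with a warning; unresolvable sites are excluded and
#' reported.
#'
#' @param sites data.frame with `accession`, `position` (target lysines)
#' @param proteins data.frame from [readProteome()]
#' @param charges integer set of precursor charges (default 2:4)
#' @param methylStates integer set of methyl states (default 0:3)
#' @return data.frame sorted by accession, position, state, charge with
#'   columns `accession`, `sitePosition`, `peptide`, `siteOffset`,
#'   `methylState`, `charge`, `mz`; attribute `errors` lists unresolvable
#'   sites.
#' @export
buildIsolationList <- function(sites, proteins, charges = 2:4,
                               methylStates = 0:3) {
  dup <- duplicated(sites[c("accession", "position")])
  if (any(dup)) {
    warning(sum(dup), " duplicate site(s) removed from isolation list input")
    sites <- sites[!dup, , drop = FALSE]
  }
  seqs <- setNames(proteins$sequence, proteins$accession)
  rows <- list()
  errors <- list()
  for (i in seq_len(nrow(sites))) {
    acc <- sites$accession[i]
    pos <- sites$position[i]
    s <- if (acc %in% names(seqs)) seqs[[acc]] else NA_character_
    pep <- tryCatch(
      if (is.na(s)) stop("unknown accession ", acc)
      else sitePeptide(s, pos, acc),
      error = function(e) conditionMessage(e))
    if (is.character(pep)) {
      errors[[length(errors) + 1L]] <- data.frame(
        accession = acc, position = pos, reason = pep)
      next
    }
    grid <- expand.grid(methylState = sort(methylStates),
                        charge = sort(charges))
    rows[[length(rows) + 1L]] <- data.frame(
      accession = acc, sitePosition = pos, peptide = pep$sequence,
      siteOffset = pep$siteOffset, methylState = grid$methylState,
      charge = grid$charge,
      mz = mapply(function(st, z) precursorMz(pep$sequence, st, z),
                  grid$methylState, grid$charge))
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(accession = character(), sitePosition = integer(),
                         peptide = character(), siteOffset = integer(),
                         methylState = integer(), charge = integer(),
                         mz = numeric())
  out <- out[order(out$accession, out$sitePosition, out$methylState,
                   out$charge), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errors") <- if (length(errors)) do.call(rbind, errors)
                         else data.frame()
  out
}

#' Write an isolation list CSV
#'
#' @param isolationList data.frame from [buildIsolationList()]
#' @param path output CSV path (m/z to 6 decimal places)
#' @return The path, invisibly.
#' @export
writeIsolationList <- function(isolationList, path) {
  isolationList$mz <- sprintf("%.6f", isolationList$mz)
  utils::write.csv(isolationList, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tally targeted-MS validation outcomes
#'
#' @param outcomes character vector of per-site outcomes in
#'   \{"methylated", "unmethylated_only", "inconclusive"\}
#' @return list with counts (`nAssayed`, `nMethylated`,
#'   `nUnmethylatedOnly`, `nInconclusive`) and two precision figures in
#'   percent to one decimal: `precisionWorst` counts inconclusive sites as
#'   negatives; `precisionConclusive` discards them (NA when no site was
#'   conclusive).
#' @examples
#' tallyValidation(rep(c("methylated", "unmethylated_only", "inconclusive"),
#'                     c(68, 6, 26)))
#' @export
tallyValidation <- function(outcomes) {
  if (!length(outcomes)) stop("outcomes must be non-empty")
  ok <- c("methylated", "unmethylated_only", "inconclusive")
  bad <- setdiff(unique(outcomes), ok)
  if (length(bad))
    stop("unknown outcome(s): ", paste(bad, collapse = ", "))
  nMe <- sum(outcomes == "methylated")
  nUn <- sum(outcomes == "unmethylated_only")
  nIn <- sum(outcomes == "inconclusive")
  list(nAssayed = length(outcomes), nMethylated = nMe,
       nUnmethylatedOnly = nUn, nInconclusive = nIn,
       precisionWorst = round(100 * nMe / length(outcomes), 1),
       precisionConclusive = if (nMe + nUn > 0)
         round(100 * nMe / (nMe + nUn), 1) else NA_real_)
}
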