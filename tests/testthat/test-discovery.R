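test_that("proteome scan scores every lysine and summarises thresholds", {
  st <- tinyStudy(nPerTask = 30L, seed = 121, d = 8L)
  prots <- st$sim$proteins[1:3, ]
  model <- initTransformer(reducedSpec(d = 8L, embed = 8L), seed = 122)
  res <- scanProteome(prots, st$prov, model, threshold = 0)
  nK <- sum(vapply(prots$sequence, function(s)
    sum(strsplit(s, "")[[1]] == "K"), numeric(1)))
  expect_equal(nrow(scanRecords(res)), nK)
  expect_equal(nPredicted(res), nK)
  expect_equal(nPredicted(scanProteome(prots, st$prov, model,
                                       threshold = 1 + 1e-9)), 0L)
})

test_that("predicted-site counts are monotone in the threshold", {
  st <- tinyStudy(nPerTask = 30L, seed = 123, d = 8L)
  prots <- st$sim$proteins[1:4, ]
  model <- initTransformer(reducedSpec(d = 8L, embed = 8L), seed = 124)
  fp <- kmethyl:::.flattenParams(model@params)
  set.seed(125)
  for (k in names(fp)) fp[[k]] <- fp[[k]] + rnorm(length(fp[[k]]), sd = 0.3)
  model@params <- kmethyl:::.unflattenParams(fp, model@params)
  counts <- vapply(seq(0, 1, by = 0.1), function(th)
    nPredicted(scanProteome(prots, st$prov, model, threshold = th)),
    integer(1))
  expect_true(all(diff(counts) <= 0L))
  # determinism
  r1 <- scanRecords(scanProteome(prots, st$prov, model, 0.5))
  r2 <- scanRecords(scanProteome(prots, st$prov, model, 0.5))
  expect_identical(r1, r2)
})

test_that("methylome extrapolation follows n x precision / recall", {
  expect_equal(estimateMethylomeSize(1234, 0.4, 0.4), 1234)
  expect_equal(estimateMethylomeSize(1000, 0.5, 0.25), 2000)
  # the deployment-scale worked example: 62,567 sites at precision 0.75
  # and recall 0.30
  expect_equal(estimateMethylomeSize(62567, 0.75, 0.30), 156418)
  expect_error(estimateMethylomeSize(10, 0.5, 0), "recall")
  expect_error(estimateMethylomeSize(10, 1.5, 0.5), "precision")
})

test_that("matched candidate sampling yields disjoint, eligible, similar sets", {
  set.seed(126)
  n <- 3000
  scores <- data.frame(accession = sprintf("P%04d", seq_len(n)),
                       position = 16L,
                       score = runif(n, 0.5, 1))
  # a third carry another PTM; a sprinkle are known methylation sites
  otherIdx <- sample(n, 1000)
  methIdx <- sample(setdiff(seq_len(n), otherIdx), 100)
  annotations <- rbind(
    data.frame(accession = scores$accession[otherIdx], position = 16L,
               ptm = sample(c("acetylation", "ubiquitination",
                              "sumoylation"), 1000, TRUE)),
    data.frame(accession = scores$accession[methIdx], position = 16L,
               ptm = "methylation"))
  rsa <- data.frame(accession = scores$accession, position = 16L,
                    rsa = runif(n))
  cs <- sampleMatchedCandidates(scores, annotations, rsa, threshold = 0.5,
                                perSetN = 50L, seed = 127)
  expect_equal(nrow(cs$set1), 50L)
  expect_equal(nrow(cs$set2), 50L)
  k1 <- paste(cs$set1$accession, cs$set1$position)
  k2 <- paste(cs$set2$accession, cs$set2$position)
  expect_length(intersect(k1, k2), 0L)
  methKey <- paste(scores$accession[methIdx], 16L)
  expect_length(intersect(c(k1, k2), methKey), 0L)
  # set 1 carries another PTM, set 2 does not
  otherKey <- paste(scores$accession[otherIdx], 16L)
  expect_true(all(k1 %in% otherKey))
  expect_false(any(k2 %in% otherKey))
  # exposure and score eligibility
  rsaMap <- setNames(rsa$rsa, paste(rsa$accession, rsa$position))
  expect_true(all(rsaMap[c(k1, k2)] >= 0.2))
  expect_true(all(c(cs$set1$score, cs$set2$score) >= 0.5))

  # matching quality across seeds
  ds <- vapply(1:100, function(s)
    sampleMatchedCandidates(scores, annotations, rsa, threshold = 0.5,
                            perSetN = 50L, seed = s)$cdfDistance,
    numeric(1))
  expect_lt(mean(ds), 0.15)

  expect_error(
    sampleMatchedCandidates(scores[1:60, ], annotations, rsa,
                            threshold = 0.5, perSetN = 50L, seed = 1),
    "too small")
})

test_that("mutation delta-scores are local, signed and oracle-consistent", {
  st <- tinyStudy(nPerTask = 25L, seed = 131, d = 8L)
  prots <- st$sim$proteins[1:5, ]
  model <- initTransformer(reducedSpec(d = 8L, embed = 8L), seed = 132)
  fp <- kmethyl:::.flattenParams(model@params)
  set.seed(133)
  for (k in names(fp)) fp[[k]] <- fp[[k]] + rnorm(length(fp[[k]]), sd = 0.3)
  model@params <- kmethyl:::.unflattenParams(fp, model@params)

  seqs <- setNames(prots$sequence, prots$accession)
  firstNonK <- function(s) which(strsplit(s, "")[[1]] != "K")[10]
  muts <- do.call(rbind, lapply(prots$accession, function(a) {
    p <- firstNonK(seqs[[a]])
    data.frame(accession = a, position = p,
               ref = substr(seqs[[a]], p, p), alt = "W")
  }))
  out <- mutationDeltaScores(muts, prots, st$prov, model, threshold = 0.5,
                             minDelta = 0.001)
  expect_equal(nrow(out$errors), 0L)
  if (nrow(out$impacts)) {
    # locality: every reported lysine lies within 15 residues
    expect_true(all(abs(out$impacts$lysinePosition -
                          out$impacts$mutationPosition) <= 15))
    expect_equal(out$impacts$delta,
                 out$impacts$wildScore - out$impacts$mutantScore)
    # oracle: exhaustive recomputation flags exactly the same impacts
    for (i in seq_len(min(5, nrow(out$impacts)))) {
      r <- out$impacts[i, ]
      s <- seqs[[r$accession]]
      m <- s; substr(m, r$mutationPosition, r$mutationPosition) <- r$alt
      wEmb <- residueEmbeddings(st$prov, r$accession, s)
      mEmb <- residueEmbeddings(st$prov, r$accession, m)
      w <- predictSites(model, kmethyl:::.embedPositions(
        wEmb, r$lysinePosition, 31L))
      mu <- predictSites(model, kmethyl:::.embedPositions(
        mEmb, r$lysinePosition, 31L))
      expect_equal(r$wildScore, w, tolerance = 1e-12)
      expect_equal(r$mutantScore, mu, tolerance = 1e-12)
    }
  }

  # synonymous substitution: delta exactly zero
  syn <- muts[1, ]; syn$alt <- syn$ref
  outSyn <- mutationDeltaScores(syn, prots, st$prov, model, minDelta = 0)
  if (nrow(outSyn$impacts)) expect_true(all(outSyn$impacts$delta == 0))

  # a mutation far from every lysine emits nothing
  far <- data.frame(accession = "PFAR", position = 100L, ref = "A",
                    alt = "V")
  farProt <- data.frame(accession = "PFAR",
                        sequence = paste0("K", strrep("A", 119)))
  provFar <- syntheticEmbeddingProvider(
    farProt, data.frame(accession = character(), position = integer(),
                        label = integer(), task = character()),
    d = 8L, seed = 134)
  outFar <- mutationDeltaScores(far, farProt, provFar, model, minDelta = 0)
  expect_equal(nrow(outFar$impacts), 0L)

  # reference mismatches become error records, not failures
  bad <- muts[1, ]; bad$ref <- "X"
  outBad <- mutationDeltaScores(bad, prots, st$prov, model)
  expect_match(outBad$errors$reason, "ref mismatch")

  # antisymmetry under swapping wild and mutant sequences
  a <- muts$accession[1]; p <- muts$position[1]
  s <- seqs[[a]]; m <- s; substr(m, p, p) <- "W"
  kp <- which(strsplit(s, "")[[1]] == "K")
  kp <- kp[abs(kp - p) <= 15][1]
  if (!is.na(kp)) {
    f <- function(sq) predictSites(model, kmethyl:::.embedPositions(
      residueEmbeddings(st$prov, a, sq), kp, 31L))
    expect_equal(f(s) - f(m), -(f(m) - f(s)), tolerance = 1e-15)
  }
})
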