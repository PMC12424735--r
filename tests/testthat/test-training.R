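test_that("binary cross-entropy anchors: ln 2, near-zero, hand value", {
  expect_equal(bceLoss(rep(0.5, 4), c(1, 0, 1, 0)), log(2))
  expect_equal(bceLoss(rep(0.5, 3), c(1, 1, 1)), log(2))
  expect_lt(bceLoss(c(1, 0), c(1, 0)), 1e-10)
  expect_equal(bceLoss(c(0.9, 0.2), c(1, 0)),
               -0.5 * (log(0.9) + log(0.8)))
  expect_gte(bceLoss(runif(10), rbinom(10, 1, 0.5)), 0)
  expect_error(bceLoss(numeric(0), numeric(0)), "empty")
})

test_that("multitask loss gates by batch task and scales methylation by gamma", {
  # scores chosen so that the plain cross-entropy is exactly 0.5
  s <- exp(-0.5)
  expect_equal(bceLoss(c(s, s), c(1, 1)), 0.5)
  expect_equal(multitaskBatchLoss(c(s, s), c(1, 1), "methylation",
                                  gamma = 20), 10)
  for (t in c("ubiquitination", "acetylation", "sumoylation"))
    expect_equal(multitaskBatchLoss(c(s, s), c(1, 1), t, gamma = 20), 0.5)
  set.seed(91)
  sc <- runif(8); lb <- rbinom(8, 1, 0.5)
  for (t in ptmTasks())
    expect_equal(multitaskBatchLoss(sc, lb, t, gamma = 1), bceLoss(sc, lb))
  expect_error(multitaskBatchLoss(sc, lb, "methylation", gamma = 0.5),
               "gamma")
})

test_that("task batch sampler emits homogeneous, exhaustive epochs", {
  idx <- setNames(lapply(1:4, function(i) (i - 1) * 100 + 1:100), ptmTasks())
  batches <- taskBatchSampler(idx, 10L, seed = 92)
  expect_length(batches, 40L)
  expect_equal(as.vector(table(vapply(batches, `[[`, character(1),
                                      "task"))),
               rep(10L, 4))
  all_idx <- unlist(lapply(batches, `[[`, "idx"))
  expect_setequal(all_idx, 1:400)
  expect_length(all_idx, 400L)

  # homogeneity + exhaustiveness over many random configurations
  set.seed(93)
  for (rep in 1:200) {
    sizes <- sample(0:25, 4)
    ti <- setNames(lapply(sizes, function(s) sample(1000, s)), ptmTasks())
    bs <- sample(1:12, 1)
    suppressMessages(b <- taskBatchSampler(ti, bs, seed = rep))
    for (bb in b) {
      expect_lte(length(bb$idx), bs)
      expect_true(all(bb$idx %in% ti[[bb$task]]))
    }
    got <- unlist(lapply(b, `[[`, "idx"))
    expect_setequal(got, unlist(ti))
    expect_length(got, sum(sizes))
  }
})

test_that("one optimisation step leaves inactive heads bitwise unchanged", {
  spec <- reducedSpec(tasks = ptmTasks(), context = 5L, d = 4L, embed = 8L)
  model <- initTransformer(spec, seed = 94)
  # randomise the zero-initialised output layers so trunk gradients flow
  fp <- kmethyl:::.flattenParams(model@params)
  set.seed(940)
  for (k in names(fp)) fp[[k]] <- fp[[k]] + rnorm(length(fp[[k]]), sd = 0.3)
  model@params <- kmethyl:::.unflattenParams(fp, model@params)
  batch <- randomEmbeddedBatch(6, context = 5L, d = 4L, seed = 95)
  labels <- c(1, 0, 1, 0, 1, 0)
  state <- kmethyl:::.adamInit()
  before <- model@params
  g <- kmethyl:::.transformerGrad(model, batch, "ubiquitination", labels)
  after <- kmethyl:::.adamStep(state, model@params, g$grads, 1e-3)
  for (t in c("methylation", "acetylation", "sumoylation"))
    expect_identical(after$heads[[t]], before$heads[[t]])
  expect_false(identical(after$heads$ubiquitination,
                         before$heads$ubiquitination))
  # shared trunk parameters move
  expect_false(identical(after$input, before$input))
  expect_false(identical(after$blocks, before$blocks))
})

test_that("methylation-batch gradient norms scale linearly in gamma", {
  spec <- reducedSpec(tasks = ptmTasks(), context = 5L, d = 4L, embed = 8L)
  model <- initTransformer(spec, seed = 96)
  batch <- randomEmbeddedBatch(5, context = 5L, d = 4L, seed = 97)
  labels <- c(1, 0, 0, 1, 1)
  norms <- vapply(c(1, 13.5, 20), function(g)
    kmethyl:::.gradNorm(kmethyl:::.transformerGrad(
      model, batch, "methylation", labels, lossScale = g)$grads),
    numeric(1))
  expect_equal(norms[2] / norms[1], 13.5, tolerance = 1e-8)
  expect_equal(norms[3] / norms[1], 20, tolerance = 1e-8)
})

test_that("early stopping restores the best state and respects patience", {
  st <- tinyStudy(nPerTask = c(methylation = 120L, ubiquitination = 30L,
                               acetylation = 30L, sumoylation = 30L),
                  seed = 98, d = 8L)
  me <- st$sim$records[st$sim$records$task == "methylation", ]
  set.seed(99); vi <- sample(nrow(me), 40)
  trainData <- embedDataset(me[-vi, ], st$prov, 15L)
  valData <- embedDataset(me[vi, ], st$prov, 15L)
  model <- initTransformer(reducedSpec(context = 15L, d = 8L, embed = 8L),
                           seed = 100)
  fit <- fitEarlyStopping(model, trainData, valData, lr = 3e-3,
                          batchSize = 32L, patience = 0L, maxEpochs = 30L,
                          seed = 101)
  h <- fit$history
  expect_equal(fit$bestValidationLoss, min(h$validationLoss))
  expect_equal(fit$bestEpoch, which.min(h$validationLoss))
  # patience 0: exactly one epoch beyond the first non-improvement
  firstBad <- which(diff(cummin(h$validationLoss)) == 0)[1] + 1L
  expect_equal(nrow(h), firstBad)
  # restored parameters reproduce the recorded best validation loss
  sc <- predictSites(fit$model, valData)
  expect_equal(bceLoss(sc, valData$label), fit$bestValidationLoss,
               tolerance = 1e-12)
})

test_that("training on a strong planted signal beats the 0.5 baseline", {
  st <- tinyStudy(nPerTask = c(methylation = 300L, ubiquitination = 20L,
                               acetylation = 20L, sumoylation = 20L),
                  seed = 102, d = 8L, sharedEffect = 4)
  me <- st$sim$records[st$sim$records$task == "methylation", ]
  set.seed(103); vi <- sample(nrow(me), 90)
  trainData <- embedDataset(me[-vi, ], st$prov, 15L)
  valData <- embedDataset(me[vi, ], st$prov, 15L)
  model <- initTransformer(reducedSpec(context = 15L, d = 8L, embed = 8L),
                           seed = 104)
  fit <- fitEarlyStopping(model, trainData, valData, lr = 5e-3,
                          batchSize = 32L, patience = 6L, maxEpochs = 30L,
                          seed = 105)
  expect_gt(fit$bestValidationAUPRC, 0.7)
  expect_lt(fit$bestValidationLoss, log(2))
})

test_that("random search is seeded and finds a top-decile configuration", {
  space <- list(lr = logUniformSampler(1e-5, 1e-1), width = c(8L, 16L, 32L))
  # unimodal objective of the learning rate, maximised at lr = 1e-3
  obj <- function(cfg) -abs(log10(cfg$lr) + 3)
  r1 <- randomSearch(space, obj, nTrials = 50L, seed = 106)
  r2 <- randomSearch(space, obj, nTrials = 50L, seed = 106)
  expect_identical(r1$trials$score, r2$trials$score)
  expect_equal(nrow(r1$trials), 50L)
  # top decile of the objective over the lr range [-4, 0] in |log10+3|
  expect_gt(r1$bestScore, -0.2)

  one <- randomSearch(space, obj, nTrials = 1L, seed = 107)
  expect_equal(one$bestScore, one$trials$score[1])

  failing <- function(cfg) stop("boom")
  expect_error(randomSearch(space, failing, nTrials = 3L, seed = 108),
               "all 3 trials failed")
})
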