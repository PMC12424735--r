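test_that("sinusoidal positional encoding matches its closed form", {
  pe <- sinusoidalPositionalEncoding(31, 8)
  expect_equal(pe[1, c(1, 3, 5, 7)], rep(0, 4))  # sin(0)
  expect_equal(pe[1, c(2, 4, 6, 8)], rep(1, 4))  # cos(0)
  expect_equal(pe[2, 1], sin(1))
  expect_equal(sinusoidalPositionalEncoding(5, 64)[2, 1], sin(1))
  expect_true(all(abs(sinusoidalPositionalEncoding(100, 32)) <= 1))
  expect_error(sinusoidalPositionalEncoding(31, 7), "even")
})

test_that("vectorised forward pass matches a hand-coded naive oracle", {
  spec <- transformerSpec(tokenDim = 5L, embedWidth = 8L, nBlocks = 2L,
                          nHeads = 2L,
                          headHidden = list(methylation = c(7L, 4L),
                                            acetylation = 5L),
                          context = 5L)
  model <- initTransformer(spec, seed = 61)
  # randomise all parameters so the zero-initialised output layer does not
  # trivialise the comparison
  fp <- kmethyl:::.flattenParams(model@params)
  set.seed(62)
  for (k in names(fp)) fp[[k]] <- fp[[k]] + rnorm(length(fp[[k]]), sd = 0.4)
  model@params <- kmethyl:::.unflattenParams(fp, model@params)

  batch <- randomEmbeddedBatch(3, context = 5L, d = 5L, seed = 63)
  for (task in c("methylation", "acetylation")) {
    fast <- predictSites(model, batch, task = task)
    for (i in 1:3) {
      rows <- ((i - 1) * 5 + 1):(i * 5)
      slow <- naiveForward(spec, model@params,
                           batch$tokens[rows, , drop = FALSE],
                           batch$mask[i, ], task)
      expect_equal(fast[i], slow, tolerance = 1e-6)
    }
  }
})

test_that("evaluation-mode scoring is deterministic and 0.5 when untrained", {
  spec <- reducedSpec(tasks = ptmTasks(), context = 7L, d = 6L, embed = 8L)
  model <- initTransformer(spec, seed = 64)
  batch <- randomEmbeddedBatch(4, context = 7L, d = 6L, seed = 65)
  expect_identical(predictSites(model, batch), predictSites(model, batch))
  # zero-initialised final layer: sigmoid(0) exactly
  expect_equal(predictSites(model, batch), rep(0.5, 4))
  zero <- batch; zero$tokens[] <- 0
  expect_equal(predictSites(model, zero), rep(0.5, 4))
})

test_that("scores are invariant to the content of masked pad rows", {
  spec <- reducedSpec(context = 9L, d = 4L, embed = 8L)
  model <- initTransformer(spec, seed = 66)
  fp <- kmethyl:::.flattenParams(model@params)
  set.seed(67)
  for (k in names(fp)) fp[[k]] <- fp[[k]] + rnorm(length(fp[[k]]), sd = 0.4)
  model@params <- kmethyl:::.unflattenParams(fp, model@params)
  batch <- randomEmbeddedBatch(5, context = 9L, d = 4L, seed = 68)
  tampered <- batch
  padRows <- which(as.vector(t(batch$mask)) == 0L)
  tampered$tokens[padRows, ] <- rnorm(length(padRows) * 4, sd = 10)
  expect_equal(predictSites(model, batch), predictSites(model, tampered),
               tolerance = 1e-12)
})

test_that("the shared trunk output is identical whichever head is probed", {
  spec <- reducedSpec(tasks = ptmTasks(), context = 5L, d = 4L, embed = 8L)
  model <- initTransformer(spec, seed = 69)
  batch <- randomEmbeddedBatch(3, context = 5L, d = 4L, seed = 70)
  t1 <- kmethyl:::.transformerForward(model, batch, "methylation")
  t2 <- kmethyl:::.transformerForward(model, batch, "sumoylation")
  expect_equal(t1$trunk$Z, t2$trunk$Z, tolerance = 1e-12)
  # heads with identical parameters give identical scores
  model@params$heads <- lapply(model@params$heads, function(h)
    model@params$heads$methylation)
  sc <- predictAllTasks(model, batch)
  expect_true(all(abs(sc - sc[, 1]) < 1e-12))
})

test_that("analytic gradients agree with finite differences", {
  spec <- transformerSpec(tokenDim = 4L, embedWidth = 8L, nBlocks = 1L,
                          nHeads = 2L,
                          headHidden = list(methylation = 6L,
                                            ubiquitination = 5L),
                          context = 5L)
  model <- initTransformer(spec, seed = 71)
  fp <- kmethyl:::.flattenParams(model@params)
  set.seed(72)
  for (k in names(fp)) fp[[k]] <- fp[[k]] + rnorm(length(fp[[k]]), sd = 0.3)
  model@params <- kmethyl:::.unflattenParams(fp, model@params)
  batch <- randomEmbeddedBatch(3, context = 5L, d = 4L, seed = 73)
  labels <- c(1, 0, 1)
  g <- kmethyl:::.transformerGrad(model, batch, "methylation", labels,
                                  train = FALSE)
  flatG <- kmethyl:::.flattenParams(g$grads)
  lossAt <- function(params) {
    m <- model; m@params <- params
    kmethyl:::.transformerGrad(m, batch, "methylation", labels,
                               train = FALSE)$loss
  }
  eps <- 1e-6
  set.seed(74)
  for (key in names(fp)) {
    p <- kmethyl:::.flattenParams(model@params)[[key]]
    for (j in sample(length(p), min(2, length(p)))) {
      fp2 <- kmethyl:::.flattenParams(model@params)
      fp2[[key]][j] <- fp2[[key]][j] + eps
      up <- lossAt(kmethyl:::.unflattenParams(fp2, model@params))
      fp2[[key]][j] <- fp2[[key]][j] - 2 * eps
      dn <- lossAt(kmethyl:::.unflattenParams(fp2, model@params))
      num <- (up - dn) / (2 * eps)
      ana <- if (is.null(flatG[[key]])) 0 else flatG[[key]][j]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("only the requested head receives gradients", {
  spec <- reducedSpec(tasks = ptmTasks(), context = 5L, d = 4L, embed = 8L)
  model <- initTransformer(spec, seed = 75)
  batch <- randomEmbeddedBatch(4, context = 5L, d = 4L, seed = 76)
  g <- kmethyl:::.transformerGrad(model, batch, "acetylation", c(1, 0, 0, 1))
  expect_null(g$grads$heads$methylation)
  expect_null(g$grads$heads$ubiquitination)
  expect_null(g$grads$heads$sumoylation)
  expect_false(is.null(g$grads$heads$acetylation))
  expect_false(is.null(g$grads$input))
})

test_that("parameter counts match the closed-form formula", {
  specs <- list(
    reducedSpec(),
    reducedSpec(tasks = ptmTasks(), context = 7L, d = 12L, embed = 24L),
    transformerSpec(10L, embedWidth = 8L, nBlocks = 3L, nHeads = 4L,
                    headHidden = list(methylation = c(9L, 3L)),
                    context = 5L),
    defaultTransformerSpec())
  for (spec in specs)
    expect_equal(nParameters(initTransformer(spec, seed = 1)),
                 nParametersFormula(spec))
})

test_that("shape and task mismatches raise named validation errors", {
  spec <- reducedSpec(context = 5L, d = 4L, embed = 8L)
  model <- initTransformer(spec, seed = 77)
  batch <- randomEmbeddedBatch(2, context = 5L, d = 4L, seed = 78)
  expect_error(predictSites(model, batch, task = "phosphorylation"),
               "unknown PTM task")
  expect_error(predictSites(model, batch, task = "acetylation"), "no head")
  wrong <- batch; wrong$tokens <- cbind(wrong$tokens, 0)
  expect_error(predictSites(model, wrong), "tokenDim")
})

test_that("MLP forward matches a direct dense-stack computation", {
  spec <- mlpSpec(6L, hiddenWidths = c(5L, 3L))
  model <- initMLP(spec, seed = 79)
  fp <- kmethyl:::.flattenParams(model@params)
  set.seed(80)
  for (k in names(fp)) fp[[k]] <- fp[[k]] + rnorm(length(fp[[k]]), sd = 0.5)
  model@params <- kmethyl:::.unflattenParams(fp, model@params)
  x <- matrix(rnorm(12), 2, 6)
  L <- model@params$layers
  manual <- apply(x, 1, function(v) {
    h1 <- pmax(as.vector(v %*% L[[1]]$W) + L[[1]]$b, 0)
    h2 <- pmax(as.vector(h1 %*% L[[2]]$W) + L[[2]]$b, 0)
    1 / (1 + exp(-(sum(h2 * L[[3]]$W) + L[[3]]$b)))
  })
  expect_equal(predictSites(model, x), manual, tolerance = 1e-12)
  expect_equal(nParameters(model),
               6 * 5 + 5 + 5 * 3 + 3 + 3 * 1 + 1)
})
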