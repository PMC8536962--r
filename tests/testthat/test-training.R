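test_that("hybrid loss matches its closed forms", {
  y1 <- matrix(1, 8, 8)
  expect_equal(hybridLoss(y1, y1), -1.0, tolerance = 1e-6)
  expect_equal(hybridLoss(matrix(0.5, 8, 8), y1),
               -(0.5 * log(0.5) + 2 / 3), tolerance = 1e-6)
  y0 <- matrix(0, 8, 8)
  expect_equal(hybridLoss(y0, y0), -1.0, tolerance = 1e-12)
})

test_that("hybrid loss is minimised at the truth and permutation-invariant", {
  set.seed(3)
  for (r in 1:20) {
    y <- randomMask(6, 6, 0.4)
    atTruth <- hybridLoss(y, y)
    p <- pmin(pmax(y + matrix(rnorm(36, sd = 0.2), 6, 6), 0), 1)
    expect_lte(atTruth, hybridLoss(p, y) + 1e-12)
    perm <- sample(36)
    expect_equal(hybridLoss(p, y),
                 hybridLoss(matrix(p[perm], 6, 6), matrix(y[perm], 6, 6)),
                 tolerance = 1e-12)
  }
})

test_that("hybrid loss enforces its preconditions", {
  expect_error(hybridLoss(matrix(0.5, 2, 2), matrix(0.5, 2, 2)), "binary")
  expect_error(hybridLoss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("the multi-output objective is linear in the head weights", {
  set.seed(8)
  y <- array(rbinom(32, 1, 0.5), c(4, 8))
  heads <- lapply(1:5, function(i) matrix(runif(32), 4, 8))
  l1 <- totalObjective(heads, y, c(1, 0, 0, 0, 0))
  expect_equal(l1, hybridLoss(heads[[1]], y), tolerance = 1e-12)
  same <- lapply(1:5, function(i) heads[[2]])
  expect_equal(totalObjective(same, y, rep(1, 5)),
               5 * hybridLoss(heads[[2]], y), tolerance = 1e-12)
  perHead <- vapply(heads, hybridLoss, numeric(1), truth = y)
  expect_equal(totalObjective(heads, y, rep(0.2, 5)), mean(perHead),
               tolerance = 1e-12)
  a <- runif(5); b <- runif(5)
  expect_equal(totalObjective(heads, y, a + 2 * b),
               totalObjective(heads, y, a) + 2 * totalObjective(heads, y, b),
               tolerance = 1e-12)
  expect_error(totalObjective(heads, y, c(1, 1)), "length 5")
})

test_that("fold plans group subjects, balance strata and are deterministic", {
  m6 <- data.frame(subject_id = paste0("s", 1:6), stratum = "all")
  p <- stratifiedGroupFolds(m6, k = 3, seed = 4)
  expect_identical(tabulate(p@assignments, 3), rep(2L, 3))
  expect_identical(sort(names(p@assignments)), sort(m6$subject_id))
  p2 <- stratifiedGroupFolds(m6, k = 3, seed = 4)
  expect_identical(p@assignments, p2@assignments)
  # 8 subjects in 4 strata of 2, k = 2: exactly one subject per stratum per fold
  m8 <- data.frame(subject_id = paste0("s", 1:8),
                   stratum = rep(c("a", "b", "c", "d"), each = 2))
  p8 <- stratifiedGroupFolds(m8, k = 2, seed = 1)
  tab <- table(p8@strata[names(p8@assignments)], p8@assignments)
  expect_true(all(tab == 1L))
  expect_error(stratifiedGroupFolds(m6, k = 7), "exceeds")
})

test_that("fold plans partition subjects across many sizes and seeds", {
  for (n in c(6L, 9L, 13L, 24L)) {
    m <- data.frame(subject_id = paste0("s", seq_len(n)),
                    stratum = paste0("Q", ceiling(4 * seq_len(n) / n)))
    for (seed in 1:3) {
      p <- stratifiedGroupFolds(m, k = 3, seed = seed)
      expect_identical(sort(names(p@assignments)), sort(m$subject_id))
      expect_true(all(tabulate(p@assignments, 3) >= floor(n / 3)))
      tab <- table(p@strata[names(p@assignments)], p@assignments)
      expect_true(all(apply(tab, 1, function(r) diff(range(r))) <= 1))
    }
  }
})

test_that("training reduces the objective and is seed-reproducible", {
  d <- tinyData(12)
  spec <- tinySpec()
  cfg <- trainingConfig(learningRate = 3e-3, batchSize = 4, maxEpochs = 4,
                        earlyStopPatience = 3, augmentation = FALSE, seed = 2)
  fit <- trainModel(buildModel(spec, 1), d$images[1:8], d$masks[1:8],
                    d$images[9:12], d$masks[9:12], cfg)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_identical(nrow(fit$history), 4L)
  expect_true(all(is.finite(fit$history$val_loss)))
  fit2 <- trainModel(buildModel(spec, 1), d$images[1:8], d$masks[1:8],
                     d$images[9:12], d$masks[9:12], cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model@params, fit2$model@params)
})

test_that("early stopping halts after patience and keeps the best weights", {
  d <- tinyData(8)
  spec <- tinySpec()
  # high learning rate makes validation loss fluctuate, triggering the rule
  cfg <- trainingConfig(learningRate = 5e-2, batchSize = 4, maxEpochs = 40,
                        earlyStopPatience = 1, augmentation = FALSE, seed = 3)
  fit <- trainModel(buildModel(spec, 2), d$images[1:6], d$masks[1:6],
                    d$images[7:8], d$masks[7:8], cfg)
  ran <- nrow(fit$history)
  expect_lt(ran, 40L)
  expect_identical(fit$bestEpoch, which.min(fit$history$val_loss))
  expect_identical(ran, fit$bestEpoch + 1L)  # stopped one epoch after the best
})

test_that("training with augmentation runs and logs validation metrics", {
  d <- tinyData(6)
  cfg <- trainingConfig(learningRate = 3e-3, batchSize = 4, maxEpochs = 2,
                        earlyStopPatience = 1, augmentation = TRUE, seed = 5)
  fit <- trainModel(buildModel(tinySpec(), 4), d$images[1:4], d$masks[1:4],
                    d$images[5:6], d$masks[5:6], cfg)
  expect_true(all(c("val_dice", "val_jaccard") %in% names(fit$history)))
  expect_true(all(fit$history$val_dice >= 0 & fit$history$val_dice <= 1))
})
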