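test_that("default SIMOU spec exposes the printed structural facts", {
  spec <- simouSpec(c(64, 64), widthMultiplier = 1)
  expect_identical(nSideTaps(spec), 15L)
  expect_identical(nHeads(spec), 5L)
  expect_identical(nLevels(spec), 8L)
  expect_identical(specChannels(spec),
                   c(32L, 32L, 64L, 64L, 128L, 128L, 256L, 512L))
  expect_identical(specChannels(spec)[1], 32L)
  expect_identical(specChannels(spec)[8], 512L)
})

test_that("width multiplier scales every channel count", {
  spec <- simouSpec(c(64, 64), widthMultiplier = 1 / 8)
  expect_identical(specChannels(spec), c(4L, 4L, 8L, 8L, 16L, 16L, 32L, 64L))
  expect_identical(spec@postConcatChannels, 8L)
  expect_identical(simouSpec(c(64, 64), 1)@postConcatChannels, 64L)
})

test_that("head compositions follow the side-output listing", {
  spec <- simouSpec(c(64, 64))
  expect_identical(spec@headDefs$du, 1:15)
  expect_identical(spec@headDefs$dux, 1:14)
  expect_identical(spec@headDefs$d, 1:8)
  expect_identical(spec@headDefs$u, 9:15)
  taps <- spec@sideTaps
  expect_identical(taps$path, c(rep("down", 8), rep("up", 7)))
  expect_identical(taps$level[9:15], 7:1)
})

test_that("the SIMO-wrapped plain U-Net has 9 taps, 5 heads, same head pattern", {
  spec <- simoUnetSpec(c(64, 64), widthMultiplier = 1 / 16)
  expect_identical(nSideTaps(spec), 9L)
  expect_identical(nHeads(spec), 5L)
  expect_identical(nLevels(spec), 5L)
  expect_identical(spec@headDefs$d, 1:5)
  expect_identical(spec@headDefs$u, 6:9)
  expect_length(spec@headDefs$d[spec@sideTaps$path[spec@headDefs$d] == "down"], 5L)
})

test_that("indivisible input shapes are rejected with the required factor", {
  expect_error(simouSpec(c(65, 65)), "divisible")
  expect_error(simoUnetSpec(c(24, 24)), "divisible")
})

test_that("prediction heads keep the input resolution and batch shape", {
  spec <- simouSpec(c(64, 64), widthMultiplier = 1 / 8)
  model <- buildModel(spec, seed = 1)
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  p <- predictModel(model, x)
  expect_named(p, c("dux", "du", "u", "d", "f"))
  for (h in p) expect_identical(dim(h), c(64L, 64L, 2L))
  # a different (valid) input size runs through the same weights' spec family
  spec32 <- simouSpec(c(32, 32), widthMultiplier = 1 / 8)
  p32 <- predictModel(buildModel(spec32, 1), array(rnorm(32 * 32), c(32, 32, 1)))
  for (h in p32) expect_identical(dim(h), c(32L, 32L, 1L))
})

test_that("all-zero weights with zero biases force probability 0.5 everywhere", {
  spec <- tinySpec()
  model <- buildModel(spec, seed = 1)
  model@params <- simounet:::zeroLike(model@params)
  p <- predictModel(model, matrix(0.7, 32, 32))
  for (h in p) expect_true(all(abs(h - 0.5) < 1e-12))
})

test_that("instantiation and prediction are deterministic given the seed", {
  spec <- tinySpec()
  x <- matrix(seq(0, 1, length.out = 32 * 32), 32, 32)
  p1 <- predictModel(buildModel(spec, seed = 7), x)
  p2 <- predictModel(buildModel(spec, seed = 7), x)
  expect_identical(p1, p2)
  p3 <- predictModel(buildModel(spec, seed = 8), x)
  expect_false(identical(p1$f, p3$f))
})

test_that("kernel initialisation follows the sqrt(2/eta) Gaussian", {
  set.seed(42)
  k <- drawConvKernel(3, 3, 32, 400)  # eta = 288, 115200 draws
  expect_equal(sd(k), sqrt(2 / 288), tolerance = 0.05)
  set.seed(43)
  k2 <- drawConvKernel(1, 2, 1, 50000)  # eta = 2 -> sd exactly 1
  expect_equal(sd(k2), 1.0, tolerance = 0.05)
  i1 <- initWeights(tinySpec(), seed = 5)
  i2 <- initWeights(tinySpec(), seed = 5)
  expect_identical(i1, i2)
})

test_that("concatenated head inputs carry one channel slot per side output", {
  spec <- simouSpec(c(64, 64), 1 / 8, sideHeadChannels = 2L)
  p <- initWeights(spec, 1)$params
  shc <- 2L
  expect_identical(dim(p$head$du$conv1$W)[3], 15L * shc)
  expect_identical(dim(p$head$dux$conv1$W)[3], 14L * shc)
  expect_identical(dim(p$head$d$conv1$W)[3], 8L * shc)
  expect_identical(dim(p$head$u$conv1$W)[3], 7L * shc)
})

test_that("each head's loss reaches every level it is wired to", {
  spec <- tinySpec()
  model <- buildModel(spec, seed = 2)
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 1, 2))
  fw <- simounet:::modelForward(model@params, model@state, spec, x,
                                training = TRUE)
  L <- spec@nLevels
  zero <- lapply(fw$logits, function(z) array(0, dim(z)))
  gradNorm <- function(g) if (is.null(g)) 0 else sum(abs(unlist(g)))
  for (h in c("dux", "du", "u", "d", "f")) {
    dL <- zero
    dL[[h]] <- array(1, dim(fw$logits[[h]])) / length(fw$logits[[h]])
    g <- simounet:::modelBackward(model@params, spec, fw, dL)
    for (l in seq_len(L))
      expect_gt(gradNorm(g$down[[l]]), 0)
    # head d sees no expansive block; head dux stops one block short of the
    # final tap; all other heads are wired to every expansive block
    upBlocks <- switch(h, d = integer(0), dux = seq_len(L - 2L),
                       seq_len(L - 1L))
    for (j in upBlocks)
      expect_gt(gradNorm(g$up[[j]]$conv1), 0)
  }
})

test_that("analytic gradients match central finite differences", {
  spec <- tinySpec()
  model <- buildModel(spec, seed = 3)
  set.seed(21)
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  y <- array(rbinom(32 * 32, 1, 0.3), c(32, 32, 1, 1))
  lossOf <- function(params) {
    fw <- simounet:::modelForward(params, model@state, spec, x, training = TRUE)
    sum(vapply(fw$probs, hybridLoss, numeric(1), truth = y))
  }
  fw <- simounet:::modelForward(model@params, model@state, spec, x,
                                training = TRUE)
  dL <- lapply(fw$probs, function(p)
    simounet:::hybridLossGrad(p, y) * p * (1 - p))
  g <- simounet:::modelBackward(model@params, spec, fw, dL)
  eps <- 1e-5
  paths <- list(list("down", 1, "conv1", "W"), list("down", 4, "bn", "gamma"),
                list("up", 2, "conv1", "W"), list("up", 1, "up", "W"),
                list("side", 3, "stages", 1, "W"),
                list("head", "du", "conv1", "W"), list("final", "out", "W"))
  for (pth in paths) {
    leaf <- model@params
    for (k in pth) leaf <- leaf[[k]]
    ga <- g
    for (k in pth) ga <- ga[[k]]
    i <- 1L
    bump <- function(delta) {
      p2 <- model@params
      expr <- p2
      # walk down, modify, rebuild
      modify <- function(tree, path, d) {
        if (length(path) == 1) {
          tree[[path[[1]]]][i] <- tree[[path[[1]]]][i] + d
          return(tree)
        }
        tree[[path[[1]]]] <- modify(tree[[path[[1]]]], path[-1], d)
        tree
      }
      modify(p2, pth, delta)
    }
    num <- (lossOf(bump(eps)) - lossOf(bump(-eps))) / (2 * eps)
    rel <- abs(num - ga[i]) / max(1e-8, abs(num) + abs(ga[i]))
    expect_lt(rel, 1e-4)
  }
})
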