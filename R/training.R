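#' @include forward_backward.R
NULL

.clipEps <- 1e-7

# Coerce (H, W), (H, W, B) or (H, W, 1, B) to a list of flattened images.
.asImageList <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) return(list(as.numeric(x)))
  if (length(d) == 3L) return(lapply(seq_len(d[3]), function(b) as.numeric(x[, , b])))
  lapply(seq_len(d[4]), function(b) as.numeric(x[, , , b]))
}

#' Hybrid binary cross-entropy + soft-Dice loss
#'
#' For each image in the batch, with flattened truth `y` and predicted
#' probabilities `p` (clipped to `[1e-7, 1 - 1e-7]`), computes
#' `bce = mean(0.5 * y * log(p))` over pixels and the smoothed soft-Dice
#' `dice = (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)`, and returns
#' `-(1/B) * sum(bce + dice)`. Lower is better; the minimum (-1) is attained
#' when `p = y`. The foreground-only cross-entropy term and the Dice term
#' both counteract the strong background/foreground pixel imbalance of
#' foetal-brain slices.
#'
#' @param pred probability array (`H x W`, `(H, W, B)` or `(H, W, 1, B)`).
#' @param truth binary array of the same shape.
#' @param smoothEps Dice smoothing constant.
#' @return scalar loss.
#' @examples
#' y <- matrix(1, 4, 4)
#' hybridLoss(y, y)                 # -1
#' hybridLoss(matrix(0.5, 4, 4), y) # -(0.5 * log(0.5) + 2/3)
#' @export
hybridLoss <- function(pred, truth, smoothEps = 1e-6) {
  if (!identical(dim(pred), dim(truth)) &&
      !identical(length(pred), length(truth)))
    stop("pred and truth must have the same shape")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  ps <- .asImageList(pred)
  ys <- .asImageList(truth)
  tot <- 0
  for (b in seq_along(ps)) {
    p <- ps[[b]]
    y <- ys[[b]]
    # clipping guards only the logarithm; the Dice term uses raw predictions
    bce <- mean(0.5 * y * log(pmin(pmax(p, .clipEps), 1 - .clipEps)))
    dice <- (2 * sum(y * p) + smoothEps) / (sum(y) + sum(p) + smoothEps)
    tot <- tot + bce + dice
  }
  -tot / length(ps)
}

# Gradient of hybridLoss with respect to pred, same shape as pred.
hybridLossGrad <- function(pred, truth, smoothEps = 1e-6) {
  d <- dim(pred)
  ps <- .asImageList(pred)
  ys <- .asImageList(truth)
  B <- length(ps)
  out <- numeric(0)
  for (b in seq_len(B)) {
    p <- ps[[b]]
    y <- ys[[b]]
    pc <- pmin(pmax(p, .clipEps), 1 - .clipEps)
    n <- length(p)
    den <- sum(y) + sum(p) + smoothEps
    num <- 2 * sum(y * p) + smoothEps
    g <- -(0.5 * y / pc / n + (2 * y * den - num) / den^2) / B
    out <- c(out, g)
  }
  array(out, d)
}

#' Weighted multi-output training objective
#'
#' Deep supervision over the five prediction heads:
#' `sum_t alpha_t * hybridLoss(head_t, truth)`.
#'
#' @param predictions list of five probability arrays in the head order
#'   (dux, du, u, d, f), or a [PredictionSet-class].
#' @param truth binary array matching each head.
#' @param alphaWeights five non-negative per-head weights.
#' @param smoothEps Dice smoothing constant.
#' @return scalar objective.
#' @export
totalObjective <- function(predictions, truth, alphaWeights = rep(1, 5),
                           smoothEps = 1e-6) {
  if (is(predictions, "PredictionSet")) predictions <- predictionMaps(predictions)
  if (length(predictions) != 5L) stop("predictions must contain 5 heads")
  if (length(alphaWeights) != 5L)
    stop("alphaWeights must have length 5 (one per head)")
  losses <- vapply(predictions, hybridLoss, numeric(1),
                   truth = truth, smoothEps = smoothEps)
  sum(alphaWeights * losses)
}

#' Subject-grouped stratified k-fold assignment
#'
#' Assigns whole subjects (never individual slices) to folds: within each
#' stratum subjects are shuffled (seeded) and dealt round-robin to the folds
#' ordered by current size, so fold sizes within every stratum differ by at
#' most one and global sizes stay balanced. Deterministic given `seed`.
#'
#' @param manifest data.frame with columns `subject_id` and `stratum` (any
#'   label column can be selected via `stratumColumn`).
#' @param k number of folds.
#' @param seed RNG seed.
#' @param stratumColumn name of the stratification column.
#' @return A [FoldPlan-class].
#' @examples
#' m <- data.frame(subject_id = letters[1:6], stratum = "all")
#' stratifiedGroupFolds(m, k = 3, seed = 1)
#' @export
stratifiedGroupFolds <- function(manifest, k, seed = 1L,
                                 stratumColumn = "stratum") {
  ids <- as.character(manifest$subject_id)
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  if (k > length(ids)) stop("k = ", k, " exceeds the ", length(ids),
                            " available subjects")
  strata <- as.character(manifest[[stratumColumn]])
  names(strata) <- ids
  assignments <- integer(length(ids))
  names(assignments) <- ids
  withSeed(seed, {
    sizes <- integer(k)
    for (st in sort(unique(strata))) {
      members <- ids[strata == st]
      members <- sample(members)
      for (m in members) {
        f <- order(sizes, seq_len(k))[1L]  # smallest fold, ties to lowest index
        assignments[[m]] <- f
        sizes[f] <- sizes[f] + 1L
      }
    }
  })
  new("FoldPlan", k = as.integer(k), assignments = assignments, strata = strata)
}

# Pooled overlap of a probability batch against truth at threshold 0.5,
# used for the per-epoch validation Dice/Jaccard trace.
.pooledOverlap <- function(prob, truth) {
  pred <- prob >= 0.5
  tp <- sum(pred & truth == 1)
  fp <- sum(pred & truth == 0)
  fn <- sum(!pred & truth == 1)
  c(dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    jaccard = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_)
}

.headOrder <- c("dux", "du", "u", "d", "f")

#' Train a model with RMSprop, deep supervision and early stopping
#'
#' Optimises the weighted multi-output objective with RMSprop
#' (`learningRate`, `decayFactorRho`) in shuffled mini-batches,
#' `ceiling(n / batchSize)` steps per epoch. When `augmentation` is on, each
#' epoch additionally trains on one freshly sampled augmented copy of every
#' training sample. Validation loss (and pooled validation Dice/Jaccard of
#' the mean-fused maps) is recorded every epoch; training stops when the
#' validation loss has not improved for `earlyStopPatience` epochs (or at
#' `maxEpochs`) and the best-validation weights are restored.
#'
#' @param model a [SimouModel-class].
#' @param trainImages,trainMasks training slices: `(H, W, N)` arrays or lists
#'   of matrices.
#' @param valImages,valMasks validation slices, same conventions.
#' @param config a [TrainingConfig-class].
#' @param verbose print one line per epoch.
#' @return list with `model` (best-validation weights) and `history`
#'   (data.frame: epoch, train_loss, val_loss, val_dice, val_jaccard).
#' @export
trainModel <- function(model, trainImages, trainMasks, valImages, valMasks,
                       config = trainingConfig(), verbose = FALSE) {
  validObject(config)
  spec <- model@spec
  x <- asImageBatch(trainImages)
  y <- asImageBatch(trainMasks)
  xv <- asImageBatch(valImages)
  yv <- asImageBatch(valMasks)
  n <- dim(x)[4]
  if (n < 1L || dim(xv)[4] < 1L) stop("train and validation sets must be nonempty")
  alpha <- config@alphaWeights
  names(alpha) <- .headOrder
  params <- model@params
  state <- model@state
  vOpt <- zeroLike(params)
  best <- list(loss = Inf, params = params, state = state, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_dice = numeric(),
                        val_jaccard = numeric())
  withSeed(config@seed, {
    for (epoch in seq_len(config@maxEpochs)) {
      if (config@augmentation) {
        xa <- array(0, dim(x)); ya <- array(0, dim(y))
        for (i in seq_len(n)) {
          aug <- augmentRandom(x[, , 1, i], y[, , 1, i])
          xa[, , 1, i] <- aug$image
          ya[, , 1, i] <- aug$mask
        }
        xe <- array(c(x, xa), c(dim(x)[1:3], 2L * n))
        ye <- array(c(y, ya), c(dim(y)[1:3], 2L * n))
      } else {
        xe <- x; ye <- y
      }
      ne <- dim(xe)[4]
      ord <- sample.int(ne)
      epochLoss <- 0
      nb <- 0L
      for (start in seq(1L, ne, by = config@batchSize)) {
        idx <- ord[seq.int(start, min(start + config@batchSize - 1L, ne))]
        xb <- xe[, , , idx, drop = FALSE]
        yb <- ye[, , , idx, drop = FALSE]
        fw <- modelForward(params, state, spec, xb, training = TRUE)
        state <- fw$state
        dLogits <- list()
        batchLoss <- 0
        for (h in .headOrder) {
          lh <- hybridLoss(fw$probs[[h]], yb, config@smoothEps)
          batchLoss <- batchLoss + alpha[[h]] * lh
          gP <- hybridLossGrad(fw$probs[[h]], yb, config@smoothEps)
          dLogits[[h]] <- alpha[[h]] * gP * fw$probs[[h]] * (1 - fw$probs[[h]])
        }
        if (!is.finite(batchLoss))
          stop("non-finite training loss at epoch ", epoch,
               ", batch starting at sample ", start)
        grads <- modelBackward(params, spec, fw, dLogits)
        st <- rmspropStep(params, grads, vOpt,
                          config@learningRate, config@decayFactorRho)
        params <- st$p
        vOpt <- st$v
        epochLoss <- epochLoss + batchLoss
        nb <- nb + 1L
      }
      epochLoss <- epochLoss / nb
      # validation pass (inference mode)
      valLoss <- 0
      nvb <- 0L
      ov <- c(0, 0, 0)  # tp, fp, fn pooled over the mean-fused maps
      nv <- dim(xv)[4]
      for (start in seq(1L, nv, by = config@batchSize)) {
        idx <- seq.int(start, min(start + config@batchSize - 1L, nv))
        xb <- xv[, , , idx, drop = FALSE]
        yb <- yv[, , , idx, drop = FALSE]
        fw <- modelForward(params, state, spec, xb, training = FALSE)
        for (h in .headOrder)
          valLoss <- valLoss + alpha[[h]] *
            hybridLoss(fw$probs[[h]], yb, config@smoothEps)
        avg <- Reduce(`+`, fw$probs[.headOrder]) / 5
        pred <- avg >= 0.5
        ov <- ov + c(sum(pred & yb == 1), sum(pred & yb == 0),
                     sum(!pred & yb == 1))
        nvb <- nvb + 1L
      }
      valLoss <- valLoss / nvb
      valDice <- if (2 * ov[1] + ov[2] + ov[3] > 0)
        2 * ov[1] / (2 * ov[1] + ov[2] + ov[3]) else NA_real_
      valJac <- if (sum(ov) > 0) ov[1] / sum(ov) else NA_real_
      history[epoch, ] <- list(epoch, epochLoss, valLoss, valDice, valJac)
      if (verbose)
        message(sprintf("epoch %d train %.4f val %.4f dice %.3f",
                        epoch, epochLoss, valLoss, valDice))
      if (valLoss < best$loss) {
        best <- list(loss = valLoss, params = params, state = state,
                     epoch = epoch)
      } else if (epoch - best$epoch >= config@earlyStopPatience) {
        break
      }
    }
  })
  model@params <- best$params
  model@state <- best$state
  list(model = model, history = history, bestEpoch = best$epoch)
}
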