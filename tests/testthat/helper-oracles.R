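# Independent brute-force oracles used by the metric and fusion tests.
# These deliberately avoid the package's own code paths.

# Per-pixel loop over a pair of binary matrices.
oracleConfusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; t <- truth[i, j]
      if (p == 1 && t == 1) tp <- tp + 1L
      else if (p == 1 && t == 0) fp <- fp + 1L
      else if (p == 0 && t == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# All-pairs directed nearest-point distances, maximised symmetrically.
oracleHausdorff <- function(a, b, spacing = c(1, 1)) {
  A <- which(a == 1, arr.ind = TRUE)
  B <- which(b == 1, arr.ind = TRUE)
  if (nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  directed <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      d <- sqrt(((P[i, 1] - Q[, 1]) * spacing[2])^2 +
                ((P[i, 2] - Q[, 2]) * spacing[1])^2)
      worst <- max(worst, min(d))
    }
    worst
  }
  max(directed(A, B), directed(B, A))
}

# Voxel counting, one voxel at a time.
oracleVolume <- function(stack, spacing, dz) {
  n <- 0
  for (v in as.numeric(stack)) if (v == 1) n <- n + 1
  n * spacing[1] * spacing[2] * dz / 1000
}

# Sort-based per-pixel order statistics of five maps.
oracleFuse <- function(maps, op) {
  d <- dim(maps[[1]])
  out <- array(0, d)
  for (i in seq_len(length(out))) {
    v <- sort(vapply(maps, function(m) m[i], numeric(1)))
    out[i] <- switch(op, mean = mean(v), median = v[3], max = v[5])
  }
  out
}

randomMask <- function(h, w, p = 0.3) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# Small network/training fixtures shared across tests.
tinySpec <- function() simoUnetSpec(c(32, 32), widthMultiplier = 1 / 32,
                                    dropoutRate = 0)

tinyData <- function(n = 10, seed = 99) {
  cfg <- phantomConfig(nSubjects = 1L, slicesPerSubject = c(n, n),
                       imageSize = c(32L, 32L), brainAxisRangePX = c(3, 5),
                       skullGapPX = 1, masterSeed = seed)
  st <- generateSubject(cfg, 0)
  imgs <- lapply(seq_len(n), function(s) slices(st)[s, , ])
  msks <- lapply(seq_len(n), function(s) maskStack(st)[s, , ])
  list(images = imgs, masks = msks)
}
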