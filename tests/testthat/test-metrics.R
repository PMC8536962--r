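test_that("confusion counts match hand cases and the per-pixel oracle", {
  ones <- matrix(1, 4, 4)
  expect_identical(confusionCounts(ones, ones),
                   c(TP = 16L, FP = 0L, FN = 0L, TN = 0L))
  t <- randomMask(4, 4, 0.5)
  cc <- confusionCounts(1 - t, t)
  expect_identical(unname(cc[c("TP", "TN")]), c(0L, 0L))
  set.seed(12)
  for (r in 1:10) {
    a <- randomMask(8, 8); b <- randomMask(8, 8)
    expect_identical(confusionCounts(a, b), oracleConfusion(a, b))
    expect_identical(sum(confusionCounts(a, b)), 64L)
  }
  expect_error(confusionCounts(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
  expect_error(confusionCounts(matrix(2, 2, 2), matrix(1, 2, 2)), "binary")
})

test_that("overlap metrics follow their formulas and algebraic identity", {
  expect_equal(unname(overlapMetrics(10, 0, 0)), c(1, 1, 1))
  om <- overlapMetrics(1, 1, 1)
  expect_equal(unname(om), c(1 / 3, 0.5, 0.5))
  set.seed(13)
  for (r in 1:20) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    if (tp + fp + fn == 0) next
    om <- overlapMetrics(tp, fp, fn)
    expect_equal(om[["dice"]], 2 * om[["jaccard"]] / (1 + om[["jaccard"]]),
                 tolerance = 1e-12)
    expect_lte(om[["jaccard"]], om[["dice"]])
  }
  expect_message(om0 <- overlapMetrics(0, 0, 0), "undefined")
  expect_true(all(is.na(om0)))
})

test_that("Hausdorff distance handles exact cases, spacing and symmetry", {
  m <- randomMask(8, 8, 0.4)
  m[1, 1] <- 1
  expect_equal(hausdorffMM(m, m), 0.0)
  a <- matrix(0, 10, 10); b <- matrix(0, 10, 10)
  a[2, 2] <- 1; b[5, 6] <- 1   # +3 rows, +4 cols
  expect_equal(hausdorffMM(a, b, c(1, 1)), 5.0)
  expect_equal(hausdorffMM(a, b, c(2, 2)), 10.0)  # scaling by c scales HD
  set.seed(14)
  for (r in 1:10) {
    x <- randomMask(9, 9, 0.2); y <- randomMask(9, 9, 0.2)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(hausdorffMM(x, y), oracleHausdorff(x, y), tolerance = 1e-12)
    expect_equal(hausdorffMM(x, y), hausdorffMM(y, x), tolerance = 1e-12)
    sp <- runif(2, 0.5, 3)
    expect_equal(hausdorffMM(x, y, sp), oracleHausdorff(x, y, sp),
                 tolerance = 1e-12)
  }
  expect_message(hd <- hausdorffMM(matrix(0, 3, 3), m[1:3, 1:3]), "empty")
  expect_true(is.na(hd))
})

test_that("brain volume is voxel count times voxel volume, and additive", {
  stack <- array(1, c(5, 10, 10))
  expect_equal(brainVolumeCm3(stack, c(1, 1), 2), 1.0)
  expect_equal(brainVolumeCm3(array(0, c(3, 4, 4)), c(1, 1), 2), 0.0)
  set.seed(15)
  st <- array(rbinom(4 * 6 * 6, 1, 0.4), c(4, 6, 6))
  sp <- c(0.7, 1.3); dz <- 2.5
  expect_equal(brainVolumeCm3(st, sp, dz), oracleVolume(st, sp, dz),
               tolerance = 1e-12)
  parts <- brainVolumeCm3(st[1:2, , , drop = FALSE], sp, dz) +
    brainVolumeCm3(st[3:4, , , drop = FALSE], sp, dz)
  expect_equal(brainVolumeCm3(st, sp, dz), parts, tolerance = 1e-12)
  expect_error(brainVolumeCm3(st * 2, sp, dz), "binary")
})

test_that("perfect predictions give perfect case metrics", {
  st <- generateSubject(phantomConfig(masterSeed = 21), 0)
  m <- maskStack(st)
  cm <- evaluateCase(m, m, pixelSpacing(st), sliceThickness(st))
  expect_equal(cm$jaccard, 1); expect_equal(cm$dice, 1)
  expect_equal(cm$sensitivity, 1); expect_equal(cm$hausdorff_mm, 0)
  expect_equal(cm$mavd_cm3, 0)
})

test_that("an emptied slice shifts the volumes by exactly its area", {
  st <- generateSubject(phantomConfig(masterSeed = 22), 1)
  truth <- maskStack(st)
  pred <- truth
  mid <- ceiling(dim(truth)[1] / 2)
  pred[mid, , ] <- 0
  cm <- evaluateCase(pred, truth, pixelSpacing(st), sliceThickness(st))
  expected <- sum(truth[mid, , ]) * prod(pixelSpacing(st)) *
    sliceThickness(st) / 1000
  expect_lt(cm$volume_auto_cm3, cm$volume_manual_cm3)
  expect_equal(cm$mavd_cm3, expected, tolerance = 1e-12)
})

test_that("case-level overlap equals the mean of per-slice metrics", {
  st <- generateSubject(phantomConfig(masterSeed = 23), 2)
  truth <- maskStack(st)
  set.seed(30)
  prob <- pmin(array(runif(length(truth)), dim(truth)) * 0.6 +
                 truth * 0.6, 1)  # informative maps with scattered FPs
  cm <- evaluateCase(prob, truth, pixelSpacing(st), sliceThickness(st))
  dice <- c()
  for (s in seq_len(dim(truth)[1])) {
    if (sum(truth[s, , ]) == 0) next
    pm <- (prob[s, , ] >= 0.5) * 1
    cc <- oracleConfusion(pm, truth[s, , ])
    dice <- c(dice, 2 * cc["TP"] / (2 * cc["TP"] + cc["FP"] + cc["FN"]))
  }
  expect_equal(cm$dice, mean(dice), tolerance = 1e-12)
  expect_identical(cm$n_slices_evaluated, length(dice))
})

test_that("volume agreement reproduces hand-computed statistics", {
  ag <- volumeAgreement(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ag$r_squared, 1)
  expect_equal(ag$mean_diff_cm3, 0)
  expect_equal(ag$loa_low_cm3, 0); expect_equal(ag$loa_high_cm3, 0)
  man <- c(10, 20, 30)
  ag2 <- volumeAgreement(man + c(1, 2, 3), man)  # differences {1,2,3}, sd 1
  expect_equal(ag2$mean_diff_cm3, 2)
  expect_equal(ag2$loa_low_cm3, 2 - 1.96, tolerance = 1e-12)
  expect_equal(ag2$loa_high_cm3, 2 + 1.96, tolerance = 1e-12)
  ag3 <- volumeAgreement(2 * man, man)
  expect_equal(ag3$r_squared, 1)
  expect_gt(ag3$mean_diff_cm3, 0)
  expect_message(agc <- volumeAgreement(c(5, 5, 5), man), "zero variance")
  expect_true(is.na(agc$r_squared))
  expect_error(volumeAgreement(1:2, 1:2), "at least 3")
})
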