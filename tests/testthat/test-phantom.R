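test_that("subject generation is a pure function of (masterSeed, subjectIndex)", {
  cfg <- phantomConfig(masterSeed = 123)
  a <- generateSubject(cfg, 4)
  b <- generateSubject(cfg, 4)
  expect_identical(slices(a), slices(b))
  expect_identical(maskStack(a), maskStack(b))
  c <- generateSubject(cfg, 5)
  expect_false(identical(slices(a), slices(c)))
})

test_that("generated volumes satisfy the stack contract", {
  st <- generateSubject(phantomConfig(masterSeed = 1), 0)
  expect_s4_class(st, "VolumeStack")
  expect_true(all(maskStack(st) %in% c(0, 1)))
  expect_identical(dim(maskStack(st)), dim(slices(st)))
  expect_gte(nSlices(st), 12)
  expect_lte(nSlices(st), 18)
})

test_that("contrastFalloff = 1 keeps end-slice contrast equal to mid-slice", {
  cfg <- phantomConfig(contrastFalloff = 1, noiseSD = 0.01,
                       ghostingProb = 0, masterSeed = 2)
  st <- generateSubject(cfg, 0)
  # contrast = mean brain intensity minus mean background (image border)
  contrastOf <- function(s) {
    sl <- slices(st)[s, , ]
    brain <- maskStack(st)[s, , ] == 1
    border <- c(sl[1, ], sl[nrow(sl), ], sl[, 1], sl[, ncol(sl)])
    mean(sl[brain]) - mean(border)
  }
  first <- contrastOf(1)
  mid <- contrastOf(ceiling(nSlices(st) / 2))
  expect_lt(abs(first - mid), 0.02)
  # and with the default falloff the end slices are markedly lower-contrast
  st2 <- generateSubject(phantomConfig(noiseSD = 0.01, ghostingProb = 0,
                                       masterSeed = 2), 0)
  st <- st2
  expect_lt(contrastOf(1), contrastOf(ceiling(nSlices(st2) / 2)) * 0.8)
})

test_that("per-slice mask area is unimodal with its maximum mid-stack", {
  cfg <- phantomConfig(nSubjects = 200L, masterSeed = 7)
  good <- 0L
  for (i in seq_len(200L) - 1L) {
    st <- generateSubject(cfg, i)
    area <- apply(maskStack(st), 1, sum)
    S <- length(area)
    peak <- which.max(area)
    mid <- ceiling(S / 2)
    inMiddleThird <- peak > S / 3 && peak <= 2 * S / 3 + 1
    endsSmaller <- area[1] < area[mid] && area[S] < area[mid]
    if (inMiddleThird && endsSmaller) good <- good + 1L
  }
  expect_gte(good / 200, 0.95)
})

test_that("degenerate geometry is rejected naming the offending field", {
  cfg <- phantomConfig(brainAxisRangePX = c(30, 60))
  expect_error(generateSubject(cfg, 0), "brainAxisRangePX")
})

test_that("dataset manifest has unique ids and balanced, reproducible strata", {
  ds <- generateDataset(phantomConfig(nSubjects = 6L, masterSeed = 9))
  expect_length(unique(ds$manifest$subject_id), 6L)
  ds2 <- generateDataset(phantomConfig(nSubjects = 6L, masterSeed = 9))
  expect_identical(ds$manifest$stratum, ds2$manifest$stratum)
  for (n in c(6L, 8L, 11L)) {
    m <- generateDataset(phantomConfig(nSubjects = n, masterSeed = n))$manifest
    sizes <- table(m$stratum)
    expect_true(all(sizes >= floor(n / 4) & sizes <= ceiling(n / 4)))
    # sort-and-split oracle: lowest-area quarter must be labelled Q1
    ord <- order(m$mid_area_px)
    expect_true(all(m$stratum[ord] == sort(m$stratum)))
  }
})

test_that("dataset writing refuses to clobber an existing directory", {
  dir <- file.path(tempdir(), "phantomds")
  unlink(dir, recursive = TRUE)
  cfg <- phantomConfig(nSubjects = 2L, imageSize = c(48L, 48L), masterSeed = 3)
  generateDataset(cfg, outputDir = dir, format = "png")
  expect_error(generateDataset(cfg, outputDir = dir, format = "png"),
               "overwrite")
  expect_silent(generateDataset(cfg, outputDir = dir, format = "png",
                                overwrite = TRUE))
  unlink(dir, recursive = TRUE)
})

test_that("identity augmentation leaves image and mask untouched", {
  d <- tinyData(4)
  out <- augmentPair(d$images[[2]], d$masks[[2]], thetaDeg = 0, zoom = 1)
  expect_equal(out$image, d$images[[2]], tolerance = 1e-12)
  expect_identical(out$mask, d$masks[[2]])
})

test_that("augmented masks stay binary with the input shape", {
  d <- tinyData(4)
  set.seed(5)
  for (r in 1:10) {
    out <- augmentRandom(d$images[[1]], d$masks[[1]])
    expect_identical(dim(out$mask), dim(d$masks[[1]]))
    expect_identical(dim(out$image), dim(d$images[[1]]))
    expect_true(all(out$mask %in% c(0, 1)))
  }
})

test_that("horizontal flip moves a single foreground pixel to column W-1-c", {
  W <- 9L; H <- 7L
  for (c0 in c(1L, 3L, 9L)) {
    m <- matrix(0, H, W)
    m[4, c0] <- 1
    out <- augmentPair(m, m, flipH = TRUE)
    expect_identical(which(out$mask == 1, arr.ind = TRUE)[1, ],
                     c(row = 4L, col = W + 1L - c0))
  }
})

test_that("rotation round-trip recovers the mask with Dice >= 0.95", {
  d <- tinyData(6)
  set.seed(11)
  for (r in 1:8) {
    theta <- runif(1, -180, 180)
    msk <- d$masks[[3]]
    once <- augmentPair(d$images[[3]], msk, thetaDeg = theta, zoom = 1)
    back <- augmentPair(once$image, once$mask, thetaDeg = -theta, zoom = 1)
    inter <- sum(back$mask * msk)
    dice <- 2 * inter / (sum(back$mask) + sum(msk))
    expect_gte(dice, 0.95)
  }
})

test_that("augmentation rejects mismatched shapes", {
  expect_error(augmentPair(matrix(0, 4, 4), matrix(0, 5, 4)), "shape")
})
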