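#' @include simounet-package.R
NULL

#' Configuration of the synthetic foetal-head phantom generator
#'
#' Describes the population of synthetic MR-like volumes the phantom module
#' emulates: an elliptical "brain" with a bright skull ring inside a darker
#' head, whose cross-sectional area peaks mid-stack and shrinks toward the top
#' and bottom slices while contrast degrades, with additive noise and optional
#' motion-ghosting replicas.
#'
#' @slot nSubjects number of subjects generated by [generateDataset()].
#' @slot slicesPerSubject integer range (min, max) of slices per volume.
#' @slot imageSize image height and width in pixels.
#' @slot pixelSpacingMM in-plane pixel spacing (dx, dy) in mm.
#' @slot sliceThicknessMM slice thickness dz in mm.
#' @slot brainAxisRangePX range of the mid-slice brain ellipse semi-axes (px).
#' @slot areaProfileExponent exponent of the unimodal slice-area profile
#'   `(4 t (1 - t))^e`, `t` the normalised slice position.
#' @slot skullGapPX distance between brain boundary and skull ring (px); may
#'   be `<= 0` to force brain/skull overlap.
#' @slot contrastFalloff factor by which brain/background contrast at the end
#'   slices is reduced relative to the mid slice (1 = no falloff).
#' @slot noiseSD additive Gaussian noise standard deviation (intensity units).
#' @slot ghostingProb per-slice probability of a shifted faint replica.
#' @slot masterSeed integer seed making the whole dataset deterministic.
#' @seealso [phantomConfig()], [generateSubject()], [generateDataset()]
#' @export
setClass("PhantomConfig", representation(
  nSubjects = "integer",
  slicesPerSubject = "integer",
  imageSize = "integer",
  pixelSpacingMM = "numeric",
  sliceThicknessMM = "numeric",
  brainAxisRangePX = "numeric",
  areaProfileExponent = "numeric",
  skullGapPX = "numeric",
  contrastFalloff = "numeric",
  noiseSD = "numeric",
  ghostingProb = "numeric",
  masterSeed = "integer"
))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (length(object@slicesPerSubject) != 2L || any(object@slicesPerSubject < 3L))
    msg <- c(msg, "slicesPerSubject must be a range with minimum >= 3")
  if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
    msg <- c(msg, "imageSize must be two pixel counts >= 8")
  if (any(object@pixelSpacingMM <= 0) || object@sliceThicknessMM <= 0)
    msg <- c(msg, "pixelSpacingMM and sliceThicknessMM must be > 0")
  if (any(object@brainAxisRangePX <= 0))
    msg <- c(msg, "brainAxisRangePX must be > 0")
  if (object@areaProfileExponent <= 0)
    msg <- c(msg, "areaProfileExponent must be > 0")
  if (object@contrastFalloff <= 0)
    msg <- c(msg, "contrastFalloff must be > 0")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (object@ghostingProb < 0 || object@ghostingProb > 1)
    msg <- c(msg, "ghostingProb must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' An ordered stack of 2D slices with physical geometry
#'
#' The unit of a "case": `S` grayscale slices stored as an `(S, H, W)` array,
#' an optional aligned binary mask stack, the in-plane pixel spacing and slice
#' thickness in mm, a subject identifier and free-form metadata.
#'
#' @slot slices numeric `(S, H, W)` intensity array (arbitrary units).
#' @slot mask binary `(S, H, W)` array with values in `{0, 1}`, or `NULL`.
#' @slot pixelSpacingMM (dx, dy) in mm.
#' @slot sliceThicknessMM dz in mm.
#' @slot subjectID subject identifier.
#' @slot metadata named list (e.g. the synthetic gestational-age stratum).
#' @seealso [volumeStack()], [readVolume()], [writeVolume()]
#' @export
setClass("VolumeStack", representation(
  slices = "array",
  mask = "ANY",
  pixelSpacingMM = "numeric",
  sliceThicknessMM = "numeric",
  subjectID = "character",
  metadata = "list"
))

setValidity("VolumeStack", function(object) {
  msg <- character()
  if (length(dim(object@slices)) != 3L)
    msg <- c(msg, "slices must be an (S, H, W) array")
  if (!is.null(object@mask)) {
    if (!identical(dim(object@mask), dim(object@slices)))
      msg <- c(msg, "mask must have the same (S, H, W) shape as slices")
    else if (!all(object@mask %in% c(0, 1)))
      msg <- c(msg, "mask must contain only {0, 1}")
  }
  if (length(object@pixelSpacingMM) != 2L || any(object@pixelSpacingMM <= 0))
    msg <- c(msg, "pixelSpacingMM must be two positive values (dx, dy)")
  if (object@sliceThicknessMM <= 0)
    msg <- c(msg, "sliceThicknessMM must be > 0")
  if (length(msg)) msg else TRUE
})

#' Declarative description of a SIMOU network graph
#'
#' Holds everything needed to instantiate the network: the per-level feature
#' channels of the contracting path, the stride of every inter-level
#' transition, the ordered side-output taps with their resolution depths, and
#' the composition of the five prediction heads.
#'
#' @slot inputShape (H, W, 1).
#' @slot nLevels number of contracting-path convolutional-block levels.
#' @slot channels per-level feature channel counts (length `nLevels`).
#' @slot poolStrides stride (2 or 1) of each of the `nLevels - 1` transitions;
#'   stride-1 transitions keep the resolution once it has reached 1 px.
#' @slot dropoutRate dropout fraction.
#' @slot dropoutDown,dropoutUp which contracting levels / expansive blocks
#'   carry dropout.
#' @slot activation activation name (only `"elu"` is implemented).
#' @slot sideTaps data.frame (index, path, level, depth) of the
#'   `2 * nLevels - 1` side outputs.
#' @slot headDefs named list mapping the heads `dux`, `du`, `u`, `d` to the
#'   side-tap indices they concatenate; head `f` is the final decoder map.
#' @slot sideHeadChannels channels each side output is reduced to before
#'   concatenation.
#' @slot postConcatChannels filters of the two 3x3 convolutions after
#'   concatenation.
#' @seealso [simouSpec()], [simoUnetSpec()], [buildModel()]
#' @export
setClass("NetworkSpec", representation(
  inputShape = "integer",
  nLevels = "integer",
  channels = "integer",
  poolStrides = "integer",
  dropoutRate = "numeric",
  dropoutDown = "integer",
  dropoutUp = "integer",
  activation = "character",
  sideTaps = "data.frame",
  headDefs = "list",
  sideHeadChannels = "integer",
  postConcatChannels = "integer"
))

setValidity("NetworkSpec", function(object) {
  msg <- character()
  L <- object@nLevels
  if (length(object@channels) != L)
    msg <- c(msg, "channels must have one entry per level")
  if (length(object@poolStrides) != L - 1L ||
      !all(object@poolStrides %in% c(1L, 2L)))
    msg <- c(msg, "poolStrides must be nLevels - 1 strides in {1, 2}")
  if (nrow(object@sideTaps) != 2L * L - 1L)
    msg <- c(msg, "there must be nLevels + (nLevels - 1) side taps")
  hd <- object@headDefs
  if (!identical(sort(names(hd)), sort(c("dux", "du", "u", "d"))))
    msg <- c(msg, "headDefs must define heads dux, du, u, d")
  else {
    if (!identical(hd$du, seq_len(2L * L - 1L)))
      msg <- c(msg, "head du must concatenate all side taps")
    if (!identical(hd$dux, seq_len(2L * L - 2L)))
      msg <- c(msg, "head dux must concatenate all taps but the last")
    if (!identical(hd$d, seq_len(L)))
      msg <- c(msg, "head d must concatenate the contracting-path taps")
    if (!identical(hd$u, seq.int(L + 1L, 2L * L - 1L)))
      msg <- c(msg, "head u must concatenate the expansive-path taps")
  }
  if (object@activation != "elu")
    msg <- c(msg, "only the 'elu' activation is implemented")
  if (length(msg)) msg else TRUE
})

#' The five per-slice probability maps of a SIMOU network
#'
#' @slot pDux,pDu,pU,pD,pF `H x W` probability matrices in `[0, 1]`:
#'   all-side-outputs-but-last, all side outputs, expansive-path only,
#'   contracting-path only, and the final decoder (main) output.
#' @seealso [predictionSet()], [fusePredictions()]
#' @export
setClass("PredictionSet", representation(
  pDux = "matrix", pDu = "matrix", pU = "matrix", pD = "matrix", pF = "matrix"
))

setValidity("PredictionSet", function(object) {
  maps <- list(object@pDux, object@pDu, object@pU, object@pD, object@pF)
  dims <- lapply(maps, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    return("all five maps must share the same H x W shape")
  rng <- range(vapply(maps, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 1)
    return("probability maps must lie in [0, 1]")
  TRUE
})

#' A fused (ensemble) prediction map
#'
#' @slot values `H x W` matrix in `[0, 1]`.
#' @slot opName fusion operator: `"mean"`, `"median"` or `"max"`.
#' @slot source identifier of the originating prediction set.
#' @seealso [fusePredictions()]
#' @export
setClass("FusedMap", representation(
  values = "matrix", opName = "character", source = "character"
))

setValidity("FusedMap", function(object) {
  if (!object@opName %in% c("mean", "median", "max"))
    return("opName must be one of 'mean', 'median', 'max'")
  if (min(object@values) < 0 || max(object@values) > 1)
    return("values must lie in [0, 1]")
  TRUE
})

#' Training protocol configuration
#'
#' @slot learningRate RMSprop initial learning rate.
#' @slot decayFactorRho RMSprop gradient moving-average decay factor.
#' @slot batchSize samples per gradient step.
#' @slot maxEpochs maximum number of epochs.
#' @slot earlyStopPatience epochs without validation-loss improvement before
#'   stopping.
#' @slot alphaWeights per-head weights of the multi-output objective, in the
#'   head order (dux, du, u, d, f).
#' @slot smoothEps soft-Dice smoothing constant.
#' @slot seed RNG seed covering shuffling, dropout and augmentation.
#' @slot augmentation whether each epoch adds one augmented copy per sample.
#' @seealso [trainingConfig()], [trainModel()]
#' @export
setClass("TrainingConfig", representation(
  learningRate = "numeric",
  decayFactorRho = "numeric",
  batchSize = "integer",
  maxEpochs = "integer",
  earlyStopPatience = "integer",
  alphaWeights = "numeric",
  smoothEps = "numeric",
  seed = "integer",
  augmentation = "logical"
))

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0 || object@decayFactorRho <= 0 ||
      object@decayFactorRho >= 1)
    msg <- c(msg, "learningRate must be > 0 and decayFactorRho in (0, 1)")
  if (object@batchSize < 1L || object@maxEpochs < 1L)
    msg <- c(msg, "batchSize and maxEpochs must be >= 1")
  if (object@earlyStopPatience >= object@maxEpochs)
    msg <- c(msg, "earlyStopPatience must be < maxEpochs")
  if (length(object@alphaWeights) != 5L || any(object@alphaWeights < 0) ||
      all(object@alphaWeights == 0))
    msg <- c(msg, "alphaWeights must be 5 non-negative weights, not all zero")
  if (object@smoothEps <= 0) msg <- c(msg, "smoothEps must be > 0")
  if (length(msg)) msg else TRUE
})

#' A subject-grouped stratified cross-validation plan
#'
#' @slot k fold count.
#' @slot assignments named integer vector: subject id -> fold (1..k).
#' @slot strata named character vector: subject id -> stratum label.
#' @seealso [stratifiedGroupFolds()]
#' @export
setClass("FoldPlan", representation(
  k = "integer", assignments = "integer", strata = "character"
))

setValidity("FoldPlan", function(object) {
  msg <- character()
  if (is.null(names(object@assignments)) ||
      anyDuplicated(names(object@assignments)))
    msg <- c(msg, "assignments must be uniquely named by subject id")
  if (any(object@assignments < 1L) || any(object@assignments > object@k))
    msg <- c(msg, "fold indices must lie in 1..k")
  tab <- table(object@strata, factor(object@assignments, levels = seq_len(object@k)))
  if (nrow(tab) && any(apply(tab, 1L, function(r) diff(range(r))) > 1L))
    msg <- c(msg, "within each stratum fold sizes must differ by at most 1")
  if (length(msg)) msg else TRUE
})

#' An instantiated SIMOU network
#'
#' Executable model: the declarative [NetworkSpec-class] plus all layer
#' parameters, batch-normalisation running statistics, and the seed the
#' parameters were drawn from.
#'
#' @slot spec the [NetworkSpec-class] the model was built from.
#' @slot params nested list of parameter arrays.
#' @slot state nested list of batch-normalisation running statistics.
#' @slot seed initialisation seed.
#' @seealso [buildModel()], [predictModel()], [trainModel()]
#' @export
setClass("SimouModel", representation(
  spec = "NetworkSpec", params = "list", state = "list", seed = "integer"
))

# ---- constructors ----------------------------------------------------------

#' Create a phantom generator configuration
#'
#' Defaults describe the study conditions of the package's self-contained
#' experiments: 12 subjects of 12-18 slices at 64 x 64 px, 1 mm in-plane
#' spacing and 2.4 mm slice thickness (within the 2.0-2.6 mm range typical of
#' foetal acquisitions), a mid-slice brain of 8-16 px semi-axes, contrast at
#' the end slices reduced to 0.35 of the mid-slice contrast, and a 15% chance
#' of a ghosting replica per slice.
#'
#' @param nSubjects,slicesPerSubject,imageSize,pixelSpacingMM,sliceThicknessMM
#'   see [PhantomConfig-class].
#' @param brainAxisRangePX,areaProfileExponent,skullGapPX,contrastFalloff
#'   see [PhantomConfig-class].
#' @param noiseSD,ghostingProb,masterSeed see [PhantomConfig-class].
#' @return A validated [PhantomConfig-class].
#' @examples
#' cfg <- phantomConfig(nSubjects = 2, masterSeed = 1)
#' stack <- generateSubject(cfg, 0)
#' dim(slices(stack))
#' @export
phantomConfig <- function(nSubjects = 12L,
                          slicesPerSubject = c(12L, 18L),
                          imageSize = c(64L, 64L),
                          pixelSpacingMM = c(1.0, 1.0),
                          sliceThicknessMM = 2.4,
                          brainAxisRangePX = c(8, 16),
                          areaProfileExponent = 1.0,
                          skullGapPX = 3,
                          contrastFalloff = 0.35,
                          noiseSD = 0.05,
                          ghostingProb = 0.15,
                          masterSeed = 42L) {
  new("PhantomConfig",
      nSubjects = as.integer(nSubjects),
      slicesPerSubject = as.integer(slicesPerSubject),
      imageSize = as.integer(imageSize),
      pixelSpacingMM = as.numeric(pixelSpacingMM),
      sliceThicknessMM = as.numeric(sliceThicknessMM),
      brainAxisRangePX = as.numeric(brainAxisRangePX),
      areaProfileExponent = as.numeric(areaProfileExponent),
      skullGapPX = as.numeric(skullGapPX),
      contrastFalloff = as.numeric(contrastFalloff),
      noiseSD = as.numeric(noiseSD),
      ghostingProb = as.numeric(ghostingProb),
      masterSeed = as.integer(masterSeed))
}

#' Create a volume stack
#'
#' @param slices `(S, H, W)` intensity array.
#' @param mask optional aligned binary `(S, H, W)` array.
#' @param pixelSpacingMM (dx, dy) in mm.
#' @param sliceThicknessMM dz in mm.
#' @param subjectID subject identifier.
#' @param metadata named list of free-form metadata.
#' @return A validated [VolumeStack-class].
#' @export
volumeStack <- function(slices, mask = NULL, pixelSpacingMM = c(1, 1),
                        sliceThicknessMM = 1, subjectID = "case",
                        metadata = list()) {
  if (!is.null(mask)) {
    mask <- array(as.numeric(mask), dim(mask))
  }
  new("VolumeStack", slices = slices, mask = mask,
      pixelSpacingMM = as.numeric(pixelSpacingMM),
      sliceThicknessMM = as.numeric(sliceThicknessMM),
      subjectID = as.character(subjectID), metadata = metadata)
}

#' Bundle five probability maps into a prediction set
#'
#' @param pDux,pDu,pU,pD,pF `H x W` probability matrices (see
#'   [PredictionSet-class]).
#' @return A validated [PredictionSet-class].
#' @export
predictionSet <- function(pDux, pDu, pU, pD, pF) {
  new("PredictionSet", pDux = as.matrix(pDux), pDu = as.matrix(pDu),
      pU = as.matrix(pU), pD = as.matrix(pD), pF = as.matrix(pF))
}

#' Create a training configuration
#'
#' Defaults follow the full-scale protocol: RMSprop with learning rate 3e-4
#' and decay factor 0.8, batch size 32, up to 1000 epochs with early stopping
#' after 100 epochs without validation-loss improvement, and equal per-head
#' weights (no head is privileged).
#'
#' @param learningRate,decayFactorRho,batchSize,maxEpochs,earlyStopPatience
#'   see [TrainingConfig-class].
#' @param alphaWeights,smoothEps,seed,augmentation see
#'   [TrainingConfig-class].
#' @return A validated [TrainingConfig-class].
#' @export
trainingConfig <- function(learningRate = 3e-4,
                           decayFactorRho = 0.8,
                           batchSize = 32L,
                           maxEpochs = 1000L,
                           earlyStopPatience = 100L,
                           alphaWeights = rep(1, 5),
                           smoothEps = 1e-6,
                           seed = 1L,
                           augmentation = TRUE) {
  new("TrainingConfig",
      learningRate = learningRate, decayFactorRho = decayFactorRho,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      earlyStopPatience = as.integer(earlyStopPatience),
      alphaWeights = as.numeric(alphaWeights), smoothEps = smoothEps,
      seed = as.integer(seed), augmentation = isTRUE(augmentation))
}

# ---- accessors -------------------------------------------------------------

#' @describeIn VolumeStack-class the `(S, H, W)` intensity array.
#' @param x,object a [VolumeStack-class].
#' @export
slices <- function(x) x@slices

#' @describeIn VolumeStack-class the binary mask stack (or `NULL`).
#' @export
maskStack <- function(x) x@mask

#' @describeIn VolumeStack-class the (dx, dy) pixel spacing in mm.
#' @export
pixelSpacing <- function(x) x@pixelSpacingMM

#' @describeIn VolumeStack-class the slice thickness in mm.
#' @export
sliceThickness <- function(x) x@sliceThicknessMM

#' @describeIn VolumeStack-class the subject identifier.
#' @export
subjectID <- function(x) x@subjectID

#' @describeIn VolumeStack-class the number of slices.
#' @export
nSlices <- function(x) dim(x@slices)[1]

#' @describeIn NetworkSpec-class number of side-output taps.
#' @param spec a [NetworkSpec-class].
#' @export
nSideTaps <- function(spec) nrow(spec@sideTaps)

#' @describeIn NetworkSpec-class number of prediction heads (always 5: the
#'   four side-output heads plus the final decoder map).
#' @export
nHeads <- function(spec) length(spec@headDefs) + 1L

#' @describeIn NetworkSpec-class number of contracting-path levels.
#' @export
nLevels <- function(spec) spec@nLevels

#' @describeIn NetworkSpec-class per-level feature channel counts.
#' @export
specChannels <- function(spec) spec@channels

#' @describeIn PredictionSet-class the five maps as a named list in the head
#'   order (dux, du, u, d, f).
#' @param x a [PredictionSet-class].
#' @export
predictionMaps <- function(x) {
  list(dux = x@pDux, du = x@pDu, u = x@pU, d = x@pD, f = x@pF)
}

#' @describeIn FoldPlan-class subject ids assigned to fold `i`.
#' @param plan a [FoldPlan-class].
#' @param i fold index in `1..k`.
#' @export
foldSubjects <- function(plan, i) names(plan@assignments)[plan@assignments == i]

# ---- show methods ----------------------------------------------------------

setMethod("show", "VolumeStack", function(object) {
  d <- dim(object@slices)
  cat(sprintf(
    "VolumeStack '%s': %d slices of %d x %d px, spacing %.3g x %.3g mm, thickness %.3g mm, mask %s\n",
    object@subjectID, d[1], d[2], d[3],
    object@pixelSpacingMM[1], object@pixelSpacingMM[2],
    object@sliceThicknessMM, if (is.null(object@mask)) "absent" else "present"))
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf(
    "NetworkSpec: %d levels (channels %s), input %d x %d, %d side taps, %d heads\n",
    object@nLevels, paste(object@channels, collapse = "-"),
    object@inputShape[1], object@inputShape[2],
    nSideTaps(object), nHeads(object)))
  cat(sprintf("  transitions: strides %s; dropout %.2g on down levels %s / up blocks %s\n",
              paste(object@poolStrides, collapse = ","),
              object@dropoutRate,
              paste(object@dropoutDown, collapse = ","),
              paste(object@dropoutUp, collapse = ",")))
})

setMethod("show", "PredictionSet", function(object) {
  d <- dim(object@pF)
  cat(sprintf("PredictionSet: 5 maps of %d x %d px\n", d[1], d[2]))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d subjects in %d folds (sizes %s)\n",
              length(object@assignments), object@k,
              paste(tabulate(object@assignments, object@k), collapse = ", ")))
})

setMethod("show", "SimouModel", function(object) {
  np <- sum(rapply(object@params, length, how = "unlist"))
  cat(sprintf("SimouModel: %d-level network, %d parameters, seed %d\n",
              object@spec@nLevels, np, object@seed))
})

setMethod("show", "FusedMap", function(object) {
  cat(sprintf("FusedMap (%s) of %d x %d px from %s\n", object@opName,
              nrow(object@values), ncol(object@values), object@source))
})
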