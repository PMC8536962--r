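#' @include AllClasses.R
NULL

# Volumes are stored on disk in radiological-tool-friendly layouts:
#  - NIfTI: data as (W, H, S) with pixdim (dx, dy, dz); image as float64,
#    mask as uint8 {0, 1}; files <path>_image.nii.gz and <path>_mask.nii.gz.
#  - PNG + JSON: one 16-bit grayscale PNG per slice (intensities affinely
#    mapped to [0, 1]; the mapping is recorded in the sidecar so reading
#    restores the original units up to 16-bit quantisation), an optional
#    8-bit mask PNG, and a JSON sidecar per slice with subject_id,
#    slice_index, dx, dy, dz and the intensity window.

.niftiPaths <- function(path) {
  list(image = paste0(path, "_image.nii.gz"), mask = paste0(path, "_mask.nii.gz"))
}

.stackToXYZ <- function(a) aperm(a, c(3, 2, 1))   # (S,H,W) -> (W,H,S)
.xyzToStack <- function(a) aperm(a, c(3, 2, 1))

#' Write a volume stack to disk
#'
#' @param stack a [VolumeStack-class].
#' @param path output prefix (NIfTI) or directory (PNG).
#' @param format `"nifti"` or `"png"`.
#' @return `path`, invisibly.
#' @seealso [readVolume()]
#' @export
writeVolume <- function(stack, path, format = c("nifti", "png")) {
  format <- match.arg(format)
  sl <- slices(stack)
  msk <- maskStack(stack)
  dx <- pixelSpacing(stack)[1]; dy <- pixelSpacing(stack)[2]
  dz <- sliceThickness(stack)
  if (format == "nifti") {
    p <- .niftiPaths(path)
    img <- RNifti::asNifti(structure(.stackToXYZ(sl), pixdim = c(dx, dy, dz)),
                           datatype = "double")
    RNifti::writeNifti(img, p$image)
    if (!is.null(msk)) {
      m <- RNifti::asNifti(structure(.stackToXYZ(msk), pixdim = c(dx, dy, dz)),
                           datatype = "uint8")
      RNifti::writeNifti(m, p$mask)
    }
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    S <- dim(sl)[1]
    lo <- min(sl); hi <- max(sl)
    scale <- if (hi > lo) hi - lo else 1
    for (s in seq_len(S)) {
      base <- file.path(path, sprintf("slice_%03d", s - 1L))
      png::writePNG((sl[s, , ] - lo) / scale, paste0(base, ".png"))
      if (!is.null(msk))
        png::writePNG(msk[s, , ], paste0(base, "_mask.png"))
      jsonlite::write_json(
        list(subject_id = subjectID(stack), slice_index = s - 1L,
             dx = dx, dy = dy, dz = dz,
             intensity_min = lo, intensity_max = lo + scale,
             has_mask = !is.null(msk)),
        paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(path)
}

#' Read a volume stack from disk
#'
#' Accepts a NIfTI prefix (as written by [writeVolume()]), a single
#' `.nii`/`.nii.gz` file, or a PNG+JSON slice directory. PNG slices are
#' ordered by the `slice_index` of their sidecars regardless of file naming.
#'
#' @param path NIfTI prefix/file or PNG directory.
#' @param subjectID identifier for the returned stack (defaults to the
#'   sidecar value or the file name).
#' @return A [VolumeStack-class].
#' @export
readVolume <- function(path, subjectID = NULL) {
  if (dir.exists(path)) {
    sidecars <- sort(dir(path, pattern = "\\.json$", full.names = TRUE))
    if (!length(sidecars)) stop("no JSON sidecars found in ", path)
    meta <- lapply(sidecars, jsonlite::read_json)
    ord <- order(vapply(meta, function(m) m$slice_index, numeric(1)))
    meta <- meta[ord]; sidecars <- sidecars[ord]
    if (is.null(meta[[1]]$dx))
      stop("sidecar lacks pixel geometry; supply explicit dx/dy/dz metadata")
    S <- length(sidecars)
    first <- png::readPNG(sub("\\.json$", ".png", sidecars[1]))
    sl <- array(0, c(S, nrow(first), ncol(first)))
    msk <- if (isTRUE(meta[[1]]$has_mask)) array(0, dim(sl)) else NULL
    for (s in seq_len(S)) {
      m <- meta[[s]]
      v <- png::readPNG(sub("\\.json$", ".png", sidecars[s]))
      sl[s, , ] <- m$intensity_min + v * (m$intensity_max - m$intensity_min)
      if (!is.null(msk))
        msk[s, , ] <- round(png::readPNG(sub("\\.json$", "_mask.png", sidecars[s])))
    }
    volumeStack(sl, msk, c(meta[[1]]$dx, meta[[1]]$dy), meta[[1]]$dz,
                subjectID = subjectID %||% meta[[1]]$subject_id)
  } else {
    p <- .niftiPaths(path)
    imgFile <- if (file.exists(p$image)) p$image
               else if (file.exists(path)) path
               else stop("no volume found at ", path)
    img <- RNifti::readNifti(imgFile)
    pd <- RNifti::pixdim(img)
    if (any(pd[1:3] <= 0))
      stop("NIfTI lacks positive pixel geometry; supply explicit spacing")
    msk <- NULL
    if (file.exists(p$mask))
      msk <- .xyzToStack(array(as.numeric(RNifti::readNifti(p$mask)),
                               dim(RNifti::readNifti(p$mask))))
    volumeStack(.xyzToStack(array(as.numeric(img), dim(img))), msk,
                pd[1:2], pd[3],
                subjectID = subjectID %||% sub("_image\\.nii(\\.gz)?$", "",
                                               basename(imgFile)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- YAML serialisation of specs and configs ------------------------------

#' Serialise a network spec to YAML (and back)
#'
#' @param spec a [NetworkSpec-class].
#' @param path file path.
#' @return `readNetworkSpec` returns a [NetworkSpec-class].
#' @export
writeNetworkSpec <- function(spec, path) {
  yaml::write_yaml(list(
    inputShape = spec@inputShape, nLevels = spec@nLevels,
    channels = spec@channels, poolStrides = spec@poolStrides,
    dropoutRate = spec@dropoutRate, dropoutDown = spec@dropoutDown,
    dropoutUp = spec@dropoutUp, activation = spec@activation,
    sideHeadChannels = spec@sideHeadChannels,
    postConcatChannels = spec@postConcatChannels,
    sideTaps = spec@sideTaps, headDefs = spec@headDefs), path)
  invisible(path)
}

#' @rdname writeNetworkSpec
#' @export
readNetworkSpec <- function(path) {
  y <- yaml::read_yaml(path)
  new("NetworkSpec",
      inputShape = as.integer(y$inputShape), nLevels = as.integer(y$nLevels),
      channels = as.integer(y$channels), poolStrides = as.integer(y$poolStrides),
      dropoutRate = y$dropoutRate, dropoutDown = as.integer(y$dropoutDown),
      dropoutUp = as.integer(y$dropoutUp), activation = y$activation,
      sideTaps = as.data.frame(y$sideTaps),
      headDefs = lapply(y$headDefs, as.integer),
      sideHeadChannels = as.integer(y$sideHeadChannels),
      postConcatChannels = as.integer(y$postConcatChannels))
}

#' Serialise a training configuration to YAML (and back)
#'
#' @param config a [TrainingConfig-class].
#' @param path file path.
#' @return `readTrainingConfig` returns a [TrainingConfig-class].
#' @export
writeTrainingConfig <- function(config, path) {
  yaml::write_yaml(list(
    learningRate = config@learningRate, decayFactorRho = config@decayFactorRho,
    batchSize = config@batchSize, maxEpochs = config@maxEpochs,
    earlyStopPatience = config@earlyStopPatience,
    alphaWeights = config@alphaWeights, smoothEps = config@smoothEps,
    seed = config@seed, augmentation = config@augmentation), path)
  invisible(path)
}

#' @rdname writeTrainingConfig
#' @export
readTrainingConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(trainingConfig, y)
}

# Tiny FNV-1a hash for run manifests (no external digest dependency).
.fnvHash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 216613626L
  for (b in bytes)
    h <- as.integer((bitwXor(h, b) * 16777619) %% 2147483647)
  sprintf("%08x", h)
}

#' Save / load a trained model checkpoint
#'
#' Weights are stored as an RDS checkpoint with a JSON sidecar recording the
#' spec hash and initialisation seed, making runs auditable.
#'
#' @param model a [SimouModel-class].
#' @param path checkpoint path (without extension).
#' @return `loadModel` returns the [SimouModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(list(params = model@params, state = model@state,
               spec = model@spec, seed = model@seed),
          paste0(path, ".rds"))
  specYaml <- tempfile(); on.exit(unlink(specYaml))
  writeNetworkSpec(model@spec, specYaml)
  jsonlite::write_json(list(spec_hash = .fnvHash(readLines(specYaml)),
                            seed = model@seed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(paste0(path, ".rds"))
  new("SimouModel", spec = x$spec, params = x$params, state = x$state,
      seed = as.integer(x$seed))
}

#' Write a colour overlay PNG of a segmentation result
#'
#' True positives cyan, false positives red, false negatives yellow, true
#' negatives as the (darkened) image.
#'
#' @param image grayscale slice matrix.
#' @param predMask,truthMask binary matrices.
#' @param path output PNG path.
#' @export
writeOverlayPNG <- function(image, predMask, truthMask, path) {
  g <- (image - min(image)) / max(1e-12, diff(range(image))) * 0.6
  r <- g; b <- g
  tp <- predMask == 1 & truthMask == 1
  fp <- predMask == 1 & truthMask == 0
  fn <- predMask == 0 & truthMask == 1
  r[tp] <- 0;   g[tp] <- 1;   b[tp] <- 1
  r[fp] <- 1;   g[fp] <- 0;   b[fp] <- 0
  r[fn] <- 1;   g[fn] <- 1;   b[fn] <- 0
  png::writePNG(array(c(r, g, b), c(dim(image), 3L)), path)
  invisible(path)
}
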