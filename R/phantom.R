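#' @include AllClasses.R
NULL

# Rasterize a rotated ellipse: semi-axes (a, b) px, centre (cx, cy), angle phi.
# Returns an H x W 0/1 matrix (rows = y, cols = x, 1-based pixel centres).
ellipseMask <- function(H, W, cx, cy, a, b, phi) {
  if (a < 1e-3 || b < 1e-3) return(matrix(0, H, W))
  x <- matrix(rep(seq_len(W), each = H), H, W) - cx
  y <- matrix(rep(seq_len(H), W), H, W) - cy
  xr <- cos(phi) * x + sin(phi) * y
  yr <- -sin(phi) * x + cos(phi) * y
  (xr / a)^2 + (yr / b)^2 <= 1
}

# Noise-free structural drawing of one slice on full contrast: background,
# head tissue, skull ring and brain, as intensity levels.
.phantomLevels <- c(bg = 0.10, head = 0.35, brain = 0.75, skull = 0.95)

#' Generate one synthetic subject volume
#'
#' Draws a randomised brain ellipse (centre, orientation, semi-axes), scales
#' its area along the stack with the unimodal profile `(4 t (1 - t))^e` so the
#' brain is largest mid-stack and vanishingly small at the ends, surrounds it
#' with a bright skull ring at `skullGapPX` inside a darker head ellipse,
#' degrades brain/background contrast toward the end slices, and adds Gaussian
#' noise plus (with probability `ghostingProb` per slice) a shifted faint
#' replica of the head emulating a motion ghost. The result is bit-identical
#' for a given `(masterSeed, subjectIndex)` pair.
#'
#' @param config a [PhantomConfig-class].
#' @param subjectIndex non-negative subject index.
#' @return A [VolumeStack-class] with ground-truth mask present.
#' @examples
#' stack <- generateSubject(phantomConfig(masterSeed = 7), 0)
#' stack
#' @export
generateSubject <- function(config, subjectIndex) {
  stopifnot(is(config, "PhantomConfig"), subjectIndex >= 0)
  validObject(config)
  H <- config@imageSize[1]; W <- config@imageSize[2]
  skullW <- 2; headPad <- 4
  # brain + skull ring must fit; the outer head tissue may clip at the FOV
  # edge, as it commonly does in foetal acquisitions
  margin <- max(config@brainAxisRangePX) + max(config@skullGapPX, 0) +
    skullW + 1
  if (2 * margin >= min(H, W))
    stop("degenerate phantom geometry: brainAxisRangePX (with skullGapPX and ",
         "head padding) does not fit inside imageSize ", H, " x ", W)
  withSeed(subSeed(config@masterSeed, subjectIndex), {
    S <- config@slicesPerSubject[1] +
      sample.int(config@slicesPerSubject[2] - config@slicesPerSubject[1] + 1L, 1L) - 1L
    a0 <- runif(1, config@brainAxisRangePX[1], config@brainAxisRangePX[2])
    b0 <- runif(1, config@brainAxisRangePX[1], config@brainAxisRangePX[2])
    phi <- runif(1, -pi, pi)
    cx0 <- runif(1, margin, W - margin)
    cy0 <- runif(1, margin, H - margin)
    drift <- runif(2, -1.5, 1.5)  # px of in-plane drift across the stack
    ghostShift <- round(runif(2, 6, 12)) * sample(c(-1, 1), 2, replace = TRUE)
    img <- array(0, c(S, H, W))
    msk <- array(0, c(S, H, W))
    lv <- .phantomLevels
    for (s in seq_len(S)) {
      t <- (s - 0.5) / S
      areaScale <- (4 * t * (1 - t))^config@areaProfileExponent
      axScale <- sqrt(areaScale)
      contrast <- config@contrastFalloff +
        (1 - config@contrastFalloff) * 4 * t * (1 - t)
      cx <- cx0 + drift[1] * (2 * t - 1)
      cy <- cy0 + drift[2] * (2 * t - 1)
      a <- a0 * axScale; b <- b0 * axScale
      brain <- ellipseMask(H, W, cx, cy, a, b, phi)
      skullOuter <- ellipseMask(H, W, cx, cy,
                                a + config@skullGapPX + skullW,
                                b + config@skullGapPX + skullW, phi)
      skullInner <- ellipseMask(H, W, cx, cy,
                                a + config@skullGapPX,
                                b + config@skullGapPX, phi)
      headM <- ellipseMask(H, W, cx, cy,
                           a + config@skullGapPX + skullW + headPad,
                           b + config@skullGapPX + skullW + headPad, phi)
      struct <- matrix(lv["bg"], H, W)
      struct[headM == 1] <- lv["head"]
      struct[skullOuter == 1 & skullInner == 0] <- lv["skull"]
      struct[brain == 1] <- lv["brain"]
      slice <- lv["bg"] + contrast * (struct - lv["bg"])
      if (runif(1) < config@ghostingProb) {
        ghost <- matrix(0, H, W)
        src <- struct - lv["bg"]
        rs <- ghostShift[2]; cs <- ghostShift[1]
        rIdx <- intersect(seq_len(H), seq_len(H) - rs)
        cIdx <- intersect(seq_len(W), seq_len(W) - cs)
        ghost[rIdx + rs, cIdx + cs] <- src[rIdx, cIdx]
        slice <- slice + 0.15 * contrast * ghost
      }
      if (config@noiseSD > 0)
        slice <- slice + matrix(rnorm(H * W, sd = config@noiseSD), H, W)
      img[s, , ] <- slice
      msk[s, , ] <- brain
    }
    ga <- 18 + 19 * (mean(c(a0, b0)) - config@brainAxisRangePX[1]) /
      diff(range(config@brainAxisRangePX))  # synthetic gestational-age proxy
    volumeStack(img, msk, config@pixelSpacingMM, config@sliceThicknessMM,
                subjectID = sprintf("subj%03d", subjectIndex),
                metadata = list(gestationalAgeWeeks = ga,
                                subjectIndex = subjectIndex))
  })
}

# Balanced quartile labels by rank (ties broken by order).
.quartileStrata <- function(x) {
  n <- length(x)
  q <- ceiling(4 * rank(x, ties.method = "first") / n)
  paste0("Q", q)
}

#' Generate a phantom dataset with a stratification manifest
#'
#' Generates `nSubjects` volumes with unique subject ids and a manifest
#' recording, per subject, the slice count, the mid-slice brain area (px) and
#' its balanced quartile as stratum label (a gestational-age surrogate used
#' for stratified folding). Optionally writes everything to disk via
#' [writeVolume()].
#'
#' @param config a [PhantomConfig-class].
#' @param outputDir optional directory; refuses to overwrite an existing
#'   non-empty directory unless `overwrite = TRUE`.
#' @param format on-disk format, `"nifti"` or `"png"`.
#' @param overwrite allow writing into an existing directory.
#' @return list with `stacks` (list of [VolumeStack-class]) and `manifest`
#'   (data.frame: subject_id, n_slices, mid_area_px, stratum).
#' @examples
#' ds <- generateDataset(phantomConfig(nSubjects = 4, masterSeed = 3))
#' ds$manifest
#' @export
generateDataset <- function(config, outputDir = NULL, format = c("nifti", "png"),
                            overwrite = FALSE) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  format <- match.arg(format)
  stacks <- lapply(seq_len(config@nSubjects) - 1L,
                   function(i) generateSubject(config, i))
  midArea <- vapply(stacks, function(st) {
    m <- maskStack(st)
    sum(m[ceiling(dim(m)[1] / 2), , ])
  }, numeric(1))
  manifest <- data.frame(
    subject_id = vapply(stacks, subjectID, character(1)),
    n_slices = vapply(stacks, nSlices, numeric(1)),
    mid_area_px = midArea,
    stratum = .quartileStrata(midArea),
    stringsAsFactors = FALSE)
  if (!is.null(outputDir)) {
    if (dir.exists(outputDir) && length(dir(outputDir)) > 0 && !overwrite)
      stop("output directory ", outputDir,
           " exists and is not empty; use overwrite = TRUE to replace it")
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    for (st in stacks)
      writeVolume(st, file.path(outputDir, subjectID(st)), format = format)
    write.csv(manifest, file.path(outputDir, "manifest.csv"), row.names = FALSE)
  }
  list(stacks = stacks, manifest = manifest)
}

# Inverse-mapped affine resampling shared by image (bilinear) and mask
# (nearest + 0.5 threshold). The forward transform is rotate(theta) then
# zoom then flips, about the image centre; out-of-bounds is background 0.
.affineSample <- function(img, thetaDeg, zoom, flipH, flipV, bilinear) {
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yo <- matrix(rep(seq_len(H), W), H, W) - cy
  xo <- matrix(rep(seq_len(W), each = H), H, W) - cx
  if (flipH) xo <- -xo   # horizontal flip mirrors columns
  if (flipV) yo <- -yo
  xo <- xo / zoom; yo <- yo / zoom
  th <- -thetaDeg * pi / 180
  xs <- cos(th) * xo - sin(th) * yo + cx
  ys <- sin(th) * xo + cos(th) * yo + cy
  if (bilinear) {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    px <- function(yy, xx) {
      ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
      v <- matrix(0, H, W)
      v[ok] <- img[cbind(yy[ok], xx[ok])]
      v
    }
    v00 <- px(y0, x0); v01 <- px(y0, x0 + 1)
    v10 <- px(y0 + 1, x0); v11 <- px(y0 + 1, x0 + 1)
    (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  } else {
    xr <- round(xs); yr <- round(ys)
    ok <- yr >= 1 & yr <= H & xr >= 1 & xr <= W
    v <- matrix(0, H, W)
    v[ok] <- img[cbind(yr[ok], xr[ok])]
    v
  }
}

#' Apply one geometric augmentation to an image/mask pair
#'
#' Applies a rotation, an isotropic zoom and optional horizontal/vertical
#' flips, identically to image and mask, preserving the original shape
#' (out-of-bounds filled with background 0). The image is resampled
#' bilinearly; the mask by nearest neighbour and re-binarised at 0.5.
#'
#' @param image,mask equal-shaped matrices.
#' @param thetaDeg rotation angle in degrees, in `[-180, 180]`.
#' @param zoom zoom factor in `[0.1, 2]` (< 1 zooms out).
#' @param flipH,flipV horizontal / vertical flips.
#' @return list with transformed `image` and binary `mask`.
#' @examples
#' m <- matrix(0, 8, 8); m[3:5, 3:5] <- 1
#' augmentPair(m, m, thetaDeg = 90, zoom = 1)$mask
#' @export
augmentPair <- function(image, mask, thetaDeg = 0, zoom = 1,
                        flipH = FALSE, flipV = FALSE) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask must have the same shape")
  img <- .affineSample(image, thetaDeg, zoom, flipH, flipV, bilinear = TRUE)
  msk <- .affineSample(mask, thetaDeg, zoom, flipH, flipV, bilinear = FALSE)
  list(image = img, mask = (msk >= 0.5) * 1)
}

#' Sample a random augmentation from the training policy
#'
#' Draws one rotation in `[-180, 180]` degrees, one zoom factor in
#' `[0.1, 2.0]` and independent horizontal/vertical flips from the current
#' RNG stream and applies them via [augmentPair()].
#'
#' @param image,mask equal-shaped matrices.
#' @return list with `image`, `mask` and the sampled `params`.
#' @export
augmentRandom <- function(image, mask) {
  theta <- runif(1, -180, 180)
  zoom <- runif(1, 0.1, 2.0)
  flips <- runif(2) < 0.5
  out <- augmentPair(image, mask, theta, zoom, flips[1], flips[2])
  out$params <- list(thetaDeg = theta, zoom = zoom,
                     flipH = flips[1], flipV = flips[2])
  out
}
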