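#' @include fusion.R
NULL

#' Pixelwise confusion counts between two binary masks
#'
#' @param predMask,truthMask equally shaped binary arrays.
#' @return named numeric vector (TP, FP, FN, TN); the four counts sum to the
#'   pixel count.
#' @export
confusionCounts <- function(predMask, truthMask) {
  if (!identical(dim(predMask), dim(truthMask)))
    stop("masks must have the same shape")
  if (!all(predMask %in% c(0, 1)) || !all(truthMask %in% c(0, 1)))
    stop("masks must be binary")
  p <- predMask == 1
  t <- truthMask == 1
  c(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

#' Overlap metrics from confusion counts
#'
#' `J = TP / (TP + FP + FN)`, `D = 2 TP / (2 TP + FP + FN)`,
#' `Sen = TP / (TP + FN)`. Undefined ratios (all-zero denominators) are
#' returned as `NA` with a notice, never as a silent 0.
#'
#' @param TP,FP,FN non-negative counts.
#' @return named numeric vector (jaccard, dice, sensitivity).
#' @export
overlapMetrics <- function(TP, FP, FN) {
  TP <- unname(TP); FP <- unname(FP); FN <- unname(FN)
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  jac <- dice <- sen <- NA_real_
  if (TP + FP + FN > 0) {
    jac <- TP / (TP + FP + FN)
    dice <- 2 * TP / (2 * TP + FP + FN)
  } else {
    message("overlapMetrics: empty union, Jaccard/Dice undefined (NA)")
  }
  if (TP + FN > 0) sen <- TP / (TP + FN)
  else message("overlapMetrics: empty reference, sensitivity undefined (NA)")
  c(jaccard = jac, dice = dice, sensitivity = sen)
}

#' Symmetric Hausdorff distance between two masks, in mm
#'
#' `max(h(A, B), h(B, A))` with `h(A, B)` the maximum over foreground pixels
#' of A of the Euclidean distance to the nearest foreground pixel of B,
#' pixel coordinates scaled by the in-plane spacing `(dx, dy)`. The exact
#' maximum Hausdorff distance (not a percentile variant).
#'
#' @param maskA,maskB equally shaped binary matrices.
#' @param pixelSpacingMM (dx, dy) in mm; `dx` scales columns, `dy` rows.
#' @return distance in mm, or `NA` (with a notice) if either mask is empty.
#' @export
hausdorffMM <- function(maskA, maskB, pixelSpacingMM = c(1, 1)) {
  if (!identical(dim(maskA), dim(maskB)))
    stop("masks must have the same shape")
  a <- which(maskA == 1, arr.ind = TRUE)
  b <- which(maskB == 1, arr.ind = TRUE)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    message("hausdorffMM: empty mask, distance undefined (NA)")
    return(NA_real_)
  }
  ay <- a[, 1] * pixelSpacingMM[2]; ax <- a[, 2] * pixelSpacingMM[1]
  by <- b[, 1] * pixelSpacingMM[2]; bx <- b[, 2] * pixelSpacingMM[1]
  d2 <- outer(ay, by, `-`)^2 + outer(ax, bx, `-`)^2
  sqrt(max(max(apply(d2, 1L, min)), max(apply(d2, 2L, min))))
}

#' Segmented brain volume of a mask stack, in cm^3
#'
#' Sums the foreground pixel count over all slices and multiplies by the
#' voxel volume `dx * dy * dz` (mm^3), divided by 1000.
#'
#' @param maskStack binary `(S, H, W)` array (a single slice matrix is
#'   treated as one slice).
#' @param pixelSpacingMM (dx, dy) in mm.
#' @param sliceThicknessMM dz in mm.
#' @return volume in cm^3.
#' @export
brainVolumeCm3 <- function(maskStack, pixelSpacingMM, sliceThicknessMM) {
  if (!all(maskStack %in% c(0, 1))) stop("mask stack must be binary")
  stopifnot(all(pixelSpacingMM > 0), sliceThicknessMM > 0)
  sum(maskStack) * pixelSpacingMM[1] * pixelSpacingMM[2] * sliceThicknessMM / 1000
}

#' Evaluate one case from fused probability maps
#'
#' Binarises each slice at `threshold`; Jaccard, Dice and sensitivity are
#' computed per slice on slices whose ground truth contains foreground and
#' averaged over the case, as is the per-slice Hausdorff distance in mm
#' (slices where either mask is empty are excluded from the HD average).
#' Volumes are computed from the full stacks, and `MAVD = |V_auto - V_manual|`.
#'
#' @param probStack fused probability maps, `(S, H, W)`.
#' @param truthStack aligned binary ground truth, `(S, H, W)`.
#' @param pixelSpacingMM (dx, dy) in mm.
#' @param sliceThicknessMM dz in mm.
#' @param threshold binarisation threshold.
#' @return one-row data.frame: jaccard, dice, sensitivity, hausdorff_mm,
#'   mavd_cm3, volume_auto_cm3, volume_manual_cm3, n_slices_evaluated.
#' @export
evaluateCase <- function(probStack, truthStack, pixelSpacingMM,
                         sliceThicknessMM, threshold = 0.5) {
  if (!identical(dim(probStack), dim(truthStack)))
    stop("probability and truth stacks must be aligned")
  S <- dim(truthStack)[1]
  fg <- vapply(seq_len(S), function(s) sum(truthStack[s, , ]) > 0, logical(1))
  if (!any(fg))
    stop("case has no slice with ground-truth foreground; excluded from evaluation")
  predStack <- binarizeMap(probStack, threshold)
  j <- d <- sen <- hd <- numeric(0)
  for (s in which(fg)) {
    cc <- confusionCounts(predStack[s, , ], truthStack[s, , ])
    om <- overlapMetrics(cc["TP"], cc["FP"], cc["FN"])
    j <- c(j, om["jaccard"]); d <- c(d, om["dice"]); sen <- c(sen, om["sensitivity"])
    if (sum(predStack[s, , ]) > 0)
      hd <- c(hd, hausdorffMM(predStack[s, , ], truthStack[s, , ],
                              pixelSpacingMM))
  }
  vAuto <- brainVolumeCm3(predStack, pixelSpacingMM, sliceThicknessMM)
  vMan <- brainVolumeCm3(truthStack, pixelSpacingMM, sliceThicknessMM)
  data.frame(jaccard = mean(j), dice = mean(d), sensitivity = mean(sen),
             hausdorff_mm = if (length(hd)) mean(hd) else NA_real_,
             mavd_cm3 = abs(vAuto - vMan),
             volume_auto_cm3 = vAuto, volume_manual_cm3 = vMan,
             n_slices_evaluated = sum(fg))
}

#' Volume agreement statistics (correlation and Bland-Altman limits)
#'
#' @param volumesAuto,volumesManual equal-length numeric vectors (n >= 3) of
#'   automated and manual volumes in cm^3.
#' @return one-row data.frame: r_squared (squared Pearson correlation, `NA`
#'   if either vector is constant), mean_diff_cm3 (mean of auto - manual),
#'   loa_low_cm3 / loa_high_cm3 (mean difference +/- 1.96 sample sd), n_cases.
#' @examples
#' volumeAgreement(c(10, 20, 31), c(9, 18, 28))
#' @export
volumeAgreement <- function(volumesAuto, volumesManual) {
  if (length(volumesAuto) != length(volumesManual))
    stop("volume vectors must have equal length")
  n <- length(volumesAuto)
  if (n < 3L) stop("at least 3 cases are required")
  r2 <- if (sd(volumesAuto) == 0 || sd(volumesManual) == 0) {
    message("volumeAgreement: zero variance, r_squared undefined (NA)")
    NA_real_
  } else cor(volumesAuto, volumesManual)^2
  d <- volumesAuto - volumesManual
  m <- mean(d)
  s <- sd(d)
  data.frame(r_squared = r2, mean_diff_cm3 = m,
             loa_low_cm3 = m - 1.96 * s, loa_high_cm3 = m + 1.96 * s,
             n_cases = n)
}
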