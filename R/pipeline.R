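#' @include training.R metrics.R io.R
NULL

.mapNames <- c("dux", "du", "u", "d", "f", "avg", "med", "max")
.fusionOpOf <- c(avg = "mean", med = "median", max = "max")

# Slices of the given subjects as (H, W, N) arrays of images and masks.
.gatherSlices <- function(stacks, ids) {
  sel <- stacks[vapply(stacks, subjectID, character(1)) %in% ids]
  imgs <- list(); msks <- list()
  for (st in sel) {
    sl <- slices(st); mk <- maskStack(st)
    for (s in seq_len(nSlices(st))) {
      imgs[[length(imgs) + 1L]] <- sl[s, , ]
      msks[[length(msks) + 1L]] <- mk[s, , ]
    }
  }
  list(images = imgs, masks = msks)
}

#' Evaluate one subject under every head and fusion operator
#'
#' Runs the model over the stack and scores the five head maps plus the
#' requested fused maps with [evaluateCase()].
#'
#' @param model a [SimouModel-class].
#' @param stack a [VolumeStack-class] with ground truth present.
#' @param fusionOps subset of `c("avg", "med", "max")`.
#' @param threshold binarisation threshold.
#' @return data.frame with one row per map.
#' @export
evaluateSubject <- function(model, stack, fusionOps = c("avg", "med", "max"),
                            threshold = 0.5) {
  pv <- predictVolume(model, stack)
  maps <- pv
  for (op in fusionOps) maps[[op]] <- fuseArrays(pv, .fusionOpOf[[op]])
  rows <- lapply(names(maps), function(nm) {
    cm <- evaluateCase(maps[[nm]], maskStack(stack), pixelSpacing(stack),
                       sliceThickness(stack), threshold)
    cbind(data.frame(subject_id = subjectID(stack), map = nm,
                     stringsAsFactors = FALSE), cm)
  })
  do.call(rbind, rows)
}

#' Summarise per-case metrics as mean +/- sd per prediction map
#'
#' @param metrics data.frame from [evaluateSubject()] /
#'   [runCrossValidation()].
#' @return data.frame with one row per map and mean/sd columns per metric.
#' @export
summarizeCaseMetrics <- function(metrics) {
  cols <- c("jaccard", "dice", "sensitivity", "hausdorff_mm", "mavd_cm3")
  out <- lapply(split(metrics, metrics$map), function(g) {
    row <- data.frame(map = g$map[1], n = nrow(g), stringsAsFactors = FALSE)
    for (cl in cols) {
      row[[paste0(cl, "_mean")]] <- mean(g[[cl]], na.rm = TRUE)
      row[[paste0(cl, "_sd")]] <- sd(g[[cl]], na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, out)
  out[order(match(out$map, .mapNames)), , drop = FALSE]
}

#' Subject-grouped stratified cross-validation of the full pipeline
#'
#' For every fold: holds the fold's subjects out as the test set, splits the
#' remaining subjects into training and validation (about one in five
#' subjects, at least one, for early stopping), trains a freshly initialised
#' model and evaluates every head and fused map on each held-out subject.
#'
#' @param stacks list of [VolumeStack-class] with ground truth.
#' @param manifest manifest data.frame (see [generateDataset()]).
#' @param k fold count.
#' @param spec a [NetworkSpec-class] shared by all folds.
#' @param config a [TrainingConfig-class].
#' @param fusionOps fused maps to evaluate.
#' @param threshold binarisation threshold.
#' @param seed seed controlling folding, splits and initialisation.
#' @param verbose print progress.
#' @return list: `metrics` (per subject x map), `summary`
#'   (mean +/- sd per map), `plan` ([FoldPlan-class]), `histories`,
#'   `models`.
#' @export
runCrossValidation <- function(stacks, manifest, k = 3L,
                               spec = simouSpec(c(64, 64), 1 / 8),
                               config = trainingConfig(),
                               fusionOps = c("avg", "med", "max"),
                               threshold = 0.5, seed = 1L, verbose = FALSE) {
  plan <- stratifiedGroupFolds(manifest, k, seed)
  ids <- names(plan@assignments)
  allMetrics <- list()
  histories <- list()
  models <- list()
  for (i in seq_len(k)) {
    testIDs <- foldSubjects(plan, i)
    restIDs <- setdiff(ids, testIDs)
    nVal <- max(1L, ceiling(length(restIDs) / 5))
    valIDs <- withSeed(subSeed(seed, 1000 + i), sample(restIDs, nVal))
    trainIDs <- setdiff(restIDs, valIDs)
    tr <- .gatherSlices(stacks, trainIDs)
    va <- .gatherSlices(stacks, valIDs)
    model <- buildModel(spec, seed = subSeed(seed, 2000 + i))
    cfg <- config
    cfg@seed <- subSeed(seed, 3000 + i)
    fit <- trainModel(model, tr$images, tr$masks, va$images, va$masks, cfg,
                      verbose = verbose)
    histories[[i]] <- fit$history
    models[[i]] <- fit$model
    for (sid in testIDs) {
      st <- stacks[[which(vapply(stacks, subjectID, character(1)) == sid)]]
      rows <- tryCatch(
        evaluateSubject(fit$model, st, fusionOps, threshold),
        error = function(e) {
          message("subject ", sid, " excluded: ", conditionMessage(e))
          NULL
        })
      if (!is.null(rows)) {
        rows$fold <- i
        allMetrics[[length(allMetrics) + 1L]] <- rows
      }
    }
    if (verbose) message("fold ", i, " done (best epoch ", fit$bestEpoch, ")")
  }
  metrics <- do.call(rbind, allMetrics)
  list(metrics = metrics, summary = summarizeCaseMetrics(metrics),
       plan = plan, histories = histories, models = models)
}
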