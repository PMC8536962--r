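#' @include AllClasses.R
NULL

.fusionOps <- c("mean", "median", "max")

# Per-pixel fusion of a list of equally shaped probability arrays.
fuseArrays <- function(maps, opName) {
  if (!opName %in% .fusionOps)
    stop("unknown fusion operator '", opName, "'; valid operators: ",
         paste(.fusionOps, collapse = ", "))
  d <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), d), logical(1))))
    stop("all prediction maps must share the same shape")
  m <- vapply(maps, as.numeric, numeric(prod(d)))
  v <- switch(opName,
              mean = rowMeans(m),
              median = apply(m, 1L, stats::median),
              max = do.call(pmax, asplit(m, 2L)))
  array(v, d)
}

#' Fuse the five prediction maps into an ensemble map
#'
#' Per-pixel mean, median (the 3rd order statistic of 5) or maximum over the
#' five prediction maps — the within-network ensemble that produces
#' `P_AVG`, `P_MED` and `P_MAX`.
#'
#' @param predictions a [PredictionSet-class], or a named list of five
#'   equally shaped probability arrays.
#' @param opName `"mean"`, `"median"` or `"max"`.
#' @param source identifier recorded in the result.
#' @return A [FusedMap-class] when the inputs are matrices; an array of the
#'   common shape otherwise.
#' @examples
#' m <- matrix(0.2, 2, 2)
#' ps <- predictionSet(m, m + 0.1, m + 0.2, m + 0.3, m - 0.1)
#' fusePredictions(ps, "median")
#' @export
fusePredictions <- function(predictions, opName = c("mean", "median", "max"),
                            source = "predictions") {
  opName <- match.arg(opName)
  maps <- if (is(predictions, "PredictionSet")) predictionMaps(predictions)
          else predictions
  if (length(maps) != 5L) stop("exactly five prediction maps are required")
  v <- fuseArrays(maps, opName)
  if (length(dim(maps[[1]])) == 2L)
    new("FusedMap", values = as.matrix(v), opName = opName,
        source = as.character(source))
  else v
}

#' Threshold a probability map into a binary mask
#'
#' A pixel becomes foreground iff its value is `>= threshold` (ties go to
#' foreground).
#'
#' @param map probability array in `[0, 1]`, or a [FusedMap-class].
#' @param threshold scalar in (0, 1).
#' @return binary array of the same shape.
#' @export
binarizeMap <- function(map, threshold = 0.5) {
  if (is(map, "FusedMap")) map <- map@values
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  (map >= threshold) * 1
}
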