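#' @include AllClasses.R
NULL

# 2-adic valuation, used to decide how many stride-2 transitions an input
# resolution supports.
.val2 <- function(n) {
  v <- 0L
  while (n %% 2L == 0L && n > 1L) { n <- n %/% 2L; v <- v + 1L }
  v
}

# Shared builder: transitions are stride 2 until the resolution would drop
# below 1 px (or stops being divisible), and stride 1 thereafter, so very deep
# specs remain valid on moderate input sizes (the two deepest levels of the
# default 8-level network sit at 1 x 1 px for 64 x 64 inputs).
.buildSpec <- function(inputShape, widthMultiplier, baseChannels,
                       dropoutRate, sideHeadChannels, postConcatChannels,
                       activation) {
  stopifnot(widthMultiplier > 0)
  H <- as.integer(inputShape[1]); W <- as.integer(inputShape[2])
  L <- length(baseChannels)
  nHalve <- min(L - 1L, .val2(H), .val2(W),
                floor(log2(min(H, W))))
  req <- 2L^min(L - 1L, floor(log2(min(H, W))))
  if (H %% req != 0L || W %% req != 0L)
    stop("input shape ", H, " x ", W, " is not divisible by the required ",
         "downsampling factor 2^", log2(req), " = ", req)
  channels <- pmax(1L, as.integer(round(widthMultiplier * baseChannels)))
  poolStrides <- rep(1L, L - 1L)
  if (nHalve > 0L) poolStrides[seq_len(nHalve)] <- 2L
  depthDown <- c(0L, cumsum(poolStrides == 2L))  # depth of levels 1..L
  taps <- data.frame(
    index = seq_len(2L * L - 1L),
    path = c(rep("down", L), rep("up", L - 1L)),
    level = c(seq_len(L), rev(seq_len(L - 1L))),
    stringsAsFactors = FALSE)
  taps$depth <- depthDown[taps$level]
  headDefs <- list(du = seq_len(2L * L - 1L),
                   dux = seq_len(2L * L - 2L),
                   d = seq_len(L),
                   u = seq.int(L + 1L, 2L * L - 1L))
  if (is.null(postConcatChannels))
    postConcatChannels <- max(1L, as.integer(round(64 * widthMultiplier)))
  new("NetworkSpec",
      inputShape = c(H, W, 1L),
      nLevels = L,
      channels = channels,
      poolStrides = poolStrides,
      dropoutRate = dropoutRate,
      dropoutDown = seq.int(L - 2L, L),
      dropoutUp = seq_len(min(3L, L - 1L)),
      activation = activation,
      sideTaps = taps,
      headDefs = headDefs,
      sideHeadChannels = as.integer(sideHeadChannels),
      postConcatChannels = as.integer(postConcatChannels))
}

#' Build the default SIMOU network specification
#'
#' Eight contracting levels with feature channels
#' `32, 32, 64, 64, 128, 128, 256, 512` (scaled by `widthMultiplier`), each
#' level two 3x3 size-preserving convolutions with ELU followed by batch
#' normalisation, 2x2/stride-2 max pooling between levels, transposed-
#' convolution upsampling with skip concatenation on the expansive path,
#' dropout on the last three contracting and first three expansive levels,
#' one side tap per contracting step (`s1..s8`) and per expansive step
#' (`s9..s15`): 15 side outputs and 5 prediction heads in total.
#'
#' @param inputShape (H, W) or (H, W, 1) input size in pixels.
#' @param widthMultiplier positive factor scaling every channel count
#'   (including the post-concatenation 64-filter head convolutions).
#' @param dropoutRate dropout fraction (default 0.5).
#' @param sideHeadChannels channels each side output is reduced to before
#'   concatenation (default 1: one score map per scale).
#' @param postConcatChannels filters of the two 3x3 head convolutions;
#'   defaults to `round(64 * widthMultiplier)`.
#' @return A validated [NetworkSpec-class].
#' @examples
#' spec <- simouSpec(c(64, 64), widthMultiplier = 1/8)
#' nSideTaps(spec)
#' specChannels(spec)
#' @export
simouSpec <- function(inputShape = c(64, 64), widthMultiplier = 1,
                      dropoutRate = 0.5, sideHeadChannels = 1L,
                      postConcatChannels = NULL) {
  .buildSpec(inputShape, widthMultiplier,
             baseChannels = c(32, 32, 64, 64, 128, 128, 256, 512),
             dropoutRate = dropoutRate,
             sideHeadChannels = sideHeadChannels,
             postConcatChannels = postConcatChannels,
             activation = "elu")
}

#' Build a SIMO-wrapped plain U-Net specification
#'
#' The classical 5-level U-Net (base channels 64, 128, 256, 512, 1024, scaled
#' by `widthMultiplier`) wrapped with the same single-input multi-output
#' machinery: 9 side taps (5 contracting + 4 expansive) and the analogous
#' five heads (all taps, all-but-last, contracting-only, expansive-only, and
#' the final decoder map).
#'
#' @inheritParams simouSpec
#' @return A validated [NetworkSpec-class].
#' @examples
#' spec <- simoUnetSpec(c(64, 64), widthMultiplier = 1/16)
#' nSideTaps(spec)
#' @export
simoUnetSpec <- function(inputShape = c(64, 64), widthMultiplier = 1,
                         dropoutRate = 0.5, sideHeadChannels = 1L,
                         postConcatChannels = NULL) {
  .buildSpec(inputShape, widthMultiplier,
             baseChannels = c(64, 128, 256, 512, 1024),
             dropoutRate = dropoutRate,
             sideHeadChannels = sideHeadChannels,
             postConcatChannels = postConcatChannels,
             activation = "elu")
}

#' Draw a convolution kernel with He/Gaussian initialisation
#'
#' Samples `kh * kw * cin * cout` weights from a zero-mean Gaussian with
#' standard deviation `sqrt(2 / eta)`, where `eta = kh * kw * cin` is the
#' number of incoming nodes of one neuron. Consumes the current RNG stream.
#'
#' @param kh,kw kernel height and width.
#' @param cin,cout input and output channels.
#' @return numeric array of dim `(kh, kw, cin, cout)`.
#' @examples
#' set.seed(1)
#' sd(drawConvKernel(3, 3, 32, 4))  # ~ sqrt(2/288)
#' @export
drawConvKernel <- function(kh, kw, cin, cout) {
  eta <- kh * kw * cin
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / eta)),
        c(kh, kw, cin, cout))
}

.convParam <- function(kh, kw, cin, cout) {
  list(W = drawConvKernel(kh, kw, cin, cout), b = numeric(cout))
}

.bnParam <- function(ch) list(gamma = rep(1, ch), beta = rep(0, ch))
.bnState <- function(ch) list(mean = rep(0, ch), var = rep(1, ch))

# Number of input channels of the expansive block j (before up-projection).
.upInChannels <- function(spec, j) {
  L <- spec@nLevels
  if (j == 1L) spec@channels[L] else spec@channels[L - j + 1L]
}

#' Initialise all network parameters
#'
#' Every convolution kernel (including transposed and 1x1 convolutions) is
#' drawn from a zero-mean Gaussian with standard deviation `sqrt(2 / eta)`,
#' `eta` the number of incoming nodes per neuron; biases start at zero and
#' batch-normalisation at identity. Deterministic given `seed`.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed integer seed.
#' @return list with elements `params` (nested parameter arrays) and `state`
#'   (batch-normalisation running statistics).
#' @export
initWeights <- function(spec, seed = 1L) {
  validObject(spec)
  L <- spec@nLevels
  ch <- spec@channels
  shc <- spec@sideHeadChannels
  pc <- spec@postConcatChannels
  withSeed(seed, {
    down <- vector("list", L)
    downState <- vector("list", L)
    for (l in seq_len(L)) {
      cin <- if (l == 1L) 1L else ch[l - 1L]
      down[[l]] <- list(conv1 = .convParam(3, 3, cin, ch[l]),
                        conv2 = .convParam(3, 3, ch[l], ch[l]),
                        bn = .bnParam(ch[l]))
      downState[[l]] <- .bnState(ch[l])
    }
    up <- vector("list", L - 1L)
    upState <- vector("list", L - 1L)
    for (j in seq_len(L - 1L)) {
      lvl <- L - j
      cin <- .upInChannels(spec, j)
      stride <- spec@poolStrides[lvl]
      upconv <- if (stride == 2L) .convParam(2, 2, cin, ch[lvl])
                else .convParam(1, 1, cin, ch[lvl])
      up[[j]] <- list(up = upconv,
                      conv1 = .convParam(3, 3, 2L * ch[lvl], ch[lvl]),
                      conv2 = .convParam(3, 3, ch[lvl], ch[lvl]),
                      bn = .bnParam(ch[lvl]))
      upState[[j]] <- .bnState(ch[lvl])
    }
    side <- vector("list", 2L * L - 1L)
    for (n in seq_len(2L * L - 1L)) {
      tap <- spec@sideTaps[n, ]
      tapCh <- ch[tap$level]
      stages <- if (tap$depth > 0)
        lapply(seq_len(tap$depth), function(k) .convParam(2, 2, shc, shc))
      else list()
      side[[n]] <- list(reduce = .convParam(1, 1, tapCh, shc), stages = stages)
    }
    head <- lapply(spec@headDefs, function(members) {
      list(conv1 = .convParam(3, 3, length(members) * shc, pc),
           conv2 = .convParam(3, 3, pc, pc),
           out = .convParam(1, 1, pc, 1))
    })
    final <- list(out = .convParam(1, 1, ch[1L], 1))
    list(params = list(down = down, up = up, side = side,
                       head = head, final = final),
         state = list(down = downState, up = upState))
  })
}

#' Instantiate an executable model from a specification
#'
#' @param spec a [NetworkSpec-class].
#' @param seed initialisation seed; all randomness in the returned model's
#'   parameters is a pure function of it.
#' @return A [SimouModel-class].
#' @examples
#' model <- buildModel(simouSpec(c(16, 16), 1/16), seed = 1)
#' model
#' @export
buildModel <- function(spec, seed = 1L) {
  init <- initWeights(spec, seed)
  new("SimouModel", spec = spec, params = init$params, state = init$state,
      seed = as.integer(seed))
}
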