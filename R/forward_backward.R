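#' @include nn_ops.R
NULL

# One convolutional block: conv3x3 -> ELU -> conv3x3 -> ELU -> batch norm
# (-> dropout while training). Used by both the contracting and (after skip
# concatenation) the expansive path.
blockFwd <- function(p, x, bnState, training, useDrop, rate) {
  a1 <- convFwd(p$conv1, x); e1 <- eluFwd(a1)
  a2 <- convFwd(p$conv2, e1); e2 <- eluFwd(a2)
  bn <- bnFwd(p$bn, e2, bnState, training)
  out <- bn$y; mask <- NULL
  if (useDrop && training && rate > 0) {
    dr <- dropoutFwd(out, rate)
    out <- dr$y; mask <- dr$mask
  }
  list(x = x, a1 = a1, e1 = e1, a2 = a2, e2 = e2, bn = bn,
       mask = mask, out = out, state = bn$state)
}

blockBwd <- function(p, cache, dout) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  bnb <- bnBwd(p$bn, cache$bn, dout)
  da2 <- eluBwd(cache$e2, cache$a2, bnb$dx)
  c2 <- convBwd(p$conv2, cache$e1, da2)
  da1 <- eluBwd(cache$e1, cache$a1, c2$dx)
  c1 <- convBwd(p$conv1, cache$x, da1)
  list(dx = c1$dx,
       grads = list(conv1 = list(W = c1$dw, b = c1$db),
                    conv2 = list(W = c2$dw, b = c2$db),
                    bn = list(gamma = bnb$dgamma, beta = bnb$dbeta)))
}

.addG <- function(a, b) if (is.null(a)) b else a + b

# Full forward pass. `x` is (H, W, 1, B). Returns the five head
# probabilities, every intermediate needed by modelBackward, and the updated
# batch-norm running state.
modelForward <- function(params, state, spec, x, training = FALSE) {
  L <- spec@nLevels
  rate <- spec@dropoutRate
  taps <- vector("list", 2L * L - 1L)
  downCache <- vector("list", L)
  poolIdx <- vector("list", L - 1L)
  cur <- x
  for (l in seq_len(L)) {
    cc <- blockFwd(params$down[[l]], cur, state$down[[l]], training,
                   l %in% spec@dropoutDown, rate)
    state$down[[l]] <- cc$state
    taps[[l]] <- cc$out
    downCache[[l]] <- cc
    if (l < L) {
      if (spec@poolStrides[l] == 2L) {
        p <- cpp_maxpool2_fwd(cc$out)
        poolIdx[[l]] <- p$idx
        cur <- p$y
      } else cur <- cc$out
    }
  }
  upCache <- vector("list", L - 1L)
  for (j in seq_len(L - 1L)) {
    lvl <- L - j
    xin <- if (j == 1L) taps[[L]] else taps[[L + j - 1L]]
    pj <- params$up[[j]]
    u2 <- if (spec@poolStrides[lvl] == 2L) convtFwd(pj$up, xin)
          else convFwd(pj$up, xin)
    cat <- concatChannels(list(u2, taps[[lvl]]))
    cc <- blockFwd(pj[c("conv1", "conv2", "bn")], cat, state$up[[j]],
                   training, j %in% spec@dropoutUp, rate)
    state$up[[j]] <- cc$state
    taps[[L + j]] <- cc$out
    upCache[[j]] <- c(cc, list(xin = xin, u2 = u2))
  }
  zf <- convFwd(params$final$out, taps[[2L * L - 1L]])
  sideCache <- vector("list", 2L * L - 1L)
  fullres <- vector("list", 2L * L - 1L)
  for (n in seq_len(2L * L - 1L)) {
    sp <- params$side[[n]]
    cur <- convFwd(sp$reduce, taps[[n]])
    stageIns <- vector("list", length(sp$stages))
    for (k in seq_along(sp$stages)) {
      stageIns[[k]] <- cur
      cur <- convtFwd(sp$stages[[k]], cur)
    }
    sideCache[[n]] <- stageIns
    fullres[[n]] <- cur
  }
  headCache <- list()
  logits <- list()
  for (h in names(spec@headDefs)) {
    hp <- params$head[[h]]
    cat <- concatChannels(fullres[spec@headDefs[[h]]])
    a1 <- convFwd(hp$conv1, cat); e1 <- eluFwd(a1)
    a2 <- convFwd(hp$conv2, e1); e2 <- eluFwd(a2)
    z <- convFwd(hp$out, e2)
    headCache[[h]] <- list(cat = cat, a1 = a1, e1 = e1, a2 = a2, e2 = e2)
    logits[[h]] <- z
  }
  logits$f <- zf
  probs <- lapply(logits, sigmoid)
  list(probs = probs, logits = logits, taps = taps, state = state,
       cache = list(down = downCache, up = upCache, pool = poolIdx,
                    side = sideCache, fullres = fullres, head = headCache))
}

# Backward pass. `dLogits` is a named list (dux, du, u, d, f) of gradients
# with respect to the head logits, shaped like the input batch. Returns the
# parameter gradients in the same nested structure as `params`.
modelBackward <- function(params, spec, fwd, dLogits) {
  L <- spec@nLevels
  cache <- fwd$cache
  taps <- fwd$taps
  nT <- 2L * L - 1L
  tapGrad <- vector("list", nT)
  frGrad <- vector("list", nT)
  grads <- list(down = vector("list", L), up = vector("list", L - 1L),
                side = vector("list", nT), head = list(), final = NULL)
  # final (main decoder) head
  cf <- convBwd(params$final$out, taps[[nT]], dLogits$f)
  grads$final <- list(out = list(W = cf$dw, b = cf$db))
  tapGrad[[nT]] <- .addG(tapGrad[[nT]], cf$dx)
  # side-output heads
  shc <- spec@sideHeadChannels
  for (h in names(spec@headDefs)) {
    hp <- params$head[[h]]
    hc <- cache$head[[h]]
    co <- convBwd(hp$out, hc$e2, dLogits[[h]])
    da2 <- eluBwd(hc$e2, hc$a2, co$dx)
    c2 <- convBwd(hp$conv2, hc$e1, da2)
    da1 <- eluBwd(hc$e1, hc$a1, c2$dx)
    c1 <- convBwd(hp$conv1, hc$cat, da1)
    grads$head[[h]] <- list(conv1 = list(W = c1$dw, b = c1$db),
                            conv2 = list(W = c2$dw, b = c2$db),
                            out = list(W = co$dw, b = co$db))
    members <- spec@headDefs[[h]]
    pieces <- splitChannels(c1$dx, rep(shc, length(members)))
    for (i in seq_along(members))
      frGrad[[members[i]]] <- .addG(frGrad[[members[i]]], pieces[[i]])
  }
  # side taps: back through the upsampling stages and the 1x1 reduction
  for (n in seq_len(nT)) {
    sp <- params$side[[n]]
    g <- frGrad[[n]]
    stgrads <- vector("list", length(sp$stages))
    for (k in rev(seq_along(sp$stages))) {
      cb <- convtBwd(sp$stages[[k]], cache$side[[n]][[k]], g)
      stgrads[[k]] <- list(W = cb$dw, b = cb$db)
      g <- cb$dx
    }
    rb <- convBwd(sp$reduce, taps[[n]], g)
    grads$side[[n]] <- list(reduce = list(W = rb$dw, b = rb$db),
                            stages = stgrads)
    tapGrad[[n]] <- .addG(tapGrad[[n]], rb$dx)
  }
  # expansive path
  for (j in rev(seq_len(L - 1L))) {
    lvl <- L - j
    pj <- params$up[[j]]
    uc <- cache$up[[j]]
    bb <- blockBwd(pj[c("conv1", "conv2", "bn")], uc, tapGrad[[L + j]])
    ch <- spec@channels[lvl]
    sp2 <- splitChannels(bb$dx, c(ch, ch))
    tapGrad[[lvl]] <- .addG(tapGrad[[lvl]], sp2[[2]])
    ub <- if (spec@poolStrides[lvl] == 2L) convtBwd(pj$up, uc$xin, sp2[[1]])
          else convBwd(pj$up, uc$xin, sp2[[1]])
    grads$up[[j]] <- c(bb$grads, list(up = list(W = ub$dw, b = ub$db)))
    tgt <- if (j == 1L) L else L + j - 1L
    tapGrad[[tgt]] <- .addG(tapGrad[[tgt]], ub$dx)
  }
  # contracting path
  for (l in rev(seq_len(L))) {
    bb <- blockBwd(params$down[[l]], cache$down[[l]], tapGrad[[l]])
    grads$down[[l]] <- bb$grads
    if (l > 1L) {
      dprev <- if (spec@poolStrides[l - 1L] == 2L)
        cpp_maxpool2_bwd(cache$pool[[l - 1L]], bb$dx, dim(taps[[l - 1L]]))
      else bb$dx
      tapGrad[[l - 1L]] <- .addG(tapGrad[[l - 1L]], dprev)
    }
  }
  grads
}

# ---- parameter-tree arithmetic (leaves are numeric arrays/vectors) --------

zeroLike <- function(p) {
  if (is.list(p)) lapply(p, zeroLike)
  else { z <- p; z[] <- 0; z }
}

# RMSprop: v <- rho v + (1 - rho) g^2 ; p <- p - lr g / (sqrt(v) + eps)
# Branches are matched by name where names exist, so the assembly order of
# the gradient tree does not matter.
rmspropStep <- function(p, g, v, lr, rho, eps = 1e-7) {
  if (is.list(p)) {
    keys <- if (is.null(names(p))) seq_along(p) else names(p)
    for (k in keys) {
      if (is.null(p[[k]])) next
      st <- rmspropStep(p[[k]], g[[k]], v[[k]], lr, rho, eps)
      p[[k]] <- st$p
      v[[k]] <- st$v
    }
    list(p = p, v = v)
  } else {
    v2 <- rho * v + (1 - rho) * g * g
    list(p = p - lr * g / (sqrt(v2) + eps), v = v2)
  }
}

#' Run the network on a batch of images
#'
#' @param model a [SimouModel-class].
#' @param images `(H, W)` matrix, `(H, W, N)` array or list of matrices.
#' @param batchSize images per forward pass.
#' @return named list (dux, du, u, d, f) of `(H, W, N)` probability arrays.
#' @seealso [predictSlice()] for a single-slice [PredictionSet-class].
#' @export
predictModel <- function(model, images, batchSize = 16L) {
  x <- asImageBatch(images)
  N <- dim(x)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  out <- lapply(c("dux", "du", "u", "d", "f"),
                function(h) array(0, c(H, W, N)))
  names(out) <- c("dux", "du", "u", "d", "f")
  for (start in seq(1L, N, by = batchSize)) {
    idx <- seq.int(start, min(start + batchSize - 1L, N))
    fw <- modelForward(model@params, model@state, model@spec,
                       x[, , , idx, drop = FALSE], training = FALSE)
    for (h in names(out)) out[[h]][, , idx] <- fw$probs[[h]][, , 1L, ]
  }
  out
}

#' Predict a single slice as a prediction set
#'
#' @param model a [SimouModel-class].
#' @param image an `H x W` matrix.
#' @return A [PredictionSet-class] with the five probability maps.
#' @export
predictSlice <- function(model, image) {
  p <- predictModel(model, image)
  predictionSet(p$dux[, , 1], p$du[, , 1], p$u[, , 1], p$d[, , 1], p$f[, , 1])
}

#' Predict all slices of a volume
#'
#' @param model a [SimouModel-class].
#' @param stack a [VolumeStack-class].
#' @return named list (dux, du, u, d, f) of `(S, H, W)` probability arrays.
#' @export
predictVolume <- function(model, stack) {
  sl <- slices(stack)
  S <- dim(sl)[1]
  imgs <- array(0, c(dim(sl)[2], dim(sl)[3], S))
  for (s in seq_len(S)) imgs[, , s] <- sl[s, , ]
  p <- predictModel(model, imgs)
  lapply(p, function(a) {
    v <- array(0, c(S, dim(a)[1], dim(a)[2]))
    for (s in seq_len(S)) v[s, , ] <- a[, , s]
    v
  })
}

# Coerce matrices / (H, W, N) arrays / lists of matrices to (H, W, 1, N).
asImageBatch <- function(images) {
  if (is.list(images)) {
    H <- nrow(images[[1]]); W <- ncol(images[[1]])
    x <- array(0, c(H, W, 1L, length(images)))
    for (i in seq_along(images)) x[, , 1L, i] <- images[[i]]
    x
  } else if (length(dim(images)) == 2L) {
    array(images, c(dim(images), 1L, 1L))
  } else if (length(dim(images)) == 3L) {
    d <- dim(images)
    aperm(array(images, c(d[1], d[2], d[3], 1L)), c(1, 2, 4, 3))
  } else images
}
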