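#' @include architecture.R
NULL

# All activations/tensors are (H, W, C, B) numeric arrays; these wrappers
# keep dim attributes intact around the compiled kernels and provide the
# pure-R pieces (ELU, sigmoid, batch norm, dropout, channel concat).

convFwd <- function(p, x) cpp_conv2d_fwd(x, p$W, p$b)
convBwd <- function(p, x, dy) cpp_conv2d_bwd(x, p$W, dy)
convtFwd <- function(p, x) cpp_convt2_fwd(x, p$W, p$b)
convtBwd <- function(p, x, dy) cpp_convt2_bwd(x, p$W, dy)

eluFwd <- function(x) {
  y <- x
  neg <- x < 0
  y[neg] <- exp(x[neg]) - 1
  y
}

eluBwd <- function(y, x, dy) {
  g <- dy
  neg <- x < 0
  g[neg] <- dy[neg] * (y[neg] + 1)
  g
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Batch normalisation over (H, W, B) per channel. Training mode uses batch
# statistics (biased variance) and updates the running state with momentum;
# inference mode uses the running state.
.bnEps <- 1e-5
.bnMomentum <- 0.9

bnFwd <- function(p, x, state, training) {
  d <- dim(x); C <- d[3]
  xp <- aperm(x, c(1, 2, 4, 3))
  dim(xp) <- c(d[1] * d[2] * d[4], C)
  if (training) {
    mu <- colMeans(xp)
    v <- colMeans(xp * xp) - mu * mu
    v[v < 0] <- 0
    state$mean <- .bnMomentum * state$mean + (1 - .bnMomentum) * mu
    state$var <- .bnMomentum * state$var + (1 - .bnMomentum) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + .bnEps)
  xhat <- (xp - rep(mu, each = nrow(xp))) * rep(invstd, each = nrow(xp))
  yp <- xhat * rep(p$gamma, each = nrow(xp)) + rep(p$beta, each = nrow(xp))
  y <- array(yp, c(d[1], d[2], d[4], C))
  y <- aperm(y, c(1, 2, 4, 3))
  list(y = y, xhat = xhat, invstd = invstd, state = state, dims = d)
}

bnBwd <- function(p, cache, dy) {
  d <- cache$dims; C <- d[3]; N <- d[1] * d[2] * d[4]
  dyp <- aperm(dy, c(1, 2, 4, 3))
  dim(dyp) <- c(N, C)
  xhat <- cache$xhat
  dgamma <- colSums(dyp * xhat)
  dbeta <- colSums(dyp)
  dxhat <- dyp * rep(p$gamma, each = N)
  sum1 <- colSums(dxhat)
  sum2 <- colSums(dxhat * xhat)
  dxp <- (dxhat - rep(sum1 / N, each = N) - xhat * rep(sum2 / N, each = N)) *
    rep(cache$invstd, each = N)
  dx <- array(dxp, c(d[1], d[2], d[4], C))
  dx <- aperm(dx, c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropoutFwd <- function(x, rate) {
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

concatChannels <- function(xs) {
  d <- dim(xs[[1]])
  chs <- vapply(xs, function(x) dim(x)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(chs), d[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(chs[i]), ] <- xs[[i]]
    at <- at + chs[i]
  }
  out
}

splitChannels <- function(dy, chs) {
  at <- 0L
  out <- vector("list", length(chs))
  for (i in seq_along(chs)) {
    out[[i]] <- dy[, , at + seq_len(chs[i]), , drop = FALSE]
    at <- at + chs[i]
  }
  out
}
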