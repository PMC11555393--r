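# Numeric primitives for the runnable network.
#
# Internal tensor layout is [height, width, batch, channels]: R is
# column-major, so the (H*W*N) x C channel-matrix view needed by the
# convolution and batch-norm kernels is a zero-copy `dim<-`.  The
# public entry points ([forward()], [train()]) accept patches in the
# conventional [H, W, C, N] order and convert once per batch.
#
# All convolutions in the family are stride 1 with odd kernels and
# "same" padding, which is what these kernels implement; spatial
# down-sampling happens only in the 2x2 stride-2 ceil-mode pooling
# layers.  Every op returns its forward value plus whatever cache its
# backward pass needs; backward passes are exact (verified against
# finite differences in the test suite).

pad_hw <- function(x, p, value = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

#' Grouped 2-D convolution, stride 1, "same" padding
#'
#' Weights are stored as `[kh, kw, in/groups, out]`.  With `groups = 1`
#' this is a standard convolution; with `groups = g` the input and
#' output channels are partitioned into `g` independent slices,
#' dividing parameters and multiply-accumulates by `g`.
#' @noRd
conv2d_forward_ref <- function(x, W, b, groups = 1L) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  kh <- dim(W)[1]; cing <- dim(W)[3]; cout <- dim(W)[4]
  g <- groups; coutg <- cout %/% g
  stopifnot(C == cing * g, kh %% 2 == 1)
  p <- (kh - 1L) %/% 2L
  xp <- pad_hw(x, p)
  M <- H * Wd * N
  out <- array(0, c(H, Wd, N, cout))
  for (gi in seq_len(g)) {
    ci <- (gi - 1L) * cing + seq_len(cing)
    co <- (gi - 1L) * coutg + seq_len(coutg)
    acc <- matrix(0, M, coutg)
    for (dy in seq_len(kh)) for (dx in seq_len(kh)) {
      sl <- xp[dy:(dy + H - 1L), dx:(dx + Wd - 1L), , ci, drop = FALSE]
      dim(sl) <- c(M, cing)
      acc <- acc + sl %*% matrix(W[dy, dx, , co], cing, coutg)
    }
    acc <- acc + rep(b[co], each = M)
    out[, , , co] <- acc
  }
  list(out = out, cache = list(xp = xp, dims = d))
}

conv2d_backward_ref <- function(dout, W, groups, cache) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; N <- d[3]
  kh <- dim(W)[1]; cing <- dim(W)[3]; cout <- dim(W)[4]
  g <- groups; coutg <- cout %/% g
  p <- (kh - 1L) %/% 2L
  xp <- cache$xp
  dxp <- array(0, dim(xp))
  dW <- array(0, dim(W))
  db <- numeric(cout)
  M <- H * Wd * N
  for (gi in seq_len(g)) {
    ci <- (gi - 1L) * cing + seq_len(cing)
    co <- (gi - 1L) * coutg + seq_len(coutg)
    dm <- dout[, , , co, drop = FALSE]
    dim(dm) <- c(M, coutg)
    db[co] <- colSums(dm)
    for (dy in seq_len(kh)) for (dx in seq_len(kh)) {
      sl <- xp[dy:(dy + H - 1L), dx:(dx + Wd - 1L), , ci, drop = FALSE]
      dim(sl) <- c(M, cing)
      dW[dy, dx, , co] <- crossprod(sl, dm)
      dsl <- dm %*% t(matrix(W[dy, dx, , co], cing, coutg))
      dim(dsl) <- c(H, Wd, N, cing)
      dxp[dy:(dy + H - 1L), dx:(dx + Wd - 1L), , ci] <-
        dxp[dy:(dy + H - 1L), dx:(dx + Wd - 1L), , ci, drop = FALSE] + dsl
    }
  }
  dx <- if (p > 0) dxp[p + seq_len(H), p + seq_len(Wd), , , drop = FALSE]
        else dxp
  list(dx = dx, dW = dW, db = db)
}

# Batch normalisation, non-affine (no learnable scale/shift; the
# neighbouring biased convolutions absorb them).  eps 1e-5, per-channel
# statistics over (height, width, batch).
bn_forward_ref <- function(x, training, run_mean, run_var, eps = 1e-5,
                       momentum = 0.9) {
  d <- dim(x); M <- d[1] * d[2] * d[3]; C <- d[4]
  xm <- x
  dim(xm) <- c(M, C)
  if (training) {
    mu <- colMeans(xm)
    ctr <- xm - rep(mu, each = M)
    va <- colMeans(ctr^2)
    ivar <- 1 / sqrt(va + eps)
    xhat <- ctr * rep(ivar, each = M)
    out <- xhat
    dim(out) <- d
    list(out = out,
         cache = list(xhat = xhat, ivar = ivar, M = M, dims = d),
         run_mean = momentum * run_mean + (1 - momentum) * mu,
         run_var = momentum * run_var +
           (1 - momentum) * va * M / max(M - 1, 1))
  } else {
    out <- (xm - rep(run_mean, each = M)) *
      rep(1 / sqrt(run_var + eps), each = M)
    dim(out) <- d
    list(out = out, cache = NULL, run_mean = run_mean, run_var = run_var)
  }
}

bn_backward_ref <- function(dout, cache) {
  M <- cache$M
  dm <- dout
  dim(dm) <- dim(cache$xhat)
  s1 <- colSums(dm)
  s2 <- colSums(dm * cache$xhat)
  dx <- (M * dm - rep(s1, each = M) -
           cache$xhat * rep(s2, each = M)) / M *
    rep(cache$ivar, each = M)
  dim(dx) <- cache$dims
  dx
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}
relu_backward <- function(dout, mask) dout * mask

# 2x2 stride-2 pooling with ceil-mode geometry: a v-pixel map becomes
# ceil((v - 2)/2) + 1 pixels (50 -> 25 -> 13 -> 7).  Average pooling
# divides by the number of cells inside the input (no padded zeros).
pool2_forward_ref <- function(x, kind = c("max", "avg")) {
  kind <- match.arg(kind)
  d <- dim(x); H <- d[1]; Wd <- d[2]
  Ho <- as.integer(ceiling((H - 2) / 2) + 1)
  Wo <- as.integer(ceiling((Wd - 2) / 2) + 1)
  fill <- if (kind == "max") -Inf else NA_real_
  xp <- x
  if (2 * Ho > H || 2 * Wo > Wd) {
    xp <- array(fill, c(2 * Ho, 2 * Wo, d[3], d[4]))
    xp[seq_len(H), seq_len(Wd), , ] <- x
  }
  r <- seq(1L, by = 2L, length.out = Ho)
  cidx <- seq(1L, by = 2L, length.out = Wo)
  cand <- array(fill, c(Ho, Wo, d[3], d[4], 4L))
  cand[, , , , 1] <- xp[r,      cidx,      , ]
  cand[, , , , 2] <- xp[r + 1L, cidx,      , ]
  cand[, , , , 3] <- xp[r,      cidx + 1L, , ]
  cand[, , , , 4] <- xp[r + 1L, cidx + 1L, , ]
  if (kind == "max") {
    out <- pmax(cand[, , , , 1], cand[, , , , 2], cand[, , , , 3],
                cand[, , , , 4])
    amax <- max.col(matrix(cand, ncol = 4L), ties.method = "first")
    list(out = out, cache = list(amax = amax, dims = d, Ho = Ho, Wo = Wo))
  } else {
    valid <- !is.na(cand)
    cnt <- valid[, , , , 1] + valid[, , , , 2] + valid[, , , , 3] +
      valid[, , , , 4]
    cand[!valid] <- 0
    out <- (cand[, , , , 1] + cand[, , , , 2] + cand[, , , , 3] +
            cand[, , , , 4]) / cnt
    list(out = out,
         cache = list(valid = valid, cnt = cnt, dims = d, Ho = Ho,
                      Wo = Wo))
  }
}

pool2_backward_ref <- function(dout, kind, cache) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]
  Ho <- cache$Ho; Wo <- cache$Wo
  dxp <- array(0, c(2 * Ho, 2 * Wo, d[3], d[4]))
  r <- seq(1L, by = 2L, length.out = Ho)
  cidx <- seq(1L, by = 2L, length.out = Wo)
  g <- array(0, c(Ho, Wo, d[3], d[4], 4L))
  if (kind == "max") {
    gm <- matrix(g, ncol = 4L)
    gm[cbind(seq_len(nrow(gm)), cache$amax)] <- as.vector(dout)
    g <- array(gm, c(Ho, Wo, d[3], d[4], 4L))
  } else {
    dd <- dout / cache$cnt
    for (i in 1:4) g[, , , , i] <- dd * cache$valid[, , , , i]
  }
  dxp[r, cidx, , ]           <- g[, , , , 1]
  dxp[r + 1L, cidx, , ]      <- g[, , , , 2]
  dxp[r, cidx + 1L, , ]      <- g[, , , , 3]
  dxp[r + 1L, cidx + 1L, , ] <- g[, , , , 4]
  dxp[seq_len(H), seq_len(Wd), , , drop = FALSE]
}

gap_forward <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  out <- array(colMeans(xm), c(1, 1, d[3], d[4]))
  list(out = out, cache = d)
}
gap_backward <- function(dout, d) {
  array(rep(dout / (d[1] * d[2]), each = d[1] * d[2]), d)
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(out = x * mask, cache = mask)
}
dropout_backward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

# channel concatenation on internal [H, W, N, C] tensors
cbind4 <- function(arrs) {
  d <- dim(arrs[[1]])
  cs <- vapply(arrs, function(a) dim(a)[4], 0)
  out <- array(0, c(d[1], d[2], d[3], sum(cs)))
  at <- 0L
  for (a in arrs) {
    nc <- dim(a)[4]
    out[, , , at + seq_len(nc)] <- a
    at <- at + nc
  }
  out
}

# dense layer on flattened features: x is features x batch
dense_forward <- function(x, W, b) {
  list(out = crossprod(W, x) + b, cache = x)
}
dense_backward <- function(dout, W, x) {
  list(dx = W %*% dout, dW = x %*% t(dout), db = rowSums(dout))
}

softmax_rows <- function(logits) {
  # logits: classes x batch -> probabilities, columns sum to 1
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

# softmax cross-entropy; labels are 0/1 (class index + 1 into rows)
softmax_xent <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- ncol(p)
  idx <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

# ---- dispatchers: compiled kernels with the R functions above as the
# ---- reference semantics (compared in the test suite) ----------------

conv2d_forward <- function(x, W, b, groups = 1L) {
  list(out = .conv2d_fwd_cpp(x, W, b, as.integer(groups)),
       cache = list(x = x, dims = dim(x)))
}

conv2d_backward <- function(dout, W, groups, cache) {
  .conv2d_bwd_cpp(cache$x, W, dout, as.integer(groups))
}

bn_forward <- function(x, training, run_mean, run_var, eps = 1e-5,
                       momentum = 0.9) {
  if (!training)
    return(bn_forward_ref(x, FALSE, run_mean, run_var, eps, momentum))
  d <- dim(x); M <- d[1] * d[2] * d[3]
  r <- .bn_fwd_cpp(x, eps)
  list(out = r$out,
       cache = list(xhat = r$out, ivar = r$ivar),
       run_mean = momentum * run_mean + (1 - momentum) * r$mu,
       run_var = momentum * run_var +
         (1 - momentum) * r$var * M / max(M - 1, 1))
}

bn_backward <- function(dout, cache) {
  .bn_bwd_cpp(dout, cache$xhat, cache$ivar)
}

pool2_forward <- function(x, kind = c("max", "avg")) {
  kind <- match.arg(kind)
  r <- .pool2_fwd_cpp(x, if (kind == "max") 0L else 1L)
  list(out = r$out, cache = list(arg = r$arg, in_dim = dim(x)))
}

pool2_backward <- function(dout, kind, cache) {
  .pool2_bwd_cpp(dout, cache$arg, cache$in_dim,
                 if (kind == "max") 0L else 1L)
}
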