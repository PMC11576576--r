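# Minimal dense-prediction network primitives with hand-written backward
# passes: 3x3 and 1x1 convolutions (im2col + BLAS matrix products), ReLU,
# 2x2 average pooling, nearest-neighbor upsampling and channel
# concatenation. Tensors are H x W x C arrays; batches are looped.

.conv3F <- function(x, W, b) {
  d <- dim(x)
  col <- .im2col3(x, d[1], d[2], d[3])
  out <- col %*% W
  out <- sweep(out, 2, b, "+")
  list(y = array(out, c(d[1], d[2], ncol(W))), col = col, dimIn = d)
}

.conv3B <- function(dout, cache, W) {
  d <- dim(dout)
  dm <- matrix(dout, d[1] * d[2], d[3])
  dW <- crossprod(cache$col, dm)
  db <- colSums(dm)
  dcol <- tcrossprod(dm, W)
  dx <- array(.col2im3(dcol, cache$dimIn[1], cache$dimIn[2], cache$dimIn[3]),
              cache$dimIn)
  list(dx = dx, dW = dW, db = db)
}

.conv1F <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  out <- sweep(xm %*% W, 2, b, "+")
  list(y = array(out, c(d[1], d[2], ncol(W))), xm = xm, dimIn = d)
}

.conv1B <- function(dout, cache, W) {
  d <- dim(dout)
  dm <- matrix(dout, d[1] * d[2], d[3])
  list(dx = array(tcrossprod(dm, W), cache$dimIn),
       dW = crossprod(cache$xm, dm), db = colSums(dm))
}

.reluF <- function(x) {
  m <- x > 0
  list(y = x * m, mask = m)
}

.reluB <- function(dout, cache) dout * cache$mask

.poolF <- function(x) {
  d <- dim(x)
  h <- d[1] / 2; w <- d[2] / 2
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  y <- (x[io, jo, , drop = FALSE] + x[io + 1, jo, , drop = FALSE] +
        x[io, jo + 1, , drop = FALSE] + x[io + 1, jo + 1, , drop = FALSE]) / 4
  list(y = array(y, c(h, w, d[3])), dimIn = d)
}

.poolB <- function(dout, cache) {
  d <- dim(dout)
  up <- dout[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
             drop = FALSE] / 4
  array(up, cache$dimIn)
}

.upF <- function(x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
         drop = FALSE]
  list(y = array(y, c(2 * d[1], 2 * d[2], d[3])), dimIn = d)
}

.upB <- function(dout, cache) {
  io <- seq(1, dim(dout)[1], 2); jo <- seq(1, dim(dout)[2], 2)
  s <- dout[io, jo, , drop = FALSE] + dout[io + 1, jo, , drop = FALSE] +
    dout[io, jo + 1, , drop = FALSE] + dout[io + 1, jo + 1, , drop = FALSE]
  array(s, cache$dimIn)
}

.concatF <- function(a, b) {
  da <- dim(a); db <- dim(b)
  list(y = array(c(a, b), c(da[1], da[2], da[3] + db[3])),
       ca = da[3], cb = db[3])
}

.concatB <- function(dout, cache) {
  list(da = dout[, , seq_len(cache$ca), drop = FALSE],
       db = dout[, , cache$ca + seq_len(cache$cb), drop = FALSE])
}

# residual block: y = skip(x) + conv2(relu(conv1(relu(x))));
# skip is identity when cin == cout, else a 1x1 convolution
.resF <- function(x, p, prefix) {
  r1 <- .reluF(x)
  c1 <- .conv3F(r1$y, p[[paste0(prefix, "_w1")]], p[[paste0(prefix, "_b1")]])
  r2 <- .reluF(c1$y)
  c2 <- .conv3F(r2$y, p[[paste0(prefix, "_w2")]], p[[paste0(prefix, "_b2")]])
  skipKey <- paste0(prefix, "_ws")
  if (!is.null(p[[skipKey]])) {
    s <- .conv1F(x, p[[skipKey]], p[[paste0(prefix, "_bs")]])
    y <- c2$y + s$y
  } else {
    s <- NULL
    y <- c2$y + x
  }
  list(y = y, r1 = r1, c1 = c1, r2 = r2, c2 = c2, s = s)
}

.resB <- function(dout, cache, p, prefix, grads) {
  g2 <- .conv3B(dout, cache$c2, p[[paste0(prefix, "_w2")]])
  grads[[paste0(prefix, "_w2")]] <- grads[[paste0(prefix, "_w2")]] + g2$dW
  grads[[paste0(prefix, "_b2")]] <- grads[[paste0(prefix, "_b2")]] + g2$db
  dr2 <- .reluB(g2$dx, cache$r2)
  g1 <- .conv3B(dr2, cache$c1, p[[paste0(prefix, "_w1")]])
  grads[[paste0(prefix, "_w1")]] <- grads[[paste0(prefix, "_w1")]] + g1$dW
  grads[[paste0(prefix, "_b1")]] <- grads[[paste0(prefix, "_b1")]] + g1$db
  dx <- .reluB(g1$dx, cache$r1)
  if (!is.null(cache$s)) {
    gs <- .conv1B(dout, cache$s, p[[paste0(prefix, "_ws")]])
    grads[[paste0(prefix, "_ws")]] <- grads[[paste0(prefix, "_ws")]] + gs$dW
    grads[[paste0(prefix, "_bs")]] <- grads[[paste0(prefix, "_bs")]] + gs$db
    dx <- dx + gs$dx
  } else {
    dx <- dx + dout
  }
  list(dx = dx, grads = grads)
}
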