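# Minimal slice-wise encoder-decoder with skip connections, written directly
# on BLAS matrix ops (im2col convolutions). Channel-last arrays (H, W, C).
# All backward passes are exercised against central finite differences in the
# test suite.

# columns are offset-major with channels inner: block k (of 9) holds all Cin
# channels for one (di, dj) tap. Window gathers/scatters use cached linear
# indices into the zero-padded plane, so each conv is 9 block ops.
.nn_idx_cache <- new.env(parent = emptyenv())

nn_window_idx <- function(H, W) {
  key <- paste(H, W, sep = "x")
  cached <- .nn_idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  idx <- vector("list", 9L)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    idx[[k]] <- as.vector(outer(di + seq_len(H), (dj + seq_len(W) - 1L) * (H + 2L), "+"))
  }
  out <- list(taps = idx, inner = idx[[5L]])  # (di, dj) = (1, 1) is the center
  .nn_idx_cache[[key]] <- out
  out
}

nn_im2col <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  iw <- nn_window_idx(H, W)
  xpm <- matrix(0, (H + 2L) * (W + 2L), Cin)
  xpm[iw$inner, ] <- x
  out <- matrix(0, H * W, 9L * Cin)
  for (k in 1:9)
    out[, (k - 1L) * Cin + seq_len(Cin)] <- xpm[iw$taps[[k]], ]
  out
}

nn_col2im <- function(dxcol, H, W, Cin) {
  iw <- nn_window_idx(H, W)
  dxpm <- matrix(0, (H + 2L) * (W + 2L), Cin)
  for (k in 1:9)
    dxpm[iw$taps[[k]], ] <- dxpm[iw$taps[[k]], ] +
      dxcol[, (k - 1L) * Cin + seq_len(Cin)]
  array(dxpm[iw$inner, ], c(H, W, Cin))
}

nn_conv_fwd <- function(x, p) {
  d <- dim(x)
  xcol <- nn_im2col(x)
  y <- sweep(xcol %*% p$W, 2L, p$b, "+")
  list(y = array(y, c(d[1], d[2], ncol(p$W))), xcol = xcol, xdim = d)
}

nn_conv_bwd <- function(dy, p, cache) {
  d <- dim(dy)
  dy_mat <- matrix(dy, d[1] * d[2], d[3])
  dW <- crossprod(cache$xcol, dy_mat)
  db <- colSums(dy_mat)
  dxcol <- dy_mat %*% t(p$W)
  dx <- nn_col2im(dxcol, cache$xdim[1], cache$xdim[2], cache$xdim[3])
  list(dx = dx, dW = dW, db = db)
}

nn_conv1x1_fwd <- function(x, p) {
  d <- dim(x)
  xmat <- matrix(x, d[1] * d[2], d[3])
  y <- sweep(xmat %*% p$W, 2L, p$b, "+")
  list(y = array(y, c(d[1], d[2], ncol(p$W))), xmat = xmat, xdim = d)
}

nn_conv1x1_bwd <- function(dy, p, cache) {
  d <- dim(dy)
  dy_mat <- matrix(dy, d[1] * d[2], d[3])
  list(dx = array(dy_mat %*% t(p$W), cache$xdim),
       dW = crossprod(cache$xmat, dy_mat), db = colSums(dy_mat))
}

nn_relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
nn_relu_bwd <- function(dy, cache) dy * cache$mask

# instance normalization: each channel of each image standardized over H x W,
# then scaled/shifted by learnable gain/offset (stored as $W / $b so the
# generic SGD update applies). Keeps activations O(1) so the small fixed
# learning rate makes progress on the dice objective.
nn_inorm_fwd <- function(x, p, eps = 1e-5) {
  d <- dim(x); N <- d[1] * d[2]
  xm <- matrix(x, N, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu, "-")
  s <- sqrt(colMeans(xc^2) + eps)
  xhat <- sweep(xc, 2L, s, "/")
  y <- sweep(sweep(xhat, 2L, p$W, "*"), 2L, p$b, "+")
  list(y = array(y, d), xhat = xhat, s = s, xdim = d)
}

nn_inorm_bwd <- function(dy, p, cache) {
  d <- cache$xdim; N <- d[1] * d[2]
  dym <- matrix(dy, N, d[3])
  dW <- colSums(dym * cache$xhat)
  db <- colSums(dym)
  dxhat <- sweep(dym, 2L, p$W, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2L, m1, "-") - sweep(cache$xhat, 2L, m2, "*")
  dx <- sweep(dx, 2L, cache$s, "/")
  list(dx = array(dx, d), dW = dW, db = db)
}

nn_pool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  s1r <- seq(1L, H, 2L); s2r <- seq(2L, H, 2L)
  s1c <- seq(1L, W, 2L); s2c <- seq(2L, W, 2L)
  a1 <- x[s1r, s1c, , drop = FALSE]; a2 <- x[s2r, s1c, , drop = FALSE]
  a3 <- x[s1r, s2c, , drop = FALSE]; a4 <- x[s2r, s2c, , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  idx <- ifelse(a1 == m, 1L, ifelse(a2 == m, 2L, ifelse(a3 == m, 3L, 4L)))
  list(y = m, idx = idx, xdim = d)
}

nn_pool_bwd <- function(dy, cache) {
  d <- cache$xdim
  dx <- array(0, d)
  s1r <- seq(1L, d[1], 2L); s2r <- seq(2L, d[1], 2L)
  s1c <- seq(1L, d[2], 2L); s2c <- seq(2L, d[2], 2L)
  dx[s1r, s1c, ] <- dy * (cache$idx == 1L)
  dx[s2r, s1c, ] <- dy * (cache$idx == 2L)
  dx[s1r, s2c, ] <- dy * (cache$idx == 3L)
  dx[s2r, s2c, ] <- dy * (cache$idx == 4L)
  dx
}

nn_up_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  s1r <- seq(1L, 2L * d[1], 2L); s2r <- s1r + 1L
  s1c <- seq(1L, 2L * d[2], 2L); s2c <- s1c + 1L
  y[s1r, s1c, ] <- x; y[s2r, s1c, ] <- x
  y[s1r, s2c, ] <- x; y[s2r, s2c, ] <- x
  y
}

nn_up_bwd <- function(dy) {
  d <- dim(dy)
  s1r <- seq(1L, d[1], 2L); s2r <- s1r + 1L
  s1c <- seq(1L, d[2], 2L); s2c <- s1c + 1L
  dy[s1r, s1c, , drop = FALSE] + dy[s2r, s1c, , drop = FALSE] +
    dy[s1r, s2c, , drop = FALSE] + dy[s2r, s2c, , drop = FALSE]
}

nn_concat <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

# He-scaled initialization; the draw order is fixed so a seed pins the model
nn_init_conv <- function(cin, cout, k = 3L) {
  fan_in <- k * k * cin
  list(W = matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / fan_in)),
                  k * k * cin, cout),
       b = rep(0, cout))
}

nn_init_norm <- function(cout) list(W = rep(1, cout), b = rep(0, cout))

nn_init_params <- function(base_channels) {
  C <- base_channels
  list(enc1a = nn_init_conv(1L, C),      enc1a_n = nn_init_norm(C),
       enc1b = nn_init_conv(C, C),       enc1b_n = nn_init_norm(C),
       enc2a = nn_init_conv(C, 2L * C),  enc2a_n = nn_init_norm(2L * C),
       enc2b = nn_init_conv(2L * C, 2L * C), enc2b_n = nn_init_norm(2L * C),
       bota  = nn_init_conv(2L * C, 4L * C), bota_n = nn_init_norm(4L * C),
       botb  = nn_init_conv(4L * C, 4L * C), botb_n = nn_init_norm(4L * C),
       dec2a = nn_init_conv(6L * C, 2L * C), dec2a_n = nn_init_norm(2L * C),
       dec2b = nn_init_conv(2L * C, 2L * C), dec2b_n = nn_init_norm(2L * C),
       dec1a = nn_init_conv(3L * C, C),  dec1a_n = nn_init_norm(C),
       dec1b = nn_init_conv(C, C),       dec1b_n = nn_init_norm(C),
       # the head also sees the raw (standardized) input as an extra
       # channel: the normalization layers are contrast-invariant, so this
       # skip is what lets the output gate on absolute intensity. Its
       # weight starts at -1 (hypointense lesions: lower signal, higher
       # foreground logit) so the gate is present at every seed; training
       # is free to reshape or flip it
       out = list(W = matrix(c(stats::rnorm(C, 0, sqrt(2 / (C + 1L))), -1),
                             C + 1L, 1L), b = 0))
}

# conv -> instance norm -> relu, twice
conv_block_fwd <- function(x, pa, pan, pb, pbn) {
  ca <- nn_conv_fwd(x, pa); na <- nn_inorm_fwd(ca$y, pan); ra <- nn_relu_fwd(na$y)
  cb <- nn_conv_fwd(ra$y, pb); nb <- nn_inorm_fwd(cb$y, pbn); rb <- nn_relu_fwd(nb$y)
  list(y = rb$y, ca = ca, na = na, ra = ra, cb = cb, nb = nb, rb = rb)
}

conv_block_bwd <- function(dy, pa, pan, pb, pbn, cache) {
  d2 <- nn_relu_bwd(dy, cache$rb)
  gnb <- nn_inorm_bwd(d2, pbn, cache$nb)
  gb <- nn_conv_bwd(gnb$dx, pb, cache$cb)
  d1 <- nn_relu_bwd(gb$dx, cache$ra)
  gna <- nn_inorm_bwd(d1, pan, cache$na)
  ga <- nn_conv_bwd(gna$dx, pa, cache$ca)
  list(dx = ga$dx, ga = ga, gna = gna, gb = gb, gnb = gnb)
}

# full forward pass; x is an (H, W, 1) array
nn_forward <- function(params, x) {
  e1 <- conv_block_fwd(x, params$enc1a, params$enc1a_n, params$enc1b, params$enc1b_n)
  p1 <- nn_pool_fwd(e1$y)
  e2 <- conv_block_fwd(p1$y, params$enc2a, params$enc2a_n, params$enc2b, params$enc2b_n)
  p2 <- nn_pool_fwd(e2$y)
  bt <- conv_block_fwd(p2$y, params$bota, params$bota_n, params$botb, params$botb_n)
  u2 <- nn_up_fwd(bt$y)
  d2 <- conv_block_fwd(nn_concat(u2, e2$y), params$dec2a, params$dec2a_n,
                       params$dec2b, params$dec2b_n)
  u1 <- nn_up_fwd(d2$y)
  d1 <- conv_block_fwd(nn_concat(u1, e1$y), params$dec1a, params$dec1a_n,
                       params$dec1b, params$dec1b_n)
  o <- nn_conv1x1_fwd(nn_concat(d1$y, x), params$out)
  prob <- 1 / (1 + exp(-pmin(pmax(o$y, -30), 30)))
  list(prob = prob, e1 = e1, p1 = p1, e2 = e2, p2 = p2, bt = bt,
       d2 = d2, d1 = d1, o = o)
}

# backward from d(loss)/d(prob); returns gradients in the params layout
nn_backward <- function(params, cache, dprob) {
  dlogit <- dprob * cache$prob * (1 - cache$prob)
  go <- nn_conv1x1_bwd(dlogit, params$out, cache$o)
  # the head's last input channel is the raw input skip; no gradient flows
  # back into the data
  dhead <- go$dx[, , seq_len(dim(go$dx)[3] - 1L), drop = FALSE]
  g1 <- conv_block_bwd(dhead, params$dec1a, params$dec1a_n,
                       params$dec1b, params$dec1b_n, cache$d1)
  C1 <- dim(cache$e1$y)[3]
  du1 <- g1$dx[, , seq_len(dim(g1$dx)[3] - C1), drop = FALSE]
  dskip1 <- g1$dx[, , dim(g1$dx)[3] - C1 + seq_len(C1), drop = FALSE]
  dd2 <- nn_up_bwd(du1)
  g2 <- conv_block_bwd(dd2, params$dec2a, params$dec2a_n,
                       params$dec2b, params$dec2b_n, cache$d2)
  C2 <- dim(cache$e2$y)[3]
  du2 <- g2$dx[, , seq_len(dim(g2$dx)[3] - C2), drop = FALSE]
  dskip2 <- g2$dx[, , dim(g2$dx)[3] - C2 + seq_len(C2), drop = FALSE]
  dbt <- nn_up_bwd(du2)
  gb <- conv_block_bwd(dbt, params$bota, params$bota_n,
                       params$botb, params$botb_n, cache$bt)
  dp2 <- nn_pool_bwd(gb$dx, cache$p2)
  ge2 <- conv_block_bwd(dp2 + dskip2, params$enc2a, params$enc2a_n,
                        params$enc2b, params$enc2b_n, cache$e2)
  dp1 <- nn_pool_bwd(ge2$dx, cache$p1)
  ge1 <- conv_block_bwd(dp1 + dskip1, params$enc1a, params$enc1a_n,
                        params$enc1b, params$enc1b_n, cache$e1)
  list(enc1a = ge1$ga, enc1a_n = ge1$gna, enc1b = ge1$gb, enc1b_n = ge1$gnb,
       enc2a = ge2$ga, enc2a_n = ge2$gna, enc2b = ge2$gb, enc2b_n = ge2$gnb,
       bota = gb$ga, bota_n = gb$gna, botb = gb$gb, botb_n = gb$gnb,
       dec2a = g2$ga, dec2a_n = g2$gna, dec2b = g2$gb, dec2b_n = g2$gnb,
       dec1a = g1$ga, dec1a_n = g1$gna, dec1b = g1$gb, dec1b_n = g1$gnb,
       out = go)
}

# SGD with classical momentum; `vel` carries the running velocity state
nn_sgd_update <- function(params, grads, vel, lr, wd, momentum, scale) {
  for (nm in names(params)) {
    gW <- grads[[nm]]$dW * scale + wd * params[[nm]]$W
    gb <- grads[[nm]]$db * scale
    vel[[nm]]$dW <- momentum * vel[[nm]]$dW + gW
    vel[[nm]]$db <- momentum * vel[[nm]]$db + gb
    params[[nm]]$W <- params[[nm]]$W - lr * vel[[nm]]$dW
    params[[nm]]$b <- params[[nm]]$b - lr * vel[[nm]]$db
  }
  list(params = params, vel = vel)
}

nn_grad_zero <- function(params) {
  lapply(params, function(p) list(dW = p$W * 0, db = p$b * 0))
}

nn_grad_add <- function(acc, g) {
  for (nm in names(acc)) {
    acc[[nm]]$dW <- acc[[nm]]$dW + g[[nm]]$dW
    acc[[nm]]$db <- acc[[nm]]$db + g[[nm]]$db
  }
  acc
}
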