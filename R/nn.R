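# Native neural-network engine for the 1-D feature pyramid detector.
#
# Signals are (time x channel) matrices. Dense convolutions are sums over
# kernel taps of shifted row-blocks hitting BLAS; depthwise convolutions
# use vectorised elementwise products. Every op has an analytic
# reverse-mode gradient. Instance normalization uses per-instance
# population statistics with no affine parameters, so the op is identical
# in train and eval and inference is deterministic.

NN_EPS <- 1e-5

# ---- primitive ops ---------------------------------------------------------

pad_rows <- function(x, p) {
  if (p == 0L) return(x)
  n <- nrow(x)
  out <- matrix(0, n + 2L * p, ncol(x))
  out[(p + 1L):(p + n), ] <- x
  out
}

# dense conv, same padding; w is (k*cin) x cout, rows (j-1)*cin+1 .. j*cin
# hold tap j
conv_dense_fwd <- function(x, w, k) {
  n <- nrow(x); cin <- ncol(x)
  p <- (k - 1L) %/% 2L
  xp <- pad_rows(x, p)
  y <- matrix(0, n, ncol(w))
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * cin + 1L):(j * cin)
    y <- y + xp[j:(j + n - 1L), , drop = FALSE] %*% w[rows, , drop = FALSE]
  }
  list(y = y, xp = xp)
}

conv_dense_bwd <- function(dy, xp, w, k, cin) {
  n <- nrow(dy)
  p <- (k - 1L) %/% 2L
  dw <- matrix(0, nrow(w), ncol(w))
  dxp <- matrix(0, nrow(xp), cin)
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * cin + 1L):(j * cin)
    blk <- j:(j + n - 1L)
    dw[rows, ] <- crossprod(xp[blk, , drop = FALSE], dy)
    dxp[blk, ] <- dxp[blk, , drop = FALSE] + dy %*% t(w[rows, , drop = FALSE])
  }
  list(dw = dw, dx = dxp[(p + 1L):(p + n), , drop = FALSE])
}

# depthwise conv, same padding; w is k x c (compiled hot loop)
conv_dw_fwd <- function(x, w) {
  p <- (nrow(w) - 1L) %/% 2L
  xp <- pad_rows(x, p)
  list(y = dwconv_fwd_cpp(xp, w, nrow(x)), xp = xp)
}

conv_dw_bwd <- function(dy, xp, w) {
  dwconv_bwd_cpp(dy, xp, w)
}

# instance norm over time, per channel, population variance, no affine;
# returns the normalised output y and 1/sd for the backward pass
inorm_fwd <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  v <- colMeans(x * x) - mu * mu
  inv <- 1 / sqrt(pmax(v, 0) + NN_EPS)
  y <- (x - rep(mu, each = n)) * rep(inv, each = n)
  list(y = y, inv = inv)
}

inorm_bwd <- function(dy, y, inv) {
  n <- nrow(dy)
  m1 <- colMeans(dy)
  m2 <- colMeans(dy * y)
  (dy - rep(m1, each = n) - y * rep(m2, each = n)) * rep(inv, each = n)
}

relu_fwd <- function(x) x * (x > 0)
relu_bwd <- function(dy, y) dy * (y > 0)

sub2_fwd <- function(x) x[seq.int(1L, nrow(x), 2L), , drop = FALSE]
sub2_bwd <- function(dy, n) {
  dx <- matrix(0, n, ncol(dy))
  dx[seq.int(1L, n, 2L), ] <- dy
  dx
}

# nearest-neighbour x2 upsample to length m (m = 2 * nrow(x) here)
up2_fwd <- function(x, m) x[rep(seq_len(nrow(x)), each = 2L)[seq_len(m)], , drop = FALSE]
up2_bwd <- function(dy) {
  m <- nrow(dy)
  dy[seq.int(1L, m, 2L), , drop = FALSE] +
    dy[seq.int(2L, m, 2L), , drop = FALSE]
}

# moving-average pool, width w (odd), stride 1, zero padding, same length;
# the operator is symmetric, so it is its own adjoint
avgpool_same <- function(x, w) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  h <- (w - 1L) %/% 2L
  s <- rbind(0, apply(x, 2, cumsum))
  t_idx <- seq_len(n)
  (s[pmin(t_idx + h, n) + 1L, , drop = FALSE] -
     s[pmax(t_idx - h - 1L, 0L) + 1L, , drop = FALSE]) / w
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# head weights are stored as hk x d; the dense-conv kernel needs flat
# rows (j-1)*d + c  <->  head[j, c]
head_flat <- function(w) matrix(t(w), ncol = 1L)
head_unflat <- function(flat, hk, d) t(matrix(flat, nrow = d))

# ---- parameter initialization (uniform +-sqrt(1/fan_in)) -------------------

uinit <- function(nr, nc, fan_in) {
  b <- sqrt(1 / fan_in)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

nn_init_params <- function(cfg) {
  k <- cfg$kernel_size
  ch <- cfg$channels
  d <- cfg$fpn_channels
  hk <- cfg$head_kernel
  inc <- cfg$in_channels
  p <- list()
  p$stem <- uinit(k * inc, ch[1], k * inc)
  blk_ch <- rep(ch, each = 2L)
  for (i in 1:6) {
    c_i <- blk_ch[[i]]
    p[[paste0("blk", i)]] <- if (cfg$depthwise) uinit(k, c_i, k)
                             else uinit(k * c_i, c_i, k * c_i)
  }
  p$down1 <- uinit(ch[1], ch[2], ch[1])
  p$down2 <- uinit(ch[2], ch[3], ch[2])
  for (i in 1:3) {
    p[[paste0("lat", i)]] <- uinit(ch[i], d, ch[i])
    p[[paste0("latb", i)]] <- stats::runif(d, -sqrt(1 / ch[i]), sqrt(1 / ch[i]))
    p[[paste0("sm", i)]] <- uinit(k, d, k)
    p[[paste0("smb", i)]] <- stats::runif(d, -sqrt(1 / k), sqrt(1 / k))
  }
  p$head <- uinit(hk, d, hk * d)
  p
}

# ---- residual block --------------------------------------------------------

block_fwd <- function(x, w, cfg) {
  cv <- if (cfg$depthwise) conv_dw_fwd(x, w)
        else conv_dense_fwd(x, w, cfg$kernel_size)
  nm <- inorm_fwd(cv$y)
  a <- relu_fwd(nm$y)
  list(y = x + a, xp = cv$xp, ny = nm$y, inv = nm$inv, a = a)
}

block_bwd <- function(dy, cache, w, cfg) {
  da <- relu_bwd(dy, cache$a)
  dn <- inorm_bwd(da, cache$ny, cache$inv)
  cb <- if (cfg$depthwise) conv_dw_bwd(dn, cache$xp, w)
        else conv_dense_bwd(dn, cache$xp, w, cfg$kernel_size, ncol(dy))
  list(dx = dy + cb$dx, dw = cb$dw)
}

# ---- full forward ----------------------------------------------------------

nn_forward <- function(params, cfg, x, training = FALSE) {
  l0 <- nrow(x)
  abort_if(l0 < 32L, "input shorter than the model's minimum length (32 samples)")
  abort_if(ncol(x) != cfg$in_channels,
           sprintf("input has %d channels; model expects %d",
                   ncol(x), cfg$in_channels))
  pad <- (4L - l0 %% 4L) %% 4L
  if (pad > 0L) x <- rbind(x, matrix(0, pad, ncol(x)))
  n <- nrow(x)
  C <- list()

  st <- conv_dense_fwd(x, params$stem, cfg$kernel_size)
  st_nm <- inorm_fwd(st$y)
  s0 <- relu_fwd(st_nm$y)
  C$stem <- list(xp = st$xp, ny = st_nm$y, inv = st_nm$inv)

  b1 <- block_fwd(s0, params$blk1, cfg)
  b2 <- block_fwd(b1$y, params$blk2, cfg)
  C$b1 <- b1; C$b2 <- b2

  xs1 <- sub2_fwd(b2$y)
  d1_nm <- inorm_fwd(xs1 %*% params$down1)
  d1 <- relu_fwd(d1_nm$y)
  C$d1 <- list(xs = xs1, ny = d1_nm$y, inv = d1_nm$inv)

  b3 <- block_fwd(d1, params$blk3, cfg)
  b4 <- block_fwd(b3$y, params$blk4, cfg)
  C$b3 <- b3; C$b4 <- b4

  xs2 <- sub2_fwd(b4$y)
  d2_nm <- inorm_fwd(xs2 %*% params$down2)
  d2 <- relu_fwd(d2_nm$y)
  C$d2 <- list(xs = xs2, ny = d2_nm$y, inv = d2_nm$inv)

  b5 <- block_fwd(d2, params$blk5, cfg)
  b6 <- block_fwd(b5$y, params$blk6, cfg)
  C$b5 <- b5; C$b6 <- b6

  n1 <- n; n2 <- n %/% 2L; n3 <- n %/% 4L
  l1 <- b2$y %*% params$lat1 + rep(params$latb1, each = n1)
  l2 <- b4$y %*% params$lat2 + rep(params$latb2, each = n2)
  l3 <- b6$y %*% params$lat3 + rep(params$latb3, each = n3)
  p3 <- l3
  p2 <- l2 + up2_fwd(p3, n2)
  p1 <- l1 + up2_fwd(p2, n1)
  C$fpn_in <- list(b2 = b2$y, b4 = b4$y, b6 = b6$y)
  P <- list(p1, p2, p3)

  hw <- head_flat(params$head)
  maps <- vector("list", 3L)
  C$heads <- vector("list", 3L)
  for (i in 1:3) {
    smc <- conv_dw_fwd(P[[i]], params[[paste0("sm", i)]])
    m <- smc$y + rep(params[[paste0("smb", i)]], each = nrow(smc$y))
    hd <- conv_dense_fwd(m, hw, cfg$head_kernel)
    sg <- sigmoid(hd$y[, 1])
    maps[[i]] <- avgpool_same(sg, cfg$pool_size)[, 1]
    C$heads[[i]] <- list(sm_xp = smc$xp, m_xp = hd$xp, sg = sg)
  }

  out_len <- c(l0, ceiling(l0 / 2), ceiling(l0 / 4))
  maps <- lapply(1:3, function(i) maps[[i]][seq_len(out_len[[i]])])
  C$pad <- pad; C$n <- n; C$l0 <- l0
  list(maps = maps, cache = if (training) C else NULL)
}

# ---- full backward ---------------------------------------------------------

nn_backward <- function(params, cfg, C, dmaps) {
  n <- C$n
  n_at <- c(n, n %/% 2L, n %/% 4L)
  hk <- cfg$head_kernel
  d <- cfg$fpn_channels
  hw <- head_flat(params$head)
  G <- list()
  dP <- vector("list", 3L)
  dhead_flat <- matrix(0, hk * d, 1L)
  for (i in 1:3) {
    dm_full <- numeric(n_at[[i]])
    dm_full[seq_along(dmaps[[i]])] <- dmaps[[i]]
    ds <- avgpool_same(matrix(dm_full, ncol = 1L), cfg$pool_size)[, 1]
    sg <- C$heads[[i]]$sg
    dh <- matrix(ds * sg * (1 - sg), ncol = 1L)
    hb <- conv_dense_bwd(dh, C$heads[[i]]$m_xp, hw, hk, d)
    dhead_flat <- dhead_flat + hb$dw
    dm <- hb$dx
    G[[paste0("smb", i)]] <- colSums(dm)
    sb <- conv_dw_bwd(dm, C$heads[[i]]$sm_xp, params[[paste0("sm", i)]])
    G[[paste0("sm", i)]] <- sb$dw
    dP[[i]] <- sb$dx
  }
  G$head <- head_unflat(dhead_flat, hk, d)

  # top-down adjoint: p1 = l1 + up(p2); p2 = l2 + up(p3); p3 = l3
  dl1 <- dP[[1]]
  dp2 <- dP[[2]] + up2_bwd(dP[[1]])
  dl2 <- dp2
  dp3 <- dP[[3]] + up2_bwd(dp2)
  dl3 <- dp3
  fin <- C$fpn_in
  G$lat1 <- crossprod(fin$b2, dl1); G$latb1 <- colSums(dl1)
  G$lat2 <- crossprod(fin$b4, dl2); G$latb2 <- colSums(dl2)
  G$lat3 <- crossprod(fin$b6, dl3); G$latb3 <- colSums(dl3)
  db2 <- dl1 %*% t(params$lat1)
  db4 <- dl2 %*% t(params$lat2)
  db6 <- dl3 %*% t(params$lat3)

  bb6 <- block_bwd(db6, C$b6, params$blk6, cfg); G$blk6 <- bb6$dw
  bb5 <- block_bwd(bb6$dx, C$b5, params$blk5, cfg); G$blk5 <- bb5$dw

  da <- relu_bwd(bb5$dx, relu_fwd(C$d2$ny))
  dz <- inorm_bwd(da, C$d2$ny, C$d2$inv)
  G$down2 <- crossprod(C$d2$xs, dz)
  db4 <- db4 + sub2_bwd(dz %*% t(params$down2), n %/% 2L)

  bb4 <- block_bwd(db4, C$b4, params$blk4, cfg); G$blk4 <- bb4$dw
  bb3 <- block_bwd(bb4$dx, C$b3, params$blk3, cfg); G$blk3 <- bb3$dw

  da <- relu_bwd(bb3$dx, relu_fwd(C$d1$ny))
  dz <- inorm_bwd(da, C$d1$ny, C$d1$inv)
  G$down1 <- crossprod(C$d1$xs, dz)
  db2 <- db2 + sub2_bwd(dz %*% t(params$down1), n)

  bb2 <- block_bwd(db2, C$b2, params$blk2, cfg); G$blk2 <- bb2$dw
  bb1 <- block_bwd(bb2$dx, C$b1, params$blk1, cfg); G$blk1 <- bb1$dw

  da <- relu_bwd(bb1$dx, relu_fwd(C$stem$ny))
  dz <- inorm_bwd(da, C$stem$ny, C$stem$inv)
  sb <- conv_dense_bwd(dz, C$stem$xp, params$stem, cfg$kernel_size,
                       cfg$in_channels)
  G$stem <- sb$dw
  G[names(params)]
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
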