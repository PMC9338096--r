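# Native 1D neural-network engine.
#
# Layers are mutable environments holding weights (and gradients after a
# backward pass). Spatial activations for a batch of B signals of length L
# with C channels are stored as a (B*L, C) matrix, rows sample-major (rows
# 1..L belong to sample 1). Convolutions are evaluated as im2col gathers
# followed by a single BLAS GEMM, which is where essentially all the
# training time goes. Backward passes are hand-derived and validated
# against finite differences in the test suite.

glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

make_conv <- function(k, cin, cout, stride = 1L, l2 = 0, use_bias = TRUE) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"; ly$k <- as.integer(k); ly$cin <- as.integer(cin)
  ly$cout <- as.integer(cout); ly$stride <- as.integer(stride); ly$l2 <- l2
  ly$W <- matrix(glorot(k * cin, k * cout, k * cin * cout), k * cin, cout)
  ly$b <- if (use_bias) numeric(cout) else NULL
  ly$idx_cache <- list()
  ly
}

make_dense <- function(fin, units, l2 = 0) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "dense"; ly$fin <- as.integer(fin); ly$units <- as.integer(units)
  ly$l2 <- l2
  ly$W <- matrix(glorot(fin, units, fin * units), fin, units)
  ly$b <- numeric(units)
  ly
}

make_relu <- function() {
  ly <- new.env(parent = emptyenv()); ly$type <- "relu"; ly
}

make_pool <- function(pool, stride = pool) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "pool"; ly$pool <- as.integer(pool); ly$stride <- as.integer(stride)
  ly$idx_cache <- list()
  ly
}

make_bn <- function(c, momentum = 0.99, eps = 1e-3) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "bn"; ly$c <- as.integer(c); ly$momentum <- momentum; ly$eps <- eps
  ly$gamma <- rep(1, c); ly$beta <- numeric(c)
  ly$rmean <- numeric(c); ly$rvar <- rep(1, c)
  ly
}

make_flatten <- function() {
  ly <- new.env(parent = emptyenv()); ly$type <- "flatten"; ly
}

make_gap <- function() {
  ly <- new.env(parent = emptyenv()); ly$type <- "gap"; ly
}

# Bottleneck residual block (ResNet v1): 1x1 (stride) -> 3 -> 1x1 with
# batch norm after each convolution, projection shortcut when the shape
# changes, ReLU after the addition.
make_block <- function(cin, cmid, stride = 1L, l2 = 0) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "block"; ly$cin <- cin; ly$cmid <- cmid; ly$cout <- 4L * cmid
  ly$stride <- as.integer(stride)
  ly$main <- list(
    make_conv(1L, cin, cmid, stride = stride, l2 = l2), make_bn(cmid), make_relu(),
    make_conv(3L, cmid, cmid, stride = 1L, l2 = l2), make_bn(cmid), make_relu(),
    make_conv(1L, cmid, 4L * cmid, stride = 1L, l2 = l2), make_bn(4L * cmid)
  )
  ly$shortcut <- if (stride != 1L || cin != 4L * cmid) {
    list(make_conv(1L, cin, 4L * cmid, stride = stride, l2 = l2),
         make_bn(4L * cmid))
  } else NULL
  ly
}

# Gather index for 'same'-padded windows: (B*Lo x width) matrix of row
# indices into the input matrix extended with one padding row (B*L + 1).
window_index <- function(ly, B, L, width, stride) {
  key <- paste(B, L, sep = "x")
  cached <- ly$idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  Lo <- as.integer(ceiling(L / stride))
  pad_total <- max((Lo - 1L) * stride + width - L, 0L)
  pl <- pad_total %/% 2L
  pad_row <- B * L + 1L
  idx <- matrix(0L, B * Lo, width)
  offs <- rep((0:(B - 1)) * L, each = Lo)
  for (j in seq_len(width)) {
    p0 <- (0:(Lo - 1)) * stride + (j - 1L) - pl   # 0-based input positions
    valid <- p0 >= 0L & p0 < L
    col <- rep(p0 + 1L, B) + offs
    col[!rep(valid, B)] <- pad_row
    idx[, j] <- col
  }
  out <- list(idx = idx, Lo = Lo)
  ly$idx_cache[[key]] <- out
  out
}

fwd_conv <- function(ly, x, B, L) {
  gi <- window_index(ly, B, L, ly$k, ly$stride)
  Xc <- cpp_im2col(x, gi$idx)
  out <- Xc %*% ly$W
  if (!is.null(ly$b)) out <- out + rep(ly$b, each = nrow(out))
  list(out = out, L = gi$Lo, cache = list(Xc = Xc, idx = gi$idx, B = B, L = L))
}

bwd_conv <- function(ly, cache, dout) {
  ly$gW <- crossprod(cache$Xc, dout)
  if (ly$l2 > 0) ly$gW <- ly$gW + 2 * ly$l2 * ly$W
  if (!is.null(ly$b)) ly$gb <- colSums(dout)
  dXc <- tcrossprod(dout, ly$W)
  cpp_col2im(dXc, cache$idx, cache$B * cache$L)
}

fwd_pool <- function(ly, x, B, L) {
  p <- ly$pool
  if (ly$stride == p && L %% p == 0L) {
    # non-overlapping, unpadded: windows are contiguous row blocks
    r <- cpp_pool_fwd(x, p)
    return(list(out = r$out, L = L %/% p,
                cache = list(arg = r$arg, B = B, L = L, fast = TRUE)))
  }
  gi <- window_index(ly, B, L, p, ly$stride)
  r <- cpp_pool_window_fwd(x, gi$idx)
  list(out = r$out, L = gi$Lo,
       cache = list(idx = gi$idx, arg = r$arg, B = B, L = L, fast = FALSE))
}

bwd_pool <- function(ly, cache, dout) {
  if (isTRUE(cache$fast))
    return(cpp_pool_bwd(dout, cache$arg, ly$pool))
  cpp_pool_window_bwd(dout, cache$arg, cache$idx, cache$B * cache$L)
}

fwd_bn <- function(ly, x, training) {
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + ly$eps)
    xhat <- xc * rep(istd, each = n)
    ly$rmean <- ly$momentum * ly$rmean + (1 - ly$momentum) * mu
    ly$rvar <- ly$momentum * ly$rvar + (1 - ly$momentum) * v
    out <- xhat * rep(ly$gamma, each = n) + rep(ly$beta, each = n)
    list(out = out, cache = list(xhat = xhat, istd = istd, n = n))
  } else {
    istd <- 1 / sqrt(ly$rvar + ly$eps)
    out <- (x - rep(ly$rmean, each = n)) * rep(istd * ly$gamma, each = n) +
      rep(ly$beta, each = n)
    list(out = out, cache = NULL)
  }
}

bwd_bn <- function(ly, cache, dout) {
  n <- cache$n; xhat <- cache$xhat
  dxhat <- dout * rep(ly$gamma, each = n)
  s1 <- colSums(dxhat) / n
  s2 <- colSums(dxhat * xhat) / n
  ly$ggamma <- colSums(dout * xhat)
  ly$gbeta <- colSums(dout)
  rep(cache$istd, each = n) * (dxhat - rep(s1, each = n) - xhat * rep(s2, each = n))
}

fwd_dense <- function(ly, x) {
  out <- x %*% ly$W + rep(ly$b, each = nrow(x))
  list(out = out, cache = list(x = x))
}

bwd_dense <- function(ly, cache, dout) {
  ly$gW <- crossprod(cache$x, dout)
  if (ly$l2 > 0) ly$gW <- ly$gW + 2 * ly$l2 * ly$W
  ly$gb <- colSums(dout)
  tcrossprod(dout, ly$W)
}

# (B*L, C) -> (B, L*C) with channel index fastest, matching how the dense
# head reads the flattened feature map.
fwd_flatten <- function(x, B, L) {
  C <- ncol(x)
  a <- array(x, c(L, B, C))
  out <- t(matrix(aperm(a, c(3, 1, 2)), C * L, B))
  list(out = out, cache = list(B = B, L = L, C = C))
}

bwd_flatten <- function(cache, dout) {
  a <- array(t(dout), c(cache$C, cache$L, cache$B))
  matrix(aperm(a, c(2, 3, 1)), cache$L * cache$B, cache$C)
}

fwd_gap <- function(x, B, L) {
  grp <- rep(seq_len(B), each = L)
  out <- rowsum(x, grp, reorder = FALSE) / L
  list(out = out, cache = list(B = B, L = L))
}

bwd_gap <- function(cache, dout) {
  dout[rep(seq_len(cache$B), each = cache$L), , drop = FALSE] / cache$L
}

# ---- sequential execution -------------------------------------------------

seq_forward <- function(layers, x, B, L, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    r <- switch(ly$type,
      conv = fwd_conv(ly, x, B, L),
      pool = fwd_pool(ly, x, B, L),
      bn = fwd_bn(ly, x, training),
      relu = {
        mask <- x > 0
        list(out = x * mask, cache = list(mask = mask))
      },
      flatten = fwd_flatten(x, B, L),
      gap = fwd_gap(x, B, L),
      dense = fwd_dense(ly, x),
      block = fwd_block(ly, x, B, L, training),
      stop("unknown layer type: ", ly$type)
    )
    caches[[i]] <- list(r = r$cache, L_in = L)
    x <- r$out
    if (!is.null(r$L)) L <- r$L
    if (ly$type %in% c("flatten", "gap")) L <- NA_integer_
  }
  list(out = x, caches = caches, L = L)
}

seq_backward <- function(layers, caches, dout, B) {
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- caches[[i]]
    dout <- switch(ly$type,
      conv = bwd_conv(ly, cc$r, dout),
      pool = bwd_pool(ly, cc$r, dout),
      bn = bwd_bn(ly, cc$r, dout),
      relu = dout * cc$r$mask,
      flatten = bwd_flatten(cc$r, dout),
      gap = bwd_gap(cc$r, dout),
      dense = bwd_dense(ly, cc$r, dout),
      block = bwd_block(ly, cc$r, dout, B)
    )
  }
  dout
}

fwd_block <- function(ly, x, B, L, training) {
  main <- seq_forward(ly$main, x, B, L, training)
  if (is.null(ly$shortcut)) {
    sc <- list(out = x, caches = NULL, L = L)
  } else {
    sc <- seq_forward(ly$shortcut, x, B, L, training)
  }
  s <- main$out + sc$out
  mask <- s > 0
  list(out = s * mask, L = main$L,
       cache = list(main = main$caches, short = sc$caches, mask = mask, L_in = L))
}

bwd_block <- function(ly, cache, dout, B) {
  ds <- dout * cache$mask
  dx_main <- seq_backward(ly$main, cache$main, ds, B)
  dx_short <- if (is.null(ly$shortcut)) ds
              else seq_backward(ly$shortcut, cache$short, ds, B)
  dx_main + dx_short
}

# ---- parameter plumbing ---------------------------------------------------

param_names <- function(ly) {
  switch(ly$type,
    conv = if (is.null(ly$b)) "W" else c("W", "b"),
    dense = c("W", "b"),
    bn = c("gamma", "beta"),
    character(0))
}

# Flat list of trainable parameter references: list(e = <layer env>, n = <name>).
param_refs <- function(layers) {
  refs <- list()
  for (ly in layers) {
    if (ly$type == "block") {
      refs <- c(refs, param_refs(ly$main))
      if (!is.null(ly$shortcut)) refs <- c(refs, param_refs(ly$shortcut))
    } else {
      for (nm in param_names(ly)) refs <- c(refs, list(list(e = ly, n = nm)))
    }
  }
  refs
}

# BN running statistics (state, not trained parameters).
state_refs <- function(layers) {
  refs <- list()
  for (ly in layers) {
    if (ly$type == "block") {
      refs <- c(refs, state_refs(ly$main))
      if (!is.null(ly$shortcut)) refs <- c(refs, state_refs(ly$shortcut))
    } else if (ly$type == "bn") {
      refs <- c(refs, list(list(e = ly, n = "rmean")), list(list(e = ly, n = "rvar")))
    }
  }
  refs
}

# L2 penalty currently carried by the model's kernels (0 when l2 = 0).
l2_penalty <- function(layers) {
  tot <- 0
  for (ly in layers) {
    if (ly$type == "block") {
      tot <- tot + l2_penalty(ly$main)
      if (!is.null(ly$shortcut)) tot <- tot + l2_penalty(ly$shortcut)
    } else if (ly$type %in% c("conv", "dense") && ly$l2 > 0) {
      tot <- tot + ly$l2 * sum(ly$W^2)
    }
  }
  tot
}

adam_init <- function(refs) {
  list(m = lapply(refs, function(r) r$e[[r$n]] * 0),
       v = lapply(refs, function(r) r$e[[r$n]] * 0),
       t = 0L)
}

adam_step <- function(refs, st, lr, beta1, beta2, eps = 1e-7) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (i in seq_along(refs)) {
    e <- refs[[i]]$e; n <- refs[[i]]$n
    g <- e[[paste0("g", n)]]
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    e[[n]] <- e[[n]] - lr * (st$m[[i]] / c1) / (sqrt(st$v[[i]] / c2) + eps)
  }
  st
}
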