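# Internal layer framework for the SE-ResNet-style branches.
#
# Tensor layouts follow the compiled kernels: 2-D activations (H, W, C, N),
# 3-D activations (D, H, W, C, N); weights (k, k, Cin, Cout) resp.
# (k, k, k, Cin, Cout). Parameters live in named slots (W, b, W1, b1, W2, b2)
# inside layer lists; gradients mirror the same nesting, which lets one
# recursive Adam walker update everything.

PARAM_NAMES <- c("W", "b", "W1", "b1", "W2", "b2")

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

make_conv <- function(nd, k, ci, co, stride) {
  pad <- (k - 1L) %/% 2L
  wd <- c(rep(k, nd), ci, co)
  list(type = if (nd == 2) "conv2" else "conv3",
       W = he_init(wd, fan_in = k^nd * ci),
       b = numeric(co), stride = as.integer(stride), pad = pad)
}

make_se <- function(co, se_reduction) {
  cr <- max(1L, co %/% as.integer(se_reduction))
  list(type = "se",
       W1 = he_init(c(co, cr), fan_in = co), b1 = numeric(cr),
       W2 = he_init(c(cr, co), fan_in = cr), b2 = numeric(co))
}

make_resblock <- function(nd, ci, co, stride, se_reduction) {
  short <- if (ci != co || stride != 1L) make_conv(nd, 1L, ci, co, stride) else NULL
  list(type = "res",
       conv1 = make_conv(nd, 3L, ci, co, stride),
       conv2 = make_conv(nd, 3L, co, co, 1L),
       se = make_se(co, se_reduction),
       short = short)
}

conv_fw <- function(ly, x) {
  if (ly$type == "conv2") cpp_conv2d_fw(x, ly$W, ly$b, ly$stride, ly$pad)
  else cpp_conv3d_fw(x, ly$W, ly$b, ly$stride, ly$pad)
}

conv_bw <- function(ly, x, gy) {
  if (ly$type == "conv2") cpp_conv2d_bw(x, ly$W, gy, ly$stride, ly$pad)
  else cpp_conv3d_bw(x, ly$W, gy, ly$stride, ly$pad)
}

spatial_broadcast <- function(m, d) {
  # m is (C, N); replicate over the leading spatial dims of d
  nsp <- prod(d[seq_len(length(d) - 2L)])
  array(rep(as.numeric(m), each = nsp), d)
}

channel_means <- function(x) {
  d <- dim(x)
  nd <- length(d)
  nsp <- prod(d[seq_len(nd - 2L)])
  matrix(colMeans(matrix(as.numeric(x), nrow = nsp)), d[nd - 1L], d[nd])
}

se_fw <- function(ly, x) {
  d <- dim(x)
  z <- channel_means(x)
  h_pre <- crossprod(ly$W1, z) + ly$b1
  h <- h_pre * (h_pre > 0)
  g <- 1 / (1 + exp(-(crossprod(ly$W2, h) + ly$b2)))
  y <- x * spatial_broadcast(g, d)
  list(y = y, cache = list(x = x, z = z, h = h, g = g))
}

se_bw <- function(ly, cache, gy) {
  d <- dim(cache$x)
  nsp <- prod(d[seq_len(length(d) - 2L)])
  g <- cache$g
  gg <- channel_means(gy * cache$x) * nsp     # dL/dg, per (C, N)
  gx <- gy * spatial_broadcast(g, d)
  dgpre <- gg * g * (1 - g)
  gW2 <- cache$h %*% t(dgpre)
  gb2 <- rowSums(dgpre)
  dh <- (ly$W2 %*% dgpre) * (cache$h > 0)
  gW1 <- cache$z %*% t(dh)
  gb1 <- rowSums(dh)
  dz <- ly$W1 %*% dh
  gx <- gx + spatial_broadcast(dz, d) / nsp
  list(gx = gx, grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

res_fw <- function(ly, x) {
  c1 <- conv_fw(ly$conv1, x)
  r1 <- c1 * (c1 > 0)
  c2 <- conv_fw(ly$conv2, r1)
  se <- se_fw(ly$se, c2)
  sc <- if (is.null(ly$short)) x else conv_fw(ly$short, x)
  pre <- se$y + sc
  y <- pre * (pre > 0)
  list(y = y, cache = list(x = x, c1 = c1, r1 = r1, c2 = c2,
                           se = se$cache, pre_mask = pre > 0))
}

res_bw <- function(ly, cache, gy) {
  gpre <- gy * cache$pre_mask
  seb <- se_bw(ly$se, cache$se, gpre)
  c2b <- conv_bw(ly$conv2, cache$r1, seb$gx)
  gr1 <- c2b$gx * (cache$c1 > 0)
  c1b <- conv_bw(ly$conv1, cache$x, gr1)
  gx <- c1b$gx
  grads <- list(conv1 = list(W = c1b$gw, b = c1b$gb),
                conv2 = list(W = c2b$gw, b = c2b$gb),
                se = seb$grads)
  if (is.null(ly$short)) {
    gx <- gx + gpre
  } else {
    sb <- conv_bw(ly$short, cache$x, gpre)
    gx <- gx + sb$gx
    grads$short <- list(W = sb$gw, b = sb$gb)
  }
  list(gx = gx, grads = grads)
}

layer_fw <- function(ly, x) {
  switch(ly$type,
         conv2 = , conv3 = list(y = conv_fw(ly, x), cache = list(x = x)),
         relu = list(y = x * (x > 0), cache = list(mask = x > 0)),
         se = se_fw(ly, x),
         res = res_fw(ly, x),
         gap = list(y = channel_means(x), cache = list(d = dim(x))),
         stop("unknown layer type ", ly$type))
}

layer_bw <- function(ly, cache, gy) {
  switch(ly$type,
         conv2 = , conv3 = {
           r <- conv_bw(ly, cache$x, gy)
           list(gx = r$gx, grads = list(W = r$gw, b = r$gb))
         },
         relu = list(gx = gy * cache$mask, grads = NULL),
         se = se_bw(ly, cache, gy),
         res = res_bw(ly, cache, gy),
         gap = {
           nsp <- prod(cache$d[seq_len(length(cache$d) - 2L)])
           list(gx = spatial_broadcast(gy, cache$d) / nsp, grads = NULL)
         })
}

body_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fw(layers[[i]], x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

body_backward <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_bw(layers[[i]], caches[[i]], gy)
    gy <- r$gx
    grads[i] <- list(r$grads)  # keep NULL slots for param-free layers
  }
  list(gx = gy, grads = grads)
}

# recursive Adam over the mirrored param/grad nesting --------------------

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.null(g)) return(list(p = p, s = s))
    if (is.numeric(p)) {
      if (is.null(s)) s <- list(m = p * 0, v = p * 0)
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      p <- p - lr * mhat / (sqrt(vhat) + eps)
      return(list(p = p, s = s))
    }
    if (is.list(p)) {
      if (is.null(s)) s <- vector("list", length(p))
      for (nm in names(g)) {
        if (is.null(p[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p
        s[[nm]] <- r$s
      }
      # unnamed lists (per-layer grads)
      if (is.null(names(g))) {
        for (i in seq_along(g)) {
          if (is.null(g[[i]])) next
          r <- walk(p[[i]], g[[i]], s[[i]])
          p[[i]] <- r$p
          s[[i]] <- r$s
        }
      }
      return(list(p = p, s = s))
    }
    list(p = p, s = s)
  }
  walk(params, grads, state)
}

count_leaf_params <- function(x) {
  if (is.numeric(x)) return(length(x))
  if (is.list(x)) {
    total <- 0
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (is.null(nms)) "" else nms[i]
      if (is.numeric(x[[i]]) && nm %in% PARAM_NAMES) total <- total + length(x[[i]])
      else if (is.list(x[[i]])) total <- total + count_leaf_params(x[[i]])
    }
    return(total)
  }
  0
}
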