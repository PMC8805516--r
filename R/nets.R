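#' Network configuration
#'
#' Architecture and optimizer settings of the candidate classifiers. All
#' three variants share the same branch design: a strided stem convolution,
#' `branch_depth` residual stages with squeeze-and-excitation channel gating
#' (channels doubling per stage, stride-2 downsampling from the second stage
#' on), global average pooling, and a fully connected head producing one
#' aneurysm-probability logit. Defaults are deliberately small and tunable;
#' [cross_validate()] is the sanctioned tuner.
#'
#' @param patch_side cubic candidate patch side S in voxels; the planar
#'   branch consumes the (15 S) x S MIP panel, the stereoscopic branch the
#'   raw S^3 patch.
#' @param branch_depth number of SE-residual stages per branch.
#' @param base_channels channels of the first stage (doubled per stage).
#' @param se_reduction squeeze bottleneck reduction ratio (default 16).
#' @param dropout dropout rate on the pooled features (0 disables).
#' @param learning_rate Adam learning rate.
#' @param batch_size,epochs minibatch size and training epochs.
#' @param class_weights weight positives inversely to prevalence.
#' @param val_fraction fraction of training cases held out to track
#'   validation loss when no explicit validation cases are given.
#' @param seed seed controlling initialization, splits and shuffling.
#' @return An object of class `net_config`.
#' @export
net_config <- function(patch_side = 32L, branch_depth = 3L, base_channels = 16L,
                       se_reduction = 16L, dropout = 0, learning_rate = 1e-3,
                       batch_size = 32L, epochs = 10L, class_weights = TRUE,
                       val_fraction = 0.2, seed = 1L) {
  stopifnot(patch_side >= 4, branch_depth >= 1, base_channels >= 1,
            se_reduction >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, batch_size >= 1, epochs >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(patch_side = as.integer(patch_side),
                 branch_depth = as.integer(branch_depth),
                 base_channels = as.integer(base_channels),
                 se_reduction = as.integer(se_reduction),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 class_weights = class_weights,
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "net_config")
}

build_body <- function(nd, in_dim, config) {
  depth <- config$branch_depth
  channels <- config$base_channels * 2^(seq_len(depth) - 1L)
  dims <- in_dim
  step <- function(dims, s) (dims - 1L) %/% s + 1L
  layers <- list(make_conv(nd, 3L, 1L, channels[1], 2L), list(type = "relu"))
  dims <- step(dims, 2L)
  ci <- channels[1]
  for (i in seq_len(depth)) {
    s <- if (i == 1L) 1L else 2L
    if (s == 2L && any(dims < 2L))
      stop("network depth inconsistent with input size ",
           paste(in_dim, collapse = "x"),
           ": stage ", i, " has nothing left to downsample")
    layers[[length(layers) + 1L]] <-
      make_resblock(nd, ci, channels[i], s, config$se_reduction)
    dims <- step(dims, s)
    ci <- channels[i]
  }
  layers[[length(layers) + 1L]] <- list(type = "gap")
  list(layers = layers, feat_dim = ci)
}

new_net <- function(arch, config) {
  set.seed(config$seed)
  S <- config$patch_side
  body2d <- body3d <- NULL
  fdim <- 0L
  if (arch %in% c("2d", "md")) {
    b <- build_body(2L, c(15L * S, S), config)
    body2d <- b$layers
    fdim <- fdim + b$feat_dim
  }
  if (arch %in% c("3d", "md")) {
    b <- build_body(3L, c(S, S, S), config)
    body3d <- b$layers
    fdim <- fdim + b$feat_dim
  }
  head <- list(W = he_init(c(fdim, 1L), fan_in = fdim), b = 0)
  structure(list(arch = arch, config = config, body2d = body2d,
                 body3d = body3d, head = head, feat_dim = fdim,
                 norm = NULL, history = NULL, baseline_val_loss = NA_real_),
            class = "aneu_net")
}

#' Build the planar (2D) classifier
#'
#' SE-residual branch over the 15-view MIP panel, global average pooling and
#' a fully connected probability head.
#'
#' @param config a [net_config()].
#' @return An untrained `aneu_net`.
#' @export
build_2d <- function(config) new_net("2d", config)

#' Build the stereoscopic (3D) classifier
#'
#' SE-residual branch over the raw cubic patch, global average pooling and a
#' fully connected probability head.
#'
#' @param config a [net_config()].
#' @return An untrained `aneu_net`.
#' @export
build_3d <- function(config) new_net("3d", config)

#' Build the fused multidimensional (MD) classifier
#'
#' Two-input model: the planar and stereoscopic branches are pooled by
#' global average pooling, their feature vectors concatenated, and a single
#' fully connected head outputs the aneurysm probability. Both branches are
#' trained simultaneously from scratch (no weight sharing or pre-training).
#'
#' @param config a [net_config()].
#' @return An untrained `aneu_net`.
#' @export
build_md <- function(config) new_net("md", config)

#' Number of trainable parameters
#'
#' @param model an `aneu_net`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  count_leaf_params(list(model$body2d, model$body3d)) +
    length(model$head$W) + length(model$head$b)
}

#' @export
print.aneu_net <- function(x, ...) {
  cat(sprintf("<aneu_net> arch=%s, %d parameters%s\n", x$arch, n_params(x),
              if (!is.null(x$history))
                sprintf(", best val loss %.4f", min(x$history$val_loss))
              else " (untrained)"))
  invisible(x)
}

prep_inputs <- function(model, panels, patches) {
  S <- model$config$patch_side
  x2 <- x3 <- NULL
  if (model$arch %in% c("2d", "md")) {
    if (is.null(panels)) stop("arch ", model$arch, " requires MIP panels")
    if (is.list(panels)) panels <- simplify2array(panels)
    if (length(dim(panels)) == 2) dim(panels) <- c(dim(panels), 1L)
    if (dim(panels)[1] != 15L * S || dim(panels)[2] != S)
      stop("panel shape ", paste(dim(panels)[1:2], collapse = "x"),
           " inconsistent with patch_side ", S)
    x2 <- array(panels, c(dim(panels)[1:2], 1L, dim(panels)[3]))
  }
  if (model$arch %in% c("3d", "md")) {
    if (is.null(patches)) stop("arch ", model$arch, " requires 3-D patches")
    if (is.list(patches)) patches <- simplify2array(patches)
    if (length(dim(patches)) == 3) dim(patches) <- c(dim(patches), 1L)
    if (!all(dim(patches)[1:3] == S))
      stop("patch shape inconsistent with patch_side ", S)
    x3 <- array(patches, c(dim(patches)[1:3], 1L, dim(patches)[4]))
  }
  list(x2 = x2, x3 = x3,
       n = if (!is.null(x2)) dim(x2)[4] else dim(x3)[5])
}

subset_inputs <- function(x2, x3, idx) {
  list(x2 = if (!is.null(x2)) x2[, , , idx, drop = FALSE] else NULL,
       x3 = if (!is.null(x3)) x3[, , , , idx, drop = FALSE] else NULL)
}

normalize_inputs <- function(x2, x3, norm) {
  if (!is.null(x2)) x2 <- (x2 - norm$mu2) / norm$sd2
  if (!is.null(x3)) x3 <- (x3 - norm$mu3) / norm$sd3
  list(x2 = x2, x3 = x3)
}

net_forward <- function(model, x2, x3, training = FALSE, drop_mask = NULL) {
  f2 <- f3 <- NULL
  feats <- NULL
  if (!is.null(model$body2d)) {
    f2 <- body_forward(model$body2d, x2)
    feats <- f2$out
  }
  if (!is.null(model$body3d)) {
    f3 <- body_forward(model$body3d, x3)
    feats <- if (is.null(feats)) f3$out else rbind(feats, f3$out)
  }
  if (training && !is.null(drop_mask)) feats <- feats * drop_mask
  logits <- as.numeric(crossprod(model$head$W, feats) + model$head$b)
  list(logits = logits, feats = feats, f2 = f2, f3 = f3)
}

stable_bce <- function(logits, y, w = NULL) {
  l <- pmax(logits, 0) - logits * y + log1p(exp(-abs(logits)))
  if (is.null(w)) mean(l) else sum(w * l) / sum(w)
}

net_val_loss <- function(model, x2, x3, y, chunk = 64L) {
  n <- length(y)
  total <- 0
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    xb <- subset_inputs(x2, x3, idx)
    fw <- net_forward(model, xb$x2, xb$x3)
    total <- total + sum(pmax(fw$logits, 0) - fw$logits * y[idx] +
                           log1p(exp(-abs(fw$logits))))
  }
  total / n
}

#' Train a classifier on labelled candidates
#'
#' Minimizes binary cross-entropy with Adam, tracking per-epoch training and
#' validation loss; the weights from the best validation epoch are returned.
#' Validation is split at case level (candidates from one case stay
#' together) either from `val_cases` or by drawing `val_fraction` of the
#' training cases. Positives are weighted inversely to prevalence when
#' `class_weights` is set. Fully seeded: identical data, config and seed give
#' identical results.
#'
#' @param model an untrained `aneu_net` from [build_2d()], [build_3d()] or
#'   [build_md()].
#' @param panels MIP panels, array (15 S) x S x N (or list); needed for the
#'   2d/md architectures.
#' @param patches raw patches, array S x S x S x N (or list); needed for
#'   3d/md.
#' @param labels length-N vector; `"positive"`/`"negative"` or 1/0. Partial
#'   candidates must be excluded upstream.
#' @param case_ids optional length-N case identifiers for case-level splits.
#' @param val_cases optional explicit validation case ids.
#' @return The trained `aneu_net`, with `history` (one row per epoch) and
#'   `baseline_val_loss` (the best constant predictor's validation loss).
#' @export
train_net <- function(model, panels = NULL, patches = NULL, labels,
                      case_ids = NULL, val_cases = NULL) {
  stopifnot(inherits(model, "aneu_net"))
  config <- model$config
  y <- as.integer(labels == "positive" | labels == 1 | labels == TRUE)
  if (!any(y == 1) || !any(y == 0))
    stop("training requires both positive and negative candidates")
  inp <- prep_inputs(model, panels, patches)
  n <- inp$n
  stopifnot(length(y) == n)
  set.seed(config$seed + 17L)
  if (!is.null(val_cases) && !is.null(case_ids)) {
    val_idx <- which(case_ids %in% val_cases)
  } else if (!is.null(case_ids)) {
    uc <- unique(case_ids)
    vc <- sample(uc, max(1L, round(config$val_fraction * length(uc))))
    val_idx <- which(case_ids %in% vc)
  } else {
    val_idx <- sample(n, max(1L, round(config$val_fraction * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(val_idx) == 0 || length(tr_idx) == 0)
    stop("empty training or validation split")
  if (!any(y[tr_idx] == 1) || !any(y[tr_idx] == 0))
    stop("training split lacks a class; provide more cases")
  # input standardization from the training split
  norm <- list(mu2 = 0, sd2 = 1, mu3 = 0, sd3 = 1)
  if (!is.null(inp$x2)) {
    v <- inp$x2[, , , tr_idx, drop = FALSE]
    norm$mu2 <- mean(v); norm$sd2 <- max(sd(as.numeric(v)), 1e-8)
  }
  if (!is.null(inp$x3)) {
    v <- inp$x3[, , , , tr_idx, drop = FALSE]
    norm$mu3 <- mean(v); norm$sd3 <- max(sd(as.numeric(v)), 1e-8)
  }
  model$norm <- norm
  nx <- normalize_inputs(inp$x2, inp$x3, norm)
  x2 <- nx$x2; x3 <- nx$x3
  w <- rep(1, n)
  if (isTRUE(config$class_weights)) {
    npos <- sum(y[tr_idx] == 1); nneg <- sum(y[tr_idx] == 0)
    w[y == 1] <- length(tr_idx) / (2 * npos)
    w[y == 0] <- length(tr_idx) / (2 * nneg)
  }
  params <- list(body2d = model$body2d, body3d = model$body3d,
                 head = model$head)
  state <- NULL
  tstep <- 0L
  best_val <- Inf
  best_params <- params
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  xv <- subset_inputs(x2, x3, val_idx)
  yv <- y[val_idx]
  for (epoch in seq_len(config$epochs)) {
    set.seed(config$seed + 1000L + epoch)
    ord <- sample(tr_idx)
    ep_loss <- 0; ep_w <- 0
    for (s in seq(1L, length(ord), by = config$batch_size)) {
      bidx <- ord[s:min(length(ord), s + config$batch_size - 1L)]
      xb <- subset_inputs(x2, x3, bidx)
      yb <- y[bidx]; wb <- w[bidx]
      model$body2d <- params$body2d
      model$body3d <- params$body3d
      model$head <- params$head
      drop_mask <- NULL
      if (config$dropout > 0) {
        drop_mask <- matrix(
          (runif(model$feat_dim * length(bidx)) > config$dropout) /
            (1 - config$dropout),
          model$feat_dim, length(bidx))
      }
      fw <- net_forward(model, xb$x2, xb$x3, training = TRUE,
                        drop_mask = drop_mask)
      p <- 1 / (1 + exp(-fw$logits))
      lb <- sum(wb * (pmax(fw$logits, 0) - fw$logits * yb +
                        log1p(exp(-abs(fw$logits)))))
      ep_loss <- ep_loss + lb; ep_w <- ep_w + sum(wb)
      dlogit <- wb * (p - yb) / sum(wb)
      gfeats <- params$head$W %*% matrix(dlogit, nrow = 1)
      gW_head <- fw$feats %*% matrix(dlogit, ncol = 1)
      gb_head <- sum(dlogit)
      if (!is.null(drop_mask)) gfeats <- gfeats * drop_mask
      grads <- list(head = list(W = gW_head, b = gb_head))
      off <- 0L
      if (!is.null(fw$f2)) {
        d2 <- nrow(fw$f2$out)
        g2 <- gfeats[seq_len(d2), , drop = FALSE]
        grads$body2d <- body_backward(params$body2d, fw$f2$caches, g2)$grads
        off <- d2
      }
      if (!is.null(fw$f3)) {
        g3 <- gfeats[off + seq_len(nrow(fw$f3$out)), , drop = FALSE]
        grads$body3d <- body_backward(params$body3d, fw$f3$caches, g3)$grads
      }
      tstep <- tstep + 1L
      upd <- adam_step(params, grads, state, config$learning_rate, tstep)
      params <- upd$p
      state <- upd$s
    }
    model$body2d <- params$body2d
    model$body3d <- params$body3d
    model$head <- params$head
    vl <- net_val_loss(model, xv$x2, xv$x3, yv)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / ep_w,
                                   val_loss = vl))
    if (vl < best_val) {
      best_val <- vl
      best_params <- params
    }
  }
  model$body2d <- best_params$body2d
  model$body3d <- best_params$body3d
  model$head <- best_params$head
  model$history <- hist
  phat <- min(max(mean(y[tr_idx]), 1e-6), 1 - 1e-6)
  model$baseline_val_loss <- -mean(yv * log(phat) + (1 - yv) * log(1 - phat))
  model
}

#' Predict aneurysm probabilities
#'
#' Pure function of (weights, inputs): repeated calls agree exactly.
#'
#' @param object a trained `aneu_net`.
#' @param panels,patches candidate inputs as in [train_net()].
#' @param ... unused.
#' @return Numeric probabilities in `[0, 1]`.
#' @export
predict.aneu_net <- function(object, panels = NULL, patches = NULL, ...) {
  inp <- prep_inputs(object, panels, patches)
  norm <- object$norm
  if (is.null(norm)) norm <- list(mu2 = 0, sd2 = 1, mu3 = 0, sd3 = 1)
  nx <- normalize_inputs(inp$x2, inp$x3, norm)
  out <- numeric(inp$n)
  for (s in seq(1L, inp$n, by = 64L)) {
    idx <- s:min(inp$n, s + 63L)
    xb <- subset_inputs(nx$x2, nx$x3, idx)
    fw <- net_forward(object, xb$x2, xb$x3)
    out[idx] <- 1 / (1 + exp(-fw$logits))
  }
  out
}

#' Case-level k-fold cross-validation over a config grid
#'
#' Splits cases (not candidates) into k folds, trains each candidate config
#' on k-1 folds with the held-out fold as validation, and returns the config
#' with the best mean validation loss.
#'
#' @param arch `"2d"`, `"3d"` or `"md"`.
#' @param panels,patches,labels,case_ids as in [train_net()].
#' @param config_grid non-empty list of [net_config()] objects.
#' @param k number of folds (default 4).
#' @param seed fold-assignment seed.
#' @return List with `best_config`, `results` (per-config mean validation
#'   loss) and `folds` (case-to-fold assignment).
#' @export
cross_validate <- function(arch, panels = NULL, patches = NULL, labels,
                           case_ids, config_grid, k = 4L, seed = 1L) {
  if (length(config_grid) == 0) stop("config_grid is empty")
  uc <- unique(case_ids)
  if (length(uc) < k) stop("fewer cases than folds")
  set.seed(seed)
  fold_of <- setNames(rep(seq_len(k), length.out = length(uc)),
                      sample(uc))
  mean_loss <- numeric(length(config_grid))
  for (ci in seq_along(config_grid)) {
    cfg <- config_grid[[ci]]
    losses <- numeric(k)
    for (f in seq_len(k)) {
      vc <- names(fold_of)[fold_of == f]
      model <- new_net(arch, cfg)
      fit <- train_net(model, panels = panels, patches = patches,
                       labels = labels, case_ids = case_ids, val_cases = vc)
      losses[f] <- min(fit$history$val_loss)
    }
    mean_loss[ci] <- mean(losses)
  }
  best <- which.min(mean_loss)
  list(best_config = config_grid[[best]],
       results = data.frame(config = seq_along(config_grid),
                            mean_val_loss = mean_loss),
       folds = fold_of)
}
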