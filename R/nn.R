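`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal CPU training engine for the package's convolutional models.
# Tensors are R arrays with dim (H, W, C, N); convolution and pooling run in
# compiled code, the remaining ops are vectorised R. Every layer is an
# environment holding parameters, gradients, Adam state, and forward caches.

.new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

nn_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L, groups = 1L) {
  cpg <- cin %/% groups
  sd <- sqrt(2 / (kh * kw * cpg))
  W <- array(stats::rnorm(kh * kw * cpg * cout, sd = sd),
             dim = c(kh, kw, cpg, cout))
  .new_layer("conv", W = W, b = numeric(cout),
             stride = as.integer(stride), pad = as.integer(pad),
             groups = as.integer(groups), pnames = c("W", "b"))
}

nn_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  .new_layer("bn", gamma = rep(1, c), beta = numeric(c),
             rmean = numeric(c), rvar = rep(1, c), r_init = FALSE,
             momentum = momentum, eps = eps, pnames = c("gamma", "beta"))
}

nn_act <- function(kind = c("relu", "swish", "sigmoid")) {
  .new_layer("act", kind = match.arg(kind), pnames = character(0))
}

nn_pool <- function(k = 2L, stride = 2L, pad = 0L) {
  .new_layer("pool", k = as.integer(k), stride = as.integer(stride),
             pad = as.integer(pad), pnames = character(0))
}

nn_dense <- function(din, dout) {
  .new_layer("dense", W = matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)),
                                 din, dout),
             b = numeric(dout), pnames = c("W", "b"))
}

layer_forward <- function(l, x, train = TRUE) {
  switch(l$type,
    conv = {
      l$x <- x
      nn_conv2d_fwd(x, l$W, l$b, l$stride, l$pad, l$groups)
    },
    bn = {
      d <- dim(x)
      C <- d[3]
      xp <- aperm(x, c(1, 2, 4, 3))
      M <- matrix(xp, ncol = C)
      if (train) {
        mu <- colMeans(M)
        v <- colMeans(M^2) - mu^2
        if (!l$r_init) {
          # seed the running stats with the first batch seen
          l$rmean <- mu
          l$rvar <- v
          l$r_init <- TRUE
        } else {
          l$rmean <- l$momentum * l$rmean + (1 - l$momentum) * mu
          l$rvar <- l$momentum * l$rvar + (1 - l$momentum) * v
        }
      } else {
        mu <- l$rmean
        v <- l$rvar
      }
      invstd <- 1 / sqrt(v + l$eps)
      Mh <- sweep(sweep(M, 2, mu), 2, invstd, "*")
      Y <- sweep(sweep(Mh, 2, l$gamma, "*"), 2, l$beta, "+")
      if (train) {
        l$Mh <- Mh
        l$invstd <- invstd
        l$xdim <- d
      }
      aperm(array(Y, dim = dim(xp)), c(1, 2, 4, 3))
    },
    act = {
      y <- switch(l$kind,
        relu = pmax(x, 0),
        swish = x / (1 + exp(-x)),
        sigmoid = 1 / (1 + exp(-x)))
      if (is.array(x)) dim(y) <- dim(x)
      l$x <- x
      l$y <- y
      y
    },
    pool = {
      r <- nn_maxpool_fwd(x, l$k, l$stride, l$pad)
      l$arg <- r$arg
      l$xdim <- dim(x)
      r$y
    },
    dense = {
      l$x <- x
      sweep(x %*% l$W, 2, l$b, "+")
    },
    stop("unknown layer type: ", l$type))
}

layer_backward <- function(l, gy) {
  switch(l$type,
    conv = {
      r <- nn_conv2d_bwd(l$x, l$W, gy, l$stride, l$pad, l$groups)
      l$gW <- r$gw
      l$gb <- r$gb
      l$x <- NULL
      r$gx
    },
    bn = {
      d <- l$xdim
      C <- d[3]
      G <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = C)
      m <- nrow(G)
      l$ggamma <- colSums(G * l$Mh)
      l$gbeta <- colSums(G)
      dMh <- sweep(G, 2, l$gamma, "*")
      t1 <- sweep(dMh, 2, colSums(dMh) / m)
      t2 <- sweep(l$Mh, 2, colSums(dMh * l$Mh) / m, "*")
      GX <- sweep(t1 - t2, 2, l$invstd, "*")
      l$Mh <- NULL
      aperm(array(GX, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    },
    act = {
      g <- switch(l$kind,
        relu = gy * (l$x > 0),
        swish = {
          s <- 1 / (1 + exp(-l$x))
          gy * (s + l$x * s * (1 - s))
        },
        sigmoid = gy * l$y * (1 - l$y))
      if (is.array(l$x)) dim(g) <- dim(l$x)
      l$x <- NULL
      l$y <- NULL
      g
    },
    pool = {
      gx <- nn_maxpool_bwd(gy, l$arg, l$xdim)
      l$arg <- NULL
      gx
    },
    dense = {
      l$gW <- crossprod(l$x, gy)
      l$gb <- colSums(gy)
      gx <- gy %*% t(l$W)
      l$x <- NULL
      gx
    })
}

# nearest-neighbour 2x upsampling
upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsample2_backward <- function(gy) {
  d <- dim(gy)
  o1 <- seq(1, d[1], 2); e1 <- seq(2, d[1], 2)
  o2 <- seq(1, d[2], 2); e2 <- seq(2, d[2], 2)
  gy[o1, o2, , , drop = FALSE] + gy[e1, o2, , , drop = FALSE] +
    gy[o1, e2, , , drop = FALSE] + gy[e1, e2, , , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

global_avgpool_forward <- function(x) {
  d <- dim(x)
  M <- matrix(x, nrow = d[1] * d[2])
  t(matrix(colMeans(M), nrow = d[3]))       # (N, C)
}

global_avgpool_backward <- function(gy, xdim) {
  g <- array(0, dim = xdim)
  scale <- 1 / (xdim[1] * xdim[2])
  for (n in seq_len(xdim[4])) {
    g[, , , n] <- rep(gy[n, ] * scale, each = xdim[1] * xdim[2])
  }
  g
}

# softmax cross-entropy on logits (N, K); labels integer in 1..K
softmax_ce <- function(logits, labels) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(p)
  ll <- -log(pmax(p[cbind(seq_len(n), labels)], 1e-12))
  g <- p
  g[cbind(seq_len(n), labels)] <- g[cbind(seq_len(n), labels)] - 1
  list(loss = mean(ll), grad = g / n, probs = p)
}

# pixel-wise binary cross-entropy + Dice on logits (H, W, 1, N), equal
# weights; target binary array of same dim
bce_dice <- function(logits, target) {
  p <- 1 / (1 + exp(-logits))
  n <- length(p)
  eps <- 1e-7
  bce <- -mean(target * log(p + eps) + (1 - target) * log(1 - p + eps))
  sp <- sum(p); st <- sum(target); si <- sum(p * target)
  dice <- 1 - (2 * si + 1) / (sp + st + 1)
  # d(bce)/dz = (p - t)/n ; d(dice)/dp then chain through sigmoid
  ddice_dp <- (-2 * target * (sp + st + 1) + (2 * si + 1)) / (sp + st + 1)^2
  g <- (p - target) / n + ddice_dp * p * (1 - p)
  dim(g) <- dim(logits)
  list(loss = bce + dice, grad = g, probs = p)
}

collect_layers <- function(x) {
  # flatten nested lists of layer environments
  if (is.environment(x)) return(list(x))
  unlist(lapply(x, collect_layers), recursive = FALSE)
}

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  for (l in layers) {
    for (p in l$pnames) {
      g <- get(paste0("g", p), envir = l)
      if (is.null(g)) next
      # decoupled weight decay on convolution/dense weights only
      if (weight_decay > 0 && p == "W") {
        g <- g + weight_decay * get(p, envir = l)
      }
      mn <- paste0("adam_m_", p); vn <- paste0("adam_v_", p)
      m <- if (exists(mn, envir = l, inherits = FALSE)) get(mn, envir = l)
           else g * 0
      v <- if (exists(vn, envir = l, inherits = FALSE)) get(vn, envir = l)
           else g * 0
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      val <- get(p, envir = l) - lr * mh / (sqrt(vh) + eps)
      assign(p, val, envir = l)
      assign(mn, m, envir = l)
      assign(vn, v, envir = l)
    }
  }
  invisible(NULL)
}

# snapshot / restore parameter values plus per-layer state (batch-norm
# running statistics travel with the weights they were trained with)
snapshot_params <- function(layers) {
  lapply(layers, function(l) {
    nms <- l$pnames
    if (l$type == "bn") nms <- c(nms, "rmean", "rvar", "r_init")
    mget(nms, envir = l)
  })
}

restore_params <- function(layers, snap) {
  for (k in seq_along(layers)) {
    for (p in names(snap[[k]])) assign(p, snap[[k]][[p]], envir = layers[[k]])
  }
  invisible(NULL)
}
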