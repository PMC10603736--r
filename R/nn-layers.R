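# Minimal neural-network engine.
#
# Activations are (T*B) x C double matrices, column-major, time fastest,
# with attr "dims" = c(T, B); after global average pooling T = 1 and the
# matrix is B x C.  Each layer is a plain list; layer_fwd returns the
# output, a cache for the backward pass, and the (possibly updated) layer
# so batch-norm running statistics can persist.  Convolutions run through
# the float32 GEMM kernel in src/; a pure-R reference implementation is
# kept alongside as the oracle for its tests.

act_dims <- function(X) {
  d <- attr(X, "dims")
  if (is.null(d)) c(1L, nrow(X)) else d
}

set_dims <- function(X, T, B) {
  attr(X, "dims") <- c(T = as.integer(T), B = as.integer(B))
  X
}

L_conv <- function(k, c_in, c_out, pad_mode = c("zero", "circular")) {
  if (k %% 2 != 1) stop("kernel length must be odd for same padding")
  list(type = "conv", k = k, c_in = c_in, c_out = c_out,
       pad_mode = match.arg(pad_mode), W = NULL, b = NULL)
}

L_dense <- function(c_in, c_out) {
  list(type = "dense", c_in = c_in, c_out = c_out, W = NULL, b = NULL)
}

L_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", c = c, momentum = momentum, eps = eps,
       gamma = rep(1, c), beta = rep(0, c),
       running_mean = rep(0, c), running_var = rep(1, c))
}

L_act <- function(slope = 0.01) list(type = "act", slope = slope)
L_drop <- function(p) list(type = "drop", p = p)
L_gap <- function() list(type = "gap")

# fan-in-scaled (He) init from the current RNG stream
layer_init <- function(layer) {
  if (layer$type == "conv") {
    fan_in <- layer$k * layer$c_in
    layer$W <- array(rnorm(layer$k * layer$c_in * layer$c_out,
                           sd = sqrt(2 / fan_in)),
                     dim = c(layer$k, layer$c_in, layer$c_out))
    layer$b <- rep(0, layer$c_out)
  } else if (layer$type == "dense") {
    layer$W <- matrix(rnorm(layer$c_in * layer$c_out,
                            sd = sqrt(2 / layer$c_in)),
                      layer$c_in, layer$c_out)
    layer$b <- rep(0, layer$c_out)
  }
  layer
}

# Pure-R reference convolution (oracle for the C++ kernel).
conv1d_fwd_ref <- function(X, W, b, T, B, pad_mode = "zero") {
  k <- dim(W)[1]; ci <- dim(W)[2]; co <- dim(W)[3]
  pad <- (k - 1) / 2
  Y <- matrix(0, T * B, co)
  for (o in seq_len(k)) {
    S <- matrix(0, T * B, ci)
    for (bb in seq_len(B)) for (t in seq_len(T)) {
      src <- t + (o - 1) - pad
      if (pad_mode == "circular") src <- ((src - 1) %% T) + 1
      if (src >= 1 && src <= T)
        S[(bb - 1) * T + t, ] <- X[(bb - 1) * T + src, ]
    }
    Y <- Y + S %*% matrix(W[o, , ], ci, co)
  }
  sweep(Y, 2, b, `+`)
}

layer_fwd <- function(layer, X, train = FALSE) {
  d <- act_dims(X)
  out <- switch(layer$type,
    conv = {
      Y <- conv1d_fwd_cpp(X, as.numeric(layer$W), layer$b, d[1], d[2],
                          layer$k, if (layer$pad_mode == "circular") 1L else 0L)
      list(Y = set_dims(Y, d[1], d[2]), cache = list(X = X))
    },
    dense = {
      Y <- X %*% layer$W + rep(layer$b, each = nrow(X))
      list(Y = set_dims(Y, d[1], d[2]), cache = list(X = X))
    },
    bn = {
      r <- bn_fwd_cpp(X, layer$gamma, layer$beta, layer$running_mean,
                      layer$running_var, layer$eps, layer$momentum, train)
      if (train) {
        layer$running_mean <- r$running_mean
        layer$running_var <- r$running_var
      }
      list(Y = set_dims(r$Y, d[1], d[2]),
           cache = list(X = X, mu = r$mu, inv = r$inv, train = train))
    },
    act = {
      Y <- leaky_fwd_cpp(X, layer$slope)
      list(Y = set_dims(Y, d[1], d[2]), cache = list(X = X))
    },
    drop = {
      if (train && layer$p > 0) {
        mask <- (runif(length(X)) >= layer$p) / (1 - layer$p)
        Y <- X * mask
        list(Y = set_dims(Y, d[1], d[2]), cache = list(mask = mask))
      } else {
        list(Y = X, cache = list(mask = NULL))
      }
    },
    gap = {
      T <- d[1]; B <- d[2]; C <- ncol(X)
      Z <- X
      dim(Z) <- c(T, B * C)
      Y <- matrix(colMeans(Z), B, C)
      list(Y = set_dims(Y, 1, B), cache = list(T = T, B = B, C = C))
    },
    stop("unknown layer type ", layer$type))
  list(Y = out$Y, cache = out$cache, layer = layer)
}

layer_bwd <- function(layer, cache, dY) {
  d <- act_dims(dY)
  switch(layer$type,
    conv = {
      g <- conv1d_bwd_cpp(cache$X, as.numeric(layer$W), dY, d[1], d[2],
                          layer$k, if (layer$pad_mode == "circular") 1L else 0L)
      list(dX = set_dims(g$dX, d[1], d[2]),
           grads = list(W = array(g$dW, dim(layer$W)), b = as.numeric(g$db)))
    },
    dense = {
      list(dX = set_dims(dY %*% t(layer$W), d[1], d[2]),
           grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
    },
    bn = {
      r <- bn_bwd_cpp(cache$X, dY, layer$gamma, cache$mu, cache$inv,
                      isTRUE(cache$train))
      list(dX = set_dims(r$dX, d[1], d[2]),
           grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    act = {
      dX <- leaky_bwd_cpp(cache$X, dY, layer$slope)
      list(dX = set_dims(dX, d[1], d[2]), grads = list())
    },
    drop = {
      dX <- if (is.null(cache$mask)) dY else dY * cache$mask
      list(dX = set_dims(dX, d[1], d[2]), grads = list())
    },
    gap = {
      T <- cache$T; B <- cache$B; C <- cache$C
      dX <- matrix(0, T * B, C)
      # each pooled value spreads dY/T over its T time positions
      for (c in seq_len(C)) {
        dX[, c] <- rep(dY[, c], each = T) / T
      }
      list(dX = set_dims(dX, T, B), grads = list())
    },
    stop("unknown layer type ", layer$type))
}

# Sequential composition ------------------------------------------------

seq_init <- function(layers) lapply(layers, layer_init)

seq_fwd <- function(layers, X, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], X, train)
    X <- r$Y
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(Y = X, caches = caches, layers = layers)
}

seq_bwd <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_bwd(layers[[i]], caches[[i]], dY)
    dY <- r$dX
    grads[[i]] <- r$grads
  }
  list(dX = dY, grads = grads)
}

# Parameter bookkeeping: flatten trainable arrays into a named list so the
# optimizer can iterate them uniformly.
PARAM_FIELDS <- c("W", "b", "gamma", "beta")

seq_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers))
    for (f in PARAM_FIELDS)
      if (!is.null(layers[[i]][[f]]) && layers[[i]]$type %in% c("conv", "dense", "bn"))
        out[[paste0("l", i, ".", f)]] <- layers[[i]][[f]]
  out
}

seq_set_params <- function(layers, params, prefix = "") {
  for (nm in names(params)) {
    parts <- strsplit(sub(prefix, "", nm, fixed = TRUE), ".", fixed = TRUE)[[1]]
    i <- as.integer(sub("l", "", parts[1]))
    layers[[i]][[parts[2]]] <- params[[nm]]
  }
  layers
}

seq_grads_flat <- function(grads) {
  out <- list()
  for (i in seq_along(grads))
    for (f in names(grads[[i]]))
      out[[paste0("l", i, ".", f)]] <- grads[[i]][[f]]
  out
}

# Fused sequential path: runs conv->bn[->act] triples through the fused
# float kernel (one C++ call per triple, float caches via external
# pointers), other layers through the generic per-layer path.  Gradients
# come back indexed per layer so parameter bookkeeping is unchanged.
fseq_fwd <- function(layers, X, train = FALSE) {
  n <- length(layers)
  segs <- list()
  i <- 1
  while (i <= n) {
    li <- layers[[i]]
    if (li$type == "conv" && i < n && layers[[i + 1]]$type == "bn") {
      has_act <- i + 2 <= n && layers[[i + 2]]$type == "act"
      bn <- layers[[i + 1]]
      d <- act_dims(X)
      r <- fused_cba_fwd(X, as.numeric(li$W), li$b, d[1], d[2], li$k,
                         if (li$pad_mode == "circular") 1L else 0L,
                         bn$gamma, bn$beta, bn$running_mean, bn$running_var,
                         bn$eps, bn$momentum, train, has_act,
                         if (has_act) layers[[i + 2]]$slope else 0)
      if (train) {
        layers[[i + 1]]$running_mean <- r$running_mean
        layers[[i + 1]]$running_var <- r$running_var
      }
      X <- set_dims(r$Y, d[1], d[2])
      segs[[length(segs) + 1]] <- list(type = "fused", i_conv = i,
                                       i_bn = i + 1, has_act = has_act,
                                       ptr = r$cache)
      i <- i + (if (has_act) 3 else 2)
    } else {
      r <- layer_fwd(li, X, train)
      X <- r$Y
      layers[[i]] <- r$layer
      segs[[length(segs) + 1]] <- list(type = "plain", i = i, cache = r$cache)
      i <- i + 1
    }
  }
  list(Y = X, segs = segs, layers = layers)
}

fseq_bwd <- function(layers, segs, dY) {
  grads <- vector("list", length(layers))
  for (s in rev(seq_along(segs))) {
    sg <- segs[[s]]
    if (sg$type == "fused") {
      conv <- layers[[sg$i_conv]]
      bn <- layers[[sg$i_bn]]
      d <- act_dims(dY)
      r <- fused_cba_bwd(sg$ptr, as.numeric(conv$W), bn$gamma, bn$beta, dY)
      dY <- set_dims(r$dX, d[1], d[2])
      grads[[sg$i_conv]] <- list(W = array(r$dW, dim(conv$W)),
                                 b = as.numeric(r$db))
      grads[[sg$i_bn]] <- list(gamma = r$dgamma, beta = r$dbeta)
    } else {
      r <- layer_bwd(layers[[sg$i]], sg$cache, dY)
      dY <- r$dX
      grads[[sg$i]] <- r$grads
    }
  }
  list(dX = dY, grads = grads)
}
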