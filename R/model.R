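# Shared residual feature extractor + label classifier, and the two
# method-specific heads (domain classifier, decoder).
#
# The extractor reads a 6-channel window of any length T >= 7 and emits a
# 128-d feature: three residual blocks with time-axis kernels {7, 5, 3} and
# channel widths {64, 128, 128} (conv-BN-act-conv-BN plus a projected or
# identity shortcut, then activation), closed by global average pooling.
# The six sensor axes enter as input channels, so the first convolution
# mixes axes.  The classifier is 128 -> 128 -> 64 -> n_classes with batch
# norm, leaky ReLU and dropout on the hidden layers; it outputs logits.

#' Feature-extractor architecture configuration
#'
#' @param kernel_lengths Time-axis kernel lengths per residual block.
#' @param channels Channel widths per residual block.
#' @param leaky_slope Negative slope of the leaky rectifier.
#' @param pad_mode `"zero"` (default "same" padding) or `"circular"`.
#' @return An `extractor_config`.
#' @export
extractor_config <- function(kernel_lengths = c(7, 5, 3),
                             channels = c(64, 128, 128),
                             leaky_slope = 0.01,
                             pad_mode = c("zero", "circular")) {
  if (length(kernel_lengths) != length(channels))
    stop("kernel_lengths and channels must have equal length", call. = FALSE)
  structure(list(kernel_lengths = kernel_lengths, channels = channels,
                 leaky_slope = leaky_slope, pad_mode = match.arg(pad_mode)),
            class = "extractor_config")
}

#' Label-classifier architecture configuration
#'
#' @param n_classes Number of activity classes (>= 2).
#' @param hidden_sizes Hidden fully-connected widths.
#' @param dropout_rate Dropout probability on each hidden layer.
#' @param leaky_slope Negative slope of the leaky rectifier.
#' @return A `classifier_config`.
#' @export
classifier_config <- function(n_classes, hidden_sizes = c(128, 64),
                              dropout_rate = 0.2, leaky_slope = 0.01) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  structure(list(n_classes = as.integer(n_classes),
                 hidden_sizes = hidden_sizes, dropout_rate = dropout_rate,
                 leaky_slope = leaky_slope), class = "classifier_config")
}

res_block <- function(k, c_in, c_out, slope, pad_mode) {
  main <- list(L_conv(k, c_in, c_out, pad_mode), L_bn(c_out), L_act(slope),
               L_conv(k, c_out, c_out, pad_mode), L_bn(c_out))
  short <- if (c_in != c_out)
    list(L_conv(1, c_in, c_out, pad_mode), L_bn(c_out)) else NULL
  list(main = main, short = short, act = L_act(slope))
}

#' Build an (uninitialized-weights-seeded) feature extractor
#'
#' @param config An [extractor_config()].
#' @param in_channels Input channel count (6 for an IMU window).
#' @return An extractor model tree; initialize with the current RNG stream.
#' @export
build_extractor <- function(config = extractor_config(), in_channels = 6) {
  blocks <- list()
  c_in <- in_channels
  for (i in seq_along(config$channels)) {
    b <- res_block(config$kernel_lengths[i], c_in, config$channels[i],
                   config$leaky_slope, config$pad_mode)
    b$main <- seq_init(b$main)
    if (!is.null(b$short)) b$short <- seq_init(b$short)
    blocks[[i]] <- b
    c_in <- config$channels[i]
  }
  list(blocks = blocks, gap = L_gap(), out_dim = c_in, config = config)
}

block_fwd <- function(block, X, train) {
  m <- fseq_fwd(block$main, X, train)
  if (!is.null(block$short)) {
    s <- fseq_fwd(block$short, X, train)
    block$short <- s$layers
    pre <- m$Y + s$Y
    pre <- set_dims(pre, act_dims(X)[1], act_dims(X)[2])
    scache <- s$segs
  } else {
    pre <- m$Y + X
    scache <- NULL
  }
  block$main <- m$layers
  a <- layer_fwd(block$act, pre, train)
  list(Y = a$Y, block = block,
       cache = list(main = m$segs, short = scache, act = a$cache))
}

block_bwd <- function(block, cache, dY) {
  a <- layer_bwd(block$act, cache$act, dY)
  dpre <- a$dX
  m <- fseq_bwd(block$main, cache$main, dpre)
  grads <- list(main = m$grads)
  if (!is.null(block$short)) {
    s <- fseq_bwd(block$short, cache$short, dpre)
    grads$short <- s$grads
    dX <- m$dX + s$dX
  } else {
    dX <- m$dX + dpre
  }
  list(dX = set_dims(dX, act_dims(dY)[1], act_dims(dY)[2]), grads = grads)
}

extractor_fwd <- function(ext, X, train = FALSE) {
  caches <- vector("list", length(ext$blocks))
  for (i in seq_along(ext$blocks)) {
    r <- block_fwd(ext$blocks[[i]], X, train)
    X <- r$Y
    ext$blocks[[i]] <- r$block
    caches[[i]] <- r$cache
  }
  g <- layer_fwd(ext$gap, X, train)
  list(feat = g$Y, ext = ext, caches = list(blocks = caches, gap = g$cache))
}

extractor_bwd <- function(ext, caches, dfeat) {
  g <- layer_bwd(ext$gap, caches$gap, dfeat)
  dY <- g$dX
  grads <- vector("list", length(ext$blocks))
  for (i in rev(seq_along(ext$blocks))) {
    r <- block_bwd(ext$blocks[[i]], caches$blocks[[i]], dY)
    dY <- r$dX
    grads[[i]] <- r$grads
  }
  list(dX = dY, grads = list(blocks = grads))
}

#' Build the label classifier
#'
#' @param config A [classifier_config()].
#' @param in_dim Input feature width (128 from the default extractor).
#' @return A classifier layer list.
#' @export
build_classifier <- function(config, in_dim = 128) {
  h <- config$hidden_sizes
  layers <- list()
  c_in <- in_dim
  for (w in h) {
    layers <- c(layers, list(L_dense(c_in, w), L_bn(w),
                             L_act(config$leaky_slope),
                             L_drop(config$dropout_rate)))
    c_in <- w
  }
  layers <- c(layers, list(L_dense(c_in, config$n_classes)))
  seq_init(layers)
}

# Positions (layer indices) of the post-activation hidden states adapted by
# the divergence loss: after each hidden block's activation, plus logits.
clf_hidden_positions <- function(clf) {
  n <- length(clf)
  acts <- which(vapply(clf, `[[`, "", "type") == "act")
  c(acts, n)
}

classifier_fwd <- function(clf, feat, train = FALSE) {
  caches <- vector("list", length(clf))
  acts <- vector("list", length(clf))
  X <- feat
  for (i in seq_along(clf)) {
    r <- layer_fwd(clf[[i]], X, train)
    X <- r$Y
    caches[[i]] <- r$cache
    clf[[i]] <- r$layer
    acts[[i]] <- X
  }
  pos <- clf_hidden_positions(clf)
  list(logits = X, hidden = acts[pos[-length(pos)]], clf = clf,
       caches = caches, positions = pos)
}

# Backward with optional gradient injections at intermediate activations:
# `inject` is a named list mapping layer index (as character) to a gradient
# to add to that layer's output (used by the divergence loss on hidden
# states).
classifier_bwd <- function(clf, caches, dlogits, inject = list()) {
  grads <- vector("list", length(clf))
  dY <- dlogits
  for (i in rev(seq_along(clf))) {
    key <- as.character(i)
    if (!is.null(inject[[key]])) dY <- dY + inject[[key]]
    r <- layer_bwd(clf[[i]], caches[[i]], dY)
    dY <- r$dX
    grads[[i]] <- r$grads
  }
  list(dX = dY, grads = grads)
}

#' Build the adversarial domain-classifier head
#'
#' A 128 -> 64 -> 1 network with batch normalization and leaky rectifier,
#' producing a single domain logit; trained behind the gradient reversal
#' layer.
#' @param in_dim Feature width.
#' @param leaky_slope Activation slope.
#' @return A layer list.
#' @export
build_domain_head <- function(in_dim = 128, leaky_slope = 0.01) {
  seq_init(list(L_dense(in_dim, 64), L_bn(64), L_act(leaky_slope),
                L_dense(64, 1)))
}

#' Build the reconstruction decoder
#'
#' Mirrors the extractor: a learned linear map expands the pooled 128-d
#' feature to `T` time steps of 128 channels, followed by three stride-1
#' transposed-convolution blocks with the extractor's widths reversed
#' (128, 128, 64) down to the 6 sensor channels. For stride 1 and "same"
#' padding, a transposed convolution is a convolution with mirrored kernel,
#' which is how it is realized here.
#'
#' @param T Window length in samples.
#' @param feat_dim Pooled feature width.
#' @param config The paired [extractor_config()] (kernel lengths reused in
#'   reverse).
#' @return A decoder model tree.
#' @export
build_decoder <- function(T, feat_dim = 128, config = extractor_config()) {
  k <- rev(config$kernel_lengths)
  ch <- rev(config$channels)      # 128, 128, 64
  expand <- seq_init(list(L_dense(feat_dim, ch[1] * T)))
  layers <- list()
  c_in <- ch[1]
  for (i in seq_along(ch)) {
    c_out <- if (i < length(ch)) ch[i + 1] else 6
    layers <- c(layers, list(L_conv(k[i], c_in, c_out, config$pad_mode)))
    if (i < length(ch))
      layers <- c(layers, list(L_bn(c_out), L_act(config$leaky_slope)))
    c_in <- c_out
  }
  list(expand = expand, convs = seq_init(layers), T = as.integer(T),
       ch0 = ch[1])
}

decoder_fwd <- function(dec, feat, train = FALSE) {
  B <- nrow(feat)
  e <- seq_fwd(dec$expand, feat, train)
  Z <- e$Y                        # B x (ch0 * T)
  # reshape to (T*B) x ch0, time fastest
  Z3 <- array(t(Z), dim = c(dec$T, dec$ch0, B))
  X <- matrix(aperm(Z3, c(1, 3, 2)), dec$T * B, dec$ch0)
  X <- set_dims(X, dec$T, B)
  cv <- fseq_fwd(dec$convs, X, train)
  dec$expand <- e$layers
  dec$convs <- cv$layers
  list(Y = cv$Y, dec = dec, caches = list(expand = e$caches, convs = cv$segs,
                                          B = B))
}

decoder_bwd <- function(dec, caches, dY) {
  cv <- fseq_bwd(dec$convs, caches$convs, dY)
  B <- caches$B
  dX <- cv$dX                      # (T*B) x ch0
  Z3 <- array(dX, dim = c(dec$T, B, dec$ch0))
  dZ <- t(matrix(aperm(Z3, c(1, 3, 2)), dec$T * dec$ch0, B))
  e <- seq_bwd(dec$expand, caches$expand, dZ)
  list(dfeat = e$dX, grads = list(expand = e$grads, convs = cv$grads))
}

#' Assemble a model bundle
#'
#' Creates the shared extractor + classifier with seeded initialization,
#' plus the method-specific head: none for `source_only` and `dan`, a
#' domain classifier for `dann`, a decoder for `drcn`. The shared parts are
#' initialized from a stream independent of the head's, so all methods
#' start from identical shared weights under the same seed.
#'
#' @param n_classes Number of classes.
#' @param method One of `"source_only"`, `"dan"`, `"dann"`, `"drcn"`.
#' @param T Window length in samples (needed for the decoder).
#' @param seed Integer seed for initialization.
#' @param ext_config,clf_config Architecture configurations.
#' @return A `model_bundle`.
#' @export
build_model_bundle <- function(n_classes, method = c("source_only", "dan",
                                                     "dann", "drcn"),
                               T = 200, seed = 1,
                               ext_config = extractor_config(),
                               clf_config = classifier_config(n_classes)) {
  method <- match.arg(method)
  shared <- with_seed(child_seed(seed, "init", "shared"), {
    ext <- build_extractor(ext_config)
    clf <- build_classifier(clf_config, in_dim = ext$out_dim)
    list(ext = ext, clf = clf)
  })
  head <- with_seed(child_seed(seed, "init", "head"), {
    switch(method,
           dann = build_domain_head(shared$ext$out_dim,
                                    clf_config$leaky_slope),
           drcn = build_decoder(T, shared$ext$out_dim, ext_config),
           NULL)
  })
  structure(list(extractor = shared$ext, classifier = shared$clf,
                 head = head, method = method, n_classes = n_classes,
                 T = as.integer(T), seed = as.integer(seed),
                 ext_config = ext_config, clf_config = clf_config,
                 scaler = NULL),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> method=%s, %d classes, T=%d, seed=%d\n",
              x$method, x$n_classes, x$T, x$seed))
  invisible(x)
}

# Generic parameter tree walkers ---------------------------------------

is_layer <- function(x) is.list(x) && !is.null(x$type) && is.character(x$type)

collect_params <- function(x, path = "") {
  out <- list()
  if (is_layer(x)) {
    for (f in PARAM_FIELDS)
      if (!is.null(x[[f]]) && x$type %in% c("conv", "dense", "bn"))
        out[[paste0(path, f)]] <- x[[f]]
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      if (!is.list(x[[i]])) next
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, collect_params(x[[i]], paste0(path, nm, ".")))
    }
  }
  out
}

assign_params <- function(x, params, path = "") {
  if (is_layer(x)) {
    for (f in PARAM_FIELDS) {
      key <- paste0(path, f)
      if (!is.null(params[[key]])) x[[f]] <- params[[key]]
    }
    return(x)
  }
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      if (!is.list(x[[i]])) next
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      x[[i]] <- assign_params(x[[i]], params, paste0(path, nm, "."))
    }
  }
  x
}

bundle_params <- function(bundle) {
  c(collect_params(bundle$extractor, "ext."),
    collect_params(bundle$classifier, "clf."),
    if (!is.null(bundle$head)) collect_params(bundle$head, "head."))
}

bundle_set_params <- function(bundle, params) {
  bundle$extractor <- assign_params(bundle$extractor, params, "ext.")
  bundle$classifier <- assign_params(bundle$classifier, params, "clf.")
  if (!is.null(bundle$head))
    bundle$head <- assign_params(bundle$head, params, "head.")
  bundle
}

#' Save / load a model bundle
#'
#' A checkpoint is a single RDS archive holding parameters, architecture
#' configuration, the fitted standardizer and the seed.
#' @param bundle A `model_bundle`.
#' @param path File path.
#' @return `path` (save) or the restored bundle (load).
#' @export
save_bundle <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) readRDS(path)
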