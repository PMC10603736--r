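# The three unsupervised domain-adaptation objectives and their shared
# primitive losses.
#
#   DAN :  CE(f(xs), ys) + lambda * sum_n MMD(f_n(xs), f_n(xt))
#   DANN:  CE(f(xs), ys) + lambda * (BCE(g(xs), 0) + BCE(g(xt), 1)),
#          with g behind a gradient reversal layer
#   DRCN:  CE(f(xs), ys) + lambda * MSE(h(xt), xt)
#
# where f is the label classifier on shared extractor features, f_n its
# hidden states (widths 128, 64, n_classes), g the domain classifier and h
# the decoder.  All reductions are batch means.  lambda = 0 reduces every
# objective to source-only cross-entropy exactly (the target forward pass
# is skipped, so batch-norm statistics match the source-only path).

#' Mean softmax cross-entropy
#'
#' @param logits Numeric matrix, one row per sample, one column per class.
#' @param labels Integer class labels in `1..n_classes`.
#' @param grad If `TRUE` also return the gradient with respect to logits.
#' @return The scalar loss, or `(value, dlogits)` with `grad = TRUE`.
#' @export
cross_entropy <- function(logits, labels, grad = FALSE) {
  logits <- as.matrix(logits)
  n <- nrow(logits)
  if (length(labels) != n) stop("labels length mismatch", call. = FALSE)
  if (any(labels < 1 | labels > ncol(logits) | labels != round(labels)))
    stop("labels must be integers in [1, n_classes]", call. = FALSE)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  idx <- cbind(seq_len(n), labels)
  val <- -mean(log(pmax(p[idx], 1e-300)))
  if (!grad) return(val)
  d <- p
  d[idx] <- d[idx] - 1
  list(value = val, dlogits = d / n)
}

# binary cross-entropy on a single logit column; targets in {0,1}
bce_logit <- function(z, targets, grad = FALSE) {
  z <- as.numeric(z)
  n <- length(z)
  # numerically stable: log(1+exp(-|z|)) + max(z,0) - z*t
  val <- mean(pmax(z, 0) - z * targets + log1p(exp(-abs(z))))
  if (!grad) return(val)
  s <- 1 / (1 + exp(-z))
  list(value = val, dz = matrix((s - targets) / n, ncol = 1))
}

# mean squared error over all elements
mse_loss <- function(xhat, x, grad = FALSE) {
  d <- xhat - x
  val <- mean(d^2)
  if (!grad) return(val)
  list(value = val, dxhat = 2 * d / length(d))
}

#' Gradient reversal layer
#'
#' Identity in the forward pass; the backward pass multiplies the incoming
#' gradient by `-beta`. The forward function tags its input; use
#' [grl_backward()] for the gradient contract.
#'
#' @param x Numeric array.
#' @param beta Reversal strength (default 1).
#' @return `x` unchanged, with attribute `grl_beta`.
#' @export
gradient_reversal <- function(x, beta = 1) {
  attr(x, "grl_beta") <- beta
  x
}

#' @rdname gradient_reversal
#' @param grad Upstream gradient arriving at the layer output.
#' @export
grl_backward <- function(grad, beta = 1) -beta * grad

# ----------------------------------------------------------------------
# Unified forward/backward step.
#
# Runs the method's full objective on one source batch (Xs (T*Bs) x 6 with
# labels ys) and one target batch (Xt, unlabeled), returning the loss
# components and, when compute_grads, the flattened parameter gradients.
# With lam == 0 (or method source_only) the target pass is skipped
# entirely.
uda_step <- function(bundle, Xs, ys, Xt = NULL, lam = 1, bank = kernel_bank(),
                     beta = 1, train = TRUE, compute_grads = TRUE) {
  method <- bundle$method
  use_target <- method != "source_only" && lam > 0
  if (use_target && is.null(Xt)) stop("target batch required", call. = FALSE)
  ds <- act_dims(Xs)
  Bs <- ds[2]
  if (use_target) {
    dt <- act_dims(Xt)
    if (nrow(Xt) / dt[2] != nrow(Xs) / Bs)
      stop("source and target window lengths differ", call. = FALSE)
    Bt <- dt[2]
    X <- set_dims(rbind(Xs, Xt), ds[1], Bs + Bt)
  } else {
    Bt <- 0
    X <- Xs
  }
  src <- seq_len(Bs)
  tgt <- if (Bt > 0) Bs + seq_len(Bt) else integer(0)

  ef <- extractor_fwd(bundle$extractor, X, train)
  bundle$extractor <- ef$ext
  cf <- classifier_fwd(bundle$classifier, ef$feat, train)
  bundle$classifier <- cf$clf

  ce <- cross_entropy(cf$logits[src, , drop = FALSE], ys, grad = compute_grads)
  ce_val <- if (compute_grads) ce$value else ce
  adapt <- 0
  dlogits <- matrix(0, Bs + Bt, ncol(cf$logits))
  inject <- list()
  head_grads <- NULL
  dfeat_extra <- matrix(0, Bs + Bt, ncol(ef$feat))

  if (compute_grads) dlogits[src, ] <- ce$dlogits

  if (use_target && method == "dan") {
    states <- c(cf$hidden, list(cf$logits))
    pos <- cf$positions
    for (j in seq_along(states)) {
      Hs <- states[[j]][src, , drop = FALSE]
      Ht <- states[[j]][tgt, , drop = FALSE]
      r <- mk_mmd(Hs, Ht, bank, grad = compute_grads)
      v <- if (compute_grads) r$value else r
      adapt <- adapt + v
      if (compute_grads) {
        dH <- matrix(0, Bs + Bt, ncol(Hs))
        dH[src, ] <- lam * r$dA
        dH[tgt, ] <- lam * r$dB
        if (j == length(states)) dlogits <- dlogits + dH
        else inject[[as.character(pos[j])]] <- dH
      }
    }
  } else if (use_target && method == "dann") {
    hf <- classifier_fwd(bundle$head, ef$feat, train)  # head is a layer list
    bundle$head <- hf$clf
    dom <- c(rep(0, Bs), rep(1, Bt))
    bs <- bce_logit(hf$logits[src, 1], dom[src], grad = compute_grads)
    bt <- bce_logit(hf$logits[tgt, 1], dom[tgt], grad = compute_grads)
    if (compute_grads) {
      adapt <- bs$value + bt$value
      dz <- matrix(0, Bs + Bt, 1)
      dz[src, 1] <- lam * bs$dz
      dz[tgt, 1] <- lam * bt$dz
      hb <- classifier_bwd(bundle$head, hf$caches, dz)
      head_grads <- hb$grads
      # GRL: reverse the gradient entering the shared features
      dfeat_extra <- dfeat_extra + grl_backward(hb$dX, beta)
    } else adapt <- bs + bt
  } else if (use_target && method == "drcn") {
    Xt_only <- set_dims(X[nrow(Xs) + seq_len(nrow(Xt)), , drop = FALSE],
                        ds[1], Bt)
    df <- decoder_fwd(bundle$head, ef$feat[tgt, , drop = FALSE], train)
    bundle$head <- df$dec
    rec <- mse_loss(df$Y, Xt_only, grad = compute_grads)
    if (compute_grads) {
      adapt <- rec$value
      db <- decoder_bwd(bundle$head, df$caches, lam * rec$dxhat)
      head_grads <- db$grads
      dfeat_extra[tgt, ] <- dfeat_extra[tgt, ] + db$dfeat
    } else adapt <- rec
  }

  total <- ce_val + lam * adapt
  out <- list(total = total, ce = ce_val, adapt = adapt, lam = lam,
              bundle = bundle)
  if (!compute_grads) return(out)

  cb <- classifier_bwd(bundle$classifier, cf$caches, dlogits, inject)
  dfeat <- cb$dX + dfeat_extra
  eb <- extractor_bwd(bundle$extractor, ef$caches, dfeat)

  out$grads <- c(collect_grads(eb$grads, "ext."),
                 collect_grads(cb$grads, "clf."),
                 if (!is.null(head_grads)) collect_grads(head_grads, "head."))
  out
}

# Flatten a nested gradient tree with the same paths as collect_params.
collect_grads <- function(x, path = "") {
  out <- list()
  if (is.list(x) && !is.null(names(x)) &&
      all(names(x) %in% PARAM_FIELDS) && length(x)) {
    for (f in names(x)) out[[paste0(path, f)]] <- x[[f]]
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      if (!is.list(x[[i]]) || !length(x[[i]])) next
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, collect_grads(x[[i]], paste0(path, nm, ".")))
    }
  }
  out
}

#' DAN loss: source cross-entropy plus layerwise MK-MMD
#'
#' @param bundle A `model_bundle` with `method = "dan"` (no head).
#' @param Xs,ys Source batch in engine layout (`(T*B) x 6`, `dims` attr)
#'   and labels.
#' @param Xt Target batch, same window length.
#' @param bank A [kernel_bank()].
#' @param lam Trade-off parameter.
#' @param train Run normalization/dropout in training mode.
#' @return List with `total`, `ce`, `adapt` (sum of per-layer MMDs).
#' @export
dan_loss <- function(bundle, Xs, ys, Xt, bank = kernel_bank(), lam = 1,
                     train = FALSE) {
  if (!is.null(bundle$head)) stop("dan expects a bundle without a head",
                                  call. = FALSE)
  r <- uda_step(bundle, Xs, ys, Xt, lam = lam, bank = bank, train = train,
                compute_grads = FALSE)
  r[c("total", "ce", "adapt", "lam")]
}

#' DANN loss: source cross-entropy plus adversarial domain BCE
#'
#' @inheritParams dan_loss
#' @param beta Gradient-reversal strength.
#' @return List with `total`, `ce`, `adapt` (sum of the two BCE terms).
#' @export
dann_loss <- function(bundle, Xs, ys, Xt, lam = 1, beta = 1, train = FALSE) {
  if (is.null(bundle$head) || bundle$method != "dann")
    stop("dann expects a bundle with a domain-classifier head", call. = FALSE)
  r <- uda_step(bundle, Xs, ys, Xt, lam = lam, beta = beta, train = train,
                compute_grads = FALSE)
  r[c("total", "ce", "adapt", "lam")]
}

#' DRCN loss: source cross-entropy plus target reconstruction error
#'
#' @inheritParams dan_loss
#' @return List with `total`, `ce`, `adapt` (target MSE).
#' @export
drcn_loss <- function(bundle, Xs, ys, Xt, lam = 1, train = FALSE) {
  if (is.null(bundle$head) || bundle$method != "drcn")
    stop("drcn expects a bundle with a decoder head", call. = FALSE)
  r <- uda_step(bundle, Xs, ys, Xt, lam = lam, train = train,
                compute_grads = FALSE)
  r[c("total", "ce", "adapt", "lam")]
}
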