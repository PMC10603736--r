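# Latent-space analysis: pre-softmax latent extraction, PCA + t-SNE
# embedding to 2-D, and quantitative source/target mixing scores.
#
# No t-SNE implementation ships with the installed R stack, so the package
# carries an exact O(n^2) t-SNE: perplexity calibration by bisection on
# each point's conditional distribution, symmetrized affinities, Student-t
# low-dimensional kernel, gradient descent with momentum and early
# exaggeration, PCA initialization.  Adequate for the few hundred to few
# thousand points of a latent-space figure.

#' Extract latent vectors from a trained model
#'
#' Returns per-window activations in inference mode (no dropout, running
#' batch-norm statistics): either the pre-softmax logits (width n_classes,
#' the layer the reference analysis embeds) or the 64-wide penultimate
#' hidden state, which carries more geometry when n_classes is small.
#'
#' @param bundle A trained `model_bundle`.
#' @param dataset A [domain_dataset()] (standardized with the bundle's
#'   scaler when present).
#' @param layer `"logits"` (default) or `"penultimate"`.
#' @param idx Window indices (default all).
#' @return Matrix `n x width` with attribute `layer`.
#' @export
extract_latents <- function(bundle, dataset, layer = c("logits", "penultimate"),
                            idx = seq_along(dataset$windows)) {
  layer <- match.arg(layer)
  ws <- dataset$windows[idx]
  if (!is.null(bundle$scaler)) ws <- standardize_windows(ws, bundle$scaler)
  tensor <- dataset_tensor(domain_dataset(ws, dataset$class_names))
  d <- act_dims(tensor$X)
  out <- NULL
  for (s in seq(1, d[2], by = 256)) {
    ii <- s:min(d[2], s + 255)
    rows <- as.vector(outer(seq_len(d[1]), (ii - 1) * d[1], `+`))
    Xb <- set_dims(tensor$X[rows, , drop = FALSE], d[1], length(ii))
    ef <- extractor_fwd(bundle$extractor, Xb, train = FALSE)
    cf <- classifier_fwd(bundle$classifier, ef$feat, train = FALSE)
    piece <- if (layer == "logits") cf$logits
             else cf$hidden[[length(cf$hidden)]]
    out <- rbind(out, piece)
  }
  attr(out, "layer") <- layer
  out
}

# conditional affinities at a given perplexity via bisection on precision
tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_iter = 50) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (it in seq_len(max_iter)) {
      w <- exp(-d * beta)
      sw <- sum(w)
      if (sw <= 0) { beta <- beta / 2; next }
      p <- w / sw
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Embed latent vectors in 2-D with PCA then t-SNE
#'
#' Features are optionally reduced with PCA to `pca_dims` components
#' (skipped when the feature width is already at most `pca_dims`), then
#' embedded with a seeded exact t-SNE. The Kullback-Leibler divergence of
#' the final embedding is reported.
#'
#' @param features Numeric matrix, rows = samples.
#' @param labels,domains Optional per-row annotations stored in the result.
#' @param pca_dims PCA target dimensionality before t-SNE (default 30).
#' @param perplexity t-SNE perplexity (default 30; requires
#'   `n > 3 * perplexity`).
#' @param n_iter Gradient-descent iterations (default 1000).
#' @param seed Integer seed (embedding is reproducible bit-for-bit).
#' @param method `"tsne"` (default) or `"pca"` for the PCA-only fallback.
#' @return An `embedding_result`: `coords_2d`, `labels`, `domains`,
#'   `pca_variance_explained`, `kl_divergence`, `perplexity`, `seed`.
#' @export
embed_2d <- function(features, labels = NULL, domains = NULL, pca_dims = 30,
                     perplexity = 30, n_iter = 1000, seed = 1,
                     method = c("tsne", "pca")) {
  method <- match.arg(method)
  X <- as.matrix(features)
  n <- nrow(X)
  if (method == "tsne" && n <= 3 * perplexity)
    stop("too few points for perplexity ", perplexity,
         "; try perplexity <= ", floor((n - 1) / 3), call. = FALSE)
  varex <- 1
  if (ncol(X) > pca_dims) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    keep <- seq_len(min(pca_dims, ncol(pc$x)))
    varex <- sum(pc$sdev[keep]^2) / sum(pc$sdev^2)
    X <- pc$x[, keep, drop = FALSE]
  }
  if (method == "pca") {
    pc <- stats::prcomp(X, center = TRUE)
    Y <- pc$x[, 1:2, drop = FALSE]
    kl <- NA_real_
  } else {
    D2 <- pairwise_sq_dists(X, X)
    P <- tsne_affinities(D2, perplexity)
    # PCA init, tiny scale, plus seeded jitter to break ties
    pc <- stats::prcomp(X, center = TRUE)
    Y <- pc$x[, 1:2, drop = FALSE]
    Y <- Y / stats::sd(Y[, 1]) * 1e-4
    Y <- Y + with_seed(child_seed(seed, "tsne"),
                       matrix(rnorm(2 * n, sd = 1e-6), n, 2))
    lr <- 200; momentum <- 0.5; update <- Y * 0
    exaggeration <- 12
    for (it in seq_len(n_iter)) {
      Pe <- if (it <= 100) P * exaggeration else P
      num <- 1 / (1 + pairwise_sq_dists(Y, Y))
      diag(num) <- 0
      Q <- num / sum(num)
      Q <- pmax(Q, 1e-12)
      W <- (Pe - Q) * num
      grad <- 4 * (rowSums(W) * Y - W %*% Y)
      if (it == 20) momentum <- 0.8
      update <- momentum * update - lr * grad
      Y <- Y + update
      Y <- sweep(Y, 2, colMeans(Y))
    }
    num <- 1 / (1 + pairwise_sq_dists(Y, Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    kl <- sum(P * log(P / Q))
  }
  structure(list(coords_2d = Y, labels = labels, domains = domains,
                 pca_variance_explained = varex, kl_divergence = kl,
                 perplexity = perplexity, seed = seed, method = method),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d points, %s, PCA var %.3f, KL %.3f\n",
              nrow(x$coords_2d), x$method, x$pca_variance_explained,
              x$kl_divergence))
  invisible(x)
}

#' Per-class source/target neighbor mixing score
#'
#' For each class present in both domains, computes for every point the
#' fraction of its k nearest neighbors (within the class) belonging to the
#' other domain, normalized by the chance rate under perfect mixing and
#' clipped to `[0, 1]`: about 1 when the domains interleave, about 0 when
#' they separate. Invariant to global rotation/translation of the feature
#' space (it depends only on pairwise distances).
#'
#' @param features Feature (or embedding) matrix, rows = samples.
#' @param domains Character/factor vector with exactly two levels.
#' @param labels Class label per row.
#' @param k Neighborhood size (default 10).
#' @return Named numeric vector of per-class scores; classes absent from a
#'   domain are omitted with a warning.
#' @export
mixing_score <- function(features, domains, labels, k = 10) {
  features <- as.matrix(features)
  domains <- as.character(domains)
  ud <- unique(domains)
  if (length(ud) != 2) stop("need exactly two domains", call. = FALSE)
  out <- numeric(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    dom <- domains[idx]
    if (length(unique(dom)) < 2) {
      warning("class ", cl, " absent from one domain; omitted")
      next
    }
    Xc <- features[idx, , drop = FALSE]
    D2 <- pairwise_sq_dists(Xc, Xc)
    diag(D2) <- Inf
    kk <- min(k, length(idx) - 1)
    frac <- vapply(seq_along(idx), function(i) {
      nb <- order(D2[i, ])[seq_len(kk)]
      mean(dom[nb] != dom[i])
    }, 0)
    n_other <- vapply(seq_along(idx),
                      function(i) sum(dom != dom[i]), 0)
    chance <- n_other / (length(idx) - 1)
    score <- mean(frac) / mean(chance)
    out[cl] <- min(1, max(0, score))
  }
  out
}
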