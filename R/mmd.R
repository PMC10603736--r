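# Multi-kernel maximum mean discrepancy.
#
# The squared MMD between feature batches A (m x d) and B (n x d) is
# estimated per Gaussian kernel and averaged over the kernel bank with
# equal weights.  Bandwidths follow the median heuristic: the median of the
# pairwise squared distances on the joint sample, times a geometric ladder.
# The median is treated as a constant in the gradient (standard practice).

#' A Gaussian kernel bank for MK-MMD
#'
#' @param multipliers Geometric ladder of bandwidth multipliers applied to
#'   the median-heuristic base.
#' @param base Optional fixed base bandwidth (squared-distance scale); if
#'   `NULL` it is recomputed per batch from the joint sample.
#' @return A `kernel_bank`.
#' @export
kernel_bank <- function(multipliers = c(0.25, 0.5, 1, 2, 4), base = NULL) {
  if (!length(multipliers) || any(multipliers <= 0) ||
      !all(is.finite(multipliers)))
    stop("multipliers must be finite and positive", call. = FALSE)
  if (!is.null(base) && (!is.finite(base) || base <= 0))
    stop("base bandwidth must be finite and positive", call. = FALSE)
  structure(list(multipliers = multipliers, base = base),
            class = "kernel_bank")
}

pairwise_sq_dists <- function(X, Y) {
  xn <- rowSums(X^2)
  yn <- rowSums(Y^2)
  d2 <- outer(xn, yn, `+`) - 2 * tcrossprod(X, Y)
  pmax(d2, 0)
}

median_heuristic <- function(A, B) {
  Z <- rbind(A, B)
  D2 <- pairwise_sq_dists(Z, Z)
  v <- D2[upper.tri(D2)]
  b <- stats::median(v)
  if (!is.finite(b) || b <= 0) 1 else b
}

#' Multi-kernel maximum mean discrepancy between two feature batches
#'
#' Computes the squared-MMD estimate averaged over the kernel bank. The
#' unbiased estimator excludes within-set diagonals; when the two batches
#' have equal size the cross term also excludes paired indices (the
#' standard unbiased form), otherwise the all-pairs cross term is used.
#' Identical point sets give exactly 0 under the unbiased equal-size form.
#'
#' @param A,B Numeric matrices, one row per sample (`>= 2` rows each for
#'   the unbiased estimator).
#' @param bank A [kernel_bank()]; bandwidth base recomputed per call when
#'   not fixed.
#' @param estimator `"unbiased"` (default) or `"biased"` (all pairs,
#'   non-negative).
#' @param grad If `TRUE`, also return gradients of the estimate with
#'   respect to the rows of `A` and `B` (bandwidths held fixed).
#' @return The scalar estimate; with `grad = TRUE`, a list
#'   `(value, dA, dB)`.
#' @export
mk_mmd <- function(A, B, bank = kernel_bank(),
                   estimator = c("unbiased", "biased"), grad = FALSE) {
  estimator <- match.arg(estimator)
  A <- as.matrix(A); B <- as.matrix(B)
  m <- nrow(A); n <- nrow(B)
  if (estimator == "unbiased" && (m < 2 || n < 2))
    stop("unbiased MK-MMD needs at least 2 samples per batch", call. = FALSE)
  base <- if (is.null(bank$base)) median_heuristic(A, B) else bank$base
  bws <- base * bank$multipliers
  w <- 1 / length(bws)

  Daa <- pairwise_sq_dists(A, A)
  Dbb <- pairwise_sq_dists(B, B)
  Dab <- pairwise_sq_dists(A, B)

  offd <- function(K) sum(K) - sum(diag(K))
  val <- 0
  dA <- if (grad) matrix(0, m, ncol(A)) else NULL
  dB <- if (grad) matrix(0, n, ncol(B)) else NULL

  # gradient of sum(C * K(X, Y)) wrt X and Y for one Gaussian kernel
  acc_grad <- function(C, K, X, Y, bw) {
    W <- C * K
    gX <- (-2 / bw) * (rowSums(W) * X - W %*% Y)
    gY <- (-2 / bw) * (colSums(W) * Y - crossprod(W, X))
    list(gX = gX, gY = gY)
  }

  for (bw in bws) {
    Kaa <- exp(-Daa / bw)
    Kbb <- exp(-Dbb / bw)
    Kab <- exp(-Dab / bw)
    if (estimator == "unbiased") {
      caa <- 1 / (m * (m - 1))
      cbb <- 1 / (n * (n - 1))
      ta <- offd(Kaa) * caa
      tb <- offd(Kbb) * cbb
      if (m == n) {
        tc <- 2 * (sum(Kab) - sum(diag(Kab))) / (m * (m - 1))
        Cab <- matrix(-2 / (m * (m - 1)), m, n)
        diag(Cab) <- 0
      } else {
        tc <- 2 * sum(Kab) / (m * n)
        Cab <- matrix(-2 / (m * n), m, n)
      }
      v <- ta + tb - tc
      if (grad) {
        Caa <- matrix(caa, m, m); diag(Caa) <- 0
        Cbb <- matrix(cbb, n, n); diag(Cbb) <- 0
      }
    } else {
      v <- sum(Kaa) / m^2 + sum(Kbb) / n^2 - 2 * sum(Kab) / (m * n)
      if (grad) {
        Caa <- matrix(1 / m^2, m, m)
        Cbb <- matrix(1 / n^2, n, n)
        Cab <- matrix(-2 / (m * n), m, n)
      }
    }
    val <- val + w * v
    if (grad) {
      g1 <- acc_grad(Caa, Kaa, A, A, bw)
      g2 <- acc_grad(Cbb, Kbb, B, B, bw)
      g3 <- acc_grad(Cab, Kab, A, B, bw)
      dA <- dA + w * (g1$gX + g1$gY + g3$gX)
      dB <- dB + w * (g2$gX + g2$gY + g3$gY)
    }
  }
  if (grad) list(value = val, dA = dA, dB = dB) else val
}
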