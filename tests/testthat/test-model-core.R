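# Residual extractor, classifier, losses: shapes, numerics, contracts.

test_that("extractor maps any window length to a 128-d feature", {
  ext <- aaruda:::with_seed(1, build_extractor())
  for (T in c(200, 300, 50)) {
    X <- rand_batch(T, 4)
    r <- aaruda:::extractor_fwd(ext, X, train = FALSE)
    expect_equal(dim(r$feat), c(4, 128))
  }
  # all-zero input, inference mode with unit statistics: finite output
  X0 <- rand_batch(64, 2) * 0
  r0 <- aaruda:::extractor_fwd(ext, X0, train = FALSE)
  expect_true(all(is.finite(r0$feat)))
})

test_that("classifier has the contracted widths and dropout statistics", {
  clf <- aaruda:::with_seed(2, build_classifier(classifier_config(6)))
  feat <- rand_batch(1, 5, C = 128)
  r <- aaruda:::classifier_fwd(clf, feat, train = FALSE)
  expect_equal(dim(r$logits), c(5, 6))
  expect_equal(ncol(r$hidden[[1]]), 128)
  expect_equal(ncol(r$hidden[[2]]), 64)

  # inference mode is deterministic (no dropout)
  r2 <- aaruda:::classifier_fwd(clf, feat, train = FALSE)
  expect_identical(r$logits, r2$logits)

  # training mode dropout: each unit zeroed in 20% +/- 3% of 2000 passes
  drop_layer <- clf[[4]]
  x <- matrix(1, 1, 128)
  set.seed(42)
  zeroed <- colMeans(t(vapply(1:2000, function(i)
    as.numeric(aaruda:::layer_fwd(drop_layer, x, train = TRUE)$Y == 0),
    numeric(128))))
  expect_lt(abs(mean(zeroed) - 0.2), 0.005)
  expect_true(all(abs(zeroed - 0.2) <= 0.04))  # ~4.5 sigma at 2000 passes

  expect_error(classifier_config(1), "n_classes")
})

test_that("cross entropy matches closed forms and the direct formula", {
  # uniform logits over 6 classes
  expect_equal(cross_entropy(matrix(0, 4, 6), c(1, 3, 5, 6)), log(6),
               tolerance = 1e-12)
  # saturated correct logits drive the loss to 0
  big <- matrix(-50, 3, 4)
  big[cbind(1:3, c(2, 1, 4))] <- 50
  expect_lt(cross_entropy(big, c(2, 1, 4)), 1e-10)
  # random batch vs brute force
  set.seed(8)
  lg <- matrix(rnorm(5 * 3), 5, 3)
  y <- sample(3, 5, replace = TRUE)
  p <- exp(lg) / rowSums(exp(lg))
  expect_equal(cross_entropy(lg, y),
               -mean(log(p[cbind(1:5, y)])), tolerance = 1e-12)
  expect_error(cross_entropy(lg, c(0, 1, 1, 1, 1)), "labels")
})

test_that("building twice with one seed gives identical parameters", {
  b1 <- build_model_bundle(6, "dann", T = 64, seed = 33)
  b2 <- build_model_bundle(6, "dann", T = 64, seed = 33)
  expect_identical(aaruda:::bundle_params(b1), aaruda:::bundle_params(b2))
  # shared parts identical across methods under one seed
  b3 <- build_model_bundle(6, "dan", T = 64, seed = 33)
  p1 <- aaruda:::bundle_params(b1)
  p3 <- aaruda:::bundle_params(b3)
  shared <- grep("^(ext|clf)\\.", names(p1), value = TRUE)
  expect_identical(p1[shared], p3[shared])
})

test_that("pooled features are invariant to circular time shifts", {
  # exact under circular padding; approximate under default zero padding
  ext_c <- aaruda:::with_seed(4, build_extractor(
    extractor_config(pad_mode = "circular")))
  T <- 60
  t <- (0:(T - 1)) / 10
  base <- sin(2 * pi * t)  # period 10 samples
  X <- matrix(rep(base, 6), T, 6)
  Xs <- matrix(rep(base[c(8:T, 1:7)], 6), T, 6)  # circular shift by 7
  attr(X, "dims") <- c(T = T, B = 1L)
  attr(Xs, "dims") <- c(T = T, B = 1L)
  f1 <- aaruda:::extractor_fwd(ext_c, X, train = FALSE)$feat
  f2 <- aaruda:::extractor_fwd(ext_c, Xs, train = FALSE)$feat
  expect_lt(max(abs(f1 - f2)) / max(abs(f1)), 1e-5)

  ext_z <- aaruda:::with_seed(4, build_extractor())
  g1 <- aaruda:::extractor_fwd(ext_z, X, train = FALSE)$feat
  g2 <- aaruda:::extractor_fwd(ext_z, Xs, train = FALSE)$feat
  expect_lt(max(abs(g1 - g2)) / max(abs(g1)), 0.05)
})

test_that("layer backward passes match numerical gradients (double path)", {
  set.seed(5)
  # dense + bn + act chain at double precision
  layers <- aaruda:::seq_init(list(aaruda:::L_dense(7, 5), aaruda:::L_bn(5),
                                   aaruda:::L_act(0.01)))
  X <- matrix(rnorm(6 * 7), 6, 7)
  G <- matrix(rnorm(6 * 5), 6, 5)
  f <- aaruda:::seq_fwd(layers, X, train = TRUE)
  b <- aaruda:::seq_bwd(f$layers, f$caches, G)
  eps <- 1e-6
  for (idx in sample(length(X), 5)) {
    Xp <- X; Xp[idx] <- Xp[idx] + eps
    Xm <- X; Xm[idx] <- Xm[idx] - eps
    fd <- (sum(aaruda:::seq_fwd(layers, Xp, TRUE)$Y * G) -
           sum(aaruda:::seq_fwd(layers, Xm, TRUE)$Y * G)) / (2 * eps)
    expect_equal(b$dX[idx], fd, tolerance = 1e-5)
  }
})
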