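# MK-MMD estimator, gradient reversal, and the three UDA objectives.

test_that("mk_mmd identity, symmetry and sign behavior", {
  set.seed(1)
  A <- matrix(rnorm(20 * 4), 20, 4)
  expect_equal(mk_mmd(A, A), 0, tolerance = 1e-14)
  B <- matrix(rnorm(16 * 4), 16, 4)
  expect_equal(mk_mmd(A, B), mk_mmd(B, A), tolerance = 1e-14)
  expect_gte(mk_mmd(A, B, estimator = "biased"), 0)
  expect_error(mk_mmd(A[1, , drop = FALSE], B), "at least 2")

  # null: same distribution, mean over replicates within 2 SE of 0
  vals <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    mk_mmd(matrix(rnorm(64 * 3), 64, 3), matrix(rnorm(64 * 3), 64, 3))
  }, 0)
  expect_lt(abs(mean(vals)), 2 * sd(vals) / sqrt(length(vals)))

  # separated distributions: strictly positive in 200/200 replicates
  pos <- vapply(1:200, function(i) {
    set.seed(2000 + i)
    mk_mmd(matrix(rnorm(32 * 2), 32, 2), matrix(rnorm(32 * 2, 3), 32, 2))
  }, 0)
  expect_true(all(pos > 0))
})

test_that("mk_mmd equals the double-loop oracle and its gradient checks out", {
  for (s in 1:5) {
    set.seed(300 + s)
    m <- sample(4:16, 1); n <- if (s %% 2) m else sample(4:16, 1)
    d <- sample(2:8, 1)
    A <- matrix(rnorm(m * d), m, d)
    B <- matrix(rnorm(n * d, 0.5), n, d)
    base <- aaruda:::median_heuristic(A, B)
    bank <- kernel_bank(base = base)
    expect_equal(mk_mmd(A, B, bank), mmd_oracle(A, B, base * bank$multipliers),
                 tolerance = 1e-10)
    expect_equal(mk_mmd(A, B, bank, estimator = "biased"),
                 mmd_oracle(A, B, base * bank$multipliers, "biased"),
                 tolerance = 1e-10)
  }
  # analytic gradient vs finite differences (fixed bandwidths)
  set.seed(11)
  A <- matrix(rnorm(6 * 3), 6, 3)
  B <- matrix(rnorm(6 * 3, 1), 6, 3)
  bank <- kernel_bank(base = 2)
  g <- mk_mmd(A, B, bank, grad = TRUE)
  eps <- 1e-6
  for (idx in sample(length(A), 4)) {
    Ap <- A; Ap[idx] <- Ap[idx] + eps
    Am <- A; Am[idx] <- Am[idx] - eps
    fd <- (mk_mmd(Ap, B, bank) - mk_mmd(Am, B, bank)) / (2 * eps)
    expect_equal(g$dA[idx], fd, tolerance = 1e-7)
  }
})

test_that("gradient reversal is identity forward, -beta backward", {
  x <- c(1.0, 2.0)
  expect_equal(as.numeric(gradient_reversal(x)), x)
  expect_equal(grl_backward(c(0.5, -1.0), beta = 1), c(-0.5, 1.0))
  # double application restores the original gradient
  expect_equal(grl_backward(grl_backward(c(0.3, -2), 1), 1), c(0.3, -2))
})

test_that("dan_loss reduces, cancels on identical batches, and recomposes", {
  set.seed(21)
  T <- 24; B <- 6; ncls <- 3
  Xs <- rand_batch(T, B, seed = 1)
  Xt <- rand_batch(T, B, seed = 2)
  ys <- sample(ncls, B, replace = TRUE)
  bundle <- build_model_bundle(ncls, "dan", T = T, seed = 7,
                               clf_config = classifier_config(ncls, dropout_rate = 0))
  bank <- kernel_bank(base = 4)

  r0 <- dan_loss(bundle, Xs, ys, Xt, bank, lam = 0)
  expect_equal(r0$total, r0$ce, tolerance = 1e-12)

  rs <- dan_loss(bundle, Xs, ys, Xs, bank, lam = 1)
  expect_equal(rs$adapt, 0, tolerance = 1e-10)
  expect_equal(rs$total, rs$ce, tolerance = 1e-10)

  # recompose: total = CE + lam * sum of independently recomputed MMDs
  lam <- 0.6
  r <- dan_loss(bundle, Xs, ys, Xt, bank, lam = lam)
  ef <- aaruda:::extractor_fwd(bundle$extractor,
                               aaruda:::set_dims(rbind(Xs, Xt), T, 2 * B), FALSE)
  cf <- aaruda:::classifier_fwd(bundle$classifier, ef$feat, FALSE)
  states <- c(cf$hidden, list(cf$logits))
  mmds <- vapply(states, function(H)
    mk_mmd(H[1:B, , drop = FALSE], H[B + 1:B, , drop = FALSE], bank), 0)
  ce <- cross_entropy(cf$logits[1:B, ], ys)
  expect_equal(r$total, ce + lam * sum(mmds), tolerance = 1e-8)
  expect_equal(r$adapt, sum(mmds), tolerance = 1e-8)
})

test_that("dann_loss closed form and head requirement", {
  T <- 24; B <- 5; ncls <- 3
  Xs <- rand_batch(T, B, seed = 3)
  Xt <- rand_batch(T, B, seed = 4)
  ys <- rep(1, B)
  bundle <- build_model_bundle(ncls, "dann", T = T, seed = 9,
                               clf_config = classifier_config(ncls, dropout_rate = 0))
  # zero the head so g outputs a 0 logit: each BCE term is ln 2
  params <- aaruda:::bundle_params(bundle)
  for (nm in grep("^head", names(params), value = TRUE))
    params[[nm]] <- params[[nm]] * 0
  bundle <- aaruda:::bundle_set_params(bundle, params)
  r <- dann_loss(bundle, Xs, ys, Xt, lam = 1)
  expect_equal(r$adapt, 2 * log(2), tolerance = 1e-12)
  expect_equal(r$total, r$ce + 2 * log(2), tolerance = 1e-12)

  nohead <- build_model_bundle(ncls, "dan", T = T, seed = 9)
  expect_error(dann_loss(nohead, Xs, ys, Xt), "head")
})

test_that("drcn_loss equals CE plus lam times brute-force MSE", {
  T <- 24; B <- 4; ncls <- 3
  Xs <- rand_batch(T, B, seed = 5)
  Xt <- rand_batch(T, B, seed = 6)
  ys <- rep(2, B)
  bundle <- build_model_bundle(ncls, "drcn", T = T, seed = 10,
                               clf_config = classifier_config(ncls, dropout_rate = 0))
  lam <- 0.8
  r <- drcn_loss(bundle, Xs, ys, Xt, lam = lam)
  # recompute the reconstruction MSE by brute force
  ef <- aaruda:::extractor_fwd(bundle$extractor,
                               aaruda:::set_dims(rbind(Xs, Xt), T, 2 * B), FALSE)
  df <- aaruda:::decoder_fwd(bundle$head, ef$feat[B + 1:B, ], FALSE)
  mse <- sum((df$Y - Xt)^2) / length(Xt)
  expect_equal(r$adapt, mse, tolerance = 1e-10)
  expect_equal(r$total, r$ce + lam * mse, tolerance = 1e-10)
  # lam = 0 skips the target pass and equals the source-only CE
  cf0 <- aaruda:::classifier_fwd(bundle$classifier,
    aaruda:::extractor_fwd(bundle$extractor, Xs, FALSE)$feat, FALSE)
  expect_equal(drcn_loss(bundle, Xs, ys, Xt, lam = 0)$total,
               cross_entropy(cf0$logits, ys), tolerance = 1e-12)
})

test_that("decoder mirrors the extractor and can autoencode", {
  T <- 32; B <- 4
  bundle <- build_model_bundle(3, "drcn", T = T, seed = 12)
  X <- rand_batch(T, B, seed = 7)
  ef <- aaruda:::extractor_fwd(bundle$extractor, X, FALSE)
  df <- aaruda:::decoder_fwd(bundle$head, ef$feat, FALSE)
  expect_equal(dim(df$Y), c(T * B, 6))
  expect_true(all(is.finite(df$Y)))

  # optimization smoke test: autoencoding one repeated window cuts the
  # reconstruction error by >= 10x
  Xt <- rand_batch(T, 4, seed = 8)
  ys <- rep(1, 4)
  params <- aaruda:::bundle_params(bundle)
  state <- aaruda:::adam_init(params)
  set.seed(99)
  mse0 <- NULL
  for (step in 1:200) {
    r <- aaruda:::uda_step(bundle, Xt, ys, Xt, lam = 1, train = TRUE)
    if (is.null(mse0)) mse0 <- r$adapt
    upd <- aaruda:::adam_step(params, r$grads, state, 1e-3, 0)
    params <- upd$params; state <- upd$state
    bundle <- aaruda:::bundle_set_params(bundle, params)
  }
  rT <- aaruda:::uda_step(bundle, Xt, ys, Xt, lam = 1, train = TRUE,
                          compute_grads = FALSE)
  expect_lt(rT$adapt, mse0 / 10)
})

test_that("every objective is continuous in lambda at 0", {
  T <- 24; B <- 5; ncls <- 3
  Xs <- rand_batch(T, B, seed = 9)
  Xt <- rand_batch(T, B, seed = 10)
  ys <- rep(1, B)
  for (m in c("dan", "dann", "drcn")) {
    bundle <- build_model_bundle(ncls, m, T = T, seed = 13,
                                 clf_config = classifier_config(ncls, dropout_rate = 0))
    fn <- switch(m, dan = function(l) dan_loss(bundle, Xs, ys, Xt, kernel_bank(base = 2), lam = l)$total,
                 dann = function(l) dann_loss(bundle, Xs, ys, Xt, lam = l)$total,
                 drcn = function(l) drcn_loss(bundle, Xs, ys, Xt, lam = l)$total)
    l0 <- fn(0)
    expect_equal(l0, fn(1e-9), tolerance = 1e-6)
  }
})
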