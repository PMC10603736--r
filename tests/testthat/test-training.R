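# Metrics, optimization loop, cross-validation, domain probe.

test_that("compute_metrics matches hand arithmetic and the formula oracle", {
  # perfect classifier
  d <- diag(c(5L, 3L, 7L))
  m <- compute_metrics(d)
  expect_equal(m$accuracy, 1)
  expect_equal(m$per_class$f1, rep(1, 3))

  # hand example: [[3,1],[1,5]]
  cm <- matrix(c(3, 1, 1, 5), 2, 2, byrow = TRUE)
  m2 <- compute_metrics(cm)
  expect_equal(m2$accuracy, 0.8)
  expect_equal(m2$per_class$precision[1], 0.75)
  expect_equal(m2$per_class$recall[1], 0.75)
  expect_equal(m2$per_class$f1[1], 0.75)

  # random matrices vs the independent per-formula recomputation
  set.seed(31)
  for (i in 1:20) {
    cm <- matrix(rpois(36, 4), 6, 6)
    if (sum(cm) == 0) next
    got <- suppressWarnings(compute_metrics(cm))
    want <- metrics_oracle(cm)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$per_class$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$per_class$recall, want$recall, tolerance = 1e-12)
    expect_equal(got$per_class$f1, want$f1, tolerance = 1e-12)
    expect_equal(got$macro_f1, want$macro_f1, tolerance = 1e-12)
    expect_lte(got$macro_f1, max(got$per_class$f1))
    expect_true(all(unlist(got$per_class[, 2:4]) >= 0 &
                    unlist(got$per_class[, 2:4]) <= 1))
  }
  expect_error(compute_metrics(matrix(0, 3, 3)), "empty")
  # zero-denominator class reports 0 with a warning
  expect_warning(z <- compute_metrics(matrix(c(2, 0, 1, 0), 2, 2)),
                 "zero denominator")
  expect_equal(z$per_class$f1[2], 0)
})

test_that("confusion_matrix counts agree with table()", {
  set.seed(17)
  truth <- sample(4, 50, replace = TRUE)
  pred <- sample(4, 50, replace = TRUE)
  cm <- confusion_matrix(truth, pred, 4)
  expect_equal(sum(cm), 50)
  tb <- table(factor(truth, 1:4), factor(pred, 1:4))
  expect_equal(unclass(cm), unclass(tb), ignore_attr = TRUE)
})

test_that("training runs are seeded-deterministic and batch size clamps", {
  cfg0 <- synthetic_config(tiny_models(), samples_per_class = 10, seed = 3)
  pair <- generate_domain_pair(cfg0, "sensor_position")
  cfg <- benchmark_train_config(epochs = 1, seed = 2)
  expect_message(r1 <- suppressWarnings(train_source_only(pair, cfg, fold = 0)), "clamped")
  r2 <- suppressWarnings(suppressMessages(train_source_only(pair, cfg, fold = 0)))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$target_test, r2$target_test)
  expect_equal(nrow(r1$history), 1)
})

test_that("train_uda history bookkeeping and selection rules are recorded", {
  cfg0 <- synthetic_config(tiny_models(), samples_per_class = 10, seed = 5)
  pair <- generate_domain_pair(cfg0, "sensor_position")
  cfg <- benchmark_train_config(epochs = 4, seed = 3)
  r <- suppressWarnings(suppressMessages(train_uda(pair, "dan", cfg, fold = 0)))
  expect_equal(nrow(r$history), 4)
  for (rule in c("source_val_best", "target_test_best")) {
    e <- r$by_rule[[rule]]$selected_epoch
    expect_gte(e, 1); expect_lte(e, 4)
  }
  # the reference selection rule picks the best target-test epoch
  expect_equal(r$by_rule$target_test_best$target_test$accuracy,
               max(r$history$target_test_acc), tolerance = 1e-12)
  expect_error(suppressMessages(train_uda(pair, "nope", cfg)), "arg")
})

test_that("run_cv aggregates fold metrics and is order-invariant", {
  cfg0 <- synthetic_config(tiny_models(), samples_per_class = 10, seed = 7)
  pair <- generate_domain_pair(cfg0, "identity")
  pair$source <- make_folds(pair$source, seed = 1)
  pair$target <- make_folds(pair$target, seed = 1)
  cfg <- benchmark_train_config(epochs = 1, seed = 1)
  cv <- suppressWarnings(suppressMessages(run_cv(pair, "source_only", cfg, n_folds = 5)))
  expect_length(cv$reports, 5)
  acc <- vapply(cv$reports, `[[`, 0, "accuracy")
  expect_equal(cv$aggregate$accuracy_mean, mean(acc), tolerance = 1e-12)
  expect_equal(cv$aggregate$macro_f1_mean,
               mean(vapply(cv$reports, `[[`, 0, "macro_f1")),
               tolerance = 1e-12)
})

test_that("domain probe separates disjoint features and not identical ones", {
  set.seed(23)
  F1 <- matrix(rnorm(60 * 8), 60, 8)
  # identical distributions: near chance (binomial CI around 0.5)
  p0 <- domain_probe(F1, matrix(rnorm(60 * 8), 60, 8), seed = 1)
  expect_lt(abs(p0 - 0.5), 0.15)
  # disjoint constants: perfectly separable
  p1 <- domain_probe(matrix(0, 40, 4), matrix(1, 40, 4), seed = 1)
  expect_equal(p1, 1.0)
  expect_error(domain_probe(F1[1:2, ], F1), "at least 4")
})
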