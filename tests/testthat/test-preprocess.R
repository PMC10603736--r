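# Segmentation, CSV reading, folds and standardization.

make_stream <- function(ann, n = NULL, fs = 100) {
  if (is.null(n)) n <- max(ann$end)
  annotated_stream(matrix(rnorm(n * 6), n, 6), fs, ann)
}

test_that("segment_stream emits exactly the full contained windows", {
  s1 <- make_stream(data.frame(start = 0, end = 200, label = "a"))
  expect_length(segment_stream(s1), 1)

  s2 <- make_stream(data.frame(start = 0, end = 400, label = "a"))
  w2 <- segment_stream(s2)
  expect_length(w2, 3)  # starts 0, 100, 200

  # >= 1 s but shorter than one full window: zero windows by the
  # full-window rule
  s3 <- make_stream(data.frame(start = 0, end = 150, label = "a"))
  expect_length(segment_stream(s3), 0)

  # epochs shorter than min_epoch_s are dropped outright
  s4 <- make_stream(data.frame(start = 0, end = 80, label = "a"), n = 80)
  expect_length(segment_stream(s4), 0)

  # no window straddles a label boundary
  s5 <- make_stream(data.frame(start = c(0, 250), end = c(250, 500),
                               label = c("a", "b")))
  ws <- segment_stream(s5)
  expect_length(ws, 2)
  expect_equal(vapply(ws, `[[`, "", "label"), c("a", "b"))
})

test_that("window count formula matches brute-force start enumeration", {
  T <- 200; stride <- 100
  for (L in seq(0, 1000, by = 37)) {
    s <- make_stream(data.frame(start = 0, end = max(L, 1), label = "a"),
                     n = max(L, 1))
    if (L == 0) next
    got <- length(segment_stream(s))
    want <- if (L < T) 0L else count_windows_brute(L, T, stride)
    expect_identical(got, want)
  }
})

test_that("read_csv_stream run-length encodes labels and validates input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  n <- 600
  df <- data.frame(timestamp = seq_len(n) / 100,
                   ax = rnorm(n), ay = rnorm(n), az = rnorm(n),
                   gx = rnorm(n), gy = rnorm(n), gz = rnorm(n),
                   label = rep(c("A", "B"), each = 300))
  write.csv(df, tmp, row.names = FALSE)
  st <- read_csv_stream(tmp)
  expect_equal(nrow(st$annotations), 2)
  expect_equal(st$annotations$end - st$annotations$start, c(300, 300))

  # an unlabeled gap splits epochs and contributes nothing
  df2 <- df
  df2$label[301:350] <- ""
  write.csv(df2, tmp, row.names = FALSE)
  st2 <- read_csv_stream(tmp)
  expect_equal(nrow(st2$annotations), 2)
  expect_equal(st2$annotations$start, c(0, 350))

  df3 <- df
  df3$gx[100] <- NA
  write.csv(df3, tmp, row.names = FALSE)
  expect_error(read_csv_stream(tmp), "row.*100|100.*row")

  df4 <- df
  df4$timestamp[10] <- df4$timestamp[9]
  write.csv(df4, tmp, row.names = FALSE)
  expect_error(read_csv_stream(tmp), "monotone")

  write.csv(df[, -2], tmp, row.names = FALSE)
  expect_error(read_csv_stream(tmp), "missing columns")
})

test_that("windows csv round-trips a dataset", {
  cfg <- synthetic_config(tiny_models(), samples_per_class = 3, seed = 5)
  ds <- generate_domain_pair(cfg)$source
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_windows_csv(ds, tmp)
  ds2 <- read_windows_csv(tmp)
  expect_equal(length(ds2$windows), length(ds$windows))
  expect_equal(ds2$windows[[4]]$x, ds$windows[[4]]$x, tolerance = 1e-12)
  expect_equal(vapply(ds2$windows, `[[`, "", "label"),
               vapply(ds$windows, `[[`, "", "label"))
})

test_that("make_folds is a stratified partition with 3:1 train/val", {
  cfg <- synthetic_config(dog_activity_models(), samples_per_class = 50,
                          seed = 2)
  ds <- generate_domain_pair(cfg)$source
  ds <- make_folds(ds, seed = 9)
  y <- aaruda:::dataset_labels(ds)

  test_sets <- lapply(0:4, function(f) split_indices(ds, f)$test)
  expect_equal(sort(unlist(test_sets)), seq_along(ds$windows))  # partition
  for (f in 0:4) {
    si <- split_indices(ds, f)
    expect_length(si$test, 60)
    expect_true(all(table(y[si$test]) == 10))      # stratified
    expect_equal(length(si$train) / length(si$val), 3, tolerance = 0.01)
    expect_length(intersect(si$train, si$test), 0)
    expect_length(intersect(si$val, si$test), 0)
  }
  ds2 <- make_folds(ds, seed = 9)
  expect_identical(ds$splits, ds2$splits)

  small <- domain_dataset(ds$windows[y == 1][1:3], ds$class_names[1])
  expect_error(make_folds(small, n_folds = 5), "fewer windows")
})

test_that("standardizer zeroes source-train moments but preserves target shift", {
  cfg <- synthetic_config(tiny_models(), samples_per_class = 20, seed = 4)
  pair <- generate_domain_pair(cfg, shift_spec(channel_bias = rep(0.5, 6)))
  sc <- fit_standardizer(pair$source$windows)
  src <- standardize_windows(pair$source$windows, sc)
  M <- do.call(cbind, lapply(src, `[[`, "x"))
  expect_equal(rowMeans(M), rep(0, 6), tolerance = 1e-9)
  expect_equal(apply(M, 1, sd), rep(1, 6), tolerance = 1e-9)

  tgt <- standardize_windows(pair$target$windows, sc)
  Mt <- do.call(cbind, lapply(tgt, `[[`, "x"))
  expect_gt(max(abs(rowMeans(Mt))), 0.2)  # bias shift survives

  const <- list(aaruda:::imu_window(matrix(1, 6, 10), "a"),
                aaruda:::imu_window(matrix(1, 6, 10), "a"))
  expect_warning(scc <- fit_standardizer(const), "zero-variance")
  out <- standardize_windows(const, scc)
  expect_equal(max(abs(out[[1]]$x)), 0)
})
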