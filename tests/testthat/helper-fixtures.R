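# Shared fixtures and independent oracles for the test suite.
# All fixtures are generated in code; nothing is read from disk.

# small activity-model set: 3 well-separated classes, cheap to train on
tiny_models <- function() {
  unit <- function(v) v / sqrt(sum(v^2))
  list(
    rest = activity_model("rest", unit(c(0, 0, 1)), noise_sd = 0.05),
    walk = activity_model("walk", unit(c(0, 0.3, 1)), osc_frequency_hz = 1.5,
                          osc_amplitude_acc = 0.3, osc_amplitude_gyro = 40,
                          noise_sd = 0.08),
    trot = activity_model("trot", unit(c(0, 0.3, 1)), osc_frequency_hz = 3,
                          osc_amplitude_acc = 0.6, osc_amplitude_gyro = 80,
                          noise_sd = 0.08)
  )
}

# engine-layout batch of random windows
rand_batch <- function(T, B, C = 6, seed = 1) {
  with_seed <- aaruda:::with_seed
  with_seed(seed, {
    X <- matrix(rnorm(T * B * C), T * B, C)
    attr(X, "dims") <- c(T = T, B = B)
    X
  })
}

# O(n^2) double-loop MK-MMD oracle, independent of the package estimator
mmd_oracle <- function(A, B, bws, estimator = "unbiased") {
  m <- nrow(A); n <- nrow(B)
  kern <- function(x, y, bw) exp(-sum((x - y)^2) / bw)
  total <- 0
  for (bw in bws) {
    saa <- 0; sbb <- 0; sab_off <- 0; sab_all <- 0
    for (i in seq_len(m)) for (j in seq_len(m))
      if (i != j) saa <- saa + kern(A[i, ], A[j, ], bw)
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i != j) sbb <- sbb + kern(B[i, ], B[j, ], bw)
    for (i in seq_len(m)) for (j in seq_len(n)) {
      kij <- kern(A[i, ], B[j, ], bw)
      sab_all <- sab_all + kij
      if (i != j) sab_off <- sab_off + kij
    }
    if (estimator == "unbiased") {
      v <- saa / (m * (m - 1)) + sbb / (n * (n - 1))
      v <- v - if (m == n) 2 * sab_off / (m * (m - 1)) else 2 * sab_all / (m * n)
    } else {
      kaa <- 0
      for (i in seq_len(m)) for (j in seq_len(m)) kaa <- kaa + kern(A[i,], A[j,], bw)
      kbb <- 0
      for (i in seq_len(n)) for (j in seq_len(n)) kbb <- kbb + kern(B[i,], B[j,], bw)
      v <- kaa / m^2 + kbb / n^2 - 2 * sab_all / (m * n)
    }
    total <- total + v
  }
  total / length(bws)
}

# direct per-formula metric oracle (one-vs-rest precision/recall/F1)
metrics_oracle <- function(cm) {
  k <- nrow(cm)
  prec <- rec <- f1 <- numeric(k)
  for (c in seq_len(k)) {
    tp <- cm[c, c]
    fp <- sum(cm[-c, c])
    fn <- sum(cm[c, -c])
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (prec[c] + rec[c] > 0)
      2 * rec[c] * prec[c] / (rec[c] + prec[c]) else 0
  }
  list(accuracy = sum(diag(cm)) / sum(cm), precision = prec, recall = rec,
       f1 = f1, macro_f1 = mean(f1))
}

# brute-force enumeration of valid window starts within an epoch
count_windows_brute <- function(L, T, stride) {
  n <- 0L
  s <- 0
  while (s + T <= L) {
    n <- n + 1L
    s <- s + stride
  }
  n
}

# the memoised benchmark grid shared by the acceptance criteria (runs once)
acceptance_env <- new.env(parent = emptyenv())

acceptance_benchmark <- function() {
  if (!is.null(acceptance_env$bench)) return(acceptance_env$bench)
  acceptance_env$bench <- run_benchmark(
    methods = c("source_only", "dan", "dann", "drcn"),
    seeds = 1:2, preset = "sensor_position", epochs = 30,
    samples_per_class = 50, keep_bundles = TRUE)
  acceptance_env$bench
}
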