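# Synthetic IMU generator: signal structure, shifts, determinism.

test_that("noise-free static and periodic windows have exact structure", {
  # static: constant gravity, zero gyro (noise_sd must be >0 by contract,
  # so build the noise-free case through the internals)
  m <- activity_model("static", c(0, 0, 1), noise_sd = 1e-12)
  w <- aaruda:::with_seed(1, synthesize_window(m, 100, 2))
  expect_equal(dim(w$x), c(6, 200))
  expect_equal(max(abs(w$x[1:2, ])), 0, tolerance = 1e-9)
  expect_equal(max(abs(w$x[3, ] - 1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(w$x[4:6, ])), 0, tolerance = 1e-7)

  # dynamic, 3 Hz in a 2-s window: exactly 6 cycles, so the window mean of
  # every oscillating channel equals its DC term
  d <- activity_model("dyn", c(0, 0, 1), osc_frequency_hz = 3,
                      osc_amplitude_acc = 0.5, osc_amplitude_gyro = 50,
                      noise_sd = 1e-12)
  w <- aaruda:::with_seed(2, synthesize_window(d, 100, 2))
  expect_equal(rowMeans(w$x), c(0, 0, 1, 0, 0, 0), tolerance = 1e-9)
})

test_that("dominant spectral peak matches the class cadence", {
  freq_peak <- function(x, fs) {
    sp <- Mod(stats::fft(x - mean(x)))[2:(length(x) / 2)]
    which.max(sp) * fs / length(x)
  }
  hits <- matrix(0, 2, 100)
  for (i in 1:100) {
    for (j in 1:2) {
      f <- c(1.5, 3)[j]
      m <- activity_model("d", c(0, 0, 1), osc_frequency_hz = f,
                          osc_amplitude_acc = 0.5, osc_amplitude_gyro = 50,
                          noise_sd = 0.01)
      w <- aaruda:::with_seed(1000 + 2 * i + j, synthesize_window(m, 100, 2))
      hits[j, i] <- abs(freq_peak(w$x[3, ], 100) - f) <= 0.5
    }
  }
  expect_gte(sum(hits[1, ]), 99)
  expect_gte(sum(hits[2, ]), 99)
})

test_that("apply_shift honors identity, rotation and gain contracts", {
  m <- tiny_models()$walk
  w <- aaruda:::with_seed(7, synthesize_window(m, 100, 2))

  expect_identical(apply_shift(w, shift_spec())$x, w$x)

  # 90 degrees about z maps acc x onto y
  wx <- w
  wx$x <- rbind(matrix(rep(c(1, 0, 0), 200), 3), matrix(0, 3, 200))
  rot <- shift_spec(rotation = rotation_matrix("z", 90))
  expect_equal(apply_shift(wx, rot)$x[1:3, 1], c(0, 1, 0), tolerance = 1e-12)

  # gain 2 on channel 1 quadruples its variance, brute-force before/after
  g <- shift_spec(channel_gain = c(2, 1, 1, 1, 1, 1))
  ws <- apply_shift(w, g)
  expect_equal(var(ws$x[1, ]), 4 * var(w$x[1, ]), tolerance = 1e-10)
  expect_equal(ws$x[2:6, ], w$x[2:6, ])
})

test_that("shift and model validation rejects bad inputs", {
  expect_error(activity_model("a", c(1, 1, 1)), "unit vector")
  expect_error(activity_model("a", c(0, 0, 1), osc_frequency_hz = 0,
                              osc_amplitude_acc = 1), "static")
  expect_error(activity_model("a", c(0, 0, NA)), "finite")
  expect_error(shift_spec(rotation = diag(3) * 2), "orthonormal")
  expect_error(shift_spec(rotation = diag(c(1, 1, -1))), "orthonormal")
  expect_error(synthetic_config(list(activity_model("a", c(0, 0, 1),
                                                    osc_frequency_hz = 60,
                                                    osc_amplitude_acc = 1,
                                                    osc_amplitude_gyro = 1))),
               "Nyquist")
})

test_that("generate_domain_pair bookkeeping, determinism and stream splitting", {
  cfg <- synthetic_config(dog_activity_models(), samples_per_class = 5, seed = 11)
  pair <- generate_domain_pair(cfg, "species")
  for (ds in pair) {
    expect_length(ds$windows, 30)
    expect_true(all(table(vapply(ds$windows, `[[`, "", "label")) == 5))
  }
  pair2 <- generate_domain_pair(cfg, "species")
  expect_identical(pair, pair2)

  # adding a class must not perturb the other classes' draws
  cfg2 <- synthetic_config(c(dog_activity_models(), tiny_models()["trot"]),
                           samples_per_class = 5, seed = 11)
  pair3 <- generate_domain_pair(cfg2, "species")
  expect_identical(pair$source$windows[[1]]$x, pair3$source$windows[[1]]$x)
})

test_that("shifted pairs diverge in MK-MMD and the shift is monotone in angle", {
  cfg <- synthetic_config(tiny_models(), samples_per_class = 20, seed = 3)
  flat <- function(ds, idx) t(vapply(ds$windows[idx],
                                     function(w) as.numeric(w$x[3, ]),
                                     numeric(200)))
  vals <- vapply(c(0, 30, 60, 90), function(ang) {
    mean(vapply(1:10, function(s) {
      cfgs <- synthetic_config(tiny_models(), samples_per_class = 20, seed = s)
      p <- generate_domain_pair(cfgs, shift_spec(rotation_matrix("x", ang)))
      mk_mmd(flat(p$source, 1:20), flat(p$target, 1:20),
             kernel_bank(), estimator = "biased")
    }, 0))
  }, 0)
  expect_true(all(diff(vals) >= 0))
  expect_gt(vals[4], vals[1])
})
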