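test_that("optical density conversion matches its definition", {
  # constant intensity and scale invariance
  arr <- array(2, dim = c(50, 2, 2))
  od <- intensity_to_od(raw_intensity(arr))
  expect_equal(max(abs(od$data)), 0)
  arr2 <- arr * 7.3
  od2 <- intensity_to_od(raw_intensity(arr2))
  expect_equal(od2$data, od$data)

  # hand-evaluated example with a restricted reference window
  x <- c(1, 1, 1, exp(1))
  r <- raw_intensity(array(rep(x, 2), dim = c(4, 1, 2)))
  od3 <- intensity_to_od(r, reference = 1:3)
  expect_equal(od3$data[, 1, 1], c(0, 0, 0, -1))

  # zero mean over the reference window by construction
  set.seed(1)
  arr4 <- array(exp(rnorm(400, sd = 0.05)), dim = c(100, 2, 2))
  od4 <- intensity_to_od(raw_intensity(arr4))
  expect_lt(max(abs(apply(exp(-od4$data), c(2, 3), function(v) mean(v) - 1))),
            1e-9)

  expect_error(raw_intensity(array(c(-1, rep(1, 399)), dim = c(100, 2, 2))),
               "non-positive")
  expect_error(intensity_to_od(raw_intensity(arr), reference = integer(0)),
               "reference")
})

test_that("MODWT inverts exactly and motion correction behaves", {
  set.seed(42)
  x <- rnorm(300)
  w <- modwt(x, wavelet = "db5")
  expect_equal(imodwt(w), x, tolerance = 1e-12)
  w2 <- modwt(x, levels = 3, wavelet = "db2")
  expect_equal(imodwt(w2), x, tolerance = 1e-12)
  expect_error(modwt(rnorm(16), levels = 8), "too short")

  # pure tone (periodic in the window, so no boundary outliers):
  # no coefficient exceeds the IQR threshold, signal untouched
  t <- seq_len(512) / 10
  s <- sin(2 * pi * (4 / 512 * 10) * t)
  out <- wavelet_motion_correct(s)
  expect_lt(sqrt(mean((out - s)^2)), 1e-6)

  # constant signal: all detail coefficients zero
  out_c <- wavelet_motion_correct(rep(3, 256))
  expect_equal(out_c, rep(3, 256), tolerance = 1e-9)

  # spike correction reduces RMSE against the clean signal
  improved <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    clean <- sin(2 * pi * (4 / 512 * 10) * t) + 0.1 * rnorm(512)
    spiked <- clean
    k <- sample(50:450, 1)
    spiked[k] <- spiked[k] + 10
    corr <- wavelet_motion_correct(spiked)
    if (sqrt(mean((corr - clean)^2)) < sqrt(mean((spiked - clean)^2)))
      improved <- improved + 1L
  }
  expect_gte(improved, 19L)

  # idempotence on an already-corrected smooth signal
  once <- wavelet_motion_correct(s)
  twice <- wavelet_motion_correct(once)
  expect_lt(sqrt(mean((twice - once)^2)), 1e-6)
  # output length always equals input length
  expect_length(wavelet_motion_correct(rnorm(300)), 300)
})

test_that("low-pass filter has unit DC gain and the required attenuation", {
  expect_equal(lowpass(rep(5, 200), fs = 10), rep(5, 200), tolerance = 1e-9)
  t <- seq_len(4000) / 10
  slow <- sin(2 * pi * 0.05 * t)
  out <- lowpass(slow, fs = 10)
  mid <- 500:3500
  expect_lt(max(abs(out[mid] - slow[mid])) / max(abs(slow)), 0.01)
  fast <- sin(2 * pi * 3 * t)
  out_f <- lowpass(fast, fs = 10)
  expect_lt(sd(out_f[mid]) / sd(fast[mid]), 10^(-20 / 20))
  expect_error(lowpass(slow, fs = 10, cutoff = 6), "cutoff")
})

test_that("Beer-Lambert inversion is exact for any invertible configuration", {
  # zero OD maps to zero concentration
  od0 <- optical_density(array(0, dim = c(10, 2, 2)), fs = 10,
                         wavelengths = c(695, 830))
  h0 <- od_to_hemoglobin(od0)
  expect_equal(max(abs(h0$hbo)), 0)
  expect_equal(max(abs(h0$hbr)), 0)

  # identity extinction, unit pathlength: concentrations = OD (in mM)
  cfg_id <- beer_lambert_config(extinction = diag(2), dpf = c(1, 1),
                                distance = 1)
  odm <- array(0, dim = c(1, 1, 2))
  odm[1, 1, ] <- c(0.3, 0.1)
  h_id <- od_to_hemoglobin(optical_density(odm, 10, c(695, 830)), cfg_id)
  expect_equal(unname(h_id$hbo[1, 1]), 0.3 * 1000)
  expect_equal(unname(h_id$hbr[1, 1]), 0.1 * 1000)

  # round trip under several random invertible configurations
  for (seed in 1:5) {
    set.seed(seed)
    cfg <- beer_lambert_config(
      extinction = matrix(runif(4, 0.01, 0.2), 2, 2) + diag(2) * 0.3,
      dpf = runif(2, 4, 8), distance = runif(1, 20, 40))
    h <- hemo_signals(matrix(rnorm(60), 20, 3), matrix(rnorm(60), 20, 3),
                      fs = 10)
    od <- semifc:::hemoglobin_to_od(h, cfg)
    h2 <- od_to_hemoglobin(od, cfg)
    expect_equal(h2$hbo, h$hbo, tolerance = 1e-9)
    expect_equal(h2$hbr, h$hbr, tolerance = 1e-9)
  }
  expect_error(beer_lambert_config(extinction = matrix(1, 2, 2)), "singular")
})

test_that("modality separation is exact, additive, and rejects k1 = k2", {
  set.seed(7)
  n <- 100; nc <- 4
  k1 <- -0.6; k2 <- 2.0
  hbo_f <- matrix(rnorm(n * nc), n, nc)
  hbo_s <- matrix(rnorm(n * nc), n, nc)
  mix <- hemo_signals(hbo_f + hbo_s, k1 * hbo_f + k2 * hbo_s, fs = 10)
  parts <- hms_separate(mix, k1, k2)
  expect_equal(parts$functional$hbo, hbo_f, tolerance = 1e-9)
  expect_equal(parts$systemic$hbo, hbo_s, tolerance = 1e-9)
  expect_identical(parts$functional$component_tag, "functional")

  # additivity holds exactly
  expect_equal(parts$functional$hbo + parts$systemic$hbo, mix$hbo)
  expect_equal(parts$functional$hbr + parts$systemic$hbr, mix$hbr)

  # pure-component inputs separate to a null complement
  pure_f <- hemo_signals(hbo_f, k1 * hbo_f, fs = 10)
  expect_lt(max(abs(hms_separate(pure_f, k1, k2)$systemic$hbo)), 1e-12)
  pure_s <- hemo_signals(hbo_s, k2 * hbo_s, fs = 10)
  expect_lt(max(abs(hms_separate(pure_s, k1, k2)$functional$hbo)), 1e-12)

  expect_error(hms_separate(mix, 0.5, 0.5), "k1")
})

test_that("the full preprocessing chain preserves shape and recovers truth", {
  spec <- sim_spec(seed = 11, n_channels = 3, paradigm = short_paradigm())
  sim <- gen_fnirs(spec)
  res <- preprocess(sim$raw, motion_correct = FALSE)
  expect_identical(dim(res$functional$hbo), dim(sim$truth$functional$hbo))
  # functional HbO recovered up to filtering error
  err <- res$functional$hbo - sim$truth$functional$hbo
  expect_lt(sd(err) / sd(sim$truth$functional$hbo), 0.1)
})
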