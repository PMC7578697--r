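test_that("MBLL conversion inverts the forward Beer-Lambert model", {
  withr::with_seed(1, {
    n <- 400
    hbo <- matrix(0, n, 16)
    hhb <- matrix(0, n, 16)
    # zero during the 20-s baseline, arbitrary smooth changes after
    t <- (seq_len(n) - 1) * 0.65
    for (ch in 1:16) {
      hbo[t >= 20, ch] <- 0.05 * sin(t[t >= 20] / 30 + ch)
      hhb[t >= 20, ch] <- -0.02 * sin(t[t >= 20] / 25 + ch)
    }
    ser <- hb_series("S1", hbo, hhb)
    raw <- export_raw(ser)
    rec <- mbll_convert(raw)
    expect_lt(max(abs(rec$hbo - ser$hbo)), 1e-9)
    expect_lt(max(abs(rec$hhb - ser$hhb)), 1e-9)
  })
})

test_that("constant intensity maps to zero concentration change", {
  arr <- array(0.8, dim = c(300, 16, 2))
  raw <- structure(list(subject_id = "S1", intensity = arr, dt = 0.65),
                   class = "raw_intensity_series")
  hb <- mbll_convert(raw)
  expect_equal(max(abs(hb$hbo)), 0)
  expect_equal(max(abs(hb$hhb)), 0)
})

test_that("halving both intensities solves the stated 2x2 system", {
  cfg <- mbll_config()
  arr <- array(1, dim = c(100, 16, 2))
  arr[60, 3, ] <- 0.5  # one sample at half intensity, both wavelengths
  raw <- structure(list(subject_id = "S1", intensity = arr, dt = 0.65),
                   class = "raw_intensity_series")
  hb <- mbll_convert(raw, cfg)
  od <- c(log10(2), log10(2))
  expected <- solve(nirscit:::mbll_coef_matrix(cfg), od)
  expect_equal(unname(hb$hbo[60, 3]), unname(expected[1]),
               tolerance = 1e-10)
  expect_equal(unname(hb$hhb[60, 3]), unname(expected[2]),
               tolerance = 1e-10)
})

test_that("MBLL rejects bad inputs", {
  arr <- array(1, dim = c(100, 16, 2))
  arr[5, 2, 1] <- 0
  raw <- structure(list(subject_id = "S1", intensity = arr, dt = 0.65),
                   class = "raw_intensity_series")
  expect_error(mbll_convert(raw), "non-positive intensity.*CH2")
  expect_error(mbll_config(extinction = matrix(1, 2, 2)), "singular")
})

test_that("band-pass removes DC and passes mid-band with zero lag", {
  dt <- 0.65
  n <- ceiling(2000 / dt)
  t <- (seq_len(n) - 1) * dt
  # constant input is outside the passband
  const <- constant_hb_series(3, n = n)
  out <- bandpass_zero_phase(const)
  mid <- seq(round(n * 0.2), round(n * 0.8))
  expect_lt(max(abs(out$hbo[mid, 1])), 1e-6 * 3)

  probe <- sin(2 * pi * 0.05 * t)
  ser <- hb_series("S1", matrix(probe, n, 16), dt = dt)
  filt <- bandpass_zero_phase(ser)
  gain <- sd(filt$hbo[mid, 1]) / sd(probe[mid])
  expect_gt(gain, 0.9)
  expect_lt(gain, 1.1)
  cc <- ccf(filt$hbo[mid, 1], probe[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # pulsatile probe is strongly attenuated (>= 20 dB)
  fast <- sin(2 * pi * 0.5 * t)
  ser2 <- hb_series("S1", matrix(fast, n, 16), dt = dt)
  filt2 <- bandpass_zero_phase(ser2)
  atten_db <- 20 * log10(sd(fast[mid]) / sd(filt2$hbo[mid, 1]))
  expect_gt(atten_db, 20)
})

test_that("band-pass validates its preconditions", {
  expect_error(bandpass_zero_phase(constant_hb_series(1, n = 50)),
               "too short")
  expect_error(bandpass_zero_phase(constant_hb_series(1), f_lo = 0.2,
                                   f_hi = 0.1), "band edges")
  expect_error(bandpass_zero_phase(constant_hb_series(1), f_hi = 2),
               "band edges")
})

test_that("baseline standardisation subtracts channel baseline means", {
  lay <- session_layout()
  withr::with_seed(2, {
    n <- 560
    x <- matrix(rnorm(n * 16), n, 16)
    offs <- seq(1, 16)
    shifted <- sweep(x, 2, offs, "+")
    s1 <- hb_series("A", x)
    s2 <- hb_series("B", shifted)
    o1 <- baseline_standardize(s1, lay)
    o2 <- baseline_standardize(s2, lay)
    # identical post-baseline shapes with different offsets coincide
    expect_equal(o1$hbo, o2$hbo, tolerance = 1e-12)
    # definition: output = input - baseline mean
    idx <- which((seq_len(n) - 1) * 0.65 < 20)
    m <- colMeans(x[idx, ])
    expect_equal(o1$hbo, sweep(x, 2, m), tolerance = 1e-12,
                 ignore_attr = TRUE)
  })
  # z mode with flat baseline errors
  expect_error(baseline_standardize(constant_hb_series(1),
                                    session_layout(), mode = "z"),
               "zero baseline")
})

test_that("block features average HbO2 after the onset exclusion", {
  lay <- session_layout()
  n <- 560
  dt <- 0.65
  t <- (seq_len(n) - 1) * dt
  x <- matrix(0, n, 16)
  # channel 1 constant during blocks; channel 2 zero for the first 10 s of
  # each block then 2.0; channel 3 a linear ramp within block 1
  x[, 1] <- 1
  blk <- lay$blocks[[1]]
  for (b in lay$blocks) {
    x[t >= b[1] + 10 & t < b[2], 2] <- 2
  }
  in1 <- t >= blk[1] & t < blk[2]
  x[in1, 3] <- (t[in1] - blk[1]) / (blk[2] - blk[1])
  feats <- block_features(hb_series("S1", x), lay, group = "CL")
  expect_equal(nrow(feats), 3)
  expect_equal(feats$ch1, rep(1, 3))
  expect_equal(feats$ch2[1], 2)
  # closed-form mean of the retained ramp section
  keep <- t >= blk[1] + 10 & t < blk[2]
  expect_equal(feats$ch3[1], mean((t[keep] - blk[1]) / (blk[2] - blk[1])))
  expect_error(block_features(hb_series("S1", x), lay,
                              onset_exclusion_s = 95), "shorter")
})

test_that("feature pipeline is linear in the haemoglobin series", {
  lay <- session_layout()
  ses <- generate_session("S1", "CL", seed = 9)
  run <- function(s) {
    s |> bandpass_zero_phase() |> baseline_standardize(lay) |>
      block_features(lay, group = "CL")
  }
  f1 <- run(ses)
  ses2 <- ses
  ses2$hbo <- 2 * ses$hbo
  ses2$hhb <- 2 * ses$hhb
  f2 <- run(ses2)
  cols <- paste0("ch", 1:16)
  expect_equal(as.matrix(f2[cols]), 2 * as.matrix(f1[cols]),
               tolerance = 1e-10)
})

test_that("dataset assembly enforces shape, CIT selection and encoding", {
  coh_rows <- quick_feature_table(n_cl = 30, n_hc = 25,
                                  cits = c("CIT1", "CIT2", "CIT3"))
  all_rows <- build_dataset(coh_rows, include_cits = paste0("CIT", 1:3))
  expect_equal(nrow(all_rows), 165)
  two <- build_dataset(coh_rows)
  expect_equal(nrow(two), 110)
  expect_equal(names(two), c("subject_id", "group", "cit",
                             paste0("ch", 1:16)))
  expect_error(build_dataset(coh_rows, include_cits = character(0)),
               "non-empty")
  expect_error(build_dataset(rbind(coh_rows, coh_rows[1, ])), "duplicate")
  expect_equal(nirscit:::label_to_y(c("CL", "HC")), c(1, -1))
})
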