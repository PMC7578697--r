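test_that("HRF kernel integrates to one and peaks after the onset delay", {
  spec <- hrf_spec()
  dt <- 0.05
  k <- hrf_kernel(spec, dt)
  expect_equal(sum(k) * dt, 1, tolerance = 1e-9)
  t_peak <- (which.max(k) - 1) * dt
  expect_equal(t_peak, spec$onset_delay_s + spec$peak_s, tolerance = 0.5)
  expect_error(hrf_spec(peak_s = 20, undershoot_s = 16))
})

test_that("noise-free sessions are the convolved boxcar, zero when silent", {
  ns0 <- noise_spec(cardiac_amp = 0, vaso_amp = 0, drift_sd = 0,
                    rw_sd = 0, white_sd = 0, freq_jitter = 0,
                    gain_sd = 0, channel_gain_sd = 0, block_amp_sd = 0)
  silent <- generate_session("S0", "HC", noise = ns0, seed = 1,
                             base_amplitude = 0,
                             effect = effect_spec(delta = 0))
  expect_equal(max(abs(silent$hbo)), 0)
  expect_equal(max(abs(silent$hhb)), 0)

  # block-interior mean approaches the block amplitude (unit-integral HRF)
  lay <- session_layout()
  amp <- 0.8
  ses <- generate_session("S1", "HC", noise = ns0, seed = 1,
                          base_amplitude = amp,
                          effect = effect_spec(delta = 0))
  t <- (seq_len(nrow(ses$hbo)) - 1) * ses$dt
  blk <- lay$blocks[[2]]
  interior <- t >= blk[1] + 30 & t < blk[2]
  # discrete-convolution oracle on the same kernel and grid
  dtf <- ses$dt / 13
  nf <- nrow(ses$hbo) * 13
  tf <- (seq_len(nf) - 1) * dtf
  box <- numeric(nf)
  for (b in lay$blocks) box[tf >= b[1] & tf < b[2]] <- 1
  kern <- hrf_kernel(hrf_spec(), dtf)
  oracle <- amp * (stats::convolve(box, rev(kern),
                                   type = "open")[seq_len(nf)] * dtf)
  oracle_coarse <- oracle[seq(1, nf, by = 13)]
  expect_equal(ses$hbo[, 5], oracle_coarse, tolerance = 1e-10)
  expect_equal(mean(ses$hbo[interior, 5]), amp, tolerance = 0.02)
})

test_that("sessions are bit-identical under a seed and differ across seeds", {
  s1 <- generate_session("S1", "CL", seed = 11)
  s2 <- generate_session("S1", "CL", seed = 11)
  s3 <- generate_session("S1", "CL", seed = 12)
  expect_identical(s1$hbo, s2$hbo)
  expect_false(identical(s1$hbo, s3$hbo))
  bad_lay <- session_layout()
  bad_lay$blocks[[1]] <- c(10, 100)  # starts inside the baseline
  expect_error(generate_session("S1", "CL", layout = bad_lay, seed = 1),
               "overlap")
})

test_that("cohorts carry labels, planted effects and downstream shape", {
  coh <- generate_cohort(n_cl = 4, n_hc = 3, n_mhe = 2, seed = 2)
  expect_equal(nrow(coh$labels), 7)
  expect_equal(sum(coh$labels$mhe), 2)
  expect_equal(length(coh$sessions), 7)
  c2 <- generate_cohort(n_cl = 4, n_hc = 3, n_mhe = 2, seed = 2)
  expect_identical(coh$sessions[[1]]$hbo, c2$sessions[[1]]$hbo)
  expect_error(generate_cohort(n_cl = 2, n_mhe = 5))
})

test_that("planted channels separate groups in the planted direction", {
  coh <- generate_cohort(seed = 77, effect = effect_spec(delta = 1))
  feats <- cohort_features(coh)
  x <- as.matrix(feats[paste0("ch", 1:16)])
  cl <- feats$group == "CL"
  for (ch in c(6, 7, 10)) {
    expect_gt(mean(x[cl, ch]) - mean(x[!cl, ch]), 0)
  }
  for (ch in c(13, 14, 16)) {
    expect_lt(mean(x[cl, ch]) - mean(x[!cl, ch]), 0)
  }
})

test_that("strong planted effects dominate the search with correct
           weight signs", {
  coh <- generate_cohort(seed = 103, effect = effect_spec(delta = 1))
  feats <- cohort_features(coh)
  rep6 <- exhaustive_search(feats, "bilateral", max_size = 6, seed = 3,
                            tol = 1e-2)
  expect_gt(rep6$mean_mcc[1], 0.5)
  wm <- weight_sign_matrix(feats, rep6, m = 1)
  top <- as.integer(strsplit(rownames(wm)[1], ",")[[1]])
  for (ch in intersect(top, c(6, 7, 10))) expect_gt(wm[1, ch], 0)
  for (ch in intersect(top, c(13, 14, 16))) expect_lt(wm[1, ch], 0)
  expect_gte(length(intersect(top, c(6, 7, 10, 13, 14, 16))), 3)
})

test_that("single-class cohorts propagate to a training error", {
  coh <- generate_cohort(n_cl = 0, n_hc = 8, n_mhe = 0, seed = 3)
  feats <- cohort_features(coh)
  expect_error(repeated_kfold(feats, k = 2, repeats = 1, seed = 1),
               "class")
})

test_that("behaviour generator recovers its group means under truncation", {
  beh <- generate_behavior(n_cl = 10000, n_hc = 10000, seed = 13)
  spec <- behavior_spec()
  for (grp in c("CL", "HC")) {
    for (cit in paste0("CIT", 1:3)) {
      sub <- beh[beh$group == grp & beh$cit_id == cit, ]
      target <- spec$accuracy$mean[spec$accuracy$group == grp &
                                     spec$accuracy$cit == cit]
      se <- sd(sub$accuracy) / sqrt(nrow(sub))
      expect_lt(abs(mean(sub$accuracy) - target), 2 * se + 1e-3)
      expect_true(all(sub$accuracy >= 0 & sub$accuracy <= 1))
      expect_true(all(sub$mean_rt_ms > 0))
    }
  }
})

test_that("latent coupling reproduces the observed correlation signs", {
  signs_ok <- sapply(1:20, function(s) {
    beh <- generate_behavior(n_cl = 200, n_hc = 200, seed = 400 + s)
    cl1 <- beh[beh$group == "CL" & beh$cit_id == "CIT1", ]
    c(cor(cl1$accuracy, cl1$nct_a_s) < 0,
      cor(cl1$mean_rt_ms, cl1$nct_a_s) > 0,
      cor(cl1$accuracy, cl1$dst_forward) > 0,
      cor(cl1$mean_rt_ms, cl1$dst_backward) < 0)
  })
  expect_gte(mean(signs_ok), 0.95)
})

test_that("uncoupled scores show no systematic correlation", {
  beh <- generate_behavior(n_cl = 300, n_hc = 300,
                           spec = behavior_spec(rho = 0), seed = 14)
  cl1 <- beh[beh$group == "CL" & beh$cit_id == "CIT2", ]
  expect_lt(abs(cor(cl1$accuracy, cl1$nct_a_s)), 0.15)
  expect_lt(abs(cor(cl1$mean_rt_ms, cl1$dst_forward)), 0.15)
})

test_that("forward intensity export is linear in optical density", {
  n <- 100
  hbo <- matrix(0, n, 16)
  hbo[50, ] <- 0.01
  ser1 <- hb_series("S1", hbo, matrix(0, n, 16))
  ser2 <- hb_series("S2", 2 * hbo, matrix(0, n, 16))
  r1 <- export_raw(ser1)
  r2 <- export_raw(ser2)
  od1 <- -log10(r1$intensity[50, 1, ] / r1$intensity[1, 1, ])
  od2 <- -log10(r2$intensity[50, 1, ] / r2$intensity[1, 1, ])
  expect_equal(od2, 2 * od1, tolerance = 1e-12)
  # zero change keeps baseline intensities
  expect_equal(r1$intensity[1, , ], r1$intensity[2, , ])
})
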