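# Seeded synthetic fNIRS cohorts with planted channel effects, physiological
# noise, and behavioural tables whose scores are coupled through a latent
# ability. Every quantity is a pure function of its spec and seed.

#' Haemodynamic response kernel specification
#'
#' Canonical double-gamma kernel (response peak, later undershoot, ratio of
#' undershoot to peak) shifted by an onset delay. The kernel is normalised
#' to unit integral so the plateau of a convolved long block equals the
#' block amplitude.
#'
#' @param peak_s Time-to-peak of the positive lobe in s (default 6).
#' @param undershoot_s Time-to-peak of the undershoot in s (default 16).
#' @param ratio Undershoot/peak amplitude ratio (default 1/6).
#' @param onset_delay_s Response onset delay in s (default 5); an
#'   additional delay can be applied to MHE-like subjects via
#'   `mhe_extra_delay_s` in [generate_cohort()].
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_s = 6, undershoot_s = 16, ratio = 1 / 6,
                     onset_delay_s = 5) {
  stopifnot(peak_s > 0, undershoot_s > peak_s, ratio >= 0, ratio < 1,
            onset_delay_s >= 0)
  structure(list(peak_s = peak_s, undershoot_s = undershoot_s,
                 ratio = ratio, onset_delay_s = onset_delay_s),
            class = "hrf_spec")
}

#' Evaluate the (delayed, unit-integral) double-gamma kernel
#'
#' @param spec An [hrf_spec()].
#' @param dt Sampling interval of the kernel grid in s.
#' @param duration_s Kernel support after the delay (default 32 s).
#' @param extra_delay_s Additional onset delay in s.
#' @return Numeric vector of kernel samples; `sum(kernel) * dt == 1`.
#' @export
hrf_kernel <- function(spec, dt, duration_s = 32, extra_delay_s = 0) {
  delay <- spec$onset_delay_s + extra_delay_s
  t <- seq(0, delay + duration_s, by = dt)
  ts <- pmax(t - delay, 0)
  k <- dgamma(ts, shape = spec$peak_s + 1, rate = 1) -
    spec$ratio * dgamma(ts, shape = spec$undershoot_s + 1, rate = 1)
  k / (sum(k) * dt)
}

#' Planted group-effect specification
#'
#' Per-channel amplitude offsets applied to the patient (CL) group,
#' expressed in units of the within-group feature standard deviation
#' (delta). Defaults plant +delta at CH6/CH7/CH10 (CL > HC) and -delta at
#' CH13/CH14/CH16 (CL < HC); all other channels carry no group effect.
#'
#' `amp_per_sd` converts one feature-SD unit into block-amplitude units; it
#' is calibrated once against the default noise model and preprocessing
#' chain so that `delta` equals the realised between-group separation in
#' feature-SD units (see the methods vignette).
#'
#' @param delta Effect size in feature-SD units (default 0.5).
#' @param positive_channels Channels elevated in CL.
#' @param negative_channels Channels reduced in CL.
#' @param amp_per_sd Amplitude units per feature-SD unit (calibrated
#'   constant).
#' @return An object of class `effect_spec` with an `offsets` vector
#'   (length 16, feature-SD units).
#' @export
effect_spec <- function(delta = 0.5, positive_channels = c(6, 7, 10),
                        negative_channels = c(13, 14, 16),
                        amp_per_sd = 0.56) {
  stopifnot(is.finite(delta), delta >= 0,
            all(positive_channels %in% 1:16),
            all(negative_channels %in% 1:16),
            length(intersect(positive_channels, negative_channels)) == 0)
  offsets <- numeric(16)
  offsets[positive_channels] <- delta
  offsets[negative_channels] <- -delta
  structure(list(delta = delta, offsets = offsets,
                 amp_per_sd = amp_per_sd,
                 planted_channels = sort(c(positive_channels,
                                           negative_channels))),
            class = "effect_spec")
}

#' Physiological noise specification
#'
#' Cardiac pulsation (~1.1 Hz, above the 0.77 Hz Nyquist rate of the
#' 0.65 s sampling: it is injected on a fine time grid and decimated, so
#' it aliases exactly as in a real recording), ~0.1 Hz vasomotion, linear
#' drift, random-walk drift, white measurement noise, and subject/channel
#' response-gain variability.
#'
#' @param cardiac_hz,cardiac_amp Cardiac frequency (Hz) and amplitude.
#' @param vaso_hz,vaso_amp Vasomotion frequency (Hz) and amplitude.
#' @param drift_sd SD of the total linear drift over the session.
#' @param rw_sd Random-walk innovation SD per sqrt(s).
#' @param white_sd White-noise SD per sample.
#' @param freq_jitter Relative per-subject jitter of the oscillation
#'   frequencies.
#' @param gain_sd SD of the subject-level response gain (mean 1).
#' @param channel_gain_sd SD of the channel-level response gain (mean 1).
#' @param block_amp_sd SD of the multiplicative block-to-block response
#'   variability (mean 1), emulating attention/arousal fluctuation of the
#'   haemodynamic response across task blocks.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(cardiac_hz = 1.1, cardiac_amp = 0.2,
                       vaso_hz = 0.1, vaso_amp = 0.1,
                       drift_sd = 0.5, rw_sd = 0.03, white_sd = 0.12,
                       freq_jitter = 0.05, gain_sd = 0.1,
                       channel_gain_sd = 0.05, block_amp_sd = 0.35) {
  vals <- c(cardiac_amp, vaso_amp, drift_sd, rw_sd, white_sd,
            freq_jitter, gain_sd, channel_gain_sd, block_amp_sd)
  stopifnot(all(vals >= 0), cardiac_hz > 0, vaso_hz > 0)
  structure(list(cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp,
                 vaso_hz = vaso_hz, vaso_amp = vaso_amp,
                 drift_sd = drift_sd, rw_sd = rw_sd, white_sd = white_sd,
                 freq_jitter = freq_jitter, gain_sd = gain_sd,
                 channel_gain_sd = channel_gain_sd,
                 block_amp_sd = block_amp_sd),
            class = "noise_spec")
}

#' Generate one synthetic fNIRS session
#'
#' Per channel the HbO2 signal is a boxcar over the task blocks (amplitude
#' = base amplitude plus the group's planted offset for that channel,
#' scaled by subject and channel gains) convolved with the delayed
#' double-gamma kernel, plus all noise components. Signals are synthesised
#' on a fine grid (`dt / oversample`) and decimated to `dt`, so
#' above-Nyquist cardiac pulsation aliases realistically. HHb is generated
#' as a negatively scaled counterpart of the HbO2 response.
#'
#' @param subject_id Subject identifier.
#' @param group `"CL"` or `"HC"`.
#' @param layout A [session_layout()]; task blocks must not overlap the
#'   baseline.
#' @param hrf,effect,noise Specs; see [hrf_spec()], [effect_spec()],
#'   [noise_spec()].
#' @param seed Integer seed; same seed gives a bit-identical session.
#' @param dt Output sampling interval in s (default 0.65).
#' @param oversample Fine-grid oversampling factor (default 13).
#' @param base_amplitude Task-response amplitude common to both groups.
#' @param extra_delay_s Additional onset delay (MHE-like subjects).
#' @param hhb_ratio HHb/HbO2 response ratio (default -0.35).
#' @return An [hb_series()].
#' @export
generate_session <- function(subject_id, group = c("CL", "HC"),
                             layout = session_layout(), hrf = hrf_spec(),
                             effect = effect_spec(), noise = noise_spec(),
                             seed, dt = 0.65, oversample = 13,
                             base_amplitude = 1, extra_delay_s = 0,
                             hhb_ratio = -0.35) {
  group <- match.arg(group)
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (layout$blocks[[1]][1] < layout$baseline[2]) {
    stop("first task block overlaps the baseline interval", call. = FALSE)
  }
  dtf <- dt / oversample
  n <- floor(layout$total_s / dt)
  nf <- n * oversample
  tf <- (seq_len(nf) - 1) * dtf

  kern <- hrf_kernel(hrf, dtf, extra_delay_s = extra_delay_s)
  block_of <- rep(0L, nf)
  for (b in seq_along(layout$blocks)) {
    blk <- layout$blocks[[b]]
    block_of[tf >= blk[1] & tf < blk[2]] <- b
  }
  n_blocks <- length(layout$blocks)

  offs_amp <- if (group == "CL") effect$offsets * effect$amp_per_sd else
    numeric(16)

  withr::with_seed(as.integer(seed), {
    g_subj <- 1 + rnorm(1, 0, noise$gain_sd)
    f_card <- noise$cardiac_hz * (1 + rnorm(1, 0, noise$freq_jitter))
    f_vaso <- noise$vaso_hz * (1 + rnorm(1, 0, noise$freq_jitter))
    hbo <- hhb <- matrix(0, n, 16)
    coarse <- seq(1, nf, by = oversample)
    for (ch in 1:16) {
      g_ch <- 1 + rnorm(1, 0, noise$channel_gain_sd)
      amp <- (base_amplitude + offs_amp[ch]) * g_subj * g_ch
      # block-to-block response variability: the boxcar carries a
      # jittered amplitude per task block before convolution
      g_blk <- 1 + rnorm(n_blocks, 0, noise$block_amp_sd)
      boxcar <- numeric(nf)
      on <- block_of > 0L
      boxcar[on] <- amp * g_blk[block_of[on]]
      sig <- stats::convolve(boxcar, rev(kern),
                             type = "open")[seq_len(nf)] * dtf
      nz <- noise$cardiac_amp * sin(2 * pi * f_card * tf + runif(1, 0, 2 * pi)) +
        noise$vaso_amp * sin(2 * pi * f_vaso * tf + runif(1, 0, 2 * pi)) +
        rnorm(1, 0, noise$drift_sd) * tf / layout$total_s +
        noise$rw_sd * cumsum(rnorm(nf)) * sqrt(dtf)
      fine <- sig + nz
      hbo[, ch] <- fine[coarse] + rnorm(n, 0, noise$white_sd)
      hhb[, ch] <- hhb_ratio * sig[coarse] +
        rnorm(n, 0, noise$white_sd / 2)
    }
    hb_series(subject_id, hbo, hhb, dt = dt)
  })
}

# per-subject seed derived from the cohort master seed; kept < 2^31
subject_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 2027L + as.integer(i)
}

#' Generate a two-group synthetic cohort
#'
#' One session per subject, with per-subject seeds derived from the master
#' seed. Defaults emulate the study conditions: 30 patients with chronic
#' liver disease (CL; the first `n_mhe` carry an informational MHE
#' sub-label) and 25 healthy controls (HC), three task blocks per session,
#' and planted group effects at CH6/CH7/CH10 (CL higher) and
#' CH13/CH14/CH16 (CL lower).
#'
#' @param n_cl,n_hc,n_mhe Group sizes (`n_mhe` is a sub-label within CL).
#' @param seed Master seed.
#' @param layout,hrf,effect,noise Specs passed to [generate_session()].
#' @param mhe_extra_delay_s Extra response delay for MHE-labelled subjects
#'   (default 0).
#' @param ... Further arguments for [generate_session()].
#' @return An object of class `synthetic_cohort`: list with `sessions`,
#'   `labels` (tibble `subject_id`, `group`, `mhe`), `layout`, the specs
#'   and the master `seed`.
#' @export
generate_cohort <- function(n_cl = 30, n_hc = 25, n_mhe = 10, seed = 1,
                            layout = session_layout(), hrf = hrf_spec(),
                            effect = effect_spec(), noise = noise_spec(),
                            mhe_extra_delay_s = 0, ...) {
  stopifnot(n_cl >= 0, n_hc >= 0, n_mhe <= n_cl)
  labels <- tibble::tibble(
    subject_id = c(sprintf("CL%02d", seq_len(n_cl)),
                   sprintf("HC%02d", seq_len(n_hc))),
    group = rep(c("CL", "HC"), c(n_cl, n_hc)),
    mhe = c(seq_len(n_cl) <= n_mhe, rep(FALSE, n_hc))
  )
  sessions <- purrr::pmap(
    list(labels$subject_id, labels$group, labels$mhe,
         seq_len(nrow(labels))),
    function(sid, grp, mhe, i) {
      generate_session(sid, grp, layout = layout, hrf = hrf,
                       effect = effect, noise = noise,
                       seed = subject_seed(seed, i),
                       extra_delay_s = if (mhe) mhe_extra_delay_s else 0,
                       ...)
    })
  structure(list(sessions = sessions, labels = labels, layout = layout,
                 hrf = hrf, effect = effect, noise = noise, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", sum(x$labels$group == "CL"), "CL +",
      sum(x$labels$group == "HC"), "HC subjects, seed", x$seed, "\n")
  invisible(x)
}

# ---- behavioural generator -------------------------------------------------

#' Behavioural score specification
#'
#' Group-wise accuracy and reaction-time means/SDs per CIT (defaults are
#' the study's group statistics), neurocognitive test means/SDs (number
#' connection tests A/B in seconds, digit span forward/backward; synthetic
#' defaults chosen as plausible values for a hepatic-encephalopathy
#' screening battery), and the latent-ability coupling `rho` that induces
#' the observed correlation sign pattern: accuracy and digit span load
#' positively on ability, reaction time and NCT completion times load
#' negatively.
#'
#' @param accuracy,reaction_time Tibbles with columns `group`, `cit`,
#'   `mean`, `sd`.
#' @param neuro Tibble with columns `group`, `test`, `mean`, `sd` for
#'   `nct_a_s`, `nct_b_s`, `dst_forward`, `dst_backward`.
#' @param rho Latent-ability coupling in `[0, 1)` (default 0.6).
#' @return An object of class `behavior_spec`.
#' @export
behavior_spec <- function(accuracy = NULL, reaction_time = NULL,
                          neuro = NULL, rho = 0.6) {
  cits <- paste0("CIT", 1:3)
  if (is.null(accuracy)) {
    accuracy <- tibble::tibble(
      group = rep(c("CL", "HC"), each = 3), cit = rep(cits, 2),
      mean = c(0.62, 0.45, 0.32, 0.75, 0.48, 0.46),
      sd = c(0.30, 0.23, 0.21, 0.28, 0.25, 0.26))
  }
  if (is.null(reaction_time)) {
    reaction_time <- tibble::tibble(
      group = rep(c("CL", "HC"), each = 3), cit = rep(cits, 2),
      mean = c(8576.44, 9595.72, 11139.09, 5799.34, 6695.61, 6926.38),
      sd = c(816.34, 1154.55, 1490.87, 894.26, 1264.74, 1633.17))
  }
  if (is.null(neuro)) {
    neuro <- tibble::tibble(
      group = rep(c("CL", "HC"), each = 4),
      test = rep(c("nct_a_s", "nct_b_s", "dst_forward", "dst_backward"),
                 2),
      mean = c(55, 95, 5.5, 3.5, 33, 62, 6.5, 4.5),
      sd = c(22, 38, 1.3, 1.2, 11, 20, 1.1, 1.2))
  }
  stopifnot(rho >= 0, rho < 1, all(accuracy$sd > 0),
            all(reaction_time$sd > 0), all(neuro$sd > 0))
  structure(list(accuracy = accuracy, reaction_time = reaction_time,
                 neuro = neuro, rho = rho),
            class = "behavior_spec")
}

# truncated-normal quantile function on [lo, hi]
qtruncnorm <- function(p, mean, sd, lo, hi) {
  pa <- pnorm(lo, mean, sd)
  pb <- pnorm(hi, mean, sd)
  qnorm(pa + p * (pb - pa), mean, sd)
}

# mean of a normal(mu, sd) truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# location mu* such that the truncated mean equals `target`
match_truncnorm_location <- function(target, sd, lo, hi) {
  if (!is.finite(lo) && !is.finite(hi)) return(target)
  uniroot(function(mu) truncnorm_mean(mu, sd, lo, hi) - target,
          interval = c(target - 6 * sd, target + 6 * sd),
          tol = 1e-10)$root
}

# one coupled truncated-normal draw: u standard normal correlated with the
# latent ability; the inverse-CDF map preserves the truncated marginal and
# the monotone dependence on the latent.
coupled_tn_draw <- function(z, rho, sign, target, sd, lo, hi) {
  eps <- rnorm(length(z))
  u <- sign * rho * z + sqrt(1 - rho^2) * eps
  mu_star <- match_truncnorm_location(target, sd, lo, hi)
  qtruncnorm(pnorm(u), mu_star, sd, lo, hi)
}

#' Generate a synthetic behaviour table
#'
#' Per subject a latent ability `z ~ N(0, 1)` drives all scores: accuracy
#' (positively, truncated to `[0, 1]`), reaction time (negatively,
#' truncated positive), NCT completion times (negatively vs ability, hence
#' positively coupled to reaction time), and digit spans (positively).
#' Locations are adjusted so the truncated means equal the spec's group
#' means.
#'
#' @param n_cl,n_hc Group sizes.
#' @param spec A [behavior_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per subject x CIT: `subject_id`, `group`,
#'   `cit_id`, `accuracy`, `mean_rt_ms`, `nct_a_s`, `nct_b_s`,
#'   `dst_forward`, `dst_backward`.
#' @export
generate_behavior <- function(n_cl = 30, n_hc = 25,
                              spec = behavior_spec(), seed = 1) {
  rho <- spec$rho
  withr::with_seed(as.integer(seed), {
    per_group <- function(grp, n, ids) {
      z <- rnorm(n)
      neuro <- spec$neuro[spec$neuro$group == grp, ]
      nmat <- sapply(c("nct_a_s", "nct_b_s", "dst_forward",
                      "dst_backward"), function(tst) {
        row <- neuro[neuro$test == tst, ]
        sgn <- if (grepl("^nct", tst)) -1 else 1
        lo <- if (grepl("^nct", tst)) 0 else 0
        coupled_tn_draw(z, rho, sgn, row$mean, row$sd, lo, Inf)
      })
      purrr::map_dfr(paste0("CIT", 1:3), function(cit) {
        am <- spec$accuracy[spec$accuracy$group == grp &
                              spec$accuracy$cit == cit, ]
        rm_ <- spec$reaction_time[spec$reaction_time$group == grp &
                                    spec$reaction_time$cit == cit, ]
        tibble::tibble(
          subject_id = ids, group = grp, cit_id = cit,
          accuracy = coupled_tn_draw(z, rho, 1, am$mean, am$sd, 0, 1),
          mean_rt_ms = coupled_tn_draw(z, rho, -1, rm_$mean, rm_$sd, 0,
                                       Inf),
          nct_a_s = nmat[, "nct_a_s"], nct_b_s = nmat[, "nct_b_s"],
          dst_forward = nmat[, "dst_forward"],
          dst_backward = nmat[, "dst_backward"])
      })
    }
    dplyr::bind_rows(
      per_group("CL", n_cl, sprintf("CL%02d", seq_len(n_cl))),
      per_group("HC", n_hc, sprintf("HC%02d", seq_len(n_hc))))
  })
}

#' Forward Beer-Lambert export of a haemoglobin series
#'
#' Produces the two-wavelength raw intensities whose [mbll_convert()]
#' inverse recovers the input series: `I = I0 * 10^(-dOD)` with
#' `dOD = A %*% c(dHbO2, dHHb)` per channel and time, `A` the
#' pathlength-scaled extinction matrix. Enables end-to-end testing of the
#' conversion without any instrument.
#'
#' @param series An [hb_series()] (values interpreted as concentration
#'   changes relative to the baseline state).
#' @param cfg An [mbll_config()].
#' @param i0 Baseline intensity per wavelength (default 1).
#' @return A `raw_intensity_series`: list with `subject_id`, `intensity`
#'   (array time x 16 x 2), `dt`, `wavelengths_nm`.
#' @export
export_raw <- function(series, cfg = mbll_config(), i0 = c(1, 1)) {
  a_mat <- mbll_coef_matrix(cfg)
  n <- nrow(series$hbo)
  arr <- array(0, dim = c(n, 16, 2))
  for (ch in 1:16) {
    od <- cbind(series$hbo[, ch], series$hhb[, ch]) %*% t(a_mat)
    arr[, ch, 1] <- i0[1] * 10^(-od[, 1])
    arr[, ch, 2] <- i0[2] * 10^(-od[, 2])
  }
  structure(list(subject_id = series$subject_id, intensity = arr,
                 dt = series$dt, wavelengths_nm = cfg$wavelengths_nm),
            class = "raw_intensity_series")
}
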