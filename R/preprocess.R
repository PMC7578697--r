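# Raw intensity -> haemoglobin conversion (modified Beer-Lambert law),
# zero-phase band-pass filtering, baseline standardisation and block-mean
# feature extraction.

#' Modified Beer-Lambert configuration
#'
#' Extinction coefficients, differential pathlength factors (DPF) and the
#' source-detector separation used to convert optical-density changes to
#' chromophore concentration changes. Defaults correspond to a two-
#' wavelength continuous-wave prefrontal device (770/840 nm, DPF 6.0 at
#' both wavelengths, 3 cm separation) with standard adult extinction
#' coefficients in mM^-1 cm^-1. All values are configurable.
#'
#' @param wavelengths_nm Two wavelengths in nm.
#' @param extinction 2 x 2 matrix; rows = wavelengths, columns =
#'   `c("hbo", "hhb")`, units mM^-1 cm^-1.
#' @param dpf Differential pathlength factor per wavelength.
#' @param separation_cm Source-detector separation in cm.
#' @return An object of class `mbll_config`.
#' @export
mbll_config <- function(wavelengths_nm = c(770, 840),
                        extinction = matrix(c(0.650, 1.058,
                                              1.311, 0.781),
                                            nrow = 2,
                                            dimnames = list(NULL,
                                                            c("hbo", "hhb"))),
                        dpf = c(6.0, 6.0),
                        separation_cm = 3.0) {
  stopifnot(length(wavelengths_nm) == 2, all(dim(extinction) == c(2, 2)),
            length(dpf) == 2, separation_cm > 0)
  if (abs(det(extinction)) < 1e-12) {
    stop("extinction coefficient matrix is singular", call. = FALSE)
  }
  structure(list(wavelengths_nm = wavelengths_nm, extinction = extinction,
                 dpf = dpf, separation_cm = separation_cm),
            class = "mbll_config")
}

# effective pathlength-scaled coefficient matrix A (2x2):
# dOD[wavelength] = A %*% c(dHbO2, dHHb)
mbll_coef_matrix <- function(cfg) {
  cfg$extinction * (cfg$separation_cm * cfg$dpf)
}

#' Haemoglobin concentration-change series
#'
#' Container for per-channel oxy- (HbO2) and deoxy-haemoglobin (HHb)
#' concentration-change time series sampled at a uniform interval.
#'
#' @param subject_id Subject identifier.
#' @param hbo,hhb Numeric matrices, time x 16 channels (`CH1`..`CH16`).
#' @param dt Sampling interval in seconds (default 0.65).
#' @return An object of class `hb_series`.
#' @export
hb_series <- function(subject_id, hbo, hhb = NULL, dt = 0.65) {
  hbo <- as.matrix(hbo)
  if (ncol(hbo) != 16) stop("expected 16 channels", call. = FALSE)
  if (is.null(hhb)) hhb <- matrix(0, nrow(hbo), 16)
  hhb <- as.matrix(hhb)
  stopifnot(all(dim(hbo) == dim(hhb)), dt > 0)
  if (!all(is.finite(hbo)) || !all(is.finite(hhb))) {
    stop("non-finite haemoglobin values", call. = FALSE)
  }
  colnames(hbo) <- colnames(hhb) <- CHANNELS
  structure(list(subject_id = subject_id, hbo = hbo, hhb = hhb, dt = dt),
            class = "hb_series")
}

#' @export
print.hb_series <- function(x, ...) {
  cat("<hb_series>", x$subject_id, "-", nrow(x$hbo), "samples x 16 channels,",
      "dt =", x$dt, "s\n")
  invisible(x)
}

#' Session layout of a block-design recording
#'
#' Half-open time intervals `[start, end)` in seconds from recording start:
#' a pre-stimulus baseline, the ordered CIT task blocks, inter-task rests
#' and a post-task interval. Defaults: 20 s baseline, three task blocks of
#' 18 items x 5.25 s = 94.5 s, 20 s rests and a 20 s post-task period.
#'
#' @param baseline_s Baseline duration in s.
#' @param n_blocks Number of task blocks.
#' @param block_s Task-block duration in s.
#' @param rest_s Inter-task rest duration in s.
#' @param post_s Post-task duration in s.
#' @return An object of class `session_layout` with elements `baseline`
#'   (length-2 vector), `blocks` (list of length-2 vectors), `rests`,
#'   `post`, `total_s`.
#' @export
session_layout <- function(baseline_s = 20, n_blocks = 3, block_s = 94.5,
                           rest_s = 20, post_s = 20) {
  stopifnot(baseline_s > 0, n_blocks >= 1, block_s > 0)
  t <- baseline_s
  blocks <- list()
  rests <- list()
  for (i in seq_len(n_blocks)) {
    blocks[[i]] <- c(t, t + block_s)
    t <- t + block_s
    if (i < n_blocks) {
      rests[[i]] <- c(t, t + rest_s)
      t <- t + rest_s
    }
  }
  post <- c(t, t + post_s)
  structure(list(baseline = c(0, baseline_s), blocks = blocks,
                 rests = rests, post = post, total_s = t + post_s),
            class = "session_layout")
}

# indices of samples with time in [a, b); times are (i-1)*dt
interval_idx <- function(a, b, dt, n) {
  t <- (seq_len(n) - 1) * dt
  which(t >= a & t < b)
}

#' Convert raw two-wavelength intensities to haemoglobin changes
#'
#' Applies the modified Beer-Lambert law: per channel and wavelength the
#' optical-density change relative to the mean baseline intensity,
#' `dOD = -log10(I / I0)`, is mapped through the inverse of the
#' pathlength-scaled extinction system to concentration changes of HbO2 and
#' HHb (units mM, given extinction coefficients in mM^-1 cm^-1).
#'
#' @param raw A `raw_intensity_series` (see [export_raw()]): list with
#'   `subject_id`, `intensity` (array time x 16 channels x 2 wavelengths),
#'   `dt`.
#' @param cfg An [mbll_config()].
#' @param baseline Length-2 vector, baseline interval `[t0, t1)` in s.
#' @return An [hb_series()].
#' @export
mbll_convert <- function(raw, cfg = mbll_config(), baseline = c(0, 20)) {
  arr <- raw$intensity
  stopifnot(length(dim(arr)) == 3, dim(arr)[2] == 16, dim(arr)[3] == 2)
  n <- dim(arr)[1]
  idx <- interval_idx(baseline[1], baseline[2], raw$dt, n)
  if (length(idx) < 1) stop("baseline interval outside recording",
                            call. = FALSE)
  if (any(arr <= 0)) {
    bad <- which(arr <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive intensity at channel %s, sample %d",
                 CHANNELS[bad[2]], bad[1]), call. = FALSE)
  }
  a_mat <- mbll_coef_matrix(cfg)
  a_inv <- solve(a_mat)
  hbo <- hhb <- matrix(0, n, 16)
  for (ch in 1:16) {
    i0 <- colMeans(arr[idx, ch, , drop = FALSE])  # per wavelength
    od <- cbind(-log10(arr[, ch, 1] / i0[1]),
                -log10(arr[, ch, 2] / i0[2]))
    conc <- od %*% t(a_inv)
    hbo[, ch] <- conc[, 1]
    hhb[, ch] <- conc[, 2]
  }
  hb_series(raw$subject_id, hbo, hhb, dt = raw$dt)
}

#' Zero-phase Butterworth band-pass filter
#'
#' A 3rd-order Butterworth band-pass (defaults 0.01-0.09 Hz) applied
#' forward and backward so the net phase shift is zero: slow drifts below
#' the low edge and pulsatile components above the high edge are removed
#' without displacing the haemodynamic response in time. Edges are handled
#' by reflection padding of roughly one impulse-response length
#' (one period of the low cut-off).
#'
#' @param series An [hb_series()].
#' @param f_lo,f_hi Band edges in Hz; must satisfy
#'   `0 < f_lo < f_hi < 1/(2 dt)`.
#' @param order Butterworth order per pass (default 3).
#' @return The filtered [hb_series()].
#' @export
bandpass_zero_phase <- function(series, f_lo = 0.01, f_hi = 0.09,
                                order = 3) {
  dt <- series$dt
  nyq <- 1 / (2 * dt)
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < nyq)) {
    stop("band edges must satisfy 0 < f_lo < f_hi < Nyquist = ",
         signif(nyq, 3), " Hz", call. = FALSE)
  }
  n <- nrow(series$hbo)
  npad <- ceiling(1 / (f_lo * dt))  # ~ one period of the low edge
  if (n < 3 * npad / 2) {
    stop("series too short for the requested band; need >= ",
         ceiling(3 * npad / 2), " samples (pad the recording or raise ",
         "`f_lo`)", call. = FALSE)
  }
  npad <- min(npad, n - 1)
  bf <- signal::butter(order, c(f_lo, f_hi) / nyq, type = "pass")
  filt_col <- function(xcol) {
    padded <- c(2 * xcol[1] - rev(xcol[2:(npad + 1)]), xcol,
                2 * xcol[n] - rev(xcol[(n - npad):(n - 1)]))
    out <- signal::filtfilt(bf, padded)
    out[(npad + 1):(npad + n)]
  }
  out <- series
  out$hbo <- apply(series$hbo, 2, filt_col)
  out$hhb <- apply(series$hhb, 2, filt_col)
  colnames(out$hbo) <- colnames(out$hhb) <- CHANNELS
  out
}

#' Standardise a series against its pre-stimulus baseline
#'
#' Default mode subtracts each channel's mean over the baseline interval
#' from the whole series, making values directly comparable across subjects
#' and channels; `mode = "z"` additionally divides by the baseline standard
#' deviation.
#'
#' @param series An [hb_series()].
#' @param layout A [session_layout()].
#' @param mode `"subtract"` (default) or `"z"`.
#' @return The standardised [hb_series()].
#' @export
baseline_standardize <- function(series, layout,
                                 mode = c("subtract", "z")) {
  mode <- match.arg(mode)
  n <- nrow(series$hbo)
  idx <- interval_idx(layout$baseline[1], layout$baseline[2], series$dt, n)
  if (length(idx) < 2) stop("baseline interval has fewer than 2 samples",
                            call. = FALSE)
  out <- series
  for (comp in c("hbo", "hhb")) {
    m <- colMeans(series[[comp]][idx, , drop = FALSE])
    x <- sweep(series[[comp]], 2, m)
    if (mode == "z") {
      s <- apply(series[[comp]][idx, , drop = FALSE], 2, sd)
      if (any(s == 0)) {
        stop("zero baseline standard deviation in z mode", call. = FALSE)
      }
      x <- sweep(x, 2, s, "/")
    }
    out[[comp]] <- x
  }
  out
}

#' Reduce a session to per-block channel-mean HbO2 features
#'
#' For each task block, the HbO2 series is averaged per channel over
#' `[block_start + onset_exclusion_s, block_end)`; the excluded onset
#' window accounts for the delayed rise of the haemodynamic response.
#' One 16-channel feature vector is produced per subject x CIT.
#'
#' @param series A preprocessed [hb_series()].
#' @param layout A [session_layout()].
#' @param onset_exclusion_s Seconds excluded from each block onset
#'   (default 10; must be in `[0, block length)`).
#' @param group Group label attached to the rows (e.g. `"CL"`, `"HC"`).
#' @param cits CIT identifiers, one per block.
#' @return A tibble with columns `subject_id`, `group`, `cit`,
#'   `ch1`..`ch16`.
#' @export
block_features <- function(series, layout, onset_exclusion_s = 10,
                           group = NA_character_,
                           cits = paste0("CIT", seq_along(layout$blocks))) {
  stopifnot(length(cits) == length(layout$blocks))
  n <- nrow(series$hbo)
  rows <- purrr::map2_dfr(layout$blocks, cits, function(blk, cit) {
    if (onset_exclusion_s < 0 || onset_exclusion_s >= blk[2] - blk[1]) {
      stop("onset exclusion window (", onset_exclusion_s,
           " s) must be shorter than the block (", blk[2] - blk[1], " s)",
           call. = FALSE)
    }
    idx <- interval_idx(blk[1] + onset_exclusion_s, blk[2], series$dt, n)
    if (length(idx) == 0) stop("block has no retained samples", call. = FALSE)
    feat <- colMeans(series$hbo[idx, , drop = FALSE])
    tibble::tibble(subject_id = series$subject_id, group = group,
                   cit = cit, !!!setNames(as.list(feat), FEATURE_COLS))
  })
  rows
}

#' Assemble the classification feature table
#'
#' Binds per-subject feature vectors into one row-ordered table and
#' restricts it to the requested CIT set. The default keeps CIT1 and CIT2
#' only: the third task is behaviourally saturated for the patient group,
#' so its haemodynamics do not index a comparable cognitive load. Class
#' encoding downstream is CL = +1, HC = -1.
#'
#' @param vectors A data frame (or list of data frames) of feature rows as
#'   produced by [block_features()].
#' @param include_cits CITs to retain (default `c("CIT1", "CIT2")`).
#' @return A tibble with header `subject_id, group, cit, ch1..ch16`.
#' @export
build_dataset <- function(vectors, include_cits = c("CIT1", "CIT2")) {
  if (length(include_cits) == 0) {
    stop("`include_cits` must be non-empty", call. = FALSE)
  }
  tab <- if (is.data.frame(vectors)) tibble::as_tibble(vectors) else
    dplyr::bind_rows(vectors)
  if (anyDuplicated(tab[c("subject_id", "cit")])) {
    stop("duplicate (subject, cit) rows", call. = FALSE)
  }
  out <- dplyr::filter(tab, .data$cit %in% include_cits)
  dplyr::select(out, "subject_id", "group", "cit",
                dplyr::all_of(FEATURE_COLS))
}

# +1 for the patient (CL) class, -1 for controls
label_to_y <- function(group) {
  y <- ifelse(group == "CL", 1, ifelse(group == "HC", -1, NA_real_))
  if (anyNA(y)) stop("group labels must be 'CL' or 'HC'", call. = FALSE)
  y
}

#' Preprocess a whole synthetic cohort into a feature table
#'
#' Runs band-pass filtering, baseline standardisation and block-feature
#' extraction on every session of a cohort (see [generate_cohort()]) and
#' assembles the classification table.
#'
#' @param cohort A `synthetic_cohort`.
#' @param include_cits CITs to retain (default `c("CIT1", "CIT2")`).
#' @param f_lo,f_hi Band edges in Hz.
#' @param onset_exclusion_s Seconds excluded from each block onset.
#' @return Feature tibble as from [build_dataset()].
#' @export
cohort_features <- function(cohort, include_cits = c("CIT1", "CIT2"),
                            f_lo = 0.01, f_hi = 0.09,
                            onset_exclusion_s = 10) {
  layout <- cohort$layout
  rows <- purrr::map2_dfr(cohort$sessions, cohort$labels$group,
                          function(ses, grp) {
    ses |>
      bandpass_zero_phase(f_lo = f_lo, f_hi = f_hi) |>
      baseline_standardize(layout) |>
      block_features(layout, onset_exclusion_s = onset_exclusion_s,
                     group = grp)
  })
  build_dataset(rows, include_cits = include_cits)
}
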