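#' Zero-phase low-pass filter
#'
#' Butterworth design applied forward and backward (`signal::filtfilt`),
#' giving unit DC gain and no phase distortion. The default 1.7 Hz cutoff
#' removes cardiac pulsation (infant heart rates sit above 2 Hz) and
#' instrumentation noise while leaving the slow hemodynamic response
#' untouched; the default 4th-order design attenuates a 2.4 Hz component
#' by more than 20 dB after the two passes.
#'
#' @param x numeric signal (a single channel's time series).
#' @param cutoff_hz low-pass cutoff in Hz (must be below Nyquist).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param order Butterworth order of the one-way design.
#' @return filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, cutoff_hz = 1.7, sampling_rate_hz = 10,
                           order = 4) {
  nyq <- sampling_rate_hz / 2
  if (cutoff_hz >= nyq)
    stop_field("cutoff_hz", sprintf("must be below Nyquist (%.1f Hz)", nyq))
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  # odd-reflection padding suppresses the start-up transients of the
  # zero-initial-state forward/backward passes
  n <- length(x)
  p <- min(n - 1L, 100L)
  padded <- c(2 * x[1] - x[(p + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- as.numeric(signal::filtfilt(bf, padded))
  y[(p + 1L):(p + n)]
}

#' Convert optical intensity to attenuation change
#'
#' Natural-log attenuation relative to the channel's session mean:
#' `A(t) = -log(I(t) / mean(I))`, computed per channel and wavelength.
#'
#' @param intensity channel x wavelength x time array of positive intensity.
#' @return array of the same shape, attenuation change.
#' @export
intensity_to_attenuation <- function(intensity) {
  out <- intensity
  for (ch in seq_len(dim(intensity)[1]))
    for (w in seq_len(dim(intensity)[2])) {
      x <- intensity[ch, w, ]
      out[ch, w, ] <- -log(x / mean(x))
    }
  out
}

epoch_time_axis <- function(fs = 10, pre_s = 4, post_s = 20) {
  seq(-pre_s, post_s - 1 / fs, by = 1 / fs)
}

#' Segment a session into 24-s stimulus-locked blocks
#'
#' Cuts one block per experimental event spanning 4 s before stimulus
#' onset to 20 s after it (the nominal 10-s stimulus plus the following
#' 10-s baseline): 240 samples at 10 Hz on the half-open axis `[-4, 20)`.
#' Events too close to a recording edge are dropped with a warning.
#'
#' @param atten channel x wavelength x time attenuation array.
#' @param events data.frame with `onset` (s) and `condition`.
#' @param looking_proportion one value per event.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param pre_s,post_s window extent around onset, seconds.
#' @return list of epochs; each has `data` (channel x wavelength x 240),
#'   `time`, `condition`, `onset`, `looking_proportion`.
#' @export
segment_epochs <- function(atten, events, looking_proportion,
                           sampling_rate_hz = 10, pre_s = 4, post_s = 20) {
  fs <- sampling_rate_hz
  n_t <- dim(atten)[3]
  taxis <- epoch_time_axis(fs, pre_s, post_s)
  out <- list()
  for (k in seq_len(nrow(events))) {
    i_on <- round(events$onset[k] * fs) + 1L
    i0 <- i_on - round(pre_s * fs)
    i1 <- i_on + round(post_s * fs) - 1L
    if (i0 < 1L || i1 > n_t) {
      warning(sprintf("event %d at %.1f s too close to recording edge; dropped",
                      k, events$onset[k]))
      next
    }
    out[[length(out) + 1L]] <- structure(
      list(data = atten[, , i0:i1, drop = FALSE], time = taxis,
           condition = as.character(events$condition[k]),
           onset = events$onset[k],
           looking_proportion = looking_proportion[k]),
      class = "nirs_epoch")
  }
  out
}

#' Detrend a block with an anchored linear fit
#'
#' Removes, per channel and wavelength, the straight line through the
#' means of the first 4 s and the last 4 s of the block (each mean anchored
#' at its window's temporal center). Both end-window means of the output
#' are exactly zero, absorbing slow drifts and trial-to-trial activation
#' build-up without touching the response shape in between.
#'
#' @param epoch a `nirs_epoch` (attenuation block).
#' @param anchor_s anchor window length in seconds (default 4).
#' @return the detrended epoch.
#' @export
detrend_epoch <- function(epoch, anchor_s = 4) {
  taxis <- epoch$time
  fs <- 1 / (taxis[2] - taxis[1])
  n <- length(taxis)
  k <- round(anchor_s * fs)
  i_first <- seq_len(k)
  i_last <- (n - k + 1L):n
  c1 <- mean(taxis[i_first]); c2 <- mean(taxis[i_last])
  for (ch in seq_len(dim(epoch$data)[1]))
    for (w in seq_len(dim(epoch$data)[2])) {
      x <- epoch$data[ch, w, ]
      m1 <- mean(x[i_first]); m2 <- mean(x[i_last])
      slope <- (m2 - m1) / (c2 - c1)
      epoch$data[ch, w, ] <- x - (m1 + slope * (taxis - c1))
    }
  epoch
}

#' Invert the modified Beer-Lambert law for one block
#'
#' Solves, at every time point and channel, the 2x2 linear system mapping
#' HbO2/HHb concentration changes to attenuation changes at 770/850 nm
#' (extinction x separation x DPF), yielding chromophore concentration
#' changes in umol. Exact inverse of [forward_beer_lambert()].
#'
#' @param epoch a `nirs_epoch` (attenuation).
#' @param extinction 2x2 extinction table.
#' @param dpf differential pathlength factor (default 5.13).
#' @param separation_cm source-detector separation in cm.
#' @return a `nirs_conc_epoch`: `data` is channel x chromophore
#'   (hbo2, hhb) x time in umol; `valid` is a per-channel logical mask.
#' @export
mbll_inverse <- function(epoch, extinction = default_extinction(), dpf = 5.13,
                         separation_cm = 2) {
  m_inv <- solve(mbll_matrix(extinction, dpf, separation_cm))
  n_ch <- dim(epoch$data)[1]
  n_t <- dim(epoch$data)[3]
  conc <- array(NA_real_, c(n_ch, 2, n_t),
                dimnames = list(NULL, c("hbo2", "hhb"), NULL))
  for (ch in seq_len(n_ch))
    conc[ch, , ] <- m_inv %*% epoch$data[ch, , ]
  structure(list(data = conc, time = epoch$time, condition = epoch$condition,
                 onset = epoch$onset,
                 looking_proportion = epoch$looking_proportion,
                 valid = rep(TRUE, n_ch)),
            class = "nirs_conc_epoch")
}

# reference concentrations to the 4-s pre-stimulus mean so "change from
# baseline" is well defined for rejection and peak extraction
rereference_epoch <- function(epoch, pre_s = 4) {
  i_base <- which(epoch$time < 0 & epoch$time >= -pre_s)
  base <- apply(epoch$data[, , i_base, drop = FALSE], c(1, 2), mean)
  epoch$data <- epoch$data - as.vector(base)  # recycles over time
  epoch
}

#' Trial-level artifact rejection on concentration blocks
#'
#' Marks, per channel, a trial invalid if either chromophore's
#' baseline-referenced concentration change exceeds +/-3 umol anywhere in
#' the 4-s pre-stimulus baseline or +/-5 umol anywhere during the nominal
#' 10-s stimulus. Both bounds are strict (an excursion of exactly the
#' threshold is kept); the looser stimulus bound leaves room for genuine
#' evoked changes while still catching abrupt motion artifacts.
#'
#' @param epochs list of `nirs_conc_epoch` (baseline-referenced).
#' @param baseline_limit_umol baseline-window bound (default 3).
#' @param stimulus_limit_umol stimulus-window bound (default 5).
#' @param stimulus_s nominal stimulus duration used for the window (10 s).
#' @return the epochs with updated per-channel `valid` masks.
#' @export
reject_trials <- function(epochs, baseline_limit_umol = 3,
                          stimulus_limit_umol = 5, stimulus_s = 10) {
  lapply(epochs, function(ep) {
    i_base <- which(ep$time >= -4 & ep$time < 0)
    i_stim <- which(ep$time >= 0 & ep$time < stimulus_s)
    for (ch in seq_len(dim(ep$data)[1])) {
      if (!ep$valid[ch]) next
      x <- ep$data[ch, , , drop = FALSE]
      bad <- any(abs(x[1, , i_base]) > baseline_limit_umol) ||
        any(abs(x[1, , i_stim]) > stimulus_limit_umol)
      if (bad) ep$valid[ch] <- FALSE
    }
    ep
  })
}

#' Looking-time inclusion criterion
#'
#' Drops trials in which the infant watched the screen for less than 60%
#' of the trial duration (strictly below threshold is dropped; exactly the
#' threshold is kept). Trials with a missing proportion are dropped with a
#' warning.
#'
#' @param epochs list of epochs carrying `looking_proportion`.
#' @param threshold minimum proportion (default 0.6).
#' @return the surviving epochs.
#' @export
apply_looking_criterion <- function(epochs, threshold = 0.6) {
  keep <- vapply(epochs, function(ep) {
    lp <- ep$looking_proportion
    if (is.na(lp)) {
      warning("trial with missing looking proportion dropped")
      return(FALSE)
    }
    lp >= threshold
  }, logical(1))
  epochs[keep]
}

#' Per-participant condition and modality averages
#'
#' Averages valid trials within each condition (and each modality:
#' spoken = English + French, signed = BSL + LSFB) per channel, using only
#' channels that survived QC and only trials valid in that channel.
#' Inclusion bookkeeping follows the study rules: a condition needs at
#' least `min_valid` (3) valid trials; excluding one condition excludes the
#' other condition of the same modality; modality averages need at least 3
#' valid trials in that modality. A trial counts as valid for these rules
#' when it is valid in at least `trial_validity_rule` (50%) of the
#' non-rejected channels.
#'
#' @param epochs list of `nirs_conc_epoch` that already passed the looking
#'   criterion and carry rejection masks.
#' @param participant a `nirs_participant`.
#' @param design a `nirs_design`.
#' @param qc_report optional `nirs_qc_report`; its rejected channels are
#'   masked throughout.
#' @param min_valid minimum valid trials for inclusion (default 3).
#' @param trial_validity_rule fraction of non-rejected channels in which a
#'   trial must be valid to count toward inclusion (default 0.5).
#' @return list of class `nirs_condition_averages`: per condition and per
#'   modality an element with `data` (channel x chromophore x time mean),
#'   `n_valid_trials` per channel, `n_trials` (trial-level count),
#'   `included` flag, `level` ("condition"/"modality").
#' @export
average_conditions <- function(epochs, participant, design, qc_report = NULL,
                               min_valid = 3, trial_validity_rule = 0.5) {
  if (!length(epochs))
    stop_field("epochs", "no epochs to average")
  n_ch <- dim(epochs[[1]]$data)[1]
  ch_ok <- rep(TRUE, n_ch)
  if (!is.null(qc_report)) ch_ok <- !qc_report$channels$rejected
  # trial-level validity for inclusion counting
  trial_ok <- vapply(epochs, function(ep) {
    if (!any(ch_ok)) return(FALSE)
    mean(ep$valid[ch_ok]) >= trial_validity_rule
  }, logical(1))
  conds <- vapply(epochs, `[[`, "", "condition")

  n_valid_cond <- vapply(design$conditions, function(cc)
    sum(trial_ok & conds == cc), integer(1))
  included <- n_valid_cond >= min_valid
  # paired-condition rule: excluding one condition excludes its modality partner
  for (m in unique(design$modality_map)) {
    mc <- names(design$modality_map)[design$modality_map == m]
    if (any(!included[mc])) included[mc] <- FALSE
  }

  avg_over <- function(sel) {
    dat <- array(NA_real_, dim(epochs[[1]]$data),
                 dimnames = dimnames(epochs[[1]]$data))
    n_valid <- integer(n_ch)
    for (ch in seq_len(n_ch)) {
      if (!ch_ok[ch]) next
      use <- which(sel & trial_ok &
                     vapply(epochs, function(ep) ep$valid[ch], logical(1)))
      n_valid[ch] <- length(use)
      if (length(use))
        dat[ch, , ] <- Reduce(`+`, lapply(epochs[use], function(ep)
          ep$data[ch, , ])) / length(use)
    }
    list(data = dat, n_valid_trials = n_valid)
  }

  out <- list()
  for (cc in design$conditions) {
    a <- avg_over(conds == cc)
    out[[cc]] <- list(participant = participant$id, group = participant$group,
                      label = cc, level = "condition",
                      data = a$data, n_valid_trials = a$n_valid_trials,
                      n_trials = n_valid_cond[[cc]],
                      included = unname(included[cc]),
                      time = epochs[[1]]$time)
  }
  for (m in unique(design$modality_map)) {
    mc <- names(design$modality_map)[design$modality_map == m]
    n_mod <- sum(trial_ok & conds %in% mc)
    a <- avg_over(conds %in% mc)
    out[[m]] <- list(participant = participant$id, group = participant$group,
                     label = m, level = "modality",
                     data = a$data, n_valid_trials = a$n_valid_trials,
                     n_trials = n_mod, included = n_mod >= min_valid,
                     time = epochs[[1]]$time)
  }
  structure(out, class = "nirs_condition_averages")
}

#' Full preprocessing of one recording
#'
#' Runs the canonical stage order on a raw recording: low-pass filter the
#' intensity, convert to attenuation, segment into 24-s blocks, detrend
#' each block with the anchored linear fit, invert the modified
#' Beer-Lambert law, reference to the pre-stimulus baseline, apply the
#' looking-time criterion, reject artifacted trials per channel, and build
#' condition and modality averages.
#'
#' @param rec a `nirs_recording`.
#' @param config a `nirs_config`.
#' @param qc_report optional `nirs_qc_report` for the same recording.
#' @return list with `epochs` (post-rejection `nirs_conc_epoch` list) and
#'   `averages` (a `nirs_condition_averages`).
#' @export
preprocess_recording <- function(rec, config, qc_report = NULL) {
  pp <- config$preprocess
  fs <- rec$sampling_rate_hz
  filt <- rec$intensity
  for (ch in seq_len(dim(filt)[1]))
    for (w in 1:2)
      filt[ch, w, ] <- lowpass_filter(filt[ch, w, ],
                                      cutoff_hz = pp$lowpass_cutoff_hz %||% 1.7,
                                      sampling_rate_hz = fs,
                                      order = pp$filter_order %||% 4)
  atten <- intensity_to_attenuation(filt)
  eps <- segment_epochs(atten, rec$events, rec$looking_proportion, fs)
  ext <- extinction_from_config(pp)
  eps <- lapply(eps, function(ep) {
    ep <- detrend_epoch(ep)
    ep <- mbll_inverse(ep, extinction = ext, dpf = pp$dpf %||% 5.13,
                       separation_cm = config$montage$separation_cm)
    rereference_epoch(ep)
  })
  eps <- apply_looking_criterion(eps, threshold = pp$looking_threshold %||% 0.6)
  eps <- reject_trials(eps,
                       baseline_limit_umol = pp$baseline_limit_umol %||% 3,
                       stimulus_limit_umol = pp$stimulus_limit_umol %||% 5)
  avgs <- average_conditions(eps, rec$participant, config$design, qc_report,
                             min_valid = pp$min_valid_trials %||% 3,
                             trial_validity_rule = pp$trial_validity_rule %||% 0.5)
  list(epochs = eps, averages = avgs)
}
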