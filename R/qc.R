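#' Coefficient of variation of a signal, in percent
#'
#' `100 * sd(x) / mean(x)`. Used to screen channels for excess variability
#' in the raw optical intensity: a channel with too little light reaching
#' the detector is dominated by measurement noise and shows a large CoV.
#'
#' @param signal numeric intensity time series (nonempty, nonzero mean).
#' @return CoV in percent.
#' @export
coefficient_of_variation <- function(signal) {
  if (!length(signal)) stop_field("signal", "must be nonempty")
  m <- mean(signal)
  if (abs(m) < .Machine$double.eps * 100)
    stop_field("signal", "mean is zero; coefficient of variation undefined")
  100 * stats::sd(signal) / m
}

#' Normalized peak spectral power of a signal
#'
#' Fraction of periodogram power concentrated in the single largest bin,
#' searched over frequencies above `min_freq_hz`. A value near 1 indicates
#' one dominant frequency component unrelated to the experiment (e.g. an
#' unclipped optode oscillating); broadband signals score far below 0.5.
#' The frequency floor (default 0.5 Hz) keeps the slow stimulus-locked
#' hemodynamic response — which on clean recordings can legitimately
#' dominate the low-frequency spectrum — out of the artifact search, while
#' cardiac and instrumentation components (> 1 Hz) remain fully visible
#' to it.
#'
#' @param signal numeric time series, length at least twice the sampling
#'   rate.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param min_freq_hz lower edge of the artifact search band.
#' @return fraction in \[0, 1\].
#' @export
normalized_peak_power <- function(signal, sampling_rate_hz = 10,
                                  min_freq_hz = 0.5) {
  n <- length(signal)
  if (n < 2 * sampling_rate_hz)
    stop_field("signal", "too short: need at least 2 s of samples")
  x <- signal - mean(signal)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * sampling_rate_hz / n
  keep <- freq >= min_freq_hz & seq_len(n) <= floor(n / 2) + 1L & freq > 0
  p <- p[keep]
  tot <- sum(p)
  if (tot == 0) return(0)
  max(p) / tot
}

#' Channel rejection and participant-level exclusion
#'
#' Screens every montage channel on the full-session intensity of each
#' wavelength: a channel is rejected if, at either wavelength, the
#' coefficient of variation exceeds the CoV threshold (default 15%) or the
#' normalized peak power exceeds the power threshold (default 0.5). A
#' participant with more than `max_rejected` rejected channels (default 15)
#' is excluded from all analyses.
#'
#' @param rec a `nirs_recording`.
#' @param cov_threshold_percent CoV rejection threshold, percent.
#' @param power_threshold normalized-peak-power rejection threshold.
#' @param max_rejected participant excluded when `n_rejected > max_rejected`.
#' @return a list of class `nirs_qc_report`: `channels` (data.frame with
#'   per-wavelength metrics, `rejected` flag and `reasons`), `n_rejected`,
#'   `participant_excluded`, `participant`.
#' @export
apply_channel_rejection <- function(rec, cov_threshold_percent = 15,
                                    power_threshold = 0.5, max_rejected = 15) {
  n_ch <- dim(rec$intensity)[1]
  fs <- rec$sampling_rate_hz
  cov770 <- cov850 <- npp770 <- npp850 <- numeric(n_ch)
  rejected <- logical(n_ch)
  reasons <- character(n_ch)
  for (ch in seq_len(n_ch)) {
    metrics <- lapply(1:2, function(w) {
      x <- rec$intensity[ch, w, ]
      list(cov = coefficient_of_variation(x),
           npp = normalized_peak_power(x, fs))
    })
    cov770[ch] <- metrics[[1]]$cov; cov850[ch] <- metrics[[2]]$cov
    npp770[ch] <- metrics[[1]]$npp; npp850[ch] <- metrics[[2]]$npp
    why <- character()
    if (cov770[ch] > cov_threshold_percent || cov850[ch] > cov_threshold_percent)
      why <- c(why, "coefficient_of_variation")
    if (npp770[ch] > power_threshold || npp850[ch] > power_threshold)
      why <- c(why, "normalized_peak_power")
    rejected[ch] <- length(why) > 0
    reasons[ch] <- paste(why, collapse = ";")
  }
  n_rejected <- sum(rejected)
  structure(list(
    channels = data.frame(channel = seq_len(n_ch),
                          cov_percent_wl770 = cov770,
                          cov_percent_wl850 = cov850,
                          peak_power_wl770 = npp770,
                          peak_power_wl850 = npp850,
                          rejected = rejected, reasons = reasons),
    n_rejected = n_rejected,
    participant_excluded = n_rejected > max_rejected,
    participant = rec$participant$id),
    class = "nirs_qc_report")
}

#' Write a QC report as TSV plus a JSON summary
#'
#' @param report a `nirs_qc_report`.
#' @param dir output directory.
#' @return invisibly, the TSV path.
#' @export
write_qc_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, sprintf("%s_qc.tsv", report$participant))
  utils::write.table(report$channels, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(participant = report$participant, n_rejected = report$n_rejected,
         participant_excluded = report$participant_excluded),
    file.path(dir, sprintf("%s_qc.json", report$participant)),
    auto_unbox = TRUE)
  invisible(tsv)
}
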