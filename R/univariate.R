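#' Extract peak amplitudes in the analysis window
#'
#' Peak amplitude variation from baseline within the 8-16 s post-onset
#' window (where the infant hemodynamic maximum, around 12 s, falls) for
#' every included condition/modality average, channel and chromophore.
#' Peaks are signed: the maximum for HbO2 and the minimum for HHb, so a
#' negative HbO2 peak mean (deactivation) is representable. Channels with
#' no valid trials are omitted.
#'
#' @param averages a `nirs_condition_averages` (or a list of them, one per
#'   participant).
#' @param window_s numeric pair, window in seconds post-onset (closed;
#'   default `c(8, 16)`).
#' @return a `PeakTable` data.frame: participant, group, label, level,
#'   channel, chromophore, peak (umol), n_valid_trials.
#' @export
extract_peaks <- function(averages, window_s = c(8, 16)) {
  if (inherits(averages, "nirs_condition_averages")) averages <- list(averages)
  rows <- list()
  for (av_set in averages) {
    for (av in av_set) {
      if (!isTRUE(av$included)) next
      i_win <- which(av$time >= window_s[1] & av$time <= window_s[2])
      if (!length(i_win))
        stop_field("window_s", "averages do not cover the peak window")
      for (ch in seq_len(dim(av$data)[1])) {
        if (av$n_valid_trials[ch] == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          participant = av$participant, group = av$group,
          label = av$label, level = av$level, channel = ch,
          chromophore = c("hbo2", "hhb"),
          peak = c(max(av$data[ch, "hbo2", i_win]),
                   min(av$data[ch, "hhb", i_win])),
          n_valid_trials = av$n_valid_trials[ch])
      }
    }
  }
  if (!length(rows))
    return(data.frame(participant = character(), group = character(),
                      label = character(), level = character(),
                      channel = integer(), chromophore = character(),
                      peak = numeric(), n_valid_trials = integer()))
  do.call(rbind, rows)
}

#' One-sample t test of channel peaks against zero
#'
#' Classical two-tailed one-sample t test of per-participant peak
#' amplitudes against a zero baseline change. A zero-variance sample is
#' flagged degenerate rather than producing an undefined statistic.
#'
#' @param x numeric vector of per-participant peaks (length >= 2).
#' @return list: `t`, `p`, `df`, `mean`, `degenerate`.
#' @export
one_sample_channel_test <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop_field("x", "need at least 2 participants")
  if (stats::sd(x) == 0)
    return(list(t = NA_real_, p = NA_real_, df = length(x) - 1L,
                mean = mean(x), degenerate = TRUE))
  tt <- stats::t.test(x, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean = mean(x), degenerate = FALSE)
}

#' Paired t test of familiar vs unfamiliar peaks
#'
#' Two-tailed paired t test on participant-matched peak amplitudes
#' (familiar minus unfamiliar). Pairs with either member missing are
#' dropped. Identical vectors give t = 0, p = 1; a constant nonzero
#' difference is flagged degenerate.
#'
#' @param familiar,unfamiliar numeric vectors aligned by participant.
#' @return list: `t`, `p`, `df`, `mean_diff`, `n_pairs`, `degenerate`.
#' @export
paired_familiarity_test <- function(familiar, unfamiliar) {
  if (length(familiar) != length(unfamiliar))
    stop_field("familiar/unfamiliar", "must be participant-aligned vectors")
  ok <- !is.na(familiar) & !is.na(unfamiliar)
  d <- familiar[ok] - unfamiliar[ok]
  if (length(d) < 2) stop_field("pairs", "need at least 2 complete pairs")
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0,
                  n_pairs = length(d), degenerate = FALSE))
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), n_pairs = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = mean(d), n_pairs = length(d), degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values over a fixed family size: channel-wise maps
#' are corrected over the full 46-channel montage regardless of how many
#' channels produced a testable statistic.
#'
#' @param pvalues numeric p values in \[0, 1\] (NA allowed, passed through).
#' @param m family size (defaults to `length(pvalues)`; 46 for channel maps).
#' @return adjusted p values, same length and order as the input.
#' @export
fdr_adjust <- function(pvalues, m = length(pvalues)) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop_field("pvalues", "must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH", n = max(m, sum(ok)))
}

#' Channel-wise statistics for one contrast
#'
#' Runs the one-sample test per channel on a peak table (one chromophore,
#' one condition/modality label), applies the FDR correction over the
#' montage's 46 channels, and reports direction and significance before
#' and after correction.
#'
#' @param peaks a PeakTable subset (single `label` and `chromophore`).
#' @param alpha significance level (default 0.05).
#' @param m_channels FDR family size (default 46).
#' @return data.frame per channel: `channel`, `mean_peak`, `t`, `p`,
#'   `p_fdr`, `direction`, `significant_uncorrected`, `significant_fdr`,
#'   `degenerate`.
#' @export
channel_stats <- function(peaks, alpha = 0.05, m_channels = 46) {
  stopifnot(length(unique(peaks$label)) <= 1,
            length(unique(peaks$chromophore)) <= 1)
  chans <- sort(unique(peaks$channel))
  res <- lapply(chans, function(ch) {
    x <- peaks$peak[peaks$channel == ch]
    if (length(x) < 2)
      return(data.frame(channel = ch, mean_peak = mean(x), t = NA, p = NA,
                        degenerate = TRUE))
    r <- one_sample_channel_test(x)
    data.frame(channel = ch, mean_peak = r$mean, t = r$t, p = r$p,
               degenerate = r$degenerate)
  })
  res <- do.call(rbind, res)
  res$p_fdr <- fdr_adjust(res$p, m = m_channels)
  res$direction <- ifelse(res$mean_peak > 0, "increase", "decrease")
  res$significant_uncorrected <- !is.na(res$p) & res$p < alpha
  res$significant_fdr <- !is.na(res$p_fdr) & res$p_fdr < alpha
  res
}

#' Hemodynamic-consistency activation labels
#'
#' Combines the HbO2 and HHb channel maps for one contrast into activation
#' calls. A significant HbO2 increase or HHb decrease marks activation,
#' but when both chromophores change significantly in the same direction
#' the signal is inconsistent with a hemodynamic response and is never
#' reported active.
#'
#' @param hbo2_result,hhb_result outputs of [channel_stats()] for the two
#'   chromophores of the same contrast.
#' @param use_fdr label from FDR-corrected significance (default) or
#'   uncorrected.
#' @return data.frame: `channel`, `label` in
#'   `{active_hbo2, active_hhb, inconsistent, null}`.
#' @export
classify_activation <- function(hbo2_result, hhb_result, use_fdr = TRUE) {
  stopifnot(identical(hbo2_result$channel, hhb_result$channel))
  sig <- function(r) if (use_fdr) r$significant_fdr else r$significant_uncorrected
  s_o <- sig(hbo2_result); s_h <- sig(hhb_result)
  dir_o <- hbo2_result$direction; dir_h <- hhb_result$direction
  label <- rep("null", nrow(hbo2_result))
  label[s_o & s_h & dir_o == dir_h] <- "inconsistent"
  ok <- label != "inconsistent"
  label[ok & s_o] <- "active_hbo2"
  label[ok & !s_o & s_h] <- "active_hhb"
  data.frame(channel = hbo2_result$channel, label = label)
}
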