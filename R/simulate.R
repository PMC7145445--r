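#' Canonical hemodynamic response curve
#'
#' Ground-truth evoked response: a gamma-family rise
#' `(t / tp)^k * exp(k * (1 - t / tp))` up to the peak, then a Gaussian
#' decay `exp(-(t - tp)^2 / (2 * decay_sd^2))`. The curve starts at zero,
#' attains its unique extremum `amplitude` exactly at `peak_time`, and is
#' smooth at the junction (both branches have zero slope there). The
#' default peak latency of 12 s matches the maximal concentration change
#' typically seen in infants for stimuli of this length. The decay rate is
#' chosen so the response has resolved (< 5% of peak) by 16 s post-onset:
#' the block arithmetic of the preprocessing (anchored detrending on the
#' first and last 4 s of a 24-s block) presupposes a quiescent final
#' baseline, and a ground-truth curve violating that assumption would make
#' every downstream amplitude systematically unrecoverable.
#'
#' @param duration curve duration in seconds (must exceed `peak_time`).
#' @param sampling_rate_hz grid rate in Hz.
#' @param amplitude peak amplitude in umol (may be negative, e.g. for HHb).
#' @param peak_time peak latency in seconds post-onset.
#' @param dispersion unitless rise-shape parameter (larger = steeper rise).
#' @param decay_sd Gaussian decay scale in seconds.
#' @return numeric vector on the half-open grid `[0, duration)`.
#' @export
simulate_hrf <- function(duration, sampling_rate_hz = 10, amplitude = 1,
                         peak_time = 12, dispersion = 8, decay_sd = 1.6) {
  assert_scalar_number(duration, "duration", positive = TRUE)
  assert_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  assert_scalar_number(peak_time, "peak_time", positive = TRUE)
  if (duration <= peak_time)
    stop_field("duration", "must exceed peak_time")
  t <- seq(0, duration - 1 / sampling_rate_hz, by = 1 / sampling_rate_hz)
  shape <- ifelse(
    t <= peak_time,
    (t / peak_time)^dispersion * exp(dispersion * (1 - t / peak_time)),
    exp(-(t - peak_time)^2 / (2 * decay_sd^2)))
  amplitude * shape
}

#' Default hemoglobin extinction coefficient table
#'
#' Specific extinction coefficients of oxy- and deoxyhemoglobin at 770 and
#' 850 nm from compiled hemoglobin spectra, expressed in mM^-1 cm^-1 on the
#' natural-log attenuation scale used throughout the package. The table is
#' configuration data, not code: any 2x2 nonsingular table in the same
#' units can be substituted.
#'
#' @return 2x2 numeric matrix, rows `wl770`/`wl850`, columns `hbo2`/`hhb`.
#' @export
default_extinction <- function() {
  matrix(c(0.650, 1.3674,
           1.058, 0.691),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("wl770", "wl850"), c("hbo2", "hhb")))
}

# accept either a 2x2 matrix or the nested-list form a YAML config carries
extinction_from_config <- function(pp) {
  e <- pp$extinction
  if (is.null(e)) return(default_extinction())
  if (is.matrix(e)) return(e)
  matrix(c(e$wl770$hbo2, e$wl770$hhb, e$wl850$hbo2, e$wl850$hhb),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("wl770", "wl850"), c("hbo2", "hhb")))
}

check_extinction <- function(extinction) {
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2L, 2L)))
    stop_field("extinction", "must be a 2x2 matrix (wavelength x chromophore)")
  if (abs(det(extinction)) < 1e-12)
    stop_field("extinction", "matrix is singular; chromophores not separable")
  extinction
}

# attenuation change per umol of concentration: eps [mM^-1 cm^-1] * C [mM]
# * separation [cm] * DPF, with C converted from umol/L to mmol/L
mbll_matrix <- function(extinction, dpf, separation_cm) {
  check_extinction(extinction) * separation_cm * dpf / 1000
}

#' Forward modified Beer-Lambert model
#'
#' Maps chromophore concentration changes to attenuation changes at the two
#' wavelengths: `dA(lambda) = eps(lambda, .) %*% dC * d * DPF`, the exact
#' inverse of [mbll_inverse()]. Attenuation is on the natural-log scale
#' (`intensity = I0 * exp(-dA)`).
#'
#' @param hbo2,hhb concentration change time courses in umol.
#' @param extinction 2x2 extinction table (see [default_extinction()]).
#' @param dpf differential pathlength factor (default 5.13, age-appropriate
#'   for young infants).
#' @param separation_cm source-detector separation in cm.
#' @return time x 2 matrix of attenuation changes (columns `wl770`, `wl850`).
#' @export
forward_beer_lambert <- function(hbo2, hhb, extinction = default_extinction(),
                                 dpf = 5.13, separation_cm = 2) {
  if (length(hbo2) != length(hhb))
    stop_field("hbo2/hhb", "concentration courses must have equal length")
  m <- mbll_matrix(extinction, dpf, separation_cm)
  out <- cbind(hbo2, hhb) %*% t(m)
  colnames(out) <- rownames(m) %||% c("wl770", "wl850")
  out
}

#' Construct a recording noise model
#'
#' All stochastic nuisance components injected by [simulate_cohort()],
#' expressed in natural-log attenuation units (the scale on which
#' `intensity = baseline * exp(-attenuation)`):
#' cardiac oscillation (default 2.4 Hz, an infant heart rate deliberately
#' above the 1.7 Hz low-pass cutoff so filtering is testable), slow linear
#' drifts, white measurement noise, additive motion-spike artifacts
#' (short boxcars large enough to trip the +/-3 / +/-5 umol trial-rejection
#' thresholds), and dead channels (light starvation modeled as a weak,
#' highly variable intensity that fails the coefficient-of-variation
#' screen).
#'
#' @param cardiac_frequency_hz,cardiac_amplitude cardiac component.
#' @param drift_slope_sd per-channel linear drift slope SD, per second.
#' @param motion_rate_per_min,motion_magnitude motion-spike Poisson rate and
#'   attenuation magnitude.
#' @param dead_channel_prob probability a channel is dead.
#' @param white_sd white noise SD.
#' @param seed integer; fully determines the generated cohort.
#' @return a list of class `nirs_noise_model`.
#' @export
noise_model <- function(cardiac_frequency_hz = 2.4, cardiac_amplitude = 0.004,
                        drift_slope_sd = 2e-5, motion_rate_per_min = 0.3,
                        motion_magnitude = 0.12, dead_channel_prob = 0.02,
                        white_sd = 0.003, seed = 1L) {
  vals <- c(cardiac_frequency_hz, cardiac_amplitude, drift_slope_sd,
            motion_rate_per_min, motion_magnitude, dead_channel_prob, white_sd)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_field("noise_model", "all rates and scales must be >= 0")
  structure(list(cardiac_frequency_hz = cardiac_frequency_hz,
                 cardiac_amplitude = cardiac_amplitude,
                 drift_slope_sd = drift_slope_sd,
                 motion_rate_per_min = motion_rate_per_min,
                 motion_magnitude = motion_magnitude,
                 dead_channel_prob = dead_channel_prob,
                 white_sd = white_sd, seed = as.integer(seed)),
            class = "nirs_noise_model")
}

#' Noise-free noise model
#'
#' Convenience constructor with every nuisance amplitude at zero, so the
#' pipeline is exactly lossless on the generated cohort.
#'
#' @param seed integer seed (still controls trial ordering and durations).
#' @return a `nirs_noise_model`.
#' @export
noiseless_model <- function(seed = 1L) {
  noise_model(cardiac_amplitude = 0, drift_slope_sd = 0,
              motion_rate_per_min = 0, motion_magnitude = 0,
              dead_channel_prob = 0, white_sd = 0, seed = seed)
}

#' Build a hemodynamic ground-truth table
#'
#' One row per (participant, condition, channel) with the injected HbO2 and
#' HHb peak amplitudes (umol) and peak latency (s). The default HHb
#' amplitude is -1/3 of the HbO2 amplitude, the canonical oxy/deoxy
#' asymmetry of a consistent hemodynamic response.
#'
#' Scenarios:
#' \describe{
#'   \item{null}{no response anywhere (all amplitudes 0).}
#'   \item{uniform}{`hbo2_amplitude` in every channel for every condition.}
#'   \item{left_temporal}{response restricted to the left posterior temporal
#'     ROI channels, spoken conditions only; used for sensitivity and
#'     specificity checks against a known active set.}
#'   \item{modality_contrast}{spoken conditions drive the inferior frontal
#'     and posterior temporal ROI channels bilaterally; signed conditions
#'     drive the right posterior temporal channels — an illustrative
#'     class-separable pattern for decoding tests.}
#' }
#'
#' @param participants list of `nirs_participant`.
#' @param config a `nirs_config` (montage + ROIs + design).
#' @param scenario one of `"null"`, `"uniform"`, `"left_temporal"`,
#'   `"modality_contrast"`.
#' @param hbo2_amplitude peak HbO2 amplitude in umol for driven channels.
#' @param hhb_ratio HHb amplitude as a (negative) multiple of HbO2.
#' @param peak_time peak latency in s.
#' @return data.frame of class `nirs_ground_truth`.
#' @export
default_ground_truth <- function(participants, config, scenario = "uniform",
                                 hbo2_amplitude = 1.5, hhb_ratio = -1 / 3,
                                 peak_time = 12) {
  mon <- config$montage
  grid <- expand.grid(participant = vapply(participants, `[[`, "", "id"),
                      condition = config$design$conditions,
                      channel = mon$channels$id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hemi <- mon$channels$hemisphere[match(grid$channel, mon$channels$id)]
  modality <- config$design$modality_map[grid$condition]
  amp <- rep(0, nrow(grid))
  if (scenario == "uniform") {
    amp[] <- hbo2_amplitude
  } else if (scenario == "left_temporal") {
    pt_left <- intersect(config$rois$posterior_temporal,
                         mon$channels$id[mon$channels$hemisphere == "left"])
    amp[grid$channel %in% pt_left & modality == "spoken"] <- hbo2_amplitude
  } else if (scenario == "modality_contrast") {
    roi_all <- c(config$rois$inferior_frontal, config$rois$posterior_temporal)
    pt_right <- intersect(config$rois$posterior_temporal,
                          mon$channels$id[mon$channels$hemisphere == "right"])
    amp[grid$channel %in% roi_all & modality == "spoken"] <- hbo2_amplitude
    amp[grid$channel %in% pt_right & modality == "signed"] <- hbo2_amplitude
  } else if (scenario != "null") {
    stop_field("scenario", "unknown ground-truth scenario")
  }
  grid$hbo2_amplitude <- amp
  grid$hhb_amplitude <- amp * hhb_ratio
  grid$peak_time <- peak_time
  class(grid) <- c("nirs_ground_truth", "data.frame")
  grid
}

#' Convenience constructor for a cohort's participant list
#'
#' @param n_monolingual,n_unimodal,n_bimodal group sizes (defaults are the
#'   study's: 19 monolingual, 20 unimodal bilingual, 21 bimodal bilingual).
#' @return list of `nirs_participant`.
#' @export
make_participants <- function(n_monolingual = 19, n_unimodal = 20,
                              n_bimodal = 21) {
  groups <- rep(c("monolingual", "unimodal_bilingual", "bimodal_bilingual"),
                c(n_monolingual, n_unimodal, n_bimodal))
  lapply(seq_along(groups), function(i)
    participant(sprintf("P%03d", i), groups[i]))
}

# Draw an event schedule honoring the design: a leading 10-s baseline,
# trials alternating spoken/signed modality, 9-12 s stimulus durations,
# a 10-s baseline after each trial.
simulate_events <- function(design, n_trials = design$max_experimental_trials) {
  mods <- c("spoken", "signed")
  start <- sample(mods, 1)
  mod_seq <- rep(c(start, setdiff(mods, start)), length.out = n_trials)
  conds <- character(n_trials)
  for (m in mods) {
    pool <- names(design$modality_map)[design$modality_map == m]
    k <- sum(mod_seq == m)
    conds[mod_seq == m] <- sample(rep(pool, length.out = k))
  }
  durations <- round(stats::runif(n_trials, design$stimulus_duration_range_s[1],
                                  design$stimulus_duration_range_s[2]), 1)
  onsets <- numeric(n_trials)
  t <- design$baseline_duration_s
  for (i in seq_len(n_trials)) {
    onsets[i] <- t
    t <- t + durations[i] + design$baseline_duration_s
  }
  list(events = data.frame(onset = onsets, condition = conds),
       durations = durations, total_s = t)
}

#' Simulate a cohort of raw dual-wavelength recordings
#'
#' Generates one recording per participant with known hemodynamic ground
#' truth: per-trial HbO2/HHb responses are laid down as gamma curves,
#' mapped to attenuation with [forward_beer_lambert()], combined with the
#' noise model's cardiac, drift, white-noise and motion components, and
#' exponentiated onto a per-channel log-uniform baseline intensity
#' (`intensity = baseline * exp(-attenuation)`). The same seed yields a
#' bit-identical cohort.
#'
#' @param config a `nirs_config`.
#' @param participants list of `nirs_participant`.
#' @param truth ground-truth table from [default_ground_truth()] (must
#'   cover every participant x condition x channel).
#' @param noise a `nirs_noise_model`.
#' @param looking_range range of simulated looking proportions (uniform);
#'   the default keeps all trials above the 60% looking criterion.
#' @return list with `recordings` (list of `nirs_recording`) and `truth`
#'   (the table echoed back).
#' @export
simulate_cohort <- function(config, participants, truth,
                            noise = noise_model(), looking_range = c(0.7, 1)) {
  ids <- vapply(participants, `[[`, "", "id")
  need <- expand.grid(participant = ids, condition = config$design$conditions,
                      channel = config$montage$channels$id,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$participant, d$condition, d$channel)
  if (!all(key(need) %in% key(truth)))
    stop_field("truth", "table does not cover every participant x condition x channel")
  recs <- lapply(seq_along(participants), function(i)
    with_seed(derive_seed(noise$seed, i),
              simulate_recording(config, participants[[i]], truth, noise,
                                 looking_range)))
  list(recordings = recs, truth = truth)
}

simulate_recording <- function(config, p, truth, noise, looking_range) {
  mon <- config$montage
  fs <- mon$sampling_rate_hz
  sched <- simulate_events(config$design)
  total_s <- sched$total_s + 12   # cover last event + 20 s with margin
  n_t <- round(total_s * fs)
  n_ch <- nrow(mon$channels)
  tt <- seq(0, by = 1 / fs, length.out = n_t)
  hrf_len <- round(24 * fs)

  tr <- truth[truth$participant == p$id, ]
  # concentration time courses per channel
  hbo2 <- matrix(0, n_ch, n_t)
  hhb <- matrix(0, n_ch, n_t)
  for (k in seq_len(nrow(sched$events))) {
    cond <- sched$events$condition[k]
    i0 <- round(sched$events$onset[k] * fs) + 1L
    idx <- i0:(i0 + hrf_len - 1L)
    rows <- tr[tr$condition == cond, ]
    rows <- rows[match(mon$channels$id, rows$channel), ]
    shape <- simulate_hrf(24, fs, 1, rows$peak_time[1])
    hbo2[, idx] <- hbo2[, idx] + outer(rows$hbo2_amplitude, shape)
    hhb[, idx] <- hhb[, idx] + outer(rows$hhb_amplitude, shape)
  }

  ext <- extinction_from_config(config$preprocess)
  dpf <- config$preprocess$dpf %||% 5.13
  m <- mbll_matrix(ext, dpf, mon$separation_cm)

  dead <- stats::runif(n_ch) < noise$dead_channel_prob
  intensity <- array(NA_real_, c(n_ch, 2, n_t))
  for (ch in seq_len(n_ch)) {
    atten_sig <- cbind(hbo2[ch, ], hhb[ch, ]) %*% t(m)  # time x wavelength
    drift <- stats::rnorm(1, 0, noise$drift_slope_sd) * tt
    phase <- stats::runif(1, 0, 2 * pi)
    cardiac <- noise$cardiac_amplitude *
      sin(2 * pi * noise$cardiac_frequency_hz * tt + phase)
    spikes <- simulate_motion_spikes(n_t, fs, noise)
    for (w in 1:2) {
      base <- 10^stats::runif(1, -1, 0)
      atten <- atten_sig[, w] + drift + cardiac + spikes +
        stats::rnorm(n_t, 0, noise$white_sd)
      if (dead[ch]) {
        base <- base * 1e-3
        atten <- stats::rnorm(n_t, 0, 0.5)  # light starvation: huge CoV
      }
      intensity[ch, w, ] <- base * exp(-atten)
    }
  }
  raw_recording(p, intensity, sched$events,
                stats::runif(nrow(sched$events), looking_range[1],
                             looking_range[2]),
                sampling_rate_hz = fs)
}

# boxcar artifacts (0.3-1.5 s) at Poisson times, random sign
simulate_motion_spikes <- function(n_t, fs, noise) {
  out <- numeric(n_t)
  rate <- noise$motion_rate_per_min * (n_t / fs) / 60
  if (rate <= 0 || noise$motion_magnitude <= 0) return(out)
  n_spk <- stats::rpois(1, rate)
  if (n_spk == 0) return(out)
  starts <- sort(sample.int(n_t, n_spk))
  for (s in starts) {
    len <- round(stats::runif(1, 0.3, 1.5) * fs)
    idx <- s:min(n_t, s + len)
    out[idx] <- out[idx] +
      sample(c(-1, 1), 1) * noise$motion_magnitude * stats::runif(1, 0.8, 1.5)
  }
  out
}

#' Write a ground-truth table as TSV
#'
#' @param truth a `nirs_ground_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
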