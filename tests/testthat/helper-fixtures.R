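# shared fixtures, all generated in code

# parse the shipped default config once per test run
test_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- default_config()
    cfg
  }
})

# peak table with per-participant peak values drawn around ground truth:
# exercises the statistics stack without the (positively biased) window-max
# extraction step
make_peak_table <- function(n_participants, active_channels = integer(),
                            effect = 0, noise_sd = 1, label = "spoken",
                            chromophore = "hbo2", n_channels = 46,
                            group = "monolingual") {
  grid <- expand.grid(participant = sprintf("P%03d", seq_len(n_participants)),
                      channel = seq_len(n_channels),
                      stringsAsFactors = FALSE)
  mu <- ifelse(grid$channel %in% active_channels, effect, 0)
  data.frame(participant = grid$participant, group = group, label = label,
             level = "modality", channel = grid$channel,
             chromophore = chromophore,
             peak = stats::rnorm(nrow(grid), mu, noise_sd),
             n_valid_trials = 5L)
}

# two-class peak table for decoding: class-mean shift in units of noise sd
make_decoding_peaks <- function(n_participants, n_channels = 46,
                                separation = 0, noise_sd = 1,
                                group = "monolingual") {
  rows <- list()
  for (p in sprintf("P%03d", seq_len(n_participants)))
    for (lab in c("spoken", "signed")) {
      mu <- if (lab == "spoken") separation * noise_sd else 0
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, group = group, label = lab, level = "modality",
        channel = seq_len(n_channels), chromophore = "hbo2",
        peak = stats::rnorm(n_channels, mu, noise_sd), n_valid_trials = 5L)
    }
  do.call(rbind, rows)
}

# small noise-free cohort, memoised: several tests reuse it
noise_free_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- test_config()
      parts <- make_participants(1, 1, 1)
      truth <- default_ground_truth(parts, cfg, scenario = "uniform",
                                    hbo2_amplitude = 1.5)
      cache <<- list(
        cfg = cfg, parts = parts, truth = truth,
        sim = simulate_cohort(cfg, parts, truth, noiseless_model(seed = 5)))
    }
    cache
  }
})

# attenuation epoch on the canonical 240-sample axis
make_test_epoch <- function(values_fun, n_ch = 2) {
  taxis <- seq(-4, 19.9, by = 0.1)
  dat <- array(0, c(n_ch, 2, length(taxis)))
  for (ch in seq_len(n_ch)) for (w in 1:2) dat[ch, w, ] <- values_fun(taxis)
  structure(list(data = dat, time = taxis, condition = "English", onset = 100,
                 looking_proportion = 1),
            class = "nirs_epoch")
}

# concentration epoch (already baseline-referenced) for rejection tests
make_conc_epoch <- function(n_ch = 3, condition = "English",
                            looking = 1, fill = 0) {
  taxis <- seq(-4, 19.9, by = 0.1)
  dat <- array(fill, c(n_ch, 2, length(taxis)),
               dimnames = list(NULL, c("hbo2", "hhb"), NULL))
  structure(list(data = dat, time = taxis, condition = condition, onset = 100,
                 looking_proportion = looking, valid = rep(TRUE, n_ch)),
            class = "nirs_conc_epoch")
}
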