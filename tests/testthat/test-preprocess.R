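test_that("zero-phase low-pass filter meets its frequency-response contract", {
  # DC preservation
  expect_equal(lowpass_filter(rep(2.5, 200)), rep(2.5, 200), tolerance = 1e-6)
  t <- seq(0, 60 - 0.1, by = 0.1)
  # 3 Hz unit sinusoid: measured gain matches the analytic squared
  # Butterworth response |H|^2 = 1 / (1 + (f/fc)^(2 * order))
  y <- lowpass_filter(sin(2 * pi * 3 * t))
  mid <- 150:450  # avoid filtfilt edge transients
  gain <- max(abs(y[mid]))
  analytic <- 1 / (1 + (3 / 1.7)^8)  # one-way power response = two-way gain
  expect_lt(gain, 0.1)
  expect_equal(gain, analytic, tolerance = 0.05)
  # cardiac band: >= 20 dB attenuation at 2.4 Hz
  y24 <- lowpass_filter(sin(2 * pi * 2.4 * t))
  expect_lt(max(abs(y24[mid])), 10^(-20 / 20))
  expect_error(lowpass_filter(t, cutoff_hz = 5), "Nyquist")
})

test_that("segmentation yields one 240-sample block per event on the [-4, 20) axis", {
  cohort <- noise_free_cohort()
  rec <- cohort$sim$recordings[[1]]
  atten <- intensity_to_attenuation(rec$intensity)
  eps <- segment_epochs(atten, rec$events, rec$looking_proportion)
  expect_length(eps, 20)
  for (ep in eps[1:3]) {
    expect_equal(dim(ep$data)[3], 240)
    expect_equal(ep$time[1], -4)
    expect_equal(ep$time[240], 19.9)
    expect_equal(diff(range(ep$time)), 23.9)
  }
  expect_equal(eps[[5]]$looking_proportion, rec$looking_proportion[5])
  # event too close to the recording edge is dropped with a warning
  short <- atten[, , 1:300, drop = FALSE]
  expect_warning(
    eps2 <- segment_epochs(short, data.frame(onset = c(10, 18),
                                             condition = c("English", "BSL")),
                           c(1, 1)),
    "edge")
  expect_length(eps2, 1)
})

test_that("anchored detrending zeroes both 4-s end-window means", {
  # pure ramp
  ep <- make_test_epoch(function(t) 0.3 + 0.05 * t)
  d <- detrend_epoch(ep)
  expect_equal(mean(d$data[1, 1, 1:40]), 0, tolerance = 1e-12)
  expect_equal(mean(d$data[1, 1, 201:240]), 0, tolerance = 1e-12)
  # constant input: identically zero output
  dc <- detrend_epoch(make_test_epoch(function(t) 4.2))
  expect_equal(max(abs(dc$data)), 0, tolerance = 1e-12)
  # ramp + response: output equals response minus its own anchor line,
  # with the line constructed explicitly from the two window means
  taxis <- seq(-4, 19.9, by = 0.1)
  hrf <- c(rep(0, 40), simulate_hrf(20, 10, amplitude = 1))
  ep2 <- make_test_epoch(function(t) 0.1 * t + 2)
  ep2$data[1, 1, ] <- ep2$data[1, 1, ] + hrf
  d2 <- detrend_epoch(ep2)
  m1 <- mean(hrf[1:40]); m2 <- mean(hrf[201:240])
  c1 <- mean(taxis[1:40]); c2 <- mean(taxis[201:240])
  line <- m1 + (m2 - m1) / (c2 - c1) * (taxis - c1)
  expect_equal(d2$data[1, 1, ], hrf - line, tolerance = 1e-9)
})

test_that("Beer-Lambert inversion is the exact inverse of the forward model", {
  ep <- make_test_epoch(function(t) 0)
  set.seed(11)
  hbo2 <- rnorm(240, 0, 2); hhb <- rnorm(240, 0, 1)
  att <- forward_beer_lambert(hbo2, hhb)
  ep$data[1, 1, ] <- att[, 1]; ep$data[1, 2, ] <- att[, 2]
  conc <- mbll_inverse(ep)
  expect_lt(max(abs(conc$data[1, "hbo2", ] - hbo2)) / max(abs(hbo2)), 1e-9)
  expect_lt(max(abs(conc$data[1, "hhb", ] - hhb)) / max(abs(hhb)), 1e-9)
  # zero attenuation gives zero concentration
  expect_equal(max(abs(conc$data[2, , ])), 0)
  expect_error(mbll_inverse(ep, extinction = matrix(1, 2, 2)), "singular")
})

test_that("linear detrending and the linear Beer-Lambert inversion commute", {
  # both stages are linear, so their order cannot change the result; the
  # canonical order (detrend attenuation, then convert) is therefore safe
  ep <- make_test_epoch(function(t) 0.01 * t + 0.002 * sin(t))
  a <- mbll_inverse(detrend_epoch(ep))
  b <- mbll_inverse(ep)
  b_det <- detrend_epoch(structure(list(data = b$data, time = b$time),
                                   class = "nirs_epoch"))
  expect_equal(a$data, b_det$data, tolerance = 1e-10)
})

test_that("amplitude-based trial rejection applies strict +/-3 and +/-5 umol bounds", {
  flat <- make_conc_epoch()
  expect_true(all(reject_trials(list(flat))[[1]]$valid))
  # +6 umol at t = 5 s in channel 2 only
  ep <- make_conc_epoch()
  ep$data[2, "hbo2", which(ep$time == 5)] <- 6
  v <- reject_trials(list(ep))[[1]]$valid
  expect_equal(v, c(TRUE, FALSE, TRUE))
  # an excursion of exactly 5.0 umol during the stimulus is kept
  ep5 <- make_conc_epoch()
  ep5$data[1, "hbo2", which(ep5$time == 5)] <- 5
  expect_true(all(reject_trials(list(ep5))[[1]]$valid))
  # baseline bound is tighter: 3.5 umol at t = -2 s invalidates
  epb <- make_conc_epoch()
  epb$data[1, "hhb", which(epb$time == -2)] <- 3.5
  expect_equal(reject_trials(list(epb))[[1]]$valid, c(FALSE, TRUE, TRUE))
  # the same 3.5 umol during the stimulus is fine (bound is 5 there)
  eps <- make_conc_epoch()
  eps$data[1, "hhb", which(eps$time == 5)] <- 3.5
  expect_true(all(reject_trials(list(eps))[[1]]$valid))
  # post-stimulus baseline (t >= 10 s) is not screened
  epp <- make_conc_epoch()
  epp$data[1, "hbo2", which(epp$time == 15)] <- 8
  expect_true(all(reject_trials(list(epp))[[1]]$valid))
})

test_that("looking-time criterion keeps exactly the >= 60% trials", {
  mk <- function(lp) make_conc_epoch(looking = lp)
  expect_length(apply_looking_criterion(list(mk(0.59))), 0)
  expect_length(apply_looking_criterion(list(mk(0.60))), 1)
  expect_length(apply_looking_criterion(lapply(rep(1, 5), mk)), 5)
  mixed <- lapply(c(0.9, 0.3, 0.8, 0.55, 1, 0.59, 0.7, 0.61, 0.2, 0.95), mk)
  expect_length(apply_looking_criterion(mixed), 6)
  expect_warning(out <- apply_looking_criterion(list(mk(NA_real_))), "missing")
  expect_length(out, 0)
})

test_that("condition averaging enforces the >=3-trial and paired-modality rules", {
  design <- test_config()$design
  p <- participant("P1", "monolingual")
  mk <- function(cond, peak = 1) {
    ep <- make_conc_epoch(condition = cond)
    ep$data[, "hbo2", ep$time >= 10 & ep$time < 14] <- peak
    ep
  }
  # 5 English + 5 French: both spoken conditions included
  eps <- c(lapply(1:5, function(i) mk("English")),
           lapply(1:5, function(i) mk("French")),
           lapply(1:4, function(i) mk("BSL")),
           lapply(1:4, function(i) mk("LSFB")))
  av <- average_conditions(eps, p, design)
  expect_true(av$English$included && av$French$included)
  expect_true(av$spoken$included && av$signed$included)
  expect_equal(av$English$n_trials, 5)
  expect_equal(av$spoken$n_trials, 10)
  expect_equal(as.numeric(av$English$data[1, "hbo2", 150]), 1)

  # 2 English trials: English AND French excluded, modality can survive
  eps2 <- c(lapply(1:2, function(i) mk("English")),
            lapply(1:5, function(i) mk("French")),
            lapply(1:3, function(i) mk("BSL")),
            lapply(1:3, function(i) mk("LSFB")))
  av2 <- average_conditions(eps2, p, design)
  expect_false(av2$English$included)
  expect_false(av2$French$included)
  expect_true(av2$spoken$included)   # 7 spoken trials >= 3

  # modality inclusion needs >= 3 valid trials in that modality
  eps3 <- c(lapply(1:5, function(i) mk("English")),
            lapply(1:5, function(i) mk("French")),
            lapply(1:1, function(i) mk("BSL")),
            lapply(1:1, function(i) mk("LSFB")))
  av3 <- average_conditions(eps3, p, design)
  expect_false(av3$signed$included)
  expect_true(av3$spoken$included)
})

test_that("QC-rejected channels are masked out of averages", {
  design <- test_config()$design
  p <- participant("P1", "monolingual")
  eps <- c(lapply(1:4, function(i) make_conc_epoch(condition = "English", fill = 0.5)),
           lapply(1:4, function(i) make_conc_epoch(condition = "French", fill = 0.5)),
           lapply(1:4, function(i) make_conc_epoch(condition = "BSL", fill = 0.5)),
           lapply(1:4, function(i) make_conc_epoch(condition = "LSFB", fill = 0.5)))
  qc <- list(channels = data.frame(rejected = c(TRUE, FALSE, FALSE)))
  av <- average_conditions(eps, p, design, qc_report = qc)
  expect_equal(av$English$n_valid_trials, c(0L, 4L, 4L))
  expect_true(all(is.na(av$English$data[1, , ])))
  expect_equal(as.numeric(av$English$data[2, "hbo2", 1]), 0.5)
})

test_that("valid-trial counts are non-increasing through looking and artifact rejection", {
  set.seed(21)
  eps <- lapply(1:10, function(i) {
    ep <- make_conc_epoch(looking = runif(1, 0.4, 1))
    if (i %% 3 == 0) ep$data[1, "hbo2", 100] <- 7
    ep
  })
  n0 <- length(eps)
  eps_look <- apply_looking_criterion(eps)
  n1 <- length(eps_look)
  eps_rej <- reject_trials(eps_look)
  n2 <- sum(sapply(eps_rej, function(ep) all(ep$valid)))
  expect_true(n1 <= n0)
  expect_true(n2 <= n1)
})
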