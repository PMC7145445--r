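test_that("feature construction standardizes channels and sizes subsets correctly", {
  set.seed(71)
  pk <- make_decoding_peaks(10, separation = 1)
  f_all <- build_features(pk, c("spoken", "signed"), 1:46)
  expect_equal(ncol(f_all$x), 46)
  expect_equal(nrow(f_all$x), 20)  # one pattern per participant per class
  expect_equal(unname(colMeans(f_all$x)), rep(0, 46), tolerance = 1e-10)
  expect_equal(unname(apply(f_all$x, 2, sd)), rep(1, 46), tolerance = 1e-10)
  f_left <- build_features(pk, c("spoken", "signed"), 1:23)
  expect_equal(ncol(f_left$x), 23)
  f_right <- build_features(pk, c("spoken", "signed"), 24:46)
  expect_equal(ncol(f_right$x), 23)
})

test_that("standardization matches a pencil-and-paper z-score on a 4-pattern toy", {
  pk <- data.frame(
    participant = rep(c("A", "B"), each = 4),
    group = "monolingual",
    label = rep(rep(c("spoken", "signed"), each = 2), 2),
    level = "modality",
    channel = rep(1:2, 4), chromophore = "hbo2",
    peak = c(2, 1, 4, 3, 6, 5, 8, 7), n_valid_trials = 5L)
  f <- build_features(pk, c("spoken", "signed"), 1:2)
  # channel 1 values over patterns (A-spoken, A-signed, B-spoken, B-signed):
  # {2, 4, 6, 8}: mean 5, sd sqrt(20/3); channel 2: {1, 3, 5, 7}: mean 4
  s <- sqrt(20 / 3)
  expect_equal(unname(f$x[, 1]), c(2 - 5, 4 - 5, 6 - 5, 8 - 5) / s)
  expect_equal(unname(f$x[, 2]), c(1 - 4, 3 - 4, 5 - 4, 7 - 4) / s,
               tolerance = 1e-10)
})

test_that("missing channels are imputed at the standardized mean", {
  pk <- make_decoding_peaks(6)
  pk <- pk[!(pk$participant == "P001" & pk$channel == 3), ]
  f <- build_features(pk, c("spoken", "signed"), 1:5)
  expect_equal(unname(f$x[1, 3]), 0)
  expect_equal(unname(f$x[2, 3]), 0)
  expect_false(any(is.na(f$x)))
})

test_that("LOPO bookkeeping yields two trials per participant", {
  set.seed(73)
  f20 <- build_features(make_decoding_peaks(20), c("spoken", "signed"), 1:46)
  r20 <- lopo_classify(f20)
  expect_equal(r20$n_trials, 40)
  expect_equal(nrow(r20$outcomes), 40)
  expect_equal(r20$accuracy, mean(r20$outcomes$correct))
  # accuracy is always a multiple of 1/(2n)
  expect_equal(r20$accuracy * 40, round(r20$accuracy * 40))
  expect_error(lopo_classify(
    build_features(make_decoding_peaks(2), c("spoken", "signed"), 1:46)),
    "at least 3")
})

test_that("linearly separable classes are decoded perfectly", {
  set.seed(75)
  f <- build_features(make_decoding_peaks(12, separation = 5),
                      c("spoken", "signed"), 1:46)
  expect_equal(lopo_classify(f)$accuracy, 1.0)
})

test_that("compiled SMO solver agrees with the reference libsvm implementation", {
  set.seed(77)
  for (i in 1:15) {
    sep <- runif(1, 0, 1.5)
    n <- sample(5:12, 1)
    f <- build_features(make_decoding_peaks(n, separation = sep,
                                            n_channels = 12),
                        c("spoken", "signed"), 1:12)
    a <- lopo_classify(f, engine = "smo")
    b <- lopo_classify(f, engine = "e1071")
    expect_equal(a$outcomes$predicted, b$outcomes$predicted)
    # decision values agree to solver tolerance as well
    expect_equal(a$outcomes$decision, b$outcomes$decision, tolerance = 1e-2)
  }
})

test_that("permutation p values follow the inclusive counting rule", {
  set.seed(79)
  # strong signal: observed beats every permuted accuracy
  f <- build_features(make_decoding_peaks(10, separation = 5),
                      c("spoken", "signed"), 1:46)
  pt <- permutation_test(f, n_permutations = 99, seed = 3)
  expect_equal(pt$p_value, 1 / 100)
  expect_length(pt$null, 99)
  # p values can only take values m/(n_perm + 1)
  expect_equal(pt$p_value * 100, round(pt$p_value * 100))
  # determinism: same seed, same null and p
  pt2 <- permutation_test(f, n_permutations = 99, seed = 3)
  expect_identical(pt$null, pt2$null)
  expect_identical(pt$p_value, pt2$p_value)
  # different seed, different null
  pt3 <- permutation_test(f, n_permutations = 99, seed = 4)
  expect_false(identical(pt$null, pt3$null))
  # fully degenerate patterns: every accuracy (observed and permuted) ties,
  # so the inclusive count saturates at p = 1 and the tie rule is flagged
  pk_const <- make_decoding_peaks(6)
  pk_const$peak <- 1
  f_const <- build_features(pk_const, c("spoken", "signed"), 1:46)
  expect_true(lopo_classify(f_const)$tie_flagged)
  ptb <- permutation_test(f_const, n_permutations = 49, seed = 5)
  expect_equal(ptb$observed, 0.5)
  expect_true(all(ptb$null == 0.5))
  expect_equal(ptb$p_value, 1)
})

test_that("exhaustive permutation matches complete enumeration of label swaps", {
  set.seed(81)
  f <- build_features(make_decoding_peaks(3, separation = 1.5, n_channels = 6),
                      c("spoken", "signed"), 1:6)
  pt <- permutation_test(f, method = "exhaustive")
  expect_equal(pt$n_permutations, 8)
  # independent enumeration of the 2^3 swap patterns
  obs <- lopo_classify(f)$accuracy
  accs <- numeric(0)
  for (s1 in c(FALSE, TRUE)) for (s2 in c(FALSE, TRUE))
    for (s3 in c(FALSE, TRUE)) {
      y <- as.character(f$y)
      swaps <- c(s1, s2, s3)
      for (p in which(swaps)) {
        idx <- which(f$participant == unique(f$participant)[p])
        y[idx] <- rev(y[idx])
      }
      accs <- c(accs, lopo_classify(
        f, labels = factor(y, levels = levels(f$y)))$accuracy)
    }
  expect_equal(sort(pt$null), sort(accs))
  expect_equal(pt$p_value, mean(accs >= obs))
})

test_that("accuracy-difference nulls are paired by permutation index", {
  a <- structure(list(observed = 0.7, null = c(0.5, 0.6, 0.4, 0.55, 0.55),
                      n_permutations = 5, p_value = NA, seed = 1),
                 class = "nirs_permutation")
  b <- structure(list(observed = 0.5, null = c(0.45, 0.5, 0.5, 0.6, 0.35),
                      n_permutations = 5, p_value = NA, seed = 2),
                 class = "nirs_permutation")
  d <- compare_accuracies(a, b)
  # hand count: diffs {0.05, 0.1, -0.1, -0.05, 0.2} >= 0.2 -> 1 of 5
  expect_equal(d$observed, 0.2)
  expect_equal(d$null, c(0.05, 0.1, -0.1, -0.05, 0.2))
  expect_equal(d$p_value, 1 / 5)
  expect_false(d$below_resolution)
  # degenerate nulls at 0.5 and observed difference 0.2: below resolution
  a2 <- a; a2$null <- rep(0.5, 5); a2$observed <- 0.7
  b2 <- b; b2$null <- rep(0.5, 5); b2$observed <- 0.5
  d2 <- compare_accuracies(a2, b2)
  expect_equal(d2$p_value, 0)
  expect_true(d2$below_resolution)
  # identical analyses: difference 0 with an all-zero null, p = 1
  d3 <- compare_accuracies(a, a)
  expect_equal(d3$observed, 0)
  expect_equal(d3$p_value, 1)
  b3 <- b; b3$n_permutations <- 4
  expect_error(compare_accuracies(a, b3), "equal n_permutations")
})

test_that("median accuracy is monotone in class separation", {
  set.seed(83)
  med <- sapply(c(0, 0.5, 1, 2), function(sep) {
    median(replicate(50, {
      f <- build_features(make_decoding_peaks(8, separation = sep,
                                              n_channels = 20),
                          c("spoken", "signed"), 1:20)
      lopo_classify(f)$accuracy
    }))
  })
  expect_true(all(diff(med) >= 0))
})

test_that("leakage-free fold scaling is available and behaves sanely", {
  set.seed(85)
  pk <- make_decoding_peaks(10, separation = 3)
  f <- build_features(pk, c("spoken", "signed"), 1:46,
                      scaling = "training_fold")
  r <- lopo_classify(f)
  expect_equal(r$n_trials, 20)
  expect_gt(r$accuracy, 0.9)  # strong signal survives fold-wise scaling
})
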