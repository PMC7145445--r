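#' Build a standardized feature matrix for decoding
#'
#' One pattern per participant and class: the per-channel HbO2 peak
#' amplitudes of the participant's condition (or modality) average over a
#' channel subset (whole array = 46 features, one hemisphere = 23).
#' Features are z-scored within each channel across all contributing
#' patterns (both classes pooled); channels missing for a participant
#' (rejected by QC) are imputed at the standardized mean, 0. Only
#' participants contributing both class patterns are retained.
#'
#' The all-pattern standardization replicates the original analysis and
#' shares scaling information with the held-out participant; a
#' leakage-free variant that refits scaling on each training fold is
#' available via `scaling = "training_fold"` for sensitivity analyses.
#'
#' @param peaks a PeakTable.
#' @param classes character pair of `label` values to contrast, e.g.
#'   `c("spoken", "signed")`; order fixes the canonical class order.
#' @param channel_subset integer channel ids to use as features.
#' @param groups optional participant-group filter.
#' @param chromophore feature chromophore (default `"hbo2"`).
#' @param scaling `"pooled"` (default, z-score across all patterns) or
#'   `"training_fold"` (scaling deferred to the cross-validation loop).
#' @return a list of class `nirs_features`: `x` (pattern x feature matrix),
#'   `y` (factor of class labels), `participant`, `channels`, `scaling`,
#'   plus the per-channel `center`/`scale` used (pooled mode).
#' @export
build_features <- function(peaks, classes, channel_subset,
                           groups = NULL, chromophore = "hbo2",
                           scaling = c("pooled", "training_fold")) {
  scaling <- match.arg(scaling)
  if (length(classes) != 2) stop_field("classes", "need exactly two labels")
  pk <- peaks[peaks$label %in% classes & peaks$chromophore == chromophore, ]
  if (!is.null(groups)) pk <- pk[pk$group %in% groups, ]
  have_both <- tapply(pk$label, pk$participant,
                      function(l) all(classes %in% l))
  keep <- names(have_both)[have_both]
  pk <- pk[pk$participant %in% keep, ]
  if (length(keep) < 2) stop_field("peaks", "fewer than 2 complete participants")
  keep <- sort(keep)
  n_pat <- 2L * length(keep)
  x <- matrix(NA_real_, n_pat, length(channel_subset),
              dimnames = list(NULL, paste0("ch", channel_subset)))
  y <- character(n_pat)
  pid <- character(n_pat)
  r <- 0L
  for (p in keep)
    for (cl in classes) {
      r <- r + 1L
      sub <- pk[pk$participant == p & pk$label == cl, ]
      x[r, ] <- sub$peak[match(channel_subset, sub$channel)]
      y[r] <- cl
      pid[r] <- p
    }
  center <- scale_ <- rep(NA_real_, ncol(x))
  if (scaling == "pooled") {
    for (cc in seq_len(ncol(x))) {
      v <- x[, cc]
      center[cc] <- mean(v, na.rm = TRUE)
      s <- stats::sd(v, na.rm = TRUE)
      scale_[cc] <- if (is.na(s) || s == 0) 1 else s
      x[, cc] <- (v - center[cc]) / scale_[cc]
    }
    x[is.na(x)] <- 0  # rejected channels at the standardized channel mean
  }
  structure(list(x = x, y = factor(y, levels = classes), participant = pid,
                 channels = channel_subset, scaling = scaling,
                 center = center, scale = scale_),
            class = "nirs_features")
}

# fold-wise z-scoring for the leakage-free mode
scale_fold <- function(x_train, x_test) {
  for (cc in seq_len(ncol(x_train))) {
    m <- mean(x_train[, cc], na.rm = TRUE)
    s <- stats::sd(x_train[, cc], na.rm = TRUE)
    if (is.na(s) || s == 0) s <- 1
    if (is.na(m)) m <- 0
    x_train[, cc] <- (x_train[, cc] - m) / s
    x_test[, cc] <- (x_test[, cc] - m) / s
  }
  x_train[is.na(x_train)] <- 0
  x_test[is.na(x_test)] <- 0
  list(train = x_train, test = x_test)
}

lopo_decisions <- function(x, y_signed, part_index, cost, engine) {
  if (engine == "smo")
    return(.lopo_decision_cpp(x, y_signed, part_index - 1L, cost))
  dec <- numeric(nrow(x))
  for (p in unique(part_index)) {
    te <- which(part_index == p)
    tr <- which(part_index != p)
    fit <- e1071::svm(x[tr, , drop = FALSE],
                      factor(y_signed[tr], levels = c(1, -1)),
                      kernel = "linear", cost = cost, scale = FALSE)
    dv <- attr(stats::predict(fit, x[te, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    dec[te] <- as.numeric(dv)
  }
  dec
}

#' Leave-one-participant-out linear SVM classification
#'
#' For each participant, a linear soft-margin support vector machine
#' (default cost C = 1) is trained on every other participant's two class
#' patterns (a balanced training set by construction) and tested on the
#' held-out participant's two patterns, so n participants yield 2n
#' classification trials. Accuracy is the proportion of correctly guessed
#' trials. A decision value of exactly zero (degenerate fold) is resolved
#' deterministically to the first class in canonical order and flagged.
#'
#' @param features a `nirs_features` (from [build_features()], or any list
#'   with `x`, `y`, `participant`).
#' @param cost soft-margin cost C.
#' @param labels optional class labels to swap in place of `features$y`
#'   (used by the permutation machinery).
#' @param engine `"smo"` (compiled, default) or `"e1071"` (reference
#'   implementation, used as a cross-check).
#' @return a list of class `nirs_classification`: `accuracy`, `n_trials`,
#'   `outcomes` (participant, true, predicted, decision), `tie_flagged`.
#' @export
lopo_classify <- function(features, cost = 1, labels = NULL,
                          engine = c("smo", "e1071")) {
  engine <- match.arg(engine)
  y <- labels %||% features$y
  classes <- levels(features$y)
  part_index <- match(features$participant, unique(features$participant))
  if (length(unique(part_index)) < 3)
    stop_field("features", "need at least 3 participants for LOPO")
  y_signed <- ifelse(as.character(y) == classes[1], 1, -1)

  if (features$scaling == "training_fold") {
    dec <- numeric(nrow(features$x))
    for (p in unique(part_index)) {
      te <- which(part_index == p)
      tr <- which(part_index != p)
      sc <- scale_fold(features$x[tr, , drop = FALSE],
                       features$x[te, , drop = FALSE])
      xf <- rbind(sc$train, sc$test)
      pf <- c(rep(1L, length(tr)), rep(2L, length(te)))
      dec[te] <- lopo_decisions(xf, y_signed[c(tr, te)], pf, cost,
                                engine)[pf == 2L]
    }
  } else {
    dec <- lopo_decisions(features$x, y_signed, part_index, cost, engine)
  }

  tie <- dec == 0
  pred_signed <- ifelse(dec > 0, 1, ifelse(dec < 0, -1, 1))
  correct <- pred_signed == y_signed
  structure(list(
    accuracy = mean(correct),
    n_trials = length(correct),
    outcomes = data.frame(participant = features$participant,
                          true = as.character(y),
                          predicted = classes[ifelse(pred_signed == 1, 1, 2)],
                          decision = dec, correct = correct),
    tie_flagged = any(tie)),
    class = "nirs_classification")
}

swap_labels <- function(y, part_index, swap) {
  y <- as.character(y)
  for (p in which(swap)) {
    idx <- which(part_index == p)
    y[idx] <- rev(y[idx])
  }
  y
}

#' Participant-preserving permutation test of decoding accuracy
#'
#' Each permutation independently keeps or swaps (probability 1/2) every
#' participant's two condition labels, preserving the paired structure,
#' then reruns the full leave-one-participant-out evaluation. The p value
#' uses the inclusive rule, counting the observed accuracy in both
#' numerator and denominator: `p = (1 + #\{null >= observed\}) /
#' (n_permutations + 1)`, so its floor with 1,000 permutations is 1/1001.
#' With `method = "exhaustive"` all 2^n swap patterns are enumerated
#' instead (the identity pattern plays the role of the observed value and
#' `p = #\{null >= observed\} / 2^n`).
#'
#' @param features a `nirs_features`.
#' @param n_permutations number of random permutations (default 1000).
#' @param seed integer seed for the swap draws.
#' @param cost soft-margin cost C.
#' @param method `"random"` coin-flip permutations (default) or
#'   `"exhaustive"` enumeration (feasible for small cohorts).
#' @param engine classifier engine, see [lopo_classify()].
#' @return a list of class `nirs_permutation`: `observed`, `null`
#'   (numeric vector), `n_permutations`, `p_value`, `seed`, `method`.
#' @export
permutation_test <- function(features, n_permutations = 1000, seed = 1L,
                             cost = 1, method = c("random", "exhaustive"),
                             engine = c("smo", "e1071")) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  if (method == "random" && n_permutations < 1)
    stop_field("n_permutations", "must be at least 1")
  part_index <- match(features$participant, unique(features$participant))
  n_part <- length(unique(part_index))
  observed <- lopo_classify(features, cost = cost, engine = engine)$accuracy
  run_swapped <- function(swap) {
    yk <- swap_labels(features$y, part_index, swap)
    lopo_classify(features, cost = cost,
                  labels = factor(yk, levels = levels(features$y)),
                  engine = engine)$accuracy
  }
  if (method == "exhaustive") {
    if (n_part > 16) stop_field("features", "exhaustive enumeration infeasible")
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), n_part))
    null <- apply(as.matrix(combos), 1, run_swapped)
    p <- mean(null >= observed)
    n_perm <- nrow(combos)
  } else {
    null <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(k)
        run_swapped(stats::runif(n_part) < 0.5), numeric(1))
    })
    p <- (1 + sum(null >= observed)) / (n_permutations + 1)
    n_perm <- n_permutations
  }
  structure(list(observed = observed, null = as.numeric(null),
                 n_permutations = n_perm, p_value = p,
                 seed = as.integer(seed), method = method),
            class = "nirs_permutation")
}

#' Permutation test of an accuracy difference
#'
#' Between-group or between-hemisphere comparison: the null distribution
#' of the accuracy difference is formed by subtracting the two analyses'
#' null values pairwise by permutation index, and the p value is the
#' fraction of null differences greater than or equal to the observed
#' difference. A p of exactly zero is below the resolution of the null
#' sample and is flagged (report as < 1/n).
#'
#' @param result_a,result_b `nirs_permutation` objects with equal
#'   `n_permutations` (from independent seeds).
#' @return a list of class `nirs_permutation_diff`: `observed` (accuracy
#'   difference a - b), `null`, `p_value`, `below_resolution`.
#' @export
compare_accuracies <- function(result_a, result_b) {
  if (result_a$n_permutations != result_b$n_permutations)
    stop_field("n_permutations", "the two analyses must use equal n_permutations")
  null <- result_a$null - result_b$null
  observed <- result_a$observed - result_b$observed
  p <- mean(null >= observed)
  structure(list(observed = observed, null = null,
                 n_permutations = result_a$n_permutations,
                 p_value = p, below_resolution = p == 0),
            class = "nirs_permutation_diff")
}
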