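# build an ROITable for one ROI directly, from per-cell values
make_roi_table <- function(values, groups) {
  # values: participant x 4 matrix, columns (spoken,L), (spoken,R),
  # (signed,L), (signed,R)
  n <- nrow(values)
  cells <- expand.grid(hemisphere = c("left", "right"),
                       label = c("spoken", "signed"),
                       stringsAsFactors = FALSE)[, 2:1]
  rows <- list()
  for (p in seq_len(n))
    for (k in 1:4)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = sprintf("P%03d", p), group = groups[p],
        roi = "posterior_temporal", hemisphere = cells$hemisphere[k],
        label = cells$label[k],
        mean_peak = values[p, k], n_channels = 4L)
  do.call(rbind, rows)
}

test_that("ROI cell means average the available channels", {
  cfg <- test_config()
  if_left <- intersect(cfg$rois$inferior_frontal,
                       cfg$montage$channels$id[cfg$montage$channels$hemisphere == "left"])
  pk <- data.frame(participant = "P1", group = "monolingual",
                   label = "spoken", level = "modality",
                   channel = if_left, chromophore = "hbo2",
                   peak = 1.0, n_valid_trials = 5L)
  tab <- build_roi_table(pk, cfg$rois, cfg$montage)
  cell <- tab[tab$roi == "inferior_frontal" & tab$hemisphere == "left", ]
  expect_equal(cell$mean_peak, 1.0)
  expect_equal(cell$n_channels, 4L)
  # one of the four channels rejected (absent): mean of the remaining {1,2,3}
  pk2 <- pk[1:3, ]
  pk2$peak <- c(1, 2, 3)
  tab2 <- build_roi_table(pk2, cfg$rois, cfg$montage)
  cell2 <- tab2[tab2$roi == "inferior_frontal" & tab2$hemisphere == "left", ]
  expect_equal(cell2$mean_peak, 2.0)
  expect_equal(cell2$n_channels, 3L)
})

# independent oracle for the balanced mixed design, computed from
# per-participant contrast scores with explicit sums of squares
mixed_anova_oracle <- function(values, groups) {
  n <- nrow(values)
  g <- factor(groups)
  ng <- table(g)
  subj_mean <- rowMeans(values)
  cM <- (values[, 1] + values[, 2]) / 2 - (values[, 3] + values[, 4]) / 2
  cH <- (values[, 1] + values[, 3]) / 2 - (values[, 2] + values[, 4]) / 2
  cMH <- values[, 1] - values[, 2] - values[, 3] + values[, 4]
  f_between <- function(x) {
    gm <- mean(tapply(x, g, mean))  # unweighted; balanced here
    ss_g <- sum(ng * (tapply(x, g, mean) - gm)^2)
    ss_e <- sum((x - tapply(x, g, mean)[g])^2)
    (ss_g / (nlevels(g) - 1)) / (ss_e / (n - nlevels(g)))
  }
  f_within_main <- function(x) {
    gm <- mean(x)
    ss_e <- sum((x - tapply(x, g, mean)[g])^2)
    (n * gm^2) / (ss_e / (n - nlevels(g)))
  }
  list(group = f_between(subj_mean),
       modality = f_within_main(cM),
       hemisphere = f_within_main(cH),
       modality_x_hemisphere = f_within_main(cMH),
       group_x_modality = f_between(cM),
       group_x_hemisphere = f_between(cH))
}

test_that("mixed ANOVA F statistics match an explicit sums-of-squares oracle", {
  set.seed(51)
  groups <- rep(c("monolingual", "unimodal_bilingual", "bimodal_bilingual"),
                each = 4)
  values <- matrix(rnorm(12 * 4, mean = 0.5), 12, 4)
  values[, 2] <- values[, 2] + 0.8   # hemisphere offset in spoken
  res <- mixed_anova(make_roi_table(values, groups))
  oracle <- mixed_anova_oracle(values, groups)
  getF <- function(name) res$F[res$effect == name]
  expect_equal(getF("group"), oracle$group, tolerance = 1e-8)
  expect_equal(getF("modality"), oracle$modality, tolerance = 1e-8)
  expect_equal(getF("hemisphere"), oracle$hemisphere, tolerance = 1e-8)
  expect_equal(getF("modality x hemisphere"), oracle$modality_x_hemisphere,
               tolerance = 1e-8)
  expect_equal(getF("group x modality"), oracle$group_x_modality,
               tolerance = 1e-8)
  expect_equal(getF("group x hemisphere"), oracle$group_x_hemisphere,
               tolerance = 1e-8)
  # all seven effects reported with consistent partial eta^2
  expect_equal(nrow(res), 7)
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
  expect_equal(res$partial_eta_sq,
               res$F * res$df_num / (res$F * res$df_num + res$df_den),
               tolerance = 1e-8)
  # dfs of the 2 x 2 x 3 design with 12 participants
  expect_equal(res$df_den[res$effect == "group"], 9)
  expect_equal(res$df_num[res$effect == "group"], 2)
  expect_equal(res$df_den[res$effect == "modality"], 9)
})

test_that("degenerate identical-valued tables yield no spurious effects", {
  groups <- rep(c("monolingual", "unimodal_bilingual", "bimodal_bilingual"),
                each = 3)
  values <- matrix(2, 9, 4)
  res <- mixed_anova(make_roi_table(values, groups))
  expect_true(all(is.na(res$F) | res$F < 1e-10))
})

test_that("hemisphere relabeling leaves F unchanged and flips the contrast sign", {
  set.seed(53)
  groups <- rep(c("monolingual", "unimodal_bilingual", "bimodal_bilingual"),
                each = 4)
  values <- matrix(rnorm(48), 12, 4)
  values[, c(2, 4)] <- values[, c(2, 4)] + 1  # right-lateralized
  tab <- make_roi_table(values, groups)
  tab_sw <- tab
  tab_sw$hemisphere <- ifelse(tab$hemisphere == "left", "right", "left")
  res <- mixed_anova(tab)
  res_sw <- mixed_anova(tab_sw)
  expect_equal(res$F, res_sw$F, tolerance = 1e-8)
  # the lateralization contrast itself flips sign
  d <- function(tt) mean(tt$mean_peak[tt$hemisphere == "right"]) -
    mean(tt$mean_peak[tt$hemisphere == "left"])
  expect_equal(d(tab), -d(tab_sw))
})

test_that("within-group hemisphere ANOVA detects an injected lateralization", {
  # d = 1.5, n = 18: significant at alpha = .05 in >= 80% of 100 simulations
  set.seed(55)
  sig <- replicate(100, {
    values <- matrix(rnorm(18 * 4), 18, 4)
    values[, c(2, 4)] <- values[, c(2, 4)] + 1.5
    res <- per_group_hemisphere_anova(
      make_roi_table(values, rep("unimodal_bilingual", 18)),
      group = "unimodal_bilingual")
    res$p[res$effect == "hemisphere"] < 0.05
  })
  expect_gte(mean(sig), 0.8)
  # symmetric hemispheres: F near zero on average (no systematic effect)
  set.seed(56)
  fs <- replicate(50, {
    values <- matrix(rnorm(10 * 4), 10, 4)
    res <- per_group_hemisphere_anova(
      make_roi_table(values, rep("monolingual", 10)), group = "monolingual")
    res$F[res$effect == "hemisphere"]
  })
  expect_lt(median(fs), qf(0.9, 1, 9))
})

test_that("within-group F equals the squared paired-contrast t statistic", {
  set.seed(57)
  values <- matrix(rnorm(8 * 4), 8, 4)
  res <- per_group_hemisphere_anova(
    make_roi_table(values, rep("monolingual", 8)), group = "monolingual")
  cH <- (values[, 1] + values[, 3]) / 2 - (values[, 2] + values[, 4]) / 2
  t_hand <- mean(cH) / (sd(cH) / sqrt(8))
  expect_equal(res$F[res$effect == "hemisphere"], t_hand^2, tolerance = 1e-8)
  expect_equal(res$df_den[res$effect == "hemisphere"], 7)
})

test_that("participants with missing cells are dropped listwise", {
  set.seed(59)
  groups <- rep(c("monolingual", "unimodal_bilingual", "bimodal_bilingual"),
                each = 4)
  values <- matrix(rnorm(48), 12, 4)
  tab <- make_roi_table(values, groups)
  full <- mixed_anova(tab)
  tab_miss <- tab[!(tab$participant == "P001" & tab$label == "signed" &
                      tab$hemisphere == "left"), ]
  red <- mixed_anova(tab_miss)
  expect_equal(red$df_den[red$effect == "group"],
               full$df_den[full$effect == "group"] - 1)
})

test_that("mixed ANOVA p values are uniform under the null", {
  set.seed(61)
  ps <- replicate(500, {
    groups <- rep(c("monolingual", "unimodal_bilingual", "bimodal_bilingual"),
                  each = 4)
    values <- matrix(rnorm(48), 12, 4)
    res <- mixed_anova(make_roi_table(values, groups))
    res$p[res$effect == "hemisphere"]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
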