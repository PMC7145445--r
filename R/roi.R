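#' Build the ROI peak table
#'
#' Averages HbO2 peak amplitudes over each ROI's non-rejected channels
#' separately per hemisphere, participant and modality (or condition),
#' giving the cell means entering the mixed-design ANOVAs. Cells with no
#' available channel are flagged missing (NA).
#'
#' @param peaks a PeakTable from [extract_peaks()].
#' @param rois a `nirs_roi_set`.
#' @param montage the `nirs_montage` (for hemisphere lookup).
#' @param level use `"modality"` rows (default) or `"condition"` rows.
#' @param chromophore chromophore to average (default `"hbo2"`).
#' @return an `ROITable` data.frame: participant, group, roi, hemisphere,
#'   label, mean_peak, n_channels.
#' @export
build_roi_table <- function(peaks, rois, montage, level = "modality",
                            chromophore = "hbo2") {
  pk <- peaks[peaks$level == level & peaks$chromophore == chromophore, ]
  hemi_of <- function(ch)
    montage$channels$hemisphere[match(ch, montage$channels$id)]
  rows <- list()
  for (roi_name in c("inferior_frontal", "posterior_temporal")) {
    roi_ch <- rois[[roi_name]]
    for (h in c("left", "right")) {
      ch_set <- roi_ch[hemi_of(roi_ch) == h]
      sub <- pk[pk$channel %in% ch_set, ]
      if (!nrow(sub)) next
      agg <- stats::aggregate(peak ~ participant + group + label, data = sub,
                              FUN = mean)
      cnt <- stats::aggregate(peak ~ participant + group + label, data = sub,
                              FUN = length)
      agg$n_channels <- cnt$peak
      agg$roi <- roi_name
      agg$hemisphere <- h
      rows[[length(rows) + 1L]] <- agg
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "peak"] <- "mean_peak"
  out[, c("participant", "group", "roi", "hemisphere", "label",
          "mean_peak", "n_channels")]
}

# extract effect rows (F, df, p, partial eta^2) from a multistratum aov;
# ss_scale is the response's total sum of squares, used to recognize
# vanishing error strata
anova_effects <- function(fit, ss_scale = 1) {
  smry <- summary(fit)
  rows <- list()
  for (stratum in smry) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    terms <- trimws(rownames(tab))
    resid_i <- which(terms == "Residuals")
    if (!length(resid_i)) next
    ss_err <- tab[["Sum Sq"]][resid_i]
    df_err <- tab[["Df"]][resid_i]
    # a vanishing error stratum (e.g. identical-valued input) makes the F
    # ratio meaningless; flag instead of reporting numerical noise
    degenerate <- ss_err <= 1e-12 * max(ss_scale, .Machine$double.xmin)
    for (i in seq_len(nrow(tab))) {
      if (i == resid_i) next
      ss <- tab[["Sum Sq"]][i]
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub(":", " x ", terms[i]),
        F = if (degenerate) NA_real_ else tab[["F value"]][i],
        df_num = tab[["Df"]][i], df_den = df_err,
        p = if (degenerate) NA_real_ else tab[["Pr(>F)"]][i],
        partial_eta_sq = if (!degenerate && ss + ss_err > 0)
          ss / (ss + ss_err) else NA_real_,
        degenerate = degenerate)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# keep only participants with all within-subject cells present
complete_cases_roi <- function(tab, within_cols) {
  n_cells <- prod(vapply(within_cols, function(cl)
    length(unique(tab[[cl]])), integer(1)))
  cnt <- table(tab$participant)
  keep <- names(cnt)[cnt == n_cells]
  tab[tab$participant %in% keep & !is.na(tab$mean_peak), ]
}

#' Mixed-design ANOVA on ROI peaks
#'
#' The 2 x 2 x 3 analysis: language modality (spoken, signed) and
#' hemisphere (left, right) as within-participant factors, group
#' (monolingual, unimodal bilingual, bimodal bilingual) as the
#' between-participant factor, on ROI-mean HbO2 peak amplitudes of one
#' ROI. Classical repeated-measures sums-of-squares decomposition
#' (participant-level error strata) with partial eta squared per effect.
#' Both within factors have two levels, so sphericity corrections are
#' vacuous. Participants missing any within cell are dropped listwise.
#'
#' @param table an ROITable restricted to one ROI (or pass `roi` to
#'   filter).
#' @param roi optional ROI name to filter on.
#' @return an `AnovaResult` data.frame: effect, F, df_num, df_den, p,
#'   partial_eta_sq.
#' @export
mixed_anova <- function(table, roi = NULL) {
  if (!is.null(roi)) table <- table[table$roi == roi, ]
  tab <- data.frame(participant = factor(table$participant),
                    group = factor(table$group),
                    modality = factor(table$label),
                    hemisphere = factor(table$hemisphere),
                    mean_peak = table$mean_peak)
  tab <- complete_cases_roi(tab, c("modality", "hemisphere"))
  if (length(unique(tab$group)) < 2 ||
      min(table(unique(tab[, c("participant", "group")])$group)) < 2)
    stop_field("table", "need at least 2 participants per group")
  fit <- stats::aov(mean_peak ~ group * modality * hemisphere +
                      Error(participant / (modality * hemisphere)),
                    data = tab)
  anova_effects(fit, ss_scale = sum(tab$mean_peak^2))
}

#' Within-group hemisphere (x modality) ANOVA
#'
#' Per-group lateralization analysis: repeated-measures ANOVA with
#' hemisphere and modality as within-participant factors on one group's
#' ROI peaks, used to test e.g. right-lateralization of the posterior
#' temporal response within a single group.
#'
#' @param table an ROITable.
#' @param group group to analyze.
#' @param roi optional ROI filter.
#' @return an `AnovaResult` data.frame.
#' @export
per_group_hemisphere_anova <- function(table, group, roi = NULL) {
  if (!is.null(roi)) table <- table[table$roi == roi, ]
  table <- table[table$group == group, ]
  if (!nrow(table)) stop_field("group", "no rows for this group")
  tab <- data.frame(participant = factor(table$participant),
                    modality = factor(table$label),
                    hemisphere = factor(table$hemisphere),
                    mean_peak = table$mean_peak)
  tab <- complete_cases_roi(tab, c("modality", "hemisphere"))
  fit <- stats::aov(mean_peak ~ modality * hemisphere +
                      Error(participant / (modality * hemisphere)),
                    data = tab)
  anova_effects(fit, ss_scale = sum(tab$mean_peak^2))
}
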