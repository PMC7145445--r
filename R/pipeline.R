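stage_order <- c("simulate", "qc", "preprocess", "univariate", "roi", "mvpa")

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_as_list(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> qc -> preprocess -> univariate -> roi -> mvpa
#' with one master seed deriving every per-stage and per-participant
#' substream, writes the tabular outputs of each stage under `outdir`, and
#' returns a manifest recording seeds, the configuration hash, per-stage
#' counts, and every exclusion attributed to its rule (channel QC, looking
#' time, amplitude rejection, fewer than 3 valid trials).
#'
#' Later stages can be recomputed without re-simulating by passing the
#' previous run's `state` and a `stages` subset; resuming checks that the
#' configuration is unchanged via its hash.
#'
#' @param config a `nirs_config`.
#' @param participants list of `nirs_participant` (default: a small
#'   12-infant cohort balanced over groups).
#' @param scenario ground-truth scenario for the generator.
#' @param seed master seed.
#' @param outdir output directory.
#' @param stages ordered subset of
#'   `c("simulate","qc","preprocess","univariate","roi","mvpa")`.
#' @param state a previous run's `state` element, required when the first
#'   requested stage is not `"simulate"`.
#' @param n_permutations permutations for the decoding stage.
#' @param noise a `nirs_noise_model`; its seed is overridden by `seed`.
#' @return a list of class `nirs_run`: `manifest` and `state` (in-memory
#'   stage products, reusable for resume).
#' @export
run_pipeline <- function(config, participants = make_participants(4, 4, 4),
                         scenario = "modality_contrast", seed = 1L,
                         outdir = tempfile("nirs_run_"),
                         stages = stage_order, state = NULL,
                         n_permutations = 200,
                         noise = noise_model()) {
  stages <- match.arg(stages, stage_order, several.ok = TRUE)
  stages <- stage_order[stage_order %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  if (!is.null(state)) {
    if (!identical(state$config_hash, hash))
      stop_field("state", "config hash mismatch on resume")
  } else {
    state <- list(config_hash = hash)
  }
  manifest <- list(config_hash = hash, seed = as.integer(seed),
                   stages = stages, outdir = outdir,
                   counts = list(), exclusions = list(), files = character())
  first <- stages[1]
  if (first != "simulate" && is.null(state[[upstream_of(first)]]))
    stop_field("stages", sprintf("missing upstream outputs for stage '%s'",
                                 first))

  if ("simulate" %in% stages) {
    noise$seed <- derive_seed(seed, 101L)
    truth <- default_ground_truth(participants, config, scenario = scenario)
    sim <- simulate_cohort(config, participants, truth, noise)
    state$recordings <- sim$recordings
    state$truth <- truth
    f <- write_ground_truth(truth, file.path(outdir, "ground_truth.tsv"))
    manifest$files <- c(manifest$files, f)
    manifest$counts$participants_simulated <- length(sim$recordings)
  }
  if ("qc" %in% stages) {
    qcc <- config$qc
    state$qc <- lapply(state$recordings, apply_channel_rejection,
                       cov_threshold_percent = qcc$cov_threshold_percent %||% 15,
                       power_threshold = qcc$power_threshold %||% 0.5,
                       max_rejected = qcc$max_rejected_channels %||% 15)
    excluded <- vapply(state$qc, `[[`, TRUE, "participant_excluded")
    manifest$counts$participants_qc_excluded <- sum(excluded)
    for (r in state$qc[excluded])
      manifest$exclusions[[length(manifest$exclusions) + 1L]] <-
        list(participant = r$participant, rule = "channel_qc",
             detail = sprintf("%d rejected channels", r$n_rejected))
    qc_tab <- data.frame(
      participant = vapply(state$qc, `[[`, "", "participant"),
      n_rejected = vapply(state$qc, `[[`, 0L, "n_rejected"),
      excluded = excluded)
    manifest$files <- c(manifest$files,
                        write_tsv(qc_tab, file.path(outdir, "qc_summary.tsv")))
  }
  if ("preprocess" %in% stages) {
    keep <- !vapply(state$qc, `[[`, TRUE, "participant_excluded")
    state$preprocessed <- list()
    n_looking <- n_amplitude <- 0L
    for (i in which(keep)) {
      rec <- state$recordings[[i]]
      pre <- preprocess_recording(rec, config, state$qc[[i]])
      state$preprocessed[[rec$participant$id]] <- pre
      n_total <- nrow(rec$events)
      n_after_look <- length(pre$epochs)
      n_looking <- n_looking + (n_total - n_after_look)
      ch_ok <- !state$qc[[i]]$channels$rejected
      n_amplitude <- n_amplitude +
        sum(vapply(pre$epochs, function(ep) any(!ep$valid[ch_ok]), logical(1)))
      for (av in pre$averages)
        if (!av$included && av$level == "condition")
          manifest$exclusions[[length(manifest$exclusions) + 1L]] <-
            list(participant = rec$participant$id, rule = "min_valid_trials",
                 detail = sprintf("condition %s: %d valid trials",
                                  av$label, av$n_trials))
    }
    manifest$counts$trials_rejected_looking <- n_looking
    manifest$counts$trials_with_amplitude_rejection <- n_amplitude
    manifest$counts$participants_preprocessed <- length(state$preprocessed)
  }
  if ("univariate" %in% stages) {
    avgs <- lapply(state$preprocessed, `[[`, "averages")
    state$peaks <- extract_peaks(
      avgs, window_s = unlist(config$stats$peak_window_s %||% c(8, 16)))
    manifest$files <- c(manifest$files,
                        write_tsv(state$peaks,
                                  file.path(outdir, "peak_table.tsv")))
    alpha <- config$stats$alpha %||% 0.05
    m_ch <- config$stats$fdr_channels %||% 46
    maps <- list()
    for (lab in c("spoken", "signed")) {
      sub <- state$peaks[state$peaks$label == lab, ]
      if (!nrow(sub)) next
      ro <- channel_stats(sub[sub$chromophore == "hbo2", ], alpha, m_ch)
      rh <- channel_stats(sub[sub$chromophore == "hhb", ], alpha, m_ch)
      act <- classify_activation(ro, rh)
      ro$chromophore <- "hbo2"; rh$chromophore <- "hhb"
      both <- rbind(ro, rh)
      both$label <- lab
      both$activation <- act$label[match(both$channel, act$channel)]
      maps[[lab]] <- both
    }
    state$channel_maps <- do.call(rbind, maps)
    manifest$files <- c(manifest$files,
                        write_tsv(state$channel_maps,
                                  file.path(outdir, "channel_maps.tsv")))
  }
  if ("roi" %in% stages) {
    state$roi_table <- build_roi_table(state$peaks, config$rois,
                                       config$montage)
    state$roi_anova <- lapply(
      c(inferior_frontal = "inferior_frontal",
        posterior_temporal = "posterior_temporal"),
      function(r) tryCatch(mixed_anova(state$roi_table, roi = r),
                           error = function(e) NULL))
    manifest$files <- c(manifest$files,
                        write_tsv(state$roi_table,
                                  file.path(outdir, "roi_table.tsv")))
    for (r in names(state$roi_anova))
      if (!is.null(state$roi_anova[[r]]))
        manifest$files <- c(manifest$files,
                            write_tsv(state$roi_anova[[r]],
                                      file.path(outdir,
                                                sprintf("anova_%s.tsv", r))))
  }
  if ("mvpa" %in% stages) {
    mon <- config$montage$channels
    subsets <- list(all = mon$id,
                    left = mon$id[mon$hemisphere == "left"],
                    right = mon$id[mon$hemisphere == "right"])
    grps <- list(all = NULL, monolingual = "monolingual",
                 unimodal = "unimodal_bilingual", bimodal = "bimodal_bilingual")
    res <- list()
    k <- 0L
    for (g in names(grps)) for (s in names(subsets)) {
      k <- k + 1L
      cell <- tryCatch({
        feats <- build_features(state$peaks, c("spoken", "signed"),
                                subsets[[s]], groups = grps[[g]])
        pt <- permutation_test(feats, n_permutations = n_permutations,
                               seed = derive_seed(seed, 500L + k))
        list(group = g, channels = s, n_participants =
               length(unique(feats$participant)),
             accuracy = pt$observed, p_value = pt$p_value, null = pt$null)
      }, error = function(e) list(group = g, channels = s,
                                  n_participants = NA, accuracy = NA,
                                  p_value = NA, null = NULL))
      res[[paste(g, s, sep = "_")]] <- cell
    }
    state$mvpa <- res
    tab <- do.call(rbind, lapply(res, function(r)
      data.frame(group = r$group, channels = r$channels,
                 n_participants = r$n_participants,
                 accuracy = r$accuracy, p_value = r$p_value)))
    manifest$files <- c(manifest$files,
                        write_tsv(tab, file.path(outdir, "mvpa_results.tsv")))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  structure(list(manifest = manifest, state = state), class = "nirs_run")
}

upstream_of <- function(stage) {
  switch(stage, qc = "recordings", preprocess = "qc",
         univariate = "preprocessed", roi = "peaks", mvpa = "peaks",
         "recordings")
}

#' Human-readable run summary
#'
#' Renders a completed run as text: attrition counts per rule, channel
#' activation maps (uncorrected and FDR), ROI ANOVA tables, and the
#' decoding accuracy grid (group x channel subset) with permutation p
#' values. Stages absent from the run are marked not run.
#'
#' @param run a `nirs_run` from [run_pipeline()].
#' @return character vector of report lines, invisibly; also printed.
#' @export
summarize_run <- function(run) {
  st <- run$state
  m <- run$manifest
  lines <- c(sprintf("pipeline run (seed %d, config %s)", m$seed,
                     substr(m$config_hash, 1, 8)),
             "", "== attrition ==")
  for (nm in names(m$counts))
    lines <- c(lines, sprintf("  %s: %s", nm, m$counts[[nm]]))
  for (ex in m$exclusions)
    lines <- c(lines, sprintf("  excluded %s by %s (%s)", ex$participant,
                              ex$rule, ex$detail))
  lines <- c(lines, "", "== channel activation ==")
  if (!is.null(st$channel_maps)) {
    sig <- st$channel_maps[st$channel_maps$chromophore == "hbo2" &
                             st$channel_maps$activation != "null", ]
    if (nrow(sig))
      lines <- c(lines, sprintf("  %s ch%02d: %s (p=%.4f, p_fdr=%.4f)",
                                sig$label, sig$channel, sig$activation,
                                sig$p, sig$p_fdr))
    else lines <- c(lines, "  no active channels")
  } else lines <- c(lines, "  [not run]")
  lines <- c(lines, "", "== ROI ANOVA ==")
  if (!is.null(st$roi_anova)) {
    for (r in names(st$roi_anova)) {
      a <- st$roi_anova[[r]]
      if (is.null(a)) next
      lines <- c(lines, sprintf("  %s:", r),
                 sprintf("    %-28s F(%d,%d)=%.2f p=%.4f pes=%.3f",
                         a$effect, a$df_num, a$df_den, a$F, a$p,
                         a$partial_eta_sq))
    }
  } else lines <- c(lines, "  [not run]")
  lines <- c(lines, "", "== decoding (spoken vs signed) ==")
  if (!is.null(st$mvpa)) {
    for (r in st$mvpa)
      lines <- c(lines, sprintf("  %-12s %-6s n=%2s acc=%.3f p=%.4f",
                                r$group, r$channels,
                                as.character(r$n_participants),
                                r$accuracy, r$p_value))
  } else lines <- c(lines, "  [not run]")
  cat(lines, sep = "\n")
  invisible(lines)
}
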