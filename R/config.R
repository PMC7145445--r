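#' Construct and validate a channel montage
#'
#' The montage describes the optode array: 46 source-detector channels
#' (23 per hemisphere), a 2 cm source-detector separation, two continuous
#' wavelengths (770 and 850 nm) and a 10 Hz sampling rate. All invariants
#' are enforced at construction; violations name the offending field.
#'
#' @param channels data.frame with columns `id`, `source`, `detector`,
#'   `hemisphere` (`"left"`/`"right"`) and `label`.
#' @param separation_cm source-detector separation in cm.
#' @param wavelengths_nm numeric pair of wavelengths in nm.
#' @param sampling_rate_hz sampling rate in Hz.
#' @return an object of class `nirs_montage`.
#' @export
montage <- function(channels, separation_cm = 2,
                    wavelengths_nm = c(770, 850), sampling_rate_hz = 10) {
  channels <- as.data.frame(channels)
  need <- c("id", "source", "detector", "hemisphere", "label")
  missing_cols <- setdiff(need, names(channels))
  if (length(missing_cols))
    stop_field("montage.channels", paste("missing columns:",
                                         paste(missing_cols, collapse = ", ")))
  if (nrow(channels) != 46L)
    stop_field("montage.channels",
               sprintf("expected 46 channels, got %d", nrow(channels)))
  if (anyDuplicated(channels$id))
    stop_field("montage.channels.id", "channel ids must be unique")
  if (!all(channels$hemisphere %in% c("left", "right")))
    stop_field("montage.channels.hemisphere", "must be 'left' or 'right'")
  n_left <- sum(channels$hemisphere == "left")
  if (n_left != 23L)
    stop_field("montage.channels.hemisphere",
               sprintf("expected 23 channels per hemisphere, got %d left / %d right",
                       n_left, 46L - n_left))
  if (!identical(as.numeric(separation_cm), 2))
    stop_field("montage.separation_cm", "must be 2")
  if (!identical(as.numeric(wavelengths_nm), c(770, 850)))
    stop_field("montage.wavelengths_nm", "must be c(770, 850)")
  if (!identical(as.numeric(sampling_rate_hz), 10))
    stop_field("montage.sampling_rate_hz", "must be 10")
  structure(list(channels = channels,
                 separation_cm = as.numeric(separation_cm),
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 sampling_rate_hz = as.numeric(sampling_rate_hz)),
            class = "nirs_montage")
}

#' Construct a region-of-interest channel set
#'
#' Two a-priori ROIs (inferior frontal and posterior temporal), each of
#' eight channels, four per hemisphere, all resolvable in the montage.
#'
#' @param inferior_frontal,posterior_temporal integer channel ids (length 8).
#' @param montage the `nirs_montage` the ids must belong to.
#' @return an object of class `nirs_roi_set`.
#' @export
roi_set <- function(inferior_frontal, posterior_temporal, montage) {
  check_roi <- function(ids, name) {
    ids <- as.integer(ids)
    if (length(ids) != 8L)
      stop_field(name, sprintf("must contain 8 channels, got %d", length(ids)))
    unknown <- setdiff(ids, montage$channels$id)
    if (length(unknown))
      stop_field(name, paste("channels not in montage:",
                             paste(unknown, collapse = ", ")))
    hemi <- montage$channels$hemisphere[match(ids, montage$channels$id)]
    n_left <- sum(hemi == "left")
    if (n_left != 4L)
      stop_field(name, sprintf(
        "must have 4 channels per hemisphere, got %d left / %d right",
        n_left, 8L - n_left))
    ids
  }
  structure(list(
    inferior_frontal = check_roi(inferior_frontal, "roi.inferior_frontal"),
    posterior_temporal = check_roi(posterior_temporal, "roi.posterior_temporal")),
    class = "nirs_roi_set")
}

#' Construct the study design
#'
#' Four experimental conditions (two spoken, two signed languages),
#' 10-s baselines, 9-12 s stimuli, at most 20 experimental trials, and the
#' rule that consecutive experimental trials alternate language modality.
#' Familiarity is mapped per (group, condition); sign-language familiarity
#' is only defined for the bimodal bilingual group.
#'
#' @param conditions character vector of condition names.
#' @param modality_map named character vector, condition -> "spoken"/"signed".
#' @param familiarity_map named list: group -> named character vector,
#'   condition -> "familiar"/"unfamiliar"/"n/a".
#' @param baseline_duration_s baseline trial duration, seconds.
#' @param stimulus_duration_range_s numeric pair (min, max) in seconds.
#' @param max_experimental_trials maximum number of experimental trials.
#' @return an object of class `nirs_design`.
#' @export
study_design <- function(conditions = c("English", "French", "BSL", "LSFB"),
                         modality_map = c(English = "spoken", French = "spoken",
                                          BSL = "signed", LSFB = "signed"),
                         familiarity_map = default_familiarity_map(),
                         baseline_duration_s = 10,
                         stimulus_duration_range_s = c(9, 12),
                         max_experimental_trials = 20) {
  if (!setequal(names(modality_map), conditions))
    stop_field("design.modality_map", "must map exactly the design conditions")
  if (!all(modality_map %in% c("spoken", "signed")))
    stop_field("design.modality_map", "values must be 'spoken' or 'signed'")
  if (!identical(as.numeric(baseline_duration_s), 10))
    stop_field("design.baseline_duration_s", "must be 10")
  r <- as.numeric(stimulus_duration_range_s)
  if (length(r) != 2L || r[1] < 9 - 1e-9 || r[2] > 12 + 1e-9 || r[1] > r[2])
    stop_field("design.stimulus_duration_range_s", "must lie within [9, 12]")
  if (!identical(as.numeric(max_experimental_trials), 20))
    stop_field("design.max_experimental_trials", "must be 20")
  groups <- c("monolingual", "unimodal_bilingual", "bimodal_bilingual")
  if (!setequal(names(familiarity_map), groups))
    stop_field("design.familiarity_map", "must map the three participant groups")
  for (g in groups) {
    fm <- familiarity_map[[g]]
    if (!setequal(names(fm), conditions) ||
        !all(fm %in% c("familiar", "unfamiliar", "n/a")))
      stop_field(paste0("design.familiarity_map.", g),
                 "must map every condition to familiar/unfamiliar/n/a")
  }
  structure(list(conditions = conditions,
                 modality_map = modality_map,
                 familiarity_map = familiarity_map,
                 baseline_duration_s = as.numeric(baseline_duration_s),
                 stimulus_duration_range_s = r,
                 max_experimental_trials = as.integer(max_experimental_trials)),
            class = "nirs_design")
}

#' Default familiarity map
#'
#' English is familiar and French unfamiliar to every group; BSL is familiar
#' only to bimodal bilinguals (deaf-mother households); sign-language
#' familiarity is undefined (`"n/a"`) for the other two groups, so
#' familiarity contrasts in the signed modality are only formed for the
#' bimodal group.
#'
#' @return named list: group -> condition -> familiarity.
#' @export
default_familiarity_map <- function() {
  spoken_only <- c(English = "familiar", French = "unfamiliar",
                   BSL = "n/a", LSFB = "n/a")
  list(monolingual = spoken_only,
       unimodal_bilingual = spoken_only,
       bimodal_bilingual = c(English = "familiar", French = "unfamiliar",
                             BSL = "familiar", LSFB = "unfamiliar"))
}

config_as_list <- function(config) {
  list(
    montage = list(
      separation_cm = config$montage$separation_cm,
      wavelengths_nm = config$montage$wavelengths_nm,
      sampling_rate_hz = config$montage$sampling_rate_hz,
      channels = lapply(seq_len(nrow(config$montage$channels)), function(i) {
        ch <- config$montage$channels[i, ]
        list(id = as.integer(ch$id), source = as.integer(ch$source),
             detector = as.integer(ch$detector),
             hemisphere = ch$hemisphere, label = ch$label)
      })),
    rois = list(inferior_frontal = as.integer(config$rois$inferior_frontal),
                posterior_temporal = as.integer(config$rois$posterior_temporal)),
    design = list(
      conditions = config$design$conditions,
      modality_map = as.list(config$design$modality_map),
      familiarity_map = lapply(config$design$familiarity_map, as.list),
      baseline_duration_s = config$design$baseline_duration_s,
      stimulus_duration_range_s = config$design$stimulus_duration_range_s,
      max_experimental_trials = config$design$max_experimental_trials),
    qc = config$qc, preprocess = config$preprocess,
    stats = config$stats, mvpa = config$mvpa)
}

#' Load an analysis configuration
#'
#' Reads a YAML configuration defining the montage, ROI channel sets, study
#' design and per-stage parameters, and validates every structural
#' invariant. The shipped default (`default_config()`) reproduces the study
#' constants: 46 channels at 2 cm separation, 770/850 nm, 10 Hz, 8-channel
#' ROIs with hemispheric balance, 10-s baselines, at most 20 trials.
#'
#' @param path path to a YAML configuration file.
#' @return a list of class `nirs_config` with elements `montage`, `rois`,
#'   `design`, `qc`, `preprocess`, `stats`, `mvpa`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_field("config", paste("file not found:", path))
  raw <- yaml::read_yaml(path)
  for (section in c("montage", "rois", "design"))
    if (is.null(raw[[section]]))
      stop_field("config", paste("missing section:", section))
  ch <- do.call(rbind, lapply(raw$montage$channels, function(x)
    data.frame(id = as.integer(x$id), source = as.integer(x$source),
               detector = as.integer(x$detector),
               hemisphere = x$hemisphere, label = x$label)))
  mon <- montage(ch,
                 separation_cm = raw$montage$separation_cm,
                 wavelengths_nm = unlist(raw$montage$wavelengths_nm),
                 sampling_rate_hz = raw$montage$sampling_rate_hz)
  rois <- roi_set(unlist(raw$rois$inferior_frontal),
                  unlist(raw$rois$posterior_temporal), mon)
  des <- study_design(
    conditions = unlist(raw$design$conditions),
    modality_map = unlist(raw$design$modality_map),
    familiarity_map = lapply(raw$design$familiarity_map, unlist),
    baseline_duration_s = raw$design$baseline_duration_s,
    stimulus_duration_range_s = unlist(raw$design$stimulus_duration_range_s),
    max_experimental_trials = raw$design$max_experimental_trials)
  structure(list(montage = mon, rois = rois, design = des,
                 qc = raw$qc, preprocess = raw$preprocess,
                 stats = raw$stats, mvpa = raw$mvpa),
            class = "nirs_config")
}

#' Save a configuration to YAML
#'
#' Round-trips through [load_config()]: saving and re-loading yields an
#' equivalent configuration object.
#'
#' @param config a `nirs_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

#' Path to (or load of) the shipped default configuration
#'
#' @param load if `TRUE` (default) return the parsed `nirs_config`;
#'   otherwise return the file path.
#' @return a `nirs_config` or a path.
#' @export
default_config <- function(load = TRUE) {
  path <- system.file("extdata", "default_config.yaml", package = "babynirs",
                      mustWork = TRUE)
  if (load) load_config(path) else path
}
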