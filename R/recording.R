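#' Construct a participant record
#'
#' @param id participant identifier (character or coercible).
#' @param group one of `"monolingual"`, `"unimodal_bilingual"`,
#'   `"bimodal_bilingual"`.
#' @param age_months age in months.
#' @return a list of class `nirs_participant`.
#' @export
participant <- function(id, group, age_months = 6) {
  groups <- c("monolingual", "unimodal_bilingual", "bimodal_bilingual")
  if (!group %in% groups)
    stop_field("participant.group",
               paste("must be one of:", paste(groups, collapse = ", ")))
  structure(list(id = as.character(id), group = group,
                 age_months = as.numeric(age_months)),
            class = "nirs_participant")
}

#' Construct a raw dual-wavelength recording
#'
#' Per-channel optical intensity at both wavelengths with stimulus event
#' markers and per-trial looking proportions.
#'
#' @param participant a `nirs_participant`.
#' @param intensity numeric array, channel x wavelength x time,
#'   non-negative optical intensity.
#' @param events data.frame with `onset` (seconds from recording start,
#'   strictly increasing) and `condition`.
#' @param looking_proportion numeric vector, one value in \[0, 1\] per event
#'   (NA allowed; such trials are later dropped with a warning).
#' @param sampling_rate_hz sampling rate in Hz.
#' @return an object of class `nirs_recording`.
#' @export
raw_recording <- function(participant, intensity, events, looking_proportion,
                          sampling_rate_hz = 10) {
  if (length(dim(intensity)) != 3L)
    stop_field("recording.intensity", "must be a channel x wavelength x time array")
  structure(list(participant = participant,
                 intensity = intensity,
                 events = as.data.frame(events),
                 looking_proportion = as.numeric(looking_proportion),
                 sampling_rate_hz = as.numeric(sampling_rate_hz)),
            class = "nirs_recording")
}

#' Validate a recording against the study design
#'
#' Report-based validation: every breach of the recording invariants is
#' listed; an empty report means the recording conforms. Checked rules:
#' non-negative intensity; one looking proportion per event; strictly
#' increasing onsets; trial count within the design maximum; consecutive
#' experimental trials alternate spoken/signed modality; the recording
#' covers the last event plus 20 s.
#'
#' @param rec a `nirs_recording`.
#' @param design a `nirs_design`.
#' @return data.frame with columns `field` and `message` (zero rows if valid).
#' @export
validate_recording <- function(rec, design) {
  breaches <- list()
  add <- function(field, message)
    breaches[[length(breaches) + 1L]] <<- data.frame(field = field,
                                                     message = message)
  if (any(rec$intensity < 0, na.rm = TRUE))
    add("intensity", "negative optical intensity values present")
  n_ev <- nrow(rec$events)
  if (length(rec$looking_proportion) != n_ev)
    add("looking_proportion",
        sprintf("expected %d values (one per event), got %d",
                n_ev, length(rec$looking_proportion)))
  ok_lp <- rec$looking_proportion[!is.na(rec$looking_proportion)]
  if (any(ok_lp < 0 | ok_lp > 1))
    add("looking_proportion", "values outside [0, 1]")
  if (n_ev > 1 && any(diff(rec$events$onset) <= 0))
    add("events.onset", "onsets not strictly increasing")
  if (n_ev > design$max_experimental_trials)
    add("events", sprintf("%d experimental trials exceed the maximum of %d",
                          n_ev, design$max_experimental_trials))
  unknown <- setdiff(rec$events$condition, design$conditions)
  if (length(unknown))
    add("events.condition", paste("unknown conditions:",
                                  paste(unique(unknown), collapse = ", ")))
  if (n_ev > 1 && !length(unknown)) {
    mods <- design$modality_map[as.character(rec$events$condition)]
    if (any(mods[-1] == mods[-n_ev]))
      add("events", "consecutive experimental trials do not alternate modality")
  }
  if (n_ev > 0) {
    dur_s <- dim(rec$intensity)[3] / rec$sampling_rate_hz
    need <- max(rec$events$onset) + 20
    if (dur_s < need)
      add("intensity", sprintf(
        "recording lasts %.1f s but must cover last event + 20 s (%.1f s)",
        dur_s, need))
  }
  if (length(breaches)) do.call(rbind, breaches)
  else data.frame(field = character(), message = character())
}

#' Write a recording as plain text
#'
#' One wide TSV per wavelength (rows = samples, columns = channels) plus a
#' JSON sidecar holding participant metadata, events and looking
#' proportions. [read_recording()] is its exact inverse.
#'
#' @param rec a `nirs_recording`.
#' @param dir output directory (created if needed).
#' @param stem file stem; defaults to the participant id.
#' @return the sidecar path, invisibly.
#' @export
write_recording <- function(rec, dir, stem = rec$participant$id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wl <- c(770, 850)
  for (w in 1:2) {
    mat <- t(rec$intensity[, w, ])  # samples x channels
    colnames(mat) <- paste0("ch", seq_len(dim(rec$intensity)[1]))
    utils::write.table(
      format(mat, digits = 10, trim = TRUE, scientific = FALSE),
      file.path(dir, sprintf("%s_wl%d.tsv", stem, wl[w])),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sidecar <- list(participant = unclass(rec$participant),
                  sampling_rate_hz = rec$sampling_rate_hz,
                  events = rec$events,
                  looking_proportion = rec$looking_proportion)
  path <- file.path(dir, paste0(stem, "_events.json"))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir directory holding the TSV/JSON files.
#' @param stem file stem (the participant id used at write time).
#' @return a `nirs_recording`.
#' @export
read_recording <- function(dir, stem) {
  sidecar <- jsonlite::read_json(file.path(dir, paste0(stem, "_events.json")),
                                 simplifyVector = TRUE)
  mats <- lapply(c(770, 850), function(wl)
    as.matrix(utils::read.delim(file.path(dir, sprintf("%s_wl%d.tsv", stem, wl)))))
  n_ch <- ncol(mats[[1]]); n_t <- nrow(mats[[1]])
  intensity <- array(NA_real_, c(n_ch, 2, n_t))
  for (w in 1:2) intensity[, w, ] <- t(mats[[w]])
  raw_recording(
    participant = participant(sidecar$participant$id, sidecar$participant$group,
                              sidecar$participant$age_months),
    intensity = intensity,
    events = as.data.frame(sidecar$events),
    looking_proportion = sidecar$looking_proportion,
    sampling_rate_hz = sidecar$sampling_rate_hz)
}
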