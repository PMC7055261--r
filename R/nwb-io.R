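#' Write a session to an NWB-style HDF5 file
#'
#' Serializes a `session_bundle` into an HDF5 file laid out as an NWB:N 2.x
#' session of the human single-neuron recognition-memory schema:
#'
#' * `/acquisition/events`: TTL codes as text annotations (`data`, the
#'   integer-parseable string dialect produced by MATLAB's `num2str`) plus
#'   `timestamps`; the group's `description` attribute lists the code
#'   semantics.
#' * `/acquisition/experiment_ids`: block labels (`data`, `timestamps`).
#' * `/intervals/trials`: columns `id`, `start_time`, `stop_time`,
#'   `delay1_time`, `response_time`, `delay2_time`, `new_old_labels_recog`
#'   (text `"0"`/`"1"`/`"NA"`), `response_value`, `category_name`,
#'   `stimCategory`, `stim_phase`.
#' * `/units`: `id`, ragged `spike_times` + `spike_times_index`,
#'   `waveform_mean_encoding` / `waveform_mean_recognition` (samples x units,
#'   microvolts, `sampling_rate` attribute in Hz), `origClusterID`, `SNR`,
#'   `IsolDist`, `electrodes` (0-based row references).
#' * `/general/extracellular_ephys/electrodes`: `id`, `location`, `x`, `y`,
#'   `z`, `filtering`, `origChannel`, `group_name`; electrode-group subgroup
#'   carrying the device reference; `/general/devices/<name>`;
#'   `/general/subject`.
#' * `/stimulus/presentation/stimuli_learn_x` and `stimuli_recog_x`
#'   (x = 1..n in presentation order), each image stored as an integer matrix
#'   with a `stimulus_id` attribute.
#' * root: `identifier`, `session_description`, `session_start_time` — the
#'   day is always the first of the month (patient-privacy convention).
#'
#' File-level column names follow the released-dataset spelling
#' (`new_old_labels_recog`, `stimCategory`, `origClusterID`, `IsolDist`) even
#' where the in-memory names differ.
#'
#' @param s A valid `session_bundle` ([validate_session()] must return no
#'   violations).
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @seealso [read_session_nwb()]
#' @export
write_session_nwb <- function(s, path) {
  v <- validate_session(s)
  if (length(v)) {
    stop("refusing to write an invalid session:\n  ",
         paste(v, collapse = "\n  "))
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  h5w <- function(obj, name) rhdf5::h5write(obj, path, name)

  ## root metadata
  h5w(s$session_id, "identifier")
  h5w("new/old recognition memory task, human MTL single-neuron recording",
      "session_description")
  h5w(sprintf("%04d-%02d-01T00:00:00", s$start_year, s$start_month),
      "session_start_time")
  write_h5_attr(path, "/", "nwb_version", "2.0")

  ## acquisition
  rhdf5::h5createGroup(path, "acquisition")
  rhdf5::h5createGroup(path, "acquisition/events")
  h5w(as.character(s$events$code), "acquisition/events/data")
  h5w(s$events$time_s, "acquisition/events/timestamps")
  cm <- code_maps()
  write_h5_attr(path, "acquisition/events", "description",
                paste(sprintf("%s=%s", names(cm$ttl_codes), cm$ttl_codes),
                      collapse = "; "))
  rhdf5::h5createGroup(path, "acquisition/experiment_ids")
  h5w(as.integer(s$tags$xid), "acquisition/experiment_ids/data")
  h5w(s$tags$time_s, "acquisition/experiment_ids/timestamps")
  write_h5_attr(path, "acquisition/experiment_ids", "description",
                "learning: 80/83/88; recognition: 81/84/89")

  ## intervals/trials
  rhdf5::h5createGroup(path, "intervals")
  rhdf5::h5createGroup(path, "intervals/trials")
  tr <- s$trials
  h5w(as.integer(tr$trial_id - 1L), "intervals/trials/id")
  h5w(tr$start_time, "intervals/trials/start_time")
  h5w(tr$stop_time, "intervals/trials/stop_time")
  h5w(tr$delay1_time, "intervals/trials/delay1_time")
  h5w(tr$response_time, "intervals/trials/response_time")
  h5w(tr$delay2_time, "intervals/trials/delay2_time")
  h5w(ifelse(is.na(tr$new_old_label), "NA", as.character(tr$new_old_label)),
      "intervals/trials/new_old_labels_recog")
  h5w(as.integer(tr$response_value), "intervals/trials/response_value")
  h5w(tr$category_name, "intervals/trials/category_name")
  h5w(as.integer(tr$stim_category), "intervals/trials/stimCategory")
  h5w(tr$phase, "intervals/trials/stim_phase")

  ## units
  rhdf5::h5createGroup(path, "units")
  ragged <- build_ragged(s$units$spike_times)
  h5w(as.integer(s$units$unit_id - 1L), "units/id")
  h5w(ragged$data, "units/spike_times")
  h5w(ragged$index, "units/spike_times_index")
  wf_e <- do.call(cbind, s$units$waveform_mean_encoding)
  wf_r <- do.call(cbind, s$units$waveform_mean_recognition)
  h5w(wf_e, "units/waveform_mean_encoding")
  h5w(wf_r, "units/waveform_mean_recognition")
  write_h5_attr(path, "units/waveform_mean_encoding", "sampling_rate",
                s$waveform_rate_hz)
  write_h5_attr(path, "units/waveform_mean_recognition", "sampling_rate",
                s$waveform_rate_hz)
  write_h5_attr(path, "units/waveform_mean_encoding", "unit", "microvolts")
  write_h5_attr(path, "units/waveform_mean_recognition", "unit", "microvolts")
  h5w(as.integer(s$units$orig_cluster_id), "units/origClusterID")
  h5w(s$units$snr, "units/SNR")
  h5w(s$units$isol_dist, "units/IsolDist")
  h5w(as.integer(s$units$electrode_index - 1L), "units/electrodes")

  ## general
  rhdf5::h5createGroup(path, "general")
  rhdf5::h5createGroup(path, "general/devices")
  for (dev in unique(s$electrodes$device_name)) {
    rhdf5::h5createGroup(path, paste0("general/devices/", dev))
    write_h5_attr(path, paste0("general/devices/", dev), "description",
                  "recording system")
  }
  rhdf5::h5createGroup(path, "general/extracellular_ephys")
  eg <- unique(s$electrodes[, c("group_name", "device_name")])
  for (i in seq_len(nrow(eg))) {
    g <- paste0("general/extracellular_ephys/", eg$group_name[i])
    rhdf5::h5createGroup(path, g)
    h5w(eg$device_name[i], paste0(g, "/device"))
    write_h5_attr(path, g, "description", "microwires of a hybrid depth electrode")
  }
  el <- "general/extracellular_ephys/electrodes"
  rhdf5::h5createGroup(path, el)
  h5w(as.integer(s$electrodes$id), paste0(el, "/id"))
  h5w(s$electrodes$location, paste0(el, "/location"))
  h5w(s$electrodes$x, paste0(el, "/x"))
  h5w(s$electrodes$y, paste0(el, "/y"))
  h5w(s$electrodes$z, paste0(el, "/z"))
  h5w(s$electrodes$filtering, paste0(el, "/filtering"))
  h5w(as.integer(s$electrodes$orig_channel), paste0(el, "/origChannel"))
  h5w(s$electrodes$group_name, paste0(el, "/group_name"))

  rhdf5::h5createGroup(path, "general/subject")
  h5w(s$subject$subject_id, "general/subject/subject_id")
  h5w(as.character(s$subject$age), "general/subject/age")
  h5w(s$subject$sex, "general/subject/sex")
  h5w(s$subject$species, "general/subject/species")
  h5w(s$subject$description, "general/subject/description")

  ## stimuli
  rhdf5::h5createGroup(path, "stimulus")
  rhdf5::h5createGroup(path, "stimulus/presentation")
  write_stimuli(s, path, "learning", "stimuli_learn_")
  write_stimuli(s, path, "recognition", "stimuli_recog_")

  invisible(path)
}

write_stimuli <- function(s, path, phase, prefix) {
  ids <- s$trials$stimulus_id[s$trials$phase == phase]
  for (k in seq_along(ids)) {
    name <- paste0("stimulus/presentation/", prefix, k)
    rhdf5::h5write(s$stimuli[[ids[k]]], path, name)
    write_h5_attr(path, name, "stimulus_id", ids[k])
  }
}

# write one attribute on a group/dataset of an existing HDF5 file
write_h5_attr <- function(path, objname, attrname, value) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, objname)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE)
  rhdf5::h5writeAttribute(value, oid, attrname)
  invisible(NULL)
}

#' Read an NWB-style session file
#'
#' Inverse of [write_session_nwb()]. The reader is deliberately tolerant of
#' dialect differences in released datasets: event codes and numeric columns
#' may be stored as integers, doubles, or whitespace-padded numeric text (the
#' MATLAB `num2str` dialect); the stimuli group may be absent (trial
#' `stimulus_id`s are then `NA`). The task variant is recovered from the
#' experiment-ID stream.
#'
#' @param path Path to an NWB/HDF5 session file.
#' @return A `session_bundle` passing [validate_session()].
#' @export
read_session_nwb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  paths <- file.path(contents$group, contents$name)
  paths <- sub("^//", "/", paths)
  need <- c("/units", "/intervals/trials", "/acquisition/events")
  for (g in need) {
    if (!g %in% paths) {
      stop("NWB load error: required group '", sub("^/", "", g),
           "' is missing from ", path)
    }
  }
  h5r <- function(name) rhdf5::h5read(path, name)
  as_num <- function(x) as.numeric(trimws(as.character(x)))
  as_int <- function(x) as.integer(round(as_num(x)))

  events <- data.frame(time_s = as.numeric(h5r("acquisition/events/timestamps")),
                       code = as_int(h5r("acquisition/events/data")))
  tags <- data.frame(
    time_s = as.numeric(h5r("acquisition/experiment_ids/timestamps")),
    xid = as_int(h5r("acquisition/experiment_ids/data")))
  variant <- variant_from_ids(tags$xid)

  lab_raw <- as.character(h5r("intervals/trials/new_old_labels_recog"))
  trials <- data.frame(
    trial_id = as_int(h5r("intervals/trials/id")) + 1L,
    phase = as.character(h5r("intervals/trials/stim_phase")),
    start_time = as.numeric(h5r("intervals/trials/start_time")),
    stop_time = as.numeric(h5r("intervals/trials/stop_time")),
    delay1_time = as.numeric(h5r("intervals/trials/delay1_time")),
    response_time = as.numeric(h5r("intervals/trials/response_time")),
    delay2_time = as.numeric(h5r("intervals/trials/delay2_time")),
    response_value = as_int(h5r("intervals/trials/response_value")),
    category_name = as.character(h5r("intervals/trials/category_name")),
    stim_category = as_int(h5r("intervals/trials/stimCategory")),
    new_old_label = suppressWarnings(as_int(ifelse(trimws(lab_raw) == "NA",
                                                   NA, lab_raw))),
    stimulus_id = NA_character_)

  ragged <- structure(list(data = as.numeric(h5r("units/spike_times")),
                           index = as_int(h5r("units/spike_times_index"))),
                      class = "ragged_pair")
  wf_e <- h5r("units/waveform_mean_encoding")
  wf_r <- h5r("units/waveform_mean_recognition")
  n_units <- length(ragged$index)
  units <- data.frame(unit_id = as_int(h5r("units/id")) + 1L,
                      electrode_index = as_int(h5r("units/electrodes")) + 1L,
                      orig_cluster_id = as_int(h5r("units/origClusterID")),
                      snr = as.numeric(h5r("units/SNR")),
                      isol_dist = as.numeric(h5r("units/IsolDist")))
  units$spike_times <- lapply(seq_len(n_units), function(i) {
    slice_ragged(ragged, i)
  })
  units$waveform_mean_encoding <- lapply(seq_len(n_units), function(i) wf_e[, i])
  units$waveform_mean_recognition <- lapply(seq_len(n_units), function(i) wf_r[, i])
  units$snr <- as.numeric(h5r("units/SNR"))
  units$isol_dist <- as.numeric(h5r("units/IsolDist"))
  units <- units[, c("unit_id", "electrode_index", "orig_cluster_id",
                     "spike_times", "waveform_mean_encoding",
                     "waveform_mean_recognition", "snr", "isol_dist")]
  wf_attr <- rhdf5::h5readAttributes(path, "units/waveform_mean_encoding")
  wf_rate <- as.numeric(wf_attr$sampling_rate %||% 1e5)

  el <- "general/extracellular_ephys/electrodes"
  group_names <- as.character(h5r(paste0(el, "/group_name")))
  devices <- vapply(unique(group_names), function(g) {
    as.character(h5r(paste0("general/extracellular_ephys/", g, "/device")))
  }, character(1))
  electrodes <- data.frame(
    id = as_int(h5r(paste0(el, "/id"))),
    location = as.character(h5r(paste0(el, "/location"))),
    x = as.numeric(h5r(paste0(el, "/x"))),
    y = as.numeric(h5r(paste0(el, "/y"))),
    z = as.numeric(h5r(paste0(el, "/z"))),
    filtering = as.character(h5r(paste0(el, "/filtering"))),
    orig_channel = as_int(h5r(paste0(el, "/origChannel"))),
    group_name = group_names,
    device_name = unname(devices[group_names]))

  subject <- list(
    subject_id = as.character(h5r("general/subject/subject_id")),
    age = as_int(h5r("general/subject/age")),
    sex = as.character(h5r("general/subject/sex")),
    species = as.character(h5r("general/subject/species")),
    description = as.character(h5r("general/subject/description")))

  ## stimuli (tolerated absent)
  stimuli <- list()
  stim_paths <- grep("^/stimulus/presentation/", paths, value = TRUE)
  if (length(stim_paths)) {
    for (phase in c("learning", "recognition")) {
      prefix <- if (phase == "learning") "stimuli_learn_" else "stimuli_recog_"
      rows <- which(trials$phase == phase)
      for (k in seq_along(rows)) {
        name <- paste0("stimulus/presentation/", prefix, k)
        if (!paste0("/", name) %in% paths) next
        img <- h5r(name)
        storage.mode(img) <- "integer"
        at <- rhdf5::h5readAttributes(path, name)
        sid <- as.character(at$stimulus_id %||% paste0(prefix, k))
        trials$stimulus_id[rows[k]] <- sid
        stimuli[[sid]] <- img
      }
    }
  }

  start <- as.character(h5r("session_start_time"))
  yr <- as.integer(substr(start, 1, 4))
  mo <- as.integer(substr(start, 6, 7))

  session_bundle(session_id = as.character(h5r("identifier")),
                 variant = variant, subject = subject,
                 electrodes = electrodes, units = units,
                 events = events, tags = tags, trials = trials,
                 stimuli = stimuli, start_year = yr, start_month = mo,
                 waveform_rate_hz = wf_rate)
}
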