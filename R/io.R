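# Trial-bundle file formats (delimited UTF-8 text) and the pipeline driver.
#
# Per trial: a force file (time_s, force_n, target_n), an EMG file (time_s
# plus <muscle>_ch<k> columns) and a spikes file (unit_id, muscle,
# spike_time_s, accuracy). A JSON manifest ties the bundles of a cohort
# together with participant/group/level/repeat/seed metadata.

check_monotone_time <- function(time, path) {
  bad <- which(diff(time) <= 0)
  if (length(bad)) {
    stop_invalid(sprintf("%s: time column not strictly increasing at line %d",
                         path, bad[1] + 2L))  # +1 header, +1 diff offset
  }
}

check_no_na <- function(df, path) {
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) {
    stop_invalid(sprintf("%s: missing/non-numeric value at line %d",
                         path, bad[1] + 1L))
  }
}

check_header <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_invalid(sprintf("%s: malformed header, missing column(s) %s",
                         path, paste(miss, collapse = ", ")))
  }
}

#' Write / read a force trace file
#'
#' Delimited text with header `time_s, force_n, target_n`. Round-trips to
#' within 1e-6 N / 1e-6 s.
#'
#' @param trace a [force_trace()].
#' @param path file path.
#' @param level,ramp_s,hold_s,pre_s trial metadata not carried by the file
#'   itself (normally supplied from the cohort manifest).
#' @return `write_force` returns `path` invisibly; `read_force` returns a
#'   [force_trace()].
#' @export
write_force <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  n <- length(trace$samples)
  dt <- data.table::data.table(
    time_s = round((seq_len(n) - 1) / trace$fs, 9),
    force_n = round(trace$samples, 7),
    target_n = round(trace$target, 7)
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_force
#' @export
read_force <- function(path, level = NA_real_, ramp_s = 2, hold_s = 10,
                       pre_s = 0.5) {
  df <- data.table::fread(path, data.table = FALSE)
  check_header(df, c("time_s", "force_n", "target_n"), path)
  check_no_na(df, path)
  check_monotone_time(df$time_s, path)
  fs <- 1 / stats::median(diff(df$time_s))
  force_trace(df$force_n, fs = round(fs, 6), target = df$target_n[1],
              level = level, ramp_s = ramp_s, hold_s = hold_s, pre_s = pre_s)
}

#' Write / read a multi-channel EMG file
#'
#' Delimited text with a `time_s` column followed by one column per muscle
#' channel, named `<muscle>_ch<k>`.
#'
#' @param emg named list of per-muscle channel matrices (columns = channels).
#' @param fs sampling rate, Hz.
#' @param path file path.
#' @return `write_emg` returns `path` invisibly; `read_emg` returns
#'   `list(fs = , muscles = list of channel matrices)`.
#' @export
write_emg <- function(emg, fs, path) {
  n <- nrow(emg[[1]])
  cols <- list(time_s = round((seq_len(n) - 1) / fs, 9))
  for (m in names(emg)) {
    mat <- emg[[m]]
    for (ch in seq_len(ncol(mat))) {
      cols[[sprintf("%s_ch%d", m, ch)]] <- round(mat[, ch], 9)
    }
  }
  data.table::fwrite(data.table::as.data.table(cols), path)
  invisible(path)
}

#' @rdname write_emg
#' @export
read_emg <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  check_header(df, "time_s", path)
  check_no_na(df, path)
  check_monotone_time(df$time_s, path)
  chan <- grep("^(.+)_ch[0-9]+$", names(df), value = TRUE)
  if (!length(chan)) stop_invalid(path, ": no <muscle>_ch<k> columns found")
  muscles <- unique(sub("_ch[0-9]+$", "", chan))
  out <- lapply(muscles, function(m) {
    cc <- sort(grep(sprintf("^%s_ch[0-9]+$", m), names(df), value = TRUE))
    mat <- as.matrix(df[, cc, drop = FALSE])
    colnames(mat) <- sub(sprintf("^%s_", m), "", cc)
    mat
  })
  names(out) <- muscles
  list(fs = round(1 / stats::median(diff(df$time_s)), 6), muscles = out)
}

#' Write / read a spike-train table
#'
#' Delimited text with columns `unit_id, muscle, spike_time_s, accuracy`.
#' Spike times must be strictly increasing within each unit and accuracy
#' must lie in `[0, 100]`.
#'
#' @param trains list of [spike_train()]s (may be nested per muscle).
#' @param path file path.
#' @return `write_spikes` returns `path` invisibly; `read_spikes` returns a
#'   flat list of [spike_train()]s.
#' @export
write_spikes <- function(trains, path) {
  if (length(trains) && !inherits(trains[[1]], "spike_train")) {
    trains <- unlist(trains, recursive = FALSE)
  }
  rows <- lapply(trains, function(tr) {
    if (length(tr$times) == 0L) return(NULL)
    data.frame(unit_id = tr$unit_id, muscle = tr$muscle,
               spike_time_s = round(tr$times, 7),
               accuracy = round(tr$accuracy, 4))
  })
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  check_header(df, c("unit_id", "muscle", "spike_time_s", "accuracy"), path)
  check_no_na(df, path)
  bad <- which(df$accuracy < 0 | df$accuracy > 100)
  if (length(bad)) {
    stop_invalid(sprintf("%s: accuracy outside [0, 100] at line %d",
                         path, bad[1] + 1L))
  }
  out <- lapply(split(df, df$unit_id), function(d) {
    bad_t <- which(diff(d$spike_time_s) <= 0)
    if (length(bad_t)) {
      stop_invalid(sprintf(
        "%s: spike times for unit %s not strictly increasing",
        path, d$unit_id[1]))
    }
    spike_train(d$spike_time_s, unit_id = d$unit_id[1],
                muscle = d$muscle[1], accuracy = d$accuracy[1])
  })
  unname(out)
}

# Write one trial's three files; returns their paths.
write_trial_bundle <- function(trial, dir, prefix) {
  paths <- list(
    force = file.path(dir, paste0(prefix, "_force.csv")),
    emg = file.path(dir, paste0(prefix, "_emg.csv")),
    spikes = file.path(dir, paste0(prefix, "_spikes.csv"))
  )
  write_force(trial$force, paths$force)
  write_emg(trial$emg, trial$emg_fs, paths$emg)
  write_spikes(trial$spikes, paths$spikes)
  lapply(paths, normalizePath)
}

#' Read one trial bundle back from a manifest row
#'
#' @param row one row of a cohort manifest (data frame with `force_file`,
#'   `emg_file`, `spikes_file`, `level` columns).
#' @param protocol the [protocol_spec()] used to generate the cohort.
#' @return a list resembling a `synthetic_trial` (force, emg, spikes).
#' @export
read_trial_bundle <- function(row, protocol = protocol_spec()) {
  force <- read_force(row$force_file, level = row$level,
                      ramp_s = protocol$ramp_s, hold_s = protocol$hold_s,
                      pre_s = protocol$pre_s)
  emg <- read_emg(row$emg_file)
  spikes <- read_spikes(row$spikes_file)
  by_muscle <- split(spikes, vapply(spikes, `[[`, character(1), "muscle"))
  list(level = row$level, force = force,
       emg = emg$muscles, emg_fs = emg$fs,
       spikes = by_muscle, protocol = protocol)
}
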