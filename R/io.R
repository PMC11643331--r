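#' Write a partitioned design as delimited text with a JSON sidecar
#'
#' One row per trial: `run`, `trial_index`, `onset_s`, `duration_s`,
#' `type_role`, `category`, `exemplar_id`, `isi_s`, `phase`. The sidecar
#' records the seed, timing configuration, and efficiency score.
#'
#' @param runs list of run data frames from [partition_runs()].
#' @param path output table path (`.tsv`); the sidecar is written next to it
#'   as `<path>.json`.
#' @param seed,efficiency recorded in the sidecar.
#' @param cfg the [timing_config()] used.
#' @export
write_design <- function(runs, path, seed = NA, efficiency = NA,
                         cfg = timing_config()) {
  tab <- do.call(rbind, lapply(runs, function(r) {
    data.frame(run = attr(r, "run"),
               trial_index = seq_len(nrow(r)),
               onset_s = r$onset_s, duration_s = r$duration_s,
               type_role = r$role, category = r$category,
               exemplar_id = r$exemplar_id, isi_s = r$isi_s,
               phase = r$phase, stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- list(seed = seed, efficiency = efficiency,
                  run_durations_s = vapply(runs, attr, numeric(1),
                                           "duration_s"),
                  timing = unclass(cfg))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and write arrangement logs
#'
#' Delimited text, one row per placed stimulus: `task`, `participant`,
#' `trial_index`, `stimulus_id`, `x_px`, `y_px`.
#'
#' @param trials list of `arrangement_trial`s.
#' @param path file path.
#' @export
write_arrangement_log <- function(trials, path) {
  df <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(task = tr$task, participant = tr$participant,
               trial_index = tr$trial_index,
               stimulus_id = rownames(tr$coords),
               x_px = tr$coords[, 1], y_px = tr$coords[, 2],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_arrangement_log
#' @export
read_arrangement_log <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  keys <- unique(df[, c("task", "participant", "trial_index")])
  lapply(seq_len(nrow(keys)), function(k) {
    rows <- df[df$task == keys$task[k] & df$participant == keys$participant[k] &
               df$trial_index == keys$trial_index[k], , drop = FALSE]
    coords <- as.matrix(rows[, c("x_px", "y_px")])
    rownames(coords) <- rows$stimulus_id
    structure(list(task = keys$task[k], participant = keys$participant[k],
                   trial_index = keys$trial_index[k],
                   subset = rows$stimulus_id, coords = coords),
              class = "arrangement_trial")
  })
}

#' Read and write gaze logs
#'
#' Delimited text, one row per sample: `participant`, `block`,
#' `stimulus_id`, `t_ms`, `x_px`, `y_px`, `valid`.
#'
#' @param trajectories list of `gaze_trajectory`s.
#' @param path file path.
#' @export
write_gaze_log <- function(trajectories, path) {
  df <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(participant = tr$participant, block = tr$block,
               stimulus_id = tr$stimulus_id, tr$samples,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_log
#' @export
read_gaze_log <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  keys <- unique(df[, c("participant", "block", "stimulus_id")])
  lapply(seq_len(nrow(keys)), function(k) {
    rows <- df[df$participant == keys$participant[k] &
               df$block == keys$block[k] &
               df$stimulus_id == keys$stimulus_id[k], , drop = FALSE]
    structure(list(participant = keys$participant[k], block = keys$block[k],
                   stimulus_id = keys$stimulus_id[k],
                   samples = data.frame(t_ms = rows$t_ms, x_px = rows$x_px,
                                        y_px = rows$y_px,
                                        valid = as.logical(rows$valid))),
              class = "gaze_trajectory")
  })
}

#' Read and write condition-by-unit pattern tables
#'
#' Delimited text with stimulus ids in the first column and one column per
#' unit.
#'
#' @param patterns condition x unit matrix with stimulus rownames.
#' @param path file path.
#' @export
write_pattern_table <- function(patterns, path) {
  df <- data.frame(stimulus_id = rownames(patterns), patterns,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pattern_table
#' @export
read_pattern_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
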