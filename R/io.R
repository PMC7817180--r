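#' Assemble a SessionBundle from tables
#'
#' Low-level constructor used by the readers and simulators; validates
#' cross-references and invariants.
#'
#' @param trains data.frame in the wide trains schema (see [writeSession()]).
#' @param spikes data.frame with `unit_id`, `train_id`, `t_s`.
#' @param units data.frame with `unit_id`, `depth_um`, `waveform_width_ms`.
#' @param metadata named list; `pre_window_s`/`post_window_s` default to 0.5 s.
#' @return a [SessionBundle-class].
#' @export
sessionBundle <- function(trains, spikes, units, metadata = list()) {
  metadata$pre_window_s <- metadata$pre_window_s %||% 0.5
  metadata$post_window_s <- metadata$post_window_s %||% 0.5
  if (!"layer" %in% names(units))
    units$layer <- vapply(units$depth_um, assignLayer, character(1))
  if (!"cell_class" %in% names(units))
    units$cell_class <- vapply(units$waveform_width_ms, classifyWaveform,
                               character(1))
  spikes <- spikes[order(match(spikes$unit_id, units$unit_id),
                         match(spikes$train_id, trains$train_id),
                         spikes$t_s), , drop = FALSE]
  rownames(spikes) <- NULL
  new("SessionBundle", trains = trains, spikes = spikes, units = units,
      metadata = metadata)
}

#' Convert DeflectionTrain objects to / from the wide trains table
#'
#' @param trains a list of [DeflectionTrain-class] objects.
#' @return `trainsToTable`: a data.frame, one row per train;
#'   `deflectionTrain`: the [DeflectionTrain-class] for one row.
#' @export
trainsToTable <- function(trains) {
  n <- max(vapply(trains, function(tr) length(tr@onsets), integer(1)))
  rows <- lapply(trains, function(tr) {
    k <- length(tr@onsets)
    on <- am <- rep(NA_real_, n)
    on[seq_len(k)] <- tr@onsets; am[seq_len(k)] <- tr@amplitudes
    row <- data.frame(
      train_id = tr@train_id,
      baseline_amplitude = tr@baseline_amplitude,
      deviant_index = if (is.null(tr@deviant_index)) NA_integer_ else tr@deviant_index,
      deviant_sign = tr@deviant_sign,
      opto_condition = tr@opto_condition,
      n_deflections = k,
      stringsAsFactors = FALSE)
    row[onset_cols(n)] <- as.list(on)
    row[amp_cols(n)] <- as.list(am)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @param trains_table the wide trains data.frame.
#' @param i row index.
#' @rdname trainsToTable
#' @export
deflectionTrain <- function(trains_table, i) {
  r <- trains_table[i, ]
  n <- r$n_deflections
  new("DeflectionTrain",
      train_id = as.character(r$train_id),
      onsets = as.numeric(r[onset_cols(n)]),
      amplitudes = as.numeric(r[amp_cols(n)]),
      baseline_amplitude = r$baseline_amplitude,
      deviant_index = if (is.na(r$deviant_index)) NULL else as.integer(r$deviant_index),
      deviant_sign = as.integer(r$deviant_sign),
      opto_condition = as.character(r$opto_condition))
}

.schema <- list(
  trials = c("train_id", "baseline_amplitude", "deviant_index", "deviant_sign",
             "opto_condition", "n_deflections"),
  spikes = c("unit_id", "train_id", "t_s"),
  units = c("unit_id", "depth_um", "waveform_width_ms")
)

.read_table <- function(path, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.schema[[what]], names(df))
  if (length(missing))
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Read / write a session as delimited-text tables
#'
#' A session directory holds `trials.csv` (wide trains schema with
#' `onset_<k>` / `amp_<k>` columns, 0-based deflection indices), `spikes.csv`
#' (`unit_id, train_id, t_s`; times in seconds relative to the trial recording
#' window), `units.csv` (`unit_id, depth_um, waveform_width_ms`) and
#' `metadata.yaml`. Writing then reading is the identity on the bundle.
#'
#' @param dir session directory.
#' @return `readSession`: a validated [SessionBundle-class].
#' @export
readSession <- function(dir) {
  trains <- .read_table(file.path(dir, "trials.csv"), "trials")
  spikes <- .read_table(file.path(dir, "spikes.csv"), "spikes")
  units <- .read_table(file.path(dir, "units.csv"), "units")
  meta_path <- file.path(dir, "metadata.yaml")
  metadata <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  bad <- setdiff(unique(spikes$train_id), trains$train_id)
  if (length(bad)) {
    lines <- which(spikes$train_id %in% bad)
    stop(sprintf("integrity error: spikes reference unknown train_id %s (e.g. spikes.csv row %d)",
                 paste(utils::head(bad, 3L), collapse = ", "), lines[1L] + 1L),
         call. = FALSE)
  }
  sessionBundle(trains, spikes, units, metadata)
}

#' @param bundle a [SessionBundle-class].
#' @rdname readSession
#' @export
writeSession <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle@trains, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(bundle@spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(bundle@units, file.path(dir, "units.csv"), row.names = FALSE)
  yaml::write_yaml(bundle@metadata, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Write / read stage results as JSON
#'
#' Results are plain lists (or S4 stats objects, which are converted to lists)
#' serialized with full numeric precision so a round trip reproduces the
#' structure exactly.
#'
#' @param results a (possibly nested) list of numeric/character scalars and
#'   vectors, or a [BroadeningStats-class].
#' @param path output file.
#' @export
writeResults <- function(results, path) {
  if (methods::is(results, "BroadeningStats"))
    results <- list(iqr_obs = results@iqr_obs, iqr_surr = results@iqr_surr,
                    delta_H = results@delta_H,
                    p = list(iqr = results@p_iqr, entropy = results@p_entropy,
                             median_shift = results@p_median_shift),
                    ci = results@ci_median, bin_edges = results@bin_edges)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Analysis configuration
#'
#' Reads a YAML key-value configuration, filling documented defaults for any
#' key not present. Every stochastic stage takes its seed from this config (or
#' an explicit argument).
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @return named list.
#' @export
readConfig <- function(path = NULL) {
  defaults <- list(
    response_window_ms = 100,
    surrogate_draws = 1000L,
    bootstrap_draws = 10000L,
    entropy_bins = 15L,
    rng_seed = 1L,
    alpha = 0.05,
    driven_p = 0.03,
    driven_coef_floor = 0.002
  )
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  assert_that(cfg$surrogate_draws > 0 && cfg$bootstrap_draws > 0 &&
              cfg$entropy_bins > 0, "config counts must be positive")
  cfg
}
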