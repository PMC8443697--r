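# Plain-text interchange helpers for the pipeline's tabular inputs/outputs.

#' Write and read AIS fix tables as CSV
#'
#' Columns: `time_s`, `x_m`, `y_m`, `sog_mps`, `draft_m`, `vessel_id`
#' (receiver-centred planar frame).
#'
#' @param ais AIS tibble.
#' @param path CSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_ais_csv <- function(ais, path) {
  utils::write.csv(ais, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ais_csv
#' @export
read_ais_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write and read sound-speed profiles as CSV
#'
#' Long format: `date`, `depth_m`, `speed_mps`; one block per profile.
#'
#' @param profiles List of [sound_speed_profile()] objects.
#' @param path CSV path.
#' @return `path` (write) or the profile list (read).
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(date = as.character(p$date), depth_m = p$depth_m,
               speed_mps = p$speed_mps)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$date), function(d) {
    sound_speed_profile(d$depth_m, d$speed_mps, as.Date(d$date[1]))
  }) |> unname()
}

#' Read a calibration curve CSV
#'
#' Columns: `frequency_hz`, `offset_db`.
#'
#' @param path CSV path.
#' @return Tibble usable by [apply_calibration()].
#' @export
read_calibration_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write and read a ship-passage scenario as YAML
#'
#' @param scenario A [ship_scenario()]. The spectrum is stored explicitly so
#'   the file fully determines the rendered passage.
#' @param path YAML path.
#' @return `path` (write) or the `ship_scenario` (read).
#' @export
write_scenario_yaml <- function(scenario, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for scenario files")
  }
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for scenario files")
  }
  x <- yaml::read_yaml(path)
  ship_scenario(length_m = x$length_m, draft_m = x$draft_m,
                sog_mps = x$sog_mps, cpa_range_m = x$cpa_range_m,
                sl_spectrum_db = unlist(x$sl_spectrum_db),
                duration_s = x$duration_s, freq_hz = unlist(x$freq_hz),
                vessel_id = x$vessel_id)
}
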