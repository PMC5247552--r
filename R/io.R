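# CSV schemas shared by the simulator and the analysis stages. All files
# are UTF-8, comma-separated, '.' decimal, with a header row; times in
# seconds, wavelengths in nm, irradiance in umol photons m^-2 s^-1.

schema_cols <- list(
  timecourse = c("sample_id", "condition", "inhibitor", "interval_index",
                 "phase", "t_s", "t_treat_s", "t_cum_s", "t_recovery_s",
                 "irradiance_umol", "f0", "fm", "fs", "fm_prime",
                 "fm_prime_2s", "f0_prime_2s", "sigma_psii_prime_A2"),
  frr_trace  = c("time_s", "excitation_quanta_per_A2", "fluorescence",
                 "phase", "context"),
  o2_trace   = c("time_s", "o2_umol_per_L", "phase"),
  protein    = c("sample_id", "psba_fmol_per_ug", "ftsh_fmol_per_ug"),
  growth     = c("time_d", "f680"),
  spectrum   = c("replicate_id", "wavelength_nm", "a_per_m", "chl_ug_per_L")
)

read_schema_csv <- function(path, schema) {
  if (!file.exists(path)) stop_invalid(paste0("File not found: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(schema_cols[[schema]], names(d))
  if (length(miss) > 0) {
    stop_invalid(paste0(path, " is missing required columns: ",
                        paste(miss, collapse = ", ")))
  }
  d
}

#' Read and write the package's CSV interchange formats
#'
#' Thin, schema-checked wrappers around `readr`. `read_time_course()`
#' expects the per-interval yield schema written by
#' [simulate_time_course()]; the other readers expect the trace, protein,
#' growth and spectrum schemas. Missing required columns are an error
#' naming the columns.
#'
#' @param path File path.
#' @return A tibble with at least the schema columns.
#' @name psii_io
#' @export
read_time_course <- function(path) read_schema_csv(path, "timecourse")

#' @rdname psii_io
#' @export
read_frr_trace <- function(path) read_schema_csv(path, "frr_trace")

#' @rdname psii_io
#' @export
read_o2_trace <- function(path) read_schema_csv(path, "o2_trace")

#' @rdname psii_io
#' @export
read_spectra <- function(path) read_schema_csv(path, "spectrum")

#' @rdname psii_io
#' @param data A data frame containing at least the schema columns for the
#'   format being written.
#' @export
write_time_course <- function(data, path) {
  miss <- setdiff(schema_cols$timecourse, names(data))
  if (length(miss) > 0) {
    stop_invalid(paste0("`data` is missing schema columns: ",
                        paste(miss, collapse = ", ")))
  }
  readr::write_csv(data, path)
  invisible(path)
}
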