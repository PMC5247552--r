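default_config <- function() {
  list(
    seed = 1L,
    output_dir = "psiikinetics-out",
    model = list(
      repair = "inactive_pool",      # or "kok"
      npq_slow_term = TRUE,
      a_star_method = "mean"
    ),
    simulate = list(
      treatment_lights = c(24, 97, 200, 400),
      n_treatment = 6L,
      n_recovery = 2L,
      noise_cv = 0.02,
      truth = list()                 # overrides for kinetic_ground_truth()
    ),
    pools = list(psba = 79, active = 42),
    inputs = list()                  # optional: timecourse = "path.csv"
  )
}

#' Validate and resolve a run configuration
#'
#' Reads a YAML (or JSON) configuration for [run_end_to_end()], fills
#' defaults, rejects unknown keys, and checks that any referenced input
#' files exist. Validating an already-resolved configuration is a no-op, so
#' a resolved config serialises and re-validates to the identical object.
#'
#' @param path Path to a YAML/JSON config file, or a named list.
#' @return A fully resolved config of class `run_config`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop_invalid(paste0("Config file not found: ", path))
    yaml::read_yaml(path)
  } else if (is.list(path)) {
    path
  } else {
    stop_invalid("`path` must be a file path or a named list.")
  }
  if (is.null(cfg)) cfg <- list()
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown) > 0) {
    stop_invalid(paste0("Unknown config keys: ",
                        paste(unknown, collapse = ", ")))
  }
  merge_section <- function(user, dflt, section) {
    if (is.null(user)) return(dflt)
    bad <- setdiff(names(user), names(dflt))
    if (length(bad) > 0) {
      stop_invalid(paste0("Unknown keys in `", section, "`: ",
                          paste(bad, collapse = ", ")))
    }
    utils::modifyList(dflt, user)
  }
  out <- def
  for (nm in c("model", "simulate", "pools")) {
    out[[nm]] <- merge_section(cfg[[nm]], def[[nm]], nm)
  }
  if (!is.null(cfg$seed)) out$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$output_dir)) out$output_dir <- cfg$output_dir
  if (!is.null(cfg$inputs)) {
    ok_inputs <- c("timecourse", "protein", "spectrum")
    bad <- setdiff(names(cfg$inputs), ok_inputs)
    if (length(bad) > 0) {
      stop_invalid(paste0("Unknown keys in `inputs`: ",
                          paste(bad, collapse = ", ")))
    }
    for (nm in names(cfg$inputs)) {
      if (!file.exists(cfg$inputs[[nm]])) {
        stop_invalid(paste0("Input file for `", nm, "` not found: ",
                            cfg$inputs[[nm]]))
      }
    }
    out$inputs <- cfg$inputs
  }
  if (!out$model$repair %in% c("inactive_pool", "kok")) {
    stop_invalid("`model$repair` must be \"inactive_pool\" or \"kok\".")
  }
  if (!out$model$a_star_method %in% c("mean", "integral")) {
    stop_invalid("`model$a_star_method` must be \"mean\" or \"integral\".")
  }
  structure(out, class = "run_config")
}

stage_error <- function(stage, msg) {
  abort(paste0("[stage: ", stage, "] ", msg),
        class = "psiikinetics_stage_error", stage = stage)
}

#' Run the full simulate - fit - calibrate - report pipeline
#'
#' Orchestrates the analysis in its natural dependency order: simulate (or
#' load) +lincomycin and no-inhibitor time courses across treatment lights;
#' fit the pooled target size from the +lincomycin courses; inject that
#' target size into the repair fits (two-state or inactive-pool, per the
#' config) on the no-inhibitor courses; fit qP saturation and NPQ
#' induction/relaxation; calibrate the fluorescence proxy against oxygen
#' flash yields; fit PsbA clearance; and compare carotenoid bands in
#' second-derivative spectra. Writes `fits.json`, `calibration.json`,
#' `spectra_comparison.csv` and `timecourses.csv` into the output
#' directory, together with a `run_log.json` recording seeds and options.
#'
#' @param config A `run_config` from [validate_config()].
#' @param n_boot Bootstrap resamples used for fit CIs (default 200 here;
#'   individual fit functions default to 1000 when called directly).
#' @return Invisibly, a named list with every fitted object and the paths
#'   written.
#' @export
run_end_to_end <- function(config, n_boot = 200) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  truth <- do.call(kinetic_ground_truth, config$simulate$truth)
  pools_i0 <- estimate_initial_inactive_pool(config$pools$psba,
                                             config$pools$active)

  # ---- stage: data ----
  courses <- if (!is.null(config$inputs$timecourse)) {
    read_time_course(config$inputs$timecourse)
  } else {
    lights <- config$simulate$treatment_lights
    purrr::map_dfr(seq_along(lights), function(i) {
      prog <- standard_light_program(lights[i],
                                     n_treatment = config$simulate$n_treatment,
                                     n_recovery = config$simulate$n_recovery)
      dplyr::bind_rows(
        simulate_time_course(
          truth, prog, inhibitor = "lincomycin",
          noise = noise_spec(config$simulate$noise_cv, seed = seed + 100 + i),
          sample_id = paste0("linco_L", lights[i])
        ),
        simulate_time_course(
          truth, prog, inhibitor = "none",
          noise = noise_spec(config$simulate$noise_cv, seed = seed + 200 + i),
          sample_id = paste0("ctrl_L", lights[i])
        )
      )
    })
  }
  derived <- derive_time_course(courses)
  linco <- dplyr::filter(derived, .data$inhibitor == "lincomycin")
  ctrl <- dplyr::filter(derived, .data$inhibitor == "none")
  if (nrow(linco) == 0) {
    stage_error("sigma_i", "No +lincomycin courses: repair is not blocked, target size unidentifiable.")
  }
  if (nrow(ctrl) == 0) {
    stage_error("repair", "No repair-active (no-inhibitor) courses available.")
  }

  # ---- stage: sigma_i (must precede the repair fits) ----
  fit_si <- tryCatch(
    fit_sigma_i(linco, n_boot = n_boot, boot_seed = seed + 1),
    error = function(e) stage_error("sigma_i", conditionMessage(e))
  )
  sigma_i_hat <- unname(fit_si$estimate["sigma_i"])

  # ---- stage: repair ----
  fit_rep <- tryCatch({
    if (config$model$repair == "inactive_pool") {
      fit_krecinact(ctrl, sigma_i = sigma_i_hat,
                    i0_frac = pools_i0 / config$pools$active,
                    n_boot = n_boot, boot_seed = seed + 2)
    } else {
      fit_krec(ctrl, sigma_i = sigma_i_hat, n_boot = n_boot,
               boot_seed = seed + 2)
    }
  }, error = function(e) stage_error("repair", conditionMessage(e)))

  # ---- stage: quenching ----
  light_rows <- dplyr::filter(derived, .data$irradiance_umol > 0)
  fit_qp <- tryCatch(
    fit_keqp(light_rows, n_boot = n_boot, boot_seed = seed + 3),
    error = function(e) stage_error("ke_qp", conditionMessage(e))
  )
  fit_npq <- tryCatch(
    fit_npq_induction(ctrl, n_boot = n_boot, boot_seed = seed + 4),
    error = function(e) stage_error("npq_induction", conditionMessage(e))
  )
  fit_relax <- tryCatch(
    fit_npq_relaxation(ctrl, n_boot = n_boot, boot_seed = seed + 5),
    error = function(e) stage_error("npq_relaxation", conditionMessage(e))
  )

  # ---- stage: oxygen calibration ----
  # flash-yield measures at the t0 and end-of-treatment states of each
  # control course, paired with the proxy measured on the same state
  calib <- tryCatch({
    fmol_to_umol_per_L <- 2.5e-5   # cell-density dependent; arbitrary but fixed
    states <- ctrl |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::arrange(.data$t_s, .by_group = TRUE) |>
      dplyr::slice(c(which(.data$phase != "treatment")[1],
                     max(which(.data$phase == "treatment")))) |>
      dplyr::ungroup()
    pts <- purrr::map_dfr(seq_len(nrow(states)), function(i) {
      conc <- states$psii_active_true[i] * fmol_to_umol_per_L
      tr <- simulate_o2_trace(
        conc, respiration = 0.01,
        phases = tibble(phase = c("dark_pre", "preillumination",
                                  "flash_train", "dark_post"),
                        duration = c(300, 120, 240, 300)),
        noise = noise_spec(0.005, seed = seed + 300 + i)
      )
      sl <- segment_and_slopes(tr)
      est <- psii_from_flash_yield(sl$slope[sl$phase == "flash_train"],
                                   sl$slope[sl$phase == "dark_post"])
      tibble(psii_active = est, proxy = states$proxy[i])
    })
    fit_proxy_calibration(pts)
  }, error = function(e) stage_error("calibration", conditionMessage(e)))

  # ---- stage: psba ----
  fit_psba <- tryCatch({
    ps <- simulate_psba_course(config$pools$psba, truth$k_psba,
                               times = seq(0, 1800, by = 300),
                               noise = noise_spec(config$simulate$noise_cv,
                                                  seed = seed + 6))
    fit_psba_clearance(ps)
  }, error = function(e) stage_error("psba", conditionMessage(e)))

  # ---- stage: spectra ----
  spectra_cmp <- tryCatch({
    grp_a <- simulate_spectra(zeaxanthin_amp = 0.55,
                              noise = noise_spec(0.02, additive_sd = 2e-3,
                                                 seed = seed + 7))
    grp_b <- simulate_spectra(zeaxanthin_amp = 0.30,
                              noise = noise_spec(0.02, additive_sd = 2e-3,
                                                 seed = seed + 8))
    prep <- function(g) {
      g |> normalize_to_red_peak() |> second_derivative() |>
        normalize_second_derivative()
    }
    compare_band(prep(grp_a), prep(grp_b))
  }, error = function(e) stage_error("spectra", conditionMessage(e)))

  # ---- report ----
  fits <- dplyr::bind_rows(
    dplyr::mutate(tidy(fit_si), model = fit_si$model),
    dplyr::mutate(tidy(fit_rep), model = fit_rep$model),
    dplyr::mutate(tidy(fit_qp), model = fit_qp$model),
    dplyr::mutate(tidy(fit_npq), model = fit_npq$model),
    dplyr::mutate(tidy(fit_relax), model = fit_relax$model),
    dplyr::mutate(tidy(fit_psba), model = fit_psba$model)
  )
  paths <- list(
    fits = file.path(config$output_dir, "fits.json"),
    calibration = file.path(config$output_dir, "calibration.json"),
    spectra = file.path(config$output_dir, "spectra_comparison.csv"),
    timecourses = file.path(config$output_dir, "timecourses.csv"),
    log = file.path(config$output_dir, "run_log.json")
  )
  jsonlite::write_json(fits, paths$fits, digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(slope = calib$slope, intercept = calib$intercept,
         r_squared = calib$r_squared, n = calib$n),
    paths$calibration, digits = NA, auto_unbox = TRUE
  )
  readr::write_csv(as_tibble(spectra_cmp), paths$spectra)
  readr::write_csv(courses, paths$timecourses)
  jsonlite::write_json(
    list(seed = seed, model = config$model,
         simulate = config$simulate[c("treatment_lights", "n_treatment",
                                      "n_recovery", "noise_cv")],
         package_version = as.character(utils::packageVersion("psiikinetics"))),
    paths$log, digits = NA, auto_unbox = TRUE
  )

  invisible(list(
    sigma_i = fit_si, repair = fit_rep, ke_qp = fit_qp,
    npq_induction = fit_npq, npq_relaxation = fit_relax,
    calibration = calib, psba = fit_psba, spectra = spectra_cmp,
    fits_table = fits, paths = paths
  ))
}
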