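# Shared fixtures: the cold-adapted reference parameter set and small
# generators used across test files. Everything is built in code at test
# time; no stored data.

arctic_truth <- function(...) kinetic_ground_truth(...)

# a set of derived time courses across treatment lights
make_courses <- function(truth, lights, inhibitor = "none",
                         noise = noise_free(), seed0 = 0L,
                         n_treatment = 6, n_recovery = 1) {
  dplyr::bind_rows(lapply(seq_along(lights), function(i) {
    ns <- if (noise$multiplicative_cv == 0 && noise$additive_sd == 0) {
      noise_free()
    } else {
      noise_spec(noise$multiplicative_cv, noise$additive_sd,
                 seed = seed0 + i)
    }
    simulate_time_course(
      truth, standard_light_program(lights[i], n_treatment = n_treatment,
                                    n_recovery = n_recovery),
      inhibitor = inhibitor, noise = ns,
      sample_id = paste0(inhibitor, "_L", lights[i])
    )
  })) |> derive_time_course()
}

o2_phases <- function() {
  tibble::tibble(
    phase = c("dark_pre", "preillumination", "flash_train", "dark_post"),
    duration = c(300, 120, 240, 300)
  )
}

prep_spectra <- function(g) {
  normalize_second_derivative(second_derivative(normalize_to_red_peak(g)))
}
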