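test_that("identical noise seeds give bit-identical simulated outputs", {
  truth <- arctic_truth()
  n1 <- noise_spec(0.02, seed = 42)
  n2 <- noise_spec(0.02, seed = 42)
  expect_identical(simulate_frr_trace(truth, noise = n1),
                   simulate_frr_trace(truth, noise = n2))
  prog <- standard_light_program(97)
  expect_identical(simulate_time_course(truth, prog, noise = n1),
                   simulate_time_course(truth, prog, noise = n2))
  expect_identical(
    simulate_o2_trace(2e-3, 0.01, phases = o2_phases(), noise = n1),
    simulate_o2_trace(2e-3, 0.01, phases = o2_phases(), noise = n2)
  )
  expect_identical(simulate_spectra(noise = n1),
                   simulate_spectra(noise = n2))
  # and a different seed changes the draw
  expect_false(identical(
    simulate_frr_trace(truth, noise = n1),
    simulate_frr_trace(truth, noise = noise_spec(0.02, seed = 43))
  ))
})

test_that("simulators do not disturb the caller's RNG state", {
  withr::with_seed(7, {
    before <- rnorm(1)
  })
  withr::with_seed(7, {
    invisible(simulate_frr_trace(arctic_truth(), noise = noise_spec(seed = 5)))
    after <- rnorm(1)
  })
  expect_identical(before, after)
})

test_that("total PSII pool is conserved throughout a simulated course", {
  truth <- arctic_truth()
  for (inh in c("none", "lincomycin")) {
    tc <- simulate_time_course(truth, standard_light_program(200),
                               inhibitor = inh, noise = noise_free())
    expect_equal(tc$psii_active_true + tc$psii_inactive_true,
                 rep(truth$active_t0 + truth$inactive_t0, nrow(tc)),
                 tolerance = 1e-12)
  }
})

test_that("the noiseless simulator reproduces the ground-truth t0 state", {
  truth <- arctic_truth()
  tc <- simulate_time_course(truth, standard_light_program(97),
                             noise = noise_free())
  pre <- tc[tc$phase %in% c("dark", "growth"), ]
  expect_equal(pre$psii_active_true, rep(truth$active_t0, nrow(pre)))
  expect_equal(pre$y_npq_true, rep(0, nrow(pre)))
  dark <- tc[tc$phase == "dark", ]
  expect_equal(dark$f0, truth$f0)
  expect_equal(dark$fm, truth$fm)
  expect_equal(dark$qp_true, 1)
})

test_that("a course with no kinetics stays frozen at its t0 state", {
  truth <- arctic_truth(sigma_i = 0, k_recinact = 0, k_npq = 0,
                        k_npqslow = 0, kr_npq = 0)
  tc <- simulate_time_course(truth, standard_light_program(97),
                             noise = noise_free())
  expect_equal(tc$psii_active_true, rep(truth$active_t0, nrow(tc)))
  expect_equal(tc$y_npq_true, rep(0, nrow(tc)))
  # within the constant-light treatment phase every interval is identical
  tr <- tc[tc$phase == "treatment", ]
  for (col in c("f0", "fm", "fs", "fm_prime", "sigma_psii_prime_A2")) {
    expect_equal(tr[[col]], rep(tr[[col]][1], nrow(tr)))
  }
})

test_that("lincomycin courses decay strictly with no repair", {
  tc <- simulate_time_course(arctic_truth(), standard_light_program(97),
                             inhibitor = "lincomycin", noise = noise_free())
  a <- tc$psii_active_true[tc$phase == "treatment"]
  expect_true(all(diff(a) < 0))
  # pure exponential at rate sigma_i * flux
  truth <- arctic_truth()
  k_pi <- truth$sigma_i * photon_flux(97)
  t_tr <- tc$t_treat_s[tc$phase == "treatment"]
  expect_equal(a, truth$active_t0 * exp(-k_pi * t_tr), tolerance = 1e-10)
})

test_that("DTT suppresses the slow NPQ phase in simulation", {
  truth <- arctic_truth(k_npqslow = 5e-5)
  prog <- standard_light_program(97)
  y_dtt <- simulate_time_course(truth, prog, inhibitor = "DTT",
                                noise = noise_free())$y_npq_true
  y_ctl <- simulate_time_course(truth, prog, noise = noise_free())$y_npq_true
  expect_true(all(y_dtt <= y_ctl + 1e-12))
  last <- length(y_ctl) - 1   # last treatment interval
  expect_lt(y_dtt[last], y_ctl[last])
})

test_that("FRR trace degenerate and saturation limits behave", {
  truth <- arctic_truth()
  flat <- simulate_frr_trace(truth, flashlet_energy = 0, noise = noise_free())
  expect_equal(flat$fluorescence, rep(truth$f0, nrow(flat)))
  sat <- simulate_frr_trace(arctic_truth(rho = 0), flashlet_count = 200,
                            flashlet_energy = 5e-3, noise = noise_free())
  ind <- sat$fluorescence[sat$phase == "induction"]
  expect_equal(ind[length(ind)], truth$fm, tolerance = 1e-6)
  expect_error(simulate_frr_trace(truth, flashlet_energy = -1),
               class = "psiikinetics_invalid_input")
  expect_error(simulate_frr_trace(truth, flashlet_count = 5),
               class = "psiikinetics_invalid_input")
})

test_that("O2 trace slopes follow the flash-yield arithmetic", {
  # dark-only drift: 300 s at 0.01 umol/L/s consumes 3 umol/L
  tr <- simulate_o2_trace(0, 0.01,
                          phases = tibble::tibble(phase = "dark_pre",
                                                  duration = 300),
                          noise = noise_free())
  expect_equal(tr$o2_umol_per_L[1] - tr$o2_umol_per_L[nrow(tr)], 3,
               tolerance = 1e-12)
  # flash-train slope difference = psii * f / 4
  tr2 <- simulate_o2_trace(2e-3, 0.01, flash_frequency = 39.96,
                           phases = o2_phases(), noise = noise_free())
  sl <- segment_and_slopes(tr2)
  dslope <- sl$slope[sl$phase == "flash_train"] -
    sl$slope[sl$phase == "dark_post"]
  expect_equal(dslope, 2e-3 * 39.96 / 4, tolerance = 1e-9)
  # psii_conc = 0: flash slope equals dark slope
  tr3 <- simulate_o2_trace(0, 0.01, phases = o2_phases(),
                           noise = noise_free())
  sl3 <- segment_and_slopes(tr3)
  expect_equal(sl3$slope[sl3$phase == "flash_train"],
               sl3$slope[sl3$phase == "dark_post"], tolerance = 1e-12)
})

test_that("PsbA decay series has the right anchors", {
  p <- simulate_psba_course(79, 7e-5, times = c(0, log(2) / 7e-5),
                            noise = noise_free())
  expect_equal(p$psba_fmol_per_ug[1], 79)
  expect_equal(p$psba_fmol_per_ug[2], 79 / 2, tolerance = 1e-12)
})

test_that("simulated spectra cover and normalise the red peak", {
  sp <- simulate_spectra(noise = noise_free())
  np <- normalize_to_red_peak(sp)
  for (r in unique(np$replicate_id)) {
    g <- np[np$replicate_id == r, ]
    expect_equal(max(g$a_per_m[g$wavelength_nm >= 673 &
                                 g$wavelength_nm <= 675]), 1)
  }
  expect_error(simulate_spectra(grid = seq(500, 750, 1)),
               class = "psiikinetics_invalid_input")
})
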