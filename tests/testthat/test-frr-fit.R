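test_that("noiseless induction fits recover the generating parameters", {
  # dark-acclimated cross section with and without connectivity
  for (pars in list(c(sigma = 747, rho = 0), c(sigma = 747, rho = 0.3))) {
    truth <- arctic_truth(sigma_psii = pars[["sigma"]], rho = pars[["rho"]])
    fit <- fit_frr_induction(simulate_frr_trace(truth, noise = noise_free()))
    expect_lt(abs(fit$sigma_psii - pars[["sigma"]]) / pars[["sigma"]], 1e-3)
    expect_lt(abs(fit$rho - pars[["rho"]]), 1e-3)
    expect_equal(fit$f0, truth$f0, tolerance = 1e-3)
    expect_equal(fit$fm, truth$fm, tolerance = 1e-3)
    expect_lt(fit$rmse, 1e-5)
  }
})

test_that("fitted cross section depends on dose, not on flashlet layout", {
  # doubling per-flashlet energy while halving the count leaves sigma alone
  truth <- arctic_truth()
  f1 <- fit_frr_induction(simulate_frr_trace(truth, flashlet_count = 40,
                                             flashlet_energy = 1.5e-4,
                                             noise = noise_free()))
  f2 <- fit_frr_induction(simulate_frr_trace(truth, flashlet_count = 20,
                                             flashlet_energy = 3e-4,
                                             noise = noise_free()))
  expect_equal(f1$sigma_psii, f2$sigma_psii, tolerance = 1e-4)
})

test_that("degenerate induction traces raise classed errors", {
  truth <- arctic_truth()
  zero <- simulate_frr_trace(truth, flashlet_energy = 0, noise = noise_free())
  expect_error(fit_frr_induction(zero),
               class = "psiikinetics_degenerate_trace")
  flat <- tibble::tibble(time_s = seq(0, 1e-4, length.out = 40),
                         excitation_quanta_per_A2 = 1.5e-4,
                         fluorescence = 0.5)
  expect_error(fit_frr_induction(flat),
               class = "psiikinetics_degenerate_trace")
  expect_error(fit_frr_induction(zero[1:5, ]),
               class = "psiikinetics_invalid_input")
})

test_that("noisy replicate fits recover sigma_PSII without bias", {
  # light-acclimated temperate cross section, moderate connectivity
  truth <- arctic_truth(sigma_psii = 934, rho = 0.2)
  sig <- vapply(1:100, function(s) {
    tr <- simulate_frr_trace(truth, noise = noise_spec(0.02, seed = s))
    fit_frr_induction(tr)$sigma_psii
  }, numeric(1))
  expect_lt(abs(mean(sig) - 934) / 934, 0.02)
})

test_that("reopening fits recover one- and two-phase lifetimes", {
  # pure single exponential collapses to one slow lifetime
  # (log-spaced sampling: dense where the fast phase decays)
  t <- c(0, exp(seq(log(5e-5), log(0.3), length.out = 79)))
  single <- tibble::tibble(time_s = t,
                           fluorescence = 0.4 + 0.6 * exp(-t / 1.3e-2))
  expect_warning(fit1 <- fit_reopening(single), "single-phase")
  expect_equal(fit1$tau1, 1.3e-2, tolerance = 1e-3)
  expect_lt(fit1$fast_fraction, 0.05)
  expect_true(fit1$single_phase)

  # two-phase with equal amplitude fractions
  two <- tibble::tibble(
    time_s = t,
    fluorescence = 0.4 + 0.6 * (0.5 * exp(-t / 3e-4) + 0.5 * exp(-t / 1.3e-2))
  )
  fit2 <- fit_reopening(two)
  expect_lt(abs(fit2$tau1 - 1.3e-2) / 1.3e-2, 0.01)
  expect_lt(abs(fit2$tau2 - 3e-4) / 3e-4, 0.01)
  expect_equal(fit2$fast_fraction, 0.5, tolerance = 0.01)
})

test_that("reopening lifetimes are always ordered tau1 >= tau2", {
  t <- c(0, exp(seq(log(5e-5), log(0.3), length.out = 59)))
  set.seed(11)
  for (i in 1:8) {
    tau_a <- 10^stats::runif(1, -3.5, -1.5)
    tau_b <- 10^stats::runif(1, -3.5, -1.5)
    p <- stats::runif(1, 0.2, 0.8)
    tr <- tibble::tibble(
      time_s = t,
      fluorescence = 0.4 + 0.6 * (p * exp(-t / tau_a) +
                                    (1 - p) * exp(-t / tau_b))
    )
    fit <- suppressWarnings(fit_reopening(tr))
    expect_gte(fit$tau1, fit$tau2)
  }
})

test_that("constant reopening traces never succeed silently", {
  flat <- tibble::tibble(time_s = seq(0, 0.3, length.out = 40),
                         fluorescence = 0.7)
  expect_error(fit_reopening(flat), class = "psiikinetics_degenerate_trace")
  short <- tibble::tibble(time_s = seq(0, 0.1, length.out = 40),
                          fluorescence = 0.7 * exp(-seq(0, 0.1, length.out = 40)))
  expect_error(fit_reopening(short), class = "psiikinetics_invalid_input")
})

test_that("round trip through the simulator recovers reopening truth", {
  truth <- arctic_truth()
  fit <- fit_reopening(simulate_frr_trace(truth, noise = noise_free()))
  expect_equal(fit$tau1, truth$tau1, tolerance = 1e-3)
  expect_equal(fit$tau2, truth$tau2, tolerance = 5e-3)
  expect_equal(fit$fast_fraction, truth$reopen_fast_frac, tolerance = 1e-2)
})
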