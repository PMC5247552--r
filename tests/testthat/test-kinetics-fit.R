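test_that("pooled target size matches a log-linear oracle on clean data", {
  truth <- arctic_truth()
  d <- make_courses(truth, 97, inhibitor = "lincomycin")
  tr <- d[d$phase == "treatment", ]
  # independent oracle: regression of log(active) on t gives -slope/flux
  oracle <- -unname(coef(lm(log(tr$proxy) ~ tr$t_treat_s))[2]) /
    photon_flux(97)
  fit <- fit_sigma_i(d, n_boot = 20)
  expect_lt(abs(fit$estimate - oracle) / oracle, 1e-9)
  expect_lt(abs(fit$estimate - truth$sigma_i) / truth$sigma_i, 1e-6)
})

test_that("zero target size is recovered as zero, flat data errors", {
  # noisy courses generated with no photoinactivation at all
  d <- make_courses(arctic_truth(sigma_i = 0), c(97, 200),
                    inhibitor = "lincomycin", noise = noise_spec(0.02),
                    seed0 = 8)
  fit <- fit_sigma_i(d, n_boot = 10)
  expect_lt(fit$estimate, 0.05e-24)
  # exactly flat data carry no information at all
  d0 <- make_courses(arctic_truth(sigma_i = 0), 97,
                     inhibitor = "lincomycin")
  expect_error(fit_sigma_i(d0, n_boot = 2),
               class = "psiikinetics_degenerate_trace")
})

test_that("pooled multi-light recovery of a small target size is unbiased", {
  truth <- arctic_truth(sigma_i = 1.3e-24)
  ests <- vapply(1:10, function(s) {
    d <- make_courses(truth, c(24, 97, 200, 400), inhibitor = "lincomycin",
                      noise = noise_spec(0.02), seed0 = s * 10)
    fit_sigma_i(d, n_boot = 2)$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - 1.3e-24) / 1.3e-24, 0.05)
})

test_that("repair fits recover their generating rates exactly on clean data", {
  # two-state data fitted with the two-state model
  truth_kok <- arctic_truth(inactive_t0 = 0, k_recinact = 2.7e-4)
  d_kok <- make_courses(truth_kok, 97)
  f_kok <- fit_krec(d_kok, sigma_i = truth_kok$sigma_i, n_boot = 10)
  expect_lt(abs(f_kok$estimate - 2.7e-4) / 2.7e-4, 1e-6)

  # inactive-pool data fitted with the inactive-pool model
  truth <- arctic_truth()
  d <- make_courses(truth, 97)
  f_in <- fit_krecinact(d, sigma_i = truth$sigma_i, i0_frac = 37 / 42,
                        n_boot = 10)
  expect_lt(abs(f_in$estimate - 7e-5) / 7e-5, 1e-6)

  # zero repair rate data
  d0 <- make_courses(arctic_truth(k_recinact = 0), 97)
  f0 <- fit_krec(d0, sigma_i = 3.6e-24, n_boot = 10)
  expect_lt(f0$estimate, 1e-10)
})

test_that("the inactive-pool fit with i0 = 0 equals the two-state fit", {
  truth <- arctic_truth()
  d <- make_courses(truth, 97, noise = noise_spec(0.02), seed0 = 4)
  f1 <- fit_krec(d, sigma_i = truth$sigma_i, n_boot = 5)
  f2 <- fit_krecinact(d, sigma_i = truth$sigma_i, i0 = 0, n_boot = 5)
  expect_equal(unname(f1$estimate), unname(f2$estimate), tolerance = 1e-9)
})

test_that("ignoring a real inactive pool inflates the fitted repair rate", {
  truth <- arctic_truth()  # i0/a0 = 37/42, k_recinact = 7e-5
  d <- make_courses(truth, 97)
  k_kok <- fit_krec(d, sigma_i = truth$sigma_i, n_boot = 5)$estimate
  k_in <- fit_krecinact(d, sigma_i = truth$sigma_i, i0_frac = 37 / 42,
                        n_boot = 5)$estimate
  expect_gte(unname(k_kok / k_in), 3)
})

test_that("qP half-saturation is recovered and misfits are flagged", {
  set.seed(2)
  irr <- rep(c(10, 25, 64, 120, 250, 400), each = 3)
  clean <- tibble::tibble(irradiance_umol = irr, qp = predict_qp(irr, 64))
  fit <- fit_keqp(clean, n_boot = 10)
  expect_lt(abs(fit$estimate - 64) / 64, 1e-6)
  expect_length(fit$flags, 0)

  rising <- tibble::tibble(irradiance_umol = c(10, 100, 400),
                           qp = c(0.2, 0.5, 0.9))
  expect_warning(fit_bad <- fit_keqp(rising, n_boot = 5), "misfit")
  expect_true("model_misfit" %in% fit_bad$flags)
})

test_that("the joint NPQ induction fit recovers all three parameters", {
  truth <- arctic_truth()
  d <- make_courses(truth, c(24, 49, 97, 200))
  fit <- fit_npq_induction(d, n_boot = 5)
  expect_equal(unname(fit$estimate["ke_npq"]), 49, tolerance = 1e-3)
  expect_equal(unname(fit$estimate["k_npq"]), 0.003, tolerance = 1e-3)
  expect_equal(unname(fit$estimate["k_npqslow"]), 2e-6, tolerance = 1e-2)

  # data without a slow phase yield a negligible slow-term estimate
  d0 <- make_courses(arctic_truth(k_npqslow = 0), c(49, 200))
  fit0 <- fit_npq_induction(d0, n_boot = 5)
  expect_lte(unname(fit0$estimate["k_npqslow"]), 1e-7)
})

test_that("NPQ relaxation fitting matches a half-life oracle", {
  truth <- arctic_truth(kr_npq = 5.6e-4)
  d <- make_courses(truth, 97, n_recovery = 4)
  fit <- fit_npq_relaxation(d, n_boot = 10)
  expect_equal(unname(fit$estimate), 5.6e-4, tolerance = 1e-6)
  # half-decay time of the fitted exponential is ln 2 / kr
  rec <- d[!is.na(d$t_recovery_s), ]
  y0 <- rec$y_npq[1] / exp(-unname(fit$estimate) * rec$t_recovery_s[1])
  t_half <- log(2) / unname(fit$estimate)
  expect_equal(y0 * exp(-unname(fit$estimate) * t_half), y0 / 2)

  flat <- tibble::tibble(sample_id = "x", t_recovery_s = c(0, 300, 600),
                         y_npq = 0.4)
  expect_equal(unname(fit_npq_relaxation(flat, n_boot = 5)$estimate), 0)
  rising <- tibble::tibble(sample_id = "x", t_recovery_s = c(0, 300, 600),
                           y_npq = c(0.1, 0.2, 0.3))
  expect_warning(fit_npq_relaxation(rising, n_boot = 5), "increases")
})

test_that("PsbA clearance fits agree across methods and handle edge cases", {
  clean <- simulate_psba_course(79, 7e-5, seq(0, 7200, by = 900),
                                noise = noise_free())
  f_log <- fit_psba_clearance(clean, method = "loglinear")
  f_exp <- fit_psba_clearance(clean, method = "exponential")
  expect_equal(unname(f_log$estimate), 7e-5, tolerance = 1e-8)
  expect_lt(abs(f_log$estimate - f_exp$estimate) / f_log$estimate, 0.01)

  const <- tibble::tibble(time_s = c(0, 300, 600), psba_fmol_per_ug = 50)
  expect_equal(unname(fit_psba_clearance(const)$estimate), 0)
  rising <- tibble::tibble(time_s = c(0, 300, 600),
                           psba_fmol_per_ug = c(50, 55, 60))
  expect_warning(f_r <- fit_psba_clearance(rising), "does not decline")
  expect_gte(unname(f_r$estimate), 0)
})

test_that("bootstrap intervals contain their point estimates", {
  truth <- arctic_truth()
  d <- make_courses(truth, c(97, 200), noise = noise_spec(0.02), seed0 = 9)
  for (fit in list(fit_sigma_i(make_courses(truth, c(97, 200),
                                            inhibitor = "lincomycin",
                                            noise = noise_spec(0.02),
                                            seed0 = 3),
                               n_boot = 50),
                   fit_krecinact(d, sigma_i = truth$sigma_i,
                                 i0_frac = 37 / 42, n_boot = 50),
                   fit_npq_induction(d, n_boot = 50))) {
    expect_true(all(fit$ci[, 1] <= fit$estimate + 1e-15))
    expect_true(all(fit$ci[, 2] >= fit$estimate - 1e-15))
    expect_gte(fit$n, 1)
  }
})
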