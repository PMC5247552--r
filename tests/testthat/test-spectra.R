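test_that("red-peak normalisation is idempotent and scale-invariant", {
  sp <- simulate_spectra(noise = noise_free(), n_replicates = 1)
  n1 <- normalize_to_red_peak(sp)
  expect_equal(max(n1$a_per_m[n1$wavelength_nm >= 673 &
                                n1$wavelength_nm <= 675]), 1)
  n2 <- normalize_to_red_peak(n1)
  expect_equal(n2$a_per_m, n1$a_per_m, tolerance = 1e-14)
  scaled <- dplyr::mutate(sp, a_per_m = a_per_m * 5)
  expect_equal(normalize_to_red_peak(scaled)$a_per_m, n1$a_per_m,
               tolerance = 1e-14)
  zero <- dplyr::mutate(sp, a_per_m = 0)
  expect_error(normalize_to_red_peak(zero),
               class = "psiikinetics_invalid_input")
})

test_that("second differences annihilate affine spectra and find curvature", {
  wl <- seq(400, 750, by = 1)
  line <- tibble::tibble(wavelength_nm = wl, a_per_m = 0.002 * wl + 1)
  expect_true(all(abs(second_derivative(line)$d2) < 1e-12))

  cc <- 3e-5
  parab <- tibble::tibble(wavelength_nm = wl, a_per_m = cc * wl^2)
  d2 <- second_derivative(parab)
  expect_equal(d2$d2, rep(2 * cc, nrow(d2)), tolerance = 1e-9)

  gauss <- tibble::tibble(wavelength_nm = wl,
                          a_per_m = exp(-0.5 * ((wl - 560) / 12)^2))
  dg <- second_derivative(gauss)
  expect_lte(abs(dg$wavelength_nm[which.min(dg$d2)] - 560), 2)

  coarse <- tibble::tibble(wavelength_nm = seq(400, 750, by = 5),
                           a_per_m = 1)
  expect_error(second_derivative(coarse),
               class = "psiikinetics_invalid_input")
})

test_that("second-derivative normalisation pins the red trough at -1", {
  sp <- simulate_spectra(noise = noise_free())
  nd <- normalize_second_derivative(second_derivative(normalize_to_red_peak(sp)))
  for (r in unique(nd$replicate_id)) {
    g <- nd[nd$replicate_id == r, ]
    expect_equal(min(g$d2[g$wavelength_nm >= 677 & g$wavelength_nm <= 679]),
                 -1)
  }
  # global rescale of the input leaves the normalised derivative unchanged
  d <- second_derivative(sp)
  expect_equal(normalize_second_derivative(dplyr::mutate(d, d2 = d2 * 7))$d2,
               normalize_second_derivative(d)$d2, tolerance = 1e-14)
  flat <- tibble::tibble(replicate_id = 1,
                         wavelength_nm = seq(670, 690, 2), d2 = 1)
  expect_error(normalize_second_derivative(flat),
               class = "psiikinetics_invalid_input")
})

test_that("replicate averaging gives means and 1/sqrt(n) interval scaling", {
  wl <- seq(400, 750, 2)
  ident <- purrr::map_dfr(1:3, function(r) {
    tibble::tibble(replicate_id = r, wavelength_nm = wl, d2 = sin(wl / 30))
  })
  avg <- average_replicates(ident)
  expect_equal(avg$mean, sin(wl / 30))
  expect_equal(avg$ci_hi - avg$ci_lo, rep(0, nrow(avg)), tolerance = 1e-12)

  # f +/- eps alternating cancels in the mean
  pm <- purrr::map_dfr(1:2, function(r) {
    tibble::tibble(replicate_id = r, wavelength_nm = wl,
                   d2 = sin(wl / 30) + c(1, -1)[r] * 0.05)
  })
  expect_equal(average_replicates(pm)$mean, sin(wl / 30), tolerance = 1e-12)

  # iid noise: mean CI width shrinks like 1/sqrt(n)
  width_for_n <- function(n) {
    reps <- purrr::map_dfr(seq_len(n), function(r) {
      tibble::tibble(replicate_id = r, wavelength_nm = wl,
                     d2 = withr::with_seed(1000 * n + r, rnorm(length(wl))))
    })
    a <- average_replicates(reps)
    mean(a$ci_hi - a$ci_lo) / (2 * qt(0.975, n - 1))   # mean pointwise SE
  }
  expect_equal(width_for_n(16) / width_for_n(4), sqrt(4 / 16),
               tolerance = 0.15)

  bad <- dplyr::mutate(ident, wavelength_nm = wavelength_nm +
                         (replicate_id == 2) * 0.5)
  expect_error(average_replicates(bad), class = "psiikinetics_invalid_input")
})

test_that("band comparison flags a constructed zeaxanthin difference", {
  ga <- simulate_spectra(zeaxanthin_amp = 0.55,
                         noise = noise_spec(0.02, additive_sd = 2e-3,
                                            seed = 1))
  gb <- simulate_spectra(zeaxanthin_amp = 0.30,
                         noise = noise_spec(0.02, additive_sd = 2e-3,
                                            seed = 101))
  cmp <- compare_band(prep_spectra(ga), prep_spectra(gb))
  sig <- cmp$wavelength_nm[cmp$significant]
  expect_gt(length(sig), 0)
  # detection sits on and around the 485-nm zeaxanthin band
  expect_true(any(sig >= 482 & sig <= 488))
  expect_gte(mean(sig >= 478 & sig <= 494), 0.5)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(cmp$p_holm >= cmp$p_value - 1e-15))
})

test_that("identical groups yield no more than chance-level detections", {
  ga <- simulate_spectra(noise = noise_spec(0.02, additive_sd = 2e-3,
                                            seed = 11))
  gb <- simulate_spectra(noise = noise_spec(0.02, additive_sd = 2e-3,
                                            seed = 211))
  cmp <- compare_band(prep_spectra(ga), prep_spectra(gb))
  expect_lte(sum(cmp$significant), 2)
})

test_that("per-wavelength type-I error is near alpha under an iid null", {
  # the test machinery itself, on iid Gaussian replicate values
  wl <- seq(470, 500, 2)
  n_sim <- 300
  null_rate <- function(n_rep) {
    fp <- vapply(seq_len(n_sim), function(s) {
      mk <- function(offset) {
        purrr::map_dfr(seq_len(n_rep), function(r) {
          tibble::tibble(replicate_id = r, wavelength_nm = wl,
                         d2 = withr::with_seed(offset + 100 * s + r,
                                               rnorm(length(wl))))
        })
      }
      mean(compare_band(mk(0), mk(5e6))$significant)
    }, numeric(1))
    mean(fp)
  }
  se <- sqrt(0.05 * 0.95 / (n_sim * length(wl)))
  # with ample replication Welch's approximation is accurate and the rate
  # sits inside the binomial band around alpha
  expect_lt(abs(null_rate(30) - 0.05), 4 * se)
  # at the experimental n = 3 Welch is known to run slightly conservative:
  # the rate must stay near alpha and never exceed it beyond Monte Carlo
  # error
  p3 <- null_rate(3)
  expect_lt(p3, 0.05 + 4 * se)
  expect_gt(p3, 0.02)
})

test_that("chl-specific absorption follows its definition and scalings", {
  wl <- seq(400, 750, 1)
  flat <- tibble::tibble(wavelength_nm = wl, a_per_m = 1,
                         chl_ug_per_L = 100)
  expect_equal(chl_specific_absorption(flat)$a_star_m2_per_mg, 0.01)
  expect_equal(
    chl_specific_absorption(dplyr::mutate(flat, chl_ug_per_L = 200))$a_star_m2_per_mg,
    0.005
  )
  expect_equal(
    chl_specific_absorption(dplyr::mutate(flat, a_per_m = 2))$a_star_m2_per_mg,
    0.02
  )
  expect_equal(chl_specific_absorption(flat, method = "integral")$a_star_m2_per_mg,
               0.01, tolerance = 1e-12)
  expect_error(chl_specific_absorption(dplyr::mutate(flat, chl_ug_per_L = 0)),
               class = "psiikinetics_invalid_input")
  # the simulated reference spectrum lands near the observed ~0.009 m2/mg
  sp <- simulate_spectra(noise = noise_free(), n_replicates = 1,
                         chl_ug_per_L = 40)
  astar <- chl_specific_absorption(sp)$a_star_m2_per_mg
  expect_gt(astar, 0.001)
  expect_lt(astar, 0.05)
})
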