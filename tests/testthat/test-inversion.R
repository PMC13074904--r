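make_curve2 <- function(rho, R) {
  cv <- tibble::tibble(rho_mm = rho, R = R, n_pixels = rep(8L, length(rho)))
  attr(cv, "d_rho") <- diff(rho[1:2])
  class(cv) <- c("srr_radial", class(cv))
  cv
}

test_that("chi-squared: exact arithmetic on constructed curves", {
  rho <- (1:20 - 0.5) * 0.1
  w <- structure(list(rho_0 = 0.25, rho_m = 0.55, P = 4, truncated = FALSE),
                 class = "srr_window")
  a <- make_curve2(rho, exp(-rho))
  expect_equal(chi_squared(a, a, w), 0)
  b <- make_curve2(rho, exp(-rho) / 10)
  expect_equal(chi_squared(a, b, w), 1, tolerance = 1e-12)
  # P = 4 with one bin off by a factor of 10
  cc <- make_curve2(rho, ifelse(seq_along(rho) == 3, exp(-rho) * 10,
                                exp(-rho)))
  expect_equal(chi_squared(cc, a, w), 0.25, tolerance = 1e-12)
  # non-positive bins shrink P with a warning
  d <- make_curve2(rho, ifelse(seq_along(rho) == 3, 0, exp(-rho)))
  expect_warning(x <- chi_squared(d, a, w), "excluded")
  expect_equal(x, 0)
  expect_error(chi_squared(make_curve2(rho, rep(0, 20)), a, w), "P = 0")
})

test_that("chi-squared under common random numbers is deterministic in the
           parameters", {
  s <- test_sim_mid()
  curve <- radial_bin(s$image)
  beam <- test_beam(192)
  geom <- sample_geometry(55.5)
  w <- suppressWarnings(fit_window(curve, rho_r = beam$rho_r))
  eval_once <- function() {
    sim <- simulate_srr_image(optical_props(0.012, 1.9, g = 0.8, n = 1.33),
                              geom, beam, sim_config(3e4, seed = 123))
    chi_squared(radial_bin(sim$image), curve, w, quiet = TRUE)
  }
  expect_identical(eval_once(), eval_once())
})

test_that("flat information-free curves do not crash the fit", {
  rho <- (1:150 - 0.5) * 0.0361
  flat <- make_curve2(rho, rep(0.01, 150))
  beam <- test_beam(128)
  fit <- suppressWarnings(
    lm_fit(flat, beam, sample_geometry(55.5),
           fit_config(n_photons_per_iter = 5e3, seed = 2,
                      max_iterations = 6)))
  expect_s3_class(fit, "srr_fit")
  expect_true(is.finite(fit$chi2_final))
})

test_that("accepted LM steps never increase the cost and the trace is
           tidy-able", {
  s <- test_sim_mid()
  curve <- radial_bin(s$image)
  beam <- test_beam(192)
  fit <- suppressWarnings(
    lm_fit(curve, beam, sample_geometry(55.5),
           fit_config(n_photons_per_iter = 2e4, seed = 31,
                      max_iterations = 8)))
  for (nf in unique(fit$trace$n_photons)) {
    ch <- fit$trace$chi2[fit$trace$n_photons == nf]
    expect_true(all(diff(ch) <= 0))
  }
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("iteration", "mu_a", "mu_s_prime", "chi2") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mu_a_hat, fit$mu_a_hat)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("zero-bin origin shift reports exact zero differences", {
  s <- test_sim_mid()
  curve <- radial_bin(s$image)
  beam <- test_beam(192)
  rep0 <- suppressWarnings(
    origin_shift_sensitivity(curve, beam, sample_geometry(55.5),
                             fit_config(n_photons_per_iter = 1e4, seed = 3,
                                        max_iterations = 4),
                             shift_bins = 0))
  expect_equal(rep0$comparison$rel_diff, c(0, 0))
  expect_equal(rep0$chi2_ratio, 1)
})
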