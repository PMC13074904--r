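test_that("identity perturbation returns the original image bit-exactly", {
  s <- test_sim_mid()
  p <- s$props
  img <- rescale_reflectance(s$paths, p, p)
  expect_identical(img$values, s$image$values)
  expect_error(
    rescale_reflectance(s$paths, p,
                        optical_props(p$mu_a, p$mu_s_prime, g = 0.5)),
    "unsupported")
})

test_that("pMC weight factors match hand evaluation", {
  # one photon, j = 2, L = 10 mm, mu_s 1.0 -> 1.1 (g = 0): factor
  # 1.1^2 * exp(-0.1*10); deposited value = weight * factor / area
  p1 <- optical_props(0.01, 1, g = 0, n = 1)
  paths <- make_paths(4, 4, weight = 0.5, j = 2, L = 10, props = p1)
  p2 <- optical_props(0.01, 1.1, g = 0, n = 1)
  img <- rescale_reflectance(paths, p1, p2)
  f <- 1.1^2 * exp(-0.1 * 10)
  expect_equal(f, 0.44513, tolerance = 1e-4)
  expect_equal(img$values[4, 4], 0.5 * f)
  # mu_a 0.01 -> 0.02, L = 10: factor exp(-0.1)
  p3 <- optical_props(0.02, 1, g = 0, n = 1)
  img3 <- rescale_reflectance(paths, p1, p3)
  expect_equal(img3$values[4, 4] / img$values[4, 4] * f,
               exp(-0.1), tolerance = 1e-12)
  expect_equal(exp(-0.1), 0.90484, tolerance = 1e-4)
})

test_that("rescale-then-bin equals bin-then-rescale for a mu_a shift", {
  # binning is linear in the weights, and a pure mu_a perturbation scales
  # every photon by exp(-dmua*L); with equal L the image scales globally
  p1 <- optical_props(0.01, 1, g = 0, n = 1)
  paths <- make_paths(c(2, 6, 4), c(3, 5, 4), weight = c(0.2, 0.4, 0.9),
                      j = c(1, 3, 2), L = c(5, 5, 5), props = p1)
  p2 <- optical_props(0.03, 1, g = 0, n = 1)
  img1 <- rescale_reflectance(paths, p1, p1)
  img2 <- rescale_reflectance(paths, p1, p2)
  expect_equal(img2$values, img1$values * exp(-0.02 * 5), tolerance = 1e-14)
})

test_that("Jacobian columns: identity gives zeros, absorption derivative
           is non-positive", {
  s <- test_sim_mid()
  p <- s$props
  # mu_a = 0 makes the mu_a perturbation an identity: derivative all zero
  p0 <- optical_props(0, p$mu_s_prime, g = p$g, n = p$n)
  paths0 <- s$paths
  attr(paths0, "props") <- p0
  jc0 <- jacobian_columns(paths0, p0, perturbation_spec("mu_a", 0.05))
  expect_true(all(jc0$dR_dmu_a == 0))
  jc <- suppressWarnings(
    jacobian_columns(s$paths, p, list(perturbation_spec("mu_a"),
                                      perturbation_spec("mu_s_prime"))))
  expect_true(all(jc$dR_dmu_a[!is.na(jc$dR_dmu_a)] <= 0))
  expect_named(jc, c("rho_mm", "R", "dR_dmu_a", "dR_dmu_s_prime"))
})

test_that("pMC rescaling reproduces a fresh common-seed simulation", {
  s <- test_sim_mid()
  p <- s$props
  geom <- sample_geometry(55.5)
  beam <- test_beam(192)
  d <- 0.05
  p2 <- optical_props(p$mu_a * (1 + d), p$mu_s_prime * (1 + d),
                      g = p$g, n = p$n)
  s2 <- simulate_srr_image(p2, geom, beam,
                           sim_config(s$config$n_photons,
                                      seed = s$config$seed))
  c_pmc <- radial_bin(rescale_reflectance(s$paths, p, p2))
  c_sim <- radial_bin(s2$image)
  w <- suppressWarnings(fit_window(radial_bin(s$image), rho_r = 0.27))
  sel <- c_pmc$rho_mm >= w$rho_0 & c_pmc$rho_mm <= w$rho_m &
    !is.na(c_sim$R) & c_sim$R > 0 & !is.na(c_pmc$R)
  npx <- c_sim$n_pixels[sel]
  area <- s$image$pixel_scale^2
  counts <- c_sim$R[sel] * npx * area * s$config$n_photons
  se_rel <- sqrt(2 / pmax(counts, 1))
  z <- abs(c_pmc$R[sel] / c_sim$R[sel] - 1) / se_rel
  expect_lt(mean(z > 3), 0.02)
})

test_that("Eq. (5) pMC derivative matches the Eq. (4) brute-force finite
           difference", {
  s <- test_sim_mid()
  p <- s$props
  geom <- sample_geometry(55.5)
  beam <- test_beam(192)
  d <- 0.05
  coarse <- 10 * s$image$pixel_scale
  c0 <- radial_bin(s$image, d_rho = coarse)
  w <- suppressWarnings(fit_window(c0, rho_r = 0.27))
  sel <- which(c0$rho_mm >= w$rho_0 & c0$rho_mm <= w$rho_m)
  # mu_a: common random numbers leave every path identical, so the two
  # estimators coincide to rounding
  p2 <- optical_props(p$mu_a * (1 + d), p$mu_s_prime, g = p$g, n = p$n)
  s2 <- simulate_srr_image(p2, geom, beam,
                           sim_config(s$config$n_photons,
                                      seed = s$config$seed))
  fd <- (radial_bin(s2$image, d_rho = coarse)$R[sel] - c0$R[sel]) /
    (p$mu_a * d)
  jc <- jacobian_columns(s$paths, p, perturbation_spec("mu_a", d), w,
                         d_rho = coarse)
  expect_lt(max(abs(jc$dR_dmu_a - fd) / pmax(abs(fd), 1e-12)), 0.05)
  # mu_s': the re-simulated paths genuinely move between bins, so the
  # brute-force column carries migration noise; agreement is statistical
  p3 <- optical_props(p$mu_a, p$mu_s_prime * (1 + d), g = p$g, n = p$n)
  s3 <- simulate_srr_image(p3, geom, beam,
                           sim_config(s$config$n_photons,
                                      seed = s$config$seed))
  fd3 <- (radial_bin(s3$image, d_rho = coarse)$R[sel] - c0$R[sel]) /
    (p$mu_s_prime * d)
  jc3 <- suppressWarnings(
    jacobian_columns(s$paths, p, perturbation_spec("mu_s_prime", d), w,
                     d_rho = coarse))
  scale <- max(abs(fd3))
  expect_lt(median(abs(jc3$dR_dmu_s_prime - fd3)) / scale, 0.05)
  expect_gt(cor(jc3$dR_dmu_s_prime, fd3), 0.95)
})

test_that("over-large perturbations trigger the validity warning", {
  p1 <- optical_props(0.01, 1, g = 0, n = 1)
  paths <- make_paths(4, 4, weight = 0.5, j = 200, L = 1, props = p1)
  expect_warning(
    jacobian_columns(paths, p1, perturbation_spec("mu_s_prime", 0.1)),
    "pMC validity")
  expect_error(perturbation_spec("mu_a", -0.1), "delta")
})
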