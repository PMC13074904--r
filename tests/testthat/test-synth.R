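test_that("synthetic beam profile: normalization, core confinement,
           monotone halo", {
  beam <- make_beam_profile(grid = test_grid(128))
  expect_equal(sum(beam$weights), 1, tolerance = 1e-12)
  expect_true(all(beam$weights >= 0))
  # halo off: 99% of the energy within 2 rho_r
  pure <- make_beam_profile(grid = test_grid(128), halo_amplitude = 0)
  cv <- radial_bin(pure$weights, origin = pure$origin,
                   pixel_scale = pure$pixel_scale)
  inside <- cv$rho_mm <= 2 * pure$rho_r
  expect_gt(sum(cv$R[inside] * cv$n_pixels[inside], na.rm = TRUE), 0.99)
  # radial profile decays monotonically beyond the core
  cvh <- radial_bin(beam$weights, origin = beam$origin,
                    pixel_scale = beam$pixel_scale)
  tail_sel <- which(cvh$rho_mm > 2 * beam$rho_r & !is.na(cvh$R))
  expect_true(all(diff(cvh$R[tail_sel]) <= 1e-15))
})

test_that("render linearity: 10x exposure scales mean counts by 10", {
  truth <- radial_test_image(64, 0.1, function(r) 1e-2 * exp(-r / 3))
  cam <- camera_model(dark_offset = 0, read_noise_sd = 0)
  f1 <- render_frame(truth, 5, 2, cam, seed = 1)
  f10 <- render_frame(truth, 50, 2, cam, seed = 2)
  hot <- truth$values > quantile(truth$values, 0.9)
  ratio <- mean(f10$counts[hot]) / mean(f1$counts[hot])
  expect_lt(abs(ratio - 10) / 10, 0.05)
  # fixed seed: bit-identical frames
  expect_identical(render_frame(truth, 5, 2, cam, seed = 1)$counts,
                   f1$counts)
})

test_that("auto-exposure hits the 30,000-count operating point", {
  truth <- radial_test_image(64, 0.1, function(r) 2e-3 * exp(-r))
  cam <- camera_model(read_noise_sd = 0)
  t1 <- auto_exposure(truth, cam, pd_voltage_v = 2)
  f <- render_frame(truth, t1, 2, cam, seed = 4, noise = "none")
  expect_equal(max(f$counts), 30000, tolerance = 1e-6)
  fn <- render_frame(truth, t1, 2, camera_model(), seed = 4)
  expect_lt(abs(max(fn$counts) - 30000) / 30000, 0.05)
  # doubling the gain halves the integration time
  t2 <- auto_exposure(truth, camera_model(gain = 2 * cam$gain,
                                          read_noise_sd = 0), 2)
  expect_equal(t2, t1 / 2, tolerance = 1e-12)
  expect_warning(auto_exposure(truth, cam, 2, target_max = 7e4),
                 "full well")
})

test_that("bloom conserves charge and is recovered by detection", {
  truth <- radial_test_image(64, 0.1, function(r) 1e-3 * exp(-(r / 0.4)^2))
  cam <- camera_model(read_noise_sd = 0, dark_offset = 0)
  t1 <- auto_exposure(truth, cam, 2)
  # drive the core 5x over the full well
  f <- render_frame(truth, t1 * 5 * 65535 / 30000, 2, cam, seed = 6,
                    noise = "none")
  expect_lte(max(f$counts), 65535)
  # conservation up to the clip at frame edges
  expected <- truth$values * cam$gain * (t1 * 5 * 65535 / 30000) * 2
  edge <- attr(f, "bloom_edge_loss")
  expect_lt(abs(sum(f$counts) + edge - sum(expected)) / sum(expected),
            1e-6)
  # the streak is columnar and detect_bloom finds the spilled pixels
  over <- expected > cam$full_well
  mask <- detect_bloom(f)
  spilled <- f$counts >= 0.9 * 0.95 * 65535 & !over
  expect_gt(sum(mask[spilled]) / max(sum(spilled), 1), 0.95)
  expect_true(all(mask[over]))
})

test_that("noise-free render + normalize closes on the truth", {
  truth <- radial_test_image(64, 0.1, function(r) 1e-3 * exp(-r / 2))
  cam <- camera_model(read_noise_sd = 0)
  t1 <- auto_exposure(truth, cam, 2)
  f <- render_frame(truth, t1, 2, cam, noise = "none")
  dark <- camera_frame(matrix(cam$dark_offset, 64, 64), t1, 2)
  img <- normalize_frame(subtract_dark(f, dark), 0.1, truth$origin)
  # values = truth * gain / pixel_area, exactly
  expect_equal(img$values, truth$values * cam$gain / 0.1^2,
               tolerance = 1e-9)
})

test_that("two identically seeded measurements are identical", {
  scen <- synthetic_scenario(grid = test_grid(48), n_photons_truth = 2e3,
                             seed = 5, beam = test_beam(48))
  m1 <- synth_measurement(scen, 0.01, 1.5, sample_k = 1)
  m2 <- synth_measurement(scen, 0.01, 1.5, sample_k = 1)
  expect_identical(m1$frames[[2]]$counts, m2$frames[[2]]$counts)
  expect_identical(m1$truth_sim$image$values, m2$truth_sim$image$values)
  expect_equal(m1$t1_ms, m2$t1_ms)
})

test_that("acceptance grid spans the validated property envelope", {
  gr <- srr_acceptance_grid()
  expect_gte(nrow(gr), 6)
  expect_equal(range(gr$mu_s_prime), c(1, 4))
  expect_equal(range(gr$mu_a), c(5e-4, 0.5))
  expect_gte(sum(gr$mu_a >= 1e-3), 4)
  st <- srr_sample_table()
  expect_equal(nrow(st), 8)
  expect_equal(max(st$mu_a) / min(st$mu_a), 1001, tolerance = 0.01)
})
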