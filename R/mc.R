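#' Incident beam profile
#'
#' The launch distribution of the forward Monte Carlo: a 2D non-negative
#' weight image on the detector pixel grid, the pixel scale, the origin pixel
#' where the beam axis meets the surface, and the incidence angle in air.
#'
#' @param weights non-negative numeric matrix of relative beam intensity.
#' @param pixel_scale pixel side length in mm.
#' @param origin integer `(row, col)` of the beam incidence pixel (1-based).
#' @param incidence_deg beam angle from the surface normal, in air (degrees).
#' @param rho_r nominal focused beam radius in mm.
#' @return An object of class `srr_beam`.
#' @export
beam_profile <- function(weights, pixel_scale, origin,
                         incidence_deg = 21, rho_r = 0.27) {
  if (!is.matrix(weights) || !is.numeric(weights))
    abort("`weights` must be a numeric matrix.")
  if (any(weights < 0)) abort("beam weights must be non-negative.")
  if (sum(weights) <= 0) abort("beam profile must have positive total weight.")
  if (pixel_scale <= 0) abort("`pixel_scale` must be positive.")
  origin <- as.integer(round(origin))
  if (length(origin) != 2 || origin[1] < 1 || origin[1] > nrow(weights) ||
      origin[2] < 1 || origin[2] > ncol(weights))
    abort("`origin` must be a (row, col) pair inside the grid.")
  structure(list(weights = weights, pixel_scale = as.numeric(pixel_scale),
                 origin = origin, incidence_deg = as.numeric(incidence_deg),
                 rho_r = as.numeric(rho_r)),
            class = "srr_beam")
}

#' Monte Carlo simulation settings
#'
#' @param n_photons number of launched photons.
#' @param seed integer seed; a fixed seed reproduces images bit-exactly.
#' @param roulette_threshold effective-weight threshold below which Russian
#'   roulette is played.  With the splitting detector every surface crossing
#'   deposits its refracted fraction, so continuations below about 1% weight
#'   carry almost no remaining signal; the default kills them early, which
#'   is unbiased and roughly halves the run time relative to a much smaller
#'   threshold at indistinguishable tail noise.
#' @param roulette_survival survival probability of the roulette (the
#'   surviving photon's weight is divided by this, keeping the estimate
#'   unbiased).
#' @param max_path_events hard cap on scattering events per photon.
#' @param lateral_kill_radius radius (mm) beyond which photons face an
#'   unbiased distance roulette (survival 0.2 with a 5x weight boost, the
#'   shell growing 1.5x per survival).  `NULL` (default) picks 1.5x the
#'   grid corner radius; photons that far out rarely return to the
#'   detector, so killing most of them is a large, bias-free saving.
#' @return An object of class `srr_sim_config`.
#' @export
sim_config <- function(n_photons = 1e5, seed = 1,
                       roulette_threshold = 1e-2, roulette_survival = 0.1,
                       max_path_events = 1e6,
                       lateral_kill_radius = NULL) {
  if (n_photons < 1) abort("`n_photons` must be >= 1.")
  if (roulette_survival <= 0 || roulette_survival >= 1)
    abort("`roulette_survival` must lie in (0, 1).")
  structure(list(n_photons = as.numeric(n_photons), seed = as.numeric(seed),
                 roulette_threshold = as.numeric(roulette_threshold),
                 roulette_survival = as.numeric(roulette_survival),
                 max_path_events = as.numeric(max_path_events),
                 lateral_kill_radius = if (is.null(lateral_kill_radius))
                   NULL else as.numeric(lateral_kill_radius)),
            class = "srr_sim_config")
}

new_srr_image <- function(values, pixel_scale, origin, n_launched = NA_real_,
                          seed = NA_real_, units = "mm^-2 per photon") {
  structure(list(values = values, pixel_scale = as.numeric(pixel_scale),
                 origin = as.integer(round(origin)),
                 n_launched = as.numeric(n_launched),
                 seed = as.numeric(seed), units = units),
            class = "srr_image")
}

#' @export
print.srr_image <- function(x, ...) {
  cat(sprintf(
    "<srr_image> %d x %d px @ %g mm, origin (%d, %d), total R = %.4g [%s]\n",
    nrow(x$values), ncol(x$values), x$pixel_scale, x$origin[1], x$origin[2],
    sum(x$values) * x$pixel_scale^2, x$units))
  invisible(x)
}

# deposit detected-photon weights onto the pixel grid
bin_paths_to_image <- function(row, col, weight, nr, nc) {
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  img <- numeric(nr * nc)
  if (any(ok)) {
    idx <- (col[ok] - 1L) * nr + row[ok]
    acc <- rowsum(weight[ok], idx)
    img[as.integer(rownames(acc))] <- acc[, 1]
  }
  matrix(img, nr, nc)
}

run_transport <- function(props, geom, cfg, pencil, beam = NULL,
                          grid = NULL) {
  stopifnot(inherits(props, "srr_props"), inherits(geom, "srr_geometry"),
            inherits(cfg, "srr_sim_config"))
  if (pencil) {
    nr <- grid$nrow; nc <- grid$ncol
    ps <- grid$pixel_scale; org <- as.integer(round(grid$origin))
    ang <- grid$incidence_deg %||% 0
    bw <- matrix(0, 1, 1)
  } else {
    stopifnot(inherits(beam, "srr_beam"))
    nr <- nrow(beam$weights); nc <- ncol(beam$weights)
    ps <- beam$pixel_scale; org <- beam$origin
    ang <- beam$incidence_deg
    bw <- beam$weights
  }
  res <- cpp_mc_transport(
    mu_a = props$mu_a, mu_s = props$mu_s, g = props$g, n_medium = props$n,
    n_above = geom$n_above, thickness = geom$thickness_d,
    beam_w = bw, origin_row = org[1], origin_col = org[2],
    pixel_scale = ps, incidence_deg = ang,
    n_photons = cfg$n_photons, seed = cfg$seed,
    roulette_threshold = cfg$roulette_threshold,
    roulette_survival = cfg$roulette_survival,
    max_events = cfg$max_path_events, pencil = pencil,
    lateral_kill_radius = cfg$lateral_kill_radius %||%
      (1.5 * sqrt(sum((pmax(org, c(nr, nc) - org) * ps)^2))))
  p <- res$paths
  # exit positions (mm relative to the origin pixel center) -> pixel indices
  row <- org[1] + as.integer(floor(p[, "y"] / ps + 0.5))
  col <- org[2] + as.integer(floor(p[, "x"] / ps + 0.5))
  w_det <- p[, "weight_r"] * exp(-props$mu_a * p[, "L"])
  img <- bin_paths_to_image(row, col, w_det, nr, nc) /
    (cfg$n_photons * ps^2)
  image <- new_srr_image(img, ps, org, n_launched = cfg$n_photons,
                         seed = cfg$seed)
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  paths <- tibble(row = row[ok], col = col[ok], weight = w_det[ok],
                  j = p[ok, "j"], L = p[ok, "L"])
  attr(paths, "props") <- props
  attr(paths, "pixel_scale") <- ps
  attr(paths, "origin") <- org
  attr(paths, "dims") <- c(nr, nc)
  attr(paths, "n_launched") <- cfg$n_photons
  class(paths) <- c("srr_paths", class(paths))
  structure(list(image = image, paths = paths, energy = res$energy,
                 props = props, geom = geom, config = cfg),
            class = "srr_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the SRR reflectance image with an integrated beam profile
#'
#' Runs the photon-transport Monte Carlo for a homogeneous slab.  Photons are
#' launched at surface positions drawn from the beam-profile weights
#' (jittered uniformly within the selected pixel), travel with free paths
#' sampled from the scattering coefficient, scatter by the Henyey-Greenstein
#' phase function, and meet an unpolarized-Fresnel decision at the top
#' interface.  Every photon that refracts out through the top surface is
#' detected at its exit pixel with weight `exp(-mu_a * L)` (no solid-angle
#' cut); absorption is a terminal weight factor, which makes stored paths
#' exactly rescalable to perturbed coefficients (see
#' [rescale_reflectance()]).
#'
#' @param props [optical_props()] of the medium.
#' @param geom [sample_geometry()].
#' @param beam [beam_profile()]; detector grid and beam grid coincide.
#' @param cfg [sim_config()].
#' @return An object of class `srr_sim`: a list with `image` (an
#'   `srr_image`, units mm^-2 per launched photon), `paths` (a tibble of
#'   per-photon sufficient statistics: exit `row`, `col`, detected `weight`,
#'   collision count `j`, path length `L` in mm), and `energy` (the exact
#'   weight ledger: top, bottom, absorbed, roulette_killed, roulette_gain,
#'   truncated).
#' @seealso [simulate_pencil_image()], [convolve_with_beam()],
#'   [diffusion_reflectance()]
#' @export
simulate_srr_image <- function(props, geom, beam, cfg = sim_config()) {
  run_transport(props, geom, cfg, pencil = FALSE, beam = beam)
}

#' Simulate a pencil-beam reflectance image
#'
#' As [simulate_srr_image()] but all photons enter at the origin pixel
#' center with the refracted oblique direction.  The result can be
#' convolved with a measured beam profile ([convolve_with_beam()]) to
#' reproduce the integrated-beam simulation.
#'
#' @inheritParams simulate_srr_image
#' @param grid detector grid description: a list with `nrow`, `ncol`,
#'   `pixel_scale` (mm), `origin` (row, col) and optional `incidence_deg`
#'   (defaults to 0, i.e. normal incidence).
#' @return An `srr_sim` object (see [simulate_srr_image()]).
#' @export
simulate_pencil_image <- function(props, geom, cfg = sim_config(),
                                  grid = grid_spec()) {
  run_transport(props, geom, cfg, pencil = TRUE, grid = grid)
}

#' Detector grid description
#'
#' @param nrow,ncol grid dimensions in pixels.
#' @param pixel_scale pixel side length in mm (instrument value 0.0361 mm).
#' @param origin `(row, col)` of the beam axis; defaults to the grid center.
#' @param incidence_deg incidence angle used for pencil launches.
#' @export
grid_spec <- function(nrow = 512, ncol = 512, pixel_scale = 0.0361,
                      origin = NULL, incidence_deg = 0) {
  origin <- origin %||% c(nrow %/% 2, ncol %/% 2)
  list(nrow = as.integer(nrow), ncol = as.integer(ncol),
       pixel_scale = as.numeric(pixel_scale),
       origin = as.integer(round(origin)),
       incidence_deg = as.numeric(incidence_deg))
}

#' Convolve a pencil-beam image with a beam profile
#'
#' Discrete 2D convolution of a pencil-beam reflectance image with a
#' beam-profile kernel (weights normalized to unit sum), cropped back to the
#' original grid with the origin preserved.  Equivalent in expectation to
#' launching photons from the beam-weighted distribution directly.
#'
#' @param pencil_image an `srr_image` from [simulate_pencil_image()].
#' @param beam a [beam_profile()] on the same grid.
#' @return An `srr_image` on the same grid.
#' @export
convolve_with_beam <- function(pencil_image, beam) {
  if (inherits(pencil_image, "srr_sim")) pencil_image <- pencil_image$image
  stopifnot(inherits(pencil_image, "srr_image"), inherits(beam, "srr_beam"))
  v <- pencil_image$values
  if (!identical(dim(v), dim(beam$weights)) ||
      abs(pencil_image$pixel_scale - beam$pixel_scale) > 1e-12 ||
      !identical(pencil_image$origin, beam$origin))
    abort("pencil image and beam profile must share grid, scale and origin.")
  nr <- nrow(v); nc <- ncol(v)
  w <- beam$weights / sum(beam$weights)
  # zero-padded linear convolution; kernel indexed by offset from the origin
  P1 <- 2L * nr; P2 <- 2L * nc
  ker <- matrix(0, P1, P2)
  dr <- (seq_len(nr) - beam$origin[1]) %% P1 + 1L
  dc <- (seq_len(nc) - beam$origin[2]) %% P2 + 1L
  ker[dr, dc] <- w
  pad <- matrix(0, P1, P2)
  pad[seq_len(nr), seq_len(nc)] <- v
  out <- Re(fft(fft(pad) * fft(ker), inverse = TRUE)) / (P1 * P2)
  out <- out[seq_len(nr), seq_len(nc)]
  out[out < 0 & out > -1e-12] <- 0  # FFT rounding
  new_srr_image(out, pencil_image$pixel_scale, pencil_image$origin,
                n_launched = pencil_image$n_launched,
                seed = pencil_image$seed, units = pencil_image$units)
}

#' Diffusion-dipole reflectance oracle
#'
#' Closed-form steady-state diffuse reflectance of a pencil beam on a
#' semi-infinite medium, from the dipole (image-source) solution of the
#' diffusion approximation with an extrapolated boundary: an isotropic
#' source at depth `z0 = 1/(mu_a + mu_s')` and its mirror image above the
#' extrapolated boundary at `-z0 - 2*zb`, `zb = 2*A*D`, with the
#' internal-reflection parameter `A` from the Groenhuis polynomial in the
#' relative index.  The reflectance integrates the boundary radiance
#' (fluence plus flux term) against the Fresnel transmission of the
#' interface, the form that tracks transport solutions well down to a few
#' transport lengths.  Serves as an independent check of the Monte Carlo in
#' the diffusive regime (`mu_a << mu_s'`, `rho * mu_s' >~ 2`).
#'
#' @param props [optical_props()]; the relative index is `props$n / n_above`.
#' @param rho radial distances from the entry point (mm), > 0.
#' @param n_above refractive index above the surface.
#' @return Diffuse reflectance in mm^-2 per incident photon, one value per
#'   `rho`.
#' @export
diffusion_reflectance <- function(props, rho, n_above = 1.0) {
  stopifnot(inherits(props, "srr_props"))
  if (any(rho <= 0)) abort("`rho` must be positive.")
  if (props$mu_a > 0.1 * props$mu_s_prime)
    warn("diffusion approximation is unreliable for mu_a > 0.1 * mu_s'.")
  mua <- props$mu_a; mutp <- props$mu_a + props$mu_s_prime
  z0 <- 1 / mutp
  D <- 1 / (3 * mutp)
  mueff <- sqrt(3 * mua * mutp)
  nrel <- props$n / n_above
  rd <- -1.440 / nrel^2 + 0.710 / nrel + 0.668 + 0.0636 * nrel
  A <- (1 + rd) / (1 - rd)
  zb <- 2 * A * D
  # Fresnel-weighted moments of the escaping radiance
  # L = phi/(4 pi) + 3 j cos(theta)/(4 pi)
  trans <- function(mu) 1 - fresnel_unpolarized(props$n, n_above, mu)
  c_phi <- stats::integrate(function(mu) trans(mu) * mu, 0, 1)$value / 2
  c_j <- 3 * stats::integrate(function(mu) trans(mu) * mu^2, 0, 1)$value / 2
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  phi <- (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
  flux <- (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
             (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) /
    (4 * pi)
  c_phi * phi + c_j * flux
}
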