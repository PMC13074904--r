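# shared fixtures, built lazily and cached for the duration of the run
srr_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = srr_test_cache))
    assign(key, expr, envir = srr_test_cache)
  get(key, envir = srr_test_cache)
}

test_grid <- function(n = 128, ps = 0.0361, angle = 21)
  grid_spec(n, n, ps, incidence_deg = angle)

test_beam <- function(n = 128, ps = 0.0361)
  cached(sprintf("beam_%d_%g", n, ps),
         make_beam_profile(grid = test_grid(n, ps)))

# a mid-absorption simulation reused by several tests
test_sim_mid <- function() cached("sim_mid", {
  simulate_srr_image(optical_props(0.01, 2, g = 0.8, n = 1.33),
                     sample_geometry(55.5), test_beam(192),
                     sim_config(2e5, seed = 5))
})

# hand-made path-statistics tibble for exact pMC factor checks
make_paths <- function(row, col, weight, j, L, nr = 8, nc = 8, ps = 1,
                       origin = c(4, 4), props = optical_props(0.01, 1),
                       n_launched = 1) {
  p <- tibble::tibble(row = row, col = col, weight = weight, j = j, L = L)
  attr(p, "props") <- props
  attr(p, "pixel_scale") <- ps
  attr(p, "origin") <- origin
  attr(p, "dims") <- c(nr, nc)
  attr(p, "n_launched") <- n_launched
  class(p) <- c("srr_paths", class(p))
  p
}

# radially symmetric synthetic image for binning tests
radial_test_image <- function(n = 64, ps = 0.1, fun = function(r) exp(-r)) {
  org <- c(n %/% 2, n %/% 2)
  d <- (seq_len(n) - org[1]) * ps
  r <- sqrt(outer(d^2, d^2, "+"))
  srrtwin:::new_srr_image(matrix(fun(r), n, n), ps, org)
}

# image constant within each radial bin: annulus means equal pixel values
annulus_test_image <- function(n = 64, ps = 0.1,
                               fun = function(rc) exp(-rc)) {
  org <- c(n %/% 2, n %/% 2)
  d <- (seq_len(n) - org[1]) * ps
  r <- sqrt(outer(d^2, d^2, "+"))
  rc <- (floor(r / ps) + 0.5) * ps
  srrtwin:::new_srr_image(matrix(fun(rc), n, n), ps, org)
}

# independent transcription of the dipole oracle used as a cross-check
dipole_reference <- function(mu_a, mu_sp, n_rel, rho) {
  mut <- mu_a + mu_sp
  D <- 1 / (3 * mut)
  z0 <- 1 / mut
  mueff <- sqrt(mu_a / D)
  rd <- 0.0636 * n_rel + 0.668 + 0.710 / n_rel - 1.440 / n_rel^2
  zb <- (1 + rd) / (1 - rd) * 2 * D
  fres <- function(mu) {
    si <- sqrt(1 - mu^2)
    st <- n_rel * si
    out <- rep(1, length(mu))
    ok <- st < 1
    ct <- sqrt(1 - st[ok]^2)
    r_s <- ((n_rel * mu[ok] - ct) / (n_rel * mu[ok] + ct))^2
    r_p <- ((n_rel * ct - mu[ok]) / (n_rel * ct + mu[ok]))^2
    out[ok] <- (r_s + r_p) / 2
    out
  }
  cphi <- stats::integrate(function(m) (1 - fres(m)) * m, 0, 1)$value / 2
  cj <- 1.5 * stats::integrate(function(m) (1 - fres(m)) * m^2, 0, 1)$value
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  phi <- (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
  jz <- (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
           (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) /
    (4 * pi)
  cphi * phi + cj * jz
}
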