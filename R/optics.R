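#' Optical properties of a homogeneous turbid medium
#'
#' Container for the transport coefficients at a single wavelength.  The
#' reduced scattering coefficient is the primary scattering parameter
#' (`mu_s_prime = mu_s * (1 - g)` under the Henyey-Greenstein similarity
#' relation); the full scattering coefficient `mu_s` is derived from it and
#' the anisotropy factor.
#'
#' @param mu_a absorption coefficient (mm^-1), >= 0.
#' @param mu_s_prime reduced scattering coefficient (mm^-1), > 0.
#' @param g anisotropy factor (mean scattering cosine), |g| < 1.
#' @param n refractive index of the medium, >= 1.
#' @param wavelength wavelength in nm (metadata only).
#' @return An object of class `srr_props`: a list with fields `mu_a`,
#'   `mu_s_prime`, `g`, `n`, `wavelength` and the derived `mu_s`.
#' @examples
#' optical_props(mu_a = 0.01, mu_s_prime = 1, g = 0.8, n = 1.33)
#' @export
optical_props <- function(mu_a, mu_s_prime, g = 0.8, n = 1.33,
                          wavelength = NA_real_) {
  if (!is.numeric(mu_a) || length(mu_a) != 1 || is.na(mu_a) || mu_a < 0)
    abort("`mu_a` must be a single non-negative number (mm^-1).")
  if (!is.numeric(mu_s_prime) || length(mu_s_prime) != 1 ||
      is.na(mu_s_prime) || mu_s_prime <= 0)
    abort("`mu_s_prime` must be a single positive number (mm^-1).")
  if (!is.numeric(g) || length(g) != 1 || is.na(g) || abs(g) >= 1)
    abort("`g` must satisfy |g| < 1.")
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1)
    abort("`n` must be >= 1.")
  structure(
    list(mu_a = as.numeric(mu_a), mu_s_prime = as.numeric(mu_s_prime),
         g = as.numeric(g), n = as.numeric(n),
         wavelength = as.numeric(wavelength),
         mu_s = as.numeric(mu_s_prime) / (1 - as.numeric(g))),
    class = "srr_props")
}

#' @export
print.srr_props <- function(x, ...) {
  cat(sprintf(
    "<srr_props> mu_a = %g mm^-1, mu_s' = %g mm^-1 (mu_s = %g), g = %g, n = %g\n",
    x$mu_a, x$mu_s_prime, x$mu_s, x$g, x$n))
  invisible(x)
}

#' Slab sample geometry
#'
#' @param thickness_d slab thickness in mm (the medium occupies
#'   `0 <= z <= thickness_d`).
#' @param n_above refractive index of the upper half-space (air by default).
#' @return An object of class `srr_geometry`.
#' @export
sample_geometry <- function(thickness_d = 55.5, n_above = 1.0) {
  if (!is.numeric(thickness_d) || thickness_d <= 0)
    abort("`thickness_d` must be positive (mm).")
  if (!is.numeric(n_above) || n_above < 1)
    abort("`n_above` must be >= 1.")
  structure(list(thickness_d = as.numeric(thickness_d),
                 n_above = as.numeric(n_above)),
            class = "srr_geometry")
}

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the scattering deflection cosine under the
#' Henyey-Greenstein phase function.  The azimuth of a full direction update
#' is uniform on `[0, 2 pi)` and handled separately.
#'
#' @param g anisotropy factor, |g| < 1.
#' @param u uniform variates in `[0, 1)`.
#' @return Deflection cosines in `[-1, 1]`, one per element of `u`.  For
#'   `g = 0` this reduces to `2 u - 1` (isotropic scattering); the mean of the
#'   sampled cosine equals `g`.
#' @examples
#' mean(sample_hg_cosine(0.8, runif(1e4)))  # ~ 0.8
#' @export
sample_hg_cosine <- function(g, u) {
  if (!is.numeric(g) || length(g) != 1 || is.na(g) || abs(g) >= 1)
    abort("`g` must satisfy |g| < 1.")
  if (any(u < 0 | u >= 1)) abort("`u` must lie in [0, 1).")
  if (abs(g) < 1e-12) return(2 * u - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
}

#' Unpolarized Fresnel reflection probability
#'
#' Mean of the s- and p-polarized Fresnel power reflectances for light
#' incident from index `n_i` onto index `n_t`.  Beyond the critical angle
#' (possible when `n_i > n_t`) the reflectance is 1.
#'
#' @param n_i refractive index of the incidence medium (>= 1).
#' @param n_t refractive index of the transmission medium (>= 1).
#' @param cos_theta_i cosine(s) of the incidence angle, in `(0, 1]`.
#' @return Reflection probabilities in `[0, 1]`, vectorized over
#'   `cos_theta_i`.
#' @examples
#' fresnel_unpolarized(1, 1.33, 1)  # ~ 0.02006 at normal incidence
#' @export
fresnel_unpolarized <- function(n_i, n_t, cos_theta_i) {
  if (!is.numeric(n_i) || n_i < 1 || !is.numeric(n_t) || n_t < 1)
    abort("refractive indices must be >= 1.")
  if (any(cos_theta_i <= 0) || any(cos_theta_i > 1))
    abort("`cos_theta_i` must lie in (0, 1].")
  sin_i <- sqrt(pmax(0, 1 - cos_theta_i^2))
  sin_t <- n_i / n_t * sin_i
  R <- rep(1, length(cos_theta_i))
  ok <- sin_t < 1
  if (any(ok)) {
    ci <- cos_theta_i[ok]
    ct <- sqrt(1 - sin_t[ok]^2)
    rs <- ((n_i * ci - n_t * ct) / (n_i * ci + n_t * ct))^2
    rp <- ((n_i * ct - n_t * ci) / (n_i * ct + n_t * ci))^2
    R[ok] <- (rs + rp) / 2
  }
  R
}

#' Snell refraction of a ray at a planar interface
#'
#' @param theta_i incidence angle from the surface normal, degrees, in
#'   `[0, 90)`.
#' @param n_i,n_t refractive indices of the incidence and transmission media.
#' @return A list with `theta_t` (refracted angle in degrees, `NA` under
#'   total internal reflection) and logical `tir`.
#' @examples
#' snell_refract(21, 1, 1.33)$theta_t  # ~ 15.6 degrees
#' @export
snell_refract <- function(theta_i, n_i, n_t) {
  if (any(theta_i < 0) || any(theta_i >= 90))
    abort("`theta_i` must lie in [0, 90) degrees.")
  s <- n_i * sin(theta_i * pi / 180) / n_t
  tir <- s > 1
  theta_t <- ifelse(tir, NA_real_, asin(pmin(1, s)) * 180 / pi)
  list(theta_t = theta_t, tir = tir)
}

#' Analytic Henyey-Greenstein density of the deflection cosine
#'
#' @param ct deflection cosines.
#' @param g anisotropy factor.
#' @return Density values `p(cos theta)` normalized on `[-1, 1]`.
#' @keywords internal
#' @export
hg_density <- function(ct, g) {
  0.5 * (1 - g^2) / (1 + g^2 - 2 * g * ct)^1.5
}
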