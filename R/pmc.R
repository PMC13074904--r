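#' Perturbation specification for pMC derivatives
#'
#' @param parameter which coefficient to perturb: `"mu_a"` or
#'   `"mu_s_prime"`.
#' @param delta relative step size (dimensionless); the perturbed value is
#'   `p * (1 + delta)`.
#' @return An object of class `srr_perturbation`.
#' @export
perturbation_spec <- function(parameter = c("mu_a", "mu_s_prime"),
                              delta = 0.05) {
  parameter <- match.arg(parameter)
  if (!is.numeric(delta) || delta <= 0)
    abort("`delta` must be positive.")
  structure(list(parameter = parameter, delta = as.numeric(delta)),
            class = "srr_perturbation")
}

perturb_props <- function(props, spec) {
  p2 <- props
  if (spec$parameter == "mu_a") {
    p2$mu_a <- props$mu_a * (1 + spec$delta)
  } else {
    p2$mu_s_prime <- props$mu_s_prime * (1 + spec$delta)
    p2$mu_s <- p2$mu_s_prime / (1 - p2$g)
  }
  p2
}

# per-photon pMC weight factors for a mu_a / mu_s perturbation
pmc_factors <- function(paths, props, perturbed) {
  mus1 <- props$mu_s; mus2 <- perturbed$mu_s
  dmua <- perturbed$mu_a - props$mu_a
  dmus <- mus2 - mus1
  if (dmus == 0 && dmua == 0) return(rep(1, nrow(paths)))
  # computed in log space so huge j or L cannot produce 0 * Inf
  logf <- -(dmus + dmua) * paths$L
  if (dmus != 0) logf <- logf + paths$j * log(mus2 / mus1)
  exp(logf)
}

#' Rescale stored photon paths to perturbed optical properties
#'
#' Perturbation Monte Carlo: re-weights every detected photon of a stored
#' simulation so that the re-binned image estimates the reflectance the same
#' random experiment would have produced under perturbed `mu_a` and/or
#' `mu_s` (at fixed `g`), without re-simulating.  With free paths sampled
#' from `mu_s` and absorption applied as a terminal factor, the exact
#' per-photon factor is
#' `(mu_s_hat/mu_s)^j * exp(-(mu_s_hat - mu_s) * L) * exp(-(mu_a_hat - mu_a) * L)`.
#'
#' @param stats an `srr_paths` tibble (from [simulate_srr_image()] or
#'   [simulate_pencil_image()]), carrying its grid attributes.
#' @param props the [optical_props()] the paths were generated under.
#' @param perturbed [optical_props()] differing from `props` only in `mu_a`
#'   and/or `mu_s_prime`; perturbing `g` or `n` is unsupported.
#' @return An `srr_image` of the rescaled reflectance.  An unperturbed input
#'   returns the original image bit-exactly.
#' @export
rescale_reflectance <- function(stats, props, perturbed) {
  stopifnot(inherits(stats, "srr_paths"), inherits(props, "srr_props"),
            inherits(perturbed, "srr_props"))
  if (abs(perturbed$g - props$g) > 0 || abs(perturbed$n - props$n) > 0)
    abort("perturbations of `g` or `n` are unsupported by pMC rescaling.")
  f <- pmc_factors(stats, props, perturbed)
  ps <- attr(stats, "pixel_scale")
  dims <- attr(stats, "dims")
  nl <- attr(stats, "n_launched")
  img <- bin_paths_to_image(stats$row, stats$col, stats$weight * f,
                            dims[1], dims[2]) / (nl * ps^2)
  new_srr_image(img, ps, attr(stats, "origin"), n_launched = nl)
}

#' Finite-difference Jacobian columns from pMC rescaling
#'
#' Builds the derivative of the radially binned Monte Carlo reflectance with
#' respect to each requested coefficient by the perturbation-MC finite
#' difference `dR/dp = (S_p(R(p)) - R(p)) / (p * delta)`, where `S_p` is the
#' path-rescaling operator of [rescale_reflectance()], evaluated on the
#' binned curve over the fit window.
#'
#' @param stats an `srr_paths` tibble.
#' @param props generating [optical_props()].
#' @param specs a list of [perturbation_spec()] objects.
#' @param window an `srr_window` ([fit_window()]); pass `NULL` to use all
#'   bins.
#' @param d_rho radial bin width in mm (defaults to the pixel scale).
#' @param at optionally evaluate the curve and derivatives at these
#'   [optical_props()] instead of at `props`, by composing the pMC
#'   rescaling from the stored paths (both the baseline and the perturbed
#'   curves are rescaled from `props`).
#' @return A tibble with `rho_mm`, the baseline curve `R`, and one
#'   derivative column `dR_d<parameter>` per spec.
#' @export
jacobian_columns <- function(stats, props, specs, window = NULL,
                             d_rho = NULL, at = NULL) {
  stopifnot(inherits(stats, "srr_paths"))
  if (inherits(specs, "srr_perturbation")) specs <- list(specs)
  ps <- attr(stats, "pixel_scale")
  d_rho <- d_rho %||% ps
  at <- at %||% props
  base_img <- rescale_reflectance(stats, props, at)
  base <- radial_bin(base_img, d_rho = d_rho)
  out <- tibble(rho_mm = base$rho_mm, R = base$R)
  for (spec in specs) {
    perturbed <- perturb_props(at, spec)
    f <- pmc_factors(stats, props, perturbed)
    if (length(f) && max(f) > 1e3)
      warn(sprintf(
        "pMC validity: max path weight factor %.3g > 1e3 for delta = %g",
        max(f), spec$delta))
    img <- rescale_reflectance(stats, props, perturbed)
    curve <- radial_bin(img, d_rho = d_rho)
    p0 <- if (spec$parameter == "mu_a") at$mu_a else at$mu_s_prime
    num <- curve$R - base$R
    der <- num / (p0 * spec$delta)
    der[num == 0] <- 0  # exact zeros survive a zero denominator
    out[[paste0("dR_d", spec$parameter)]] <- der
  }
  if (!is.null(window)) {
    out <- dplyr::filter(out, .data$rho_mm >= window$rho_0 - 1e-9,
                         .data$rho_mm <= window$rho_m + 1e-9)
  }
  out
}
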