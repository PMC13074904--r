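#' Raw camera frame
#'
#' A 16-bit CCD frame with the metadata needed for normalization: the
#' integration time and the mean voltage of the incident-light monitoring
#' photodiode recorded during the exposure.
#'
#' @param counts numeric matrix of ADU counts.  Raw frames must lie in
#'   `[0, 65535]`; dark-subtracted frames are stored as floats and may be
#'   slightly negative.
#' @param t_int_ms integration time in ms.
#' @param pd_voltage_v mean monitor-photodiode voltage in V.
#' @param wavelength_nm wavelength in nm.
#' @param dark_subtracted has a shutter-closed dark frame been subtracted?
#' @param exposure_tag one of `"1x"`, `"10x"`, `"100x"`, `"dark"` (or `NA`).
#' @return An object of class `srr_frame`.
#' @export
camera_frame <- function(counts, t_int_ms, pd_voltage_v,
                         wavelength_nm = NA_real_, dark_subtracted = FALSE,
                         exposure_tag = NA_character_) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort("`counts` must be a numeric matrix.")
  if (!dark_subtracted && (any(counts < 0) || any(counts > 65535)))
    abort("raw counts must lie in [0, 65535].")
  if (!is.numeric(t_int_ms) || is.na(t_int_ms) || t_int_ms <= 0)
    abort("`t_int_ms` must be positive.")
  if (!is.numeric(pd_voltage_v) || is.na(pd_voltage_v) || pd_voltage_v <= 0)
    abort("`pd_voltage_v` must be positive.")
  structure(list(counts = counts, t_int_ms = as.numeric(t_int_ms),
                 pd_voltage_v = as.numeric(pd_voltage_v),
                 wavelength_nm = as.numeric(wavelength_nm),
                 dark_subtracted = isTRUE(dark_subtracted),
                 exposure_tag = as.character(exposure_tag)),
            class = "srr_frame")
}

#' @export
print.srr_frame <- function(x, ...) {
  cat(sprintf(
    "<srr_frame %s> %d x %d px, t = %g ms, PD = %g V, %g nm%s\n",
    x$exposure_tag, nrow(x$counts), ncol(x$counts), x$t_int_ms,
    x$pd_voltage_v, x$wavelength_nm,
    if (x$dark_subtracted) ", dark-subtracted" else ""))
  invisible(x)
}

#' Subtract a shutter-closed dark frame
#'
#' @param frame,dark [camera_frame()] objects with matching shapes and
#'   integration times.
#' @return The dark-subtracted frame (float counts).
#' @export
subtract_dark <- function(frame, dark) {
  stopifnot(inherits(frame, "srr_frame"), inherits(dark, "srr_frame"))
  if (!identical(dim(frame$counts), dim(dark$counts)))
    abort("frame and dark must have the same shape.")
  out <- frame
  out$counts <- frame$counts - dark$counts
  out$dark_subtracted <- TRUE
  out
}

#' Flat-field correction
#'
#' Divides the frame pixelwise by a gain map normalized to mean one,
#' compensating pixel-to-pixel sensitivity and illumination non-uniformity.
#'
#' @param frame a [camera_frame()].
#' @param field positive numeric matrix, same shape, mean ~ 1.
#' @return The corrected frame (float counts).
#' @export
flatfield_correct <- function(frame, field) {
  stopifnot(inherits(frame, "srr_frame"))
  if (!identical(dim(frame$counts), dim(field)))
    abort("`field` must match the frame shape.")
  if (any(field <= 0)) abort("`field` must be positive everywhere.")
  out <- frame
  out$counts <- frame$counts / field
  out
}

#' Normalize a frame to experimental reflectance units
#'
#' Converts a dark-subtracted, flat-fielded frame to the experimental
#' reflectance scale `counts V^-1 ms^-1 mm^-2`:
#' `values = counts / (t_int * pd_voltage * pixel_area)`.  Dividing by
#' integration time and photodiode voltage makes frames taken at different
#' exposures and source intensities directly comparable; the remaining
#' instrument factor is absorbed by the scaling coefficient
#' ([scaling_coefficient()]).
#'
#' @param frame a [camera_frame()] with valid metadata.
#' @param pixel_scale pixel side length in mm.
#' @param origin `(row, col)` of the beam incidence pixel.
#' @return An `srr_image` with units `counts V^-1 ms^-1 mm^-2`.
#' @export
normalize_frame <- function(frame, pixel_scale = 0.0361, origin = NULL) {
  stopifnot(inherits(frame, "srr_frame"))
  if (is.na(frame$t_int_ms) || is.na(frame$pd_voltage_v))
    abort("frame metadata (t_int_ms, pd_voltage_v) is missing.")
  origin <- origin %||% c(nrow(frame$counts) %/% 2, ncol(frame$counts) %/% 2)
  v <- frame$counts / (frame$t_int_ms * frame$pd_voltage_v * pixel_scale^2)
  new_srr_image(v, pixel_scale, origin,
                units = "counts V^-1 ms^-1 mm^-2")
}

#' Detect saturated and bloomed pixels
#'
#' CCD blooming bleeds charge from saturated pixels along the readout axis.
#' The mask marks every pixel at or above `sat_fraction * 65535` and, along
#' the bloom axis, every contiguous run of near-saturated pixels (at or
#' above `grow_fraction` of the saturation level) connected to a saturated
#' pixel.  When a run's edge pixel is itself fully saturated, one guard
#' pixel beyond that end is masked as well: the partially filled bloom
#' front sits there, below the growth level but still holding displaced
#' charge; a dim run edge already is the front, and its neighbor is clean.
#'
#' @param frame a [camera_frame()] (raw or dark-subtracted).
#' @param sat_fraction saturation threshold as a fraction of full well.
#' @param grow_fraction run-growth threshold as a fraction of the
#'   saturation level.
#' @param axis bloom direction: `"col"` (vertical streaks) or `"row"`.
#' @return A logical matrix, `TRUE` for saturated/bloomed pixels.
#' @export
detect_bloom <- function(frame, sat_fraction = 0.95, grow_fraction = 0.9,
                         axis = c("col", "row")) {
  axis <- match.arg(axis)
  counts <- if (inherits(frame, "srr_frame")) frame$counts else frame
  thr <- sat_fraction * 65535
  grow <- grow_fraction * thr
  cc <- if (axis == "col") counts else t(counts)
  seed <- cc >= thr
  mask <- matrix(FALSE, nrow(cc), ncol(cc))
  nr <- nrow(cc)
  for (ci in which(colSums(seed) > 0)) {
    above <- cc[, ci] >= grow
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (any(seed[starts[k]:ends[k], ci])) {
        mask[starts[k]:ends[k], ci] <- TRUE
        # when a run's edge pixel is itself fully saturated, the partially
        # filled bloom front sits just beyond it (below the growth level
        # but corrupted); guard that one pixel.  A dim run edge already is
        # the front, and the pixel beyond it is clean.
        if (seed[starts[k], ci] && starts[k] > 1L)
          mask[starts[k] - 1L, ci] <- TRUE
        if (seed[ends[k], ci] && ends[k] < nr)
          mask[ends[k] + 1L, ci] <- TRUE
      }
    }
  }
  if (axis == "row") mask <- t(mask)
  mask
}

# per-pixel radial bin index (0-based) about the origin pixel center
rho_bin_index <- function(nr, nc, origin, pixel_scale, d_rho) {
  dr <- (seq_len(nr) - origin[1]) * pixel_scale
  dc <- (seq_len(nc) - origin[2]) * pixel_scale
  rho <- sqrt(outer(dr^2, dc^2, "+"))
  list(idx = floor(rho / d_rho), rho = rho)
}

#' Back-fill masked pixels with the radial average
#'
#' Each masked pixel is replaced by the mean of the unmasked pixels of its
#' annulus (width `d_rho` about the origin).  Annuli whose pixels are all
#' masked cannot be filled; they are reported in the `unfilled_annuli`
#' attribute and left untouched.
#'
#' @param image an `srr_image`, a [camera_frame()] or a bare matrix.
#' @param mask logical matrix of pixels to replace.
#' @param origin `(row, col)` origin pixel (taken from the image if absent).
#' @param d_rho annulus width in mm (defaults to the pixel scale).
#' @param pixel_scale pixel scale in mm for bare-matrix input.
#' @return The input with masked pixels replaced; same class as `image`.
#' @export
backfill_with_radial_average <- function(image, mask, origin = NULL,
                                         d_rho = NULL, pixel_scale = NULL) {
  if (inherits(image, "srr_image")) {
    v <- image$values
    origin <- origin %||% image$origin
    pixel_scale <- pixel_scale %||% image$pixel_scale
  } else if (inherits(image, "srr_frame")) {
    v <- image$counts
    pixel_scale <- pixel_scale %||% 1
    origin <- origin %||% (dim(v) %/% 2)
  } else {
    v <- image
    pixel_scale <- pixel_scale %||% 1
    origin <- origin %||% (dim(v) %/% 2)
  }
  if (!identical(dim(v), dim(mask)))
    abort("`mask` must match the image shape.")
  d_rho <- d_rho %||% pixel_scale
  if (!any(mask)) return(image)
  rb <- rho_bin_index(nrow(v), ncol(v), origin, pixel_scale, d_rho)
  idx <- rb$idx + 1
  good <- !mask
  sums <- rowsum(as.numeric(v[good]), idx[good])
  cnts <- rowsum(rep(1, sum(good)), idx[good])
  means <- setNames(sums[, 1] / cnts[, 1], rownames(sums))
  fill <- means[as.character(idx[mask])]
  unfilled <- sort(unique(idx[mask][is.na(fill)])) - 1
  v[mask] <- ifelse(is.na(fill), v[mask], fill)
  out <- image
  if (inherits(image, "srr_image")) out$values <- v
  else if (inherits(image, "srr_frame")) out$counts <- v
  else out <- v
  attr(out, "unfilled_annuli") <- unfilled
  out
}

#' Radially bin an image about the beam origin
#'
#' Bin `i` collects the pixels whose center distance from the origin pixel
#' center lies in `[i * d_rho, (i + 1) * d_rho)`; the curve value is the
#' mean of the collected pixel values, so the identity
#' `sum_i R(rho_i) * n_pixels_i = sum(pixels)` holds exactly.
#'
#' @param image an `srr_image` or a bare matrix.
#' @param origin `(row, col)` origin pixel (from the image if absent).
#' @param d_rho bin width in mm; the instrument convention is one pixel
#'   (0.0361 mm).
#' @param pixel_scale pixel scale for bare-matrix input.
#' @return A tibble of class `srr_radial` with `rho_mm` (bin centers), `R`
#'   (mean value, `NA` for empty bins) and `n_pixels`; bin width and origin
#'   are carried as attributes.
#' @export
radial_bin <- function(image, origin = NULL, d_rho = NULL,
                       pixel_scale = NULL) {
  if (inherits(image, "srr_image")) {
    v <- image$values
    origin <- origin %||% image$origin
    pixel_scale <- pixel_scale %||% image$pixel_scale
  } else {
    v <- image
    if (is.null(pixel_scale) || is.null(origin))
      abort("bare-matrix input needs `origin` and `pixel_scale`.")
  }
  d_rho <- d_rho %||% pixel_scale
  if (d_rho <= 0) abort("`d_rho` must be positive.")
  rb <- rho_bin_index(nrow(v), ncol(v), origin, pixel_scale, d_rho)
  idx <- rb$idx + 1
  sums <- rowsum(as.numeric(v), as.vector(idx))
  cnts <- rowsum(rep(1, length(v)), as.vector(idx))
  imax <- max(idx)
  R <- rep(NA_real_, imax)
  np <- rep(0L, imax)
  ii <- as.integer(rownames(sums))
  R[ii] <- sums[, 1] / cnts[, 1]
  np[ii] <- as.integer(cnts[, 1])
  out <- tibble(rho_mm = (seq_len(imax) - 0.5) * d_rho, R = R,
                n_pixels = np)
  attr(out, "d_rho") <- d_rho
  attr(out, "origin") <- origin
  attr(out, "pixel_scale") <- pixel_scale
  class(out) <- c("srr_radial", class(out))
  out
}

#' Select the radial fit window
#'
#' The fitted range starts one bin outside the nominal beam radius
#' (`rho_0` = first bin center at or beyond `rho_r + d_rho`) and ends at
#' `rho_m`, the first bin at which the 5-bin median-smoothed curve has
#' decayed by three orders of magnitude relative to `rho_0` — beyond that
#' attenuation the binned reflectance is noise-dominated.  If the curve
#' never reaches the attenuation target the window is truncated at the last
#' valid bin with a warning.
#'
#' @param curve an `srr_radial` curve.
#' @param rho_r nominal beam radius in mm.
#' @param attenuation window-closing attenuation ratio.
#' @return An object of class `srr_window`: list with `rho_0`, `rho_m`, the
#'   inclusive bin count `P`, and a `truncated` flag.
#' @export
fit_window <- function(curve, rho_r = 0.27, attenuation = 1e3) {
  stopifnot(inherits(curve, "srr_radial"))
  d_rho <- attr(curve, "d_rho")
  ok <- !is.na(curve$R)
  rho <- curve$rho_mm[ok]
  R <- curve$R[ok]
  sm <- if (length(R) >= 5) as.numeric(runmed(R, 5)) else R
  i0 <- which(rho >= rho_r + d_rho - 1e-9)[1]
  if (is.na(i0)) abort("curve does not extend beyond the beam radius.")
  R0 <- sm[i0]
  cand <- which(seq_along(rho) > i0 & sm > 0 & R0 / sm >= attenuation)
  truncated <- length(cand) == 0
  if (truncated) {
    warn("curve never reaches the attenuation target; window truncated at the last valid bin.")
    im <- length(rho)
  } else {
    im <- cand[1]
  }
  structure(list(rho_0 = rho[i0], rho_m = rho[im], P = im - i0 + 1L,
                 truncated = truncated),
            class = "srr_window")
}

#' @export
print.srr_window <- function(x, ...) {
  cat(sprintf("<srr_window> [%.4g, %.4g] mm, P = %d bins%s\n",
              x$rho_0, x$rho_m, x$P,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

window_bins <- function(curve, window) {
  curve$rho_mm >= window$rho_0 - 1e-9 & curve$rho_mm <= window$rho_m + 1e-9
}

#' Stitch a 1x/10x/100x exposure series into one reflectance image
#'
#' Each frame is dark-subtracted (when darks are given), flat-fielded,
#' bloom-masked and back-filled, and normalized.  Annulus by annulus the
#' patched image then takes its pixels from the longest exposure that is
#' still usable there — usable meaning that less than `max_masked_fraction`
#' of the annulus was saturated or bloomed (those pixels having been
#' back-filled with the annulus radial average).  Long exposures resolve the
#' faint large-radius tail; short exposures supply the saturated core, so
#' the composite covers the full dynamic range of the reflectance with
#' maximal SNR.  Annuli whose chosen frame averages fewer than
#' `min_counts` ADU are flagged low-SNR in the `annulus_map` attribute.
#'
#' @param frames list of [camera_frame()] objects (any order; sorted by
#'   integration time internally).  A single frame degenerates to plain
#'   normalization.
#' @param field optional flat-field gain map.
#' @param origin `(row, col)` beam origin pixel.
#' @param darks optional list of dark frames matched to `frames` by
#'   position.
#' @param pixel_scale pixel scale in mm.
#' @param sat_fraction,grow_fraction bloom detection thresholds
#'   (see [detect_bloom()]).
#' @param max_masked_fraction largest tolerable masked fraction of an
#'   annulus before the next-shorter exposure takes over.
#' @param min_counts expected-count SNR floor per annulus (ADU).
#' @return An `srr_image` in `counts V^-1 ms^-1 mm^-2`, with an
#'   `annulus_map` attribute (tibble: bin, chosen exposure index, masked
#'   fraction, mean raw counts, low-SNR flag).
#' @export
patch_exposure_series <- function(frames, field = NULL, origin = NULL,
                                  darks = NULL, pixel_scale = 0.0361,
                                  sat_fraction = 0.95, grow_fraction = 0.9,
                                  max_masked_fraction = 0.5,
                                  min_counts = 50) {
  if (inherits(frames, "srr_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1, all(vapply(frames, inherits, TRUE,
                                            "srr_frame")))
  wl <- vapply(frames, function(f) f$wavelength_nm, 1)
  if (length(unique(wl[!is.na(wl)])) > 1)
    abort("exposure series mixes wavelengths.")
  dims <- lapply(frames, function(f) dim(f$counts))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1)
    abort("exposure series mixes frame geometries.")
  ord <- order(vapply(frames, function(f) f$t_int_ms, 1))
  frames <- frames[ord]
  if (!is.null(darks)) darks <- darks[ord]
  nr <- nrow(frames[[1]]$counts); nc <- ncol(frames[[1]]$counts)
  origin <- origin %||% c(nr %/% 2, nc %/% 2)

  rb <- rho_bin_index(nr, nc, origin, pixel_scale, pixel_scale)
  idx <- rb$idx + 1
  nbin <- max(idx)

  n_exp <- length(frames)
  norm_imgs <- vector("list", n_exp)
  masked_frac <- matrix(0, nbin, n_exp)
  mean_counts <- matrix(NA_real_, nbin, n_exp)
  for (k in seq_len(n_exp)) {
    f <- frames[[k]]
    mask <- detect_bloom(f, sat_fraction, grow_fraction)
    if (!is.null(darks) && !f$dark_subtracted)
      f <- subtract_dark(f, darks[[k]])
    if (!is.null(field)) f <- flatfield_correct(f, field)
    f$counts <- backfill_with_radial_average(f$counts, mask, origin,
                                             pixel_scale, pixel_scale)
    norm_imgs[[k]] <- normalize_frame(f, pixel_scale, origin)
    mf <- rowsum(as.numeric(mask), as.vector(idx)) /
      rowsum(rep(1, length(mask)), as.vector(idx))
    masked_frac[as.integer(rownames(mf)), k] <- mf[, 1]
    mc <- rowsum(as.numeric(f$counts), as.vector(idx)) /
      rowsum(rep(1, length(mask)), as.vector(idx))
    mean_counts[as.integer(rownames(mc)), k] <- mc[, 1]
  }
  # longest usable exposure per annulus; fall back to the shortest
  usable <- masked_frac < max_masked_fraction
  choice <- apply(usable, 1, function(u) if (any(u)) max(which(u)) else 1L)
  out <- matrix(NA_real_, nr, nc)
  for (k in unique(choice)) {
    sel <- idx %in% which(choice == k)
    out[sel] <- norm_imgs[[k]]$values[sel]
  }
  low_snr <- mean_counts[cbind(seq_len(nbin), choice)] < min_counts
  img <- new_srr_image(out, pixel_scale, origin,
                       units = "counts V^-1 ms^-1 mm^-2")
  attr(img, "annulus_map") <- tibble(
    bin = seq_len(nbin), rho_mm = (seq_len(nbin) - 0.5) * pixel_scale,
    exposure = choice,
    masked_fraction = masked_frac[cbind(seq_len(nbin), choice)],
    mean_counts = mean_counts[cbind(seq_len(nbin), choice)],
    low_snr = low_snr)
  img
}
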