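sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path, required = character()) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    abort(sprintf("missing metadata sidecar '%s'", sp), class = "srr_io_error")
  meta <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                   error = function(e)
                     abort(sprintf("malformed metadata sidecar '%s': %s", sp,
                                   conditionMessage(e)),
                           class = "srr_io_error"))
  missing <- setdiff(required, names(meta))
  if (length(missing))
    abort(sprintf("sidecar '%s' lacks required fields: %s", sp,
                  paste(missing, collapse = ", ")),
          class = "srr_io_error")
  meta
}

#' Write / read a reflectance image as 32-bit float TIFF with JSON sidecar
#'
#' Values are stored scaled into `[0, 1]` by their maximum; the sidecar
#' (`<path>.json`) records the scale factor together with the pixel scale,
#' origin, launch count, seed and units, so the round trip is lossless to
#' float precision.
#'
#' @param image an `srr_image`.
#' @param path TIFF file path.
#' @return `read_reflectance_image()` returns the `srr_image`.
#' @export
write_reflectance_image <- function(image, path) {
  stopifnot(inherits(image, "srr_image"))
  mn <- min(image$values, 0)
  mx <- max(image$values, mn + 1e-300)
  tiff::writeTIFF((image$values - mn) / (mx - mn), path,
                  bits.per.sample = 32)
  jsonlite::write_json(
    list(pixel_scale_mm = image$pixel_scale, origin = image$origin,
         n_launched = image$n_launched, seed = image$seed,
         units = image$units, scale_min = mn, scale_max = mx),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_reflectance_image
#' @export
read_reflectance_image <- function(path) {
  meta <- read_sidecar(path, c("pixel_scale_mm", "origin", "scale_max"))
  mn <- meta$scale_min %||% 0
  v <- tiff::readTIFF(path) * (meta$scale_max - mn) + mn
  new_srr_image(v, meta$pixel_scale_mm, unlist(meta$origin),
                n_launched = meta$n_launched %||% NA_real_,
                seed = meta$seed %||% NA_real_,
                units = meta$units %||% "mm^-2 per photon")
}

#' Write / read a 16-bit camera frame with JSON sidecar
#'
#' @param frame a [camera_frame()] (counts are rounded to integers on
#'   write).
#' @param path TIFF file path; the sidecar goes to `<path>.json`.
#' @return `read_camera_frame()` returns the [camera_frame()].
#' @export
write_camera_frame <- function(frame, path) {
  stopifnot(inherits(frame, "srr_frame"))
  counts <- pmin(pmax(round(frame$counts), 0), 65535)
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(t_int_ms = frame$t_int_ms, pd_voltage_V = frame$pd_voltage_v,
         wavelength_nm = frame$wavelength_nm,
         exposure_tag = frame$exposure_tag,
         dark_subtracted = frame$dark_subtracted),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_camera_frame
#' @export
read_camera_frame <- function(path) {
  meta <- read_sidecar(path, c("t_int_ms", "pd_voltage_V"))
  counts <- round(tiff::readTIFF(path) * 65535)
  camera_frame(counts, meta$t_int_ms, meta$pd_voltage_V,
               meta$wavelength_nm %||% NA_real_,
               isTRUE(meta$dark_subtracted),
               meta$exposure_tag %||% NA_character_)
}

#' Write / read a logical mask as 8-bit TIFF
#'
#' @param mask logical matrix.
#' @param path TIFF file path.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  tiff::readTIFF(path) > 0.5
}

#' Write / read a radial reflectance curve as CSV
#'
#' Plain CSV with header `rho_mm, R, n_pixels`; the bin width is recovered
#' from the bin-center spacing on read.
#'
#' @param curve an `srr_radial` tibble.
#' @param path CSV file path.
#' @return `read_radial_csv()` returns the `srr_radial` curve.
#' @export
write_radial_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve[, c("rho_mm", "R", "n_pixels")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_radial_csv
#' @export
read_radial_csv <- function(path) {
  d <- tryCatch(suppressWarnings(utils::read.csv(path)),
                error = function(e)
                  abort(sprintf("cannot read radial curve '%s'", path),
                        class = "srr_io_error"))
  if (!all(c("rho_mm", "R") %in% names(d)))
    abort(sprintf("radial curve '%s' lacks rho_mm/R columns", path),
          class = "srr_io_error")
  if (is.null(d$n_pixels)) d$n_pixels <- NA_integer_
  out <- as_tibble(d[, c("rho_mm", "R", "n_pixels")])
  attr(out, "d_rho") <- if (nrow(out) > 1) median(diff(out$rho_mm)) else
    2 * out$rho_mm[1]
  class(out) <- c("srr_radial", class(out))
  out
}

#' Write / read per-photon path statistics
#'
#' Columnar binary file (Apache Parquet via the arrow package) with the
#' documented column order `row, col, weight, j, L`; grid attributes travel
#' in an adjacent JSON sidecar.
#'
#' @param paths an `srr_paths` tibble.
#' @param path parquet file path.
#' @return `read_path_stats()` returns the `srr_paths` tibble.
#' @export
write_path_stats <- function(paths, path) {
  if (!requireNamespace("arrow", quietly = TRUE))
    abort("the arrow package is required for path-statistics files.")
  stopifnot(inherits(paths, "srr_paths"))
  arrow::write_parquet(paths[, c("row", "col", "weight", "j", "L")], path)
  pr <- attr(paths, "props")
  jsonlite::write_json(
    list(pixel_scale_mm = attr(paths, "pixel_scale"),
         origin = attr(paths, "origin"), dims = attr(paths, "dims"),
         n_launched = attr(paths, "n_launched"),
         props = list(mu_a = pr$mu_a, mu_s_prime = pr$mu_s_prime,
                      g = pr$g, n = pr$n)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_path_stats
#' @export
read_path_stats <- function(path) {
  if (!requireNamespace("arrow", quietly = TRUE))
    abort("the arrow package is required for path-statistics files.")
  meta <- read_sidecar(path, c("pixel_scale_mm", "origin", "dims",
                               "n_launched"))
  d <- as_tibble(arrow::read_parquet(path))
  attr(d, "pixel_scale") <- meta$pixel_scale_mm
  attr(d, "origin") <- as.integer(unlist(meta$origin))
  attr(d, "dims") <- as.integer(unlist(meta$dims))
  attr(d, "n_launched") <- meta$n_launched
  attr(d, "props") <- optical_props(meta$props$mu_a, meta$props$mu_s_prime,
                                    meta$props$g, meta$props$n)
  class(d) <- c("srr_paths", class(d))
  d
}

#' Write / read a beam profile (32-bit float TIFF + sidecar)
#'
#' @param beam a [beam_profile()].
#' @param path TIFF file path.
#' @export
write_beam_profile <- function(beam, path) {
  stopifnot(inherits(beam, "srr_beam"))
  mx <- max(beam$weights)
  tiff::writeTIFF(beam$weights / mx, path, bits.per.sample = 32)
  jsonlite::write_json(
    list(pixel_scale_mm = beam$pixel_scale, origin = beam$origin,
         incidence_deg = beam$incidence_deg, rho_r_mm = beam$rho_r,
         scale_max = mx),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_beam_profile
#' @export
read_beam_profile <- function(path) {
  meta <- read_sidecar(path, c("pixel_scale_mm", "origin", "incidence_deg",
                               "rho_r_mm", "scale_max"))
  w <- tiff::readTIFF(path) * meta$scale_max
  beam_profile(w, meta$pixel_scale_mm, unlist(meta$origin),
               incidence_deg = meta$incidence_deg, rho_r = meta$rho_r_mm)
}

#' Estimate a flat-field gain map from light-box frames
#'
#' Averages uniform-illumination frames (optionally dark-subtracted) and
#' normalizes the result to mean 1.
#'
#' @param frames list of [camera_frame()] objects.
#' @param dark optional matching dark frame.
#' @return A positive matrix with mean 1.
#' @export
build_flatfield <- function(frames, dark = NULL) {
  if (inherits(frames, "srr_frame")) frames <- list(frames)
  acc <- Reduce(`+`, lapply(frames, function(f) f$counts)) / length(frames)
  if (!is.null(dark)) acc <- acc - dark$counts
  acc <- pmax(acc, 1e-6)
  acc / mean(acc)
}

#' Write a complete synthetic measurement campaign to disk
#'
#' For every sample of the scenario: the truth reflectance image, the
#' 1x/10x/100x exposure triplet with matched darks (16-bit TIFF + JSON
#' sidecars), and the ground-truth properties; plus the beam profile, the
#' flat-field map and frames, and a manifest.  Two runs with the same
#' scenario seed produce byte-identical trees.
#'
#' @param scenario an [synthetic_scenario()].
#' @param dir output directory (created).
#' @param noise noise mode for the renders.
#' @return Invisibly, a manifest tibble of written files.
#' @export
generate_scenario <- function(scenario, dir, noise = "full") {
  stopifnot(inherits(scenario, "srr_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  field <- make_flatfield(scenario$grid$nrow, scenario$grid$ncol)
  write_beam_profile(scenario$beam, file.path(dir, "beam.tif"))
  # flat-field light-box frames: uniform truth through the field
  flat_truth <- new_srr_image(
    matrix(1e-3, scenario$grid$nrow, scenario$grid$ncol),
    scenario$grid$pixel_scale, scenario$grid$origin)
  t_flat <- auto_exposure(flat_truth, scenario$cam, scenario$pd_voltage_v)
  flat_frames <- character(3)
  for (i in 1:3) {
    fr <- render_frame(flat_truth, t_flat, scenario$pd_voltage_v,
                       scenario$cam, seed = child_seed(scenario$seed, i),
                       field = field, exposure_tag = "flat", noise = noise)
    flat_frames[i] <- file.path(dir, sprintf("flat_%d.tif", i))
    write_camera_frame(fr, flat_frames[i])
  }
  rows <- list()
  for (k in seq_len(nrow(scenario$samples))) {
    sid <- scenario$samples$sample_id[k]
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    m <- synth_measurement(scenario, scenario$samples$mu_a[k],
                           scenario$samples$mu_s_prime[k], sample_k = k,
                           field = field, noise = noise)
    write_reflectance_image(m$truth_sim$image,
                            file.path(sdir, "truth.tif"))
    tags <- c("1x", "10x", "100x")
    for (i in 1:3) {
      write_camera_frame(m$frames[[i]],
                         file.path(sdir, paste0(tags[i], ".tif")))
      write_camera_frame(m$darks[[i]],
                         file.path(sdir, paste0("dark_", tags[i], ".tif")))
    }
    jsonlite::write_json(
      list(sample_id = sid, wavelength_nm = scenario$wavelength_nm[1],
           mu_a = scenario$samples$mu_a[k],
           mu_s_prime = scenario$samples$mu_s_prime[k],
           g = scenario$g, n = scenario$n, seed = scenario$seed,
           t1_ms = m$t1_ms),
      file.path(sdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    rows[[k]] <- tibble(sample_id = sid, dir = sdir)
  }
  jsonlite::write_json(
    list(seed = scenario$seed, wavelength_nm = scenario$wavelength_nm[1],
         grid = scenario$grid[c("nrow", "ncol", "pixel_scale")],
         samples = scenario$samples$sample_id, noise = noise),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dplyr::bind_rows(rows))
}
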