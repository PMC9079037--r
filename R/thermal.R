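#' Thermal frame container
#'
#' A thermogram: a height x width map of surface temperatures in degrees
#' Celsius plus the spatial resolution of the IRT optics.
#'
#' @param temperatures Numeric matrix (degrees C, finite).
#' @param mm_per_px Spatial resolution (default 0.5 mm/px).
#' @param frame_id Optional identifier.
#' @return Object of class `thermal_frame`.
#' @export
thermal_frame <- function(temperatures, mm_per_px = 0.5, frame_id = NA_character_) {
  temperatures <- as.matrix(temperatures)
  if (!all(is.finite(temperatures))) stop("thermal frame contains non-finite temperatures")
  structure(list(temperatures = temperatures, mm_per_px = mm_per_px,
                 frame_id = frame_id),
            class = "thermal_frame")
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf("<thermal_frame> %d x %d px, %.3g-%.3g degC, %.2f mm/px\n",
              ncol(x$temperatures), nrow(x$temperatures),
              min(x$temperatures), max(x$temperatures), x$mm_per_px))
  invisible(x)
}

#' Linear 16-bit temperature encoding
#'
#' Centikelvin mapping `raw = round((T + 273.15) * 100)`, valid for
#' temperatures in \[-273.15, 382.2\] degC, i.e. raw values 0-65535. The
#' 0.01 degC step is finer than the 20 mK sensitivity of the IRT sensor, so
#' a round trip loses at most 0.005 degC.
#'
#' @param temp_c Temperature(s) in degrees Celsius.
#' @param raw Raw 16-bit integer value(s).
#' @return `encode_temperature()` returns integer raw values;
#'   `decode_temperature()` returns degrees Celsius.
#' @export
encode_temperature <- function(temp_c) {
  if (any(temp_c < -273.15 | temp_c > 382.2)) {
    stop("temperature outside the encodable range [-273.15, 382.2] degC")
  }
  r <- round((temp_c + 273.15) * 100)
  storage.mode(r) <- "integer"
  r
}

#' @rdname encode_temperature
#' @export
decode_temperature <- function(raw) {
  if (any(raw < 0 | raw > 65535)) stop("raw value outside the 16-bit range")
  raw / 100 - 273.15
}

#' Read / write a thermogram as 16-bit single-channel TIFF
#'
#' Temperatures are stored with the centikelvin encoding of
#' [encode_temperature()].
#'
#' @param frame A [thermal_frame()].
#' @param path TIFF file path.
#' @param mm_per_px Spatial resolution attached on read.
#' @return `write_thermal_tiff()` returns `path` invisibly;
#'   `read_thermal_tiff()` returns a [thermal_frame()].
#' @export
write_thermal_tiff <- function(frame, path) {
  raw <- encode_temperature(frame$temperatures)
  tiff::writeTIFF(raw / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_thermal_tiff
#' @export
read_thermal_tiff <- function(path, mm_per_px = 0.5) {
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  thermal_frame(decode_temperature(raw), mm_per_px = mm_per_px,
                frame_id = basename(path))
}

#' Maximum temperature in a square ROI around a landmark
#'
#' The window covers columns `[round(cx) - s %/% 2, round(cx) + s %/% 2)`
#' for even sizes `s` and `[round(cx) - s %/% 2, round(cx) + s %/% 2]` for
#' odd sizes (and likewise for rows), i.e. the half-open center-rounded
#' convention `lo = round(c) - s %/% 2`, `hi = lo + s - 1` in 0-based
#' coordinates. Windows are clipped at the frame border and the maximum is
#' taken over the remaining pixels.
#'
#' @param frame A [thermal_frame()] (or bare temperature matrix).
#' @param center_px `c(x, y)` ROI center in IRT pixel coordinates.
#' @param roi_size Window side length in px (default 10).
#' @return List with `max_c` (degrees C) and `n_valid_px`.
#' @export
roi_max_temperature <- function(frame, center_px, roi_size = 10L) {
  temps <- if (inherits(frame, "thermal_frame")) frame$temperatures else frame
  stopifnot(roi_size >= 1L)
  w <- ncol(temps); h <- nrow(temps)
  cx <- center_px[1]; cy <- center_px[2]
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1) {
    stop("ROI center outside the thermal frame")
  }
  half <- roi_size %/% 2
  x_lo <- max(0L, round(cx) - half); x_hi <- min(w - 1L, round(cx) - half + roi_size - 1L)
  y_lo <- max(0L, round(cy) - half); y_hi <- min(h - 1L, round(cy) - half + roi_size - 1L)
  win <- temps[(y_lo + 1L):(y_hi + 1L), (x_lo + 1L):(x_hi + 1L), drop = FALSE]
  list(max_c = max(win), n_valid_px = length(win))
}

#' Central-peripheral temperature difference for one frame
#'
#' For each labeled landmark inside the frame, the maximum temperature in a
#' `roi_size` x `roi_size` window is extracted; landmarks are grouped into
#' central and peripheral regions, each group's readings are averaged
#' (unweighted arithmetic mean of the ROI maxima), and
#' `cptd = central_mean - peripheral_mean`. Landmarks with visibility 0 or
#' centers outside the frame are excluded and listed. If either group ends
#' up empty the record is flagged (`defined = FALSE`, `cptd = NA`) without
#' raising an error: negative cpTD values are a legitimate output (e.g.
#' clothing covering peripheral limbs), only an empty group is undefined.
#'
#' @param frame A [thermal_frame()].
#' @param irt_keypoints A [keypoint_set()] in IRT coordinates (e.g. from
#'   [transform_points()]).
#' @param scheme Region scheme (default [default_region_scheme()]).
#' @param roi_size ROI side length in px (default 10).
#' @return Object of class `cptd_record`: `central_mean`,
#'   `peripheral_mean`, `cptd`, `defined`, `n_central`, `n_peripheral`,
#'   `readings` (per-keypoint data frame), `excluded` (names).
#' @export
compute_cptd <- function(frame, irt_keypoints, scheme = default_region_scheme(),
                         roi_size = 10L) {
  validate_region_scheme(scheme)
  temps <- frame$temperatures
  w <- ncol(temps); h <- nrow(temps)
  readings <- NULL
  excluded <- character()
  for (i in seq_len(nrow(irt_keypoints))) {
    nm <- irt_keypoints$name[i]
    if (irt_keypoints$visibility[i] < 1L) { excluded <- c(excluded, nm); next }
    cx <- irt_keypoints$x[i]; cy <- irt_keypoints$y[i]
    if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1) { excluded <- c(excluded, nm); next }
    r <- roi_max_temperature(frame, c(cx, cy), roi_size)
    readings <- rbind(readings, data.frame(
      name = nm, region = unname(scheme[nm]), x = cx, y = cy,
      roi_max_c = r$max_c, n_valid_px = r$n_valid_px, stringsAsFactors = FALSE))
  }
  cm <- if (!is.null(readings) && any(readings$region == "central")) {
    mean(readings$roi_max_c[readings$region == "central"])
  } else NA_real_
  pm <- if (!is.null(readings) && any(readings$region == "peripheral")) {
    mean(readings$roi_max_c[readings$region == "peripheral"])
  } else NA_real_
  defined <- !is.na(cm) && !is.na(pm)
  structure(list(central_mean = cm, peripheral_mean = pm,
                 cptd = if (defined) cm - pm else NA_real_,
                 defined = defined,
                 n_central = if (is.null(readings)) 0L else sum(readings$region == "central"),
                 n_peripheral = if (is.null(readings)) 0L else sum(readings$region == "peripheral"),
                 readings = readings, excluded = excluded),
            class = "cptd_record")
}

#' @export
print.cptd_record <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<cptd_record> cpTD = %.3f degC (central %.3f over %d ROIs, peripheral %.3f over %d ROIs)\n",
                x$cptd, x$central_mean, x$n_central, x$peripheral_mean, x$n_peripheral))
  } else {
    cat("<cptd_record> cpTD undefined (a region has no usable landmark)\n")
  }
  if (length(x$excluded)) cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Error statistics for extracted cpTD values
#'
#' Mean absolute error and the sample standard deviation (n-1 denominator)
#' of the absolute deviations between estimated and ground-truth cpTD.
#' Frames where either value is `NA` (undefined cpTD) are excluded
#' pairwise.
#'
#' @param estimated,ground_truth Equal-length numeric vectors (degrees C).
#' @return List with `mae_c`, `sd_c`, `n`.
#' @export
cptd_error_stats <- function(estimated, ground_truth) {
  stopifnot(length(estimated) == length(ground_truth))
  keep <- !is.na(estimated) & !is.na(ground_truth)
  if (!any(keep)) stop("no frame pairs with defined cpTD")
  ae <- abs(estimated[keep] - ground_truth[keep])
  list(mae_c = mean(ae),
       sd_c = if (length(ae) > 1L) stats::sd(ae) else 0,
       n = length(ae))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `ground_truth - estimated` (a positive mean difference
#' means the method underestimates); the x-coordinates are the pairwise
#' means. Limits of agreement are `MD +/- 1.96 SD` of the differences.
#'
#' @param estimated,ground_truth Equal-length numeric vectors, n >= 2 after
#'   pairwise removal of `NA`s.
#' @return List with `mean_difference`, `sd_difference`, `loa` (length-2
#'   lower/upper limits), and `points` (data frame with `mean` and
#'   `difference` per pair).
#' @export
bland_altman <- function(estimated, ground_truth) {
  stopifnot(length(estimated) == length(ground_truth))
  keep <- !is.na(estimated) & !is.na(ground_truth)
  est <- estimated[keep]; gt <- ground_truth[keep]
  if (length(est) < 2L) stop("Bland-Altman analysis needs at least 2 paired values")
  d <- gt - est
  m <- (gt + est) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  list(mean_difference = md, sd_difference = sdd,
       loa = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
       points = data.frame(mean = m, difference = d))
}
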