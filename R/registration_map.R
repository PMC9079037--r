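#' RGB-to-IRT registration map
#'
#' The mapping between modalities is a symmetric field-of-view crop of the
#' full RGB frame followed by an affine transform into IRT pixel
#' coordinates:
#' `p' = A %*% (p - crop) + t`,
#' with `A` the 2x2 linear part, `t` the translation and `crop = (crop_x,
#' crop_y)` the margins removed from each left/right and top/bottom border.
#' All coordinates are 0-based pixel centers, x = column, y = row, origin
#' top-left.
#'
#' @param affine Either a 2x3 matrix `[a b tx; c d ty]` or the length-6
#'   vector `c(a, b, tx, c, d, ty)` mapping cropped-RGB coordinates to IRT
#'   coordinates.
#' @param crop_x,crop_y Non-negative crop margins in px (each border).
#' @return Object of class `registration_map` with elements `A` (2x2), `t`
#'   (length 2), `crop` (length 2).
#' @export
registration_map <- function(affine, crop_x = 0, crop_y = 0) {
  if (is.matrix(affine)) {
    stopifnot(nrow(affine) == 2L, ncol(affine) == 3L)
    A <- affine[, 1:2]
    t <- affine[, 3]
  } else {
    stopifnot(length(affine) == 6L)
    A <- matrix(affine[c(1, 4, 2, 5)], 2, 2)
    t <- affine[c(3, 6)]
  }
  if (abs(det(A)) < 1e-12) stop("degenerate registration map: affine part is not invertible")
  if (crop_x < 0 || crop_y < 0) stop("crop margins must be non-negative")
  structure(list(A = A, t = as.numeric(t), crop = c(as.numeric(crop_x), as.numeric(crop_y))),
            class = "registration_map")
}

#' Build a registration map from decomposed parameters
#'
#' Parameterization used by the optimizer: anisotropic scale and rotation
#' without shear, `A = R(theta) %*% diag(sx, sy)`.
#'
#' @param tx,ty Translation (IRT px).
#' @param sx,sy Scales (dimensionless, non-zero).
#' @param theta Rotation in radians.
#' @param crop_x,crop_y Crop margins (px).
#' @return A [registration_map()].
#' @export
map_from_params <- function(tx = 0, ty = 0, sx = 1, sy = 1, theta = 0,
                            crop_x = 0, crop_y = 0) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  A <- R %*% diag(c(sx, sy))
  registration_map(cbind(A, c(tx, ty)), crop_x, crop_y)
}

#' @export
print.registration_map <- function(x, ...) {
  cat("<registration_map>\n  A    =",
      sprintf("[% .4f % .4f; % .4f % .4f]", x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2]),
      "\n  t    =", sprintf("(% .2f, % .2f) px", x$t[1], x$t[2]),
      "\n  crop =", sprintf("(%.1f, %.1f) px", x$crop[1], x$crop[2]), "\n")
  invisible(x)
}

validate_map_for_image <- function(map, rgb_size) {
  if (2 * map$crop[1] >= rgb_size[1] || 2 * map$crop[2] >= rgb_size[2]) {
    stop("crop margins exceed half the RGB frame (",
         map$crop[1], ", ", map$crop[2], " px for a ",
         rgb_size[1], "x", rgb_size[2], " frame)")
  }
  invisible(map)
}

#' Transform points from full-RGB into IRT coordinates
#'
#' Applies `p' = A %*% (p - crop) + t`. Points are transformed exactly (no
#' rounding); visibility flags of a [keypoint_set()] pass through untouched.
#' When `irt_size` is supplied, points mapping outside the IRT frame are
#' flagged out-of-bounds (logical attribute/column `oob`) but still
#' returned.
#'
#' @param points Either an n x 2 matrix of (x, y) coordinates or a
#'   [keypoint_set()] in full-RGB pixel coordinates.
#' @param map A [registration_map()].
#' @param irt_size Optional `c(width, height)` of the IRT frame.
#' @return Transformed points of the same type as the input.
#' @export
transform_points <- function(points, map, irt_size = NULL) {
  is_kps <- inherits(points, "keypoint_set")
  xy <- if (is_kps) cbind(points$x, points$y) else as.matrix(points)
  stopifnot(ncol(xy) == 2L)
  d <- sweep(xy, 2, map$crop)
  out <- d %*% t(map$A)
  out[, 1] <- out[, 1] + map$t[1]
  out[, 2] <- out[, 2] + map$t[2]
  oob <- if (!is.null(irt_size)) {
    out[, 1] < 0 | out[, 1] > irt_size[1] - 1 | out[, 2] < 0 | out[, 2] > irt_size[2] - 1
  } else rep(FALSE, nrow(out))
  if (is_kps) {
    res <- points
    res$x <- out[, 1]
    res$y <- out[, 2]
    res$oob <- oob
    # mask area scales with the Jacobian determinant of the affine part
    sa <- attr(points, "scale_area")
    attr(res, "scale_area") <- if (is.null(sa)) NA_real_ else sa * abs(det(map$A))
    res
  } else {
    attr(out, "oob") <- oob
    out
  }
}

#' Inverse point transform (IRT to full-RGB coordinates)
#'
#' @param points n x 2 matrix or [keypoint_set()] in IRT coordinates.
#' @param map A [registration_map()].
#' @return Points in full-RGB coordinates, `p = A^-1 %*% (p' - t) + crop`.
#' @export
inverse_transform_points <- function(points, map) {
  is_kps <- inherits(points, "keypoint_set")
  xy <- if (is_kps) cbind(points$x, points$y) else as.matrix(points)
  Ainv <- solve(map$A)
  d <- sweep(xy, 2, map$t)
  out <- d %*% t(Ainv)
  out[, 1] <- out[, 1] + map$crop[1]
  out[, 2] <- out[, 2] + map$crop[2]
  if (is_kps) {
    res <- points
    res$x <- out[, 1]
    res$y <- out[, 2]
    res
  } else out
}

#' Serialize / deserialize a registration map as JSON
#'
#' Schema: `{"affine": [a,b,tx,c,d,ty], "crop_x": int, "crop_y": int,
#' "mi": float, "seed": int, "n_evals": int}`. The `mi`, `seed` and
#' `n_evals` fields are optional provenance from [fit_registration()].
#'
#' @param map A [registration_map()].
#' @param path Output / input file path.
#' @param mi,seed,n_evals Optional provenance values stored alongside.
#' @return `write_registration_map()` returns `path` invisibly;
#'   `read_registration_map()` returns a [registration_map()] with any
#'   provenance attached as attributes.
#' @export
write_registration_map <- function(map, path, mi = NULL, seed = NULL, n_evals = NULL) {
  obj <- list(affine = c(map$A[1, 1], map$A[1, 2], map$t[1],
                         map$A[2, 1], map$A[2, 2], map$t[2]),
              crop_x = round(map$crop[1]), crop_y = round(map$crop[2]))
  if (!is.null(mi)) obj$mi <- mi
  if (!is.null(seed)) obj$seed <- as.integer(seed)
  if (!is.null(n_evals)) obj$n_evals <- as.integer(n_evals)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_registration_map
#' @export
read_registration_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  map <- registration_map(obj$affine, obj$crop_x, obj$crop_y)
  for (f in c("mi", "seed", "n_evals")) if (!is.null(obj[[f]])) attr(map, f) <- obj[[f]]
  map
}
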