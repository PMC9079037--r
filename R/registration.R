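#' Convert an RGB raster to grayscale luminance
#'
#' Rec. 601 luma weights: `0.299 R + 0.587 G + 0.114 B`, rounded to the
#' nearest integer (round-half-even).
#'
#' @param rgb_image Height x width x 3 numeric array with 8-bit values
#'   (0-255).
#' @return Height x width matrix of integer-valued intensities.
#' @export
to_grayscale <- function(rgb_image) {
  if (length(dim(rgb_image)) != 3L || dim(rgb_image)[3] != 3L) {
    stop("to_grayscale expects a 3-channel (h x w x 3) image")
  }
  round(0.299 * rgb_image[, , 1] + 0.587 * rgb_image[, , 2] + 0.114 * rgb_image[, , 3])
}

#' Warp a full RGB-frame image onto the IRT pixel grid
#'
#' The crop is applied internally: for each IRT output pixel the inverse of
#' the affine part locates its source in cropped-RGB coordinates, which is
#' sampled bilinearly from the full frame. The validity mask is true where
#' the inverse-mapped source lies inside the cropped-RGB bounds.
#'
#' @param image Single-channel matrix (full RGB frame, e.g. from
#'   [to_grayscale()]).
#' @param map A [registration_map()].
#' @param irt_size `c(width, height)` of the output grid.
#' @return List with `image` (height x width matrix, 0 outside the mask) and
#'   `mask` (logical matrix).
#' @export
warp_to_irt <- function(image, map, irt_size) {
  h_in <- nrow(image); w_in <- ncol(image)
  validate_map_for_image(map, c(w_in, h_in))
  wo <- as.integer(irt_size[1]); ho <- as.integer(irt_size[2])
  Ainv <- solve(map$A)
  # output pixel-center coordinates, flattened column-major (matches matrix())
  xo <- rep(0:(wo - 1L), each = ho)
  yo <- rep.int(0:(ho - 1L), wo)
  dx <- xo - map$t[1]
  dy <- yo - map$t[2]
  xc <- Ainv[1, 1] * dx + Ainv[1, 2] * dy   # cropped-RGB coords
  yc <- Ainv[2, 1] * dx + Ainv[2, 2] * dy
  wc <- w_in - 2 * map$crop[1]
  hc <- h_in - 2 * map$crop[2]
  valid <- xc >= 0 & xc <= wc - 1 & yc >= 0 & yc <= hc - 1
  xs <- clamp(xc + map$crop[1], 0, w_in - 1)
  ys <- clamp(yc + map$crop[2], 0, h_in - 1)
  x0 <- floor(xs); fx <- xs - x0
  y0 <- floor(ys); fy <- ys - y0
  x1 <- pmin(x0 + 1, w_in - 1)
  y1 <- pmin(y0 + 1, h_in - 1)
  i00 <- y0 + 1 + x0 * h_in
  i10 <- y1 + 1 + x0 * h_in
  i01 <- y0 + 1 + x1 * h_in
  i11 <- y1 + 1 + x1 * h_in
  v <- (1 - fx) * ((1 - fy) * image[i00] + fy * image[i10]) +
       fx       * ((1 - fy) * image[i01] + fy * image[i11])
  v[!valid] <- 0
  list(image = matrix(v, ho, wo), mask = matrix(valid, ho, wo))
}

#' Joint intensity histogram of two images over a mask
#'
#' Equal-width bins spanning each image's min-max range over the masked
#' pixels.
#'
#' @param img_a,img_b Equal-shaped numeric matrices.
#' @param mask Logical matrix (same shape); only masked pixels are counted.
#' @param bins Number of bins per image (>= 1).
#' @return Object of class `joint_histogram`: `counts` (bins x bins, rows
#'   index `img_a` bins), `edges_a`, `edges_b`, `n`, `overlap_fraction`.
#' @export
joint_histogram <- function(img_a, img_b, mask = NULL, bins = 64L) {
  stopifnot(all(dim(img_a) == dim(img_b)), bins >= 1L)
  if (is.null(mask)) mask <- array(TRUE, dim(img_a))
  va <- img_a[mask]; vb <- img_b[mask]
  if (length(va) == 0L) stop("joint_histogram: empty mask")
  bins <- as.integer(bins)
  bin_index <- function(v) {
    r <- range(v)
    if (r[2] > r[1]) {
      pmin(floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L, bins)
    } else rep(1L, length(v))
  }
  ia <- bin_index(va); ib <- bin_index(vb)
  counts <- matrix(tabulate((ia - 1L) * bins + ib, nbins = bins * bins),
                   nrow = bins, ncol = bins, byrow = TRUE)
  structure(list(counts = counts,
                 edges_a = seq(min(va), max(va), length.out = bins + 1L),
                 edges_b = seq(min(vb), max(vb), length.out = bins + 1L),
                 n = length(va),
                 overlap_fraction = sum(mask) / length(mask)),
            class = "joint_histogram")
}

#' Mutual information of a joint histogram
#'
#' `I(X, Y) = sum_{x,y} p(x,y) log( p(x,y) / (p(x) p(y)) )` in natural-log
#' units (nats), with the convention `0 log 0 = 0`. `p(x,y)` is the joint
#' probability mass function estimated from the histogram counts and `p(x)`,
#' `p(y)` are its marginals.
#'
#' @param h A [joint_histogram()] (or a bare counts matrix) with positive
#'   total count.
#' @return Mutual information in nats (non-negative up to floating point).
#' @export
mutual_information <- function(h) {
  counts <- if (inherits(h, "joint_histogram")) h$counts else h
  n <- sum(counts)
  if (n <= 0) stop("mutual information undefined for an empty histogram")
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / (outer(px, py)[pos])))
}

#' Optimizer settings for mutual-information registration
#'
#' The search runs in the decomposed parameter space of [map_from_params()]:
#' `(tx, ty, sx, sy, theta, crop_x, crop_y)`.
#'
#' @param n_evals Total objective-evaluation budget (default 500).
#' @param stage_split Fraction of the budget spent on the global stage
#'   (Latin-hypercube sample plus moment-matching initial guesses); the
#'   remainder refines the incumbent by Nelder-Mead simplex descent with
#'   one restart, then a short Gaussian polish.
#' @param bounds 7 x 2 matrix of lower/upper parameter bounds (rows named
#'   `tx, ty, sx, sy, theta, crop_x, crop_y`; theta in radians).
#' @param seed RNG seed (the whole fit is deterministic given the seed).
#' @param bins Joint-histogram bins per image.
#' @param min_overlap_fraction Candidates whose warped field of view covers
#'   less than this fraction of the IRT frame have their MI scaled down
#'   proportionally, guarding against degenerate high-MI tiny overlaps.
#' @param downsample Integer block-mean downsampling factor applied to both
#'   images during the search (the returned map is expressed at full
#'   resolution).
#' @return List of class `optimizer_settings`.
#' @export
optimizer_settings <- function(n_evals = 500L,
                               stage_split = 0.3,
                               bounds = default_search_bounds(),
                               seed = 0L,
                               bins = 64L,
                               min_overlap_fraction = 0.25,
                               downsample = 4L) {
  stopifnot(n_evals >= 1L, stage_split >= 0, stage_split <= 1,
            all(is.finite(bounds)), nrow(bounds) == 7L,
            min_overlap_fraction > 0, min_overlap_fraction <= 1,
            downsample >= 1L)
  structure(list(n_evals = as.integer(n_evals), stage_split = stage_split,
                 bounds = bounds, seed = as.integer(seed), bins = as.integer(bins),
                 min_overlap_fraction = min_overlap_fraction,
                 downsample = as.integer(downsample)),
            class = "optimizer_settings")
}

#' Default search bounds for the registration parameters
#'
#' Scale bounds center on the IRT/RGB sensor-size ratio (~0.6); rotation is
#' limited to +/- 15 degrees (cameras share a rig); translation to +/- 200
#' IRT px; crop margins to at most 400 px per border.
#'
#' @return 7 x 2 numeric matrix with rownames
#'   `tx, ty, sx, sy, theta, crop_x, crop_y`.
#' @export
default_search_bounds <- function() {
  b <- rbind(tx = c(-200, 200), ty = c(-200, 200),
             sx = c(0.3, 1.5), sy = c(0.3, 1.5),
             theta = c(-15, 15) * pi / 180,
             crop_x = c(0, 400), crop_y = c(0, 400))
  colnames(b) <- c("lower", "upper")
  b
}

params_to_map <- function(p) {
  map_from_params(tx = p[["tx"]], ty = p[["ty"]], sx = p[["sx"]], sy = p[["sy"]],
                  theta = p[["theta"]], crop_x = p[["crop_x"]], crop_y = p[["crop_y"]])
}

#' Registration objective: masked mutual information of a candidate map
#'
#' Warps the (grayscale) RGB frame onto the IRT grid under the candidate
#' map and returns the mutual information of the two images over the
#' validity mask. If the overlap fraction falls below
#' `settings$min_overlap_fraction` the MI is scaled by
#' `overlap / min_overlap_fraction`. A non-invertible candidate yields
#' `-Inf` rather than an error, so random search can step over it.
#'
#' @param params Named parameter vector (`tx, ty, sx, sy, theta, crop_x,
#'   crop_y`) or a [registration_map()].
#' @param rgb_gray Grayscale full-RGB-frame matrix.
#' @param irt_image IRT intensity/temperature matrix.
#' @param settings An [optimizer_settings()].
#' @return Scalar objective value (nats).
#' @export
registration_objective <- function(params, rgb_gray, irt_image,
                                   settings = optimizer_settings()) {
  map <- if (inherits(params, "registration_map")) params else {
    ok <- try(params_to_map(params), silent = TRUE)
    if (inherits(ok, "try-error")) return(-Inf)
    ok
  }
  if (2 * map$crop[1] >= ncol(rgb_gray) || 2 * map$crop[2] >= nrow(rgb_gray)) return(-Inf)
  w <- warp_to_irt(rgb_gray, map, c(ncol(irt_image), nrow(irt_image)))
  ov <- sum(w$mask) / length(w$mask)
  if (ov == 0) return(-Inf)
  h <- joint_histogram(w$image, irt_image, w$mask, settings$bins)
  mi <- mutual_information(h)
  if (ov < settings$min_overlap_fraction) mi * ov / settings$min_overlap_fraction else mi
}

# Express a map fitted on f-times-downsampled images at full resolution.
# With pixel-center coordinates, x_coarse = (x_full + 0.5)/f - 0.5, so the
# linear part is unchanged, crop margins scale by f, and
# t_full = f t_coarse + h (1 - A 1) with h = (f - 1)/2.
rescale_map <- function(map, f) {
  if (f == 1) return(map)
  h <- (f - 1) / 2
  t_full <- f * map$t + h * (c(1, 1) - as.numeric(map$A %*% c(1, 1)))
  registration_map(cbind(map$A, t_full), map$crop[1] * f, map$crop[2] * f)
}

# Moment-based initial guess: match intensity-weighted foreground
# centroids and principal axes of the two images (the standard
# moments-of-inertia initializer for intensity-based registration).
# Returns a decomposed parameter vector, or NULL when either image has no
# usable foreground.
moment_init <- function(rgb_c, irt_c, bounds) {
  fg_moments <- function(img) {
    r <- range(img)
    if (r[2] <= r[1]) return(NULL)
    thr <- r[1] + 0.3 * (r[2] - r[1])
    idx <- which(img > thr)
    if (length(idx) < 50L) return(NULL)
    y <- (idx - 1L) %% nrow(img)
    x <- (idx - 1L) %/% nrow(img)
    mu <- c(mean(x), mean(y))
    list(mu = mu, cov = stats::cov(cbind(x, y)))
  }
  mr <- fg_moments(rgb_c); mi <- fg_moments(irt_c)
  if (is.null(mr) || is.null(mi)) return(NULL)
  axis_angle <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    v <- e$vectors[, 1]
    atan2(v[2], v[1])
  }
  dtheta <- axis_angle(mi$cov) - axis_angle(mr$cov)
  # principal axes are only defined modulo 180 degrees; the rig rotation is
  # small, so pick the representative closest to zero
  dtheta <- atan2(sin(dtheta), cos(dtheta))
  if (dtheta > pi / 2) dtheta <- dtheta - pi
  if (dtheta < -pi / 2) dtheta <- dtheta + pi
  R <- matrix(c(cos(-dtheta), sin(-dtheta), -sin(-dtheta), cos(-dtheta)), 2, 2)
  Si <- R %*% mi$cov %*% t(R)   # IRT covariance in the de-rotated frame
  sx <- sqrt(max(Si[1, 1], 1e-9) / max(mr$cov[1, 1], 1e-9))
  sy <- sqrt(max(Si[2, 2], 1e-9) / max(mr$cov[2, 2], 1e-9))
  crop0 <- c(mean(bounds["crop_x", ]), mean(bounds["crop_y", ]))
  A <- matrix(c(cos(dtheta), sin(dtheta), -sin(dtheta), cos(dtheta)), 2, 2) %*% diag(c(sx, sy))
  t0 <- mi$mu - as.numeric(A %*% (mr$mu - crop0))
  p <- c(tx = t0[1], ty = t0[2], sx = sx, sy = sy, theta = dtheta,
         crop_x = crop0[1], crop_y = crop0[2])
  clamp(p, bounds[, 1], bounds[, 2])
}

#' Fit the RGB-to-IRT registration by maximizing mutual information
#'
#' Seeded two-stage search over the affine parameters plus the two crop
#' margins, with a fixed total budget of `settings$n_evals` objective
#' evaluations. The global stage evaluates a Latin-hypercube sample of the
#' bounds, augmented with a moment-matching initial guess (foreground
#' centroids and principal axes of both images) and jittered copies of it.
#' The local stage refines the best candidate by derivative-free
#' Nelder-Mead simplex descent on the bound-normalized parameters,
#' followed by a short Gaussian polish of decaying step width around the
#' incumbent. The search runs on block-mean downsampled images for speed;
#' the returned map and its MI are expressed and evaluated at full
#' resolution. Deterministic given `settings$seed`.
#'
#' @param rgb_image Full RGB frame (h x w x 3 array) or a grayscale matrix.
#' @param irt_image IRT intensity/temperature matrix (or [thermal_frame()]).
#' @param settings An [optimizer_settings()].
#' @return List with `map` (the best [registration_map()]), `mi` (its
#'   full-resolution masked mutual information), and `trace` (data frame of
#'   all evaluations: stage, objective value).
#' @export
fit_registration <- function(rgb_image, irt_image, settings = optimizer_settings()) {
  rgb_gray <- if (length(dim(rgb_image)) == 3L) to_grayscale(rgb_image) else rgb_image
  if (inherits(irt_image, "thermal_frame")) irt_image <- irt_image$temperatures
  if (diff(range(rgb_gray)) == 0 || diff(range(irt_image)) == 0) {
    stop("degenerate input: constant image has no intensity structure to register")
  }
  f <- settings$downsample
  rgb_c <- downsample_image(rgb_gray, f)
  irt_c <- downsample_image(irt_image, f)
  b_c <- settings$bounds
  b_c[c("tx", "ty", "crop_x", "crop_y"), ] <- b_c[c("tx", "ty", "crop_x", "crop_y"), ] / f
  # half the RGB frame is a hard ceiling for the crop
  b_c["crop_x", 2] <- min(b_c["crop_x", 2], ncol(rgb_c) / 2 - 1)
  b_c["crop_y", 2] <- min(b_c["crop_y", 2], nrow(rgb_c) / 2 - 1)
  rng <- b_c[, 2] - b_c[, 1]
  pn <- rownames(b_c)

  n_used <- 0L
  vals <- numeric(settings$n_evals)
  stages <- character(settings$n_evals)
  obj <- function(p) {
    v <- registration_objective(stats::setNames(p, pn), rgb_c, irt_c, settings)
    if (n_used < settings$n_evals) {
      n_used <<- n_used + 1L
      vals[n_used] <<- v
      stages[n_used] <<- "local"
    }
    v
  }

  n1 <- max(1L, min(settings$n_evals, round(settings$n_evals * settings$stage_split)))
  best <- with_seed(settings$seed, {
    init <- moment_init(rgb_c, irt_c, b_c)
    n_jit <- if (is.null(init)) 0L else min(30L, n1 %/% 4L)
    n_lhs <- n1 - n_jit
    cand <- sweep(sweep(lhs::randomLHS(n_lhs, 7L), 2, rng, "*"), 2, b_c[, 1], "+")
    if (n_jit > 0L) {
      jit <- matrix(rep(init, n_jit), n_jit, 7L, byrow = TRUE)
      if (n_jit > 1L) {
        jit[-1, ] <- jit[-1, ] + matrix(stats::rnorm(7L * (n_jit - 1L)), n_jit - 1L, 7L) %*% diag(0.02 * rng)
        jit <- t(apply(jit, 1, clamp, lo = b_c[, 1], hi = b_c[, 2]))
      }
      cand <- rbind(jit, cand)
    }
    best_v <- -Inf; best_p <- NULL
    for (i in seq_len(nrow(cand))) {
      v <- obj(cand[i, ])
      stages[n_used] <- "global"
      if (v > best_v) { best_v <- v; best_p <- cand[i, ] }
    }
    if (!is.finite(best_v)) {
      stop("no candidate reached the minimum overlap fraction (min_overlap_fraction = ",
           settings$min_overlap_fraction, "); widen the bounds or lower the threshold")
    }
    n2 <- settings$n_evals - n_used
    n_polish <- min(60L, n2 %/% 4L)
    n_nm <- n2 - n_polish
    if (n_nm > 20L) {
      objn <- function(z) -obj(clamp(z, 0, 1) * rng + b_c[, 1])
      z <- (best_p - b_c[, 1]) / rng
      # two simplex runs: restarting resets the simplex around the incumbent
      # and routinely escapes premature convergence
      for (budget in c(ceiling(0.58 * n_nm), floor(0.42 * n_nm)) - 2L) {
        if (budget < 10L) next
        o <- stats::optim(z, objn, method = "Nelder-Mead",
                          control = list(maxit = budget, reltol = 1e-10))
        z <- o$par
        if (-o$value > best_v) {
          best_v <- -o$value
          best_p <- clamp(z, 0, 1) * rng + b_c[, 1]
        }
      }
    }
    while (n_used < settings$n_evals) {
      frac <- (settings$n_evals - n_used) / max(1, n_polish)
      sig <- 0.01 * frac + 0.001
      p <- clamp(best_p + stats::rnorm(7L, 0, sig * rng), b_c[, 1], b_c[, 2])
      v <- obj(p)
      if (v > best_v) { best_v <- v; best_p <- p }
    }
    best_p
  })

  map <- rescale_map(params_to_map(stats::setNames(best, pn)), f)
  mi_full <- registration_objective(map, rgb_gray, irt_image, settings)
  list(map = map, mi = mi_full,
       trace = data.frame(eval = seq_len(n_used),
                          stage = stages[seq_len(n_used)],
                          objective = vals[seq_len(n_used)]))
}

#' Point-transformation error in pixels and millimeters
#'
#' Per-axis mean absolute error between transformed and ground-truth IRT
#' landmarks, with the standard deviation (n-1 denominator) of the absolute
#' deviations, both in px and converted to mm via the spatial resolution.
#'
#' @param predicted,gt n x 2 matrices or [keypoint_set()]s of matched
#'   points in IRT coordinates; rows where either set has visibility 0 are
#'   dropped when keypoint sets are supplied.
#' @param mm_per_px Spatial resolution (default 0.5 mm/px at ~1 m distance).
#' @return Data frame with one row per axis (`x`, `y`) and columns
#'   `mae_px`, `sd_px`, `mae_mm`, `sd_mm`, `n`.
#' @export
point_transform_error <- function(predicted, gt, mm_per_px = 0.5) {
  pair <- matched_point_pairs(predicted, gt)
  if (nrow(pair$a) == 0L) stop("no matched visible point pairs")
  adx <- abs(pair$a[, 1] - pair$b[, 1])
  ady <- abs(pair$a[, 2] - pair$b[, 2])
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  out <- data.frame(axis = c("x", "y"),
                    mae_px = c(mean(adx), mean(ady)),
                    sd_px = c(sd0(adx), sd0(ady)),
                    n = length(adx))
  out$mae_mm <- px_to_mm(out$mae_px, mm_per_px)
  out$sd_mm <- px_to_mm(out$sd_px, mm_per_px)
  out[, c("axis", "mae_px", "sd_px", "mae_mm", "sd_mm", "n")]
}

matched_point_pairs <- function(a, b) {
  if (inherits(a, "keypoint_set") && inherits(b, "keypoint_set")) {
    keep <- a$visibility >= 1L & b$visibility >= 1L
    list(a = cbind(a$x, a$y)[keep, , drop = FALSE],
         b = cbind(b$x, b$y)[keep, , drop = FALSE])
  } else {
    a <- as.matrix(a); b <- as.matrix(b)
    stopifnot(nrow(a) == nrow(b))
    list(a = a, b = b)
  }
}

#' Convert a pixel distance to millimeters
#'
#' @param value_px Distance(s) in pixels.
#' @param mm_per_px Spatial resolution in mm per pixel (> 0); the recording
#'   geometry at about 1 m camera distance gives 0.5 mm/px.
#' @return Distance(s) in mm.
#' @export
px_to_mm <- function(value_px, mm_per_px = 0.5) {
  if (any(mm_per_px <= 0)) stop("mm_per_px must be positive")
  value_px * mm_per_px
}
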