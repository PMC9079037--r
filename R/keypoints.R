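#' Body-landmark names used throughout the package
#'
#' The 17 COCO person keypoints in their canonical order, followed by the
#' derived `"neck"` landmark (midpoint of the two shoulders). Every
#' [keypoint_set()] carries exactly these 18 slots in this order.
#'
#' @return Character vector of length 18.
#' @export
kp_names <- function() {
  c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle", "neck")
}

#' Per-keypoint OKS constants
#'
#' The published COCO keypoint "sigmas" (nose 0.026, eyes 0.025, ears 0.035,
#' shoulders 0.079, elbows 0.072, wrists 0.062, hips 0.107, knees 0.087,
#' ankles 0.089), doubled as in the reference evaluation code so that the
#' object keypoint similarity is `exp(-d^2 / (2 s^2 k^2))` with `s^2` the
#' annotated mask area. The neck inherits the shoulder constant.
#'
#' @return Named numeric vector of length 18 (the `k_i` constants).
#' @export
kp_constants <- function() {
  sigmas <- c(0.026, 0.025, 0.025, 0.035, 0.035,
              0.079, 0.079, 0.072, 0.072, 0.062, 0.062,
              0.107, 0.107, 0.087, 0.087, 0.089, 0.089, 0.079)
  stats::setNames(2 * sigmas, kp_names())
}

#' Construct a keypoint set
#'
#' A `keypoint_set` is a data frame with one row per landmark (fixed order,
#' see [kp_names()]) and columns `name`, `x`, `y`, `visibility`
#' (0 = absent, 1 = labeled but occluded, 2 = visible) and `confidence`.
#' Consumers ignore coordinates of landmarks with visibility 0. The subject
#' scale used by OKS is attached as the `scale_area` attribute (mask area in
#' square pixels).
#'
#' @param x,y Numeric vectors of length 18 (full-frame pixel coordinates,
#'   0-based, x = column, y = row, origin top-left).
#' @param visibility Integer vector in \{0, 1, 2\}, recycled.
#' @param confidence Numeric in \[0, 1\] (detector score per landmark),
#'   recycled; `NA` for ground truth.
#' @param scale_area Subject mask area in px^2 (> 0 when used for OKS).
#' @return Object of class `keypoint_set`.
#' @export
keypoint_set <- function(x, y, visibility = 2L, confidence = NA_real_,
                         scale_area = NA_real_) {
  nm <- kp_names()
  if (length(x) != 18L || length(y) != 18L) {
    stop("a keypoint_set has exactly 18 slots (17 COCO keypoints + neck)")
  }
  visibility <- as.integer(rep_len(visibility, 18L))
  if (any(!visibility %in% 0:2)) stop("visibility flags must be 0, 1 or 2")
  df <- data.frame(name = nm, x = as.numeric(x), y = as.numeric(y),
                   visibility = visibility,
                   confidence = rep_len(as.numeric(confidence), 18L),
                   stringsAsFactors = FALSE)
  if (!is.na(scale_area) && scale_area <= 0) stop("scale_area must be > 0")
  structure(df, scale_area = as.numeric(scale_area),
            class = c("keypoint_set", "data.frame"))
}

as_keypoint_set <- function(df, scale_area = attr(df, "scale_area")) {
  keypoint_set(df$x, df$y, df$visibility,
               if ("confidence" %in% names(df)) df$confidence else NA_real_,
               scale_area %||% NA_real_)
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set> %d/18 labeled, scale_area = %s px^2\n",
              sum(x$visibility >= 1L),
              format(attr(x, "scale_area"))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Derive the neck landmark from the shoulders
#'
#' The neck is defined as the midpoint of the left and right shoulder; its
#' visibility is the minimum of the two shoulder flags. If either shoulder is
#' absent (visibility 0) the neck is marked absent. Any pre-existing neck
#' entry is overwritten.
#'
#' @param kps A [keypoint_set()].
#' @return The keypoint set with its `neck` row replaced.
#' @export
derive_neck <- function(kps) {
  ls <- kps[kps$name == "left_shoulder", ]
  rs <- kps[kps$name == "right_shoulder", ]
  i <- which(kps$name == "neck")
  if (ls$visibility >= 1L && rs$visibility >= 1L) {
    kps$x[i] <- (ls$x + rs$x) / 2
    kps$y[i] <- (ls$y + rs$y) / 2
    kps$visibility[i] <- min(ls$visibility, rs$visibility)
    kps$confidence[i] <- mean(c(ls$confidence, rs$confidence))
  } else {
    kps$visibility[i] <- 0L
  }
  kps
}

#' Default central/peripheral region scheme
#'
#' Facial landmarks and the upper-body girdle (nose, eyes, ears, shoulders,
#' neck) are central; elbows, wrists, hips, knees and ankles are peripheral.
#' The assignment of the hips is a modeling choice and can be overridden by
#' passing a modified scheme to [classify_regions()] or [compute_cptd()].
#'
#' @return Named character vector mapping each of the 18 landmark names to
#'   `"central"` or `"peripheral"`.
#' @export
default_region_scheme <- function() {
  central <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
               "left_shoulder", "right_shoulder", "neck")
  out <- stats::setNames(rep("peripheral", 18L), kp_names())
  out[central] <- "central"
  out
}

validate_region_scheme <- function(scheme) {
  if (!all(kp_names() %in% names(scheme))) {
    stop("region scheme must map every keypoint name; missing: ",
         paste(setdiff(kp_names(), names(scheme)), collapse = ", "))
  }
  if (!any(scheme == "central") || !any(scheme == "peripheral")) {
    stop("region scheme needs at least one central and one peripheral landmark")
  }
  invisible(scheme)
}

#' Partition labeled keypoints into central and peripheral groups
#'
#' Only landmarks with visibility >= 1 are assigned; order is preserved.
#'
#' @param kps A [keypoint_set()].
#' @param scheme Named map landmark -> `"central"`/`"peripheral"`
#'   (default [default_region_scheme()]).
#' @return List with elements `central` and `peripheral`, each a character
#'   vector of landmark names.
#' @export
classify_regions <- function(kps, scheme = default_region_scheme()) {
  validate_region_scheme(scheme)
  lab <- kps$name[kps$visibility >= 1L]
  list(central   = lab[scheme[lab] == "central"],
       peripheral = lab[scheme[lab] == "peripheral"])
}

#' Detector-noise configuration for the mock keypoint detector
#'
#' @param coord_sd Isotropic Gaussian jitter of each detected coordinate (px).
#' @param dropout_prob Probability that a labeled ground-truth landmark is
#'   missed entirely.
#' @param false_positive_rate Expected number of spurious landmark detections
#'   per frame (Poisson), placed uniformly at random and assigned to empty
#'   slots.
#' @param seed Integer RNG seed.
#' @return List of class `detector_noise_config`.
#' @export
detector_noise_config <- function(coord_sd = 0, dropout_prob = 0,
                                  false_positive_rate = 0, seed = 0L) {
  stopifnot(coord_sd >= 0,
            dropout_prob >= 0, dropout_prob <= 1,
            false_positive_rate >= 0)
  structure(list(coord_sd = coord_sd, dropout_prob = dropout_prob,
                 false_positive_rate = false_positive_rate,
                 seed = as.integer(seed)),
            class = "detector_noise_config")
}

#' Seeded mock keypoint detector
#'
#' Stands in for a trained pose-estimation network: each labeled ground-truth
#' landmark is independently dropped with `dropout_prob`, otherwise jittered
#' by an isotropic Gaussian of `coord_sd` px. Detected landmarks receive a
#' confidence of `exp(-r^2 / (2 coord_sd^2))` (floored at 0.05) where `r` is
#' the realized jitter, so confidence ordering correlates with quality.
#' Spurious detections (Poisson count `false_positive_rate`) are placed
#' uniformly in the frame on slots the ground truth left empty, with
#' confidence uniform in \[0.05, 0.5\].
#'
#' @param truth Ground-truth [keypoint_set()].
#' @param cfg A [detector_noise_config()].
#' @param frame_size `c(width, height)` in px, for false-positive placement.
#' @return A [keypoint_set()] of detections.
#' @export
mock_detect <- function(truth, cfg, frame_size = c(1920, 1200)) {
  stopifnot(inherits(cfg, "detector_noise_config"))
  with_seed(cfg$seed, {
    det <- truth
    for (i in seq_len(18L)) {
      if (truth$visibility[i] >= 1L) {
        if (stats::runif(1) < cfg$dropout_prob) {
          det$visibility[i] <- 0L
          det$confidence[i] <- NA_real_
        } else {
          jit <- stats::rnorm(2, 0, cfg$coord_sd)
          det$x[i] <- truth$x[i] + jit[1]
          det$y[i] <- truth$y[i] + jit[2]
          det$visibility[i] <- 2L
          det$confidence[i] <- if (cfg$coord_sd > 0) {
            max(0.05, exp(-sum(jit^2) / (2 * cfg$coord_sd^2)))
          } else 1
        }
      } else {
        det$visibility[i] <- 0L
        det$confidence[i] <- NA_real_
      }
    }
    n_fp <- stats::rpois(1, cfg$false_positive_rate)
    empty <- which(det$visibility == 0L)
    if (n_fp > 0 && length(empty) > 0) {
      slots <- empty[sample.int(length(empty), min(n_fp, length(empty)))]
      for (i in slots) {
        det$x[i] <- stats::runif(1, 0, frame_size[1] - 1)
        det$y[i] <- stats::runif(1, 0, frame_size[2] - 1)
        det$visibility[i] <- 2L
        det$confidence[i] <- stats::runif(1, 0.05, 0.5)
      }
    }
    det
  })
}

#' Object keypoint similarity (OKS)
#'
#' Scale- and visibility-aware similarity between a ground-truth and a
#' detected keypoint set:
#' `OKS = sum_i exp(-d_i^2 / (2 s^2 k_i^2)) [v_i >= 1] / sum_i [v_i >= 1]`,
#' where `d_i` is the Euclidean distance between corresponding landmarks,
#' `v_i` the ground-truth visibility, `s = sqrt(scale_area)` and `k_i` the
#' per-keypoint constants of [kp_constants()]. Landmarks the detector missed
#' contribute 0 to the numerator.
#'
#' @param gt Ground-truth [keypoint_set()] with positive `scale_area`.
#' @param det Detected [keypoint_set()].
#' @param constants Per-keypoint constants (default [kp_constants()]).
#' @return OKS in \[0, 1\].
#' @export
oks <- function(gt, det, constants = kp_constants()) {
  area <- attr(gt, "scale_area")
  if (is.na(area) || area <= 0) stop("gt scale_area must be > 0 for OKS")
  lab <- gt$visibility >= 1L
  if (!any(lab)) stop("OKS undefined: no labeled ground-truth keypoints")
  k <- constants[gt$name]
  d2 <- (gt$x - det$x)^2 + (gt$y - det$y)^2
  term <- exp(-d2 / (2 * area * k^2))
  term[det$visibility < 1L] <- 0
  sum(term[lab]) / sum(lab)
}
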