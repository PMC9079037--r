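# Canonical supine-neonate skeleton: unit body frame, x right, y down,
# origin at the body center, total height ~1. Left/right follow the COCO
# convention (subject's left at positive x).
canonical_skeleton <- function() {
  m <- rbind(
    nose           = c( 0.000, -0.420),
    left_eye       = c( 0.035, -0.460),
    right_eye      = c(-0.035, -0.460),
    left_ear       = c( 0.075, -0.430),
    right_ear      = c(-0.075, -0.430),
    left_shoulder  = c( 0.140, -0.280),
    right_shoulder = c(-0.140, -0.280),
    left_elbow     = c( 0.260, -0.150),
    right_elbow    = c(-0.260, -0.150),
    left_wrist     = c( 0.380, -0.030),
    right_wrist    = c(-0.380, -0.030),
    left_hip       = c( 0.100,  0.100),
    right_hip      = c(-0.100,  0.100),
    left_knee      = c( 0.220,  0.280),
    right_knee     = c(-0.220,  0.280),
    left_ankle     = c( 0.310,  0.460),
    right_ankle    = c(-0.310,  0.460),
    neck           = c( 0.000, -0.280)
  )
  colnames(m) <- c("x", "y")
  m[kp_names(), , drop = FALSE]
}

#' Skeleton pose for the synthetic neonate phantom
#'
#' A fixed canonical supine pose (head up, limbs splayed) with a global
#' scale, translation and rotation, giving per-keypoint full-RGB-frame
#' pixel coordinates.
#'
#' @param scale Body height in RGB px (default 850 for the 1920 x 1200
#'   default frame).
#' @param center `c(x, y)` body center in RGB px.
#' @param rotation In-plane rotation in radians.
#' @return Object of class `phantom_pose`: `points` (18 x 2 matrix),
#'   `scale`, `center`, `rotation`.
#' @export
phantom_pose <- function(scale = 850, center = c(960, 600), rotation = 0) {
  stopifnot(scale > 0)
  sk <- canonical_skeleton()
  R <- matrix(c(cos(rotation), sin(rotation), -sin(rotation), cos(rotation)), 2, 2)
  pts <- sk %*% t(R) * scale
  pts[, 1] <- pts[, 1] + center[1]
  pts[, 2] <- pts[, 2] + center[2]
  colnames(pts) <- c("x", "y")
  structure(list(points = pts, scale = scale, center = center, rotation = rotation),
            class = "phantom_pose")
}

#' Configuration for a synthetic RGB/IRT phantom pair
#'
#' The phantom stands in for a clinical recording: a neonate-like figure
#' (capsules along the skeleton plus head/trunk ellipses) in skin tones on
#' a dark background in RGB, and the same figure as a temperature field in
#' the IRT frame, related by a known crop-plus-affine registration map.
#' Surface temperature is `t_central` over the head/trunk and decreases
#' linearly along each limb to `t_peripheral` at the wrists/ankles. Each
#' landmark additionally carries a small flat-topped warm spot of height
#' `kp_bump` so that its local ROI maximum is analytically known
#' (`kp_peak_temp = base temperature + kp_bump`).
#'
#' @param rgb_size `c(width, height)` of the RGB frame (default 1920 x
#'   1200, the recording resolution).
#' @param irt_size `c(width, height)` of the IRT frame (default 1024 x
#'   768).
#' @param true_map Ground-truth [registration_map()] (default: scale 0.55,
#'   2 degrees rotation, crop (160, 60), translation chosen to center the
#'   figure in the IRT frame).
#' @param pose A [phantom_pose()].
#' @param t_central Head/trunk peak temperature, degC (default 37.0).
#' @param t_peripheral Limb-end peak temperature, degC (default 33.5).
#' @param t_background Background temperature, degC (default 22.0).
#' @param kp_bump Height of the per-landmark warm spot, degC (default
#'   0.5); it cancels in the cpTD but pins each landmark's ROI maximum.
#' @param noise_sd_irt Gaussian sensor noise on the thermogram, degC
#'   (default 0.05, a few times the 20 mK sensitivity).
#' @param noise_sd_rgb Gaussian noise on each RGB channel, intensity units
#'   (default 2).
#' @param occlusions List of clothing patches, each
#'   `list(rect = c(x0, y0, x1, y1), temp_c = <surface degC>)` with the
#'   rectangle in full-RGB pixel coordinates; patches overwrite the surface
#'   temperature in IRT, recolor the RGB frame, and mark covered landmarks
#'   as occluded.
#' @param seed Integer seed; identical config + seed reproduces identical
#'   outputs.
#' @param allow_nonphysiological Permit `t_central <= t_peripheral`
#'   (used only to emulate pathological or clothed scenarios).
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(rgb_size = c(1920, 1200), irt_size = c(1024, 768),
                           true_map = NULL, pose = NULL,
                           t_central = 37.0, t_peripheral = 33.5,
                           t_background = 22.0, kp_bump = 0.5,
                           noise_sd_irt = 0.05, noise_sd_rgb = 2,
                           occlusions = list(), seed = 0L,
                           allow_nonphysiological = FALSE) {
  stopifnot(all(rgb_size > 0), all(irt_size > 0),
            kp_bump > 0, noise_sd_irt >= 0, noise_sd_rgb >= 0)
  if (!allow_nonphysiological &&
      !(t_central > t_peripheral && t_peripheral > t_background)) {
    stop("physiological phantom requires t_central > t_peripheral > t_background ",
         "(set allow_nonphysiological = TRUE to override)")
  }
  if (is.null(pose)) {
    pose <- phantom_pose(scale = 0.71 * rgb_size[2],
                         center = rgb_size / 2)
  }
  if (is.null(true_map)) {
    true_map <- centered_map(sx = 0.55, sy = 0.55, theta = 2 * pi / 180,
                             crop_x = 160 * rgb_size[1] / 1920,
                             crop_y = 60 * rgb_size[2] / 1200,
                             pose = pose, irt_size = irt_size)
  }
  validate_map_for_image(true_map, rgb_size)
  cfg <- structure(list(rgb_size = as.integer(rgb_size), irt_size = as.integer(irt_size),
                        true_map = true_map, pose = pose,
                        t_central = t_central, t_peripheral = t_peripheral,
                        t_background = t_background, kp_bump = kp_bump,
                        noise_sd_irt = noise_sd_irt, noise_sd_rgb = noise_sd_rgb,
                        occlusions = occlusions, seed = as.integer(seed)),
                   class = "phantom_config")
  cfg
}

#' Registration map that centers the phantom figure in the IRT frame
#'
#' Given the decomposed affine parameters and crop, solves for the
#' translation that maps the pose center to the IRT frame center plus an
#' optional offset.
#'
#' @param sx,sy,theta,crop_x,crop_y Affine/crop parameters as in
#'   [map_from_params()].
#' @param pose A [phantom_pose()].
#' @param irt_size `c(width, height)`.
#' @param offset Extra IRT-px displacement of the figure center.
#' @return A [registration_map()].
#' @export
centered_map <- function(sx, sy, theta, crop_x, crop_y, pose, irt_size,
                         offset = c(0, 0)) {
  m0 <- map_from_params(0, 0, sx, sy, theta, crop_x, crop_y)
  at0 <- transform_points(matrix(pose$center, 1, 2), m0)
  t <- irt_size / 2 + offset - as.numeric(at0)
  map_from_params(t[1], t[2], sx, sy, theta, crop_x, crop_y)
}

# Body geometry in full-RGB coordinates: capsule segments (with proximal /
# distal temperatures), ellipses, and per-keypoint base temperatures.
body_geometry <- function(pose, t_central, t_peripheral) {
  P <- pose$points
  s <- pose$scale
  seg <- function(a, b, r, t1, t2) {
    c(P[a, 1], P[a, 2], P[b, 1], P[b, 2], r * s, t1, t2)
  }
  limb_mid_temp <- function(a, mid, b) {
    l1 <- sqrt(sum((P[mid, ] - P[a, ])^2))
    l2 <- sqrt(sum((P[b, ] - P[mid, ])^2))
    t_central + l1 / (l1 + l2) * (t_peripheral - t_central)
  }
  t_le <- limb_mid_temp("left_shoulder", "left_elbow", "left_wrist")
  t_re <- limb_mid_temp("right_shoulder", "right_elbow", "right_wrist")
  t_lk <- limb_mid_temp("left_hip", "left_knee", "left_ankle")
  t_rk <- limb_mid_temp("right_hip", "right_knee", "right_ankle")
  segments <- rbind(
    seg("left_shoulder", "right_shoulder", 0.055, t_central, t_central),
    seg("left_hip", "right_hip", 0.060, t_central, t_central),
    seg("left_shoulder", "left_elbow", 0.035, t_central, t_le),
    seg("left_elbow", "left_wrist", 0.030, t_le, t_peripheral),
    seg("right_shoulder", "right_elbow", 0.035, t_central, t_re),
    seg("right_elbow", "right_wrist", 0.030, t_re, t_peripheral),
    seg("left_hip", "left_knee", 0.045, t_central, t_lk),
    seg("left_knee", "left_ankle", 0.040, t_lk, t_peripheral),
    seg("right_hip", "right_knee", 0.045, t_central, t_rk),
    seg("right_knee", "right_ankle", 0.040, t_rk, t_peripheral)
  )
  colnames(segments) <- c("x1", "y1", "x2", "y2", "r", "t1", "t2")
  # neck link bridges head and trunk ellipses
  R <- matrix(c(cos(pose$rotation), sin(pose$rotation),
                -sin(pose$rotation), cos(pose$rotation)), 2, 2)
  canon_pt <- function(xy) as.numeric(R %*% xy) * s + pose$center
  head_c <- canon_pt(c(0, -0.44))
  trunk_c <- canon_pt(c(0, -0.09))
  segments <- rbind(segments,
                    c(head_c, P["neck", ], 0.050 * s, t_central, t_central))
  ellipses <- rbind(head = c(head_c, 0.095 * s, 0.065 * s),
                    trunk = c(trunk_c, 0.180 * s, 0.250 * s))
  colnames(ellipses) <- c("cx", "cy", "rx", "ry")

  base <- stats::setNames(rep(t_central, 18L), kp_names())
  base[c("left_elbow", "right_elbow")] <- c(t_le, t_re)
  base[c("left_knee", "right_knee")] <- c(t_lk, t_rk)
  base[c("left_wrist", "right_wrist", "left_ankle", "right_ankle")] <- t_peripheral
  list(segments = segments, ellipses = ellipses, rotation = pose$rotation,
       t_central = t_central, kp_base_temp = base)
}

# Evaluate the body temperature field at arbitrary full-RGB query
# coordinates. Returns -Inf outside the body; overlapping primitives
# combine with pmax so the field is continuous at the joints.
body_field <- function(qx, qy, geom) {
  temp <- rep(-Inf, length(qx))
  el <- geom$ellipses
  for (i in seq_len(nrow(el))) {
    # ellipses are axis-aligned in the rotated body frame
    th <- geom$rotation
    dx0 <- qx - el[i, "cx"]; dy0 <- qy - el[i, "cy"]
    dx <- cos(th) * dx0 + sin(th) * dy0
    dy <- -sin(th) * dx0 + cos(th) * dy0
    idx <- which((dx / el[i, "rx"])^2 + (dy / el[i, "ry"])^2 <= 1)
    if (length(idx)) temp[idx] <- pmax(temp[idx], geom$t_central)
  }
  sg <- geom$segments
  for (i in seq_len(nrow(sg))) {
    x1 <- sg[i, "x1"]; y1 <- sg[i, "y1"]; x2 <- sg[i, "x2"]; y2 <- sg[i, "y2"]
    r <- sg[i, "r"]
    xmin <- min(x1, x2) - r; xmax <- max(x1, x2) + r
    ymin <- min(y1, y2) - r; ymax <- max(y1, y2) + r
    idx <- which(qx >= xmin & qx <= xmax & qy >= ymin & qy <= ymax)
    if (!length(idx)) next
    dxv <- x2 - x1; dyv <- y2 - y1
    len2 <- dxv^2 + dyv^2
    s <- if (len2 > 0) clamp(((qx[idx] - x1) * dxv + (qy[idx] - y1) * dyv) / len2, 0, 1) else 0
    px <- x1 + s * dxv; py <- y1 + s * dyv
    d2 <- (qx[idx] - px)^2 + (qy[idx] - py)^2
    inside <- d2 <= r^2
    if (any(inside)) {
      tt <- sg[i, "t1"] + s[inside] * (sg[i, "t2"] - sg[i, "t1"])
      ii <- idx[inside]
      temp[ii] <- pmax(temp[ii], tt)
    }
  }
  temp
}

#' Generate one synthetic RGB/thermal frame pair with ground truth
#'
#' Renders the configured figure into an 8-bit RGB frame (skin tones,
#' intensity shaded with surface temperature, dark background emulating
#' OLED-only illumination) and into the IRT frame as a temperature field.
#' The thermal rendering is the exact pull-back of the RGB-space geometry
#' through the inverse of `config$true_map`, so the two silhouettes are in
#' perfect correspondence under the ground-truth map. Per-landmark
#' flat-topped warm spots make every landmark's noiseless ROI maximum equal
#' to its analytic `kp_peak_temp`.
#'
#' @param config A [phantom_config()].
#' @return List with `pair` (fields `rgb`, an h x w x 3 array in 0-255,
#'   and `irt`, a [thermal_frame()], plus `frame_id`) and `truth` (class
#'   `phantom_truth`: `true_map`, `kps_rgb`, `kps_irt`, `kp_peak_temp`,
#'   `mask_area_rgb`).
#' @export
generate_phantom_pair <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  map <- config$true_map
  w_rgb <- config$rgb_size[1]; h_rgb <- config$rgb_size[2]
  w_irt <- config$irt_size[1]; h_irt <- config$irt_size[2]
  geom <- body_geometry(config$pose, config$t_central, config$t_peripheral)

  with_seed(config$seed, {
    ## ---- RGB frame -----------------------------------------------------
    qx <- rep(0:(w_rgb - 1L), each = h_rgb)
    qy <- rep.int(0:(h_rgb - 1L), w_rgb)
    field_rgb <- body_field(qx, qy, geom)
    body <- is.finite(field_rgb)
    mask_area <- sum(body)
    tc <- config$t_central; tp <- config$t_peripheral
    shade <- rep(10, length(qx))
    frac <- if (tc > tp) (field_rgb[body] - tp) / (tc - tp) else 0.5
    shade[body] <- 140 + 55 * frac
    r_ch <- shade + 35 * body
    g_ch <- shade - 5 * body
    b_ch <- shade - 25 * body
    for (occ in config$occlusions) {
      rc <- occ$rect
      inr <- qx >= rc[1] & qx <= rc[3] & qy >= rc[2] & qy <= rc[4]
      r_ch[inr] <- 120; g_ch[inr] <- 120; b_ch[inr] <- 170
    }
    rgb <- array(0, c(h_rgb, w_rgb, 3L))
    rgb[, , 1] <- r_ch; rgb[, , 2] <- g_ch; rgb[, , 3] <- b_ch
    if (config$noise_sd_rgb > 0) {
      rgb <- rgb + stats::rnorm(length(rgb), 0, config$noise_sd_rgb)
    }
    rgb <- round(clamp(rgb, 0, 255))

    ## ---- IRT frame (pull-back of the RGB geometry) ---------------------
    ox <- rep(0:(w_irt - 1L), each = h_irt)
    oy <- rep.int(0:(h_irt - 1L), w_irt)
    src <- inverse_transform_points(cbind(ox, oy), map)
    field_irt <- body_field(src[, 1], src[, 2], geom)
    temps <- ifelse(is.finite(field_irt), field_irt, config$t_background)

    ## landmark warm spots, rendered in IRT coordinates
    kps_rgb_mat <- config$pose$points
    kps_irt_mat <- transform_points(kps_rgb_mat, map)
    bump_r <- 6; plateau_r <- 1.5
    for (i in seq_len(18L)) {
      cx <- kps_irt_mat[i, 1]; cy <- kps_irt_mat[i, 2]
      base <- geom$kp_base_temp[i]
      idx <- which(ox >= cx - bump_r & ox <= cx + bump_r &
                   oy >= cy - bump_r & oy <= cy + bump_r)
      if (!length(idx)) next
      r <- sqrt((ox[idx] - cx)^2 + (oy[idx] - cy)^2)
      val <- base + config$kp_bump * clamp((bump_r - r) / (bump_r - plateau_r), 0, 1)
      temps[idx] <- pmax(temps[idx], val)
    }

    ## clothing occlusions overwrite the surface temperature
    vis <- rep(2L, 18L)
    for (occ in config$occlusions) {
      rc <- occ$rect
      ino <- src[, 1] >= rc[1] & src[, 1] <= rc[3] & src[, 2] >= rc[2] & src[, 2] <= rc[4]
      temps[ino] <- occ$temp_c
      covered <- kps_rgb_mat[, 1] >= rc[1] & kps_rgb_mat[, 1] <= rc[3] &
                 kps_rgb_mat[, 2] >= rc[2] & kps_rgb_mat[, 2] <= rc[4]
      vis[covered] <- 1L
    }
    if (config$noise_sd_irt > 0) {
      temps <- temps + stats::rnorm(length(temps), 0, config$noise_sd_irt)
    }
    irt <- thermal_frame(matrix(temps, h_irt, w_irt), frame_id = "phantom")

    kps_rgb <- keypoint_set(kps_rgb_mat[, 1], kps_rgb_mat[, 2], vis,
                            scale_area = mask_area)
    kps_irt <- transform_points(kps_rgb, map, config$irt_size)
    truth <- structure(list(true_map = map,
                            kps_rgb = kps_rgb,
                            kps_irt = kps_irt,
                            kp_peak_temp = geom$kp_base_temp + config$kp_bump,
                            mask_area_rgb = mask_area),
                       class = "phantom_truth")
    list(pair = list(rgb = rgb, irt = irt, frame_id = "phantom"), truth = truth)
  })
}

#' Analytic cpTD of a phantom configuration
#'
#' Closed form from the configuration alone: each landmark's peak
#' temperature is its limb-interpolated base temperature plus the warm-spot
#' height, and the cpTD is the mean over central landmarks minus the mean
#' over peripheral landmarks (the warm-spot height cancels).
#'
#' @param config A [phantom_config()].
#' @param scheme Region scheme (default [default_region_scheme()]).
#' @return Named list `central_mean`, `peripheral_mean`, `cptd` (degC).
#' @export
analytic_cptd <- function(config, scheme = default_region_scheme()) {
  validate_region_scheme(scheme)
  geom <- body_geometry(config$pose, config$t_central, config$t_peripheral)
  peak <- geom$kp_base_temp + config$kp_bump
  nm <- kp_names()
  cm <- mean(peak[nm[scheme[nm] == "central"]])
  pm <- mean(peak[nm[scheme[nm] == "peripheral"]])
  list(central_mean = cm, peripheral_mean = pm, cptd = cm - pm)
}

#' Sample a ground-truth registration map within the optimizer bounds
#'
#' Draws scale, rotation and crop uniformly from a physically plausible
#' sub-range of the search bounds and solves for the translation that
#' places the phantom figure near the center of the IRT frame (with a
#' random offset), redrawing until the translation itself lies inside the
#' bounds. Used to create recoverable ground-truth maps for registration
#' validation.
#'
#' @param pose A [phantom_pose()].
#' @param irt_size `c(width, height)` of the IRT frame.
#' @param seed Integer seed.
#' @param bounds Search bounds (default [default_search_bounds()]).
#' @return A [registration_map()].
#' @export
sample_registration_map <- function(pose, irt_size, seed = 0L,
                                    bounds = default_search_bounds()) {
  with_seed(seed, {
    for (attempt in 1:50) {
      sx <- stats::runif(1, 0.45, 0.70)
      sy <- stats::runif(1, 0.45, 0.70)
      theta <- stats::runif(1, -8, 8) * pi / 180
      crop_x <- stats::runif(1, bounds["crop_x", 1], min(200, bounds["crop_x", 2]))
      crop_y <- stats::runif(1, bounds["crop_y", 1], min(90, bounds["crop_y", 2]))
      offset <- stats::runif(2, -50, 50)
      m <- centered_map(sx, sy, theta, crop_x, crop_y, pose, irt_size, offset)
      if (all(m$t >= bounds[c("tx", "ty"), 1]) && all(m$t <= bounds[c("tx", "ty"), 2])) {
        return(m)
      }
    }
    stop("could not sample a ground-truth map inside the bounds")
  })
}

#' Write a phantom dataset to disk
#'
#' RGB frames are saved as 8-bit PNG, thermograms as 16-bit TIFF with the
#' centikelvin encoding of [encode_temperature()], RGB keypoints as a COCO
#' keypoint JSON (single `person` category with 18 keypoints, mask area in
#' the annotation `area` field), and the ground truth (registration maps,
#' IRT keypoints, analytic peak temperatures) as a sidecar JSON. A manifest
#' CSV lists the pairings.
#'
#' @param pairs List of frame pairs from [generate_phantom_pair()].
#' @param truths Matching list of `phantom_truth` objects.
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data frame (invisibly written to
#'   `manifest.csv`).
#' @export
write_phantom_dataset <- function(pairs, truths, out_dir) {
  if (length(pairs) == 0L) stop("empty phantom dataset")
  if (length(pairs) != length(truths)) stop("pairs and truths differ in length")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  n <- length(pairs)
  rgb_paths <- file.path(out_dir, sprintf("rgb_%03d.png", seq_len(n)))
  irt_paths <- file.path(out_dir, sprintf("irt_%03d.tiff", seq_len(n)))
  for (i in seq_len(n)) {
    png::writePNG(pairs[[i]]$rgb / 255, rgb_paths[i])
    write_thermal_tiff(pairs[[i]]$irt, irt_paths[i])
  }
  sets <- lapply(truths, `[[`, "kps_rgb")
  sizes <- lapply(pairs, function(p) c(ncol(p$rgb), nrow(p$rgb)))
  write_coco_keypoints(sets, file.path(out_dir, "keypoints.json"),
                       image_sizes = sizes, file_names = basename(rgb_paths))
  truth_obj <- lapply(seq_len(n), function(i) {
    tr <- truths[[i]]
    list(frame = i,
         affine = c(tr$true_map$A[1, 1], tr$true_map$A[1, 2], tr$true_map$t[1],
                    tr$true_map$A[2, 1], tr$true_map$A[2, 2], tr$true_map$t[2]),
         crop_x = tr$true_map$crop[1], crop_y = tr$true_map$crop[2],
         kps_irt = as.data.frame(tr$kps_irt)[, c("name", "x", "y", "visibility")],
         kp_peak_temp = as.list(tr$kp_peak_temp),
         mask_area_rgb = tr$mask_area_rgb)
  })
  jsonlite::write_json(truth_obj, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- data.frame(frame_id = seq_len(n),
                         rgb_path = basename(rgb_paths),
                         irt_path = basename(irt_paths))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return List with `pairs` (rgb array + [thermal_frame()] per frame),
#'   `kps_rgb` (list of [keypoint_set()]), and `truth` (parsed sidecar, or
#'   `NULL` if absent).
#' @export
read_phantom_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  pairs <- lapply(seq_len(nrow(manifest)), function(i) {
    rgb <- png::readPNG(file.path(dir, manifest$rgb_path[i])) * 255
    list(rgb = rgb, irt = read_thermal_tiff(file.path(dir, manifest$irt_path[i])),
         frame_id = manifest$frame_id[i])
  })
  kps <- read_coco_keypoints(file.path(dir, "keypoints.json"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    lapply(jsonlite::read_json(truth_path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
           function(tr) {
             kdf <- as.data.frame(do.call(rbind, lapply(tr$kps_irt, as.data.frame)))
             ord <- match(kp_names(), kdf$name)
             list(true_map = registration_map(unlist(tr$affine), tr$crop_x, tr$crop_y),
                  kps_irt = keypoint_set(kdf$x[ord], kdf$y[ord], kdf$visibility[ord],
                                         scale_area = tr$mask_area_rgb),
                  kp_peak_temp = unlist(tr$kp_peak_temp),
                  mask_area_rgb = tr$mask_area_rgb)
           })
  } else NULL
  list(pairs = pairs, kps_rgb = kps, truth = truth)
}
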