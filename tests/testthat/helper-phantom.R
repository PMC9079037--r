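# Small, fast phantom used throughout the unit tests: 640 x 400 RGB,
# 320 x 240 IRT. The landmark warm-spot height is raised to 1 degC because
# at this scale the limb thermal gradient is steep enough that a 10 px ROI
# window spans ~0.6 degC of gradient; the taller plateau keeps every
# landmark's ROI maximum analytically exact.
small_phantom_config <- function(seed = 0L, noise_sd_irt = 0.05, noise_sd_rgb = 2,
                                 true_map = NULL, pose = NULL, occlusions = list(),
                                 t_central = 37, t_peripheral = 33.5,
                                 t_background = 22) {
  phantom_config(rgb_size = c(640, 400), irt_size = c(320, 240),
                 true_map = true_map, pose = pose,
                 t_central = t_central, t_peripheral = t_peripheral,
                 t_background = t_background,
                 kp_bump = 1.0, noise_sd_irt = noise_sd_irt,
                 noise_sd_rgb = noise_sd_rgb, occlusions = occlusions,
                 seed = seed)
}

# keypoint-transfer mean Euclidean error of a fitted map against truth
kp_transfer_mae <- function(map, truth) {
  pred <- transform_points(truth$kps_rgb, map)
  mean(sqrt((pred$x - truth$kps_irt$x)^2 + (pred$y - truth$kps_irt$y)^2))
}

# quick keypoint_set builder for synthetic fixtures
make_kps <- function(jitter = 0, visibility = 2L, confidence = NA_real_,
                     scale_area = 4e4, seed = NULL) {
  base_x <- seq(100, 440, length.out = 18)
  base_y <- rep(c(100, 180, 260), 6)
  if (!is.null(seed)) set.seed(seed)
  dx <- if (jitter > 0) rnorm(18, 0, jitter) else 0
  dy <- if (jitter > 0) rnorm(18, 0, jitter) else 0
  keypoint_set(base_x + dx, base_y + dy, visibility, confidence, scale_area)
}
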