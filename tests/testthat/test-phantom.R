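test_that("phantom generation is byte-identical under a fixed seed", {
  cfg <- small_phantom_config(seed = 12)
  a <- generate_phantom_pair(cfg)
  b <- generate_phantom_pair(cfg)
  expect_identical(a$pair$rgb, b$pair$rgb)
  expect_identical(a$pair$irt$temperatures, b$pair$irt$temperatures)
  expect_identical(a$truth, b$truth)
})

test_that("forward-transformed RGB keypoints match the rendered IRT keypoints", {
  for (s in 0:4) {
    pose <- phantom_pose(scale = 280, center = c(320, 200))
    map <- sample_registration_map(pose, c(320, 240), seed = s)
    gp <- generate_phantom_pair(small_phantom_config(seed = s, true_map = map,
                                                     pose = pose))
    fwd <- transform_points(cbind(gp$truth$kps_rgb$x, gp$truth$kps_rgb$y),
                            gp$truth$true_map)
    dev <- sqrt((fwd[, 1] - gp$truth$kps_irt$x)^2 + (fwd[, 2] - gp$truth$kps_irt$y)^2)
    expect_lt(max(dev), 0.5)
  }
})

test_that("noiseless ROI maxima equal the analytic per-keypoint peaks exactly", {
  gp <- generate_phantom_pair(small_phantom_config(seed = 1, noise_sd_irt = 0,
                                                   noise_sd_rgb = 0))
  for (i in 1:18) {
    r <- roi_max_temperature(gp$pair$irt,
                             c(gp$truth$kps_irt$x[i], gp$truth$kps_irt$y[i]), 10L)
    expect_identical(r$max_c, unname(gp$truth$kp_peak_temp[i]))
  }
})

test_that("central peaks dominate peripheral peaks and cpTD has a closed form", {
  cfg <- small_phantom_config(seed = 0)
  gp <- generate_phantom_pair(cfg)
  scheme <- default_region_scheme()
  peaks <- gp$truth$kp_peak_temp
  expect_gte(min(peaks[names(scheme)[scheme == "central"]]),
             max(peaks[names(scheme)[scheme == "peripheral"]]) - 1e-12)

  an <- analytic_cptd(cfg)
  expect_equal(an$cptd, an$central_mean - an$peripheral_mean)
  # central landmarks all sit at t_central (+ bump)
  expect_equal(an$central_mean, cfg$t_central + cfg$kp_bump)
  expect_gt(an$cptd, 0)
})

test_that("phantom config validates physiological ordering and geometry", {
  expect_error(small_phantom_config(t_central = 33, t_peripheral = 35),
               "t_central > t_peripheral")
  expect_silent(phantom_config(rgb_size = c(640, 400), irt_size = c(320, 240),
                               t_central = 33, t_peripheral = 35,
                               allow_nonphysiological = TRUE))
  expect_error(phantom_config(rgb_size = c(640, 400),
                              true_map = registration_map(c(1, 0, 0, 0, 1, 0),
                                                          crop_x = 350)),
               "crop margins exceed")
  expect_error(registration_map(c(1, 0, 0, 1e-14, 2e-14, 0)), "invertible")
})

test_that("occlusions overwrite surface temperature and mark covered landmarks", {
  cfg0 <- small_phantom_config(seed = 6, noise_sd_irt = 0, noise_sd_rgb = 0)
  base <- generate_phantom_pair(cfg0)
  # cover the left wrist with warm clothing, in full-RGB coordinates
  i <- which(kp_names() == "left_wrist")
  wx <- base$truth$kps_rgb$x[i]; wy <- base$truth$kps_rgb$y[i]
  occ <- list(list(rect = c(wx - 25, wy - 25, wx + 25, wy + 25), temp_c = 36.6))
  cfg <- small_phantom_config(seed = 6, noise_sd_irt = 0, noise_sd_rgb = 0,
                              occlusions = occ)
  gp <- generate_phantom_pair(cfg)
  expect_identical(gp$truth$kps_rgb$visibility[i], 1L)
  r <- roi_max_temperature(gp$pair$irt,
                           c(gp$truth$kps_irt$x[i], gp$truth$kps_irt$y[i]), 10L)
  expect_equal(r$max_c, 36.6)
  # occluded-by-clothing peripheral landmark raises the peripheral mean
  rec0 <- compute_cptd(base$pair$irt, base$truth$kps_irt)
  rec1 <- compute_cptd(gp$pair$irt, gp$truth$kps_irt)
  expect_gt(rec0$cptd, rec1$cptd)
})

test_that("phantom dataset round trips through PNG/TIFF/COCO files", {
  dir <- withr::local_tempdir()
  pairs <- list(); truths <- list()
  for (s in 1:3) {
    gp <- generate_phantom_pair(small_phantom_config(seed = s))
    pairs[[s]] <- gp$pair; truths[[s]] <- gp$truth
  }
  manifest <- write_phantom_dataset(pairs, truths, dir)
  expect_equal(nrow(manifest), 3)
  expect_length(list.files(dir, pattern = "\\.png$"), 3)
  expect_length(list.files(dir, pattern = "\\.tiff$"), 3)
  expect_true(file.exists(file.path(dir, "keypoints.json")))

  ds <- read_phantom_dataset(dir)
  expect_length(ds$pairs, 3)
  for (s in 1:3) {
    kps <- ds$kps_rgb[[s]][[1]]
    expect_equal(kps$x, truths[[s]]$kps_rgb$x, tolerance = 1e-9)
    expect_equal(kps$y, truths[[s]]$kps_rgb$y, tolerance = 1e-9)
    # thermogram survives the 16-bit centikelvin encoding within 0.005 degC
    expect_lt(max(abs(ds$pairs[[s]]$irt$temperatures -
                      pairs[[s]]$irt$temperatures)), 0.005)
    expect_equal(ds$truth[[s]]$kps_irt$x, truths[[s]]$kps_irt$x, tolerance = 1e-9)
  }
  expect_error(write_phantom_dataset(pairs, truths[1:2], dir), "differ in length")
  expect_error(write_phantom_dataset(list(), list(), dir), "empty")
})
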