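test_that("temperature encoding is linear centikelvin and round trips", {
  expect_identical(encode_temperature(36.50), 30965L)
  expect_equal(decode_temperature(0), -273.15)
  set.seed(20)
  temps <- runif(1000, 20, 45)
  expect_lt(max(abs(decode_temperature(encode_temperature(temps)) - temps)), 0.005)
  expect_error(encode_temperature(400), "range")
  expect_error(decode_temperature(-5), "16-bit")
})

test_that("thermal TIFF round trip stays within the quantization bound", {
  fr <- thermal_frame(matrix(runif(120, 25, 40), 10, 12))
  path <- withr::local_tempfile(fileext = ".tiff")
  write_thermal_tiff(fr, path)
  fr2 <- read_thermal_tiff(path)
  expect_lt(max(abs(fr2$temperatures - fr$temperatures)), 0.005)
  expect_equal(dim(fr2$temperatures), c(10, 12))
})

test_that("ROI maximum uses the half-open centered window with border clipping", {
  temps <- matrix(34.0, 60, 60)
  expect_equal(roi_max_temperature(temps, c(30, 30), 10)$max_c, 34.0)

  temps[25, 28] <- 37.2  # 0-based (x = 27, y = 24)
  r <- roi_max_temperature(temps, c(30, 27), 10)
  expect_equal(r$max_c, 37.2)
  expect_equal(r$n_valid_px, 100)

  # window at the corner is clipped to 5 x 5
  r <- roi_max_temperature(temps, c(0, 0), 10)
  expect_equal(r$n_valid_px, 25)

  # odd sizes center symmetrically: [c-2, c+2] for size 5
  temps2 <- matrix(0, 9, 9)
  temps2[3, 3] <- 1   # (x = 2, y = 2)
  expect_equal(roi_max_temperature(temps2, c(4, 4), 5)$max_c, 1)
  expect_equal(roi_max_temperature(temps2, c(5, 5), 5)$max_c, 0)

  expect_error(roi_max_temperature(temps, c(-1, 5), 10), "outside")

  # enlarging the window never decreases the maximum
  set.seed(9)
  field <- matrix(runif(3600, 25, 38), 60, 60)
  for (i in 1:20) {
    ctr <- runif(2, 5, 54)
    sizes <- c(3, 6, 10, 14, 21)
    vals <- sapply(sizes, function(s) roi_max_temperature(field, ctr, s)$max_c)
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("cpTD record follows the mean-of-ROI-maxima arithmetic", {
  # hand-constructed frame: two central and two peripheral landmarks with
  # known ROI maxima 37.0/36.8 and 34.1/34.3
  temps <- matrix(20, 100, 200)
  put <- function(x, y, v) temps[y + 1, x + 1] <<- v
  put(30, 30, 37.0); put(90, 30, 36.8); put(30, 70, 34.1); put(90, 70, 34.3)
  fr <- thermal_frame(temps)
  kps <- keypoint_set(c(30, 90, 30, 90, rep(150, 14)),
                      c(30, 30, 70, 70, rep(90, 14)),
                      c(2L, 2L, 2L, 2L, rep(0L, 14)), scale_area = 1e4)
  # explicit scheme so the fixture controls the regions
  scheme <- stats::setNames(rep("peripheral", 18), kp_names())
  scheme[c("nose", "left_eye")] <- "central"
  rec <- compute_cptd(fr, kps, scheme)
  expect_equal(rec$central_mean, 36.9)
  expect_equal(rec$peripheral_mean, 34.2)
  expect_equal(rec$cptd, 2.7)
  expect_equal(rec$n_central, 2L)
  expect_equal(rec$n_peripheral, 2L)
  expect_true(rec$defined)

  # a warmer periphery produces a negative cpTD, not an error
  scheme2 <- scheme
  scheme2[c("nose", "left_eye")] <- "peripheral"
  scheme2[c("right_eye", "left_ear")] <- "central"
  rec2 <- compute_cptd(fr, kps, scheme2)
  expect_lt(rec2$cptd, 0)
  expect_equal(rec2$cptd, -rec$cptd)

  # empty region: flagged, no exception
  kps0 <- kps; kps0$visibility[c(3, 4)] <- 0L
  rec3 <- compute_cptd(fr, kps0, scheme)
  expect_false(rec3$defined)
  expect_true(is.na(rec3$cptd))
  expect_true(all(c("right_eye", "left_ear") %in% rec3$excluded))
})

test_that("swapping the region scheme negates the cpTD exactly", {
  gp <- generate_phantom_pair(small_phantom_config(seed = 4))
  scheme <- default_region_scheme()
  swapped <- ifelse(scheme == "central", "peripheral", "central")
  names(swapped) <- names(scheme)
  a <- compute_cptd(gp$pair$irt, gp$truth$kps_irt, scheme)
  b <- compute_cptd(gp$pair$irt, gp$truth$kps_irt, swapped)
  expect_identical(a$cptd, -b$cptd)
})

test_that("cpTD error statistics match the direct formulas", {
  expect_equal(cptd_error_stats(c(2, 3), c(2.5, 2.5))$mae_c, 0.5)
  st <- cptd_error_stats(c(1.2, 3.4), c(1.2, 3.4))
  expect_equal(st$mae_c, 0)
  expect_equal(st$sd_c, 0)

  set.seed(30)
  est <- rnorm(50, 2.5, 1); gt <- rnorm(50, 2.5, 1)
  st <- cptd_error_stats(est, gt)
  expect_equal(st$mae_c, mean(abs(est - gt)), tolerance = 1e-12)
  expect_equal(st$sd_c, sd(abs(est - gt)), tolerance = 1e-12)
  # undefined frames drop out pairwise
  est[7] <- NA
  expect_equal(cptd_error_stats(est, gt)$n, 49)
  expect_error(cptd_error_stats(NA_real_, 1), "no frame")
})

test_that("Bland-Altman statistics match the direct formulas", {
  ba <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba$mean_difference, 0)
  expect_equal(unname(ba$loa), c(0, 0))

  ba <- bland_altman(c(1, 2, 3), c(1.5, 2.5, 3.5))
  expect_equal(ba$mean_difference, 0.5)
  expect_equal(ba$sd_difference, 0)
  expect_equal(unname(ba$loa), c(0.5, 0.5))

  set.seed(31)
  est <- rnorm(50, 2, 0.8); gt <- est + rnorm(50, -0.1, 0.3)
  ba <- bland_altman(est, gt)
  d <- gt - est
  expect_equal(ba$mean_difference, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd_difference, sd(d), tolerance = 1e-12)
  expect_equal(unname(ba$loa), mean(d) + c(-1.96, 1.96) * sd(d), tolerance = 1e-12)
  expect_equal(ba$points$mean, (est + gt) / 2, tolerance = 1e-12)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("small registration offsets are absorbed by the ROI window", {
  cfg <- small_phantom_config(seed = 14, noise_sd_irt = 0, noise_sd_rgb = 0)
  gp <- generate_phantom_pair(cfg)
  truth_rec <- compute_cptd(gp$pair$irt, gp$truth$kps_irt)
  # limb thermal gradient in IRT px (steepest chain: the arm)
  arm_px <- 0.347 * cfg$pose$scale * sqrt(abs(det(cfg$true_map$A)))
  g <- (cfg$t_central - cfg$t_peripheral) / arm_px
  for (e in c(0, 1, 2, 3, 5, 8, 12)) {
    shifted <- gp$truth$kps_irt
    shifted$x <- shifted$x + e / sqrt(2)
    shifted$y <- shifted$y + e / sqrt(2)
    rec <- compute_cptd(gp$pair$irt, shifted)
    err <- abs(rec$cptd - truth_rec$cptd)
    if (e <= 3) {
      expect_identical(err, 0)   # plateau still inside every window
    } else {
      expect_lte(err, 2 * (cfg$kp_bump + g * e))
    }
  }
})
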