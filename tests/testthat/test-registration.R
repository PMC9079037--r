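test_that("grayscale conversion uses Rec. 601 luma weights", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(255, 255, 255)
  img[1, 2, ] <- c(255, 0, 0)
  img[2, 1, ] <- c(90, 90, 90)
  g <- to_grayscale(img)
  expect_equal(g[1, 1], 255)
  expect_equal(g[1, 2], 76)  # 0.299 * 255 = 76.245
  expect_equal(g[2, 1], 90)
  expect_error(to_grayscale(matrix(0, 3, 3)), "3-channel")
})

test_that("warping reproduces identity and pure translation exactly", {
  set.seed(1)
  img <- matrix(runif(60 * 80, 0, 255), 60, 80)
  w <- warp_to_irt(img, registration_map(c(1, 0, 0, 0, 1, 0)), c(80, 60))
  expect_equal(w$image, img)
  expect_true(all(w$mask))

  w <- warp_to_irt(img, registration_map(c(1, 0, 10, 0, 1, 0)), c(80, 60))
  expect_equal(w$image[, 11:80], img[, 1:70])
  expect_false(any(w$mask[, 1:10]))
})

test_that("downscale warping preserves mean intensity on a checkerboard", {
  cb <- 255 * outer(0:127, 0:127, function(r, c) (r %/% 8 + c %/% 8) %% 2)
  map <- registration_map(c(0.5, 0, 0, 0, 0.5, 0))
  w <- warp_to_irt(cb, map, c(64, 64))
  expect_lt(abs(mean(w$image[w$mask]) - mean(cb)) / mean(cb), 0.01)
})

test_that("joint histogram counts and marginals follow the definition", {
  a <- matrix(c(0, 1, 0, 1), 2, 2)
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  h <- joint_histogram(a, b, bins = 2)
  expect_equal(h$counts, matrix(1, 2, 2))
  expect_equal(h$n, 4)

  h <- joint_histogram(a, a, bins = 2)
  expect_equal(h$counts, diag(c(2, 2)))

  h <- joint_histogram(a, b, bins = 1)
  expect_equal(h$counts, matrix(4, 1, 1))

  expect_error(joint_histogram(a, b, mask = matrix(FALSE, 2, 2)), "empty mask")

  # marginals reproduce each image's own histogram over the mask
  set.seed(2)
  x <- matrix(runif(400), 20, 20); y <- matrix(runif(400), 20, 20)
  msk <- matrix(runif(400) > 0.3, 20, 20)
  h <- joint_histogram(x, y, msk, bins = 8)
  expect_equal(sum(h$counts), sum(msk))
  hx <- tabulate(pmin(floor((x[msk] - min(x[msk])) / diff(range(x[msk])) * 8) + 1, 8), 8)
  expect_equal(rowSums(h$counts), hx)
})

test_that("mutual information matches closed forms", {
  expect_equal(mutual_information(matrix(25, 2, 2)), 0)
  expect_equal(mutual_information(diag(c(50, 50))), log(2))
  expect_equal(mutual_information(matrix(c(0, 50, 50, 0), 2, 2)), log(2))
  expect_error(mutual_information(matrix(0, 2, 2)), "empty")
})

test_that("MI is symmetric, non-negative, and bounded by marginal entropies", {
  set.seed(3)
  entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  for (i in 1:200) {
    bins <- sample(2:8, 1)
    counts <- matrix(rpois(bins^2, 3), bins, bins)
    if (sum(counts) == 0) counts[1, 1] <- 1
    mi <- mutual_information(counts)
    expect_gte(mi, -1e-9)
    expect_equal(mi, mutual_information(t(counts)), tolerance = 1e-12)
    p <- counts / sum(counts)
    expect_lte(mi, min(entropy(rowSums(p)), entropy(colSums(p))) + 1e-9)
  }
})

test_that("point transforms compose crop and affine, and round trip", {
  m <- registration_map(c(1, 0, 0, 0, 1, 0))
  expect_equal(as.numeric(transform_points(matrix(c(100, 50), 1), m)), c(100, 50))

  m <- registration_map(c(1, 0, 10, 0, 1, -5))
  expect_equal(as.numeric(transform_points(matrix(c(100, 50), 1), m)), c(110, 45))

  m <- registration_map(c(1, 0, 0, 0, 1, 0), crop_x = 160, crop_y = 0)
  expect_equal(as.numeric(transform_points(matrix(c(200, 100), 1), m)), c(40, 100))

  set.seed(4)
  for (i in 1:10) {
    m <- map_from_params(runif(1, -50, 50), runif(1, -50, 50),
                         runif(1, 0.4, 1.4), runif(1, 0.4, 1.4),
                         runif(1, -0.3, 0.3), runif(1, 0, 100), runif(1, 0, 100))
    pts <- matrix(runif(40, 0, 1000), 20, 2)
    back <- inverse_transform_points(transform_points(pts, m), m)
    expect_lt(max(abs(back - pts)), 1e-6)
  }

  # out-of-bounds points are flagged but returned
  m <- registration_map(c(1, 0, 0, 0, 1, 0))
  p <- transform_points(matrix(c(500, 10), 1), m, irt_size = c(100, 100))
  expect_true(attr(p, "oob"))
  expect_equal(as.numeric(p), c(500, 10))

  expect_error(registration_map(c(1, 2, 0, 2, 4, 0)), "invertible")
})

test_that("point-transformation error matches hand values and a brute-force oracle", {
  gt <- matrix(c(10, 20), 1)
  pred <- matrix(c(13, 16), 1)
  e <- point_transform_error(pred, gt, mm_per_px = 0.5)
  expect_equal(e$mae_px, c(3, 4))
  expect_equal(e$mae_mm, c(1.5, 2.0))
  expect_equal(e$sd_px, c(0, 0))

  set.seed(5)
  p0 <- matrix(runif(200, 0, 500), 100, 2)
  p1 <- p0 + matrix(rnorm(200, 0, 12), 100, 2)
  e <- point_transform_error(p1, p0, mm_per_px = 0.5)
  expect_equal(e$mae_px, c(mean(abs(p1[, 1] - p0[, 1])), mean(abs(p1[, 2] - p0[, 2]))),
               tolerance = 1e-12)
  expect_equal(e$sd_px, c(sd(abs(p1[, 1] - p0[, 1])), sd(abs(p1[, 2] - p0[, 2]))),
               tolerance = 1e-12)
})

test_that("pixel-to-millimeter conversion", {
  expect_equal(px_to_mm(16.4, 0.5), 8.2)
  expect_equal(px_to_mm(22.4, 0.5), 11.2)
  expect_equal(px_to_mm(0, 0.5), 0)
  expect_error(px_to_mm(1, 0), "positive")
})

test_that("objective equals the warp + histogram + MI composition", {
  gp <- generate_phantom_pair(small_phantom_config(seed = 3))
  g <- to_grayscale(gp$pair$rgb)
  irt <- gp$pair$irt$temperatures
  st <- optimizer_settings()
  for (m in list(gp$truth$true_map,
                 map_from_params(5, -3, 0.5, 0.55, 0.02, 30, 10))) {
    w <- warp_to_irt(g, m, c(ncol(irt), nrow(irt)))
    h <- joint_histogram(w$image, irt, w$mask, st$bins)
    mi <- mutual_information(h)
    ov <- mean(w$mask)
    expected <- if (ov < st$min_overlap_fraction) mi * ov / st$min_overlap_fraction else mi
    expect_equal(registration_objective(m, g, irt, st), expected, tolerance = 1e-12)
  }
})

test_that("objective prefers the true map and penalizes low overlap", {
  gp <- generate_phantom_pair(small_phantom_config(seed = 5, noise_sd_irt = 0,
                                                   noise_sd_rgb = 0))
  g <- to_grayscale(gp$pair$rgb)
  irt <- gp$pair$irt$temperatures
  st <- optimizer_settings()
  m <- gp$truth$true_map
  shifted <- registration_map(cbind(m$A, m$t + c(30, 0)), m$crop[1], m$crop[2])
  expect_gt(registration_objective(m, g, irt, st),
            registration_objective(shifted, g, irt, st))

  # constant IRT image carries no information
  expect_equal(registration_objective(m, g, matrix(30, nrow(irt), ncol(irt)), st), 0)

  # non-invertible candidate yields -Inf, not an error
  p <- c(tx = 0, ty = 0, sx = 0, sy = 1, theta = 0, crop_x = 0, crop_y = 0)
  expect_identical(registration_objective(p, g, irt, st), -Inf)
})

test_that("self-registration recovers a known synthetic map within 2 px", {
  gp <- generate_phantom_pair(small_phantom_config(seed = 8))
  g <- to_grayscale(gp$pair$rgb)
  m <- map_from_params(18, -10, 0.5, 0.52, 0.03, 40, 20)
  irt <- warp_to_irt(g, m, c(320, 240))$image
  fit <- fit_registration(g, irt, optimizer_settings(seed = 0, downsample = 2L))
  pts <- cbind(gp$truth$kps_rgb$x, gp$truth$kps_rgb$y)
  err <- sqrt(rowSums((transform_points(pts, fit$map) - transform_points(pts, m))^2))
  expect_lt(mean(err), 2)
})

test_that("registration is deterministic given the seed and errors on degenerate input", {
  gp <- generate_phantom_pair(small_phantom_config(seed = 2))
  st <- optimizer_settings(n_evals = 60L, seed = 9, downsample = 2L)
  f1 <- fit_registration(gp$pair$rgb, gp$pair$irt, st)
  f2 <- fit_registration(gp$pair$rgb, gp$pair$irt, st)
  expect_identical(f1$map, f2$map)
  expect_identical(f1$trace$objective, f2$trace$objective)
  expect_equal(nrow(f1$trace), 60L)

  const <- matrix(5, 240, 320)
  expect_error(fit_registration(const, gp$pair$irt$temperatures, st), "constant image")
  expect_error(fit_registration(to_grayscale(gp$pair$rgb), const * 0 + 1, st),
               "constant image")
})

test_that("registration map JSON round trips", {
  m <- map_from_params(12.5, -3.25, 0.61, 0.58, 0.04, 120, 40)
  path <- withr::local_tempfile(fileext = ".json")
  write_registration_map(m, path, mi = 0.71, seed = 3L, n_evals = 500L)
  m2 <- read_registration_map(path)
  expect_equal(m2$A, m$A, tolerance = 1e-12)
  expect_equal(m2$t, m$t, tolerance = 1e-12)
  expect_equal(m2$crop, m$crop)
  expect_equal(attr(m2, "mi"), 0.71)
})
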