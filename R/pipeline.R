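#' Pipeline configuration
#'
#' Describes one end-to-end run: where the frame pairs come from (a phantom
#' study or a dataset directory), which detector produces RGB keypoints,
#' how the per-subject registration map is obtained, and the extraction
#' parameters. One registration map is fitted (or supplied) per subject and
#' reused for all of that subject's frames.
#'
#' @param n_subjects,n_frames Number of phantom subjects and frames per
#'   subject (ignored when `manifest_dir` is given).
#' @param manifest_dir Optional directory with a dataset written by
#'   [write_phantom_dataset()]; mutually exclusive with phantom
#'   generation settings.
#' @param phantom Base [phantom_config()] for generated subjects (sizes,
#'   temperatures, noise); per-subject maps and per-frame pose jitter are
#'   derived from the global seed.
#' @param detector `"ground_truth"`, `"mock"`, or a function
#'   `(rgb, frame_seed) -> keypoint_set`.
#' @param detector_noise A [detector_noise_config()] for the mock
#'   detector.
#' @param registration `"ground_truth"`, `"fit"`, or the path of a map
#'   JSON from [write_registration_map()] (applied to every subject).
#' @param optimizer An [optimizer_settings()] used when
#'   `registration = "fit"`.
#' @param scheme Region scheme (default [default_region_scheme()]).
#' @param roi_size ROI side length in px (default 10).
#' @param mm_per_px Spatial resolution (default 0.5).
#' @param out_dir Optional output directory for results CSVs.
#' @param seed Global seed; propagated to every stochastic component.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 3L, n_frames = 5L,
                            manifest_dir = NULL,
                            phantom = phantom_config(),
                            detector = c("ground_truth", "mock"),
                            detector_noise = detector_noise_config(coord_sd = 5, dropout_prob = 0.1),
                            registration = c("ground_truth", "fit"),
                            optimizer = optimizer_settings(),
                            scheme = default_region_scheme(),
                            roi_size = 10L, mm_per_px = 0.5,
                            out_dir = NULL, seed = 0L) {
  if (!is.function(detector)) detector <- match.arg(detector)
  reg_ok <- inherits(registration, "registration_map") ||
    (is.character(registration) &&
       (registration[1] %in% c("ground_truth", "fit") || file.exists(registration[1])))
  if (!reg_ok) stop("registration must be 'ground_truth', 'fit', a registration_map, ",
                    "or the path of a map JSON")
  if (is.character(registration)) registration <- registration[1]
  validate_region_scheme(scheme)
  structure(list(n_subjects = as.integer(n_subjects), n_frames = as.integer(n_frames),
                 manifest_dir = manifest_dir, phantom = phantom,
                 detector = detector, detector_noise = detector_noise,
                 registration = registration, optimizer = optimizer,
                 scheme = scheme, roi_size = as.integer(roi_size),
                 mm_per_px = mm_per_px, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

phantom_subject_frames <- function(config) {
  ph <- config$phantom
  subjects <- list()
  for (s in seq_len(config$n_subjects)) {
    map <- sample_registration_map(ph$pose, ph$irt_size,
                                   seed = derive_seed(config$seed, 1000 + s))
    frames <- list()
    for (f in seq_len(config$n_frames)) {
      fs <- derive_seed(config$seed, s * 100 + f)
      jit <- with_seed(fs, list(dc = stats::runif(2, -30, 30),
                                dr = stats::runif(1, -5, 5) * pi / 180))
      pose <- phantom_pose(scale = ph$pose$scale,
                           center = ph$pose$center + jit$dc,
                           rotation = ph$pose$rotation + jit$dr)
      cfg <- phantom_config(rgb_size = ph$rgb_size, irt_size = ph$irt_size,
                            true_map = map, pose = pose,
                            t_central = ph$t_central, t_peripheral = ph$t_peripheral,
                            t_background = ph$t_background, kp_bump = ph$kp_bump,
                            noise_sd_irt = ph$noise_sd_irt, noise_sd_rgb = ph$noise_sd_rgb,
                            occlusions = ph$occlusions, seed = fs)
      frames[[f]] <- generate_phantom_pair(cfg)
    }
    subjects[[s]] <- list(id = s, true_map = map, frames = frames)
  }
  subjects
}

#' Run the camera-fusion temperature pipeline end to end
#'
#' For every frame pair: obtain RGB keypoints from the configured detector,
#' derive the neck, transform the keypoints into IRT coordinates through
#' the subject's registration map, classify regions, and extract the cpTD.
#' Ground-truth cpTD (from the true IRT keypoints on the same thermogram)
#' and per-keypoint point-transformation deviations are recorded whenever
#' ground truth is available. Fully deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`: `frames` (per-frame data frame
#'   with cpTD columns), `records` (list of [compute_cptd()] records),
#'   `point_errors` (per-keypoint deviations, px), `maps` (per-subject
#'   registration maps), `config`. If `config$out_dir` is set, writes
#'   `results.csv` and `map_subject<NN>.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$manifest_dir)) {
    ds <- read_phantom_dataset(config$manifest_dir)
    subjects <- list(list(id = 1L,
                          true_map = if (!is.null(ds$truth)) ds$truth[[1]]$true_map else NULL,
                          frames = lapply(seq_along(ds$pairs), function(i) {
                            list(pair = ds$pairs[[i]],
                                 truth = if (!is.null(ds$truth)) {
                                   tr <- ds$truth[[i]]
                                   tr$kps_rgb <- ds$kps_rgb[[i]][[1]]
                                   tr
                                 } else list(kps_rgb = ds$kps_rgb[[i]][[1]]))
                          })))
  } else {
    subjects <- phantom_subject_frames(config)
  }

  frames_df <- NULL
  records <- list()
  point_err <- NULL
  maps <- list()
  for (sub in subjects) {
    ## registration source: one map per subject, reused for all frames
    map <- if (inherits(config$registration, "registration_map")) {
      config$registration
    } else if (identical(config$registration, "ground_truth")) {
      if (is.null(sub$true_map)) stop("ground-truth registration requested but unavailable")
      sub$true_map
    } else if (identical(config$registration, "fit")) {
      opt <- config$optimizer
      opt$seed <- derive_seed(config$seed, 5000 + sub$id)
      first <- sub$frames[[1]]
      fit <- fit_registration(first$pair$rgb, first$pair$irt, opt)
      fit$map
    } else {
      read_registration_map(config$registration)
    }
    maps[[sub$id]] <- map

    for (fi in seq_along(sub$frames)) {
      fr <- sub$frames[[fi]]
      truth <- fr$truth
      frame_seed <- derive_seed(config$seed, 7000 + sub$id * 100 + fi)
      kps <- if (is.function(config$detector)) {
        config$detector(fr$pair$rgb, frame_seed)
      } else if (config$detector == "ground_truth") {
        truth$kps_rgb
      } else {
        noise <- config$detector_noise
        noise$seed <- frame_seed
        mock_detect(truth$kps_rgb, noise,
                    frame_size = c(ncol(fr$pair$rgb), nrow(fr$pair$rgb)))
      }
      kps <- derive_neck(kps)
      irt_size <- c(ncol(fr$pair$irt$temperatures), nrow(fr$pair$irt$temperatures))
      kps_irt <- transform_points(kps, map, irt_size)
      rec <- compute_cptd(fr$pair$irt, kps_irt, config$scheme, config$roi_size)

      cptd_gt <- NA_real_
      if (!is.null(truth$kps_irt)) {
        rec_gt <- compute_cptd(fr$pair$irt, truth$kps_irt, config$scheme, config$roi_size)
        cptd_gt <- rec_gt$cptd
        keep <- kps_irt$visibility >= 1L & truth$kps_irt$visibility >= 1L
        if (any(keep)) {
          point_err <- rbind(point_err, data.frame(
            subject = sub$id, frame = fi, name = kps$name[keep],
            dx = kps_irt$x[keep] - truth$kps_irt$x[keep],
            dy = kps_irt$y[keep] - truth$kps_irt$y[keep]))
        }
      }
      frames_df <- rbind(frames_df, data.frame(
        subject = sub$id, frame = fi,
        central_mean = rec$central_mean, peripheral_mean = rec$peripheral_mean,
        cptd = rec$cptd, defined = rec$defined,
        n_central = rec$n_central, n_peripheral = rec$n_peripheral,
        cptd_gt = cptd_gt,
        excluded_keypoints = paste(rec$excluded, collapse = ";")))
      records[[length(records) + 1L]] <- rec
    }
  }

  report <- structure(list(frames = frames_df, records = records,
                           point_errors = point_err, maps = maps,
                           config = config, seed = config$seed),
                      class = "run_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(frames_df, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    for (sid in seq_along(maps)) {
      write_registration_map(maps[[sid]],
                             file.path(config$out_dir, sprintf("map_subject%02d.json", sid)),
                             seed = config$seed)
    }
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  n_def <- sum(x$frames$defined)
  cat(sprintf("<run_report> %d frames (%d with defined cpTD), %d subject(s)\n",
              nrow(x$frames), n_def, length(x$maps)))
  if (n_def > 0 && any(!is.na(x$frames$cptd_gt))) {
    st <- cptd_error_stats(x$frames$cptd, x$frames$cptd_gt)
    cat(sprintf("  cpTD MAE vs GT: %.3f degC (SD %.3f, n = %d)\n",
                st$mae_c, st$sd_c, st$n))
  }
  invisible(x)
}

#' Summarize a pipeline run against ground truth
#'
#' Produces the two standard evaluation tables plus Bland-Altman
#' statistics: per-subject and pooled point-transformation MAE/SD (px and
#' mm) and per-subject and pooled cpTD MAE/SD. The `Total` rows pool all
#' frames (and all point pairs) across subjects rather than averaging the
#' per-subject means.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Optional directory; writes `evaluation_points.csv`,
#'   `evaluation_cptd.csv` and `bland_altman.csv`.
#' @return List with `point_table`, `cptd_table`, `bland_altman` (or `NA`
#'   fields when ground truth was unavailable).
#' @export
evaluate_run <- function(report, out_dir = NULL) {
  stopifnot(inherits(report, "run_report"))
  mm <- report$config$mm_per_px
  pt <- report$point_errors
  point_table <- NULL
  if (!is.null(pt)) {
    row_for <- function(d, label) {
      sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
      data.frame(subject = label,
                 mae_x_px = mean(abs(d$dx)), sd_x_px = sd0(abs(d$dx)),
                 mae_y_px = mean(abs(d$dy)), sd_y_px = sd0(abs(d$dy)),
                 mae_x_mm = px_to_mm(mean(abs(d$dx)), mm),
                 mae_y_mm = px_to_mm(mean(abs(d$dy)), mm),
                 n_points = nrow(d))
    }
    per <- lapply(split(pt, pt$subject), function(d) row_for(d, as.character(d$subject[1])))
    point_table <- rbind(do.call(rbind, per), row_for(pt, "Total"))
    rownames(point_table) <- NULL
  }
  fr <- report$frames
  cptd_table <- NULL
  ba <- NULL
  if (any(!is.na(fr$cptd_gt))) {
    row_for <- function(d, label) {
      keep <- !is.na(d$cptd) & !is.na(d$cptd_gt)
      if (!any(keep)) {
        return(data.frame(subject = label, mae_c = NA_real_, sd_c = NA_real_,
                          n_frames = 0L, n_undefined = sum(!keep)))
      }
      st <- cptd_error_stats(d$cptd[keep], d$cptd_gt[keep])
      data.frame(subject = label, mae_c = st$mae_c, sd_c = st$sd_c,
                 n_frames = st$n, n_undefined = sum(!keep))
    }
    per <- lapply(split(fr, fr$subject), function(d) row_for(d, as.character(d$subject[1])))
    cptd_table <- rbind(do.call(rbind, per), row_for(fr, "Total"))
    rownames(cptd_table) <- NULL
    keep <- !is.na(fr$cptd) & !is.na(fr$cptd_gt)
    if (sum(keep) >= 2L) ba <- bland_altman(fr$cptd[keep], fr$cptd_gt[keep])
  }
  out <- list(point_table = point_table, cptd_table = cptd_table, bland_altman = ba)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(point_table)) {
      utils::write.csv(point_table, file.path(out_dir, "evaluation_points.csv"), row.names = FALSE)
    }
    if (!is.null(cptd_table)) {
      utils::write.csv(cptd_table, file.path(out_dir, "evaluation_cptd.csv"), row.names = FALSE)
    }
    if (!is.null(ba)) {
      utils::write.csv(data.frame(mean_difference = ba$mean_difference,
                                  sd_difference = ba$sd_difference,
                                  loa_lower = ba$loa[1], loa_upper = ba$loa[2]),
                       file.path(out_dir, "bland_altman.csv"), row.names = FALSE)
    }
  }
  out
}
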