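coco_skeleton_edges <- function() {
  # 1-based indices into kp_names(); standard COCO person skeleton plus the
  # neck-to-shoulder links
  list(c(16, 14), c(14, 12), c(17, 15), c(15, 13), c(12, 13),
       c(6, 12), c(7, 13), c(6, 8), c(7, 9), c(8, 10), c(9, 11),
       c(2, 3), c(1, 2), c(1, 3), c(2, 4), c(3, 5),
       c(18, 6), c(18, 7))
}

#' Write keypoint sets as COCO keypoint JSON
#'
#' Produces a standard COCO-format file with one `person` category (18
#' keypoints: the 17 COCO landmarks plus `neck`), one image entry per
#' frame, and one annotation per keypoint set with the `keypoints`
#' (x, y, v) triplets and the subject mask area in `area`.
#'
#' @param sets List (one element per frame) of [keypoint_set()]s, or of
#'   lists of keypoint sets for multi-instance frames.
#' @param path Output path.
#' @param image_sizes Optional list of `c(width, height)` per frame.
#' @param file_names Optional image file names.
#' @return `path`, invisibly.
#' @export
write_coco_keypoints <- function(sets, path, image_sizes = NULL, file_names = NULL) {
  per_frame <- lapply(sets, function(s) if (inherits(s, "keypoint_set")) list(s) else s)
  images <- lapply(seq_along(per_frame), function(i) {
    img <- list(id = i,
                file_name = if (is.null(file_names)) sprintf("frame_%03d.png", i) else file_names[[i]])
    if (!is.null(image_sizes)) {
      img$width <- image_sizes[[i]][1]
      img$height <- image_sizes[[i]][2]
    }
    img
  })
  ann_id <- 0L
  annotations <- list()
  for (i in seq_along(per_frame)) {
    for (s in per_frame[[i]]) {
      ann_id <- ann_id + 1L
      triplets <- as.numeric(t(cbind(s$x, s$y, s$visibility)))
      triplets[rep(s$visibility == 0L, each = 3)] <- 0
      ann <- list(id = ann_id, image_id = i, category_id = 1L,
                  keypoints = triplets,
                  num_keypoints = sum(s$visibility > 0L),
                  area = attr(s, "scale_area"),
                  iscrowd = 0L)
      if (any(!is.na(s$confidence))) ann$score <- mean(s$confidence, na.rm = TRUE)
      annotations[[ann_id]] <- ann
    }
  }
  obj <- list(images = images,
              annotations = annotations,
              categories = list(list(id = 1L, name = "person",
                                     supercategory = "person",
                                     keypoints = as.list(kp_names()),
                                     skeleton = coco_skeleton_edges())))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read COCO keypoint JSON into keypoint sets
#'
#' Accepts both the 18-keypoint dialect written by
#' [write_coco_keypoints()] and the standard 17-keypoint COCO dialect; in
#' the latter case the neck is derived from the shoulders on load and the
#' returned sets carry the attribute `neck_derived = TRUE`.
#'
#' @param path COCO keypoint JSON file.
#' @return List with one element per image; each element is a list of
#'   [keypoint_set()]s (annotations for that image, possibly empty).
#' @export
read_coco_keypoints <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("failed to parse COCO JSON '", path, "': ",
                                           conditionMessage(e)))
  if (is.null(obj$categories) || is.null(obj$annotations) || is.null(obj$images)) {
    stop("'", path, "' is not a COCO keypoint file (missing images/annotations/categories)")
  }
  cat1 <- obj$categories[[1]]
  if (!identical(cat1$name, "person")) stop("unknown category '", cat1$name, "' in ", path)
  n_kp <- length(cat1$keypoints)
  if (!n_kp %in% c(17L, 18L)) {
    stop("unsupported keypoint count ", n_kp, " in ", path, " (expected 17 or 18)")
  }
  derive <- n_kp == 17L
  img_ids <- vapply(obj$images, function(im) as.integer(im$id), integer(1))
  out <- stats::setNames(vector("list", length(img_ids)), as.character(img_ids))
  for (ann in obj$annotations) {
    tri <- matrix(as.numeric(unlist(ann$keypoints)), ncol = 3, byrow = TRUE)
    if (nrow(tri) != n_kp) stop("annotation ", ann$id, " has ", nrow(tri), " keypoints")
    if (derive) tri <- rbind(tri, c(0, 0, 0))
    s <- keypoint_set(tri[, 1], tri[, 2], as.integer(tri[, 3]),
                      confidence = if (!is.null(ann$score)) ann$score else NA_real_,
                      scale_area = if (!is.null(ann$area)) as.numeric(ann$area) else NA_real_)
    if (derive) {
      s <- derive_neck(s)
      attr(s, "neck_derived") <- TRUE
    }
    key <- as.character(ann$image_id)
    out[[key]] <- c(out[[key]], list(s))
  }
  unname(out)
}
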