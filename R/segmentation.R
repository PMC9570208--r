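#' Segment red blood cells from a dual-channel image
#'
#' Default (unsupervised) procedure: (a) foreground by Otsu threshold on
#' the summed channels (or by a trained pixel classifier, see
#' [train_pixel_classifier()]); (b) holes filled; (c) connected
#' components; (d) objects rejected when their area falls outside
#' `[min_area_um2, max_area_um2]` or their solidity (pixel area over
#' convex-hull area) falls below `min_solidity` — this removes debris
#' and aggregates; (e) optionally, border-touching objects rejected.
#' Every rejection is logged per object. A blank image yields an empty
#' mask set with a warning, not an error.
#'
#' @param image a [dual_channel_image()].
#' @param min_area_um2,max_area_um2 retained object area range
#'   (micrometres squared); defaults bracket the typical RBC projected
#'   area (~50 um^2).
#' @param min_solidity minimum solidity of retained objects.
#' @param exclude_border reject objects touching the frame edge?
#' @param connectivity component connectivity (8 matches ImageJ).
#' @param mode "otsu" or "classifier".
#' @param classifier fitted [train_pixel_classifier()] object (required
#'   for `mode = "classifier"`).
#' @return object of class `cell_mask_set`: `labels` (raster, 0
#'   background, labels 1..n_cells), `n_cells`, `filter_log`
#'   (data.frame: object, n_px, area_um2, solidity, border, kept,
#'   reason), `pixel_size_um`.
#' @export
segment_cells <- function(image, min_area_um2 = 20, max_area_um2 = 120,
                          min_solidity = 0.85, exclude_border = FALSE,
                          connectivity = 8, mode = c("otsu", "classifier"),
                          classifier = NULL) {
  stopifnot(inherits(image, "dual_channel_image"))
  mode <- match.arg(mode)
  ps <- image$pixel_size_um
  total <- image$blue + image$green
  if (mode == "classifier") {
    if (is.null(classifier)) stopf("mode = 'classifier' requires a classifier")
    fg <- predict_pixels(classifier, image) == "cell"
  } else {
    rng <- range(total)
    if (rng[2] <= rng[1]) {
      warnf("blank image: no foreground found")
      return(empty_mask_set(image))
    }
    x <- (total - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(x, range = c(0, 1))
    fg <- x > thr
  }
  if (!any(fg)) {
    warnf("blank image: no foreground found")
    return(empty_mask_set(image))
  }
  fg <- EBImage::fillHull(fg) > 0
  lab <- label_components(fg, connectivity = connectivity)
  n_obj <- max(lab)
  idx <- which(lab > 0, arr.ind = TRUE)
  lab_at <- lab[lab > 0]
  log <- data.frame(object = seq_len(n_obj), n_px = NA_integer_,
                    area_um2 = NA_real_, solidity = NA_real_,
                    border = FALSE, kept = FALSE, reason = "")
  keep_ids <- integer(0)
  for (i in seq_len(n_obj)) {
    px <- idx[lab_at == i, , drop = FALSE]
    n_px <- nrow(px)
    area <- n_px * ps^2
    hull <- convex_hull(pixel_corners(px[, 1], px[, 2]))
    hull_area <- polygon_area(hull)
    sol <- if (hull_area > 0) min(1, n_px / hull_area) else 1
    border <- any(px[, 1] %in% c(1L, nrow(lab))) || any(px[, 2] %in% c(1L, ncol(lab)))
    reason <- ""
    if (area < min_area_um2) reason <- "area_below_min"
    else if (area > max_area_um2) reason <- "area_above_max"
    else if (sol < min_solidity) reason <- "low_solidity"
    else if (exclude_border && border) reason <- "touches_border"
    log[i, c("n_px", "area_um2", "solidity", "border")] <-
      list(n_px, area, sol, border)
    if (reason == "") {
      log$kept[i] <- TRUE
      keep_ids <- c(keep_ids, i)
    } else log$reason[i] <- reason
  }
  relabel <- integer(n_obj)
  relabel[keep_ids] <- seq_along(keep_ids)
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  structure(list(labels = out, n_cells = length(keep_ids), filter_log = log,
                 pixel_size_um = ps),
            class = "cell_mask_set")
}

empty_mask_set <- function(image) {
  structure(list(labels = matrix(0L, nrow(image$blue), ncol(image$blue)),
                 n_cells = 0L,
                 filter_log = data.frame(object = integer(0), n_px = integer(0),
                                         area_um2 = numeric(0), solidity = numeric(0),
                                         border = logical(0), kept = logical(0),
                                         reason = character(0)),
                 pixel_size_um = image$pixel_size_um),
            class = "cell_mask_set")
}

#' @export
print.cell_mask_set <- function(x, ...) {
  cat(sprintf("<cell_mask_set> %d cell(s), %d object(s) rejected\n",
              x$n_cells, sum(!x$filter_log$kept)))
  invisible(x)
}

# Per-pixel feature stack: Gaussian-smoothed summed intensity and
# gradient magnitude at each scale.
pixel_features <- function(image, scales = c(1, 2, 4)) {
  total <- image$blue + image$green
  total <- total / max(total, 1)
  feats <- list()
  for (s in scales) {
    g <- as.matrix(EBImage::gblur(total, sigma = s))
    nr <- nrow(g); nc <- ncol(g)
    gx <- g[, c(2:nc, nc)] - g[, c(1, 1:(nc - 1))]
    gy <- g[c(2:nr, nr), ] - g[c(1, 1:(nr - 1)), ]
    feats[[paste0("smooth_s", s)]] <- as.vector(g)
    feats[[paste0("grad_s", s)]] <- as.vector(sqrt(gx^2 + gy^2))
  }
  as.data.frame(feats)
}

#' Train a supervised pixel classifier
#'
#' Random-forest per-pixel classification on Gaussian-smoothed summed
#' intensity and gradient-magnitude features at several scales — a
#' lightweight stand-in for interactive supervised pixel-classification
#' workflows. Labels are sparse: 0 = unlabeled, and at least two
#' classes among "cell", "background", "debris" (coded 1, 2, 3) must be
#' present.
#'
#' @param image a [dual_channel_image()].
#' @param label_raster integer matrix: 0 unlabeled, 1 cell,
#'   2 background, 3 debris.
#' @param scales Gaussian scales (pixels) of the feature stack.
#' @param ntree random-forest size.
#' @param seed RNG seed for the forest.
#' @return object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(image, label_raster, scales = c(1, 2, 4),
                                   ntree = 100L, seed = 1L) {
  stopifnot(inherits(image, "dual_channel_image"))
  lv <- as.vector(label_raster)
  labeled <- which(lv > 0)
  if (length(labeled) == 0) stopf("no labeled pixels supplied")
  class_names <- c("cell", "background", "debris")
  y <- factor(class_names[lv[labeled]], levels = class_names)
  if (length(unique(y)) < 2) stopf("need labeled pixels from at least 2 classes")
  X <- pixel_features(image, scales)[labeled, , drop = FALSE]
  fit <- with_seed(seed, randomForest::randomForest(X, droplevels(y), ntree = ntree))
  structure(list(fit = fit, scales = scales), class = "pixel_classifier")
}

#' Predict per-pixel classes with a trained classifier
#'
#' @param classifier a [train_pixel_classifier()] object.
#' @param image a [dual_channel_image()].
#' @return character matrix of class labels ("cell", "background",
#'   "debris") with the image's shape.
#' @export
predict_pixels <- function(classifier, image) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  X <- pixel_features(image, classifier$scales)
  pred <- predict(classifier$fit, X)
  matrix(as.character(pred), nrow(image$blue), ncol(image$blue))
}
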