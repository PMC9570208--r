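#' Compute a per-pixel generalized polarization (GP) map
#'
#' GP = (I_blue - G * I_green) / (I_blue + G * I_green), the ratiometric
#' index of Laurdan emission: +1 for purely ordered (blue-shifted)
#' membrane, -1 for purely fluid (green-shifted). G is the
#' instrument-dependent calibration factor applied to the green channel.
#' Pixels whose denominator does not exceed `denom_floor` (dark pixels,
#' where the ratio is noise-dominated) are flagged undefined (NA) and
#' excluded from all downstream statistics and domain masks.
#'
#' @param image a [dual_channel_image()]; negative intensities are an
#'   error (upstream corruption).
#' @param G calibration factor (> 0).
#' @param denom_floor minimum denominator (detector counts) for a pixel
#'   to be defined.
#' @return object of class `gp_map`: `gp` (matrix in [-1, 1] with NA =
#'   undefined), `G`, `denom_floor`, `pixel_size_um`, `source` (image
#'   metadata).
#' @export
compute_gp <- function(image, G = 1, denom_floor = 1) {
  stopifnot(inherits(image, "dual_channel_image"))
  if (G <= 0) stopf("G must be positive")
  if (min(image$blue) < 0 || min(image$green) < 0)
    stopf("negative intensities: corrupted input")
  denom <- image$blue + G * image$green
  gp <- (image$blue - G * image$green) / denom
  gp[denom <= denom_floor] <- NA_real_
  structure(list(gp = gp, G = G, denom_floor = denom_floor,
                 pixel_size_um = image$pixel_size_um, source = image$meta),
            class = "gp_map")
}

#' @export
print.gp_map <- function(x, ...) {
  d <- x$gp[!is.na(x$gp)]
  cat(sprintf("<gp_map> %d x %d px, G = %.4g, %d defined px, mean GP %.3f\n",
              nrow(x$gp), ncol(x$gp), x$G, length(d),
              if (length(d)) mean(d) else NA))
  invisible(x)
}

#' Calibrate the G factor from a reference image
#'
#' Solves GP(reference) = `gp_ref` for G over a reference mask:
#' G = (mean I_blue / mean I_green) * (1 - gp_ref) / (1 + gp_ref).
#' Typical use: a reference dye solution or sample of known GP.
#'
#' @param ref_image a [dual_channel_image()] of the reference.
#' @param gp_ref known GP of the reference, |gp_ref| < 1.
#' @param mask logical matrix selecting reference pixels; default: all
#'   pixels with positive intensity in both channels.
#' @return the calibration factor G.
#' @export
calibrate_g <- function(ref_image, gp_ref, mask = NULL) {
  stopifnot(inherits(ref_image, "dual_channel_image"))
  if (abs(gp_ref) >= 1) stopf("gp_ref = +/-1 is degenerate; need |gp_ref| < 1")
  if (is.null(mask)) mask <- ref_image$blue > 0 & ref_image$green > 0
  if (!any(mask)) stopf("empty reference mask")
  mb <- mean(ref_image$blue[mask]); mg <- mean(ref_image$green[mask])
  if (mb <= 0 || mg <= 0) stopf("reference pixels must have positive mean intensity")
  (mb / mg) * (1 - gp_ref) / (1 + gp_ref)
}

#' Aggregate GP maps to a per-subject summary
#'
#' Pools all defined GP pixels inside cell masks across the subject's
#' images (the subject's GP index) and also emits per-cell means for
#' drill-down plus the cell-averaged alternative (`mean_gp_cellwise`).
#'
#' @param gp_maps list of [compute_gp()] maps, aligned with `masks`.
#' @param masks list of [segment_cells()] mask sets (same length/order).
#' @param subject_id,group identifiers for the summary row.
#' @return object of class `subject_summary`: `subject_id`, `group`,
#'   `mean_gp`, `sd_gp`, `mean_gp_cellwise`, `n_cells`, `n_pixels`, and
#'   `cell_means` (data.frame image, cell_id, mean_gp, n_px).
#' @export
subject_gp_summary <- function(gp_maps, masks, subject_id = "subject",
                               group = NA_character_) {
  if (length(gp_maps) != length(masks))
    stopf("gp_maps and masks must be aligned per image")
  pooled <- numeric(0)
  cell_means <- data.frame(image = integer(0), cell_id = integer(0),
                           mean_gp = numeric(0), n_px = integer(0))
  n_cells <- 0L
  for (i in seq_along(gp_maps)) {
    gp <- gp_maps[[i]]$gp
    lab <- masks[[i]]$labels
    if (!identical(dim(gp), dim(lab)))
      stopf("image %d: GP map and mask shapes differ", i)
    for (cid in seq_len(masks[[i]]$n_cells)) {
      v <- gp[lab == cid]
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      pooled <- c(pooled, v)
      n_cells <- n_cells + 1L
      cell_means <- rbind(cell_means, data.frame(
        image = i, cell_id = cid, mean_gp = mean(v), n_px = length(v)))
    }
  }
  if (length(pooled) == 0)
    stopf("subject %s: no defined GP pixels inside cell masks", subject_id)
  structure(list(subject_id = subject_id, group = group,
                 mean_gp = mean(pooled), sd_gp = sd(pooled),
                 mean_gp_cellwise = mean(cell_means$mean_gp),
                 n_cells = n_cells, n_pixels = length(pooled),
                 cell_means = cell_means),
            class = "subject_summary")
}

#' @export
print.subject_summary <- function(x, ...) {
  cat(sprintf("<subject_summary> %s (%s): GP %.4f +/- %.4f over %d cells / %d px\n",
              x$subject_id, x$group, x$mean_gp, x$sd_gp, x$n_cells, x$n_pixels))
  invisible(x)
}

#' Collect subject summaries into a data frame
#' @param summaries list of [subject_gp_summary()] objects.
#' @export
subject_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) data.frame(
    subject_id = s$subject_id, group = s$group, mean_gp = s$mean_gp,
    sd_gp = s$sd_gp, mean_gp_cellwise = s$mean_gp_cellwise,
    n_cells = s$n_cells, n_pixels = s$n_pixels)))
}
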