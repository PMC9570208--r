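#' Dual-channel Laurdan image
#'
#' Container for one registered pair of blue (ordered-phase, 450/50 nm)
#' and green (fluid-phase, 525/50 nm) emission intensity rasters, in
#' detector counts, plus the physical pixel size.
#'
#' @param blue,green numeric matrices of identical shape, finite, >= 0.
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @param meta named list of free-form metadata (subject id, group,
#'   image index, ...).
#' @return object of class `dual_channel_image`.
#' @export
dual_channel_image <- function(blue, green, pixel_size_um, meta = list()) {
  blue <- as.matrix(blue); green <- as.matrix(green)
  if (!identical(dim(blue), dim(green)))
    stopf("blue and green channels must have identical shape (%s vs %s)",
          paste(dim(blue), collapse = "x"), paste(dim(green), collapse = "x"))
  if (!all(is.finite(blue)) || !all(is.finite(green)))
    stopf("channel intensities must be finite")
  if (min(blue) < 0 || min(green) < 0)
    stopf("channel intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stopf("pixel_size_um must be a single positive number")
  structure(list(blue = blue, green = green,
                 pixel_size_um = pixel_size_um, meta = meta),
            class = "dual_channel_image")
}

#' @export
print.dual_channel_image <- function(x, ...) {
  cat(sprintf("<dual_channel_image> %d x %d px, %.3f um/px\n",
              nrow(x$blue), ncol(x$blue), x$pixel_size_um))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Run configuration for the GP pipeline
#'
#' @param G calibration factor applied to the green channel (> 0).
#' @param lc_percentile percentile of the reference GP distribution used
#'   as the LC-domain threshold, in (0, 100); default 75 (highest
#'   quartile).
#' @param min_domain_px minimum connected-component size (pixels) kept
#'   as an LC domain.
#' @param connectivity pixel connectivity for particle analysis, 4 or 8.
#' @param reference_group group whose cells form the reference GP stack.
#' @param pixel_size_um fallback pixel size when images carry no
#'   resolution tags.
#' @param seed integer seed for the seeded steps (reference-cell
#'   sampling).
#' @return object of class `run_config`.
#' @export
run_config <- function(G = 1, lc_percentile = 75, min_domain_px = 2,
                       connectivity = 8, reference_group = "DM",
                       pixel_size_um = 0.1, seed = 1L) {
  if (G <= 0) stopf("G must be positive")
  if (lc_percentile <= 0 || lc_percentile >= 100)
    stopf("lc_percentile must be in (0, 100)")
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  if (min_domain_px < 1) stopf("min_domain_px must be >= 1")
  if (pixel_size_um <= 0) stopf("pixel_size_um must be positive")
  structure(list(G = G, lc_percentile = lc_percentile,
                 min_domain_px = as.integer(min_domain_px),
                 connectivity = as.integer(connectivity),
                 reference_group = reference_group,
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "run_config")
}

#' Write/read a run configuration as JSON
#' @param config a [run_config()] object.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

# 16-bit scale used for on-disk rasters
.TIFF_MAX <- 65535

#' Read a multi-channel TIFF as a dual-channel image
#'
#' Channels are stored as TIFF pages; `channel_map` selects which page
#' is which channel (default page 1 = blue, page 2 = green). Pixel size
#' is taken from the TIFF resolution tags when present (assumed
#' pixels/cm or pixels/inch per the resolution unit tag), otherwise from
#' `pixel_size_um`. Intensities are returned in 16-bit detector counts.
#'
#' @param path TIFF file with >= 2 pages.
#' @param channel_map named integer vector with entries `blue`, `green`.
#' @param pixel_size_um fallback pixel size (micrometres) when the file
#'   carries no resolution tags.
#' @param meta metadata list attached to the image.
#' @return a [dual_channel_image()].
#' @export
read_dual_tiff <- function(path, channel_map = c(blue = 1L, green = 2L),
                           pixel_size_um = NULL, meta = list()) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stopf("cannot read TIFF %s: %s", path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < max(channel_map))
    stopf("%s has %d channel(s); need at least %d (channel_map: %s)",
          path, length(pages), max(channel_map),
          paste(names(channel_map), channel_map, sep = "=", collapse = ", "))
  px <- pixel_size_um
  xres <- attr(pages[[1]], "x.resolution")
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    unit <- attr(pages[[1]], "resolution.unit")
    cm <- if (!is.null(unit) && identical(unit, "inch")) 2.54 else 1
    px <- 1e4 * cm / xres  # pixels per cm -> um per pixel
  }
  if (is.null(px)) stopf("%s has no resolution tags and no pixel_size_um was supplied", path)
  take <- function(p) {
    m <- pages[[p]]
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # first sample of multi-sample page
    matrix(round(as.vector(m) * .TIFF_MAX), nrow(m), ncol(m))
  }
  dual_channel_image(take(channel_map[["blue"]]), take(channel_map[["green"]]),
                     pixel_size_um = px, meta = meta)
}

#' Write a dual-channel image as a 2-page 16-bit TIFF
#'
#' @param image a [dual_channel_image()].
#' @param path output path.
#' @export
write_dual_tiff <- function(image, path) {
  stopifnot(inherits(image, "dual_channel_image"))
  clip <- function(m) {
    if (max(m) > .TIFF_MAX) warnf("intensities clipped to %d for 16-bit storage", .TIFF_MAX)
    pmin(m, .TIFF_MAX) / .TIFF_MAX
  }
  tiff::writeTIFF(list(clip(image$blue), clip(image$green)), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Write/read an integer label raster as a single-page 16-bit TIFF
#' @param labels integer matrix (values 0..65535).
#' @param path file path.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > .TIFF_MAX) stopf("more than %d labels cannot be stored in 16 bit", .TIFF_MAX)
  tiff::writeTIFF(labels / .TIFF_MAX, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * .TIFF_MAX)), nrow(m), ncol(m))
}

#' Write pipeline tables to CSV (lossless round-trip)
#'
#' Writes each element of a named list of data frames to
#' `<dir>/<name>.csv` in UTF-8 with a header row; an empty data frame
#' produces a header-only file. Numeric columns round-trip exactly
#' (written with full precision).
#'
#' @param tables named list of data.frames (e.g. `domains`, `cells`,
#'   `subjects`).
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_tables <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    df <- tables[[nm]]
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back a table written by [write_tables()]
#' @param path CSV file path.
#' @export
read_table_csv <- function(path) {
  read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}
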