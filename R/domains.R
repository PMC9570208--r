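#' Build a reference GP distribution from a stack of cells
#'
#' Samples `n_cells` cells (default 20) without replacement from the
#' designated reference group's GP maps and pools their defined GP
#' pixels — the "stacked GP distribution" from which the LC-domain
#' threshold is derived.
#'
#' @param gp_maps list of [compute_gp()] maps.
#' @param masks list of [segment_cells()] mask sets, aligned with
#'   `gp_maps`.
#' @param n_cells number of reference cells to sample.
#' @param seed RNG seed for the cell draw (deterministic subset).
#' @param source_group label recorded on the distribution.
#' @return object of class `reference_distribution`: `gp_values`
#'   (pooled numeric vector), `n_cells`, `source_group`, `cells`
#'   (data.frame image, cell_id of the sampled cells).
#' @export
build_reference_distribution <- function(gp_maps, masks, n_cells = 20L,
                                         seed = 1L, source_group = "DM") {
  if (length(gp_maps) != length(masks)) stopf("gp_maps and masks must be aligned")
  univ <- do.call(rbind, lapply(seq_along(masks), function(i) {
    n <- masks[[i]]$n_cells
    if (n == 0) return(NULL)
    data.frame(image = i, cell_id = seq_len(n))
  }))
  n_avail <- if (is.null(univ)) 0L else nrow(univ)
  if (n_avail < n_cells)
    stopf("reference stack needs %d cells but only %d are available", n_cells, n_avail)
  pick <- with_seed(seed, sample.int(n_avail, n_cells))
  chosen <- univ[sort(pick), , drop = FALSE]
  vals <- unlist(lapply(seq_len(nrow(chosen)), function(k) {
    i <- chosen$image[k]; cid <- chosen$cell_id[k]
    v <- gp_maps[[i]]$gp[masks[[i]]$labels == cid]
    v[!is.na(v)]
  }))
  structure(list(gp_values = vals, n_cells = as.integer(n_cells),
                 source_group = source_group, cells = chosen),
            class = "reference_distribution")
}

#' Derive the LC-domain GP threshold from a reference distribution
#'
#' The threshold gp_star is the stated empirical percentile (linear
#' interpolation between order statistics) of the pooled reference GP
#' values; pixels with GP strictly above gp_star are considered
#' liquid-crystalline. With the default 75th percentile, LC domains are
#' the highest quartile of the reference distribution.
#'
#' @param ref a [build_reference_distribution()] object.
#' @param percentile percentile in (0, 100); default 75.
#' @return object of class `domain_threshold`: `gp_star`, `percentile`,
#'   `n_reference`, `source_group`.
#' @export
derive_threshold <- function(ref, percentile = 75) {
  stopifnot(inherits(ref, "reference_distribution"))
  if (length(ref$gp_values) == 0) stopf("empty reference distribution")
  if (percentile <= 0 || percentile >= 100) stopf("percentile must be in (0, 100)")
  gp_star <- unname(quantile(ref$gp_values, percentile / 100, type = 7))
  structure(list(gp_star = gp_star, percentile = percentile,
                 n_reference = length(ref$gp_values),
                 source_group = ref$source_group),
            class = "domain_threshold")
}

#' @export
print.domain_threshold <- function(x, ...) {
  cat(sprintf("<domain_threshold> GP* = %.4f (%gth percentile of %d %s reference px)\n",
              x$gp_star, x$percentile, x$n_reference, x$source_group))
  invisible(x)
}

#' Extract LC domains from a GP map
#'
#' Binary mask = defined pixels with GP strictly above the threshold,
#' inside cell masks; connected components at the configured
#' connectivity; components smaller than `min_px` pixels discarded
#' (single-pixel components are indistinguishable from shot noise).
#' Each domain is keyed to its parent cell. With `per_cell = TRUE` the
#' threshold percentile is re-derived from each cell's own GP
#' distribution instead of using the global gp_star.
#'
#' @param gp_map a [compute_gp()] map.
#' @param cells a [segment_cells()] mask set.
#' @param thr a [derive_threshold()] object.
#' @param min_px minimum domain size in pixels.
#' @param connectivity 4 or 8 (8 matches ImageJ particle analysis).
#' @param per_cell use a per-cell threshold at `thr$percentile`?
#' @return integer domain label raster with attributes `cell_id` (named
#'   map label -> parent cell), `gp_star`, `pixel_size_um`. An empty
#'   raster (no domains) is a legal outcome.
#' @export
extract_domains <- function(gp_map, cells, thr, min_px = 2L,
                            connectivity = 8, per_cell = FALSE) {
  stopifnot(inherits(gp_map, "gp_map"), inherits(cells, "cell_mask_set"),
            inherits(thr, "domain_threshold"))
  gp <- gp_map$gp
  lab <- cells$labels
  if (!identical(dim(gp), dim(lab))) stopf("GP map and cell mask shapes differ")
  mask <- !is.na(gp) & lab > 0
  if (per_cell) {
    bin <- matrix(FALSE, nrow(gp), ncol(gp))
    for (cid in seq_len(cells$n_cells)) {
      sel <- mask & lab == cid
      if (!any(sel)) next
      star_c <- quantile(gp[sel], thr$percentile / 100, type = 7)
      bin[sel & gp > star_c] <- TRUE
    }
  } else {
    bin <- mask & gp > thr$gp_star
  }
  dl <- label_components(bin, connectivity = connectivity)
  if (max(dl) > 0 && min_px > 1) {
    sizes <- tabulate(dl[dl > 0])
    drop <- which(sizes < min_px)
    if (length(drop)) {
      dl[dl %in% drop] <- 0L
      keep <- which(sizes >= min_px)
      relab <- integer(length(sizes)); relab[keep] <- seq_along(keep)
      dl[dl > 0] <- relab[dl[dl > 0]]
    }
  }
  labs <- seq_len(max(dl))
  cell_map <- integer(0)
  if (length(labs)) {
    cell_map <- vapply(labs, function(l) {
      cl <- lab[dl == l]
      # majority parent cell (components cannot span cells unless two
      # segmented cells touch)
      as.integer(names(which.max(table(cl))))
    }, integer(1))
    names(cell_map) <- labs
  }
  attr(dl, "cell_id") <- cell_map
  attr(dl, "gp_star") <- if (per_cell) NA_real_ else thr$gp_star
  attr(dl, "pixel_size_um") <- gp_map$pixel_size_um
  dl
}
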