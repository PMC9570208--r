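#' Place non-overlapping circular cells in a frame
#'
#' Rejection-samples cell centres until all cells fit without overlap
#' (a >= 2 px gap is enforced so neighbouring cells never touch, even
#' diagonally). Cells are filled discs by default; `annulus = TRUE`
#' renders membrane-like rims instead (outer radius minus
#' `rim_frac` fraction hollowed out).
#'
#' @param n_cells number of cells (>= 0).
#' @param image_shape c(rows, cols) of the frame in pixels.
#' @param radius_um range (min, max) of cell radii, micrometres.
#' @param pixel_size_um physical pixel size, micrometres.
#' @param seed RNG seed.
#' @param annulus render annular rims instead of filled discs.
#' @param rim_frac rim thickness as a fraction of the radius.
#' @param max_retries placement attempts per cell before giving up.
#' @return integer label raster (0 background, labels 1..n_cells) with
#'   attributes `pixel_size_um` and `cells` (data.frame: id, row, col,
#'   radius_px).
#' @export
make_cell_geometry <- function(n_cells, image_shape = c(256L, 256L),
                               radius_um = c(3.0, 3.6), pixel_size_um = 0.1,
                               seed = 1L, annulus = FALSE, rim_frac = 0.35,
                               max_retries = 2000L) {
  if (n_cells < 0) stopf("n_cells must be >= 0")
  if (any(radius_um <= 0)) stopf("radii must be positive")
  nr <- image_shape[1]; nc <- image_shape[2]
  lab <- matrix(0L, nr, nc)
  cells <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      radius_px = numeric(0))
  if (n_cells > 0) {
    r_px <- sort(radius_um, decreasing = TRUE) / pixel_size_um
    if (2 * max(r_px) + 2 > min(nr, nc))
      stopf("cannot place %d cells: a cell of radius %.1f px does not fit a %dx%d frame",
            n_cells, max(r_px), nr, nc)
    with_seed(seed, {
      radii <- runif(n_cells, min(r_px), max(r_px))
      rows <- cols <- numeric(n_cells)
      for (i in seq_len(n_cells)) {
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          r0 <- runif(1, radii[i] + 1, nr - radii[i] - 1)
          c0 <- runif(1, radii[i] + 1, nc - radii[i] - 1)
          if (i == 1 || all(sqrt((rows[seq_len(i - 1)] - r0)^2 +
                                 (cols[seq_len(i - 1)] - c0)^2) >=
                            radii[seq_len(i - 1)] + radii[i] + 2)) {
            rows[i] <- r0; cols[i] <- c0; placed <- TRUE; break
          }
        }
        if (!placed)
          stopf("cannot place %d cells of radius %.1f-%.1f um in a %dx%d frame (gave up at cell %d)",
                n_cells, min(radius_um), max(radius_um), nr, nc, i)
      }
      for (i in seq_len(n_cells)) {
        rr <- ceiling(radii[i])
        ri <- max(1L, floor(rows[i] - rr)):min(nr, ceiling(rows[i] + rr))
        ci <- max(1L, floor(cols[i] - rr)):min(nc, ceiling(cols[i] + rr))
        d2 <- outer((ri - rows[i])^2, (ci - cols[i])^2, "+")
        inside <- d2 <= radii[i]^2
        if (annulus) inside <- inside & d2 >= (radii[i] * (1 - rim_frac))^2
        lab[ri, ci][inside] <- i
      }
      cells <- data.frame(id = seq_len(n_cells), row = rows, col = cols,
                          radius_px = radii)
    })
  }
  attr(lab, "pixel_size_um") <- pixel_size_um
  attr(lab, "cells") <- cells
  lab
}

# lognormal meanlog/sdlog from mean m and sd s
.lnorm_pars <- function(m, s) {
  if (s <= 0) return(c(log(m), 0))
  sdlog2 <- log(1 + (s / m)^2)
  c(log(m) - sdlog2 / 2, sqrt(sdlog2))
}

#' Scatter LC domains inside cells
#'
#' Per cell, draws a Poisson number of elliptical LC domains with
#' lognormally distributed Feret diameter (preset mean/SD), fixed
#' elongation and random orientation, clipped to the parent cell. A
#' domain is guaranteed at least 2 rasterized pixels (sub-grid domains
#' cannot be represented). Placement rejection-samples positions so
#' domains do not touch; if no free position is found the domain is
#' placed anyway and merges with its neighbour.
#'
#' Each domain carries a radial GP profile from `gp_lc_core` (centre)
#' to `gp_lc_edge` at its nominal rim, continuing linearly into a soft
#' "skirt" out to `skirt_factor` times the nominal radius — a
#' transition zone between the ordered domain and the fluid phase.
#' The skirt is part of the GP field but not of the domain label mask,
#' so a percentile threshold derived from the pooled GP distribution
#' falls inside the rim band and cleanly separates domains from the
#' fluid phase.
#'
#' @param cell_labels cell label raster from [make_cell_geometry()].
#' @param preset a [group_preset()].
#' @param seed RNG seed.
#' @param pixel_size_um pixel size; defaults to the raster attribute.
#' @param max_retries placement attempts per domain before accepting a
#'   merge.
#' @param skirt_factor soft-rim extent as a multiple of the nominal
#'   domain radius.
#' @return integer domain label raster with attributes `cell_id` (named
#'   vector: domain label -> parent cell), `gp` (matrix of LC GP values
#'   including the soft skirt, NA elsewhere), `pixel_size_um`.
#' @export
make_domain_field <- function(cell_labels, preset, seed = 1L,
                              pixel_size_um = attr(cell_labels, "pixel_size_um"),
                              max_retries = 150L, skirt_factor = 1.15) {
  stopifnot(inherits(preset, "group_preset"))
  if (is.null(pixel_size_um)) stopf("pixel_size_um missing")
  nr <- nrow(cell_labels); nc <- ncol(cell_labels)
  dom_mask <- matrix(FALSE, nr, nc)   # nominal domain support (labels)
  skirt_mask <- matrix(FALSE, nr, nc) # support including soft rims
  gp_prof <- matrix(NA_real_, nr, nc)
  cells <- attr(cell_labels, "cells")
  cell_ids <- sort(unique(cell_labels[cell_labels > 0]))
  lp <- .lnorm_pars(preset$domain_feret_um, preset$domain_feret_sd_um)
  with_seed(seed, {
    for (cid in cell_ids) {
      in_cell <- cell_labels == cid
      cell_px <- which(in_cell, arr.ind = TRUE)
      r_cell_um <- if (!is.null(cells) && cid <= nrow(cells))
        cells$radius_px[cid] * pixel_size_um else sqrt(nrow(cell_px) / pi) * pixel_size_um
      k <- rpois(1, preset$n_domains_per_cell)
      if (k == 0) next
      # draw all Feret diameters, then place large domains first:
      # big grains are hardest to fit, so descending order minimizes
      # forced merges at high domain density
      f_hi <- 1.4 * r_cell_um
      ferets <- rlnorm(k, lp[1], lp[2])
      for (rs in 1:50) {
        over <- ferets > f_hi
        if (!any(over)) break
        ferets[over] <- rlnorm(sum(over), lp[1], lp[2])
      }
      ferets <- sort(pmin(ferets, f_hi), decreasing = TRUE)
      for (d in seq_len(k)) {
        feret <- ferets[d]
        a_px <- max(feret / (2 * pixel_size_um), 0.1)
        b_px <- a_px / preset$domain_elongation
        theta <- runif(1, 0, pi)
        ct <- cos(theta); st <- sin(theta)
        placed_px <- NULL; placed_rho <- NULL
        # candidate centres: cell pixels not yet claimed by a domain or rim
        free_px <- cell_px[!skirt_mask[cell_px], , drop = FALSE]
        if (nrow(free_px) == 0) free_px <- cell_px
        for (try in seq_len(max_retries)) {
          ctr <- free_px[sample.int(nrow(free_px), 1L), ]
          rr <- ceiling(a_px * skirt_factor) + 1L
          ri <- max(1L, ctr[1] - rr):min(nr, ctr[1] + rr)
          ci <- max(1L, ctr[2] - rr):min(nc, ctr[2] + rr)
          dy <- rep(ri - ctr[1], times = length(ci))
          dx <- rep(ci - ctr[2], each = length(ri))
          rho2 <- ((dx * ct + dy * st) / a_px)^2 + ((-dx * st + dy * ct) / b_px)^2
          sel <- rho2 <= skirt_factor^2
          px <- cbind(rep(ri, times = length(ci))[sel], rep(ci, each = length(ri))[sel])
          rho <- sqrt(rho2[sel])
          keep <- in_cell[px]
          px <- px[keep, , drop = FALSE]; rho <- rho[keep]
          if (sum(rho <= 1) < 2) {
            # guarantee a representable 2-pixel domain along the major axis
            nb <- ctr + c(round(st), round(ct))
            if (all(nb == ctr)) nb <- ctr + c(0, 1)
            nb[1] <- min(max(nb[1], 1L), nr); nb[2] <- min(max(nb[2], 1L), nc)
            px <- rbind(ctr, nb)
            rho <- c(0, 0.5)
            keep <- in_cell[px]
            px <- px[keep, , drop = FALSE]; rho <- rho[keep]
            if (nrow(px) == 0) next
          }
          # conflict if the candidate (incl. rim) or its 8-neighbourhood
          # hits an existing domain/rim of this cell
          conflict <- FALSE
          for (dr in -1:1) {
            for (dc in -1:1) {
              nbr <- cbind(pmin(pmax(px[, 1] + dr, 1L), nr),
                           pmin(pmax(px[, 2] + dc, 1L), nc))
              if (any(skirt_mask[nbr])) { conflict <- TRUE; break }
            }
            if (conflict) break
          }
          if (!conflict || try == max_retries) {
            placed_px <- px; placed_rho <- rho
            break
          }
        }
        if (!is.null(placed_px) && nrow(placed_px) > 0) {
          vals <- preset$gp_lc_core - (preset$gp_lc_core - preset$gp_lc_edge) * placed_rho
          old <- gp_prof[placed_px]
          gp_prof[placed_px] <- pmax(old, vals, na.rm = TRUE)
          skirt_mask[placed_px] <- TRUE
          core <- placed_px[placed_rho <= 1, , drop = FALSE]
          dom_mask[core] <- TRUE
        }
      }
    }
  })
  labels <- label_components(dom_mask, connectivity = 8)
  labs <- sort(unique(labels[labels > 0]))
  cell_map <- integer(0)
  if (length(labs)) {
    first_px <- which(labels > 0, arr.ind = TRUE)
    lab_at <- labels[labels > 0]
    cell_map <- vapply(labs, function(l) {
      p <- first_px[which(lab_at == l)[1], , drop = FALSE]
      cell_labels[p]
    }, integer(1))
    names(cell_map) <- labs
  }
  attr(labels, "cell_id") <- cell_map
  attr(labels, "gp") <- gp_prof
  attr(labels, "pixel_size_um") <- pixel_size_um
  labels
}

#' Ground truth for one synthetic image
#'
#' Bundles the cell labels, domain labels and the true per-pixel GP
#' field. The fluid-phase GP level is solved per cell so that the cell's
#' mean GP equals `preset$mean_gp` exactly; the subject offset
#' `gp_offset` is then added to the whole field (both phases shift
#' together), so each cell's mean is `preset$mean_gp + gp_offset`.
#'
#' @param cell_labels,domain_labels label rasters (domains inside cells).
#' @param preset a [group_preset()].
#' @param gp_offset subject-level additive GP offset.
#' @param seed seed recorded for provenance.
#' @return object of class `ground_truth` with elements `cell_labels`,
#'   `domain_labels`, `true_gp_field`, `preset`, `gp_offset`, `seed`,
#'   `pixel_size_um`.
#' @export
ground_truth <- function(cell_labels, domain_labels, preset, gp_offset = 0,
                         seed = NA_integer_) {
  if (any(domain_labels > 0 & cell_labels == 0))
    stopf("every domain pixel must lie inside a cell")
  gp_dom <- attr(domain_labels, "gp")
  if (is.null(gp_dom)) gp_dom <- matrix(NA_real_, nrow(cell_labels), ncol(cell_labels))
  gp <- matrix(NA_real_, nrow(cell_labels), ncol(cell_labels))
  target0 <- preset$mean_gp
  for (cid in sort(unique(cell_labels[cell_labels > 0]))) {
    in_cell <- cell_labels == cid
    ordered <- in_cell & !is.na(gp_dom)  # domains plus their soft rims
    n_tot <- sum(in_cell); n_ord <- sum(ordered)
    sum_ord <- if (n_ord) sum(gp_dom[ordered]) else 0
    if (n_ord == n_tot) {
      gp[in_cell] <- gp_dom[in_cell]
    } else {
      fluid <- (n_tot * target0 - sum_ord) / (n_tot - n_ord)
      fluid <- min(max(fluid, -1), preset$gp_lc_edge - 0.02)
      gp[in_cell] <- fluid
      if (n_ord) gp[ordered] <- gp_dom[ordered]
    }
  }
  gp[!is.na(gp)] <- gp[!is.na(gp)] + gp_offset
  gp[!is.na(gp)] <- pmin(pmax(gp[!is.na(gp)], -1), 1)
  structure(list(cell_labels = cell_labels, domain_labels = domain_labels,
                 true_gp_field = gp, preset = preset, gp_offset = gp_offset,
                 seed = seed,
                 pixel_size_um = attr(cell_labels, "pixel_size_um")),
            class = "ground_truth")
}

#' Render a ground-truth GP field as a dual-channel image
#'
#' Inverts the GP definition: on membrane pixels the expected blue
#' intensity is I*(1+GP)/2 and the expected green intensity is
#' I*(1-GP)/(2*G_true), so that GP computed from the noise-free image
#' with G = G_true reproduces the truth exactly. Background pixels get a
#' low dark level. With `noise = TRUE` both channels receive independent
#' Poisson (photon) noise.
#'
#' @param truth a [ground_truth()].
#' @param total_intensity expected blue + G*green photon sum per
#'   membrane pixel (detector counts).
#' @param noise apply Poisson noise?
#' @param G_true calibration factor used in the inversion.
#' @param seed RNG seed (noise).
#' @param dark_level expected background counts per channel.
#' @return a [dual_channel_image()].
#' @export
render_dual_channel <- function(truth, total_intensity = 10000, noise = TRUE,
                                G_true = 1, seed = 1L, dark_level = 10) {
  stopifnot(inherits(truth, "ground_truth"))
  if (total_intensity <= 0) stopf("total_intensity must be positive")
  if (G_true <= 0) stopf("G_true must be positive")
  gp <- truth$true_gp_field
  defined <- !is.na(gp)
  if (any(abs(gp[defined]) > 1)) stopf("|GP| > 1 in the truth field")
  blue <- matrix(dark_level, nrow(gp), ncol(gp))
  green <- matrix(dark_level, nrow(gp), ncol(gp))
  blue[defined] <- total_intensity * (1 + gp[defined]) / 2
  green[defined] <- total_intensity * (1 - gp[defined]) / (2 * G_true)
  if (noise) {
    with_seed(seed, {
      blue[] <- rpois(length(blue), blue)
      green[] <- rpois(length(green), green)
    })
  }
  dual_channel_image(blue, green, pixel_size_um = truth$pixel_size_um,
                     meta = list(group = truth$preset$group_name,
                                 gp_offset = truth$gp_offset,
                                 G_true = G_true, noise = noise))
}

#' Simulate one subject's image series
#'
#' Draws a subject-level GP offset once (Normal(0, subject_sd_gp), or
#' uses `gp_offset` when supplied) and applies it to all of the
#' subject's cells, then generates `n_images` independent fields of
#' view.
#'
#' @param preset a [group_preset()].
#' @param n_images number of images (fields of view).
#' @param seed RNG seed; the whole series is deterministic given it.
#' @param image_shape,cells_per_image,radius_um,pixel_size_um,annulus
#'   geometry settings passed to [make_cell_geometry()].
#' @param total_intensity,noise,G_true,dark_level rendering settings
#'   passed to [render_dual_channel()].
#' @param gp_offset optional fixed subject offset (bypasses the draw).
#' @param subject_id identifier stored in image metadata.
#' @return list of length `n_images`; each element is
#'   `list(image = dual_channel_image, truth = ground_truth)`.
#' @export
simulate_subject <- function(preset, n_images = 5L, seed = 1L,
                             image_shape = c(512L, 512L),
                             cells_per_image = 20L,
                             radius_um = c(3.0, 3.6), pixel_size_um = 0.1,
                             annulus = FALSE, total_intensity = 10000,
                             noise = TRUE, G_true = 1, dark_level = 10,
                             gp_offset = NULL,
                             subject_id = preset$group_name) {
  stopifnot(inherits(preset, "group_preset"))
  if (n_images == 0) return(list())
  draws <- with_seed(seed, list(
    offset = if (is.null(gp_offset)) rnorm(1, 0, preset$subject_sd_gp) else gp_offset,
    seeds = matrix(sample.int(2^30, 3L * n_images), ncol = 3L)
  ))
  lapply(seq_len(n_images), function(i) {
    cl <- make_cell_geometry(cells_per_image, image_shape, radius_um,
                             pixel_size_um, seed = draws$seeds[i, 1],
                             annulus = annulus)
    dl <- make_domain_field(cl, preset, seed = draws$seeds[i, 2])
    tr <- ground_truth(cl, dl, preset, gp_offset = draws$offset,
                       seed = draws$seeds[i, 2])
    img <- render_dual_channel(tr, total_intensity = total_intensity,
                               noise = noise, G_true = G_true,
                               seed = draws$seeds[i, 3],
                               dark_level = dark_level)
    img$meta$subject_id <- subject_id
    img$meta$image_index <- i
    list(image = img, truth = tr)
  })
}

#' Simulate a full three-group cohort
#'
#' Generates every subject of every preset group. By default the drawn
#' subject GP offsets are re-centred to mean zero within each group
#' (conditional simulation), so the simulated cohort's group mean GP
#' equals the preset target exactly while preserving the between-subject
#' spread; set `center_subject_effects = FALSE` for fully unconditional
#' draws.
#'
#' @param presets list of [group_preset()]s (default [group_presets()]).
#' @param n_images images per subject.
#' @param seed master RNG seed.
#' @param center_subject_effects centre subject GP offsets per group?
#' @param n_subjects optional named vector overriding the preset cohort
#'   sizes.
#' @param ... further arguments passed to [simulate_subject()].
#' @return list of subjects; each element has `subject_id`, `group`,
#'   `gp_offset` and `data` (the [simulate_subject()] output).
#' @export
simulate_cohort <- function(presets = group_presets(), n_images = 5L,
                            seed = 1L, center_subject_effects = TRUE,
                            n_subjects = NULL, ...) {
  out <- list()
  sd_draws <- with_seed(seed, {
    lapply(presets, function(p) {
      n <- if (!is.null(n_subjects)) n_subjects[[p$group_name]] else p$n_subjects
      off <- rnorm(n, 0, p$subject_sd_gp)
      if (center_subject_effects && n > 1) off <- off - mean(off)
      list(n = n, offsets = off, seeds = sample.int(2^30, n))
    })
  })
  for (gi in seq_along(presets)) {
    p <- presets[[gi]]
    dg <- sd_draws[[gi]]
    for (si in seq_len(dg$n)) {
      sid <- sprintf("%s_%02d", p$group_name, si)
      out[[sid]] <- list(
        subject_id = sid, group = p$group_name, gp_offset = dg$offsets[si],
        data = simulate_subject(p, n_images = n_images, seed = dg$seeds[si],
                                gp_offset = dg$offsets[si],
                                subject_id = sid, ...))
    }
  }
  class(out) <- "laurdan_cohort"
  out
}

#' Write a simulated cohort to disk
#'
#' Canonical layout: `<dir>/<subject>/<image_idx>.tif` (2-page 16-bit
#' dual-channel TIFF), `<dir>/<subject>/<image_idx>_cells.tif` and
#' `_domains.tif` (truth label rasters), plus `<dir>/subjects.csv`
#' (subject_id, group, gp_offset, pixel_size_um).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory.
#' @return invisibly, the subjects table.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  subs <- data.frame(subject_id = character(0), group = character(0),
                     gp_offset = numeric(0), pixel_size_um = numeric(0))
  for (s in cohort) {
    sd <- file.path(dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    for (i in seq_along(s$data)) {
      write_dual_tiff(s$data[[i]]$image, file.path(sd, sprintf("%d.tif", i)))
      write_label_tiff(s$data[[i]]$truth$cell_labels,
                       file.path(sd, sprintf("%d_cells.tif", i)))
      write_label_tiff(s$data[[i]]$truth$domain_labels,
                       file.path(sd, sprintf("%d_domains.tif", i)))
    }
    subs <- rbind(subs, data.frame(
      subject_id = s$subject_id, group = s$group, gp_offset = s$gp_offset,
      pixel_size_um = s$data[[1]]$image$pixel_size_um))
  }
  write.csv(subs, file.path(dir, "subjects.csv"), row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(subs)
}
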