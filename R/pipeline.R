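#' Run the full GP / LC-domain pipeline on a simulated cohort
#'
#' End-to-end analysis mirroring the imaging workflow: segment every
#' image (Otsu mode), compute GP maps, pool per-subject GP indices,
#' build the reference GP stack from the configured reference group,
#' derive the LC threshold, extract and measure LC domains on
#' `cells_per_group` cells per group, and assemble subject- and
#' cell-level tables ready for [full_report()].
#'
#' @param cohort a [simulate_cohort()] result (or any list of subjects
#'   with `subject_id`, `group` and `data` = list of
#'   `list(image, truth)` pairs; only `image` is used).
#' @param config a [run_config()].
#' @param cells_per_group number of cells per group entered into the
#'   domain morphometry (the paper-style "n = 20 RBC" unit).
#' @param ref_cells number of cells in the reference GP stack.
#' @param segment_args extra arguments passed to [segment_cells()].
#' @param verbose log per-stage timings to stderr?
#' @return list with `subjects` (per-subject GP table), `cells`
#'   (per-cell morphometry table with group), `domains` (per-domain
#'   records), `threshold` (the [derive_threshold()] object),
#'   `summaries` (subject_summary objects).
#' @export
analyze_cohort <- function(cohort, config = run_config(),
                           cells_per_group = 20L, ref_cells = 20L,
                           segment_args = list(), verbose = FALSE) {
  t0 <- Sys.time()
  stage <- function(what) if (verbose)
    message(sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"), what))
  summaries <- list()
  # per-subject segmentation + GP
  per_subject <- lapply(cohort, function(s) {
    imgs <- lapply(s$data, `[[`, "image")
    masks <- lapply(imgs, function(im)
      do.call(segment_cells, c(list(im), segment_args)))
    gps <- lapply(imgs, compute_gp, G = config$G)
    list(subject_id = s$subject_id, group = s$group, masks = masks, gps = gps)
  })
  stage("segmentation + GP maps done")
  for (ps in per_subject)
    summaries[[ps$subject_id]] <- subject_gp_summary(
      ps$gps, ps$masks, subject_id = ps$subject_id, group = ps$group)
  stage("subject GP summaries done")

  # reference stack from the configured group, pooled across its subjects
  ref_sub <- Filter(function(ps) ps$group == config$reference_group, per_subject)
  if (length(ref_sub) == 0)
    stopf("reference group '%s' not present in cohort", config$reference_group)
  ref_gps <- do.call(c, lapply(ref_sub, `[[`, "gps"))
  ref_masks <- do.call(c, lapply(ref_sub, `[[`, "masks"))
  ref <- build_reference_distribution(ref_gps, ref_masks, n_cells = ref_cells,
                                      seed = config$seed,
                                      source_group = config$reference_group)
  thr <- derive_threshold(ref, percentile = config$lc_percentile)
  stage(sprintf("reference threshold GP* = %.4f", thr$gp_star))

  # domain morphometry on cells_per_group cells per group, taken in
  # deterministic image order
  domains <- NULL
  cell_rows <- NULL
  for (grp in unique(vapply(per_subject, `[[`, character(1), "group"))) {
    gs <- Filter(function(ps) ps$group == grp, per_subject)
    n_done <- 0L
    for (ps in gs) {
      if (n_done >= cells_per_group) break
      for (i in seq_along(ps$gps)) {
        if (n_done >= cells_per_group) break
        msk <- ps$masks[[i]]
        if (msk$n_cells == 0) next
        dl <- extract_domains(ps$gps[[i]], msk, thr,
                              min_px = config$min_domain_px,
                              connectivity = config$connectivity)
        rec <- measure_domains(dl, ps$gps[[i]]$pixel_size_um)
        take <- seq_len(min(msk$n_cells, cells_per_group - n_done))
        stats <- per_cell_domain_stats(rec[rec$cell_id %in% take, , drop = FALSE],
                                       cell_ids = take)
        stats$group <- grp
        stats$subject_id <- ps$subject_id
        stats$image <- i
        cell_rows <- rbind(cell_rows, stats)
        if (nrow(rec)) {
          reck <- rec[rec$cell_id %in% take, , drop = FALSE]
          if (nrow(reck)) {
            reck$group <- grp
            reck$subject_id <- ps$subject_id
            reck$image <- i
            domains <- rbind(domains, reck)
          }
        }
        n_done <- n_done + length(take)
      }
    }
  }
  stage("domain morphometry done")
  list(subjects = subject_table(summaries), cells = cell_rows,
       domains = domains, threshold = thr, summaries = summaries)
}
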