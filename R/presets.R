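#' Group simulation presets
#'
#' Construct and validate a preset describing one study group's
#' membrane state: the target per-subject mean GP, between-subject GP
#' spread, and the LC-domain geometry (count per cell, Feret diameter
#' distribution, elongation). These values are simulation truth — the
#' generator is built to realize them — not a claim that the pipeline
#' reproduces any clinical dataset.
#'
#' GP (generalized polarization) is dimensionless in [-1, 1]; higher GP
#' means a more ordered, less fluid membrane. LC domains are the
#' high-GP phase: each domain carries a radial GP profile from
#' `gp_lc_core` at its centre to `gp_lc_edge` at its rim, and the fluid
#' phase level is solved per cell so that the cell's mean GP equals the
#' subject's target exactly.
#'
#' @param group_name group label.
#' @param mean_gp target mean GP of a subject's pooled membrane pixels.
#' @param subject_sd_gp between-subject SD of the GP offset.
#' @param n_domains_per_cell Poisson mean of the LC-domain count per cell.
#' @param domain_feret_um,domain_feret_sd_um mean and SD of the
#'   per-domain Feret diameter (lognormal), micrometres.
#' @param domain_elongation major/minor axis ratio of domain ellipses
#'   (>= 1).
#' @param mean_gp_fluid nominal fluid-phase GP (informational; the
#'   realized fluid level is solved per cell).
#' @param mean_gp_lc mean LC-phase GP, must exceed `mean_gp_fluid`.
#' @param gp_lc_core,gp_lc_edge GP at domain centre and rim.
#' @param n_subjects default cohort size for this group.
#' @return object of class `group_preset`.
#' @export
group_preset <- function(group_name, mean_gp, subject_sd_gp,
                         n_domains_per_cell, domain_feret_um,
                         domain_feret_sd_um, domain_elongation,
                         mean_gp_fluid, mean_gp_lc = (gp_lc_core + gp_lc_edge) / 2,
                         gp_lc_core = 0.72, gp_lc_edge = 0.60,
                         n_subjects = 10L) {
  gp_pars <- c(mean_gp, mean_gp_fluid, mean_gp_lc, gp_lc_core, gp_lc_edge)
  if (any(abs(gp_pars) > 1)) stopf("all GP parameters must lie in [-1, 1]")
  if (mean_gp_lc <= mean_gp_fluid)
    stopf("mean_gp_lc must exceed mean_gp_fluid (LC domains are the high-GP phase)")
  if (n_domains_per_cell < 0) stopf("n_domains_per_cell must be >= 0")
  if (domain_elongation < 1) stopf("domain_elongation must be >= 1")
  if (domain_feret_um <= 0 || domain_feret_sd_um < 0)
    stopf("domain Feret parameters must be positive")
  if (subject_sd_gp < 0) stopf("subject_sd_gp must be >= 0")
  structure(list(group_name = group_name, mean_gp = mean_gp,
                 subject_sd_gp = subject_sd_gp,
                 n_domains_per_cell = n_domains_per_cell,
                 domain_feret_um = domain_feret_um,
                 domain_feret_sd_um = domain_feret_sd_um,
                 domain_elongation = domain_elongation,
                 mean_gp_fluid = mean_gp_fluid, mean_gp_lc = mean_gp_lc,
                 gp_lc_core = gp_lc_core, gp_lc_edge = gp_lc_edge,
                 n_subjects = as.integer(n_subjects)),
            class = "group_preset")
}

#' Study-group presets: CTRL, DM, DM+PAD
#'
#' Returns the three simulation presets used as ground truth throughout
#' the package: healthy controls (CTRL), type-2 diabetes without
#' peripheral artery disease (DM), and with PAD (DM_PAD). Group mean GP,
#' between-subject SD, domains per cell, Feret diameter mean/SD and
#' cohort sizes encode the study conditions the generator emulates:
#' diabetic membranes carry many small round LC domains, controls few
#' large elongated ones, and fluidity increases (GP drops) from CTRL to
#' DM to DM_PAD.
#'
#' @return named list of three [group_preset()] objects
#'   (`CTRL`, `DM`, `DM_PAD`).
#' @export
group_presets <- function() {
  list(
    CTRL = group_preset("CTRL", mean_gp = 0.534, subject_sd_gp = 0.018,
                        n_domains_per_cell = 20.2, domain_feret_um = 1.028,
                        domain_feret_sd_um = 1.655, domain_elongation = 3.0,
                        mean_gp_fluid = 0.50, n_subjects = 10L),
    DM = group_preset("DM", mean_gp = 0.519, subject_sd_gp = 0.007,
                      n_domains_per_cell = 95.4, domain_feret_um = 0.245,
                      domain_feret_sd_um = 0.281, domain_elongation = 1.2,
                      mean_gp_fluid = 0.47, n_subjects = 12L),
    DM_PAD = group_preset("DM_PAD", mean_gp = 0.501, subject_sd_gp = 0.026,
                          n_domains_per_cell = 100.1, domain_feret_um = 0.183,
                          domain_feret_sd_um = 0.124, domain_elongation = 1.1,
                          mean_gp_fluid = 0.46, n_subjects = 15L)
  )
}
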