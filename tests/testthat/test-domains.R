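fake_map <- function(gp) structure(list(gp = gp, G = 1, pixel_size_um = 0.1),
                                   class = "gp_map")
fake_masks <- function(lab, n) structure(list(labels = lab, n_cells = n,
                                              pixel_size_um = 0.1),
                                         class = "cell_mask_set")

test_that("reference stacks conserve pixel counts and are seed-deterministic", {
  # 25 cells with 100 defined pixels each, across several images
  maps <- list(); masks <- list()
  for (i in 1:5) {
    lab <- matrix(0L, 50, 50); gp <- matrix(NA_real_, 50, 50)
    for (c in 1:5) {
      rows <- ((c - 1) * 10 + 1):((c - 1) * 10 + 10)
      lab[rows, 1:10] <- c
      gp[rows, 1:10] <- runif(100)
    }
    maps[[i]] <- fake_map(gp); masks[[i]] <- fake_masks(lab, 5L)
  }
  ref <- build_reference_distribution(maps, masks, n_cells = 20, seed = 4)
  expect_length(ref$gp_values, 2000)
  ref2 <- build_reference_distribution(maps, masks, n_cells = 20, seed = 4)
  expect_identical(ref$cells, ref2$cells)
  expect_error(build_reference_distribution(maps, masks, n_cells = 26),
               "only 25")
})

test_that("threshold is the exact percentile with at most one-pixel slack above", {
  vals <- seq(0, 1, length.out = 1001)
  ref <- structure(list(gp_values = vals, n_cells = 1L, source_group = "DM"),
                   class = "reference_distribution")
  thr <- derive_threshold(ref, 75)
  expect_identical(thr$gp_star, 0.750)
  # all-equal distribution: gp_star = c and the strict mask is empty
  refc <- structure(list(gp_values = rep(0.3, 500), n_cells = 1L,
                         source_group = "DM"),
                    class = "reference_distribution")
  thrc <- derive_threshold(refc, 75)
  expect_equal(thrc$gp_star, 0.3)
  expect_equal(sum(refc$gp_values > thrc$gp_star), 0)
  # strict-exceedance property on random reference stacks (with ties)
  set.seed(10)
  for (k in 1:50) {
    n <- sample(50:2000, 1)
    v <- round(runif(n), sample(1:3, 1))
    pct <- runif(1, 50, 95)
    t <- derive_threshold(structure(list(gp_values = v, n_cells = 1L,
                                         source_group = "DM"),
                                    class = "reference_distribution"), pct)
    expect_lte(mean(v > t$gp_star), (100 - pct) / 100 + 1 / n)
  }
  expect_error(derive_threshold(structure(list(gp_values = numeric(0),
                                               n_cells = 0L, source_group = "DM"),
                                          class = "reference_distribution")),
               "empty")
})

test_that("domain extraction honours threshold, min size and containment", {
  lab <- matrix(0L, 40, 40); lab[5:35, 5:35] <- 1L
  gp <- matrix(NA_real_, 40, 40); gp[lab == 1L] <- 0.4
  thr <- structure(list(gp_star = 0.582, percentile = 75, n_reference = 100L,
                        source_group = "DM"), class = "domain_threshold")
  cells <- fake_masks(lab, 1L)
  # constant GP below threshold: zero domains
  expect_equal(max(extract_domains(fake_map(gp), cells, thr)), 0)
  # one 5x5 high-GP square: exactly one 25-px domain
  gp2 <- gp; gp2[10:14, 10:14] <- 0.9
  dl <- extract_domains(fake_map(gp2), cells, thr, min_px = 2)
  expect_equal(max(dl), 1)
  expect_equal(sum(dl == 1), 25)
  expect_equal(unname(attr(dl, "cell_id")["1"]), 1L)
  # min_px filters small components
  gp3 <- gp; gp3[20, 20] <- 0.9
  expect_equal(max(extract_domains(fake_map(gp3), cells, thr, min_px = 2)), 0)
  expect_equal(max(extract_domains(fake_map(gp3), cells, thr, min_px = 1)), 1)
  # domain mask is always inside cell mask and defined pixels
  dl2 <- extract_domains(fake_map(gp2), cells, thr)
  expect_true(all(lab[dl2 > 0] > 0))
  expect_true(all(!is.na(gp2[dl2 > 0])))
})

test_that("noise-free generator cells yield exactly the true domain count", {
  p <- group_presets()$DM
  cl <- make_cell_geometry(3, c(256, 256), seed = 71)
  dl_true <- make_domain_field(cl, p, seed = 72)
  tr <- ground_truth(cl, dl_true, p, gp_offset = 0)
  img <- render_dual_channel(tr, noise = FALSE)
  gp <- compute_gp(img)
  cells <- fake_masks(cl, 3L)
  # gp_star placed in the rim band between fluid and domain edge values
  thr <- structure(list(gp_star = 0.59, percentile = 75, n_reference = 1L,
                        source_group = "DM"), class = "domain_threshold")
  dl <- extract_domains(gp, cells, thr, min_px = 1)
  expect_equal(max(dl), max(dl_true))
})

test_that("connectivity setting separates diagonal components", {
  lab <- matrix(0L, 20, 20); lab[2:18, 2:18] <- 1L
  gp <- matrix(NA_real_, 20, 20); gp[lab == 1L] <- 0.3
  gp[5, 5] <- 0.9; gp[6, 6] <- 0.9
  thr <- structure(list(gp_star = 0.5, percentile = 75, n_reference = 10L,
                        source_group = "DM"), class = "domain_threshold")
  cells <- fake_masks(lab, 1L)
  expect_equal(max(extract_domains(fake_map(gp), cells, thr, min_px = 1,
                                   connectivity = 8)), 1)
  expect_equal(max(extract_domains(fake_map(gp), cells, thr, min_px = 1,
                                   connectivity = 4)), 2)
})

test_that("per-cell thresholding adapts to each cell's distribution", {
  lab <- matrix(0L, 30, 60)
  lab[5:25, 5:25] <- 1L; lab[5:25, 35:55] <- 2L
  gp <- matrix(NA_real_, 30, 60)
  gp[lab == 1L] <- 0.4; gp[lab == 2L] <- 0.6
  gp[10:12, 10:12] <- 0.55   # high for cell 1, below cell 2's level
  gp[10:12, 40:42] <- 0.75
  thr <- structure(list(gp_star = 0.7, percentile = 75, n_reference = 10L,
                        source_group = "DM"), class = "domain_threshold")
  cells <- fake_masks(lab, 2L)
  glob <- extract_domains(fake_map(gp), cells, thr)
  expect_equal(max(glob), 1)  # only the 0.75 block beats the global 0.7
  pc <- extract_domains(fake_map(gp), cells, thr, per_cell = TRUE)
  expect_equal(max(pc), 2)    # each cell yields its own quartile domain
})
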