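test_that("cell geometry: empty, sized, disjoint, and infeasible cases", {
  z <- make_cell_geometry(0, c(64, 64))
  expect_true(all(z == 0))
  cl <- make_cell_geometry(3, c(256, 256), radius_um = c(3, 4),
                           pixel_size_um = 0.1, seed = 5)
  expect_equal(sort(unique(cl[cl > 0])), 1:3)
  areas <- tabulate(cl[cl > 0])
  expect_true(all(areas >= pi * 30^2 * 0.9 & areas <= pi * 40^2 * 1.1))
  # pairwise disjoint with a gap: no two labels are 8-adjacent
  for (sh in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    a <- cl[seq(1, 256 - abs(sh[1])) + max(sh[1], 0), seq(1, 256 - abs(sh[2])) + max(sh[2], 0)]
    b <- cl[seq(1, 256 - abs(sh[1])) + max(-sh[1], 0), seq(1, 256 - abs(sh[2])) + max(-sh[2], 0)]
    expect_false(any(a > 0 & b > 0 & a != b))
  }
  expect_error(make_cell_geometry(500, c(64, 64), c(3, 4), 0.1),
               "cannot place")
  expect_identical(make_cell_geometry(4, seed = 9), make_cell_geometry(4, seed = 9))
})

test_that("annulus mode hollows out the cell interior", {
  solid <- make_cell_geometry(1, c(128, 128), c(3, 3), 0.1, seed = 2)
  ring <- make_cell_geometry(1, c(128, 128), c(3, 3), 0.1, seed = 2, annulus = TRUE)
  expect_lt(sum(ring > 0), sum(solid > 0))
  expect_true(all(which(ring > 0) %in% which(solid > 0)))
})

test_that("domain field: empty preset, determinism, containment, count recovery", {
  cl <- make_cell_geometry(4, c(256, 256), seed = 3)
  p0 <- group_preset("NONE", 0.5, 0, n_domains_per_cell = 0,
                     domain_feret_um = 0.3, domain_feret_sd_um = 0,
                     domain_elongation = 1, mean_gp_fluid = 0.4)
  expect_equal(max(make_domain_field(cl, p0, seed = 1)), 0)

  p <- group_presets()$DM
  d1 <- make_domain_field(cl, p, seed = 8)
  d2 <- make_domain_field(cl, p, seed = 8)
  expect_identical(unclass(d1), unclass(d2))
  expect_true(all(cl[d1 > 0] > 0))  # domains inside cells
  # every domain lies inside exactly one cell
  cm <- attr(d1, "cell_id")
  for (l in as.integer(names(cm)))
    expect_equal(unique(cl[d1 == l]), unname(cm[as.character(l)]))
})

test_that("realized domain counts recover preset means within 15% over 20 cells", {
  ps <- group_presets()
  for (g in c("CTRL", "DM")) {
    realized <- 0; n_cells <- 0
    for (s in 1:4) {
      cl <- make_cell_geometry(5, c(256, 256), seed = 20 + s)
      dl <- make_domain_field(cl, ps[[g]], seed = 40 + s)
      realized <- realized + max(dl)
      n_cells <- n_cells + 5
    }
    expect_equal(realized / n_cells, ps[[g]]$n_domains_per_cell,
                 tolerance = 0.15)
  }
})

test_that("presets carry the study conditions and validate", {
  ps <- group_presets()
  expect_equal(ps$DM$n_domains_per_cell, 95.4)
  expect_equal(ps$CTRL$mean_gp, 0.534)
  expect_equal(ps$DM_PAD$domain_feret_um, 0.183)
  expect_equal(ps$DM$mean_gp, 0.519)
  expect_equal(ps$DM_PAD$mean_gp, 0.501)
  expect_equal(vapply(ps, `[[`, integer(1), "n_subjects"),
               c(CTRL = 10L, DM = 12L, DM_PAD = 15L))
  for (p in ps) expect_gt(p$mean_gp_lc, p$mean_gp_fluid)
  expect_error(group_preset("X", 0.5, 0.01, 10, 0.3, 0.1, 2,
                            mean_gp_fluid = 0.7, mean_gp_lc = 0.6),
               "high-GP phase")
  expect_error(group_preset("X", 1.5, 0.01, 10, 0.3, 0.1, 2,
                            mean_gp_fluid = 0.4), "GP parameters")
})

test_that("ground truth is defined exactly on cells and hits per-cell targets", {
  tr <- tiny_truth(seed = 4)
  gp <- tr$true_gp_field
  expect_true(all(is.finite(gp[tr$cell_labels > 0])))
  expect_true(all(is.na(gp[tr$cell_labels == 0])))
  expect_equal(mean(gp[tr$cell_labels == 1]), tr$preset$mean_gp, tolerance = 1e-12)
  # subject offset shifts every cell mean by the same amount
  tr2 <- ground_truth(tr$cell_labels, tr$domain_labels, tr$preset,
                      gp_offset = 0.02)
  expect_equal(mean(tr2$true_gp_field[tr$cell_labels == 1]),
               tr$preset$mean_gp + 0.02, tolerance = 1e-12)
})

test_that("rendering inverts the GP definition exactly (noise off)", {
  cl <- matrix(0L, 8, 8); cl[3:6, 3:6] <- 1L
  attr(cl, "pixel_size_um") <- 0.1
  dl <- matrix(0L, 8, 8)
  p <- group_presets()$DM
  tr <- ground_truth(cl, dl, p, gp_offset = 0)
  tr$true_gp_field[cl == 1] <- 0
  img <- render_dual_channel(tr, total_intensity = 1000, noise = FALSE, G_true = 1)
  expect_true(all(img$blue[cl == 1] == 500 & img$green[cl == 1] == 500))
  tr$true_gp_field[cl == 1] <- 0.5
  img <- render_dual_channel(tr, total_intensity = 1000, noise = FALSE, G_true = 1)
  expect_true(all(img$blue[cl == 1] == 750 & img$green[cl == 1] == 250))
  tr$true_gp_field[cl == 1] <- 1.5
  expect_error(render_dual_channel(tr, noise = FALSE), "GP")
})

test_that("noise-free render/compute round-trip is exact for any G_true", {
  tr <- tiny_truth(seed = 6)
  for (g_true in c(1, 1.3)) {
    img <- render_dual_channel(tr, noise = FALSE, G_true = g_true)
    gp <- compute_gp(img, G = g_true)
    defined <- tr$cell_labels > 0
    expect_lt(max(abs(gp$gp[defined] - tr$true_gp_field[defined])), 1e-9)
  }
})

test_that("Poisson-noise rendering recovers a cell's mean GP to 0.01", {
  tr <- tiny_truth(seed = 12)
  img <- render_dual_channel(tr, total_intensity = 10000, noise = TRUE, seed = 13)
  gp <- compute_gp(img)
  rec <- mean(gp$gp[tr$cell_labels == 1], na.rm = TRUE)
  expect_equal(rec, tr$preset$mean_gp, tolerance = 0.01 / tr$preset$mean_gp)
})

test_that("subject simulation is seed-deterministic and respects n_images", {
  expect_equal(simulate_subject(group_presets()$CTRL, n_images = 0), list())
  p <- group_presets()$CTRL
  a <- simulate_subject(p, n_images = 2, seed = 3, image_shape = c(160, 160),
                        cells_per_image = 2)
  b <- simulate_subject(p, n_images = 2, seed = 3, image_shape = c(160, 160),
                        cells_per_image = 2)
  expect_identical(a[[1]]$image$blue, b[[1]]$image$blue)
  expect_identical(a[[2]]$image$green, b[[2]]$image$green)
  expect_equal(length(a), 2)
})

test_that("default subject conditions give about 100 cells over 5 images", {
  p <- group_presets()$CTRL
  s <- simulate_subject(p, seed = 21)  # defaults: 5 images x 20 cells, 512px
  n_cells <- sum(vapply(s, function(x) max(x$truth$cell_labels), integer(1)))
  expect_equal(length(s), 5)
  expect_equal(n_cells, 100)
})

test_that("zero between-subject SD gives identical expected GP across subjects", {
  p <- group_preset("X", 0.52, subject_sd_gp = 0, n_domains_per_cell = 5,
                    domain_feret_um = 0.4, domain_feret_sd_um = 0.1,
                    domain_elongation = 1.5, mean_gp_fluid = 0.45)
  s1 <- simulate_subject(p, 1, seed = 1, image_shape = c(160, 160), cells_per_image = 2)
  s2 <- simulate_subject(p, 1, seed = 99, image_shape = c(160, 160), cells_per_image = 2)
  m1 <- mean(s1[[1]]$truth$true_gp_field[s1[[1]]$truth$cell_labels > 0])
  m2 <- mean(s2[[1]]$truth$true_gp_field[s2[[1]]$truth$cell_labels > 0])
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("cohort simulation centres subject effects per group", {
  co <- simulate_cohort(n_images = 1, seed = 5, n_subjects = c(CTRL = 3, DM = 3, DM_PAD = 3),
                        image_shape = c(160, 160), cells_per_image = 2)
  offs <- vapply(co, `[[`, numeric(1), "gp_offset")
  grp <- vapply(co, `[[`, character(1), "group")
  for (g in unique(grp)) expect_equal(mean(offs[grp == g]), 0, tolerance = 1e-12)
  co2 <- simulate_cohort(n_images = 1, seed = 5, center_subject_effects = FALSE,
                         n_subjects = c(CTRL = 3, DM = 3, DM_PAD = 3),
                         image_shape = c(160, 160), cells_per_image = 2)
  offs2 <- vapply(co2, `[[`, numeric(1), "gp_offset")
  expect_false(isTRUE(all.equal(mean(offs2[grp == "DM_PAD"]), 0)))
})
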