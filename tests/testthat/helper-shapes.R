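# Shared fixtures and independent oracles, built in code.

# Digitized disc: pixels whose centre lies within radius r of a
# (possibly sub-pixel offset) centre.
disc_matrix <- function(r, ox = 0, oy = 0) {
  n <- 2 * ceiling(r) + 7
  cc <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - cc - oy)^2 + (j - cc - ox)^2 <= r^2)
}

rect_matrix <- function(h, w, pad = 2) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# Random connected blob of <= n_px pixels (random walk growth),
# guaranteed 8-connected.
random_blob <- function(n_px, extent = 40) {
  px <- matrix(c(sample.int(extent, 1), sample.int(extent, 1)), ncol = 2)
  while (nrow(px) < n_px) {
    base <- px[sample.int(nrow(px), 1), ]
    step <- base + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    step <- pmin(pmax(step, 1L), extent)
    if (!any(px[, 1] == step[1] & px[, 2] == step[2]))
      px <- rbind(px, step)
  }
  px
}

# Brute-force Feret oracle: maximum pairwise distance over ALL boundary
# pixel corners (independent of the convex hull / calipers code path).
feret_bruteforce <- function(rows, cols) {
  x <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  y <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  sqrt(max(d2))
}

# Small noise-free single-cell ground truth for GP tests.
tiny_truth <- function(preset = group_presets()$DM, seed = 1,
                       shape = c(128L, 128L), n_cells = 1L) {
  cl <- make_cell_geometry(n_cells, shape, c(3.0, 3.3), 0.1, seed = seed)
  dl <- make_domain_field(cl, preset, seed = seed + 1)
  ground_truth(cl, dl, preset, gp_offset = 0, seed = seed)
}
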