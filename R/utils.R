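#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov chisq.test median na.omit p.adjust pf pnorm
#'   ppoints predict qnorm quantile rlnorm rnorm rpois runif sd t.test
#'   TukeyHSD var setNames
#' @importFrom utils read.csv write.csv head
#' @importFrom grDevices chull
#' @importFrom rlang .data
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Label connected components of a binary mask
#'
#' Run-based two-pass labeling with union-find. Connectivity 8 matches
#' ImageJ's Analyze Particles default (diagonal neighbours join);
#' connectivity 4 joins only edge-sharing pixels. Labels are assigned in
#' column-major scan order starting at 1.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8, got %s", connectivity)
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  m[is.na(m)] <- FALSE
  nr <- nrow(m); nc <- ncol(m)
  v <- as.vector(m)
  if (!any(v)) return(matrix(0L, nr, nc))
  # vertical runs (column-major scan lines)
  first_row <- rep(c(TRUE, rep(FALSE, nr - 1L)), nc)
  starts <- v & (first_row | !c(FALSE, v[-length(v)]))
  run <- cumsum(starts)
  run[!v] <- 0L
  R <- matrix(as.integer(run), nr, nc)
  n_run <- max(R)

  parent <- seq_len(n_run)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union_pairs <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    if (!any(keep)) return(invisible())
    ab <- unique(cbind(a[keep], b[keep]))
    for (i in seq_len(nrow(ab))) {
      ra <- find(ab[i, 1L]); rb <- find(ab[i, 2L])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  if (nc > 1L) {
    union_pairs(R[, -nc], R[, -1L])
    if (connectivity == 8L && nr > 1L) {
      union_pairs(R[-nr, -nc], R[-1L, -1L])  # down-right diagonal
      union_pairs(R[-1L, -nc], R[-nr, -1L])  # up-right diagonal
    }
  }
  root <- vapply(seq_len(n_run), find, integer(1))
  # runs are created in scan order, so unique(root) enumerates components
  # in order of first appearance
  ord <- unique(root)
  lab_of_root <- integer(n_run)
  lab_of_root[ord] <- seq_along(ord)
  out <- R
  out[R > 0L] <- lab_of_root[root[R[R > 0L]]]
  out
}

# Pixel-corner coordinates (x = column, y = row) of all pixels in `idx`
# (matrix indices). Each pixel (r, c) contributes corners
# (c - 0.5, r - 0.5) ... (c + 0.5, r + 0.5).
pixel_corners <- function(rows, cols) {
  x <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  y <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  unique(cbind(x = x, y = y))
}

# Shoelace area of a closed polygon given vertex matrix (x, y).
polygon_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Convex hull (as vertex matrix) of a point set.
convex_hull <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) <= 2) return(xy)
  xy[chull(xy[, 1], xy[, 2]), , drop = FALSE]
}
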