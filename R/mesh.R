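# Rectilinear tensor-product grid with uniform fine bands and geometric
# coarsening between/outside them. Cell-centered; a cell's material is decided
# by its center point.

# Spacings that bridge a gap, growing geometrically away from both end
# spacings up to h_max, then rescaled so they sum exactly to the gap.
geometric_fill <- function(gap, h_left, h_right, ratio = 1.4, h_max = 0.012) {
  stopifnot(gap > 0)
  if (gap <= max(h_left, h_right)) return(gap)
  ls <- c(); rs <- c()
  sl <- min(h_left, h_max); sr <- min(h_right, h_max)
  nl <- sl; nr <- sr
  while (sum(ls) + sum(rs) + nl + nr < gap) {
    if (nl <= nr) { ls <- c(ls, nl); nl <- min(nl * ratio, h_max) }
    else          { rs <- c(rs, nr); nr <- min(nr * ratio, h_max) }
  }
  s <- c(ls, nl, nr, rev(rs))
  s * (gap / sum(s))
}

# bands: data.frame(lo, hi, h) of non-overlapping uniform-spacing windows,
# clipped to [lo, hi]. Returns sorted cell-edge coordinates.
grade_axis <- function(lo, hi, bands, ratio = 1.4, h_max = 0.012) {
  stopifnot(hi > lo)
  bands <- bands[order(bands$lo), , drop = FALSE]
  bands$lo <- pmax(bands$lo, lo); bands$hi <- pmin(bands$hi, hi)
  bands <- bands[bands$hi > bands$lo, , drop = FALSE]
  if (nrow(bands) == 0) stop("no fine band intersects the axis range")
  edges <- lo
  cursor <- lo
  for (b in seq_len(nrow(bands))) {
    blo <- bands$lo[b]; bhi <- bands$hi[b]; h <- bands$h[b]
    if (blo > cursor + 1e-12) {
      h_prev <- if (b == 1) h_max else bands$h[b - 1]
      sp <- geometric_fill(blo - cursor, h_prev, h, ratio, h_max)
      edges <- c(edges, cursor + cumsum(sp))
    }
    n <- max(1L, round((bhi - blo) / h))
    edges <- c(edges, blo + (bhi - blo) * seq_len(n) / n)
    cursor <- bhi
  }
  if (hi > cursor + 1e-12) {
    sp <- geometric_fill(hi - cursor, bands$h[nrow(bands)], h_max, ratio, h_max)
    edges <- c(edges, cursor + cumsum(sp))
  }
  edges <- sort(unique(edges))
  edges[length(edges)] <- hi
  edges
}

make_grid <- function(x_edges, y_edges) {
  dx <- diff(x_edges); dy <- diff(y_edges)
  if (any(dx <= 0) || any(dy <= 0)) stop("grid edges must be increasing")
  structure(list(
    x = x_edges, y = y_edges,
    xc = x_edges[-1] - dx / 2, yc = y_edges[-1] - dy / 2,
    dx = dx, dy = dy,
    nx = length(dx), ny = length(dy)
  ), class = "rect_grid")
}

cell_areas <- function(grid) outer(grid$dx, grid$dy)

# 5-point finite-volume diffusion operator for div(coef * grad u) on the grid
# (negated, so the matrix is positive semi-definite). Face transmissibilities
# are distance-weighted harmonic means of the adjacent cell coefficients;
# outer boundaries are natural (zero normal flux).
diffusion_matrix <- function(grid, coef) {
  nx <- grid$nx; ny <- grid$ny; N <- nx * ny
  idx <- matrix(seq_len(N), nx, ny)
  gx <- sweep(2 / (sweep(1 / coef[-nx, , drop = FALSE], 1, grid$dx[-nx], "*") +
                   sweep(1 / coef[-1, , drop = FALSE], 1, grid$dx[-1], "*")),
              2, grid$dy, "*")
  gy <- sweep(2 / (sweep(1 / coef[, -ny, drop = FALSE], 2, grid$dy[-ny], "*") +
                   sweep(1 / coef[, -1, drop = FALSE], 2, grid$dy[-1], "*")),
              1, grid$dx, "*")
  i1 <- c(idx[-nx, ], idx[, -ny]); i2 <- c(idx[-1, ], idx[, -1])
  gg <- c(gx, gy)
  Matrix::sparseMatrix(
    i = c(i1, i2, i1, i2), j = c(i2, i1, i1, i2),
    x = c(-gg, -gg, gg, gg), dims = c(N, N)
  )
}
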