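# Independent brute-force conduction solver: plain-loop dense assembly of the
# same physics (harmonic-mean face conductances, Dirichlet electrode cells,
# insulating outer boundary), solved by dense LU. Kept deliberately naive and
# separate from the package's sparse path.
dense_solve_potential <- function(domain) {
  g <- domain$grid
  mats <- domain$materials
  sigma <- matrix(mats$electrical_conductivity[
    match(c("blood", "wall", "muscle", "electrode"),
          mats$label)][domain$material], g$nx, g$ny)
  N <- g$nx * g$ny
  A <- matrix(0, N, N)
  b <- numeric(N)
  k <- function(i, j) i + (j - 1) * g$nx
  for (j in seq_len(g$ny)) {
    for (i in seq_len(g$nx)) {
      kk <- k(i, j)
      if (domain$electrode_id[i, j] > 0) {
        A[kk, kk] <- 1
        b[kk] <- domain$electrode_potential[domain$electrode_id[i, j]]
        next
      }
      nb <- list()
      if (i > 1) nb <- c(nb, list(c(
        k(i - 1, j),
        g$dy[j] * 2 / (g$dx[i] / sigma[i, j] + g$dx[i - 1] / sigma[i - 1, j]))))
      if (i < g$nx) nb <- c(nb, list(c(
        k(i + 1, j),
        g$dy[j] * 2 / (g$dx[i] / sigma[i, j] + g$dx[i + 1] / sigma[i + 1, j]))))
      if (j > 1) nb <- c(nb, list(c(
        k(i, j - 1),
        g$dx[i] * 2 / (g$dy[j] / sigma[i, j] + g$dy[j - 1] / sigma[i, j - 1]))))
      if (j < g$ny) nb <- c(nb, list(c(
        k(i, j + 1),
        g$dx[i] * 2 / (g$dy[j] / sigma[i, j] + g$dy[j + 1] / sigma[i, j + 1]))))
      for (e in nb) {
        A[kk, e[1]] <- A[kk, e[1]] - e[2]
        A[kk, kk] <- A[kk, kk] + e[2]
      }
    }
  }
  matrix(solve(A, b), g$nx, g$ny)
}

# small, fast geometry for unit tests: same vessel, much smaller muscle box
small_geometry <- function() {
  aorta_geometry(vessel_length = 0.12, muscle_width = 0.16,
                 muscle_height = 0.08)
}

# insulated homogeneous muscle box for energy-bookkeeping checks
fixture_domain_box <- function(n = 10, h = 1e-3) {
  arteryfield:::fixture_domain(n, n, h, h, label = "muscle")
}

# tiny model whose full grid stays under ~2500 cells for the dense oracle
tiny_model <- function(spacing = 5e-4) {
  geo <- aorta_geometry(vessel_length = 0.024, muscle_width = 0.03,
                        muscle_height = 0.024)
  build_model(geo, electrode_configuration(1, 2, spacing = 0.005),
              grid_spacing = spacing, h_max = 0.002)
}
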