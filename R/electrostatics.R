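#' Assemble the conduction linear system
#'
#' Discretizes the electro-quasistatic conduction equation
#' \eqn{\nabla\cdot(\sigma\nabla\phi)=0} with a 5-point finite-volume stencil
#' on the rectilinear grid. Face conductances use the distance-weighted
#' harmonic mean of the adjacent cell conductivities, which reproduces the
#' series-resistor composition exactly at material interfaces. Electrode
#' cells are Dirichlet (fixed potential); the outer boundary is insulating
#' (zero normal current density, a natural boundary of the finite-volume
#' scheme). For a 10 ms pulse the charge relaxation time of the tissues
#' (epsilon/sigma, of order microseconds) is negligible, so the resistive
#' stationary solution describes the pulse plateau and permittivity is
#' unused.
#'
#' @param domain a \code{domain_model} with electrodes placed.
#' @return an object of class \code{conduction_system} holding the sparse
#'   symmetric positive-definite system reduced to the non-electrode cells.
#' @export
assemble_system <- function(domain) {
  g <- domain$grid
  sigma <- property_map(domain, "electrical_conductivity")
  if (any(sigma <= 0)) stop("all conductivities must be positive")
  if (!any(domain$electrode_id != 0L))
    stop("singular-system error: no electrode present, potential is floating")

  N <- g$nx * g$ny
  L <- diffusion_matrix(g, sigma)

  dir <- which(domain$electrode_id != 0L)
  phi_d <- domain$electrode_potential[domain$electrode_id[dir]]
  free <- setdiff(seq_len(N), dir)
  A <- Matrix::forceSymmetric(L[free, free, drop = FALSE])
  b <- as.numeric(-L[free, dir, drop = FALSE] %*% phi_d)

  structure(list(A = A, b = b, free = free, dirichlet = dir,
                 phi_dirichlet = phi_d, L = L, domain = domain,
                 sigma = sigma),
            class = "conduction_system")
}

#' Solve for the electric potential
#'
#' Sparse Cholesky factorization of the reduced SPD system (the structured
#' grid analogue of the direct solver used for the original unstructured
#' model). The solution satisfies the discrete maximum principle: the
#' potential everywhere lies between the smallest and largest electrode
#' potential, and is exactly linear in the pulse potential.
#'
#' @param system a \code{conduction_system} from \code{\link{assemble_system}}.
#' @param rtol relative residual tolerance for the sanity check.
#' @return an object of class \code{field_solution} with the potential on the
#'   full grid (V); apply \code{\link{compute_field}} to fill field
#'   magnitude and current density.
#' @export
solve_potential <- function(system, rtol = 1e-10) {
  phi_f <- tryCatch(
    as.numeric(Matrix::solve(system$A, system$b)),
    error = function(e) stop("numerical error in sparse solve: ",
                             conditionMessage(e))
  )
  bn <- sqrt(sum(system$b^2))
  if (bn > 0) {
    res <- sqrt(sum((as.numeric(system$A %*% phi_f) - system$b)^2)) / bn
    if (!is.finite(res) || res > rtol)
      stop("numerical error: relative residual ", format(res),
           " exceeds ", rtol)
  }
  dom <- system$domain
  N <- dom$grid$nx * dom$grid$ny
  phi <- numeric(N)
  phi[system$free] <- phi_f
  phi[system$dirichlet] <- system$phi_dirichlet
  structure(list(
    potential = matrix(phi, dom$grid$nx, dom$grid$ny),
    domain = dom,
    pulse_potential = if (!is.null(dom$configuration))
      dom$configuration$pulse_potential else max(dom$electrode_potential),
    system = system
  ), class = "field_solution")
}

#' Derive electric-field magnitude and current density
#'
#' The field is evaluated from face current fluxes: on each interior face the
#' normal field is the face current density divided by the face (harmonic
#' mean) conductivity, and a cell's field component is the mean of its two
#' face values. Insulating boundary faces carry zero normal field. This
#' face-based evaluation keeps the normal field consistent with current
#' continuity across material interfaces (blood/wall/muscle), where the raw
#' potential gradient jumps.
#'
#' @param solution a \code{field_solution} from \code{\link{solve_potential}}.
#' @return the solution with \code{field_magnitude} (V/m) and
#'   \code{current_density} (A/m^2) matrices filled.
#' @export
compute_field <- function(solution) {
  dom <- solution$domain
  g <- dom$grid
  phi <- solution$potential
  sigma <- solution$system$sigma
  nx <- g$nx; ny <- g$ny

  # face fields: E_face = (phi1 - phi2) / center distance * sigma_mean/sigma_face
  # expressed via flux: J_face = g_face * dphi / face_length; E = J / sigma_face
  dcx <- (g$dx[-nx] + g$dx[-1]) / 2
  sfx <- sweep(1 / (sweep(1 / sigma[-nx, , drop = FALSE], 1, g$dx[-nx], "*") +
                    sweep(1 / sigma[-1, , drop = FALSE], 1, g$dx[-1], "*")),
               1, g$dx[-nx] + g$dx[-1], "*")
  Efx <- sweep(phi[-nx, , drop = FALSE] - phi[-1, , drop = FALSE], 1, dcx, "/")
  dcy <- (g$dy[-ny] + g$dy[-1]) / 2
  sfy <- sweep(1 / (sweep(1 / sigma[, -ny, drop = FALSE], 2, g$dy[-ny], "*") +
                    sweep(1 / sigma[, -1, drop = FALSE], 2, g$dy[-1], "*")),
               2, g$dy[-ny] + g$dy[-1], "*")
  Efy <- sweep(phi[, -ny, drop = FALSE] - phi[, -1, drop = FALSE], 2, dcy, "/")

  # continuity-consistent normal field in each adjacent cell: J_face / sigma_cell
  Jfx <- sfx * Efx
  Jfy <- sfy * Efy
  zx <- matrix(0, 1, ny); zy <- matrix(0, nx, 1)
  Ex <- (cbind2m(zx, Jfx) + cbind2m(Jfx, zx)) / (2 * sigma) *
    boundary_face_weight(nx, ny, "x")
  Ey <- (rbind2m(zy, Jfy) + rbind2m(Jfy, zy)) / (2 * sigma) *
    boundary_face_weight(nx, ny, "y")

  solution$field_magnitude <- sqrt(Ex^2 + Ey^2)
  solution$current_density <- sigma * solution$field_magnitude
  solution$Ex <- Ex
  solution$Ey <- Ey
  solution
}

# stack face arrays back to cell shape (rows = x index, cols = y index)
cbind2m <- function(a, b) rbind(a, b) # along x
rbind2m <- function(a, b) cbind(a, b) # along y

# cells on an insulating boundary have one zero face; average over the single
# interior face instead of halving it
boundary_face_weight <- function(nx, ny, dir) {
  w <- matrix(1, nx, ny)
  if (dir == "x") w[c(1, nx), ] <- 2 else w[, c(1, ny)] <- 2
  w
}

#' Solve the full conduction problem in one call
#'
#' @param domain a \code{domain_model} with electrodes placed.
#' @return a \code{field_solution} with potential, field magnitude and
#'   current density.
#' @export
#' @examples
#' dom <- build_model(aorta_geometry(), electrode_configuration(1, 2, 0.019),
#'                    grid_spacing = 5e-4)
#' sol <- solve_field(dom)
#' max(sol$field_magnitude)
solve_field <- function(domain) {
  compute_field(solve_potential(assemble_system(domain)))
}

#' Net current delivered by each electrode
#'
#' Sums the face currents leaving every electrode's footprint. Charge
#' conservation requires the current leaving the active electrodes to match
#' the current entering the returns.
#'
#' @param solution a \code{field_solution}.
#' @return a numeric vector, one signed current (A per unit depth) per
#'   electrode, positive for net outflow.
#' @export
electrode_currents <- function(solution) {
  dom <- solution$domain
  sys <- solution$system
  phi <- as.numeric(solution$potential)
  # row sums of the full Laplacian restricted to each electrode's cells give
  # the net current injected there
  inj <- as.numeric(sys$L %*% phi)
  ids <- dom$electrode_id
  vapply(seq_along(dom$electrode_potential),
         function(k) sum(inj[which(ids == k)]), numeric(1))
}

#' @export
print.field_solution <- function(x, ...) {
  cat("<field_solution> Vp = ", x$pulse_potential, " V, grid ",
      x$domain$grid$nx, "x", x$domain$grid$ny, "\n", sep = "")
  if (!is.null(x$field_magnitude))
    cat("  |E| range: ", format(min(x$field_magnitude), digits = 4), " - ",
        format(max(x$field_magnitude), digits = 4), " V/m\n", sep = "")
  invisible(x)
}
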