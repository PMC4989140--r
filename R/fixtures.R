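# Analytic verification fixtures: every expected value here is a closed form,
# computable without running the main solvers.

# minimal single-material rectangular domain for fixtures (no vessel)
fixture_domain <- function(nx, ny, hx, hy, label = "muscle",
                           materials = material_table()) {
  code <- match(label, c("blood", "wall", "muscle", "electrode"))
  if (is.na(code)) stop("unknown material label: ", label)
  grid <- make_grid(hx * 0:nx, hy * 0:ny)
  structure(list(
    grid = grid, geometry = NULL, material = matrix(code, nx, ny),
    materials = materials,
    electrode_id = matrix(0L, nx, ny), electrode_potential = numeric(0),
    electrode_active = logical(0), configuration = NULL, grid_spacing = hx
  ), class = "domain_model")
}

#' Parallel-plate capacitor fixture
#'
#' Uniform conductor between two full-width plates: the exact field is
#' \code{Vp / gap}, uniform, independent of the conductivity. The plates are
#' single cell rows at the top and bottom of the grid; \code{gap} is the
#' separation between the plate inner surfaces. Plate conductivity is set 10
#' orders of magnitude above the medium so the plate cells are equipotential
#' and the closed form holds to rounding error.
#'
#' @param gap plate separation, m.
#' @param Vp plate potential difference, V.
#' @param sigma medium conductivity, S/m.
#' @param n number of interior cell rows across the gap.
#' @param nx number of cell columns.
#' @return a \code{fixture_case}: \code{domain} ready to solve,
#'   \code{expected} field magnitude (V/m), \code{tol} relative tolerance.
#' @export
#' @examples
#' fx <- make_parallel_plate(0.01, 40)
#' fx$expected  # 4000 V/m
make_parallel_plate <- function(gap, Vp = 40, sigma = 1, n = 20, nx = 8) {
  stopifnot(gap > 0)
  h <- gap / n
  mat <- material_table(list(
    muscle = list(electrical_conductivity = sigma),
    electrode = list(electrical_conductivity = sigma * 1e10)))
  dom <- fixture_domain(nx, n + 2, hx = h, hy = h, label = "muscle",
                        materials = mat)
  W <- nx * h
  dom <- stamp_electrode(dom, 0, xlim = c(0, W), ylim = c(0, h))
  dom <- stamp_electrode(dom, Vp, xlim = c(0, W), ylim = c((n + 1) * h,
                                                           (n + 2) * h))
  structure(list(name = "parallel_plate", domain = dom,
                 expected = Vp / gap, tol = 1e-8),
            class = "fixture_case")
}

#' Two-layer slab fixture
#'
#' Two conductivities in series between parallel plates. Current continuity
#' fixes the layer fields: \eqn{J = V_p / (L_1/\sigma_1 + L_2/\sigma_2)},
#' \eqn{E_i = J / \sigma_i}, so the field ratio is \eqn{\sigma_2/\sigma_1}.
#' The layer interface falls exactly on a cell face, where the harmonic-mean
#' face conductance reproduces the series-resistor composition.
#'
#' @param gap separation between the plate inner surfaces, m (split equally
#'   between the two layers).
#' @param Vp plate potential difference, V.
#' @param sigma1,sigma2 lower and upper layer conductivities, S/m.
#' @param n interior cell rows per layer.
#' @return a \code{fixture_case} with \code{expected} a list
#'   (\code{E1}, \code{E2}, \code{J}).
#' @export
make_layered_slab <- function(gap, Vp = 40, sigma1 = 1, sigma2 = 4, n = 10) {
  stopifnot(gap > 0)
  h <- gap / (2 * n)
  mat <- material_table(list(
    blood = list(electrical_conductivity = sigma1),
    muscle = list(electrical_conductivity = sigma2),
    electrode = list(electrical_conductivity = max(sigma1, sigma2) * 1e10)))
  nx <- 6
  dom <- fixture_domain(nx, 2 * n + 2, hx = h, hy = h, label = "muscle",
                        materials = mat)
  dom$material[, 2:(n + 1)] <- 1L  # lower layer
  W <- nx * h
  dom <- stamp_electrode(dom, 0, xlim = c(0, W), ylim = c(0, h))
  dom <- stamp_electrode(dom, Vp, xlim = c(0, W),
                         ylim = c((2 * n + 1) * h, (2 * n + 2) * h))
  L1 <- n * h; L2 <- n * h
  J <- Vp / (L1 / sigma1 + L2 / sigma2)
  structure(list(name = "layered_slab", domain = dom,
                 expected = list(E1 = J / sigma1, E2 = J / sigma2, J = J),
                 layer_rows = list(lower = 3:n, upper = (n + 3):(2 * n)),
                 tol = 1e-8),
            class = "fixture_case")
}

#' Lumped (single-cell) Pennes fixture
#'
#' One perfused cell with a constant volumetric source has the closed-form
#' rise \eqn{\theta(t) = \theta_\infty (1 - e^{-t/\tau})} with
#' \eqn{\theta_\infty = p / (w_b c_b \rho_b)} and
#' \eqn{\tau = \rho c_p / (w_b c_b \rho_b)}; with no perfusion the rise is
#' the linear ramp \eqn{p t / (\rho c_p)}.
#'
#' @param p volumetric source, W/m^3.
#' @param perfusion_factor multiplier on the baseline blood perfusion.
#' @param size cell edge length, m.
#' @return a \code{fixture_case} with a \code{closed_form(t)} function for
#'   the exact temperature rise (K).
#' @export
make_lumped_thermal <- function(p, perfusion_factor = 1, size = 0.001) {
  stopifnot(p >= 0)
  dom <- fixture_domain(1, 1, size, size, label = "blood")
  blood <- material_lookup("blood", perfusion_factor)
  a <- blood$perfusion_rate * blood$heat_capacity * blood$density  # W/(m^3 K)
  rc <- blood$density * blood$heat_capacity
  closed_form <- if (a > 0) {
    function(t) (p / a) * (1 - exp(-t * a / rc))
  } else {
    function(t) p * t / rc
  }
  structure(list(name = "lumped_thermal", domain = dom, p = p,
                 perfusion_factor = perfusion_factor,
                 sink_coefficient = a, heat_capacity_volumetric = rc,
                 closed_form = closed_form, tol = 0.01),
            class = "fixture_case")
}

#' Canned study configurations
#'
#' The nine electrode configurations at their tabulated optimal spacings
#' (schemes 1-3, each with one to four endovascular electrodes) and the nine
#' thermal scenarios (pulse repetition rates 1, 10 and 50 Hz crossed with
#' perfusion factors 1, 0.1 and 0.01) used throughout the study.
#'
#' @param pulse_potential Vp, V.
#' @return a list with components \code{electrostatic} (9 entries:
#'   \code{configuration}, \code{distance}) and \code{thermal} (9 entries:
#'   \code{pulse}, \code{perfusion_factor}), each thermal entry using the
#'   optimal 4-electrode scheme-1 configuration at 13 mm.
#' @export
paper_configs <- function(pulse_potential = 40) {
  specs <- list(
    list(scheme = 1, n = 2, d = 0.025),
    list(scheme = 1, n = 3, d = 0.017),
    list(scheme = 1, n = 4, d = 0.013),
    list(scheme = 2, n = 1, d = NA_real_),
    list(scheme = 2, n = 2, d = 0.035),
    list(scheme = 2, n = 3, d = 0.0145),
    list(scheme = 3, n = 1, d = NA_real_),
    list(scheme = 3, n = 2, d = 0.020),
    list(scheme = 3, n = 3, d = 0.010)
  )
  electrostatic <- lapply(specs, function(s) {
    list(configuration = electrode_configuration(
      s$scheme, s$n, spacing = if (is.na(s$d)) NULL else s$d,
      pulse_potential = pulse_potential),
      distance = s$d)
  })
  grid <- expand.grid(rate = c(1, 10, 50), perfusion = c(1, 0.1, 0.01))
  thermal <- lapply(seq_len(nrow(grid)), function(i) {
    list(pulse = pulse_train(amplitude = pulse_potential,
                             repetition_rate = grid$rate[i]),
         perfusion_factor = grid$perfusion[i],
         configuration = electrode_configuration(
           1, 4, spacing = 0.013, pulse_potential = pulse_potential))
  })
  list(electrostatic = electrostatic, thermal = thermal)
}
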