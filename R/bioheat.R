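#' Stimulation pulse train
#'
#' @param amplitude pulse potential, V.
#' @param pulse_duration single pulse length, s.
#' @param repetition_rate pulses per second, Hz.
#' @param session_duration total stimulation time, s.
#' @return an object of class \code{pulse_train}. The duty cycle
#'   (\code{pulse_duration * repetition_rate}) must not exceed 1.
#' @export
#' @examples
#' pulse_train(repetition_rate = 50)$duty_cycle  # 0.5
pulse_train <- function(amplitude = 40, pulse_duration = 0.010,
                        repetition_rate = 1, session_duration = 40) {
  stopifnot(amplitude > 0, pulse_duration > 0, repetition_rate > 0,
            session_duration > 0)
  duty <- pulse_duration * repetition_rate
  if (duty > 1 + 1e-12)
    stop("duty cycle ", duty, " exceeds 1: pulses overlap")
  structure(list(amplitude = amplitude, pulse_duration = pulse_duration,
                 repetition_rate = repetition_rate,
                 session_duration = session_duration, duty_cycle = duty),
            class = "pulse_train")
}

#' Joule heating source of a solved field
#'
#' Volumetric power deposited by the conduction current,
#' \eqn{p = \sigma |E|^2}. Electrode cells use the steel conductivity, but
#' the field inside a near-perfect conductor is essentially zero so their
#' contribution is negligible.
#'
#' @param solution a \code{field_solution} with the field computed.
#' @return matrix of volumetric power, W/m^3 per cell.
#' @export
joule_source <- function(solution) {
  if (is.null(solution$field_magnitude))
    solution <- compute_field(solution)
  sigma <- solution$system$sigma
  sigma * solution$field_magnitude^2
}

#' Transient Pennes bioheat operator
#'
#' Prepares the spatial operators for
#' \eqn{\rho c_p \partial T/\partial t = \nabla\cdot(k \nabla T) +
#' w_b c_b \rho_b (T_a - T) + q''' + p}
#' on the domain grid, with zero-total-heat-flux outer boundaries (the body
#' interior is at steady state). The equation is advanced for the
#' temperature rise above the equilibrated 310.15 K baseline: by linearity
#' the baseline terms (metabolic heat, arterial temperature) cancel and the
#' rise responds to the Joule source alone. The perfusion heat sink acts in
#' the lumen blood only, using blood density and heat capacity, scaled by
#' the perfusion factor.
#'
#' @param domain a \code{domain_model}.
#' @param perfusion_factor multiplier on the baseline perfusion rate
#'   (1, 0.1, 0.01 for a normal to almost fully constricted vessel).
#' @param include_metabolic if TRUE, the metabolic heat of the material
#'   table is added as a persistent source instead of being absorbed into
#'   the baseline (useful for studying the unequilibrated problem).
#' @return an object of class \code{bioheat_operator} with a factorization
#'   cache so repeated steps at the same dt cost one triangular solve.
#' @export
bioheat_operator <- function(domain, perfusion_factor = 1,
                             include_metabolic = FALSE) {
  g <- domain$grid
  areas <- cell_areas(g)
  rho <- property_map(domain, "density")
  cp <- property_map(domain, "heat_capacity")
  k <- property_map(domain, "thermal_conductivity")
  wb <- property_map(domain, "perfusion_rate") * perfusion_factor
  blood <- material_lookup("blood", materials = domain$materials)
  M <- as.numeric(rho * cp * areas)                       # J/K per cell
  P <- as.numeric(wb * blood$heat_capacity * blood$density * areas)  # W/K
  q <- if (include_metabolic)
    as.numeric(property_map(domain, "metabolic_heat") * areas) else 0
  K <- diffusion_matrix(g, k)
  structure(list(M = M, P = P, K = K, q = q, domain = domain,
                 perfusion_factor = perfusion_factor,
                 cache = new.env(parent = emptyenv())),
            class = "bioheat_operator")
}

bioheat_factor <- function(op, dt) {
  key <- format(dt, digits = 17)
  if (is.null(op$cache[[key]])) {
    A <- op$K + Matrix::Diagonal(x = op$M / dt + op$P)
    op$cache[[key]] <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  }
  op$cache[[key]]
}

#' Advance the bioheat equation one implicit step
#'
#' Backward-Euler step, unconditionally stable for any dt.
#'
#' @param op a \code{\link{bioheat_operator}}.
#' @param theta temperature-rise vector (K per cell, length nx*ny).
#' @param dt time step, s.
#' @param source volumetric Joule power matrix or vector (W/m^3 per cell),
#'   or NULL for no source.
#' @param source_on logical gate on the source (pulse on/off).
#' @return the new temperature-rise vector.
#' @export
step_bioheat <- function(op, theta, dt, source = NULL, source_on = TRUE) {
  if (dt <= 0) stop("time-step error: dt must be positive")
  rhs <- op$M * theta / dt + op$q
  if (!is.null(source) && source_on) {
    rhs <- rhs + as.numeric(source) * as.numeric(cell_areas(op$domain$grid))
  }
  out <- as.numeric(Matrix::solve(bioheat_factor(op, dt), rhs,
                                  system = "A"))
  if (any(!is.finite(out)))
    stop("time-step error: non-physical temperature produced")
  out
}

#' Run a full pulsed stimulation session
#'
#' Alternates heated intervals (pulse on, fine time step) and cooling
#' intervals (pulse off, coarser step) for the whole session, tracking the
#' hottest point of the upper-wall ROI at every step. The conduction field
#' is solved once and its Joule source reused for every pulse
#' (temperature-independent conductivities; one-way electro-thermal
#' coupling).
#'
#' @param domain a \code{domain_model} with electrodes placed.
#' @param pulse a \code{\link{pulse_train}}.
#' @param perfusion_factor multiplier on the baseline lumen perfusion.
#' @param solution optional pre-computed \code{field_solution} for the
#'   domain (solved internally when NULL). Its pulse potential should match
#'   \code{pulse$amplitude}; the Joule source is rescaled by
#'   \code{(amplitude / pulse_potential)^2} otherwise.
#' @param dt_on time step during pulses, s.
#' @param dt_off maximum time step between pulses, s.
#' @param ... ROI parameters passed to \code{\link{wall_roi}}.
#' @return an object of class \code{thermal_result}:
#'   \code{temperature_history} (data.frame time_s, T_K of the hottest wall
#'   cell), \code{max_wall_rise} (K), \code{final_temperature_map} (K),
#'   \code{perfusion_factor}, \code{baseline} (310.15 K).
#' @export
run_session <- function(domain, pulse, perfusion_factor = 1,
                        solution = NULL, dt_on = 1e-3, dt_off = 1e-2, ...) {
  if (is.null(solution)) solution <- solve_field(domain)
  p <- joule_source(solution)
  if (!isTRUE(all.equal(pulse$amplitude, solution$pulse_potential)))
    p <- p * (pulse$amplitude / solution$pulse_potential)^2
  src <- as.numeric(p) * as.numeric(cell_areas(domain$grid))

  op <- bioheat_operator(domain, perfusion_factor)
  wall <- which(wall_roi(domain, ...))
  period <- 1 / pulse$repetition_rate
  n_periods <- floor(pulse$session_duration / period + 1e-9)
  n_on <- max(1L, round(pulse$pulse_duration / dt_on))
  dt1 <- pulse$pulse_duration / n_on
  t_off <- period - pulse$pulse_duration
  n_off <- if (t_off > 1e-12) max(1L, ceiling(t_off / dt_off)) else 0L
  dt2 <- if (n_off > 0) t_off / n_off else 0

  f_on <- bioheat_factor(op, dt1)
  f_off <- if (n_off > 0) bioheat_factor(op, dt2) else NULL
  areas_src_on <- src  # W per unit depth per cell while the pulse is on

  N <- length(op$M)
  theta <- numeric(N)
  nstep <- n_periods * (n_on + n_off)
  times <- numeric(nstep); probe <- numeric(nstep)
  s <- 0L; t <- 0
  Mon <- op$M / dt1; Moff <- if (n_off > 0) op$M / dt2 else NULL
  for (per in seq_len(n_periods)) {
    for (i in seq_len(n_on)) {
      theta <- as.numeric(Matrix::solve(f_on, Mon * theta + areas_src_on,
                                        system = "A"))
      s <- s + 1L; t <- t + dt1
      times[s] <- t; probe[s] <- max(theta[wall])
    }
    if (n_off > 0) for (i in seq_len(n_off)) {
      theta <- as.numeric(Matrix::solve(f_off, Moff * theta, system = "A"))
      s <- s + 1L; t <- t + dt2
      times[s] <- t; probe[s] <- max(theta[wall])
    }
  }
  if (any(!is.finite(theta)))
    stop("time-step error: non-physical temperature produced")
  baseline <- 310.15
  structure(list(
    temperature_history = data.frame(time_s = times, T_K = baseline + probe),
    max_wall_rise = max(probe),
    final_temperature_map = matrix(baseline + theta,
                                   domain$grid$nx, domain$grid$ny),
    perfusion_factor = perfusion_factor,
    pulse = pulse,
    baseline = baseline
  ), class = "thermal_result")
}

#' @export
print.thermal_result <- function(x, ...) {
  cat(sprintf(
    "<thermal_result> %g s at %g Hz, perfusion x%g: max wall rise %.3f K\n",
    x$pulse$session_duration, x$pulse$repetition_rate, x$perfusion_factor,
    x$max_wall_rise))
  invisible(x)
}
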