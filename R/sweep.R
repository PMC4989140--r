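#' Sweep inter-electrode distance for one configuration
#'
#' Runs one full conduction solve plus wall metrics per candidate distance.
#' Geometrically infeasible distances (electrode group longer than the
#' vessel) are skipped with a warning. The whole pipeline is deterministic:
#' re-running with the same inputs is bit-identical.
#'
#' @param scheme 1, 2 or 3 (see \code{\link{electrode_configuration}}).
#' @param n_electrodes endovascular electrode count.
#' @param distances candidate center-to-center distances, m; default
#'   1-50 mm in 1 mm steps, a grid wide enough to contain every scheme's
#'   optimum.
#' @param pulse_potential Vp, V.
#' @param geometry an \code{\link{aorta_geometry}}.
#' @param grid_spacing fine cell size, m.
#' @param ... further arguments to \code{\link{build_domain}}.
#' @return an object of class \code{sweep_result}: a data.frame with one row
#'   per solved distance (columns \code{distance}, \code{mean_field},
#'   \code{normalized_std}, \code{localization_value}) plus attributes
#'   recording the configuration.
#' @export
run_sweep <- function(scheme, n_electrodes, distances = seq(0.001, 0.05, 0.001),
                      pulse_potential = 40, geometry = aorta_geometry(),
                      grid_spacing = 2.5e-4, ...) {
  if (length(distances) == 0) stop("empty distance grid")
  if (is.unsorted(distances, strictly = TRUE))
    stop("distances must be strictly increasing")
  if (n_electrodes == 1 && scheme != 1) distances <- distances[1]
  rows <- vector("list", length(distances))
  for (k in seq_along(distances)) {
    d <- distances[k]
    cfg <- tryCatch(
      electrode_configuration(scheme, n_electrodes, spacing = d,
                              pulse_potential = pulse_potential),
      error = function(e) e)
    if (inherits(cfg, "error")) {
      warning("distance ", d * 1e3, " mm skipped: ", conditionMessage(cfg))
      next
    }
    dom <- tryCatch(build_model(geometry, cfg, grid_spacing, ...),
                    error = function(e) e)
    if (inherits(dom, "error")) {
      warning("distance ", d * 1e3, " mm skipped: ", conditionMessage(dom))
      next
    }
    m <- wall_metrics(solve_field(dom))
    rows[[k]] <- data.frame(distance = d, mean_field = m$mean_field,
                            normalized_std = m$normalized_std,
                            localization_value = m$localization_value)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0)
    stop("no feasible distance in the sweep")
  structure(out, class = c("sweep_result", "data.frame"),
            scheme = scheme, n_electrodes = n_electrodes,
            pulse_potential = pulse_potential)
}

#' Locate the optimal distance in a sweep
#'
#' @param sweep a \code{sweep_result}.
#' @param criterion \code{"field"} (maximize mean field), \code{"std"}
#'   (minimize normalized STD) or \code{"lv"} (maximize localization value).
#' @return the optimal distance, m; ties break toward the smaller distance.
#' @export
find_optimum <- function(sweep, criterion = c("field", "std", "lv")) {
  criterion <- match.arg(criterion)
  if (nrow(sweep) == 0) stop("empty sweep result")
  v <- switch(criterion,
              field = sweep$mean_field,
              std = -sweep$normalized_std,
              lv = sweep$localization_value)
  sweep$distance[which.max(v)]  # which.max takes the first (smallest d) tie
}

#' Summary table of sweeps at their optimal distances
#'
#' One row per configuration at its field-optimal distance, with the
#' STD-optimal and LV-optimal distances reported alongside (the criteria
#' coincide only for the best configuration).
#'
#' @param sweeps a list of \code{sweep_result} objects (may be empty).
#' @return a data.frame with columns \code{scheme}, \code{n_electrodes},
#'   \code{optimal_distance_mm}, \code{mean_field}, \code{normalized_std},
#'   \code{localization_value}, \code{std_optimal_distance_mm},
#'   \code{lv_optimal_distance_mm}.
#' @export
summary_table <- function(sweeps) {
  empty <- data.frame(scheme = integer(), n_electrodes = integer(),
                      optimal_distance_mm = numeric(), mean_field = numeric(),
                      normalized_std = numeric(),
                      localization_value = numeric(),
                      std_optimal_distance_mm = numeric(),
                      lv_optimal_distance_mm = numeric())
  if (length(sweeps) == 0) return(empty)
  rows <- lapply(sweeps, function(s) {
    d <- find_optimum(s, "field")
    at <- s[s$distance == d, , drop = FALSE]
    data.frame(scheme = attr(s, "scheme"),
               n_electrodes = attr(s, "n_electrodes"),
               optimal_distance_mm = d * 1e3,
               mean_field = at$mean_field,
               normalized_std = at$normalized_std,
               localization_value = at$localization_value,
               std_optimal_distance_mm = find_optimum(s, "std") * 1e3,
               lv_optimal_distance_mm = find_optimum(s, "lv") * 1e3)
  })
  do.call(rbind, rows)
}
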