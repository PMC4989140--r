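#' Regions of interest on the arterial wall and in the surrounding tissue
#'
#' The wall ROI is the upper arterial wall through its full thickness over a
#' 50 mm axial window centered on the electrode group. The tissue ROI is the
#' muscle block directly above the outer wall surface over the same axial
#' window, extending from the wall to the edge of the geometry (about
#' 100 mm for the default muscle block; for the scheme-3 domain it reaches
#' the remote return). A finite \code{tissue_height} restricts it, with a
#' warning if the request exceeds the domain. Electrode cells (scheme-2
#' returns sit inside the tissue window) are excluded, so each ROI contains
#' a single material.
#'
#' @param domain a \code{domain_model}.
#' @param axial_length axial window length, m.
#' @param center axial center of the window, m (default: the electrode
#'   group's midpoint, which is the vessel midpoint for all configurations).
#' @param tissue_height height of the tissue ROI above the outer wall, m;
#'   \code{NULL} (default) extends to the domain edge.
#' @return a logical mask matrix over the grid cells.
#' @name rois
NULL

#' @rdname rois
#' @export
wall_roi <- function(domain, axial_length = 0.05, center = 0) {
  g <- domain$grid
  geo <- domain$geometry
  inx <- abs(g$xc - center) <= axial_length / 2
  iny <- g$yc > geo$r_lumen & g$yc < geo$r_outer
  mask <- outer(inx, iny) & domain$material == 2L
  if (!any(mask)) stop("region error: wall ROI is empty")
  mask
}

#' @rdname rois
#' @export
tissue_roi <- function(domain, axial_length = 0.05, center = 0,
                       tissue_height = NULL) {
  g <- domain$grid
  geo <- domain$geometry
  if (is.null(tissue_height)) {
    top <- max(g$y)
  } else {
    top <- geo$r_outer + tissue_height
    if (top > max(g$y) + 1e-12) {
      top <- max(g$y)
      warning("tissue ROI truncated at the domain boundary (",
              format((top - geo$r_outer) * 1e3), " mm of ",
              tissue_height * 1e3, " mm)")
    }
  }
  inx <- abs(g$xc - center) <= axial_length / 2
  iny <- g$yc > geo$r_outer & g$yc < top
  mask <- outer(inx, iny) & domain$material == 3L
  if (!any(mask)) stop("region error: tissue ROI is empty")
  mask
}

roi_mean <- function(values, mask, areas) {
  w <- areas[mask]
  sum(w * values[mask]) / sum(w)
}

#' Area-weighted mean field over an ROI
#'
#' @param solution a \code{field_solution} with the field computed.
#' @param roi logical cell mask, e.g. from \code{\link{wall_roi}}.
#' @return mean field magnitude, V/m.
#' @export
wall_average <- function(solution, roi) {
  if (!any(roi)) stop("region error: empty ROI")
  roi_mean(solution$field_magnitude, roi, cell_areas(solution$domain$grid))
}

#' Field homogeneity over an ROI (normalized standard deviation)
#'
#' 100 times the area-weighted standard deviation of the field magnitude
#' divided by its area-weighted mean. Lower values mean a more uniform
#' constriction stimulus along the wall.
#'
#' @inheritParams wall_average
#' @return normalized standard deviation, percent.
#' @export
homogeneity <- function(solution, roi) {
  areas <- cell_areas(solution$domain$grid)
  m <- roi_mean(solution$field_magnitude, roi, areas)
  if (m <= 0) stop("undefined-homogeneity error: zero mean field on ROI")
  v <- roi_mean((solution$field_magnitude - m)^2, roi, areas)
  100 * sqrt(v) / m
}

#' Localization value of the field on the arterial wall
#'
#' Ratio of the mean field magnitude on the wall ROI to the mean on the
#' tissue ROI. Values above 1 indicate the treatment field concentrates on
#' the vessel wall rather than the surrounding muscle — the safety metric
#' used to compare electrode configurations.
#'
#' @inheritParams wall_average
#' @param wall_mask,tissue_mask masks from \code{\link{wall_roi}} and
#'   \code{\link{tissue_roi}}.
#' @return dimensionless localization value.
#' @export
localization_value <- function(solution, wall_mask, tissue_mask) {
  tm <- wall_average(solution, tissue_mask)
  if (tm <= 0) stop("division error: zero mean field on tissue ROI")
  wall_average(solution, wall_mask) / tm
}

#' All wall metrics of a solved field
#'
#' @inheritParams wall_average
#' @param axial_length,center,tissue_height ROI parameters, see
#'   \code{\link{wall_roi}}.
#' @return an object of class \code{wall_metrics}: \code{mean_field} (V/m),
#'   \code{normalized_std} (percent), \code{localization_value}.
#' @export
#' @examples
#' dom <- build_model(aorta_geometry(), electrode_configuration(1, 2, 0.019),
#'                    grid_spacing = 5e-4)
#' wall_metrics(solve_field(dom))
wall_metrics <- function(solution, axial_length = 0.05, center = 0,
                         tissue_height = NULL) {
  dom <- solution$domain
  wm <- wall_roi(dom, axial_length, center)
  tm <- suppressWarnings(tissue_roi(dom, axial_length, center, tissue_height))
  structure(list(
    mean_field = wall_average(solution, wm),
    normalized_std = homogeneity(solution, wm),
    localization_value = localization_value(solution, wm, tm)
  ), class = "wall_metrics")
}

#' @export
print.wall_metrics <- function(x, ...) {
  cat(sprintf(
    "<wall_metrics> mean |E| = %.4g V/m, STD = %.3g%%, LV = %.4g\n",
    x$mean_field, x$normalized_std, x$localization_value))
  invisible(x)
}
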