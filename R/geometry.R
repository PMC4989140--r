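#' Geometry of the artery-in-muscle computational domain
#'
#' The vessel is modeled in a 2-D plane: a rectangular vessel strip of
#' height \code{vessel_diameter} whose upper and lower \code{wall_thickness}
#' layers are arterial wall and whose interior is the blood-filled lumen,
#' embedded in a rectangular block of skeletal muscle. The vessel axis runs
#' horizontally (x); the plane is assigned unit depth for volumetric
#' quantities. Defaults describe a porcine abdominal aorta: a 12 mm vessel
#' with 1.5 mm walls, i.e. a 9 mm lumen (the wall-field metrics computed
#' with this reading reproduce the reference simulations; treating 12 mm as
#' the lumen instead underestimates them by 25-30 percent).
#'
#' @param vessel_diameter outer diameter of the vessel (lumen plus both
#'   walls), m.
#' @param wall_thickness arterial wall thickness, m.
#' @param vessel_length modeled vessel length, m (extended well beyond the
#'   stimulated section so domain boundaries do not influence the field).
#' @param muscle_width,muscle_height extent of the surrounding muscle block,
#'   m. The vessel is centered in the block.
#' @return an object of class \code{aorta_geometry}.
#' @export
#' @examples
#' geo <- aorta_geometry()
#' geo$lumen_diameter  # 0.009 m
aorta_geometry <- function(vessel_diameter = 0.012, wall_thickness = 0.0015,
                           vessel_length = 0.25, muscle_width = 0.7,
                           muscle_height = 0.2) {
  stopifnot(vessel_diameter > 0, wall_thickness > 0, vessel_length > 0)
  if (vessel_diameter <= 2 * wall_thickness)
    stop("geometry error: walls thicker than the vessel")
  if (vessel_length > muscle_width || vessel_diameter > muscle_height)
    stop("geometry error: vessel does not fit inside the muscle domain")
  structure(list(
    vessel_diameter = vessel_diameter,
    lumen_diameter = vessel_diameter - 2 * wall_thickness,
    wall_thickness = wall_thickness,
    vessel_length = vessel_length,
    muscle_width = muscle_width,
    muscle_height = muscle_height,
    r_lumen = vessel_diameter / 2 - wall_thickness,
    r_outer = vessel_diameter / 2
  ), class = "aorta_geometry")
}

#' Electrode configuration for endovascular stimulation
#'
#' Three schemes are supported. Scheme 1 (\code{endo_bipolar}): 1x1 mm
#' endovascular electrodes on the vessel centerline alternating between the
#' pulse potential and ground (for an odd count, the center electrode is
#' active and the flanking electrodes are returns). Scheme 2
#' (\code{endo_active_extravascular_return}): all endovascular electrodes are
#' active, with two circular 3 mm return electrodes in the muscle 1.5 mm
#' outside the wall, one above and one below the vessel. Scheme 3 (\code{remote_ground}): all endovascular
#' electrodes are active against a remote 15 x 150 mm grounded plate 40 cm
#' from the vessel, as in standard electro-surgical grounding pads.
#'
#' @param scheme 1, 2 or 3.
#' @param n_electrodes number of endovascular electrodes (total for scheme 1;
#'   all are active for schemes 2-3).
#' @param spacing center-to-center inter-electrode distance, m. Required when
#'   \code{n_electrodes >= 2}.
#' @param pulse_potential pulse amplitude Vp applied to active electrodes, V.
#' @param electrode_size side of the square endovascular electrodes, m.
#' @param return_diameter,return_gap scheme-2 circular return diameter and
#'   gap between the outer wall surface and the return, m.
#' @param remote_return_size scheme-3 return plate (width along vessel,
#'   height), m.
#' @param remote_return_distance distance from the outer wall surface to the
#'   scheme-3 return, m.
#' @return an object of class \code{electrode_configuration} with fields
#'   including \code{x_centers} (endovascular electrode centers) and
#'   \code{potentials} (one per endovascular electrode).
#' @export
#' @examples
#' cfg <- electrode_configuration(1, 4, spacing = 0.013)
#' cfg$potentials  # 40 0 40 0
electrode_configuration <- function(scheme, n_electrodes, spacing = NULL,
                                    pulse_potential = 40,
                                    electrode_size = 0.001,
                                    return_diameter = 0.003,
                                    return_gap = 0.0015,
                                    remote_return_size = c(0.15, 0.015),
                                    remote_return_distance = 0.4) {
  scheme <- as.integer(scheme)
  if (!scheme %in% 1:3) stop("scheme must be 1, 2 or 3")
  n <- as.integer(n_electrodes)
  if (scheme == 1 && n < 2)
    stop("configuration error: scheme 1 needs at least one active and one return electrode")
  if (n < 1) stop("configuration error: need at least one electrode")
  if (n >= 2) {
    if (is.null(spacing)) stop("spacing required for n_electrodes >= 2")
    if (spacing < electrode_size)
      stop("configuration error: electrodes overlap at spacing ",
           format(spacing), " m")
  } else spacing <- 0
  x_centers <- (seq_len(n) - (n + 1) / 2) * spacing
  potentials <- if (scheme == 1) {
    if (n %% 2 == 1) {
      p <- rep(0, n); p[(n + 1) / 2] <- pulse_potential; p
    } else rep(c(pulse_potential, 0), length.out = n)
  } else rep(pulse_potential, n)
  structure(list(
    scheme = scheme,
    scheme_name = c("endo_bipolar", "endo_active_extravascular_return",
                    "remote_ground")[scheme],
    n_electrodes = n,
    spacing = spacing,
    pulse_potential = pulse_potential,
    electrode_size = electrode_size,
    return_diameter = return_diameter,
    return_gap = return_gap,
    remote_return_size = remote_return_size,
    remote_return_distance = remote_return_distance,
    x_centers = x_centers,
    potentials = potentials
  ), class = "electrode_configuration")
}

#' Build the rasterized computational domain
#'
#' Rasterizes the planar artery-in-muscle geometry onto a rectilinear grid
#' with uniform fine spacing across the vessel (and around the electrodes
#' when a configuration is given) and geometric coarsening into the far
#' muscle. Each cell carries exactly one material label, decided by its
#' center point.
#'
#' @param geometry an \code{\link{aorta_geometry}}.
#' @param grid_spacing fine cell size, m. Must be at most 0.5 mm so the wall
#'   spans at least 3 cells, and must divide the lumen radius and wall
#'   thickness.
#' @param configuration optional \code{\link{electrode_configuration}}; when
#'   given, the fine region is extended to cover the electrode group (and the
#'   domain itself is extended for scheme 3 to contain the remote return).
#' @param h_max coarsest allowed cell size in the far muscle, m.
#' @param ratio geometric growth ratio of cell sizes outside fine bands.
#' @param materials material table (see \code{\link{material_table}}).
#' @return an object of class \code{domain_model}: grid, per-cell material
#'   codes (1 blood, 2 wall, 3 muscle, 4 electrode), and bookkeeping for
#'   electrodes once placed.
#' @seealso \code{\link{place_electrodes}}, \code{\link{build_model}}
#' @export
build_domain <- function(geometry, grid_spacing = 2.5e-4,
                         configuration = NULL, h_max = 0.012, ratio = 1.4,
                         materials = material_table()) {
  h <- grid_spacing
  if (geometry$wall_thickness / h < 3 - 1e-9)
    stop("resolution error: grid_spacing too coarse to resolve the wall ",
         "(needs >= 3 cells across ", geometry$wall_thickness, " m)")
  for (len in c(geometry$r_lumen, geometry$wall_thickness)) {
    if (abs(len / h - round(len / h)) > 0.5 - 1e-9)
      stop("resolution error: grid_spacing must divide layer thicknesses ",
           "to within half a cell")
  }

  half_w <- geometry$muscle_width / 2
  y_lo <- -geometry$muscle_height / 2
  y_hi <- geometry$muscle_height / 2

  # fine band half-extents, snapped to multiples of h so material interfaces
  # fall on cell faces
  pad <- ceiling(0.001 / h) * h
  yband_hi <- geometry$r_outer + pad
  x_half <- 0.03
  ybands <- data.frame(lo = -yband_hi, hi = yband_hi, h = h)
  if (!is.null(configuration)) {
    span <- diff(range(configuration$x_centers)) + configuration$electrode_size
    x_half <- max(x_half, span / 2 + 0.005)
    if (configuration$scheme == 2) {
      top <- geometry$r_outer + configuration$return_gap +
        configuration$return_diameter + pad
      ybands$hi <- ceiling(top / h) * h
      ybands$lo <- -ybands$hi
    }
    if (configuration$scheme == 3) {
      ret_lo <- geometry$r_outer + configuration$remote_return_distance
      y_hi <- ret_lo + configuration$remote_return_size[2]
      ybands <- rbind(ybands,
                      data.frame(lo = ret_lo, hi = y_hi, h = 0.005))
    }
  }
  x_half <- ceiling(x_half / h) * h
  xbands <- data.frame(lo = -x_half, hi = x_half, h = h)

  grid <- make_grid(
    grade_axis(-half_w, half_w, xbands, ratio, h_max),
    grade_axis(y_lo, y_hi, ybands, ratio, h_max)
  )

  material <- matrix(3L, grid$nx, grid$ny)  # muscle
  in_vessel_x <- abs(grid$xc) <= geometry$vessel_length / 2
  ay <- abs(grid$yc)
  wall_rows <- which(ay > geometry$r_lumen & ay < geometry$r_outer)
  blood_rows <- which(ay < geometry$r_lumen)
  material[in_vessel_x, wall_rows] <- 2L
  material[in_vessel_x, blood_rows] <- 1L

  structure(list(
    grid = grid,
    geometry = geometry,
    material = material,
    materials = materials,
    electrode_id = matrix(0L, grid$nx, grid$ny),
    electrode_potential = numeric(0),
    electrode_active = logical(0),
    configuration = NULL,
    grid_spacing = h
  ), class = "domain_model")
}

#' Stamp a fixed-potential electrode region onto the domain
#'
#' Marks every cell whose center lies in the given rectangle (or circle) as
#' electrode material held at a fixed potential. Electrodes are modeled as
#' Dirichlet regions: steel conducts roughly seven orders of magnitude better
#' than tissue, so the potential across an electrode footprint is uniform.
#'
#' @param domain a \code{domain_model}.
#' @param potential potential of the electrode, V.
#' @param xlim,ylim rectangle extents \code{c(lo, hi)} in m, or
#' @param center,radius circle center \code{c(x, y)} and radius in m
#'   (used when \code{xlim} is NULL).
#' @param active logical flag marking the electrode as active (driven) rather
#'   than a return; used for current bookkeeping.
#' @return the domain with the electrode added.
#' @export
stamp_electrode <- function(domain, potential, xlim = NULL, ylim = NULL,
                            center = NULL, radius = NULL, active = NA) {
  g <- domain$grid
  if (!is.null(xlim)) {
    sel <- outer(g$xc >= xlim[1] & g$xc <= xlim[2],
                 g$yc >= ylim[1] & g$yc <= ylim[2], "&")
  } else {
    sel <- outer((g$xc - center[1])^2, (g$yc - center[2])^2, "+") <= radius^2
  }
  if (!any(sel)) stop("placement error: electrode footprint contains no cell")
  if (any(domain$electrode_id[sel] != 0L))
    stop("configuration error: electrodes overlap")
  id <- length(domain$electrode_potential) + 1L
  domain$electrode_id[sel] <- id
  domain$material[sel] <- 4L
  domain$electrode_potential <- c(domain$electrode_potential, potential)
  domain$electrode_active <- c(domain$electrode_active,
                               if (is.na(active)) potential > 0 else active)
  domain
}

#' Place a configuration's electrodes in the domain
#'
#' Endovascular electrodes are centered on the vessel axis at the domain's
#' axial midpoint, equally spaced. Scheme 2 adds two circular extravascular
#' returns, one above and one below the vessel, at the axial midpoint of the
#' active group. Scheme 3 adds the remote grounded plate at the top of the
#' (extended) domain.
#'
#' @param domain a \code{domain_model} built with the same configuration (so
#'   the grid resolves the electrode region).
#' @param configuration an \code{\link{electrode_configuration}}.
#' @return the domain with electrode cells labeled and potentials recorded.
#' @export
place_electrodes <- function(domain, configuration) {
  geo <- domain$geometry
  cf <- configuration
  half <- cf$electrode_size / 2
  span <- diff(range(cf$x_centers))
  if (span / 2 + half > geo$vessel_length / 2)
    stop("placement error: electrode group does not fit in the vessel")
  if (half > geo$r_lumen)
    stop("placement error: electrode taller than the lumen")
  for (i in seq_len(cf$n_electrodes)) {
    domain <- stamp_electrode(domain, cf$potentials[i],
                              xlim = cf$x_centers[i] + c(-half, half),
                              ylim = c(-half, half),
                              active = cf$potentials[i] > 0)
  }
  if (cf$scheme == 2) {
    r <- cf$return_diameter / 2
    yc <- geo$r_outer + cf$return_gap + r
    for (y0 in c(yc, -yc))
      domain <- stamp_electrode(domain, 0, center = c(0, y0), radius = r,
                                active = FALSE)
  }
  if (cf$scheme == 3) {
    ret_lo <- geo$r_outer + cf$remote_return_distance
    w <- cf$remote_return_size[1]
    if (ret_lo + cf$remote_return_size[2] > max(domain$grid$y) + 1e-9)
      stop("placement error: domain does not contain the remote return; ",
           "build the domain with this configuration")
    domain <- stamp_electrode(domain, 0, xlim = c(-w / 2, w / 2),
                              ylim = c(ret_lo, ret_lo + cf$remote_return_size[2]),
                              active = FALSE)
  }
  if (!any(domain$electrode_potential > 0) ||
      !any(domain$electrode_potential == 0))
    stop("configuration error: need at least one active and one return electrode")
  domain$configuration <- cf
  domain
}

#' Build domain and place electrodes in one call
#'
#' @inheritParams build_domain
#' @param configuration an \code{\link{electrode_configuration}}.
#' @param ... passed to \code{\link{build_domain}}.
#' @return a \code{domain_model} ready for \code{\link{solve_field}}.
#' @export
#' @examples
#' dom <- build_model(aorta_geometry(), electrode_configuration(1, 2, 0.019),
#'                    grid_spacing = 5e-4)
build_model <- function(geometry, configuration, grid_spacing = 2.5e-4, ...) {
  dom <- build_domain(geometry, grid_spacing, configuration, ...)
  place_electrodes(dom, configuration)
}

#' @export
print.domain_model <- function(x, ...) {
  g <- x$grid
  cat("<domain_model> ", g$nx, "x", g$ny, " cells (",
      format(g$nx * g$ny, big.mark = ","), "), fine spacing ",
      x$grid_spacing * 1e3, " mm\n", sep = "")
  tab <- table(factor(x$material, 1:4,
                      c("blood", "wall", "muscle", "electrode")))
  print(tab)
  invisible(x)
}

#' @export
print.electrode_configuration <- function(x, ...) {
  cat("<electrode_configuration> scheme ", x$scheme, " (", x$scheme_name,
      "), n = ", x$n_electrodes, ", spacing = ", x$spacing * 1e3,
      " mm, Vp = ", x$pulse_potential, " V\n", sep = "")
  invisible(x)
}
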