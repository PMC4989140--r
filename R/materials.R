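#' Material property table for the artery-in-muscle model
#'
#' Dielectric and thermal properties of blood, aortic wall, surrounding
#' skeletal muscle and the 304 stainless-steel electrodes used throughout
#' the simulations. Baseline lumen blood perfusion corresponds to a flow of
#' about 1.575 L/min through a 6 mm (inner radius) vessel over the heated
#' length; tissue metabolic heat generation is 33,800 W/m^3.
#'
#' @param overrides optional named list of the form
#'   \code{list(wall = list(electrical_conductivity = 0.3))} replacing
#'   individual entries.
#' @return a data.frame with one row per material label
#'   (\code{blood}, \code{wall}, \code{muscle}, \code{electrode}) and columns
#'   \code{electrical_conductivity} (S/m), \code{relative_permittivity},
#'   \code{density} (kg/m^3), \code{thermal_conductivity} (W/(m K)),
#'   \code{heat_capacity} (J/(kg K)), \code{perfusion_rate} (1/s) and
#'   \code{metabolic_heat} (W/m^3).
#' @export
#' @examples
#' material_table()
material_table <- function(overrides = NULL) {
  tab <- data.frame(
    label = c("blood", "wall", "muscle", "electrode"),
    electrical_conductivity = c(0.7, 0.25, 0.25, 2.22e6),
    relative_permittivity = c(1.4e3, 1e7, 1.4e7, 1),
    density = c(1000, 1102, 1090, 7900),
    thermal_conductivity = c(0.52, 0.46, 0.49, 14),
    heat_capacity = c(3640, 3306, 3421, 477),
    perfusion_rate = c(58.34, 0, 0, 0),
    metabolic_heat = c(0, 33800, 33800, 0),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (lab in names(overrides)) {
      i <- match(lab, tab$label)
      if (is.na(i)) stop("unknown material label in overrides: ", lab)
      for (fld in names(overrides[[lab]])) {
        if (!fld %in% names(tab)) stop("unknown material field: ", fld)
        tab[i, fld] <- overrides[[lab]][[fld]]
      }
    }
  }
  validate_materials(tab)
  tab
}

validate_materials <- function(tab) {
  pos <- c("electrical_conductivity", "density", "thermal_conductivity",
           "heat_capacity")
  for (fld in pos) {
    if (any(tab[[fld]] <= 0))
      stop("material field '", fld, "' must be strictly positive")
  }
  if (any(tab$perfusion_rate < 0)) stop("perfusion_rate must be >= 0")
  if (any(tab$metabolic_heat < 0)) stop("metabolic_heat must be >= 0")
  invisible(tab)
}

#' Look up the properties of one material
#'
#' @param label one of \code{"blood"}, \code{"wall"}, \code{"muscle"},
#'   \code{"electrode"}.
#' @param perfusion_factor multiplier on the baseline blood perfusion rate
#'   (1, 0.1 and 0.01 emulate a normal, partly constricted and almost fully
#'   constricted vessel). Applies to blood only; other materials are not
#'   perfused.
#' @param materials material table, by default \code{\link{material_table}()}.
#' @return a list with the fields of one \code{\link{material_table}} row,
#'   perfusion scaled by \code{perfusion_factor}.
#' @export
#' @examples
#' material_lookup("blood")$electrical_conductivity  # 0.7 S/m
material_lookup <- function(label, perfusion_factor = 1,
                            materials = material_table()) {
  i <- match(label, materials$label)
  if (is.na(i)) stop("unknown material label: ", label)
  row <- as.list(materials[i, setdiff(names(materials), "label")])
  row$perfusion_rate <- row$perfusion_rate * perfusion_factor
  row
}

# per-cell property matrix for one field, from the material label matrix
property_map <- function(domain, field, materials = domain$materials) {
  vals <- materials[[field]][match(c("blood", "wall", "muscle", "electrode"),
                                   materials$label)]
  m <- matrix(vals[domain$material], nrow = domain$grid$nx)
  m
}
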