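#' Export cell data on the simulation grid to a VTK rectilinear-grid file
#'
#' ASCII XML \code{.vtr} (RectilinearGrid) with one CellData array per named
#' entry. Values are written with 17 significant digits so a read-back
#' reproduces them bit-for-bit.
#'
#' @param path output file path.
#' @param grid a grid from a \code{domain_model} (\code{domain$grid}).
#' @param celldata named list of nx-by-ny matrices.
#' @return \code{path}, invisibly.
#' @export
write_vtr <- function(path, grid, celldata) {
  stopifnot(length(celldata) > 0, !is.null(names(celldata)))
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  arrays <- vapply(names(celldata), function(nm) {
    m <- celldata[[nm]]
    stopifnot(nrow(m) == grid$nx, ncol(m) == grid$ny)
    paste0('      <DataArray type="Float64" Name="', nm,
           '" format="ascii">\n        ', num(as.numeric(m)),
           "\n      </DataArray>")
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="RectilinearGrid" version="0.1" byte_order="LittleEndian">\n',
    '  <RectilinearGrid WholeExtent="0 ', grid$nx, ' 0 ', grid$ny, ' 0 0">\n',
    '  <Piece Extent="0 ', grid$nx, ' 0 ', grid$ny, ' 0 0">\n',
    "    <Coordinates>\n",
    '      <DataArray type="Float64" Name="x" format="ascii">\n        ',
    num(grid$x), "\n      </DataArray>\n",
    '      <DataArray type="Float64" Name="y" format="ascii">\n        ',
    num(grid$y), "\n      </DataArray>\n",
    '      <DataArray type="Float64" Name="z" format="ascii">\n        ',
    "0 0\n      </DataArray>\n",
    "    </Coordinates>\n",
    "    <CellData>\n",
    paste(arrays, collapse = "\n"), "\n",
    "    </CellData>\n",
    "  </Piece>\n  </RectilinearGrid>\n</VTKFile>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Read back a rectilinear-grid file written by \code{\link{write_vtr}}
#'
#' @param path file path.
#' @return a list with \code{grid} (x, y edge vectors) and \code{celldata}
#'   (named list of nx-by-ny matrices).
#' @export
read_vtr <- function(path) {
  doc <- xml2::read_xml(path)
  coords <- xml2::xml_find_all(doc, ".//Coordinates/DataArray")
  getv <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)),
                                             "\\s+")[[1]])
  x <- getv(coords[[1]]); y <- getv(coords[[2]])
  nx <- length(x) - 1; ny <- length(y) - 1
  arrays <- xml2::xml_find_all(doc, ".//CellData/DataArray")
  celldata <- lapply(arrays, function(a) matrix(getv(a), nx, ny))
  names(celldata) <- xml2::xml_attr(arrays, "Name")
  list(grid = list(x = x, y = y, nx = nx, ny = ny), celldata = celldata)
}

#' Export a solved field (potential, |E|, J) to a VTK file
#'
#' @param solution a \code{field_solution} with the field computed.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_field_vtr <- function(solution, path) {
  write_vtr(path, solution$domain$grid, list(
    potential = solution$potential,
    field_magnitude = solution$field_magnitude,
    current_density = solution$current_density,
    material = matrix(as.numeric(solution$domain$material),
                      solution$domain$grid$nx)))
}

#' Axial field profile along the wall mid-line
#'
#' Thickness-averaged field magnitude of the upper wall as a function of
#' axial position — the quantity plotted as the one-dimensional wall
#' profiles of each configuration.
#'
#' @param solution a \code{field_solution}.
#' @return a data.frame with columns \code{x_m} and \code{mean_field_V_per_m}.
#' @export
wall_profile <- function(solution) {
  dom <- solution$domain
  g <- dom$grid
  geo <- dom$geometry
  rows <- which(g$yc > geo$r_lumen & g$yc < geo$r_outer)
  cols <- which(abs(g$xc) <= geo$vessel_length / 2)
  w <- g$dy[rows]
  prof <- as.numeric(solution$field_magnitude[cols, rows, drop = FALSE] %*%
                       w) / sum(w)
  data.frame(x_m = g$xc[cols], mean_field_V_per_m = prof)
}

#' Write / read a plain-text (YAML) model configuration
#'
#' The config captures geometry, electrode configuration, fine grid spacing
#' and any material overrides, and can be rebuilt into a ready-to-solve
#' domain with \code{\link{model_from_config}}.
#'
#' @param path file path.
#' @param geometry an \code{\link{aorta_geometry}}.
#' @param configuration an \code{\link{electrode_configuration}}.
#' @param grid_spacing fine cell size, m.
#' @param material_overrides optional named list of material overrides (see
#'   \code{\link{material_table}}).
#' @return \code{path} invisibly (write); a config list (read).
#' @export
write_config <- function(path, geometry, configuration,
                         grid_spacing = 2.5e-4, material_overrides = NULL) {
  cfg <- list(
    geometry = geometry[c("vessel_diameter", "wall_thickness",
                          "vessel_length", "muscle_width", "muscle_height")],
    configuration = configuration[c("scheme", "n_electrodes", "spacing",
                                    "pulse_potential", "electrode_size",
                                    "return_diameter", "return_gap",
                                    "remote_return_size",
                                    "remote_return_distance")],
    grid_spacing = grid_spacing,
    material_overrides = material_overrides)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname write_config
#' @param config a config list from \code{\link{read_config}}.
#' @export
model_from_config <- function(config) {
  geo <- do.call(aorta_geometry, config$geometry)
  cc <- config$configuration
  cfg <- electrode_configuration(
    cc$scheme, cc$n_electrodes,
    spacing = if (cc$n_electrodes >= 2) cc$spacing else NULL,
    pulse_potential = cc$pulse_potential, electrode_size = cc$electrode_size,
    return_diameter = cc$return_diameter, return_gap = cc$return_gap,
    remote_return_size = cc$remote_return_size,
    remote_return_distance = cc$remote_return_distance)
  mats <- material_table(config$material_overrides)
  build_model(geo, cfg, config$grid_spacing, materials = mats)
}
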