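#' Load a material and its attenuation table
#'
#' Materials ship as plain-text two-column tables (energy keV, mass
#' attenuation cm^2/g) under `inst/extdata/attenuation/`, with density and
#' Z/A in the header.  Between grid points the mass attenuation is
#' interpolated log-log, the standard choice for photon cross-section
#' tables.
#'
#' @param name one of `ct_materials()`: "water", "pmma", "polypropylene",
#'   "lead", "aluminium", "copper".  "plexiglas" is accepted as an alias
#'   for "pmma".
#' @return an object of class `ct_material` with fields `name`, `density`
#'   (g/cm^3), `z_over_a`, `energy` (keV grid), `mu_rho` (cm^2/g) and
#'   `electron_density_rel` (electrons per cm^3 relative to water).
#' @export
ct_material <- function(name) {
  if (inherits(name, "ct_material")) return(name)
  stopifnot(is.character(name), length(name) == 1)
  name <- tolower(name)
  if (name == "plexiglas") name <- "pmma"
  if (!name %in% ct_materials())
    stop("unknown material '", name, "'; available: ",
         paste(ct_materials(), collapse = ", "))
  cached <- .material_cache[[name]]
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "attenuation", paste0(name, ".txt"),
                      package = "ctscatter", mustWork = TRUE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", ln[1]))
  }
  density <- get_field("density_g_cm3")
  z_over_a <- get_field("z_over_a")
  tab <- read.table(text = lines[!grepl("^#", lines) & nzchar(lines)],
                    col.names = c("energy", "mu_rho"))
  stopifnot(all(tab$mu_rho > 0), all(diff(tab$energy) > 0),
            min(tab$energy) <= 10, max(tab$energy) >= 150)
  # electron density relative to water (water: rho = 1, Z/A = 0.55509)
  e_rel <- (density * z_over_a) / (1.000 * 0.55509)
  m <- structure(
    list(name = name, density = density, z_over_a = z_over_a,
         energy = tab$energy, mu_rho = tab$mu_rho,
         electron_density_rel = e_rel),
    class = "ct_material")
  assign(name, m, envir = .material_cache)
  m
}

.material_cache <- new.env(parent = emptyenv())

#' @rdname ct_material
#' @export
ct_materials <- function() {
  c("water", "pmma", "polypropylene", "lead", "aluminium", "copper")
}

#' @export
print.ct_material <- function(x, ...) {
  cat(sprintf("<ct_material> %s: density %.3f g/cm^3, Z/A %.5f, %d-point table %g-%g keV\n",
              x$name, x$density, x$z_over_a, length(x$energy),
              min(x$energy), max(x$energy)))
  invisible(x)
}

#' Mass attenuation coefficient at arbitrary energies
#'
#' Log-log interpolation of the shipped table; energies outside the table
#' range are a domain error.
#'
#' @param material a `ct_material` or material name
#' @param energy photon energies, keV (vectorised)
#' @return mu/rho in cm^2/g
#' @export
mass_attenuation <- function(material, energy) {
  m <- ct_material(material)
  if (any(!is.finite(energy)) || any(energy < min(m$energy)) ||
      any(energy > max(m$energy)))
    stop("energy outside the tabulated range [", min(m$energy), ", ",
         max(m$energy), "] keV for material '", m$name, "'")
  exp(approx(log(m$energy), log(m$mu_rho), xout = log(energy),
             ties = "ordered")$y)
}

#' Linear attenuation coefficient
#'
#' @inheritParams mass_attenuation
#' @return mu in cm^-1 (mass attenuation times density)
#' @export
linear_attenuation <- function(material, energy) {
  m <- ct_material(material)
  mass_attenuation(m, energy) * m$density
}

#' Narrow-beam transmission through a slab
#'
#' `exp(-mu t)` with `mu = linear_attenuation(material, energy)`.
#'
#' @inheritParams mass_attenuation
#' @param thickness slab thickness, cm (nonnegative)
#' @export
transmission <- function(material, energy, thickness) {
  if (any(thickness < 0)) stop("thickness must be nonnegative")
  exp(-linear_attenuation(material, energy) * thickness)
}

#' Energy-independent lead attenuation used for the blocker shadow
#'
#' The blocker model uses the single published value
#' mu/rho = 3.32 cm^2/g at rho = 11.3 g/cm^3, i.e. mu = 37.52 cm^-1,
#' rather than the full energy-resolved lead table; this mirrors how the
#' bar transmission (3 mm of lead) is quoted for the measurement.
#'
#' @return linear attenuation coefficient, cm^-1
#' @export
lead_blocker_attenuation <- function() 3.32 * 11.3

# absolute electron density of water, electrons / cm^3
.water_electron_density <- function() 1.000 * 0.55509 * .const$avogadro

#' Linear attenuation due to incoherent (Compton) scattering
#'
#' Electron density of the material times the total Klein-Nishina cross
#' section per electron.  Used to weight interaction sampling in the
#' scatter simulator; always below the total attenuation from the tables
#' at CT energies.
#'
#' @inheritParams mass_attenuation
#' @return mu_compton in cm^-1
#' @export
compton_linear_attenuation <- function(material, energy) {
  m <- ct_material(material)
  n_e <- m$electron_density_rel * .water_electron_density()
  n_e * kn_total_cross_section(energy) * .const$r_e_cm^2
}
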