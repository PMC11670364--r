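# Materials: density plus energy-dependent mass attenuation (mu/rho) and
# mass energy-absorption (mu_en/rho) curves, bundled as plain-text tables
# spanning 10 keV to 6 MeV.

#' Construct a material from attenuation curves
#'
#' A material couples a nominal density with two energy-dependent curves:
#' the mass attenuation coefficient \eqn{(\mu/\rho)(E)} in cm^2/g used for
#' transmission, and the mass energy-absorption coefficient
#' \eqn{(\mu_{en}/\rho)(E)} used for dose. Curves are interpolated
#' log-log between table points, which keeps them positive everywhere.
#'
#' @param name character label.
#' @param density nominal density in g/cm^3 (> 0).
#' @param table data frame with columns `energy_keV`, `mu_over_rho_cm2g`,
#'   `muen_over_rho_cm2g`, strictly increasing in energy.
#' @return an object of class `mvkv_material`.
#' @seealso [load_material()] for the bundled tables.
#' @export
material <- function(name, density, table) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(density), length(density) == 1L, density > 0)
  req <- c("energy_keV", "mu_over_rho_cm2g", "muen_over_rho_cm2g")
  if (!all(req %in% names(table))) {
    stop("material table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tab <- table[order(table$energy_keV), req]
  if (any(tab$mu_over_rho_cm2g <= 0) || any(tab$muen_over_rho_cm2g <= 0)) {
    stop("attenuation curves must be positive", call. = FALSE)
  }
  structure(
    list(
      name = name,
      density = density,
      table = tab,
      mass_atten = loglog_interp_fun(tab$energy_keV, tab$mu_over_rho_cm2g),
      mass_energy_abs = loglog_interp_fun(tab$energy_keV,
                                          tab$muen_over_rho_cm2g)
    ),
    class = "mvkv_material"
  )
}

#' Load a bundled material table
#'
#' Bundled materials: `"tissue"` (soft tissue, basis density 1.06 g/cm^3),
#' `"bone"` (cortical bone, basis density 1.85 g/cm^3), `"water"`,
#' `"silicon"`, `"cdte"` and `"aluminum"`. Tables are whitespace-delimited
#' text with a `# density_g_cm3:` header line, columns
#' `energy_keV mu_over_rho_cm2g muen_over_rho_cm2g`, spanning
#' 10 keV - 6 MeV. A path to a user table in the same format is also
#' accepted.
#'
#' @param name bundled material name or path to a table file.
#' @return an `mvkv_material`.
#' @examples
#' bone <- load_material("bone")
#' mass_atten(bone, c(60, 511, 3000))
#' @export
load_material <- function(name) {
  key <- paste0("material_", name)
  cached <- .mvkv_env[[key]]
  if (!is.null(cached)) return(cached)
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "materials", paste0(name, ".txt"),
                package = "mvkvdect")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown material '", name, "'; bundled: ",
         paste(list_materials(), collapse = ", "), call. = FALSE)
  }
  header <- readLines(path, n = 20L)
  dens_line <- grep("^#\\s*density_g_cm3:", header, value = TRUE)
  if (length(dens_line) != 1L) {
    stop("material file lacks a '# density_g_cm3:' header", call. = FALSE)
  }
  density <- as.numeric(sub("^#\\s*density_g_cm3:\\s*", "", dens_line))
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("energy_keV", "mu_over_rho_cm2g",
                                         "muen_over_rho_cm2g"))
  m <- material(sub("\\.txt$", "", basename(path)), density, tab)
  .mvkv_env[[key]] <- m
  m
}

#' @rdname load_material
#' @export
list_materials <- function() {
  dir <- system.file("extdata", "materials", package = "mvkvdect")
  sub("\\.txt$", "", list.files(dir, pattern = "\\.txt$"))
}

#' Evaluate material curves
#'
#' `mass_atten()` returns \eqn{(\mu/\rho)(E)} and `mass_energy_abs()`
#' returns \eqn{(\mu_{en}/\rho)(E)}, both in cm^2/g, at energies `E_keV`
#' (vectorized, must lie within the tabulated range).
#'
#' @param material an `mvkv_material`.
#' @param E_keV photon energies in keV.
#' @export
mass_atten <- function(material, E_keV) {
  stopifnot(inherits(material, "mvkv_material"))
  material$mass_atten(E_keV)
}

#' @rdname mass_atten
#' @export
mass_energy_abs <- function(material, E_keV) {
  stopifnot(inherits(material, "mvkv_material"))
  material$mass_energy_abs(E_keV)
}

#' Fraction of photons stopped by a slab
#'
#' Computes \eqn{1 - \exp[-(\mu/\rho)(E)\,\rho\,t]}, the fraction of an
#' incident monoenergetic beam attenuated by a slab of the given material.
#' Used for quick detector-slab feasibility estimates, e.g. the stopping
#' power of centimeter-scale Si or CdTe converters for 3-MeV photons.
#'
#' @param material an `mvkv_material`.
#' @param thickness_cm slab thickness in cm (>= 0).
#' @param E_keV photon energy in keV.
#' @param density slab density in g/cm^3; defaults to the material's
#'   nominal density.
#' @return attenuated fraction in `[0, 1)`.
#' @examples
#' stopping_fraction(load_material("silicon"), 3, 3000)  # ~0.2
#' @export
stopping_fraction <- function(material, thickness_cm, E_keV,
                              density = material$density) {
  stopifnot(inherits(material, "mvkv_material"))
  if (any(thickness_cm < 0)) {
    stop("thickness must be non-negative", call. = FALSE)
  }
  1 - exp(-mass_atten(material, E_keV) * density * thickness_cm)
}

#' Basis material pair for two-material decomposition
#'
#' The default decomposition basis: soft tissue at 1.06 g/cm^3 and cortical
#' bone at 1.85 g/cm^3.
#'
#' @return named list with `mvkv_material` elements `tissue` and `bone`.
#' @export
default_basis <- function() {
  list(tissue = load_material("tissue"), bone = load_material("bone"))
}

#' @export
print.mvkv_material <- function(x, ...) {
  rng <- range(x$table$energy_keV)
  cat(sprintf("<mvkv_material> %s  density %.3f g/cm3  (%g-%g keV)\n",
              x$name, x$density, rng[1], rng[2]))
  invisible(x)
}
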