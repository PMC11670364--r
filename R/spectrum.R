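# Polychromatic x-ray spectra: energy-bin centers plus photons per bin for
# a single ray. Analytic models stand in for measured spectrum files and
# are swappable via a two-column text format.

new_spectrum <- function(energies, fluence, label) {
  energies <- as.numeric(energies)
  fluence <- as.numeric(fluence)
  if (length(energies) != length(fluence) || length(energies) < 1L) {
    stop("energies and fluence must be equal-length, non-empty",
         call. = FALSE)
  }
  if (any(diff(energies) <= 0)) {
    stop("energies must be strictly increasing", call. = FALSE)
  }
  if (any(fluence < 0) || any(!is.finite(fluence))) {
    stop("fluence must be finite and non-negative", call. = FALSE)
  }
  structure(list(energies = energies, fluence = fluence,
                 label = as.character(label)),
            class = "mvkv_spectrum")
}

#' Construct a spectrum from energy and fluence vectors
#'
#' A spectrum is a grid of strictly increasing energy-bin centers (keV)
#' with the number of photons per bin carried by a single ray. Absolute
#' fluence is meaningful only after dose normalization (see
#' [scale_to_dose()] / [allocate_dose()]).
#'
#' @param energies bin-center energies in keV, strictly increasing.
#' @param fluence photons per bin (non-negative).
#' @param label text label.
#' @return an `mvkv_spectrum`.
#' @export
spectrum <- function(energies, fluence, label = "spectrum") {
  new_spectrum(energies, fluence, label)
}

#' Analytic kilovoltage bremsstrahlung spectrum
#'
#' Kramers-type thin-target bremsstrahlung, fluence proportional to
#' `(kvp - E)/E`, hardened by an aluminum filter of the given thickness.
#' The energy grid uses 1-keV bins from 10 keV to the tube potential, so
#' the fluence endpoint at `kvp` is exact. Intended as a typical
#' diagnostic-imaging beam (default 80 kVp, 2.5 mm Al); a measured spectrum
#' in the same two-column text format can be dropped in via
#' [read_spectrum()].
#'
#' @param kvp tube potential in kV (peak energy in keV), in `[40, 150]`.
#' @param filtration_mm_al aluminum filtration in mm (>= 0).
#' @return an `mvkv_spectrum` (arbitrary overall scale).
#' @export
build_kv_spectrum <- function(kvp = 80, filtration_mm_al = 2.5) {
  if (!is.numeric(kvp) || length(kvp) != 1L || kvp < 40 || kvp > 150) {
    stop("kvp must be a single value in [40, 150]", call. = FALSE)
  }
  if (filtration_mm_al < 0) {
    stop("filtration must be non-negative", call. = FALSE)
  }
  edges <- seq(10, kvp, by = 1)
  E <- (edges[-length(edges)] + edges[-1]) / 2
  raw <- (kvp - E) / E
  al <- load_material("aluminum")
  filt <- exp(-mass_atten(al, E) * al$density * filtration_mm_al / 10)
  new_spectrum(E, raw * filt, sprintf("%gkVp_%gmmAl", kvp, filtration_mm_al))
}

#' Analytic detuned megavoltage spectrum
#'
#' Models a 6-MV treatment beam softened for imaging: fluence proportional
#' to `E * exp(-E / 1 MeV)`, truncated at 6 MeV, on 20-keV bins. The mode
#' of the fluence sits at ~1 MeV and the fluence-weighted mean energy is
#' ~1.9 MeV, matching the spectral properties of a detuned linac imaging
#' beam (peak flux near 1 MeV, mean below 3 MeV).
#'
#' @param mode_keV energy of peak fluence in keV (default 1000).
#' @param emax_keV truncation energy in keV (default 6000).
#' @param bin_keV bin width in keV (default 20).
#' @return an `mvkv_spectrum` (arbitrary overall scale).
#' @export
build_detuned_mv_spectrum <- function(mode_keV = 1000, emax_keV = 6000,
                                      bin_keV = 20) {
  stopifnot(mode_keV > 0, emax_keV > mode_keV, bin_keV > 0)
  edges <- seq(bin_keV, emax_keV, by = bin_keV)
  E <- (edges[-length(edges)] + edges[-1]) / 2
  new_spectrum(E, E * exp(-E / mode_keV),
               sprintf("detunedMV_%gMeV", emax_keV / 1000))
}

#' Read / write a spectrum as two-column text
#'
#' Whitespace-delimited text, `energy_keV fluence`, `#` comment lines.
#'
#' @param path file path.
#' @param label label for the loaded spectrum (defaults to the file name).
#' @return `read_spectrum()` returns an `mvkv_spectrum`;
#'   `write_spectrum()` returns `path` invisibly.
#' @export
read_spectrum <- function(path, label = basename(path)) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("energy_keV", "fluence"))
  new_spectrum(tab$energy_keV, tab$fluence, label)
}

#' @rdname read_spectrum
#' @param x an `mvkv_spectrum`.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "mvkv_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# spectrum: %s", x$label),
               "# columns: energy_keV fluence"), con)
  utils::write.table(data.frame(x$energies, signif(x$fluence, 10)), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Rebin a spectrum onto coarser bins
#'
#' Aggregates photons-per-bin into wider bins (sums fluence, bin centers at
#' the fluence-weighted mean energy of each group). Total photon count and
#' dose are preserved up to the energy discretization. Useful for speeding
#' up CT-scale simulations.
#'
#' @param x an `mvkv_spectrum`.
#' @param bin_keV target bin width in keV.
#' @export
rebin_spectrum <- function(x, bin_keV) {
  stopifnot(inherits(x, "mvkv_spectrum"), bin_keV > 0)
  grp <- floor((x$energies - min(x$energies)) / bin_keV)
  flu <- as.numeric(tapply(x$fluence, grp, sum))
  wE <- as.numeric(tapply(x$fluence * x$energies, grp, sum))
  E0 <- as.numeric(tapply(x$energies, grp, mean))
  E <- ifelse(flu > 0, wE / pmax(flu, .Machine$double.xmin), E0)
  keep <- order(E)
  new_spectrum(E[keep], flu[keep], x$label)
}

#' Fluence-weighted mean energy of a spectrum
#'
#' @param x an `mvkv_spectrum`.
#' @return mean energy in keV.
#' @export
mean_energy <- function(x) {
  stopifnot(inherits(x, "mvkv_spectrum"))
  tot <- sum(x$fluence)
  if (tot <= 0) stop("spectrum has zero total fluence", call. = FALSE)
  sum(x$fluence * x$energies) / tot
}

#' @export
print.mvkv_spectrum <- function(x, ...) {
  cat(sprintf(
    "<mvkv_spectrum> %s  %d bins, %.4g-%.4g keV, total fluence %.4g\n",
    x$label, length(x$energies), min(x$energies), max(x$energies),
    sum(x$fluence)))
  if (sum(x$fluence) > 0) {
    cat(sprintf("  mean energy %.4g keV\n", mean_energy(x)))
  }
  invisible(x)
}
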