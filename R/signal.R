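# Per-ray signal statistics for a polychromatic spectrum traversing a
# two-material composition, plus the dose normalization that anchors
# absolute fluence (and hence noise) levels.

KEV_PER_G_TO_UGY <- 1.602176634e-7  # 1 keV/g = 1.602e-16 J / 1e-3 kg, in uGy

#' Two-material ray composition
#'
#' Thicknesses of the basis materials intersected by a single ray. Mass
#' thicknesses \eqn{A_j = \rho_j t_j} (g/cm^2) are derived from the basis
#' densities.
#'
#' @param t_tissue_cm,t_bone_cm thicknesses in cm (>= 0).
#' @param basis basis material pair, see [default_basis()].
#' @return an `mvkv_composition` with `t_cm`, `rho`, `A` (all named
#'   `tissue` / `bone`).
#' @export
ray_composition <- function(t_tissue_cm, t_bone_cm, basis = default_basis()) {
  t <- c(tissue = t_tissue_cm, bone = t_bone_cm)
  if (any(t < 0)) stop("thicknesses must be >= 0", call. = FALSE)
  rho <- c(tissue = basis$tissue$density, bone = basis$bone$density)
  structure(list(t_cm = t, rho = rho, A = rho * t, basis = basis),
            class = "mvkv_composition")
}

# Per-energy weights reused by the signal, variance, Fisher and
# decomposition code: w = I * eta * D (signal weights), wc = I * eta
# (detected-count weights), wE2 = I * eta * E^2 (EID quantum variance
# weights), and the basis mass-attenuation curves on the spectrum grid.
spectral_cache <- function(spectrum, basis, detector) {
  stopifnot(inherits(spectrum, "mvkv_spectrum"),
            inherits(detector, "mvkv_detector"))
  E <- spectrum$energies
  eta <- detector$efficiency(E)
  if (any(eta < 0) || any(eta > 1)) {
    stop("efficiency must lie in [0, 1]", call. = FALSE)
  }
  D <- detector$response(E)
  I <- spectrum$fluence
  list(E = E, I = I, eta = eta, D = D,
       w = I * eta * D, wc = I * eta, wE2 = I * eta * E^2,
       mu = cbind(tissue = mass_atten(basis$tissue, E),
                  bone = mass_atten(basis$bone, E)),
       Ebar = if (sum(I) > 0) sum(I * E) / sum(I) else 0,
       sigma_e = detector$electronic_noise_sd)
}

transmission <- function(cache, A) {
  exp(-(cache$mu[, "tissue"] * A[["tissue"]] + cache$mu[, "bone"] * A[["bone"]]))
}

#' Expected detected signal along a single ray
#'
#' Discretizes the polychromatic signal model
#' \deqn{\lambda = \sum_E I(E)\, e^{-\sum_j (\mu/\rho)_j(E) A_j}\,
#'   \eta(E)\, D(E)}
#' on the spectrum's energy grid. For a PCD the result is expected counts;
#' for an EID it is the expected count-weighted energy sum (keV).
#'
#' @param spectrum an `mvkv_spectrum` (already dose-scaled if absolute
#'   values are wanted).
#' @param composition an `mvkv_composition`.
#' @param basis basis material pair.
#' @param detector an `mvkv_detector`.
#' @export
expected_signal <- function(spectrum, composition, basis = default_basis(),
                            detector = detector_model("pcd")) {
  stopifnot(inherits(composition, "mvkv_composition"))
  cache <- spectral_cache(spectrum, basis, detector)
  sum(cache$w * transmission(cache, composition$A))
}

#' Variance of the detected signal along a single ray
#'
#' PCD: pure Poisson counting, variance equal to the expected counts.
#' EID: Gaussian approximation of the compound-Poisson energy-weighted sum,
#' \eqn{\sum_E I e^{-\mu t} \eta E^2}, plus the additive electronic term
#' \eqn{(\sigma_e \bar E)^2} where \eqn{\bar E} is the fluence-weighted
#' mean energy of the incident spectrum.
#'
#' @inheritParams expected_signal
#' @export
signal_variance <- function(spectrum, composition, basis = default_basis(),
                            detector = detector_model("pcd")) {
  stopifnot(inherits(composition, "mvkv_composition"))
  cache <- spectral_cache(spectrum, basis, detector)
  T <- transmission(cache, composition$A)
  if (detector$kind == "pcd") {
    sum(cache$wc * T)
  } else {
    sum(cache$wE2 * T) + (cache$sigma_e * cache$Ebar)^2
  }
}

#' Dose delivered by one ray to the center of a 40-cm water cylinder
#'
#' Primary-beam collision kerma at 20-cm water depth:
#' \deqn{D = k \sum_E I(E)\, e^{-\mu_w(E)\cdot 20\,\mathrm{cm}}\,
#'  (\mu_{en}/\rho)_w(E)\, E}
#' with `k` converting keV/g to micrograys. No scatter buildup is modeled;
#' the quantity serves as the normalization target that fixes absolute
#' fluence. Linear in fluence; an empty or zero spectrum gives 0.
#'
#' @param spectrum an `mvkv_spectrum`.
#' @param depth_cm water depth (default 20, the center of a 40-cm
#'   cylinder).
#' @return dose in microgray (uGy).
#' @export
dose_per_ray <- function(spectrum, depth_cm = 20) {
  stopifnot(inherits(spectrum, "mvkv_spectrum"))
  if (sum(spectrum$fluence) == 0) return(0)
  water <- load_material("water")
  E <- spectrum$energies
  trans <- exp(-mass_atten(water, E) * water$density * depth_cm)
  KEV_PER_G_TO_UGY *
    sum(spectrum$fluence * trans * mass_energy_abs(water, E) * E)
}

#' Rescale a spectrum to deliver a target per-ray dose
#'
#' @param spectrum an `mvkv_spectrum` with positive dose.
#' @param dose_uGy target dose per ray in uGy.
#' @export
scale_to_dose <- function(spectrum, dose_uGy) {
  d <- dose_per_ray(spectrum)
  if (d <= 0) stop("spectrum delivers zero dose; cannot rescale",
                   call. = FALSE)
  new_spectrum(spectrum$energies, spectrum$fluence * dose_uGy / d,
               spectrum$label)
}

#' Split a fixed total dose between the MV and kV spectra
#'
#' Rescales the MV spectrum to deliver `r * total_uGy` per ray and the kV
#' spectrum to deliver the remaining `(1 - r) * total_uGy`, so the summed
#' per-ray dose is conserved exactly.
#'
#' @param mv,kv `mvkv_spectrum` objects.
#' @param r fraction of the total dose given to the MV spectrum, in
#'   `[0.01, 0.99]`.
#' @param total_uGy total per-ray dose in uGy (> 0).
#' @return list with rescaled spectra `mv` and `kv`.
#' @export
allocate_dose <- function(mv, kv, r, total_uGy = 1) {
  if (!is.numeric(r) || length(r) != 1L || r < 0.01 || r > 0.99) {
    stop("r must lie in [0.01, 0.99]", call. = FALSE)
  }
  if (total_uGy <= 0) stop("total dose must be > 0", call. = FALSE)
  list(mv = scale_to_dose(mv, r * total_uGy),
       kv = scale_to_dose(kv, (1 - r) * total_uGy))
}
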