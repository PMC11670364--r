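# Detector models. Both detector kinds share one detective-efficiency
# curve so that comparisons isolate the photon weighting scheme: an EID
# weights each detected photon by its energy (D(E) = E, in keV) and adds
# electronic readout noise; a non-spectral PCD counts photons with unit
# weight (D(E) = 1) and a low pulse-height threshold suppresses the
# electronic noise background entirely.

#' Shared detective efficiency curve
#'
#' Probability that a photon of energy `E_keV` contributes to the detector
#' signal, modeled on high-efficiency xenon-gas fan-beam detectors used for
#' megavoltage CT: unity up to 150 keV, then decreasing linearly in log
#' energy to 0.20 at 6 MeV. The same curve is applied to both detector
#' kinds.
#'
#' @param E_keV photon energies in keV, within `[10, 6000]`.
#' @return efficiency values in `[0.2, 1]`.
#' @export
detective_efficiency <- function(E_keV) {
  if (any(!is.finite(E_keV)) || any(E_keV < 10) || any(E_keV > 6000)) {
    stop("energy outside [10, 6000] keV", call. = FALSE)
  }
  eta <- 1 + (0.2 - 1) * (log(E_keV) - log(150)) / (log(6000) - log(150))
  pmin(pmax(eta, 0.2), 1)
}

#' Construct a detector model
#'
#' @param kind `"pcd"` (photon counting, unit response, no electronic
#'   noise) or `"eid"` (energy integrating, response `D(E) = E` keV,
#'   additive electronic noise).
#' @param electronic_noise_sd electronic noise standard deviation in
#'   counts; defaults to 10 for EID, must be 0 for PCD.
#' @param efficiency detective efficiency function of energy in keV;
#'   defaults to [detective_efficiency()].
#' @return an `mvkv_detector` with elements `kind`, `response` (function
#'   keV -> weight), `efficiency`, `electronic_noise_sd`.
#' @export
detector_model <- function(kind = c("pcd", "eid"),
                           electronic_noise_sd = NULL,
                           efficiency = detective_efficiency) {
  kind <- match.arg(kind)
  sd_default <- if (kind == "eid") 10 else 0
  sigma_e <- electronic_noise_sd %||% sd_default
  if (sigma_e < 0) stop("electronic_noise_sd must be >= 0", call. = FALSE)
  if (kind == "pcd" && sigma_e != 0) {
    stop("a PCD has no electronic noise (threshold suppression)",
         call. = FALSE)
  }
  response <- if (kind == "eid") function(E) E else function(E) rep(1, length(E))
  structure(list(kind = kind, response = response, efficiency = efficiency,
                 electronic_noise_sd = sigma_e),
            class = "mvkv_detector")
}

#' @export
print.mvkv_detector <- function(x, ...) {
  cat(sprintf("<mvkv_detector> %s  (D(E) = %s, sigma_e = %g counts)\n",
              toupper(x$kind), if (x$kind == "eid") "E" else "1",
              x$electronic_noise_sd))
  invisible(x)
}
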