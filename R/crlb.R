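# Fisher information / CRLB machinery for two-material, two-spectrum line
# integrals. The likelihood is Gaussian with mean lambda_i(A) and fixed
# variance v_i, so F_jk = sum_i (1/v_i) (d lambda_i / dA_j)
# (d lambda_i / dA_k); the variance-derivative term is omitted.

# Scale-separated per-spectrum quantities at unit dose. For a fluence
# scale factor c the Fisher contribution of spectrum i is
#   c^2 * M_i / (c * vq_i + add_i)
# with M_i the unit-dose gradient outer product, vq_i the unit-dose
# quantum variance and add_i the (scale-free) electronic variance.
fisher_parts <- function(spectrum, composition, basis, detector) {
  unit <- scale_to_dose(spectrum, 1)
  cache <- spectral_cache(unit, basis, detector)
  T <- transmission(cache, composition$A)
  wT <- cache$w * T
  grad <- -c(tissue = sum(wT * cache$mu[, "tissue"]),
             bone = sum(wT * cache$mu[, "bone"]))
  vq <- if (detector$kind == "pcd") sum(cache$wc * T) else sum(cache$wE2 * T)
  add <- if (detector$kind == "pcd") 0 else (cache$sigma_e * cache$Ebar)^2
  list(M = tcrossprod(grad), vq = vq, add = add)
}

fisher_from_parts <- function(parts, scales) {
  F <- matrix(0, 2, 2, dimnames = list(c("tissue", "bone"),
                                       c("tissue", "bone")))
  for (i in seq_along(parts)) {
    c_i <- scales[i]
    v <- c_i * parts[[i]]$vq + parts[[i]]$add
    if (v > 0 && c_i > 0) F <- F + c_i^2 * parts[[i]]$M / v
  }
  structure(F, class = c("mvkv_fisher", "matrix"))
}

#' Fisher information matrix for a two-spectrum, two-material ray
#'
#' Assembles the 2x2 Fisher information matrix for the basis mass
#' thicknesses \eqn{(A_{tissue}, A_{bone})} measured with a pair of
#' spectra (typically MV and kV) and one detector model:
#' \deqn{F_{jk} = \sum_i \frac{1}{v_i}
#'   \frac{\partial\lambda_i}{\partial A_j}
#'   \frac{\partial\lambda_i}{\partial A_k}}
#' with \eqn{\partial\lambda_i/\partial A_j =
#' -\sum_E I_i e^{-\sum_m (\mu/\rho)_m A_m} (\mu/\rho)_j \eta D} and
#' \eqn{v_i} from [signal_variance()]. Units (g/cm^2)^-2. Spectra are used
#' at their current (already dose-allocated) fluence scale.
#'
#' @param spectra list of two `mvkv_spectrum` objects.
#' @param composition an `mvkv_composition`.
#' @param basis basis material pair.
#' @param detector an `mvkv_detector`.
#' @return 2x2 symmetric positive-semidefinite matrix, class
#'   `mvkv_fisher`. Singular when the two spectra carry no independent
#'   material information (e.g. identical spectra).
#' @export
fisher_matrix <- function(spectra, composition, basis = default_basis(),
                          detector = detector_model("pcd")) {
  stopifnot(length(spectra) == 2L, inherits(composition, "mvkv_composition"))
  F <- matrix(0, 2, 2, dimnames = list(c("tissue", "bone"),
                                       c("tissue", "bone")))
  for (sp in spectra) {
    cache <- spectral_cache(sp, basis, detector)
    T <- transmission(cache, composition$A)
    wT <- cache$w * T
    grad <- -c(sum(wT * cache$mu[, "tissue"]), sum(wT * cache$mu[, "bone"]))
    v <- if (detector$kind == "pcd") sum(cache$wc * T) else
      sum(cache$wE2 * T) + (cache$sigma_e * cache$Ebar)^2
    if (v > 0) F <- F + tcrossprod(grad) / v
  }
  structure(F, class = c("mvkv_fisher", "matrix"))
}

#' Cramer-Rao lower bound on basis mass-thickness variance
#'
#' Inverts the Fisher matrix and returns the diagonal,
#' \eqn{\sigma^2_{A_j} = (F^{-1})_{jj}} in (g/cm^2)^2. Each bound is at
#' least the reciprocal of the corresponding diagonal Fisher entry
#' (marginal vs. conditional information).
#'
#' @param F a 2x2 Fisher matrix.
#' @return named vector `c(tissue=, bone=)` of variances.
#' @export
crlb_variance <- function(F) {
  F <- unclass(F)
  det_F <- F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1]
  scale <- max(abs(F))
  if (scale == 0 || abs(det_F) < 1e-12 * scale^2) {
    stop("Fisher matrix is singular: CRLB is infinite", call. = FALSE)
  }
  inv_diag <- c(F[2, 2], F[1, 1]) / det_F
  stats::setNames(inv_diag, c("tissue", "bone"))
}

#' Basis-material SNR of a single dose-allocated ray
#'
#' Allocates the total per-ray dose between the MV and kV spectra, builds
#' the Fisher matrix, and returns the unitless basis-material
#' signal-to-noise ratios \eqn{A_j / \sigma_{A_j}} with
#' \eqn{\sigma^2_{A_j}} the CRLB.
#'
#' @param mv,kv unscaled `mvkv_spectrum` objects.
#' @param composition an `mvkv_composition`.
#' @param basis basis material pair.
#' @param detector an `mvkv_detector`.
#' @param r MV dose fraction in `[0.01, 0.99]`.
#' @param total_dose_uGy total per-ray dose in uGy (default 1).
#' @return list of class `mvkv_snr`: `snr`, `crlb` (named vectors), `r`,
#'   `total_dose_uGy`, `detector`.
#' @export
basis_snr <- function(mv, kv, composition, basis = default_basis(),
                      detector = detector_model("pcd"), r = 0.5,
                      total_dose_uGy = 1) {
  alloc <- allocate_dose(mv, kv, r, total_dose_uGy)
  F <- fisher_matrix(list(alloc$mv, alloc$kv), composition, basis, detector)
  crlb <- crlb_variance(F)
  structure(list(snr = composition$A / sqrt(crlb), crlb = crlb, r = r,
                 total_dose_uGy = total_dose_uGy, detector = detector$kind),
            class = "mvkv_snr")
}

#' @export
print.mvkv_snr <- function(x, ...) {
  cat(sprintf(
    "<mvkv_snr> %s  r = %.2f, dose %.3g uGy: SNR tissue %.4g, bone %.4g\n",
    toupper(x$detector), x$r, x$total_dose_uGy,
    x$snr[["tissue"]], x$snr[["bone"]]))
  invisible(x)
}

#' Optimize the MV dose-allocation fraction per basis material
#'
#' Sweeps the MV dose fraction `r` over a grid and returns, independently
#' for each basis material, the `r` maximizing its SNR (ties broken toward
#' smaller `r`).
#'
#' @inheritParams basis_snr
#' @param r_grid increasing grid of allocation fractions within
#'   `[0.01, 0.99]` (default 99 points, step 0.01).
#' @return list: `r_opt` (named vector), `snr_opt` (SNR of each material
#'   at its own optimum), `curves` (data frame `r`, `snr_tissue`,
#'   `snr_bone`).
#' @export
optimize_allocation <- function(mv, kv, composition,
                                basis = default_basis(),
                                detector = detector_model("pcd"),
                                total_dose_uGy = 1,
                                r_grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(r_grid) < 1L) stop("r_grid is empty", call. = FALSE)
  if (any(r_grid < 0.01) || any(r_grid > 0.99)) {
    stop("r_grid must lie within [0.01, 0.99]", call. = FALSE)
  }
  r_grid <- sort(r_grid)
  parts <- list(fisher_parts(mv, composition, basis, detector),
                fisher_parts(kv, composition, basis, detector))
  snr <- matrix(NA_real_, length(r_grid), 2,
                dimnames = list(NULL, c("tissue", "bone")))
  for (k in seq_along(r_grid)) {
    F <- fisher_from_parts(parts, total_dose_uGy *
                             c(r_grid[k], 1 - r_grid[k]))
    crlb <- crlb_variance(F)
    snr[k, ] <- composition$A / sqrt(crlb)
  }
  idx <- apply(snr, 2, which.max)  # first max = smallest r on ties
  list(
    r_opt = stats::setNames(r_grid[idx], c("tissue", "bone")),
    snr_opt = stats::setNames(c(snr[idx[1], 1], snr[idx[2], 2]),
                              c("tissue", "bone")),
    curves = data.frame(r = r_grid, snr_tissue = snr[, "tissue"],
                        snr_bone = snr[, "bone"])
  )
}

#' Dose-optimized SNR surface over tissue/bone thickness grids
#'
#' For every thickness pair on the grid, optimizes the MV dose fraction
#' per material for both detector models and records the optimized SNRs,
#' the optimizing fractions, and the percent improvement of the PCD over
#' the EID.
#'
#' @param mv,kv unscaled `mvkv_spectrum` objects.
#' @param tissue_cm,bone_cm thickness grids in cm (tissue nominally
#'   10-50 cm, bone 0.1-10 cm).
#' @param basis basis material pair.
#' @param total_dose_uGy total per-ray dose in uGy.
#' @param r_grid allocation-fraction grid.
#' @param detectors named list of the two detector models to compare.
#' @return data frame of class `mvkv_snr_surface`, one row per thickness
#'   pair, columns `t_tissue_cm`, `t_bone_cm`,
#'   `snr_<material>_<detector>`, `r_opt_<material>_<detector>`, and
#'   `pct_improvement_<material>` (100 * (PCD - EID) / EID).
#' @export
snr_surface <- function(mv, kv,
                        tissue_cm = seq(10, 50, length.out = 17),
                        bone_cm = exp(seq(log(0.1), log(10),
                                          length.out = 21)),
                        basis = default_basis(), total_dose_uGy = 1,
                        r_grid = seq(0.01, 0.99, by = 0.01),
                        detectors = list(pcd = detector_model("pcd"),
                                         eid = detector_model("eid"))) {
  stopifnot(all(tissue_cm >= 0), all(bone_cm >= 0))
  grid <- expand.grid(t_tissue_cm = tissue_cm, t_bone_cm = bone_cm,
                      KEEP.OUT.ATTRS = FALSE)
  out <- grid
  for (dname in names(detectors)) {
    det <- detectors[[dname]]
    res <- lapply(seq_len(nrow(grid)), function(i) {
      comp <- ray_composition(grid$t_tissue_cm[i], grid$t_bone_cm[i], basis)
      optimize_allocation(mv, kv, comp, basis, det, total_dose_uGy, r_grid)
    })
    out[[paste0("snr_tissue_", dname)]] <-
      vapply(res, function(x) x$snr_opt[["tissue"]], 0)
    out[[paste0("snr_bone_", dname)]] <-
      vapply(res, function(x) x$snr_opt[["bone"]], 0)
    out[[paste0("r_opt_tissue_", dname)]] <-
      vapply(res, function(x) x$r_opt[["tissue"]], 0)
    out[[paste0("r_opt_bone_", dname)]] <-
      vapply(res, function(x) x$r_opt[["bone"]], 0)
  }
  if (all(c("pcd", "eid") %in% names(detectors))) {
    out$pct_improvement_tissue <-
      100 * (out$snr_tissue_pcd - out$snr_tissue_eid) / out$snr_tissue_eid
    out$pct_improvement_bone <-
      100 * (out$snr_bone_pcd - out$snr_bone_eid) / out$snr_bone_eid
  }
  class(out) <- c("mvkv_snr_surface", "data.frame")
  out
}
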