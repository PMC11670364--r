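# Equiangular fan-beam filtered back-projection, virtual monoenergetic
# image synthesis, HU conversion, CNR and noise-map analysis.

# Band-limited ramp kernel sampled at gamma spacing dg, cut at frac of the
# Nyquist limit, with the equiangular (gamma / sin gamma)^2 modification.
ramp_kernel <- function(n_channels, dg, cutoff_frac = 0.8) {
  fc <- cutoff_frac / (2 * dg)  # cycles per radian
  n <- seq(-(n_channels - 1), n_channels - 1)
  x <- n * dg
  sinc <- function(u) ifelse(u == 0, 1, sin(pi * u) / (pi * u))
  h <- 2 * fc^2 * sinc(2 * fc * x) - fc^2 * sinc(fc * x)^2
  eqmod <- ifelse(n == 0, 1, (x / sin(x))^2)
  0.5 * h * eqmod
}

#' Fan-beam filtered back-projection of a basis sinogram
#'
#' Equiangular fan-beam FBP: cosine pre-weighting of each channel by
#' `SID * cos(gamma)`, row filtering with a band-limited ramp cut at 80%
#' of the Nyquist limit (no apodization window), and distance-weighted
#' (`1/L^2`) back-projection over the full rotation. A sinogram of basis
#' mass thickness (g/cm^2, i.e. line integrals of density in g/cm^3)
#' reconstructs to basis density in g/cm^3.
#'
#' @param values sinogram matrix (`n_views` x `n_channels`) of line
#'   integrals, or an `mvkv_decomposition` basis matrix.
#' @param geometry the `mvkv_geometry` of the acquisition.
#' @param n output matrix size (default 512).
#' @param fov_cm reconstruction field of view in cm (default 50).
#' @param cutoff_frac ramp cutoff as a fraction of Nyquist (default 0.8).
#' @return an `mvkv_image`: `pixels` (`n` x `n`), `fov_cm`, `units`.
#' @export
fbp_reconstruct <- function(values, geometry, n = 512, fov_cm = 50,
                            cutoff_frac = 0.8) {
  stopifnot(inherits(geometry, "mvkv_geometry"))
  if (!all(dim(values) == c(geometry$n_views, geometry$n_channels))) {
    stop("sinogram shape does not match the geometry", call. = FALSE)
  }
  nv <- geometry$n_views; nc <- geometry$n_channels
  fan <- deg2rad(geometry$fan_angle_deg)
  dg <- fan / nc
  gamma <- -fan / 2 + (seq_len(nc) - 0.5) * dg
  dbeta <- deg2rad(geometry$arc_deg) / nv

  # frequency-domain convolution with the sampled kernel
  g <- ramp_kernel(nc, dg, cutoff_frac)
  nfft <- 2^ceiling(log2(2 * nc))
  gpad <- numeric(nfft)
  gpad[1:nc] <- g[nc:(2 * nc - 1)]          # non-negative lags
  gpad[(nfft - nc + 2):nfft] <- g[1:(nc - 1)]  # negative lags wrapped
  Gf <- stats::fft(gpad)
  P <- t(values) * (geometry$sid * cos(gamma))  # nc x nv, pre-weighted
  Ppad <- matrix(0, nfft, nv)
  Ppad[1:nc, ] <- P
  Q <- Re(stats::mvfft(stats::mvfft(Ppad) * Gf, inverse = TRUE)) / nfft
  Q <- Q[1:nc, , drop = FALSE] * dg  # filtered projections

  ax <- pixel_axis(n, fov_cm)
  px <- matrix(ax, n, n); py <- matrix(ax, n, n, byrow = TRUE)
  img <- matrix(0, n, n)
  for (v in seq_len(nv)) {
    beta <- deg2rad((v - 1) * geometry$arc_deg / nv)
    sx <- geometry$sid * sin(beta); sy <- geometry$sid * cos(beta)
    d0x <- -sin(beta); d0y <- -cos(beta)
    dx <- px - sx; dy <- py - sy
    L2 <- dx^2 + dy^2
    gpix <- atan2(d0x * dy - d0y * dx, d0x * dx + d0y * dy)
    # channel angles rotate as u = R(gamma) d0 with the same sign as gpix
    idx <- (gpix + fan / 2) / dg + 0.5
    i0 <- floor(idx)
    frac <- idx - i0
    q <- Q[, v]
    valid <- i0 >= 1 & i0 < nc
    qi <- numeric(length(idx))
    qi[valid] <- q[i0[valid]] * (1 - frac[valid]) +
      q[i0[valid] + 1] * frac[valid]
    img <- img + dbeta * qi / L2
  }
  structure(list(pixels = img, fov_cm = fov_cm, units = "g/cm^3"),
            class = "mvkv_image")
}

#' @export
print.mvkv_image <- function(x, ...) {
  cat(sprintf("<mvkv_image> %d x %d, fov %g cm, units %s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$fov_cm, x$units,
              if (!is.null(x$E0_keV)) sprintf(" @ %g keV", x$E0_keV) else ""))
  invisible(x)
}

as_image <- function(pixels, fov_cm, units, E0_keV = NULL) {
  structure(list(pixels = pixels, fov_cm = fov_cm, units = units,
                 E0_keV = E0_keV), class = "mvkv_image")
}

#' Virtual monoenergetic image from basis-density images
#'
#' Pixelwise linear combination of the reconstructed basis densities with
#' the tabulated mass attenuation coefficients at the requested energy:
#' \deqn{VMI(E_0) = \rho_1 (\mu/\rho)_1(E_0) + \rho_2 (\mu/\rho)_2(E_0)}
#' giving linear attenuation in 1/cm.
#'
#' @param rho_tissue,rho_bone `mvkv_image` basis-density images (g/cm^3)
#'   of matching shape.
#' @param E0_keV monoenergy in keV, within `[20, 120]`.
#' @param basis basis material pair.
#' @return an `mvkv_image` in 1/cm tagged with `E0_keV`.
#' @export
synthesize_vmi <- function(rho_tissue, rho_bone, E0_keV,
                           basis = default_basis()) {
  stopifnot(inherits(rho_tissue, "mvkv_image"),
            inherits(rho_bone, "mvkv_image"))
  if (E0_keV < 20 || E0_keV > 120) {
    stop("VMI energy must lie in [20, 120] keV", call. = FALSE)
  }
  if (!all(dim(rho_tissue$pixels) == dim(rho_bone$pixels))) {
    stop("basis images must have matching shapes", call. = FALSE)
  }
  mu <- rho_tissue$pixels * mass_atten(basis$tissue, E0_keV) +
    rho_bone$pixels * mass_atten(basis$bone, E0_keV)
  as_image(mu, rho_tissue$fov_cm, "1/cm", E0_keV)
}

#' Convert a linear-attenuation image to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water(E0)) / mu_water(E0)`.
#'
#' @param vmi an `mvkv_image` in 1/cm.
#' @param E0_keV energy at which water attenuation is evaluated (defaults
#'   to the VMI's energy tag).
#' @export
to_hu <- function(vmi, E0_keV = vmi$E0_keV) {
  stopifnot(inherits(vmi, "mvkv_image"))
  if (is.null(E0_keV)) stop("E0_keV required", call. = FALSE)
  water <- load_material("water")
  mu_w <- mass_atten(water, E0_keV) * water$density
  as_image(1000 * (vmi$pixels - mu_w) / mu_w, vmi$fov_cm, "HU", E0_keV)
}

#' Contrast-to-noise ratio between two regions of interest
#'
#' `CNR = |mean(insert) - mean(background)| / sd(background)`.
#'
#' @param image an `mvkv_image` or numeric matrix.
#' @param insert,background disjoint non-empty logical masks matching the
#'   image shape.
#' @export
measure_cnr <- function(image, insert, background) {
  pix <- if (inherits(image, "mvkv_image")) image$pixels else image
  stopifnot(is.logical(insert), is.logical(background),
            all(dim(insert) == dim(pix)), all(dim(background) == dim(pix)))
  if (!any(insert) || !any(background)) {
    stop("masks must be non-empty", call. = FALSE)
  }
  if (any(insert & background)) stop("masks must be disjoint", call. = FALSE)
  s <- stats::sd(pix[background])
  if (s == 0) stop("zero background standard deviation: CNR undefined",
                   call. = FALSE)
  abs(mean(pix[insert]) - mean(pix[background])) / s
}

#' Pixelwise noise map over noisy realizations
#'
#' Elementwise sample standard deviation (n-1 denominator) across a list
#' of images of identical shape.
#'
#' @param realizations list of at least two `mvkv_image`s or matrices.
#' @return an `mvkv_image` of per-pixel standard deviations.
#' @export
noise_map <- function(realizations) {
  if (length(realizations) < 2L) {
    stop("need at least two realizations", call. = FALSE)
  }
  mats <- lapply(realizations, function(x)
    if (inherits(x, "mvkv_image")) x$pixels else x)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == d), TRUE))) {
    stop("realizations must have matching shapes", call. = FALSE)
  }
  n <- length(mats)
  s <- Reduce(`+`, mats)
  s2 <- Reduce(`+`, lapply(mats, function(m) m^2))
  sd_map <- sqrt(pmax(s2 - s^2 / n, 0) / (n - 1))
  fov <- if (inherits(realizations[[1]], "mvkv_image"))
    realizations[[1]]$fov_cm else NA_real_
  units <- if (inherits(realizations[[1]], "mvkv_image"))
    realizations[[1]]$units else "arb"
  as_image(sd_map, fov, units)
}

#' Insert and background ROI masks for the IQ phantom
#'
#' Insert ROIs are the known insert disks eroded by `erode_px` pixel
#' widths. The background ROI samples the uniform tissue between the
#' cylinder center and the insert ring: an annulus spanning 35-75% of
#' the ring radius by default, kept clear of every insert by
#' `margin_cm`. Placing the background in uniform tissue (rather than
#' against the insert edges) keeps the background standard deviation a
#' measure of image noise and residual texture instead of edge ringing.
#'
#' @param phantom the IQ phantom (first primitive = cylinder, others =
#'   inserts).
#' @param n image matrix size.
#' @param fov_cm image field of view.
#' @param erode_px erosion of the insert masks in pixels (default 2).
#' @param margin_cm exclusion margin around inserts for the background
#'   (default 1).
#' @param bg_radii_cm length-2 inner/outer background annulus radii;
#'   defaults to `c(0.35, 0.75)` of the insert ring radius.
#' @return list `inserts` (named by density, logical matrices) and
#'   `background`.
#' @export
iq_roi_masks <- function(phantom, n = 512, fov_cm = 50, erode_px = 2,
                         margin_cm = 1, bg_radii_cm = NULL) {
  stopifnot(inherits(phantom, "mvkv_phantom"), length(phantom$primitives) > 1)
  ax <- pixel_axis(n, fov_cm)
  px <- matrix(ax, n, n); py <- matrix(ax, n, n, byrow = TRUE)
  pxsz <- fov_cm / n
  inserts <- phantom$primitives[-1]
  r_ring <- vapply(inserts, function(p) sqrt(sum(p$center^2)), 0)
  masks <- lapply(seq_along(inserts), function(k) {
    p <- inserts[[k]]
    r_eff <- max(p$radii[1] - erode_px * pxsz, pxsz)  # keep ROIs non-empty
    (px - p$center[1])^2 + (py - p$center[2])^2 <= r_eff^2
  })
  names(masks) <- vapply(inserts, function(p) sprintf("%.1f", p$density), "")
  if (is.null(bg_radii_cm)) bg_radii_cm <- c(0.35, 0.75) * max(r_ring)
  rad <- sqrt(px^2 + py^2)
  band <- rad >= bg_radii_cm[1] & rad <= bg_radii_cm[2]
  for (k in seq_along(inserts)) {
    p <- inserts[[k]]
    band <- band & ((px - p$center[1])^2 + (py - p$center[2])^2 >
                      (p$radii[1] + margin_cm)^2)
  }
  list(inserts = masks, background = band)
}

#' Export an image to PNG with window/level display scaling
#'
#' Linear window/level mapping to 8-bit grayscale (values outside the
#' window are clipped). Requires the `png` package.
#'
#' @param image an `mvkv_image` or matrix.
#' @param path output file.
#' @param level,width display window center and width (e.g. level 0,
#'   width 1000 for HU display).
#' @export
write_image_png <- function(image, path, level = 0, width = 1000) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export", call. = FALSE)
  }
  pix <- if (inherits(image, "mvkv_image")) image$pixels else image
  lo <- level - width / 2
  scaled <- pmin(pmax((pix - lo) / width, 0), 1)
  # transpose so image x/y map to PNG column/row, y up
  png::writePNG(t(scaled)[rev(seq_len(ncol(scaled))), , drop = FALSE], path)
  invisible(path)
}
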