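# Fan-beam geometry, analytic polychromatic forward projection, and seeded
# per-energy-bin Poisson noise injection.

#' Equiangular fan-beam acquisition geometry
#'
#' Defaults follow a tomotherapy-style fan-beam system: 55-cm
#' source-to-isocenter and 100-cm source-to-detector distances, 800
#' equiangular channels spanning a 50-degree fan, 1200 views over a full
#' 360-degree rotation. The first view places the source at 12 o'clock;
#' channels are centered on the ray through the isocenter.
#'
#' @param source_to_isocenter_cm,source_to_detector_cm distances in cm.
#' @param n_channels number of detector channels.
#' @param fan_angle_deg total fan angle in degrees.
#' @param n_views number of projection views.
#' @param arc_deg rotation arc in degrees.
#' @return an `mvkv_geometry`.
#' @export
fan_beam_geometry <- function(source_to_isocenter_cm = 55,
                              source_to_detector_cm = 100,
                              n_channels = 800, fan_angle_deg = 50,
                              n_views = 1200, arc_deg = 360) {
  stopifnot(source_to_detector_cm > source_to_isocenter_cm,
            source_to_isocenter_cm > 0, n_channels >= 1, n_views >= 1,
            fan_angle_deg > 0, arc_deg > 0)
  structure(list(sid = source_to_isocenter_cm, sdd = source_to_detector_cm,
                 n_channels = as.integer(n_channels),
                 fan_angle_deg = fan_angle_deg,
                 n_views = as.integer(n_views), arc_deg = arc_deg),
            class = "mvkv_geometry")
}

#' @export
print.mvkv_geometry <- function(x, ...) {
  cat(sprintf(
    "<mvkv_geometry> SID %g cm, SDD %g cm, %d ch x %g deg fan, %d views / %g deg\n",
    x$sid, x$sdd, x$n_channels, x$fan_angle_deg, x$n_views, x$arc_deg))
  invisible(x)
}

# Source positions and per-channel unit ray directions for one view.
view_rays <- function(geometry, view_index) {
  beta <- deg2rad((view_index - 1) * geometry$arc_deg / geometry$n_views)
  S <- geometry$sid * c(sin(beta), cos(beta))
  d0 <- -c(sin(beta), cos(beta))
  fan <- deg2rad(geometry$fan_angle_deg)
  gamma <- -fan / 2 + (seq_len(geometry$n_channels) - 0.5) *
    fan / geometry$n_channels
  ux <- d0[1] * cos(gamma) - d0[2] * sin(gamma)
  uy <- d0[1] * sin(gamma) + d0[2] * cos(gamma)
  list(S = S, ux = ux, uy = uy, gamma = gamma)
}

#' Trace basis mass-thickness sinograms through a phantom
#'
#' Exact analytic ray-primitive intersections for every (view, channel)
#' ray, density-scaled into basis mass thicknesses (g/cm^2).
#'
#' @param phantom an `mvkv_phantom`.
#' @param geometry an `mvkv_geometry`.
#' @return list of class `mvkv_paths`: matrices `A_tissue`, `A_bone`
#'   (`n_views` x `n_channels`, g/cm^2) and the `geometry`.
#' @export
trace_path_lengths <- function(phantom, geometry = fan_beam_geometry()) {
  stopifnot(inherits(phantom, "mvkv_phantom"),
            inherits(geometry, "mvkv_geometry"))
  nv <- geometry$n_views; nc <- geometry$n_channels
  A1 <- matrix(0, nv, nc); A2 <- matrix(0, nv, nc)
  for (v in seq_len(nv)) {
    rays <- view_rays(geometry, v)
    A <- trace_basis_mass(phantom, rep(rays$S[1], nc), rep(rays$S[2], nc),
                          rays$ux, rays$uy)
    A1[v, ] <- A$tissue
    A2[v, ] <- A$bone
  }
  structure(list(A_tissue = A1, A_bone = A2, geometry = geometry),
            class = "mvkv_paths")
}

#' Polychromatic expected-signal sinogram
#'
#' Applies the per-ray signal model to every (view, channel) path, giving
#' the noiseless expected detected signal, together with the air-scan
#' reference (expected signal at zero thickness). The returned sinogram
#' retains the inputs needed by [add_noise()].
#'
#' @param paths an `mvkv_paths` from [trace_path_lengths()].
#' @param spectrum a dose-allocated `mvkv_spectrum`.
#' @param detector an `mvkv_detector`.
#' @param basis basis material pair.
#' @return an `mvkv_sinogram`: `values` (`n_views` x `n_channels`), `air`
#'   (scalar air-scan value), plus geometry/detector/spectrum metadata.
#' @export
simulate_measurement <- function(paths, spectrum,
                                 detector = detector_model("pcd"),
                                 basis = default_basis()) {
  stopifnot(inherits(paths, "mvkv_paths"))
  cache <- spectral_cache(spectrum, basis, detector)
  nv <- nrow(paths$A_tissue)
  vals <- matrix(0, nv, ncol(paths$A_tissue))
  for (v in seq_len(nv)) {  # chunk by view to bound memory
    T <- exp(-(outer(paths$A_tissue[v, ], cache$mu[, "tissue"]) +
                 outer(paths$A_bone[v, ], cache$mu[, "bone"])))
    vals[v, ] <- as.numeric(T %*% cache$w)
  }
  structure(list(values = vals, air = sum(cache$w),
                 geometry = paths$geometry, paths = paths,
                 spectrum = spectrum, detector = detector, basis = basis,
                 noisy = FALSE),
            class = "mvkv_sinogram")
}

#' Inject detector noise into an expected-signal sinogram
#'
#' Samples detected counts per energy bin as independent Poisson variates
#' (exact compound model). For a PCD the noisy signal is the summed
#' counts; for an EID it is the energy-weighted count sum plus additive
#' Gaussian electronic noise with standard deviation
#' \eqn{\sigma_e \bar E}. Results are clamped to a small positive floor
#' (1e-6 of the air value) so that log-transmission stays defined.
#'
#' @param sinogram an `mvkv_sinogram` from [simulate_measurement()].
#' @param seed integer seed; identical seeds give identical realizations.
#' @return an `mvkv_sinogram` with noisy `values`.
#' @export
add_noise <- function(sinogram, seed) {
  stopifnot(inherits(sinogram, "mvkv_sinogram"))
  if (isTRUE(sinogram$noisy)) {
    stop("sinogram is already noisy; noise is added to expected signals",
         call. = FALSE)
  }
  cache <- spectral_cache(sinogram$spectrum, sinogram$basis,
                          sinogram$detector)
  det <- sinogram$detector
  paths <- sinogram$paths
  nv <- nrow(paths$A_tissue); nc <- ncol(paths$A_tissue)
  floor_val <- 1e-6 * sinogram$air
  out <- with_seed(seed, {
    vals <- matrix(0, nv, nc)
    for (v in seq_len(nv)) {
      T <- exp(-(cache$mu[, "tissue"] %o% paths$A_tissue[v, ] +
                   cache$mu[, "bone"] %o% paths$A_bone[v, ]))
      lam <- cache$wc * T  # nE x n_channels, detected counts per bin
      counts <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
      sig <- as.numeric(crossprod(counts, cache$D))
      if (det$kind == "eid" && det$electronic_noise_sd > 0) {
        sig <- sig + stats::rnorm(nc, 0,
                                  det$electronic_noise_sd * cache$Ebar)
      }
      vals[v, ] <- pmax(sig, floor_val)
    }
    vals
  })
  res <- sinogram
  res$values <- out
  res$noisy <- TRUE
  res$seed <- seed
  res
}

#' @export
print.mvkv_sinogram <- function(x, ...) {
  cat(sprintf(
    "<mvkv_sinogram> %d views x %d channels, %s, %s%s, air = %.4g\n",
    nrow(x$values), ncol(x$values), x$spectrum$label,
    toupper(x$detector$kind), if (isTRUE(x$noisy)) " (noisy)" else "",
    x$air))
  invisible(x)
}

#' Read / write a sinogram or image as flat 32-bit floats with sidecar
#'
#' Binary little-endian float32 in row-major order plus a YAML sidecar
#' (`<path>.yml`) holding the dimensions and metadata. Intended for run
#' outputs; bundled test fixtures use plain text instead.
#'
#' @param values numeric matrix.
#' @param path output path for the binary payload.
#' @param meta named list of extra metadata for the sidecar.
#' @return `write_flat32()` returns `path` invisibly; `read_flat32()`
#'   returns a matrix with the sidecar attached as attribute `"meta"`.
#' @export
write_flat32 <- function(values, path, meta = list()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
  yaml::write_yaml(c(list(n_rows = nrow(values), n_cols = ncol(values),
                          dtype = "float32", order = "row-major"), meta),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_flat32
#' @export
read_flat32 <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  n <- meta$n_rows * meta$n_cols
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  m <- matrix(raw, meta$n_rows, meta$n_cols, byrow = TRUE)
  attr(m, "meta") <- meta
  m
}
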