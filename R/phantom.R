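# Procedural 2-D phantoms built from circle/ellipse primitives. Primitives
# later in the list override earlier ones where contained (painter's
# order); containment is recorded explicitly via a `parent` index so that
# analytic ray tracing can subtract the parent's contribution exactly.

new_primitive <- function(shape = c("circle", "ellipse"), center, radii,
                          material, density, parent = NA_integer_) {
  shape <- match.arg(shape)
  if (shape == "circle") radii <- rep(radii[1], 2)
  stopifnot(length(center) == 2L, length(radii) == 2L, all(radii > 0),
            density > 0)
  list(shape = shape, center = as.numeric(center),
       radii = as.numeric(radii), material = material,
       density = as.numeric(density), parent = as.integer(parent))
}

#' Construct a 2-D phantom from geometric primitives
#'
#' Each primitive is a circle or axis-aligned ellipse with a material name
#' (`"tissue"` or `"bone"`, selecting the basis curve used for its
#' attenuation) and its own density in g/cm^3. A primitive drawn after
#' another and fully contained in it must reference the container through
#' `parent`; ray tracing then replaces the parent's material along the
#' overlapping chord.
#'
#' @param primitives list of primitives from the `prim_*` helpers.
#' @param extent field-of-view width in cm (default 50).
#' @return an `mvkv_phantom`.
#' @seealso [make_iq_phantom()], [make_torso_phantom()]
#' @export
phantom2d <- function(primitives, extent = 50) {
  stopifnot(length(primitives) >= 0, extent > 0)
  for (p in primitives) {
    if (max(abs(p$center) + p$radii) > extent / 2 + 1e-9) {
      stop("primitive extends beyond the field of view", call. = FALSE)
    }
    if (!is.na(p$parent) &&
        (p$parent < 1L || p$parent > length(primitives))) {
      stop("invalid parent index", call. = FALSE)
    }
  }
  structure(list(primitives = primitives, extent = extent),
            class = "mvkv_phantom")
}

#' @rdname phantom2d
#' @param center,radii geometry in cm (`radii` is a scalar radius for
#'   `prim_circle()`, length-2 semi-axes for `prim_ellipse()`).
#' @param material `"tissue"` or `"bone"`.
#' @param density density in g/cm^3.
#' @param parent index of the containing primitive, or `NA` for none.
#' @export
prim_circle <- function(center, radii, material, density,
                        parent = NA_integer_) {
  new_primitive("circle", center, radii, material, density, parent)
}

#' @rdname phantom2d
#' @export
prim_ellipse <- function(center, radii, material, density,
                         parent = NA_integer_) {
  new_primitive("ellipse", center, radii, material, density, parent)
}

#' Image-quality phantom: tissue cylinder with seven bone inserts
#'
#' A 40-cm diameter soft-tissue cylinder (1.06 g/cm^3) holding seven
#' 3-cm diameter bone-material inserts with densities 1.0, 1.2, ..., 2.2
#' g/cm^3 arranged on a ring. The densest insert sits at 12 o'clock and
#' density decreases clockwise. The exact layout is configurable.
#'
#' @param ring_radius_cm radius of the insert ring (default 12).
#' @param insert_radius_cm insert radius (default 1.5).
#' @param densities insert densities in g/cm^3.
#' @return an `mvkv_phantom` (extent 50 cm).
#' @export
make_iq_phantom <- function(ring_radius_cm = 12, insert_radius_cm = 1.5,
                            densities = seq(2.2, 1.0, by = -0.2)) {
  n <- length(densities)
  ang <- 90 - (seq_len(n) - 1) * 360 / n  # degrees, clockwise from top
  prims <- vector("list", n + 1L)
  prims[[1L]] <- prim_circle(c(0, 0), 20, "tissue", 1.06)
  for (k in seq_len(n)) {
    prims[[k + 1L]] <- prim_circle(
      ring_radius_cm * c(cos(deg2rad(ang[k])), sin(deg2rad(ang[k]))),
      insert_radius_cm, "bone", densities[k], parent = 1L)
  }
  phantom2d(prims, extent = 50)
}

#' Procedural torso phantom
#'
#' A synthetic anthropomorphic slice standing in for a licensed voxel
#' torso: an elliptical soft-tissue body with two low-density lungs, a
#' spine, and two lateral bone structures, sized so that central-channel
#' basis thickness profiles resemble a human thorax (tissue-equivalent
#' roughly 18-32 cm, bone-equivalent up to about 5 cm). The `seed` adds
#' small deterministic jitter to organ positions and densities.
#'
#' @param seed integer seed controlling the jitter (default 1).
#' @return an `mvkv_phantom` (extent 50 cm).
#' @export
make_torso_phantom <- function(seed = 1) {
  j <- with_seed(seed, list(pos = stats::runif(6, -0.2, 0.2),
                            den = stats::runif(3, -0.03, 0.03)))
  body <- prim_ellipse(c(0, 0), c(16, 11.5), "tissue", 1.06)
  lung_l <- prim_ellipse(c(-6.5 + j$pos[1], 1.5 + j$pos[2]), c(3.8, 4.8),
                         "tissue", 0.35 + j$den[1], parent = 1L)
  lung_r <- prim_ellipse(c(6.5 + j$pos[3], 1.5 + j$pos[4]), c(3.8, 4.8),
                         "tissue", 0.35 + j$den[2], parent = 1L)
  spine <- prim_circle(c(0 + j$pos[5], -6.5 + j$pos[6]), 1.8, "bone",
                       1.9 + j$den[3], parent = 1L)
  rib_l <- prim_circle(c(-13.5, -3), 1.0, "bone", 1.5, parent = 1L)
  rib_r <- prim_circle(c(13.5, -3), 1.0, "bone", 1.5, parent = 1L)
  phantom2d(list(body, lung_l, lung_r, spine, rib_l, rib_r), extent = 50)
}

# Chord length of the line p + t*u (|u| = 1) through an axis-aligned
# ellipse primitive; vectorized over rays.
prim_chord <- function(prim, px, py, ux, uy) {
  rx <- prim$radii[1]; ry <- prim$radii[2]
  dx <- (px - prim$center[1]) / rx
  dy <- (py - prim$center[2]) / ry
  vx <- ux / rx; vy <- uy / ry
  a <- vx^2 + vy^2
  b <- 2 * (dx * vx + dy * vy)
  cc <- dx^2 + dy^2 - 1
  disc <- b^2 - 4 * a * cc
  ifelse(disc > 0, sqrt(pmax(disc, 0)) / a, 0)
}

# Accumulate basis mass thicknesses (g/cm^2) for a set of rays. Each
# primitive contributes chord * density to its own basis and, when nested,
# removes chord * parent_density from the parent's basis.
trace_basis_mass <- function(phantom, px, py, ux, uy) {
  A <- list(tissue = numeric(length(px)), bone = numeric(length(px)))
  prims <- phantom$primitives
  for (k in seq_along(prims)) {
    p <- prims[[k]]
    chord <- prim_chord(p, px, py, ux, uy)
    A[[p$material]] <- A[[p$material]] + chord * p$density
    if (!is.na(p$parent)) {
      par <- prims[[p$parent]]
      A[[par$material]] <- A[[par$material]] - chord * par$density
    }
  }
  A
}

#' Basis-material thickness profiles along central-channel rays
#'
#' Traces the central ray (through the isocenter) for `n_views` source
#' angles spread over `arc_deg` and converts intersected mass to
#' basis-equivalent thicknesses, \eqn{t_j^{eq} = A_j / \rho_{j,basis}}
#' (tissue basis 1.06 g/cm^3, bone basis 1.85 g/cm^3). These profiles
#' drive the approximate per-scan choice of the MV dose fraction.
#'
#' @param phantom an `mvkv_phantom`.
#' @param n_views number of views (>= 1).
#' @param arc_deg angular span in degrees (default 180).
#' @param basis basis material pair (for the equivalent densities).
#' @return data frame `view_deg`, `t_tissue_cm`, `t_bone_cm`.
#' @export
basis_thickness_profiles <- function(phantom, n_views = 360, arc_deg = 180,
                                     basis = default_basis()) {
  stopifnot(inherits(phantom, "mvkv_phantom"), n_views >= 1)
  beta <- deg2rad((seq_len(n_views) - 1) * arc_deg / n_views)
  ux <- -sin(beta); uy <- -cos(beta)  # source at 12 o'clock, aiming inward
  A <- trace_basis_mass(phantom, rep(0, n_views), rep(0, n_views), ux, uy)
  data.frame(view_deg = (seq_len(n_views) - 1) * arc_deg / n_views,
             t_tissue_cm = A$tissue / basis$tissue$density,
             t_bone_cm = A$bone / basis$bone$density)
}

#' Rasterize a phantom onto a pixel grid
#'
#' Painter's-order rasterization of density (g/cm^3) or of linear
#' attenuation at a chosen energy, mainly for display and for building
#' region-of-interest masks.
#'
#' @param phantom an `mvkv_phantom`.
#' @param n matrix size (default 512).
#' @param fov_cm field of view (defaults to the phantom extent).
#' @param what `"density"` or `"mu"` (1/cm at `E_keV`).
#' @param E_keV energy for `what = "mu"` (default 80).
#' @return `n` x `n` matrix; x increases with row, y with column.
#' @export
rasterize_phantom <- function(phantom, n = 512, fov_cm = phantom$extent,
                              what = c("density", "mu"), E_keV = 80) {
  what <- match.arg(what)
  ax <- pixel_axis(n, fov_cm)
  px <- matrix(ax, n, n); py <- matrix(ax, n, n, byrow = TRUE)
  img <- matrix(0, n, n)
  for (p in phantom$primitives) {
    inside <- ((px - p$center[1]) / p$radii[1])^2 +
      ((py - p$center[2]) / p$radii[2])^2 <= 1
    val <- if (what == "density") p$density else
      p$density * mass_atten(load_material(p$material), E_keV)
    img[inside] <- val
  }
  img
}

pixel_axis <- function(n, fov_cm) {
  (seq_len(n) - (n + 1) / 2) * fov_cm / n
}

#' @export
print.mvkv_phantom <- function(x, ...) {
  cat(sprintf("<mvkv_phantom> %d primitives, extent %g cm\n",
              length(x$primitives), x$extent))
  for (p in x$primitives) {
    cat(sprintf("  %s %-6s rho=%.2f center=(%.1f, %.1f) radii=(%.1f, %.1f)%s\n",
                p$shape, p$material, p$density, p$center[1], p$center[2],
                p$radii[1], p$radii[2],
                if (is.na(p$parent)) "" else sprintf(" in #%d", p$parent)))
  }
  invisible(x)
}
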