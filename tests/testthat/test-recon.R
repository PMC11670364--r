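recon_geom <- function() fx("recon_geom",
                            fan_beam_geometry(n_channels = 256,
                                              n_views = 240))

test_that("FBP is linear and reconstructs a uniform disk quantitatively", {
  geom <- recon_geom()
  zero <- matrix(0, geom$n_views, geom$n_channels)
  expect_equal(max(abs(fbp_reconstruct(zero, geom, n = 64)$pixels)), 0)
  # analytic sinogram of a centered 20-cm disk, density 1.5
  disk <- phantom2d(list(prim_circle(c(0, 0), 10, "tissue", 1.5)),
                    extent = 50)
  s1 <- trace_path_lengths(disk, geom)$A_tissue
  img <- fbp_reconstruct(s1, geom, n = 128, fov_cm = 50)
  ax <- (seq_len(128) - 64.5) * 50 / 128
  roi <- outer(ax^2, ax^2, "+") < 2.5^2  # central 5-cm ROI
  expect_equal(mean(img$pixels[roi]), 1.5, tolerance = 0.02)
  # linearity: recon(a s1 + b s2) = a recon(s1) + b recon(s2)
  disk2 <- phantom2d(list(prim_circle(c(4, -2), 5, "tissue", 1.0)),
                     extent = 50)
  s2 <- trace_path_lengths(disk2, geom)$A_tissue
  lhs <- fbp_reconstruct(2 * s1 + 0.5 * s2, geom, n = 64)$pixels
  rhs <- 2 * fbp_reconstruct(s1, geom, n = 64)$pixels +
    0.5 * fbp_reconstruct(s2, geom, n = 64)$pixels
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(fbp_reconstruct(zero[, 1:10], geom), "shape")
})

test_that("off-center structures reconstruct in the right place", {
  geom <- recon_geom()
  ph <- phantom2d(list(prim_circle(c(5, 3), 4, "tissue", 1.0)),
                  extent = 50)
  s <- trace_path_lengths(ph, geom)$A_tissue
  img <- fbp_reconstruct(s, geom, n = 128, fov_cm = 50)$pixels
  ax <- (seq_len(128) - 64.5) * 50 / 128
  w <- img; w[w < 0.5] <- 0
  expect_equal(sum(w * ax) / sum(w), 5, tolerance = 0.02)
  expect_equal(sum(t(w) * ax) / sum(w), 3, tolerance = 0.04)
  inside <- outer((ax - 5)^2, (ax - 3)^2, "+") < 2^2
  expect_equal(mean(img[inside]), 1.0, tolerance = 0.02)
})

test_that("VMI synthesis combines basis images with tabulated weights", {
  basis <- fx_basis()
  rt <- mvkvdect:::as_image(matrix(1.2, 8, 8), 50, "g/cm^3")
  rb <- mvkvdect:::as_image(matrix(0, 8, 8), 50, "g/cm^3")
  vmi <- synthesize_vmi(rt, rb, 70)
  expect_equal(vmi$pixels,
               matrix(1.2 * mass_atten(basis$tissue, 70), 8, 8))
  expect_equal(max(abs(synthesize_vmi(rb, rb, 70)$pixels)), 0)
  expect_error(synthesize_vmi(rt, rb, 10), "\\[20, 120\\]")
  expect_error(synthesize_vmi(rt, rb, 150), "\\[20, 120\\]")
})

test_that("decomposed water reproduces water attenuation in VMIs", {
  # a pure-water slab measured with the MV/kV pair, decomposed into the
  # tissue/bone basis, must hand back the water attenuation curve
  mv <- scale_to_dose(rebin_spectrum(fx_mv(), 100), 0.5)
  kv <- scale_to_dose(rebin_spectrum(fx_kv(), 5), 0.5)
  det <- detector_model("pcd")
  water <- load_material("water")
  t_w <- 20
  sig <- function(sp) {
    Tw <- exp(-mass_atten(water, sp$energies) * water$density * t_w)
    sum(sp$fluence * detective_efficiency(sp$energies) * Tw)
  }
  air <- function(sp) sum(sp$fluence * detective_efficiency(sp$energies))
  est <- decompose_ray(c(sig(mv), sig(kv)), c(air(mv), air(kv)),
                       mv, kv, detector = det)
  rho_hat <- est$A / t_w  # equivalent basis densities of water
  rt <- mvkvdect:::as_image(matrix(rho_hat[["tissue"]], 2, 2), 50, "g/cm^3")
  rb <- mvkvdect:::as_image(matrix(rho_hat[["bone"]], 2, 2), 50, "g/cm^3")
  for (E0 in c(40, 70, 100)) {
    mu_w <- mass_atten(water, E0) * water$density
    expect_equal(synthesize_vmi(rt, rb, E0)$pixels[1, 1], mu_w,
                 tolerance = 0.01)
  }
})

test_that("HU conversion anchors water, air, and double attenuation", {
  water <- load_material("water")
  mu_w <- mass_atten(water, 80)
  img <- mvkvdect:::as_image(matrix(c(mu_w, 0, 2 * mu_w, mu_w), 2, 2),
                             50, "1/cm", 80)
  hu <- to_hu(img)
  expect_equal(hu$pixels[1, 1], 0)
  expect_equal(hu$pixels[2, 1], -1000)
  expect_equal(hu$pixels[1, 2], 1000)
  expect_equal(hu$units, "HU")
})

test_that("CNR definition and invariances hold", {
  set.seed(5)
  img <- matrix(rnorm(64 * 64, 10, 2), 64, 64)
  ins <- matrix(FALSE, 64, 64); ins[10:20, 10:20] <- TRUE
  bg <- matrix(FALSE, 64, 64); bg[40:60, 40:60] <- TRUE
  img[ins] <- img[ins] + 5
  c0 <- measure_cnr(img, ins, bg)
  expect_gt(c0, 0)
  # affine rescaling leaves CNR unchanged
  expect_equal(measure_cnr(3 * img - 7, ins, bg), c0, tolerance = 1e-12)
  # equal ROI means give exactly zero contrast
  img2 <- matrix(rnorm(64 * 64), 64, 64)
  img2[ins] <- img2[ins] - mean(img2[ins]) + mean(img2[bg])
  expect_equal(measure_cnr(img2, ins, bg), 0)
  expect_error(measure_cnr(img, ins, ins), "disjoint")
  expect_error(measure_cnr(img, ins & FALSE, bg), "non-empty")
  expect_error(measure_cnr(matrix(1, 64, 64), ins, bg), "undefined")
})

test_that("noise maps estimate the per-pixel standard deviation", {
  base <- matrix(7, 48, 48)
  expect_equal(max(noise_map(list(base, base, base))$pixels), 0)
  set.seed(21)
  reals <- lapply(1:100, function(i)
    base + matrix(rnorm(48 * 48, 0, 5), 48, 48))
  nm <- noise_map(reals)
  expect_equal(mean(nm$pixels), 5, tolerance = 0.1)
  expect_error(noise_map(list(base)), "at least two")
})

test_that("VMI synthesis commutes with reconstruction", {
  geom <- recon_geom()
  basis <- fx_basis()
  iq <- make_iq_phantom()
  paths <- trace_path_lengths(iq, geom)
  w_t <- mass_atten(basis$tissue, 70); w_b <- mass_atten(basis$bone, 70)
  direct <- fbp_reconstruct(w_t * paths$A_tissue + w_b * paths$A_bone,
                            geom, n = 64)
  via_basis <- synthesize_vmi(fbp_reconstruct(paths$A_tissue, geom, n = 64),
                              fbp_reconstruct(paths$A_bone, geom, n = 64),
                              70)
  expect_equal(via_basis$pixels, direct$pixels, tolerance = 1e-10)
})

test_that("IQ ROI masks are disjoint, labeled, and non-empty", {
  iq <- make_iq_phantom()
  masks <- iq_roi_masks(iq, n = 128, fov_cm = 50)
  expect_length(masks$inserts, 7)
  expect_setequal(names(masks$inserts),
                  sprintf("%.1f", seq(1.0, 2.2, by = 0.2)))
  for (m in masks$inserts) {
    expect_gt(sum(m), 0)
    expect_false(any(m & masks$background))
  }
  expect_gt(sum(masks$background), 0)
})
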