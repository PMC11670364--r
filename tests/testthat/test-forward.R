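test_that("ray tracing reproduces closed-form chords", {
  geom <- fan_beam_geometry(n_channels = 21, fan_angle_deg = 40,
                            n_views = 4, arc_deg = 360)
  ph <- phantom2d(list(prim_circle(c(0, 0), 15, "tissue", 1.0)),
                  extent = 50)
  paths <- trace_path_lengths(ph, geom)
  # channel angles and the perpendicular ray-to-center distance d = SID sin(g)
  fan <- 40 * pi / 180
  gamma <- -fan / 2 + (1:21 - 0.5) * fan / 21
  d <- 55 * sin(abs(gamma))
  chord <- 2 * sqrt(pmax(15^2 - d^2, 0))
  for (v in 1:4) {
    expect_equal(paths$A_tissue[v, ], chord, tolerance = 1e-10)
  }
  # central channel of an odd detector passes through the diameter
  geom3 <- fan_beam_geometry(n_channels = 3, fan_angle_deg = 1, n_views = 2)
  iq_t <- trace_path_lengths(phantom2d(list(
    prim_circle(c(0, 0), 20, "tissue", 1.06)), extent = 50), geom3)
  expect_equal(iq_t$A_tissue[1, 2], 40 * 1.06, tolerance = 1e-12)
  # a ray that misses the phantom reads zero
  ph_small <- phantom2d(list(prim_circle(c(0, 0), 2, "tissue", 1.0)),
                        extent = 50)
  p2 <- trace_path_lengths(ph_small, geom)
  expect_true(all(p2$A_tissue[, c(1, 21)] == 0))
})

test_that("opposed views mirror for a rotationally symmetric phantom", {
  geom <- fan_beam_geometry(n_channels = 32, n_views = 8)
  sym <- phantom2d(list(prim_circle(c(0, 0), 18, "tissue", 1.06),
                        prim_circle(c(0, 0), 6, "bone", 1.5, parent = 1L)),
                   extent = 50)
  paths <- trace_path_lengths(sym, geom)
  for (v in 1:4) {
    expect_equal(paths$A_bone[v, ], rev(paths$A_bone[v + 4, ]),
                 tolerance = 1e-9)
    expect_equal(paths$A_tissue[v, ], rev(paths$A_tissue[v + 4, ]),
                 tolerance = 1e-9)
  }
})

test_that("line integrals are additive over disjoint primitives", {
  geom <- fan_beam_geometry(n_channels = 16, n_views = 6)
  a <- prim_circle(c(-5, 0), 3, "bone", 1.4)
  b <- prim_circle(c(5, 2), 2, "bone", 2.0)
  p_ab <- trace_path_lengths(phantom2d(list(a, b), extent = 50), geom)
  p_ba <- trace_path_lengths(phantom2d(list(b, a), extent = 50), geom)
  p_a <- trace_path_lengths(phantom2d(list(a), extent = 50), geom)
  p_b <- trace_path_lengths(phantom2d(list(b), extent = 50), geom)
  expect_equal(p_ab$A_bone, p_ba$A_bone, tolerance = 1e-13)
  expect_equal(p_ab$A_bone, p_a$A_bone + p_b$A_bone, tolerance = 1e-13)
})

test_that("expected-signal sinograms agree with the single-ray model", {
  fxt <- fx("fixtures", make_fixtures(1))
  mv_clean <- simulate_measurement(fxt$paths, fxt$mv, detector_model("pcd"))
  # empty phantom: every pixel equals the air value
  empty <- trace_path_lengths(phantom2d(list()), fxt$geometry)
  air_sino <- simulate_measurement(empty, fxt$mv, detector_model("pcd"))
  expect_equal(as.numeric(air_sino$values),
               rep(air_sino$air, length(air_sino$values)),
               tolerance = 1e-12)
  # cross-check one pixel against expected_signal via mass thicknesses
  v <- 10; ch <- 33
  comp <- ray_composition(fxt$paths$A_tissue[v, ch] / 1.06,
                          fxt$paths$A_bone[v, ch] / 1.85)
  expect_equal(mv_clean$values[v, ch],
               expected_signal(fxt$mv, comp, detector = detector_model("pcd")),
               tolerance = 1e-12)
  # attenuation monotonicity: signals at or below air, decreasing with mass
  expect_lte(max(mv_clean$values), mv_clean$air * (1 + 1e-9))
  total_mass <- fxt$paths$A_tissue + fxt$paths$A_bone
  expect_lt(cor(as.numeric(mv_clean$values), as.numeric(total_mass),
                method = "spearman"), -0.99)
})

test_that("noise injection is seeded and reproducible", {
  fxt <- fx("fixtures", make_fixtures(1))
  mv_clean <- simulate_measurement(fxt$paths, fxt$mv, detector_model("pcd"))
  n1 <- add_noise(mv_clean, 42)
  n2 <- add_noise(mv_clean, 42)
  n3 <- add_noise(mv_clean, 43)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  expect_error(add_noise(n1, 42), "already noisy")
  expect_error(add_noise(mv_clean, NA), "seed")
})

test_that("noisy sinogram moments match the stated noise models", {
  # 10^4 independent draws of the same ray via a repeated-composition path
  geom <- fan_beam_geometry(n_channels = 1, n_views = 10000)
  comp <- ray_composition(20, 1)
  paths <- paths_of(matrix(comp$A[["tissue"]], 10000, 1),
                    matrix(comp$A[["bone"]], 10000, 1), geom)
  kv <- scale_to_dose(rebin_spectrum(fx_kv(), 4), 0.002)
  for (det in list(detector_model("pcd"), detector_model("eid"))) {
    clean <- simulate_measurement(paths, kv, det)
    noisy <- add_noise(clean, 77)
    draws <- as.numeric(noisy$values)
    expect_equal(mean(draws), clean$values[1, 1],
                 tolerance = 3 * sd(draws) / sqrt(1e4) / clean$values[1, 1])
    truth_var <- signal_variance(kv, comp, detector = det)
    expect_equal(var(draws), truth_var, tolerance = 0.05)
  }
})
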