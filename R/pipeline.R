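# Run configuration and the two study drivers that tie the pipeline
# together: the single-ray SNR / dose-allocation study and the fan-beam
# DE-CT study. All randomness flows from one root seed split per stage so
# that identical configurations give byte-identical outputs.

#' Build a run configuration
#'
#' @param study `"single_ray"` or `"ct"`.
#' @param detector `"pcd"`, `"eid"` or `"both"`.
#' @param total_dose_mGy total scan dose in mGy (default 10).
#' @param mv_fraction MV dose-allocation fraction `r` in `[0.01, 0.99]`.
#' @param phantom `"iq"` or `"torso"`.
#' @param n_views,n_channels,matrix_size,fov_cm geometry / reconstruction
#'   parameters.
#' @param n_realizations noisy realizations for the CT study (>= 2 when
#'   noise maps are requested).
#' @param mv_bin_keV,kv_bin_keV spectrum rebinning used by the CT study.
#' @param vmi_energies_keV VMI energies for the CT study.
#' @param seed root seed.
#' @param outdir output directory.
#' @param mv_spectrum_file,kv_spectrum_file optional two-column spectrum
#'   files replacing the analytic models (must exist when given).
#' @param tissue_cm,bone_cm thickness grids for the single-ray study.
#' @return validated list of class `mvkv_config`.
#' @export
run_config <- function(study = c("single_ray", "ct"),
                       detector = "both", total_dose_mGy = 10,
                       mv_fraction = 0.85, phantom = "iq",
                       n_views = 1200, n_channels = 800,
                       matrix_size = 512, fov_cm = 50,
                       n_realizations = 20, mv_bin_keV = 20,
                       kv_bin_keV = 1,
                       vmi_energies_keV = seq(20, 120, by = 10),
                       seed = 1, outdir = tempfile("mvkv_run_"),
                       mv_spectrum_file = NULL, kv_spectrum_file = NULL,
                       tissue_cm = seq(10, 50, length.out = 17),
                       bone_cm = exp(seq(log(0.1), log(10),
                                         length.out = 21))) {
  cfg <- list(study = match.arg(study), detector = detector,
              total_dose_mGy = total_dose_mGy, mv_fraction = mv_fraction,
              phantom = phantom, n_views = n_views,
              n_channels = n_channels, matrix_size = matrix_size,
              fov_cm = fov_cm, n_realizations = n_realizations,
              mv_bin_keV = mv_bin_keV, kv_bin_keV = kv_bin_keV,
              vmi_energies_keV = vmi_energies_keV, seed = seed,
              outdir = outdir, mv_spectrum_file = mv_spectrum_file,
              kv_spectrum_file = kv_spectrum_file,
              tissue_cm = tissue_cm, bone_cm = bone_cm)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!cfg$detector %in% c("pcd", "eid", "both")) {
    stop("detector must be 'pcd', 'eid' or 'both'", call. = FALSE)
  }
  if (cfg$total_dose_mGy <= 0) stop("dose must be > 0", call. = FALSE)
  if (cfg$mv_fraction < 0.01 || cfg$mv_fraction > 0.99) {
    stop("mv_fraction must lie in [0.01, 0.99]", call. = FALSE)
  }
  if (!cfg$phantom %in% c("iq", "torso")) {
    stop("phantom must be 'iq' or 'torso'", call. = FALSE)
  }
  if (cfg$study == "ct" && cfg$n_realizations < 2) {
    stop("CT study needs n_realizations >= 2 for noise maps",
         call. = FALSE)
  }
  for (f in c(cfg$mv_spectrum_file, cfg$kv_spectrum_file)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("spectrum file not found: ", f, call. = FALSE)
    }
  }
  structure(cfg, class = "mvkv_config")
}

#' Read / write a run configuration as YAML
#'
#' Every run echoes its configuration; `read_run_config(echo)` reproduces
#' the validated configuration exactly.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$vmi_energies_keV <- as.numeric(raw$vmi_energies_keV)
  raw$tissue_cm <- as.numeric(raw$tissue_cm)
  raw$bone_cm <- as.numeric(raw$bone_cm)
  validate_config(raw)
}

#' @rdname read_run_config
#' @param cfg an `mvkv_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# the echoed configuration is location-independent so that identical runs
# in different directories produce byte-identical artifacts
portable_config <- function(cfg) {
  cfg$outdir <- "."
  cfg
}

config_spectra <- function(cfg) {
  mv <- if (!is.null(cfg$mv_spectrum_file)) {
    read_spectrum(cfg$mv_spectrum_file)
  } else {
    build_detuned_mv_spectrum()
  }
  kv <- if (!is.null(cfg$kv_spectrum_file)) {
    read_spectrum(cfg$kv_spectrum_file)
  } else {
    build_kv_spectrum()
  }
  if (cfg$mv_bin_keV > 20) mv <- rebin_spectrum(mv, cfg$mv_bin_keV)
  if (cfg$kv_bin_keV > 1) kv <- rebin_spectrum(kv, cfg$kv_bin_keV)
  list(mv = mv, kv = kv)
}

config_detectors <- function(cfg) {
  if (cfg$detector == "both") {
    list(pcd = detector_model("pcd"), eid = detector_model("eid"))
  } else {
    stats::setNames(list(detector_model(cfg$detector)), cfg$detector)
  }
}

#' Run the single-line-integral SNR study
#'
#' Computes dose-optimized basis-material SNR surfaces for both detector
#' models over the configured tissue/bone thickness grids (1 uGy per ray)
#' and writes `snr_surface.csv` (one row per thickness pair, per-detector
#' SNRs, optimizing dose fractions, and percent improvements) plus a
#' configuration echo, to `cfg$outdir`.
#'
#' @param cfg an `mvkv_config` with `study = "single_ray"`.
#' @return the surface data frame, invisibly.
#' @export
run_single_ray <- function(cfg) {
  stopifnot(inherits(cfg, "mvkv_config"))
  sp <- config_spectra(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  surf <- snr_surface(sp$mv, sp$kv, tissue_cm = cfg$tissue_cm,
                      bone_cm = cfg$bone_cm)
  utils::write.csv(surf, file.path(cfg$outdir, "snr_surface.csv"),
                   row.names = FALSE)
  write_run_config(portable_config(cfg),
                   file.path(cfg$outdir, "config_echo.yml"))
  invisible(surf)
}

#' Run the fan-beam DE-CT study
#'
#' Full pipeline for the configured phantom: analytic ray tracing,
#' dose-allocated MV/kV forward projection, `n_realizations` seeded noisy
#' acquisitions per detector, Gauss-Newton decomposition, FBP of the
#' basis sinograms, VMI synthesis, CNR tables (IQ phantom) and per-pixel
#' noise maps. Images are written as flat float32 with YAML sidecars, CNR
#' and insert-density tables as CSV, and a manifest lists every artifact
#' with its MD5 hash; runs with identical configurations are
#' byte-identical.
#'
#' @param cfg an `mvkv_config` with `study = "ct"`.
#' @return invisible list with the in-memory results (`noiseless`,
#'   `realizations`, `noise_maps`, `cnr`, `insert_stats`, `artifacts`).
#' @export
run_ct_study <- function(cfg) {
  stopifnot(inherits(cfg, "mvkv_config"), cfg$study == "ct")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  sp <- config_spectra(cfg)
  dets <- config_detectors(cfg)
  phantom <- if (cfg$phantom == "iq") make_iq_phantom() else
    make_torso_phantom(cfg$seed)
  geom <- fan_beam_geometry(n_channels = cfg$n_channels,
                            n_views = cfg$n_views)
  paths <- trace_path_lengths(phantom, geom)
  per_ray_uGy <- cfg$total_dose_mGy * 1000 / cfg$n_views
  alloc <- allocate_dose(sp$mv, sp$kv, cfg$mv_fraction, per_ray_uGy)

  masks <- if (cfg$phantom == "iq") {
    iq_roi_masks(phantom, cfg$matrix_size, cfg$fov_cm)
  } else NULL

  results <- list(); cnr_rows <- list(); insert_rows <- list()
  files <- character(0)
  save_img <- function(img, name, meta) {
    p <- file.path(cfg$outdir, name)
    write_flat32(img$pixels, p, meta)
    files <<- c(files, p, paste0(p, ".yml"))
  }

  for (dname in names(dets)) {
    det <- dets[[dname]]
    mv_clean <- simulate_measurement(paths, alloc$mv, det)
    kv_clean <- simulate_measurement(paths, alloc$kv, det)
    recon_basis <- function(dec) {
      list(tissue = fbp_reconstruct(dec$A_tissue, geom, cfg$matrix_size,
                                    cfg$fov_cm),
           bone = fbp_reconstruct(dec$A_bone, geom, cfg$matrix_size,
                                  cfg$fov_cm))
    }
    dec0 <- decompose_sinogram(mv_clean, kv_clean)
    basis0 <- recon_basis(dec0)
    save_img(basis0$tissue, sprintf("%s_noiseless_rho_tissue.f32", dname),
             list(detector = dname, content = "basis density tissue"))
    save_img(basis0$bone, sprintf("%s_noiseless_rho_bone.f32", dname),
             list(detector = dname, content = "basis density bone"))

    reals <- vector("list", cfg$n_realizations)
    for (i in seq_len(cfg$n_realizations)) {
      # per-stage split of the root seed, kept within the 32-bit range
      seed_i <- (cfg$seed %% 100000) * 10000 + i * 100 +
        match(dname, c("pcd", "eid")) * 10
      mv_noisy <- add_noise(mv_clean, seed_i + 1)
      kv_noisy <- add_noise(kv_clean, seed_i + 2)
      dec <- decompose_sinogram(mv_noisy, kv_noisy)
      reals[[i]] <- recon_basis(dec)
    }

    vmis <- lapply(cfg$vmi_energies_keV, function(E0) {
      lapply(reals, function(b) synthesize_vmi(b$tissue, b$bone, E0))
    })
    names(vmis) <- as.character(cfg$vmi_energies_keV)
    nm <- lapply(vmis, noise_map)
    for (E0 in names(nm)) {
      save_img(nm[[E0]], sprintf("%s_noise_map_%skeV.f32", dname, E0),
               list(detector = dname, E0_keV = as.numeric(E0),
                    n_realizations = cfg$n_realizations))
    }

    if (!is.null(masks)) {
      for (E0i in seq_along(cfg$vmi_energies_keV)) {
        E0 <- cfg$vmi_energies_keV[E0i]
        for (dens in names(masks$inserts)) {
          cnr_vals <- vapply(vmis[[E0i]], measure_cnr,
                             0, insert = masks$inserts[[dens]],
                             background = masks$background)
          cnr_rows[[length(cnr_rows) + 1L]] <- data.frame(
            insert_density = as.numeric(dens), E0_keV = E0,
            detector = dname, cnr = mean(cnr_vals),
            n_realizations = cfg$n_realizations)
        }
      }
      for (dens in names(masks$inserts)) {
        vals <- vapply(reals, function(b)
          mean(b$bone$pixels[masks$inserts[[dens]]]), 0)
        insert_rows[[length(insert_rows) + 1L]] <- data.frame(
          true_density = as.numeric(dens), detector = dname,
          measured_mean = mean(vals), measured_sd = stats::sd(vals),
          noiseless_mean = mean(basis0$bone$pixels[masks$inserts[[dens]]]))
      }
    }
    results[[dname]] <- list(noiseless = basis0, realizations = reals,
                             noise_maps = nm,
                             convergence = dec0$convergence)
  }

  cnr <- if (length(cnr_rows)) do.call(rbind, cnr_rows) else NULL
  insert_stats <- if (length(insert_rows)) do.call(rbind, insert_rows)
    else NULL
  if (!is.null(cnr)) {
    p <- file.path(cfg$outdir, "cnr.csv")
    utils::write.csv(cnr, p, row.names = FALSE); files <- c(files, p)
  }
  if (!is.null(insert_stats)) {
    p <- file.path(cfg$outdir, "insert_density.csv")
    utils::write.csv(insert_stats, p, row.names = FALSE)
    files <- c(files, p)
  }
  write_run_config(portable_config(cfg),
                   file.path(cfg$outdir, "config_echo.yml"))
  files <- c(files, file.path(cfg$outdir, "config_echo.yml"))
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)))
  manifest <- manifest[order(manifest$file), ]
  utils::write.table(manifest, file.path(cfg$outdir, "manifest.txt"),
                     row.names = FALSE, quote = FALSE)
  invisible(list(results = results, cnr = cnr,
                 insert_stats = insert_stats, masks = masks,
                 artifacts = c(files, file.path(cfg$outdir,
                                                "manifest.txt"))))
}

#' Small seeded fixtures for fast tests and examples
#'
#' A reduced acquisition: 60-view x 64-channel fan geometry, a 20-cm
#' three-insert mini phantom, coarsely binned MV/kV spectra allocated at
#' 1 uGy per ray, and one noisy PCD measurement pair. Regeneration with
#' the same seed is identical.
#'
#' @param seed root seed (default 1).
#' @return list `geometry`, `phantom`, `mv`, `kv`, `paths`, `mv_noisy`,
#'   `kv_noisy`.
#' @export
make_fixtures <- function(seed = 1) {
  geom <- fan_beam_geometry(n_channels = 64, n_views = 60)
  phantom <- phantom2d(list(
    prim_circle(c(0, 0), 10, "tissue", 1.06),
    prim_circle(c(0, 5), 1.5, "bone", 2.2, parent = 1L),
    prim_circle(c(-4.3, -2.5), 1.5, "bone", 1.6, parent = 1L),
    prim_circle(c(4.3, -2.5), 1.5, "bone", 1.2, parent = 1L)),
    extent = 50)
  alloc <- allocate_dose(rebin_spectrum(build_detuned_mv_spectrum(), 100),
                         rebin_spectrum(build_kv_spectrum(), 5),
                         r = 0.85, total_uGy = 1)
  paths <- trace_path_lengths(phantom, geom)
  det <- detector_model("pcd")
  mv_clean <- simulate_measurement(paths, alloc$mv, det)
  kv_clean <- simulate_measurement(paths, alloc$kv, det)
  list(geometry = geom, phantom = phantom, mv = alloc$mv, kv = alloc$kv,
       paths = paths,
       mv_noisy = add_noise(mv_clean, seed * 100 + 1),
       kv_noisy = add_noise(kv_clean, seed * 100 + 2))
}
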