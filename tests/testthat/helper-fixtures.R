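# Shared lazily-built fixtures. Everything is generated in code; nothing
# is read from disk besides the bundled material tables.

.fx_env <- new.env()

fx <- function(name, expr) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- force(expr)
  .fx_env[[name]]
}

fx_mv <- function() fx("mv", build_detuned_mv_spectrum())
fx_kv <- function() fx("kv", build_kv_spectrum())
fx_basis <- function() fx("basis", default_basis())

# detectors with the ideal flat efficiency used by analytic oracles
flat_eta <- function(E) rep(1, length(E))
pcd_flat <- function() detector_model("pcd", efficiency = flat_eta)
eid_flat <- function(sigma_e = 0) {
  detector_model("eid", electronic_noise_sd = sigma_e,
                 efficiency = flat_eta)
}

mono <- function(E_keV, n_photons, label = "mono") {
  spectrum(E_keV, n_photons, label)
}

# hand-built path container for single-composition noise studies
paths_of <- function(A_tissue, A_bone, geometry) {
  structure(list(A_tissue = A_tissue, A_bone = A_bone,
                 geometry = geometry), class = "mvkv_paths")
}
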