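# Shared fixtures. Small phantoms and protocols are rebuilt per call (cheap);
# heavyweight study runs used by several acceptance properties are memoized
# in `.study_cache` so the suite pays for them once.

.study_cache <- new.env(parent = emptyenv())

small_phantom <- function(shape = c(32, 32, 32), voxel_mm = 6, seed = 0) {
  build_phantom(shape, voxel_mm = voxel_mm, seed = seed)
}

small_protocol <- function(phantom, preset = "GRE", accel = c(1, 1)) {
  desk_protocol(protocol_presets()[[preset]], phantom, accel = accel)
}

rel_rmse <- function(a, b) {
  sqrt(mean(Mod(a - b)^2)) / sqrt(mean(Mod(b)^2))
}

# Full default-scale study shared by the reliability acceptance properties:
# 64 x 64 x 48 phantom, all three protocols, both reconstruction modes,
# NAD and |dR2*| metrics, n_pairs scan pairs.
study_run <- function(n_pairs = 20) {
  key <- paste0("study_", n_pairs)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  cfg <- experiment_config(
    shape = c(64, 64, 48), voxel_mm = c(3, 3, 3), phantom_seed = 0,
    protocols = c("GRE", "EPIx3", "EPIx5"),
    metrics = c("nad", "dr2s"),
    pair_seeds = seq_len(n_pairs)
  )
  rep <- run_experiment(cfg)
  .study_cache[[key]] <- rep
  rep
}

# Thermal-noise-floor reference for the study conditions: the ideal GRE
# image of the default phantom plus the study's thermal sigma.
study_noise_sigma <- function() {
  ph <- build_phantom(c(64, 64, 48), c(3, 3, 3), seed = 0)
  pr <- desk_protocol(protocol_presets()$GRE, ph, accel = c(1, 1))
  ideal <- ideal_image(ph, pr)
  sigma <- stats::median(magnitude(ideal, 1)[ph$mask]) / 50
  list(phantom = ph, protocol = pr, ideal = ideal, sigma = sigma)
}
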