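# End-to-end test-retest experiment orchestration: simulate two scans per
# protocol, reconstruct in the requested modes, quantify per repetition,
# coregister, and assemble the reliability report.

#' Build an experiment configuration
#'
#' Encodes one full test-retest study: the phantom, the protocols (presets
#' rescaled to the phantom grid), the physiological-noise magnitudes, the
#' thermal-noise level (via a target first-echo SNR for the GRE protocol;
#' EPI noise is bandwidth-scaled from it), the scan-pair seeds and the
#' reconstruction modes.
#'
#' @param shape,voxel_mm,phantom_seed phantom grid and seed.
#' @param protocols character subset of `c("GRE","EPIx3","EPIx5")` or a list
#'   of `epiqsm_protocol` objects.
#' @param accel length-2 acceleration used at desk scale (default `c(1, 1)`:
#'   fully sampled; parallel-imaging machinery is not part of the
#'   reliability analysis).
#' @param drift_sd_hz,resp_amp_hz,resp_period_s,grad_sd_hz_per_mm,trans_sd_mm
#'   physiological timeline magnitudes (see [sample_physio_timeline()]).
#' @param target_snr first-echo brain SNR of the GRE protocol determining
#'   the thermal-noise sigma; `NULL` with `noise_sigma` supplied directly.
#' @param noise_sigma explicit GRE-bandwidth noise SD (overrides
#'   `target_snr`).
#' @param pair_seeds integer vector of scan-pair seeds (one test-retest pair
#'   per element; all randomness of a pair derives from it).
#' @param modes reconstruction modes to run.
#' @param metrics metrics to compute, subset of
#'   `c("nad", "dr2s", "df", "dchi")`.
#' @param output_dir directory for report files, or `NULL` to only return
#'   the report object.
#' @return An `epiqsm_config` list.
#' @export
experiment_config <- function(shape = c(64, 64, 48), voxel_mm = c(3, 3, 3),
                              phantom_seed = 0,
                              protocols = c("GRE", "EPIx3", "EPIx5"),
                              accel = c(1, 1),
                              drift_sd_hz = 0.2, resp_amp_hz = 1,
                              resp_period_s = 4, grad_sd_hz_per_mm = 0,
                              trans_sd_mm = 0.02,
                              target_snr = 50, noise_sigma = NULL,
                              pair_seeds = 1L,
                              modes = c("corrected", "uncorrected"),
                              metrics = c("nad", "dr2s", "df", "dchi"),
                              output_dir = NULL) {
  if (anyDuplicated(pair_seeds)) stop("pair_seeds must be distinct")
  if (length(protocols) < 1 || length(modes) < 1) {
    stop("at least one protocol and one mode are required")
  }
  structure(list(shape = shape, voxel_mm = voxel_mm, phantom_seed = phantom_seed,
                 protocols = protocols, accel = accel,
                 drift_sd_hz = drift_sd_hz, resp_amp_hz = resp_amp_hz,
                 resp_period_s = resp_period_s,
                 grad_sd_hz_per_mm = grad_sd_hz_per_mm,
                 trans_sd_mm = trans_sd_mm,
                 target_snr = target_snr, noise_sigma = noise_sigma,
                 pair_seeds = as.integer(pair_seeds), modes = modes,
                 metrics = metrics, output_dir = output_dir),
            class = "epiqsm_config")
}

#' @keywords internal
resolve_protocols <- function(config, phantom) {
  if (is.character(config$protocols)) {
    presets <- protocol_presets()
    bad <- setdiff(config$protocols, names(presets))
    if (length(bad)) stop("unknown protocol preset(s): ", paste(bad, collapse = ", "))
    prs <- presets[config$protocols]
  } else {
    prs <- config$protocols
    names(prs) <- vapply(prs, function(p) p$name, "")
  }
  lapply(prs, desk_protocol, phantom = phantom, accel = config$accel)
}

# deterministic sub-seed derivation (stays far below 2^31)
#' @keywords internal
derive_seed <- function(pair_seed, proto_idx, scan, rep, kind) {
  (pair_seed * 131071L + proto_idx * 8191L + scan * 911L + rep * 31L + kind) %% 2000000011L
}

#' Simulate, reconstruct and quantify one scan
#'
#' One scan = `protocol$repetitions` repetitions, each with its own
#' physiological timeline and noise realization. Returns per-repetition
#' quantitative maps and images per reconstruction mode.
#'
#' @param phantom an `epiqsm_phantom`.
#' @param protocol an `epiqsm_protocol` (desk scale).
#' @param config an `epiqsm_config`.
#' @param sigma thermal-noise SD for this protocol.
#' @param pair_seed,proto_idx,scan seed-derivation coordinates.
#' @param quantify character vector of maps to fit per repetition (subset
#'   of `c("r2s", "f", "chi")`), or `character(0)` for none.
#' @return List per mode: `reps` (list of `epiqsm_image`), `maps` (list of
#'   `epiqsm_quantmaps` per repetition, if requested).
#' @export
run_scan <- function(phantom, protocol, config, sigma, pair_seed, proto_idx,
                     scan, quantify = c("r2s", "f", "chi")) {
  pattern <- pattern_for_protocol(protocol)
  n_shots <- ceiling(nrow(pattern$lines) / protocol$epi_factor)
  out <- stats::setNames(vector("list", length(config$modes)), config$modes)
  for (m in config$modes) out[[m]] <- list(reps = list(), maps = list())
  for (rep in seq_len(protocol$repetitions)) {
    tl <- sample_physio_timeline(
      n_shots, drift_sd_hz = config$drift_sd_hz, resp_amp_hz = config$resp_amp_hz,
      resp_period_s = config$resp_period_s, tr_s = protocol$tr_s,
      grad_sd_hz_per_mm = config$grad_sd_hz_per_mm,
      trans_sd_mm = config$trans_sd_mm,
      seed = derive_seed(pair_seed, proto_idx, scan, rep, 1L))
    kd <- simulate_scan(phantom, protocol, tl, noise_sigma = sigma,
                        seed = derive_seed(pair_seed, proto_idx, scan, rep, 2L))
    for (m in config$modes) {
      img <- reconstruct(kd, m, repetition = rep)
      out[[m]]$reps[[rep]] <- img
      if (length(quantify)) {
        out[[m]]$maps[[rep]] <- quantify_maps(img, phantom$mask,
                                              what = quantify,
                                              b0_tesla = phantom$b0_tesla)
      }
    }
  }
  out
}

#' Run a full test-retest reliability experiment
#'
#' For every protocol and reconstruction mode: simulates two scans per scan
#' pair, reconstructs, quantifies each repetition, coregisters scan 2 to
#' scan 1 on the echo/repetition-averaged magnitude (one translation reused
#' for all companion maps), and computes the reliability report: echo- and
#' repetition-averaged NAD, inter-scan `|dR2*|`, `|df|`, `|dchi|` of the
#' repetition-mean maps, their empirical CDFs and medians, and averaging
#' curves over repetitions. Failures are isolated per protocol and recorded
#' in the report instead of aborting the run.
#'
#' @param config an `epiqsm_config`.
#' @return An `epiqsm_report`: nested list `results[[protocol]][[mode]]` with
#'   `medians`, `cdf`, `averaging_curve` and exclusion counts, plus a
#'   `manifest` with every seed and parameter. Written as JSON/CSV/NIfTI
#'   under `config$output_dir` when set.
#' @export
run_experiment <- function(config) {
  phantom <- build_phantom(config$shape, config$voxel_mm, seed = config$phantom_seed)
  protos <- resolve_protocols(config, phantom)
  sig_ref <- config$noise_sigma
  if (is.null(sig_ref)) {
    if (is.null(config$target_snr) || config$target_snr <= 0) {
      sig_ref <- 0
    } else {
      ideal1 <- magnitude(ideal_image(phantom, protos[[1]]), 1)
      sig_ref <- stats::median(ideal1[phantom$mask]) / config$target_snr
    }
  }
  ref_bw <- if (is.character(config$protocols)) 125 else protos[[1]]$bw_hz_per_px

  results <- list()
  for (pi in seq_along(protos)) {
    pr <- protos[[pi]]
    res_p <- tryCatch(
      run_pair_analysis(phantom, pr, config, pi, sig_ref, ref_bw),
      error = function(e) list(error = conditionMessage(e))
    )
    results[[pr$name]] <- res_p
  }

  report <- structure(list(
    results = results,
    manifest = list(config = unclass(config), ref_sigma = sig_ref,
                    phantom_seed = config$phantom_seed,
                    package_version = as.character(utils::packageVersion("epiqsm")))
  ), class = "epiqsm_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir, phantom)
  report
}

#' @keywords internal
run_pair_analysis <- function(phantom, pr, config, proto_idx, sig_ref, ref_bw) {
  sigma <- if (sig_ref > 0) thermal_noise_sigma(pr$bw_hz_per_px, sig_ref, ref_bw) else 0
  mask <- phantom$mask
  out_modes <- list()
  for (pair_seed in config$pair_seeds) {
    what <- c(r2s = "dr2s", f = "df", chi = "dchi")
    what <- names(what)[what %in% config$metrics]
    s1 <- run_scan(phantom, pr, config, sigma, pair_seed, proto_idx, 1L,
                   quantify = what)
    s2 <- run_scan(phantom, pr, config, sigma, pair_seed, proto_idx, 2L,
                   quantify = what)
    for (m in config$modes) {
      cell <- analyse_scan_pair(s1[[m]], s2[[m]], mask, config$metrics)
      key <- m
      out_modes[[key]] <- c(out_modes[[key]], list(cell))
    }
  }
  # summarize across pairs: medians averaged, CDFs kept from the first pair
  lapply(out_modes, function(cells) {
    med <- Reduce(`+`, lapply(cells, `[[`, "medians")) / length(cells)
    list(medians = med,
         medians_per_pair = do.call(rbind, lapply(cells, `[[`, "medians")),
         cdf = cells[[1]]$cdf,
         averaging_curve = cells[[1]]$averaging_curve,
         n_excluded = cells[[1]]$n_excluded,
         shift_vox = cells[[1]]$shift_vox,
         n_pairs = length(cells))
  })
}

# Reliability statistics for one scan pair in one mode.
#' @keywords internal
analyse_scan_pair <- function(scan1, scan2, mask, metrics) {
  # one translation per scan pair, from the echo/rep-averaged magnitude
  avg_mag <- function(scan) {
    acc <- 0
    for (im in scan$reps) acc <- acc + echo_mean(magnitude(im))
    acc / length(scan$reps)
  }
  m1 <- avg_mag(scan1); m2 <- avg_mag(scan2)
  reg <- coregister_translation(m2, m1)
  move <- function(v) {
    v0 <- v; v0[!is.finite(v0)] <- 0
    apply_translation(v0, reg$shift_vox)
  }

  medians <- c()
  cdf <- list(); n_excluded <- list(); avg_curves <- list()

  if ("nad" %in% metrics) {
    nm <- nad_map(m1, reg$resampled, mask)
    cdf$nad <- cdf_compact(empirical_cdf(nm$nad, mask))
    medians["nad"] <- stats::median(nm$nad[mask], na.rm = TRUE)
    n_excluded$nad <- nm$n_excluded
  }
  map_metric <- function(field, metric_name, use_eroded = FALSE) {
    msk <- if (use_eroded) {
      scan1$maps[[1]]$eroded_mask & scan2$maps[[1]]$eroded_mask
    } else mask
    reps1 <- lapply(scan1$maps, `[[`, field)
    reps2 <- lapply(scan2$maps, function(q) move(q[[field]]))
    mean1 <- Reduce(`+`, lapply(reps1, nafill0)) / length(reps1)
    mean2 <- Reduce(`+`, lapply(reps2, nafill0)) / length(reps2)
    d <- interscan_abs_diff(mean1, mean2, msk)
    cdf[[metric_name]] <<- cdf_compact(empirical_cdf(d, msk))
    medians[metric_name] <<- stats::median(d[msk], na.rm = TRUE)
    if (length(reps1) > 1) {
      avg_curves[[metric_name]] <<- averaging_curve(lapply(reps1, nafill0),
                                                    lapply(reps2, nafill0), msk)
    }
  }
  if ("dr2s" %in% metrics) map_metric("r2s_hat", "dr2s")
  if ("df" %in% metrics) map_metric("f_hat", "df")
  if ("dchi" %in% metrics) map_metric("chi_hat", "dchi", use_eroded = TRUE)

  list(medians = medians, cdf = cdf, averaging_curve = avg_curves,
       n_excluded = n_excluded, shift_vox = reg$shift_vox)
}

#' @keywords internal
nafill0 <- function(x) {
  x[!is.finite(x)] <- 0
  x
}

# compact CDF representation: 201 quantile samples
#' @keywords internal
cdf_compact <- function(cdf) {
  fr <- seq(0, 1, length.out = 201)
  list(fractions = fr,
       values = as.numeric(stats::quantile(cdf$values, fr, type = 7)),
       median = cdf$median)
}

#' @keywords internal
write_report <- function(report, dir, phantom) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  med <- report_medians(report)
  utils::write.csv(med, file.path(dir, "medians.csv"), row.names = FALSE)
  invisible(dir)
}

#' @keywords internal
report_to_list <- function(report) {
  lapply(report$results, function(pm) {
    if (!is.null(pm$error)) return(pm)
    lapply(pm, function(cell) {
      list(medians = as.list(cell$medians),
           cdf = cell$cdf,
           averaging_curve = lapply(cell$averaging_curve, as.list),
           n_excluded = cell$n_excluded,
           shift_vox = cell$shift_vox,
           n_pairs = cell$n_pairs)
    })
  })
}

#' Median table of a reliability report
#'
#' @param report an `epiqsm_report`.
#' @return Data frame with one row per protocol x mode x metric.
#' @export
report_medians <- function(report) {
  rows <- list()
  for (pn in names(report$results)) {
    pm <- report$results[[pn]]
    if (!is.null(pm$error)) next
    for (mn in names(pm)) {
      med <- pm[[mn]]$medians
      for (met in names(med)) {
        rows[[length(rows) + 1]] <- data.frame(
          protocol = pn, mode = mn, metric = met, median = unname(med[met]))
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.epiqsm_report <- function(x, ...) {
  cat("epiqsm reliability report\n")
  med <- report_medians(x)
  if (!is.null(med)) print(med, row.names = FALSE)
  invisible(x)
}
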