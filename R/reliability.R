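# Test-retest reliability statistics: normalized absolute difference (NAD),
# inter-scan absolute differences, empirical CDFs and medians, averaging
# curves, Monte Carlo thermal-noise floors, translation coregistration and
# ROI consistency.

#' Normalized absolute difference (NAD) map
#'
#' Voxelwise `|m1 - m2| / ((m1 + m2) / 2)` between two magnitude images.
#' Voxels whose pair mean falls below `eps * max(pair mean)` are excluded
#' (set `NA`) and counted.
#'
#' @param m1,m2 3D magnitude arrays on the same grid.
#' @param mask logical 3D mask (non-empty).
#' @param eps relative exclusion threshold for near-zero means.
#' @return List with `nad` (3D array, `NA` outside mask and at excluded
#'   voxels) and `n_excluded`.
#' @export
nad_map <- function(m1, m2, mask, eps = 1e-12) {
  if (!all(dim(m1) == dim(m2)) || !all(dim(m1) == dim(mask))) {
    stop("m1, m2 and mask must share a grid")
  }
  if (!any(mask)) stop("mask is empty")
  mean_pair <- (m1 + m2) / 2
  thr <- eps * max(mean_pair[mask])
  ok <- mask & mean_pair > thr
  nad <- array(NA_real_, dim(m1))
  nad[ok] <- abs(m1[ok] - m2[ok]) / mean_pair[ok]
  list(nad = nad, n_excluded = sum(mask) - sum(ok))
}

#' Echo- and repetition-averaged NAD between two scans
#'
#' The magnitude-reliability variant used for scan-level summaries: the
#' magnitude images of each scan are averaged across all repetitions (to
#' retain GRE-equivalent SNR) and across echoes, then the NAD of the two
#' scan averages is computed.
#'
#' @param scan1,scan2 lists of `epiqsm_image` repetitions.
#' @param mask logical 3D mask.
#' @return As [nad_map()].
#' @export
nad_scan_pair <- function(scan1, scan2, mask) {
  avg_mag <- function(scan) {
    acc <- 0
    for (im in scan) acc <- acc + echo_mean(magnitude(im))
    acc / length(scan)
  }
  nad_map(avg_mag(scan1), avg_mag(scan2), mask)
}

#' Inter-scan absolute difference map
#'
#' @param map1,map2 3D maps on the same grid.
#' @param mask logical 3D mask.
#' @return 3D array `|map1 - map2|`, `NA` outside the mask.
#' @export
interscan_abs_diff <- function(map1, map2, mask) {
  if (!all(dim(map1) == dim(map2)) || !all(dim(map1) == dim(mask))) {
    stop("maps and mask must share a grid")
  }
  out <- array(NA_real_, dim(map1))
  out[mask] <- abs(map1[mask] - map2[mask])
  out
}

#' Median inter-scan absolute difference vs. number of averages
#'
#' For each `N`, averages the first `N` per-repetition quantitative maps of
#' each scan (averaging the fitted maps, not the underlying complex data),
#' takes the inter-scan absolute difference and reports the masked median.
#'
#' @param per_rep_maps_scan1,per_rep_maps_scan2 lists of per-repetition 3D
#'   maps (equal grids).
#' @param mask logical 3D mask.
#' @param n_max largest number of averages (defaults to the shorter scan);
#'   an error if it exceeds the available repetitions.
#' @return Data frame with columns `n_avg` and `median_abs_diff`.
#' @export
averaging_curve <- function(per_rep_maps_scan1, per_rep_maps_scan2, mask,
                            n_max = NULL) {
  n1 <- length(per_rep_maps_scan1); n2 <- length(per_rep_maps_scan2)
  if (n1 < 1 || n2 < 1) stop("each scan needs at least one repetition map")
  if (is.null(n_max)) n_max <- min(n1, n2)
  if (n_max > min(n1, n2)) stop("n_max exceeds the available repetitions")
  med <- numeric(n_max)
  for (N in seq_len(n_max)) {
    a <- Reduce(`+`, per_rep_maps_scan1[seq_len(N)]) / N
    b <- Reduce(`+`, per_rep_maps_scan2[seq_len(N)]) / N
    d <- interscan_abs_diff(a, b, mask)
    med[N] <- stats::median(d[mask], na.rm = TRUE)
  }
  data.frame(n_avg = seq_len(n_max), median_abs_diff = med)
}

#' Monte Carlo thermal-noise floor
#'
#' Adds independent circular complex Gaussian noise to a reference complex
#' multi-echo image, twice per trial, quantifies each noisy copy and reports
#' the per-trial masked median of the requested reliability metric between
#' the pair. This isolates the thermal-noise contribution to the test-retest
#' metrics. Susceptibility is deliberately not offered: its inter-scan
#' difference depends on the dipole-inversion regularization, so a
#' noise-floor defined through it would be algorithm-specific.
#'
#' @param reference an `epiqsm_image` (typically the ideal or a reconstructed
#'   GRE image).
#' @param sigma complex-noise SD per real/imaginary component, in the
#'   image domain (equal to the k-space SD under the unitary DFT).
#' @param n_trials number of trials (>= 2).
#' @param metrics subset of `c("nad", "dr2s", "df")`.
#' @param mask logical 3D mask.
#' @param seed integer seed.
#' @param n_avg number of independent repetitions averaged into each noisy
#'   copy before quantification (map-domain averaging), default 1.
#' @return List per metric: numeric vector of per-trial medians.
#' @export
monte_carlo_noise_floor <- function(reference, sigma, n_trials, metrics,
                                    mask, seed = 0, n_avg = 1L) {
  if (n_trials < 2) stop("n_trials must be >= 2")
  if (sigma < 0) stop("sigma must be non-negative")
  if (any(metrics == "dchi") || any(metrics == "chi")) {
    stop("susceptibility is excluded from the noise simulation: |d chi| is specific to the dipole-inversion regularization")
  }
  metrics <- match.arg(metrics, c("nad", "dr2s", "df"), several.ok = TRUE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  dm <- dim(reference$data)
  te <- reference$te_s

  noisy_maps <- function() {
    # average n_avg independent noisy map estimates
    racc <- 0; facc <- 0; macc <- 0
    for (i in seq_len(n_avg)) {
      noise <- array(stats::rnorm(prod(dm), 0, sigma), dm) +
        1i * array(stats::rnorm(prod(dm), 0, sigma), dm)
      img <- reference$data + noise
      mag <- Mod(img)
      out <- list()
      if ("dr2s" %in% metrics) {
        racc <- racc + fit_r2star(mag, te, mask)$r2s_hat / n_avg
      }
      if ("df" %in% metrics) {
        facc <- facc + frequency_map(Arg(img), te, mag, mask) / n_avg
      }
      if ("nad" %in% metrics) {
        macc <- macc + echo_mean(mag) / n_avg
      }
    }
    list(r2s = racc, f = facc, mag = macc)
  }

  res <- stats::setNames(vector("list", length(metrics)), metrics)
  for (m in metrics) res[[m]] <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    a <- noisy_maps(); b <- noisy_maps()
    if (sigma == 0) {
      for (m in metrics) res[[m]][tr] <- 0
      next
    }
    if ("nad" %in% metrics) {
      res$nad[tr] <- stats::median(nad_map(a$mag, b$mag, mask)$nad[mask], na.rm = TRUE)
    }
    if ("dr2s" %in% metrics) {
      res$dr2s[tr] <- stats::median(interscan_abs_diff(a$r2s, b$r2s, mask)[mask], na.rm = TRUE)
    }
    if ("df" %in% metrics) {
      res$df[tr] <- stats::median(interscan_abs_diff(a$f, b$f, mask)[mask], na.rm = TRUE)
    }
  }
  res
}

#' Translation-only inter-scan coregistration
#'
#' Estimates the rigid translation between two volumes by Fourier phase
#' correlation with quadratic sub-voxel peak refinement, and resamples the
#' moving volume onto the fixed grid with cubic-spline interpolation. The
#' returned shift can be re-applied to companion maps with
#' [apply_translation()], mirroring the use of one magnitude-derived
#' transform per scan for all quantitative maps.
#'
#' @param moving,fixed 3D arrays on the same grid.
#' @param voxel_mm voxel size (mm).
#' @param peak_threshold minimum normalized correlation peak; below it a
#'   warning is issued and a zero shift returned.
#' @return List with `shift_mm` (length 3; the shift that aligns `moving`
#'   to `fixed`), `shift_vox`, and `resampled` (moving resampled).
#' @export
coregister_translation <- function(moving, fixed, voxel_mm = c(1, 1, 1),
                                   peak_threshold = 0.1) {
  if (!all(dim(moving) == dim(fixed))) stop("volumes must share a grid")
  vox <- as_len3(voxel_mm, "voxel_mm")
  dm <- dim(fixed)
  X <- fft(fixed) * Conj(fft(moving))
  denom <- Mod(X); denom[denom < 1e-300] <- 1
  r <- Re(fft(X / denom, inverse = TRUE)) / prod(dm)
  pk <- which.max(r)
  peak_val <- r[pk]
  if (peak_val < peak_threshold) {
    warning("phase-correlation peak below threshold; returning zero shift")
    return(list(shift_mm = c(0, 0, 0), shift_vox = c(0, 0, 0), resampled = moving))
  }
  ijk <- arrayInd(pk, dm)
  int_shift <- numeric(3)
  for (ax in 1:3) {
    s <- ijk[ax] - 1
    if (s > dm[ax] / 2) s <- s - dm[ax]
    int_shift[ax] <- s
  }
  # sub-voxel refinement: weighted least-squares fit of the cross-power
  # phase plane after demodulating the integer shift
  mx <- kfreq(dm[1]); my <- kfreq(dm[2]); mz <- kfreq(dm[3])
  MX <- array(rep(mx, times = dm[2] * dm[3]), dm)
  MY <- array(rep(rep(my, each = dm[1]), times = dm[3]), dm)
  MZ <- array(rep(mz, each = dm[1] * dm[2]), dm)
  Xd <- X * exp(2i * pi * (MX * int_shift[1] / dm[1] +
                             MY * int_shift[2] / dm[2] +
                             MZ * int_shift[3] / dm[3]))
  sel <- abs(MX) <= dm[1] / 8 & abs(MY) <= dm[2] / 8 & abs(MZ) <= dm[3] / 8
  w <- Mod(Xd)[sel]^2
  phi <- Arg(Xd)[sel]
  A <- cbind(-2 * pi * MX[sel] / dm[1], -2 * pi * MY[sel] / dm[2],
             -2 * pi * MZ[sel] / dm[3])
  cf <- tryCatch(stats::lm.wfit(A, phi, w)$coefficients,
                 error = function(e) c(0, 0, 0))
  cf[!is.finite(cf)] <- 0
  frac <- pmin(pmax(cf, -0.75), 0.75)
  frac[abs(frac) < 1e-6] <- 0
  shift_vox <- unname(int_shift + frac)
  resampled <- apply_translation(moving, shift_vox)
  list(shift_mm = shift_vox * vox, shift_vox = shift_vox, resampled = resampled)
}

#' Apply a stored translation to a companion map
#'
#' @param vol 3D array.
#' @param shift_vox length-3 shift in voxels (as returned by
#'   [coregister_translation()]).
#' @return The translated volume (cubic-spline resampled).
#' @export
apply_translation <- function(vol, shift_vox) {
  if (all(shift_vox == 0)) return(vol)
  if (all(shift_vox == round(shift_vox))) {
    # integer shifts are exact circular shifts
    dm <- dim(vol)
    idx <- lapply(1:3, function(ax) ((seq_len(dm[ax]) - 1 - shift_vox[ax]) %% dm[ax]) + 1)
    return(vol[idx[[1]], idx[[2]], idx[[3]]])
  }
  spline_shift3(vol, shift_vox)
}

#' Empirical cumulative distribution function
#'
#' Right-continuous empirical CDF of the masked finite values, with the
#' median defined by linear interpolation between order statistics (the
#' value at cumulative fraction 0.5).
#'
#' @param values numeric array or vector.
#' @param mask optional logical mask (same shape).
#' @return List with `values` (sorted), `fractions` (cumulative), `median`.
#' @export
empirical_cdf <- function(values, mask = NULL) {
  v <- if (is.null(mask)) as.vector(values) else values[mask]
  v <- v[is.finite(v)]
  if (length(v) < 1) stop("no finite values")
  v <- sort(v)
  list(values = v, fractions = seq_along(v) / length(v),
       median = stats::median(v))
}

#' ROI consistency between two maps
#'
#' Per-ROI means of both maps, their Pearson correlation coefficient and the
#' ordinary-least-squares slope of the second map's ROI means on the first's.
#' Empty ROIs are excluded with a warning.
#'
#' @param map_a,map_b 3D maps on the same grid.
#' @param labels integer 3D label array.
#' @param roi_ids integer ROI labels to evaluate (>= 3 after exclusions).
#' @return List with `table` (data frame: roi, mean_a, mean_b, n_voxels),
#'   `cc` and `slope`.
#' @export
roi_consistency <- function(map_a, map_b, labels, roi_ids) {
  if (length(roi_ids) < 3) stop("at least 3 ROIs are required")
  rows <- lapply(roi_ids, function(id) {
    sel <- labels == id & is.finite(map_a) & is.finite(map_b)
    if (!any(sel)) {
      warning(sprintf("ROI %d is empty and was excluded", id))
      return(NULL)
    }
    data.frame(roi = id, mean_a = mean(map_a[sel]), mean_b = mean(map_b[sel]),
               n_voxels = sum(sel))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 3) stop("fewer than 3 non-empty ROIs")
  cc <- stats::cor(tab$mean_a, tab$mean_b)
  slope <- stats::coef(stats::lm(mean_b ~ mean_a, data = tab))[["mean_a"]]
  list(table = tab, cc = cc, slope = slope)
}
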