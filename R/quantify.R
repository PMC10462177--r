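# Quantification of R2*, tissue frequency and susceptibility from
# multi-echo complex images: mono-exponential magnitude fitting, temporally
# unwrapped weighted frequency estimation, SMV (V-SHARP) background-field
# removal and closed-form dipole inversion (TKD or Tikhonov).

#' Mono-exponential R2* fit
#'
#' Fits `S(TE) = S0 * exp(-R2* TE)` voxelwise to multi-echo magnitude data
#' by nonlinear least squares (vectorized Gauss-Newton over all voxels,
#' initialized from the log-linear fit). Voxels whose Gauss-Newton iteration
#' does not converge fall back to the log-linear estimate and are flagged;
#' all-zero voxels inside the mask get `NA` and are excluded from downstream
#' statistics. Negative R2* estimates are clipped to zero and counted.
#'
#' When the last-echo SNR appears low (< 10, estimated from the data), a
#' warning notes that magnitude-only fitting underestimates R2* in that
#' regime.
#'
#' @param mag 4D magnitude array `(x, y, z, echo)`.
#' @param te_s echo times (s), at least 2.
#' @param mask logical 3D analysis mask.
#' @param max_iter Gauss-Newton iteration cap.
#' @param tol relative step tolerance declaring convergence.
#' @return List with 3D arrays `r2s_hat` (1/s), `s0_hat`, and `diagnostics`
#'   (list: `resid_norm` 3D array, `converged` logical 3D array, `n_clipped`,
#'   `n_undefined`).
#' @export
fit_r2star <- function(mag, te_s, mask, max_iter = 25L, tol = 1e-8) {
  if (length(te_s) < 2) stop("at least two echoes are required")
  dm <- dim(mag)
  if (length(dm) != 4 || dm[4] != length(te_s)) stop("mag must be (x,y,z,echo) matching te_s")
  if (any(mag < 0)) stop("magnitudes must be non-negative")
  ne <- length(te_s)
  M <- matrix(mag, ncol = ne)[as.vector(mask), , drop = FALSE]
  nv <- nrow(M)

  bad <- rowSums(M > 0) < 2
  Mf <- pmax(M, 1e-300)

  # log-linear initialization
  y <- log(Mf)
  tbar <- mean(te_s); te_c <- te_s - tbar
  slope <- as.vector(y %*% te_c) / sum(te_c^2)
  r <- pmax(-slope, 0)
  s0 <- exp(rowMeans(y) + r * tbar)
  r_init <- r; s0_init <- s0

  converged <- rep(FALSE, nv)
  for (it in seq_len(max_iter)) {
    E <- exp(-outer(r, te_s))              # nv x ne
    res <- s0 * E - M
    # Jacobian columns: dS/dS0 = E, dS/dR = -s0 te E
    a11 <- rowSums(E * E)
    a12 <- rowSums(E * (-s0 * E * rep(te_s, each = nv)))
    a22 <- rowSums((s0 * E * rep(te_s, each = nv))^2)
    g1 <- rowSums(E * res)
    g2 <- rowSums(-s0 * E * rep(te_s, each = nv) * res)
    det <- a11 * a22 - a12^2
    det[det <= 1e-300] <- NA
    d_s0 <- -(a22 * g1 - a12 * g2) / det
    d_r  <- -(a11 * g2 - a12 * g1) / det
    step_ok <- is.finite(d_s0) & is.finite(d_r)
    d_s0[!step_ok] <- 0; d_r[!step_ok] <- 0
    s0 <- s0 + d_s0
    r <- r + d_r
    rel <- sqrt(d_s0^2 + d_r^2) / pmax(sqrt(s0^2 + r^2), 1e-12)
    newly <- step_ok & rel < tol
    converged <- converged | newly
    if (all(converged | bad)) break
  }
  # non-converged or degenerate steps fall back to the log-linear estimate
  fb <- !converged & !bad
  r[fb] <- r_init[fb]; s0[fb] <- s0_init[fb]

  n_clipped <- sum(r < 0, na.rm = TRUE)
  r <- pmax(r, 0)
  r[bad] <- NA_real_; s0[bad] <- NA_real_
  E <- exp(-outer(ifelse(is.na(r), 0, r), te_s))
  resid <- sqrt(rowSums((ifelse(is.na(s0), 0, s0) * E - M)^2))
  resid[bad] <- NA_real_

  snr_last <- stats::median(M[!bad, ne] / pmax(resid[!bad] / sqrt(ne), 1e-12), na.rm = TRUE)
  if (is.finite(snr_last) && snr_last < 10) {
    warning("last-echo SNR below 10: magnitude-only fitting can underestimate R2*")
  }

  unpack <- function(v, fill = NA_real_) {
    out <- array(fill, dm[1:3]); out[mask] <- v; out
  }
  list(
    r2s_hat = unpack(r), s0_hat = unpack(s0),
    diagnostics = list(resid_norm = unpack(resid),
                       converged = unpack(converged, NA) == 1,
                       n_clipped = n_clipped, n_undefined = sum(bad))
  )
}

#' Tissue frequency map from multi-echo phase
#'
#' Estimates the off-resonance frequency (Hz) by weighted least-squares
#' regression of the echo phases on `2 pi TE`, after temporal unwrapping:
#' each echo's phase is unwrapped against the prediction extrapolated from
#' the earlier echoes, so frequencies whose phase advances by more than pi
#' between echoes are still recovered. If any echo shows spatial wraps
#' inside the mask, spatial unwrapping ([spatial_unwrap()]) is applied to
#' that echo first. Weights are `magnitude^2 * TE` (normalized per voxel),
#' emphasizing late, high-SNR echoes as in weighted echo averaging.
#'
#' @param phase 4D phase array `(x, y, z, echo)` in radians.
#' @param te_s echo times (s), at least 2.
#' @param magnitude 4D magnitude array for the weights.
#' @param mask logical 3D mask.
#' @param intercept estimate a per-voxel phase offset (default TRUE).
#' @return 3D array `f_hat` (Hz), `NA` outside the mask.
#' @export
frequency_map <- function(phase, te_s, magnitude, mask, intercept = TRUE) {
  if (length(te_s) < 2) stop("at least two echoes are required")
  dm <- dim(phase)
  ne <- length(te_s)
  # spatial unwrap echoes that wrap inside the mask
  for (e in seq_len(ne)) {
    ph <- array(phase[, , , e], dm[1:3])
    if (has_spatial_wraps(ph, mask)) {
      phase[, , , e] <- spatial_unwrap(ph, mask)$unwrapped
    }
  }
  P <- matrix(phase, ncol = ne)[as.vector(mask), , drop = FALSE]
  W <- matrix(magnitude, ncol = ne)[as.vector(mask), , drop = FALSE]^2 *
    rep(te_s, each = sum(mask))

  # temporal unwrapping against the running linear prediction
  for (e in 2:ne) {
    pred <- if (e == 2) P[, 1] * te_s[2] / te_s[1] else {
      # slope through echoes 1..e-1 (unweighted, offset-free prediction)
      (P[, 1:(e - 1), drop = FALSE] %*% te_s[1:(e - 1)]) /
        sum(te_s[1:(e - 1)]^2) * te_s[e]
    }
    P[, e] <- P[, e] + 2 * pi * round((pred - P[, e]) / (2 * pi))
  }

  x <- 2 * pi * te_s
  if (intercept) {
    sw <- rowSums(W)
    xw <- W %*% x / sw
    yw <- rowSums(W * P) / sw
    num <- rowSums(W * (rep(x, each = nrow(P)) - as.vector(xw)) * P)
    den <- rowSums(W * (rep(x, each = nrow(P)) - as.vector(xw))^2)
    f <- num / den
  } else {
    f <- rowSums(W * rep(x, each = nrow(P)) * P) / rowSums(W * rep(x^2, each = nrow(P)))
  }
  out <- array(NA_real_, dm[1:3]); out[mask] <- f
  out
}

#' @keywords internal
has_spatial_wraps <- function(ph, mask) {
  dm <- dim(ph)
  for (ax in 1:3) {
    if (dm[ax] < 2) next
    lo <- lapply(dm, seq_len); hi <- lo
    lo[[ax]] <- 1:(dm[ax] - 1); hi[[ax]] <- 2:dm[ax]
    d <- abs(ph[hi[[1]], hi[[2]], hi[[3]], drop = FALSE] -
               ph[lo[[1]], lo[[2]], lo[[3]], drop = FALSE])
    m <- mask[hi[[1]], hi[[2]], hi[[3]], drop = FALSE] &
      mask[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]
    if (any(d[m] > pi)) return(TRUE)
  }
  FALSE
}

#' Quality-guided spatial phase unwrapping
#'
#' Flood-fill phase unwrapper: growth starts at the highest-quality voxel of
#' each connected mask component (quality = negative local wrapped
#' phase-gradient variance) and proceeds layer by layer; every frontier
#' voxel is unwrapped against its best-quality already-unwrapped neighbour
#' by adding the multiple of 2 pi that minimizes the jump. The sweep over
#' layers is fully vectorized. Disconnected mask components are unwrapped
#' independently; each keeps its own (arbitrary) global 2 pi offset.
#'
#' @param phase_3d 3D wrapped phase in (-pi, pi].
#' @param mask logical 3D mask.
#' @return List with `unwrapped` (equal to the input modulo 2 pi voxelwise)
#'   and `n_components` (number of independently unwrapped components).
#' @export
spatial_unwrap <- function(phase_3d, mask) {
  dm <- dim(phase_3d)
  unwrapped <- phase_3d
  processed <- array(FALSE, dm)
  quality <- local_phase_quality(phase_3d, mask)

  # neighbour gather: value of a at the neighbour one step along axis/dir
  nbr <- function(a, ax, dir, fill) {
    out <- array(fill, dm)
    n <- dm[ax]
    if (n < 2) return(out)
    src <- if (dir > 0) 2:n else 1:(n - 1)
    dst <- if (dir > 0) 1:(n - 1) else 2:n
    ix <- function(which) switch(ax, list(which, TRUE, TRUE),
                                 list(TRUE, which, TRUE), list(TRUE, TRUE, which))
    out[ix(dst)[[1]], ix(dst)[[2]], ix(dst)[[3]]] <-
      a[ix(src)[[1]], ix(src)[[2]], ix(src)[[3]]]
    out
  }

  n_components <- 0L
  while (any(mask & !processed)) {
    cand <- which(mask & !processed)
    seed <- cand[which.max(quality[cand])]
    processed[seed] <- TRUE
    n_components <- n_components + 1L
    repeat {
      ref_val <- array(NA_real_, dm)
      ref_q <- array(-Inf, dm)
      for (ax in 1:3) {
        for (dir in c(1L, -1L)) {
          pn <- nbr(processed & mask, ax, dir, FALSE)
          vn <- nbr(unwrapped, ax, dir, NA_real_)
          qn <- nbr(quality, ax, dir, -Inf)
          take <- pn & qn > ref_q
          ref_q[take] <- qn[take]
          ref_val[take] <- vn[take]
        }
      }
      frontier <- mask & !processed & !is.na(ref_val)
      if (!any(frontier)) break
      unwrapped[frontier] <- phase_3d[frontier] +
        2 * pi * round((ref_val[frontier] - phase_3d[frontier]) / (2 * pi))
      processed[frontier] <- TRUE
    }
  }
  list(unwrapped = unwrapped, n_components = n_components)
}

#' @keywords internal
local_phase_quality <- function(ph, mask) {
  wrap <- function(x) Arg(exp(1i * x))
  dm <- dim(ph)
  acc <- array(0, dm); cnt <- array(0, dm)
  shifts <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  shifts <- Filter(function(s) all(dm - s >= 1), shifts)
  for (s in shifts) {
    a <- array(0, dm)
    i1 <- seq_len(dm[1] - s[1]); j1 <- seq_len(dm[2] - s[2]); k1 <- seq_len(dm[3] - s[3])
    i2 <- i1 + s[1]; j2 <- j1 + s[2]; k2 <- k1 + s[3]
    d <- wrap(ph[i2, j2, k2, drop = FALSE] - ph[i1, j1, k1, drop = FALSE])
    a[i1, j1, k1] <- a[i1, j1, k1] + d^2
    acc <- acc + a
    cnt[i1, j1, k1] <- cnt[i1, j1, k1] + 1
  }
  q <- -acc / pmax(cnt, 1)
  q[!mask] <- -Inf
  q
}

#' V-SHARP background field removal
#'
#' Removes background field contributions (sources outside the mask) by
#' variable-radius spherical-mean-value (SMV) filtering: at every voxel the
#' largest sphere radius that still fits inside the mask is used, the
#' sphere-mean filtered field is subtracted, and the residual high-pass
#' field is deconvolved by the smallest-radius SMV kernel with truncated
#' inversion.
#'
#' @param f_total 3D off-resonance map (Hz).
#' @param mask logical 3D brain mask.
#' @param radii_mm descending vector of SMV radii (mm).
#' @param voxel_mm voxel size (mm).
#' @param trunc truncation threshold for the deconvolution (default 0.05).
#' @return List with `f_tissue` (Hz, `NA` outside the eroded mask) and
#'   `eroded_mask` (erosion of `mask` by the smallest radius).
#' @export
vsharp_background_removal <- function(f_total, mask, radii_mm = c(6, 5, 4, 3, 2, 1),
                                      voxel_mm = c(1, 1, 1), trunc = 0.05) {
  if (length(radii_mm) < 1 || is.unsorted(rev(radii_mm))) {
    stop("radii_mm must be a descending list with at least one radius")
  }
  vox <- as_len3(voxel_mm, "voxel_mm")
  dm <- dim(f_total)
  f0 <- f_total; f0[!mask] <- 0

  highpass <- array(NA_real_, dm)
  assigned <- array(FALSE, dm)
  bands <- list()
  kernels <- list()
  for (r in radii_mm) {
    ker <- smv_kernel(dm, vox, r)     # k-space sphere-mean kernel (DFT of it)
    er <- erode_mask_fft(mask, ker)
    if (!any(er)) next
    sm <- Re(fft(fft(f0) * ker, inverse = TRUE)) / prod(dm)
    sel <- er & !assigned
    highpass[sel] <- f_total[sel] - sm[sel]
    assigned <- assigned | er
    bands[[length(bands) + 1]] <- sel
    kernels[[length(kernels) + 1]] <- ker
  }
  if (!length(bands)) {
    stop("mask is smaller than the smallest SMV sphere")
  }
  # deconvolve each radius band with its own (delta - SMV_r) kernel,
  # truncating near-singular filter values
  hp <- highpass; hp[!assigned] <- 0
  hk <- fft(hp)
  f_tissue <- array(NA_real_, dm)
  for (i in seq_along(bands)) {
    filt <- 1 - kernels[[i]]
    inv <- ifelse(Mod(filt) < trunc, 0, 1 / filt)
    dec <- Re(fft(hk * inv, inverse = TRUE)) / prod(dm)
    f_tissue[bands[[i]]] <- dec[bands[[i]]]
  }
  list(f_tissue = f_tissue, eroded_mask = assigned)
}

# DFT of the normalized sphere indicator (sphere-mean filter) of radius r_mm.
#' @keywords internal
smv_kernel <- function(dm, vox, r_mm) {
  x <- c(0:(dm[1] %/% 2), -((dm[1] - dm[1] %/% 2 - 1):1)) * vox[1]
  y <- c(0:(dm[2] %/% 2), -((dm[2] - dm[2] %/% 2 - 1):1)) * vox[2]
  z <- c(0:(dm[3] %/% 2), -((dm[3] - dm[3] %/% 2 - 1):1)) * vox[3]
  X2 <- array(rep(x^2, times = dm[2] * dm[3]), dm)
  Y2 <- array(rep(rep(y^2, each = dm[1]), times = dm[3]), dm)
  Z2 <- array(rep(z^2, each = dm[1] * dm[2]), dm)
  sph <- (X2 + Y2 + Z2) <= r_mm^2
  fft(sph / sum(sph))
}

# Erode a mask by an SMV sphere: keep voxels whose sphere lies fully inside.
#' @keywords internal
erode_mask_fft <- function(mask, ker) {
  dm <- dim(mask)
  conv <- Re(fft(fft(mask + 0) * ker, inverse = TRUE)) / prod(dm)
  conv > 1 - 1e-6
}

#' Dipole inversion (TKD or Tikhonov)
#'
#' Inverts the tissue field for susceptibility using the k-space dipole
#' kernel: thresholded k-space division (`tkd`, kernel values clamped away
#' from zero at `param`, default 0.2) or Tikhonov-regularized closed form
#' (`tikhonov`, `chi_k = D f_k / (D^2 + param)`). The result is converted to
#' ppb and referenced to a zero mean over the mask.
#'
#' @param f_tissue 3D tissue field (Hz); values outside `mask` are ignored.
#' @param mask logical 3D mask (non-empty).
#' @param b0_tesla main field strength (T).
#' @param voxel_mm voxel size (mm).
#' @param method `"tkd"` or `"tikhonov"`.
#' @param param TKD threshold in (0, 1] or Tikhonov lambda >= 0.
#' @param underestimation_correction for TKD, divide the result by the mean
#'   k-space response of the truncated operator, compensating the known
#'   systematic amplitude underestimation of thresholded division
#'   (default TRUE).
#' @return 3D `chi_hat` (ppb, brain-mean referenced), `NA` outside the mask.
#' @export
dipole_inversion <- function(f_tissue, mask, b0_tesla, voxel_mm = c(1, 1, 1),
                             method = c("tkd", "tikhonov"), param = NULL,
                             underestimation_correction = TRUE) {
  method <- match.arg(method)
  if (!any(mask)) stop("empty mask")
  if (is.null(param)) param <- if (method == "tkd") 0.2 else 0.01
  if (method == "tkd" && (param <= 0 || param > 1)) stop("tkd threshold must be in (0, 1]")
  if (method == "tikhonov" && param < 0) stop("tikhonov lambda must be >= 0")
  vox <- as_len3(voxel_mm, "voxel_mm")
  dm <- dim(f_tissue)
  f <- f_tissue; f[!mask | !is.finite(f_tissue)] <- 0
  # field (Hz) -> ppm-equivalent normalized field, then invert the kernel
  fk <- fft(f / (GAMMA_HZ_PER_T * b0_tesla * 1e-9))   # ppb units
  D <- dipole_kernel(dm, vox)
  inv <- switch(method,
    tkd = 1 / (sign(D) * pmax(abs(D), param) + (D == 0) * param),
    tikhonov = D / (D^2 + param)
  )
  chi <- Re(fft(fk * inv, inverse = TRUE)) / prod(dm)
  if (method == "tkd" && underestimation_correction) {
    # mean response of the truncated operator (1 outside the cone,
    # |D|/threshold inside); the recovered amplitude scales with it
    chi <- chi / mean(abs(D * inv))
  }
  chi[!mask] <- NA_real_
  chi - mean(chi[mask])
}

#' Full quantification chain for one multi-echo image
#'
#' Runs [fit_r2star()], [frequency_map()], [vsharp_background_removal()] and
#' [dipole_inversion()] and assembles the quantitative maps.
#'
#' @param image an `epiqsm_image`.
#' @param mask logical brain mask.
#' @param what which maps to compute, subset of `c("r2s", "f", "chi")`
#'   (`"chi"` implies `"f"`).
#' @param radii_mm V-SHARP radii (mm), descending.
#' @param qsm_method,qsm_param dipole-inversion settings.
#' @param b0_tesla main field (T).
#' @return An `epiqsm_quantmaps` list: `r2s_hat`, `s0_hat`, `f_hat`,
#'   `chi_hat` (requested entries only), `mask` (analysis mask),
#'   `eroded_mask` (QSM-valid mask, when chi is computed) and
#'   `fit_diagnostics`.
#' @export
quantify_maps <- function(image, mask, what = c("r2s", "f", "chi"),
                          radii_mm = NULL, qsm_method = "tkd",
                          qsm_param = NULL, b0_tesla = 3) {
  what <- match.arg(what, several.ok = TRUE)
  if ("chi" %in% what) what <- union(what, "f")
  vox <- image$voxel_mm
  if (is.null(radii_mm)) radii_mm <- rev(seq_len(6)) * min(vox)
  mag <- magnitude(image)
  out <- list(mask = mask)
  if ("r2s" %in% what) {
    fit <- fit_r2star(mag, image$te_s, mask)
    out$r2s_hat <- fit$r2s_hat
    out$s0_hat <- fit$s0_hat
    out$fit_diagnostics <- fit$diagnostics
  }
  if ("f" %in% what) {
    out$f_hat <- frequency_map(phase(image), image$te_s, mag, mask)
  }
  if ("chi" %in% what) {
    f0 <- out$f_hat; f0[!is.finite(f0)] <- 0
    bg <- vsharp_background_removal(f0, mask, radii_mm = radii_mm, voxel_mm = vox)
    out$chi_hat <- dipole_inversion(bg$f_tissue, bg$eroded_mask, b0_tesla, vox,
                                    method = qsm_method, param = qsm_param)
    out$eroded_mask <- bg$eroded_mask
  }
  structure(out, class = "epiqsm_quantmaps")
}
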