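# Reconstruction of shot-resolved k-space in two modes:
#   corrected   — per-shot global-B0, linear-B0 and translation demodulation
#   uncorrected — only the scan-average global B0 is demodulated
#
# The corrected mode undoes the global frequency offset (scalar phase per
# shot and echo), the translation (conjugate Fourier-shift phase) and the
# readout-direction linear B0 term (hybrid-space ramp) exactly; linear B0
# along the phase-encode axes is undone by spreading each line through the
# conjugate modulation kernel, which is exact in the limit of small shifts
# and first-order accurate otherwise (a full iterative NUFFT solve is out of
# scope; simulated linear terms are small).

#' @keywords internal
new_multiecho_image <- function(data, te_s, voxel_mm, provenance = list()) {
  structure(list(data = data, te_s = te_s, voxel_mm = as_len3(voxel_mm, "voxel_mm"),
                 provenance = provenance),
            class = "epiqsm_image")
}

#' @export
print.epiqsm_image <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("epiqsm multi-echo image: %s, %d echoes (TE %s ms), mode '%s'\n",
              paste(dm[1:3], collapse = "x"), dm[4],
              paste(round(x$te_s * 1000, 1), collapse = "/"),
              if (is.null(x$provenance$mode)) "?" else x$provenance$mode))
  invisible(x)
}

#' Magnitude view of a multi-echo image
#' @param image an `epiqsm_image`.
#' @param echo optional echo index; default returns the 4D magnitude array.
#' @export
magnitude <- function(image, echo = NULL) {
  if (is.null(echo)) Mod(image$data) else Mod(image$data[, , , echo])
}

#' Phase view of a multi-echo image
#' @param image an `epiqsm_image`.
#' @param echo optional echo index.
#' @export
phase <- function(image, echo = NULL) {
  if (is.null(echo)) Arg(image$data) else Arg(image$data[, , , echo])
}

#' Reconstruct a multi-echo image from simulated k-space
#'
#' @param kdata an `epiqsm_kspace` from [simulate_scan()].
#' @param mode `"corrected"` (shot-wise global + linear B0 and translation
#'   demodulation) or `"uncorrected"` (scan-average global B0 only).
#' @param timeline the timeline to correct with: the simulation ground truth
#'   (oracle correction) or a [estimate_timeline()] result. Defaults to the
#'   timeline stored in `kdata`.
#' @param repetition repetition index recorded in the provenance.
#' @param coil_sens coil sensitivities matching the simulation, required for
#'   multi-coil k-space; unaliasing is a direct per-voxel-group least-squares
#'   solve. Single-coil undersampled data is density-compensated and
#'   zero-filled instead.
#' @return An `epiqsm_image` with complex 4D data `(x, y, z, echo)`.
#' @export
reconstruct <- function(kdata, mode = c("corrected", "uncorrected"),
                        timeline = NULL, repetition = 1L, coil_sens = NULL) {
  mode <- match.arg(mode)
  if (is.null(timeline)) timeline <- kdata$timeline
  if (is.null(timeline)) stop("a timeline is required (mode '", mode, "')")
  if (timeline$n_shots != kdata$n_shots) stop("timeline does not cover all shots")
  if (kdata$ncoil > 1 && is.null(coil_sens)) {
    stop("coil_sens is required to reconstruct multi-coil k-space")
  }

  pr <- kdata$protocol
  nx <- pr$matrix[1]; ny <- pr$matrix[2]; nz <- pr$matrix[3]
  ne <- length(kdata$echo_data)
  out <- array(0i, c(nx, ny, nz, ne))
  if (kdata$ncoil == 1L) {
    dens <- prod(pr$accel)
    for (e in seq_len(ne)) {
      K <- assemble_kgrid(kdata, e, mode, timeline)
      out[, , , e] <- uifft(K * dens)
    }
  } else {
    ak <- alias_kernel(kdata$pattern)
    for (e in seq_len(ne)) {
      coil_img <- array(0i, c(nx, ny, nz, kdata$ncoil))
      for (cc in seq_len(kdata$ncoil)) {
        K <- assemble_kgrid(kdata, e, mode, timeline, coil = cc)
        coil_img[, , , cc] <- uifft(K)
      }
      out[, , , e] <- unalias_lsq(coil_img, coil_sens, ak)
    }
  }
  new_multiecho_image(out, pr$te_s, kdata$voxel_mm,
                      list(mode = mode, protocol = pr$name,
                           repetition = repetition, seed = kdata$seed))
}

# Aliasing kernel of a regular (CAIPI) lattice: image-domain shifts d and
# complex weights c_d such that the zero-filled reconstruction equals
# sum_d c_d * rho(v - d). Derived numerically from the PE mask.
#' @keywords internal
alias_kernel <- function(pattern) {
  ny <- pattern$ny; nz <- pattern$nz
  M <- matrix(0, ny, nz)
  jy <- centred_to_storage(pattern$lines[, "ky"], ny)
  jz <- centred_to_storage(pattern$lines[, "kz"], nz)
  M[cbind(jy, jz)] <- 1
  h <- fft(M, inverse = TRUE) / (ny * nz)
  idx <- which(Mod(h) > 1e-9, arr.ind = TRUE)
  list(dy = idx[, 1] - 1L, dz = idx[, 2] - 1L, w = h[idx])
}

# Direct least-squares unaliasing of zero-filled coil images. Each aliasing
# group {v + d_r} is solved jointly: the measurement at group position q is
# sum_r c_(d_q - d_r) S_c(p_r) rho(p_r), stacked over coils.
#' @keywords internal
unalias_lsq <- function(coil_img, coil_sens, ak) {
  dm <- dim(coil_img)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]; ncoil <- dm[4]
  R <- length(ak$w)
  if (R == 1L) {
    num <- array(0i, dm[1:3]); den <- array(0, dm[1:3])
    for (cc in seq_len(ncoil)) {
      num <- num + Conj(coil_sens[, , , cc]) * coil_img[, , , cc]
      den <- den + Mod(coil_sens[, , , cc])^2
    }
    return(num / pmax(den, 1e-12) / ak$w[1])
  }
  # weight connecting group positions q and r: c at shift d_q - d_r
  cmat <- matrix(0i, R, R)
  for (q in seq_len(R)) {
    for (r in seq_len(R)) {
      ddy <- (ak$dy[q] - ak$dy[r]) %% ny
      ddz <- (ak$dz[q] - ak$dz[r]) %% nz
      m <- which(ak$dy == ddy & ak$dz == ddz)
      cmat[q, r] <- if (length(m)) ak$w[m[1]] else 0i
    }
  }
  out <- array(0i, dm[1:3])
  solved <- array(FALSE, c(ny, nz))
  for (vy in seq_len(ny)) {
    for (vz in seq_len(nz)) {
      if (solved[vy, vz]) next
      gy <- ((vy - 1L + ak$dy) %% ny) + 1L
      gz <- ((vz - 1L + ak$dz) %% nz) + 1L
      for (x in seq_len(nx)) {
        Smat <- matrix(0i, ncoil, R)
        for (r in seq_len(R)) Smat[, r] <- coil_sens[x, gy[r], gz[r], ]
        A <- matrix(0i, ncoil * R, R)
        b <- complex(ncoil * R)
        for (q in seq_len(R)) {
          rows <- (q - 1L) * ncoil + seq_len(ncoil)
          A[rows, ] <- Smat * rep(cmat[q, ], each = ncoil)
          b[rows] <- coil_img[x, gy[q], gz[q], ]
        }
        rho <- qr.solve(A, b)
        out[cbind(x, gy, gz)] <- rho
      }
      solved[cbind(gy, gz)] <- TRUE
    }
  }
  out
}

# Assemble the full (corrected or uncorrected) k-space grid for one echo.
#' @keywords internal
assemble_kgrid <- function(kdata, e, mode, timeline, coil = NULL) {
  pr <- kdata$protocol
  nx <- pr$matrix[1]; ny <- pr$matrix[2]; nz <- pr$matrix[3]
  te <- pr$te_s[e]
  lines <- kdata$lines
  shot <- kdata$line_shot
  vox <- kdata$voxel_mm
  data <- kdata$echo_data[[e]]
  if (!is.null(coil)) data <- data[, , coil]
  m_y <- lines[, "ky"] - ny %/% 2
  m_z <- lines[, "kz"] - nz %/% 2
  mx <- kfreq(nx)

  if (mode == "uncorrected") {
    data <- data * exp(-2i * pi * mean(timeline$global_hz) * te)
    gy <- gz <- numeric(length(shot))
  } else {
    gl <- timeline$global_hz[shot]
    sx <- timeline$trans_mm[shot, 1] / vox[1]
    sy <- timeline$trans_mm[shot, 2] / vox[2]
    sz <- timeline$trans_mm[shot, 3] / vox[3]
    ph <- exp(-2i * pi * gl * te) * exp(2i * pi * (m_y * sy / ny + m_z * sz / nz))
    data <- data * rep(ph, each = nx)
    if (any(sx != 0)) data <- data * exp(2i * pi * outer(mx / nx, sx))
    if (any(timeline$grad_hz_per_mm[, 1] != 0)) {
      x_mm <- axis_mm(nx, vox[1])
      for (s in which(timeline$grad_hz_per_mm[, 1] != 0)) {
        idx <- which(shot == s)
        ramp <- exp(-2i * pi * te * timeline$grad_hz_per_mm[s, 1] * x_mm)
        d <- stats::mvfft(stats::mvfft(data[, idx, drop = FALSE], inverse = TRUE) * ramp) / nx
        data[, idx] <- d
      }
    }
    gy <- timeline$grad_hz_per_mm[shot, 2]
    gz <- timeline$grad_hz_per_mm[shot, 3]
  }

  K <- array(0i, c(nx, ny, nz))
  jy <- centred_to_storage(lines[, "ky"], ny)
  jz <- centred_to_storage(lines[, "kz"], nz)
  plain <- gy == 0 & gz == 0
  if (any(plain)) {
    idx <- which(plain)
    Km <- matrix(0i, nx, ny * nz)
    Km[, jy[idx] + ny * (jz[idx] - 1L)] <- data[, idx]
    K <- array(Km, c(nx, ny, nz))
  }
  if (any(!plain)) {
    # conjugate phase-encode modulation kernels, spread over the grid
    idx <- which(!plain)
    y_mm <- axis_mm(ny, vox[2]); z_mm <- axis_mm(nz, vox[3])
    Wy <- matrix(0i, ny, length(idx)); Wz <- matrix(0i, nz, length(idx))
    for (j in seq_along(idx)) {
      l <- idx[j]
      ky_kernel <- fft(exp(-2i * pi * te * gy[l] * y_mm)) / ny
      kz_kernel <- fft(exp(-2i * pi * te * gz[l] * z_mm)) / nz
      # kernel centred on the line's own (ky, kz) position
      Wy[, j] <- ky_kernel[((seq_len(ny) - jy[l]) %% ny) + 1L]
      Wz[, j] <- kz_kernel[((seq_len(nz) - jz[l]) %% nz) + 1L]
    }
    iy <- rep(seq_len(ny), times = nz)
    iz <- rep(seq_len(nz), each = ny)
    W <- Wy[iy, , drop = FALSE] * Wz[iz, , drop = FALSE]
    Kadd <- data[, idx, drop = FALSE] %*% t(W)
    K <- K + array(Kadd, c(nx, ny, nz))
  }
  K
}

#' EPI odd/even (Nyquist ghost) phase correction
#'
#' Compensates the alternating readout-gradient polarity of an EPI echo
#' train: odd-parity lines within each shot are demodulated in the hybrid
#' readout (x) space by a constant plus linear phase. The calibration phase
#' is estimated from the stored non-phase-encoded central-line pair acquired
#' with both polarities (weighted least-squares fit of the odd/even phase
#' difference against readout position), or can be supplied directly.
#'
#' @param kdata an `epiqsm_kspace`.
#' @param calib_phase optional length-2 numeric `c(constant_rad,
#'   linear_rad_per_sample)`; when `NULL` it is estimated from the
#'   calibration line pair (an error if that pair is missing).
#' @return The corrected `epiqsm_kspace`.
#' @export
epi_phase_correction <- function(kdata, calib_phase = NULL) {
  nx <- kdata$protocol$matrix[1]
  if (is.null(calib_phase)) {
    if (is.null(kdata$calib)) stop("no calibration line pair available for phase estimation")
    calib_phase <- estimate_oddeven_phase(kdata$calib$even, kdata$calib$odd)
  }
  if (all(calib_phase == 0)) return(kdata)
  odd <- which(kdata$pos_in_shot %% 2 == 1L)
  if (!length(odd)) return(kdata)
  ramp <- exp(-1i * (calib_phase[1] + calib_phase[2] * (0:(nx - 1) - nx %/% 2)))
  for (e in seq_along(kdata$echo_data)) {
    d <- kdata$echo_data[[e]][, odd, drop = FALSE]
    d <- stats::mvfft(stats::mvfft(d, inverse = TRUE) * ramp) / nx
    kdata$echo_data[[e]][, odd] <- d
  }
  kdata$oddeven_corrected <- calib_phase
  kdata
}

# Estimate constant + linear odd/even phase from a calibration line pair.
#' @keywords internal
estimate_oddeven_phase <- function(even, odd) {
  nx <- length(even)
  pe <- fft(even, inverse = TRUE) / nx   # hybrid x-space profiles
  po <- fft(odd, inverse = TRUE) / nx
  w <- Mod(pe) * Mod(po)
  dphi <- Arg(po * Conj(pe))
  x <- 0:(nx - 1) - nx %/% 2
  keep <- w > 0.05 * max(w)
  fit <- stats::lm.wfit(cbind(1, x[keep]), dphi[keep], w[keep])
  c(constant_rad = fit$coefficients[[1]], linear_rad_per_sample = fit$coefficients[[2]])
}

#' Estimate a physiological timeline from navigator phase series
#'
#' Given per-shot low-resolution navigator phase maps (unwrapped relative to
#' the first shot and already spatially aligned), fits per shot the linear
#' off-resonance model `f(r) = a + g . r` by weighted least squares of
#' `phase / (2 pi nav_te)` over the support mask, mirroring navigator-based
#' B0 tracking at the nominal navigator echo time of 3.9 ms.
#'
#' @param nav_phase_series 4D array `(x, y, z, shot)` of navigator phase
#'   maps (rad), or a list of 3D arrays.
#' @param nav_te_s navigator echo time (s), default 0.0039.
#' @param voxel_mm navigator voxel size (mm).
#' @param mask logical support mask (at least 10 voxels).
#' @return An `epiqsm_timeline` with an extra `residual_hz` field (per-shot
#'   RMS residual of the fit); translations are zero (navigator magnitude
#'   registration is not modelled).
#' @export
estimate_timeline <- function(nav_phase_series, nav_te_s = 0.0039, voxel_mm, mask) {
  if (is.list(nav_phase_series)) {
    nav_phase_series <- array(unlist(nav_phase_series),
                              c(dim(nav_phase_series[[1]]), length(nav_phase_series)))
  }
  if (nav_te_s <= 0) stop("nav_te_s must be positive")
  dm <- dim(nav_phase_series)
  if (sum(mask) < 10) stop("degenerate support: fewer than 10 voxels in mask")
  vox <- as_len3(voxel_mm, "voxel_mm")
  x <- axis_mm(dm[1], vox[1]); y <- axis_mm(dm[2], vox[2]); z <- axis_mm(dm[3], vox[3])
  X <- array(rep(x, times = dm[2] * dm[3]), dm[1:3])[mask]
  Y <- array(rep(rep(y, each = dm[1]), times = dm[3]), dm[1:3])[mask]
  Z <- array(rep(z, each = dm[1] * dm[2]), dm[1:3])[mask]
  A <- cbind(1, X, Y, Z)
  n_shots <- dm[4]
  qrA <- qr(A)
  global <- numeric(n_shots); grad <- matrix(0, n_shots, 3); res <- numeric(n_shots)
  for (s in seq_len(n_shots)) {
    f <- nav_phase_series[, , , s][mask] / (2 * pi * nav_te_s)
    cf <- qr.coef(qrA, f)
    global[s] <- cf[1]; grad[s, ] <- cf[2:4]
    res[s] <- sqrt(mean((f - A %*% cf)^2))
  }
  tl <- structure(list(n_shots = as.integer(n_shots), global_hz = global,
                       grad_hz_per_mm = grad, trans_mm = matrix(0, n_shots, 3),
                       tr_s = NA_real_, seed = NA_integer_, residual_hz = res),
                  class = "epiqsm_timeline")
  tl
}
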