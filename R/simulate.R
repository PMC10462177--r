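# Shot-resolved k-space simulation.
#
# The simulator is an "inverse crime" by design: the multi-echo image is
# synthesized on the reconstruction grid, modulated per shot by the
# physiological state, transformed by a unitary DFT and sampled on the
# protocol's phase-encode lattice. This keeps every acquired sample an exact
# evaluation of the forward model, so reconstruction contracts can be tested
# to numerical precision.
#
# Sampling-pattern line indices (ky, kz) use the centred layout: the k-space
# centre (DC) sits at index N/2 along each phase-encode axis. Internally
# values are stored per line, not on a grid.

# storage (DFT-layout) index for a centred-layout phase-encode index
#' @keywords internal
centred_to_storage <- function(p, n) ((p - n %/% 2) %% n) + 1L

#' Simulate one repetition of a multi-echo scan
#'
#' For each shot `s` and echo `e`, forms the image-domain signal
#' `m0 * exp(-R2* TE_e) * exp(2i pi (f_chi + f_s(r)) TE_e)` with the
#' shot-specific off-resonance `f_s(r) = global_hz[s] + grad_hz_per_mm[s] . r`,
#' applies the shot's rigid translation as a Fourier shift, takes the unitary
#' 3D DFT and extracts the shot's assigned phase-encode lines, then adds
#' i.i.d. circular complex Gaussian noise (`noise_sigma` per real and
#' imaginary component of every sample).
#'
#' When no shot carries a spatially linear B0 term along the phase-encode
#' axes, per-shot modulation reduces to scalar k-space phases plus a
#' readout-direction hybrid-space ramp, and the whole scan is computed from
#' one 3D DFT per echo; otherwise the phase-encode part of the transform is
#' evaluated exactly per line as a matrix product. Both paths are exact.
#'
#' @param phantom an `epiqsm_phantom`.
#' @param protocol an `epiqsm_protocol` whose matrix equals the phantom grid
#'   (see [desk_protocol()]).
#' @param timeline an `epiqsm_timeline` with one entry per shot.
#' @param noise_sigma thermal-noise SD per real/imaginary component.
#' @param seed integer seed for the noise realization.
#' @param ordering shot segmentation ordering, `"interleaved"` or
#'   `"sequential"`.
#' @param odd_even_phase length-2 numeric `c(constant_rad, linear_rad_per_sample)`
#'   phase error injected on odd-parity lines within each EPI echo train
#'   (readout polarity alternation); `c(0, 0)` for none.
#' @param coil_sens optional 4D complex array `(x, y, z, coil)` of receive
#'   sensitivities (see [synth_coil_sens()]); when supplied each echo's data
#'   gains a coil dimension and [reconstruct()] unaliases by least squares.
#' @return An `epiqsm_kspace` object: per-echo complex line-sample matrices
#'   (`n_readout` x `n_lines`, or `n_readout` x `n_lines` x `n_coils`), the
#'   line table, shot assignment, calibration line pair, protocol, pattern,
#'   the timeline used, `noise_sigma` and `seed`.
#' @export
simulate_scan <- function(phantom, protocol, timeline, noise_sigma = 0,
                          seed = 0, ordering = c("interleaved", "sequential"),
                          odd_even_phase = c(0, 0), coil_sens = NULL) {
  ordering <- match.arg(ordering)
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  dm <- dim(phantom$m0)
  if (!all(dm == protocol$matrix)) {
    stop("protocol matrix must equal the phantom grid (use desk_protocol())")
  }
  pattern <- pattern_for_protocol(protocol)
  seg <- segment_shots(pattern, protocol$epi_factor, ordering)
  if (timeline$n_shots != seg$n_shots) {
    stop(sprintf("timeline has %d shots but the protocol needs %d",
                 timeline$n_shots, seg$n_shots))
  }

  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  lines <- pattern$lines
  L <- nrow(lines)
  shot <- seg$shot
  field <- chi_to_field(phantom)$hz
  vox <- as_len3(phantom$voxel_mm, "voxel_mm")
  x_mm <- axis_mm(nx, vox[1]); y_mm <- axis_mm(ny, vox[2]); z_mm <- axis_mm(nz, vox[3])
  m_y <- lines[, "ky"] - ny %/% 2    # centred integer frequencies per line
  m_z <- lines[, "kz"] - nz %/% 2
  mx <- kfreq(nx)

  gl <- timeline$global_hz[shot]
  gy <- timeline$grad_hz_per_mm[shot, 2]
  gz <- timeline$grad_hz_per_mm[shot, 3]
  sx <- timeline$trans_mm[shot, 1] / vox[1]   # translations in voxels
  sy <- timeline$trans_mm[shot, 2] / vox[2]
  sz <- timeline$trans_mm[shot, 3] / vox[3]
  any_pe_grad <- any(timeline$grad_hz_per_mm[, 2:3] != 0)
  any_x_grad <- any(timeline$grad_hz_per_mm[, 1] != 0)

  # position of each line within its shot's echo train (0-based), for
  # readout-polarity parity
  pos_in_shot <- integer(L)
  for (s in seq_len(seg$n_shots)) {
    idx <- which(shot == s)
    pos_in_shot[idx] <- seq_along(idx) - 1L
  }

  col_idx <- centred_to_storage(lines[, "ky"], ny) +
    ny * (centred_to_storage(lines[, "kz"], nz) - 1L)

  # sample all lines of one echo from one (coil-weighted) image
  sample_lines <- function(u, te) {
    if (!any_pe_grad) {
      K0 <- ufft(u)
      dim(K0) <- c(nx, ny * nz)
      data <- K0[, col_idx, drop = FALSE]
    } else {
      A <- stats::mvfft(matrix(u, nx)) / sqrt(nx)      # hybrid (kx, y, z)
      Ay <- exp((2i * pi * te) * outer(y_mm, gy) -
                  (2i * pi / ny) * outer(0:(ny - 1), m_y)) / sqrt(ny)
      Az <- exp((2i * pi * te) * outer(z_mm, gz) -
                  (2i * pi / nz) * outer(0:(nz - 1), m_z)) / sqrt(nz)
      iy <- rep(seq_len(ny), times = nz)
      iz <- rep(seq_len(nz), each = ny)
      W <- Ay[iy, , drop = FALSE] * Az[iz, , drop = FALSE]
      data <- A %*% W
    }

    # readout-direction linear B0: hybrid-space ramp, exact per shot
    if (any_x_grad) {
      for (s in which(timeline$grad_hz_per_mm[, 1] != 0)) {
        idx <- which(shot == s)
        ramp <- exp(2i * pi * te * timeline$grad_hz_per_mm[s, 1] * x_mm)
        d <- data[, idx, drop = FALSE]
        data[, idx] <- stats::mvfft(stats::mvfft(d, inverse = TRUE) * ramp) / nx
      }
    }

    # global frequency offset (scalar per shot) and translation (Fourier
    # shift phase)
    ph <- exp(2i * pi * gl * te) *
      exp(-2i * pi * (m_y * sy / ny + m_z * sz / nz))
    data <- data * rep(ph, each = nx)
    if (any(sx != 0)) data <- data * exp(-2i * pi * outer(mx / nx, sx))

    # odd/even readout-polarity phase error, injected in hybrid (x) space
    if (any(odd_even_phase != 0) && protocol$epi_factor > 1) {
      odd <- which(pos_in_shot %% 2 == 1L)
      if (length(odd)) {
        ramp <- exp(1i * (odd_even_phase[1] + odd_even_phase[2] * (0:(nx - 1) - nx %/% 2)))
        d <- data[, odd, drop = FALSE]
        data[, odd] <- stats::mvfft(stats::mvfft(d, inverse = TRUE) * ramp) / nx
      }
    }
    data
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  ncoil <- if (is.null(coil_sens)) 1L else dim(coil_sens)[4]
  echo_data <- vector("list", length(protocol$te_s))
  calib <- NULL
  for (e in seq_along(protocol$te_s)) {
    te <- protocol$te_s[e]
    u <- phantom$m0 * exp(-phantom$r2s * te) * exp(2i * pi * field * te)

    if (is.null(coil_sens)) {
      data <- sample_lines(u, te)
      if (noise_sigma > 0) {
        data <- data + noise_sigma *
          (matrix(stats::rnorm(nx * L), nx) + 1i * matrix(stats::rnorm(nx * L), nx))
      }
    } else {
      data <- array(0i, c(nx, L, ncoil))
      for (cc in seq_len(ncoil)) {
        dc <- sample_lines(u * coil_sens[, , , cc], te)
        if (noise_sigma > 0) {
          dc <- dc + noise_sigma *
            (matrix(stats::rnorm(nx * L), nx) + 1i * matrix(stats::rnorm(nx * L), nx))
        }
        data[, , cc] <- dc
      }
    }
    echo_data[[e]] <- data

    # calibration pair: central line read with even and odd polarity,
    # noiseless, first echo only
    if (e == 1L && protocol$epi_factor > 1) {
      K0c <- ufft(u)
      cline <- K0c[, centred_to_storage(ny %/% 2, ny), centred_to_storage(nz %/% 2, nz)]
      codd <- cline
      if (any(odd_even_phase != 0)) {
        ramp <- exp(1i * (odd_even_phase[1] + odd_even_phase[2] * (0:(nx - 1) - nx %/% 2)))
        codd <- fft(fft(cline, inverse = TRUE) / nx * ramp)
      }
      calib <- list(even = cline, odd = codd)
    }
  }

  structure(list(
    echo_data = echo_data, lines = lines, line_shot = shot,
    pos_in_shot = pos_in_shot, n_shots = seg$n_shots, partial = seg$partial,
    ordering = ordering, calib = calib, protocol = protocol, pattern = pattern,
    timeline = timeline, noise_sigma = noise_sigma, seed = seed,
    voxel_mm = vox, b0_tesla = phantom$b0_tesla, ncoil = ncoil
  ), class = "epiqsm_kspace")
}

#' @export
print.epiqsm_kspace <- function(x, ...) {
  cat(sprintf("epiqsm k-space: '%s', %d lines in %d shots (%d echoes, %d coil(s)), sigma = %g\n",
              x$protocol$name, nrow(x$lines), x$n_shots,
              length(x$echo_data), x$ncoil, x$noise_sigma))
  invisible(x)
}

#' Noiseless ideal multi-echo image of a phantom
#'
#' The reference image the simulator would produce with a null timeline and
#' zero noise: `m0 * exp(-R2* TE) * exp(2i pi f_chi TE)` per echo.
#'
#' @param phantom an `epiqsm_phantom`.
#' @param protocol an `epiqsm_protocol` (only `te_s` is used).
#' @return An `epiqsm_image` (see [reconstruct()]).
#' @export
ideal_image <- function(phantom, protocol) {
  field <- chi_to_field(phantom)$hz
  dm <- dim(phantom$m0)
  data <- array(0i, c(dm, length(protocol$te_s)))
  for (e in seq_along(protocol$te_s)) {
    te <- protocol$te_s[e]
    data[, , , e] <- phantom$m0 * exp(-phantom$r2s * te) * exp(2i * pi * field * te)
  }
  new_multiecho_image(data, protocol$te_s, phantom$voxel_mm,
                      list(mode = "ideal", protocol = protocol$name))
}

#' Synthetic smooth receive-coil sensitivities
#'
#' Generates `n_coils` smooth complex sensitivity maps: Gaussian amplitude
#' profiles centred on points around the FOV boundary with a mild linear
#' phase, normalized to unit root-sum-of-squares inside the support.
#'
#' @param shape length-3 grid size.
#' @param n_coils number of coils (default 8).
#' @return Complex 4D array `(x, y, z, coil)`.
#' @export
synth_coil_sens <- function(shape, n_coils = 8) {
  shape <- as.integer(as_len3(shape, "shape"))
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  xf <- (0:(nx - 1)) / (nx - 1) - 0.5
  yf <- (0:(ny - 1)) / (ny - 1) - 0.5
  zf <- (0:(nz - 1)) / (nz - 1) - 0.5
  X <- array(rep(xf, times = ny * nz), shape)
  Y <- array(rep(rep(yf, each = nx), times = nz), shape)
  Z <- array(rep(zf, each = nx * ny), shape)
  sens <- array(0i, c(shape, n_coils))
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils
  for (cc in seq_len(n_coils)) {
    cx <- 0.6 * cos(ang[cc]); cy <- 0.6 * sin(ang[cc])
    cz <- 0.3 * sin(2 * ang[cc])
    amp <- exp(-((X - cx)^2 + (Y - cy)^2 + (Z - cz)^2) / (2 * 0.35^2))
    ph <- 0.5 * (X * cos(ang[cc]) + Y * sin(ang[cc]))
    sens[, , , cc] <- amp * exp(2i * pi * ph)
  }
  rss <- sqrt(apply(Mod(sens)^2, 1:3, sum))
  sens / array(rep(rss, n_coils), c(shape, n_coils))
}
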