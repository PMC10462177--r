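#' Acquisition protocol presets
#'
#' Returns the three T2*-weighted protocols compared in the study design:
#' conventional multi-echo 3D GRE (equivalent to an EPI factor of 1) and
#' multi-shot multi-echo 3D EPI with EPI factors 3 and 5, all at isotropic
#' 1 mm resolution over a 240 x 180 x 144 mm FOV with 2 x 2 CAIPI
#' acceleration in the two phase-encode directions. The readout bandwidth
#' grows with the EPI factor so that, after repeating each EPI scan by its
#' EPI factor and averaging, the total acquisition time per echo — and hence
#' the SNR — is matched to GRE.
#'
#' @return A named list of three `epiqsm_protocol` objects: `GRE`, `EPIx3`,
#'   `EPIx5`.
#' @export
protocol_presets <- function() {
  mk <- function(name, te_ms, tr_ms, bw, epi_factor, etl_ms, reps) {
    new_protocol(
      name = name, matrix = c(240L, 180L, 144L), fov_mm = c(240, 180, 144),
      te_s = te_ms / 1000, tr_s = tr_ms / 1000, flip_deg = 20,
      bw_hz_per_px = bw, epi_factor = epi_factor, etl_s = etl_ms / 1000,
      accel = c(2L, 2L), caipi = TRUE, caipi_shift = 1L, repetitions = reps,
      gmax_mt_per_m = 40, slew_mt_per_m_per_ms = 200
    )
  }
  list(
    GRE   = mk("GRE",   c(14, 25, 36, 47), 60, 125, 1L,  8, 1L),
    EPIx3 = mk("EPIx3", c(13, 25, 37, 49), 64, 372, 3L, 10, 3L),
    EPIx5 = mk("EPIx5", c(13, 26, 39, 52), 66, 631, 5L, 10, 5L)
  )
}

#' Construct an acquisition protocol
#'
#' @param name protocol name.
#' @param matrix length-3 integer matrix size (readout, PE1, PE2).
#' @param fov_mm length-3 field of view (mm).
#' @param te_s strictly increasing echo times (s).
#' @param tr_s repetition time (s).
#' @param flip_deg excitation flip angle (degrees; carried, not used in the
#'   signal amplitude).
#' @param bw_hz_per_px readout bandwidth (Hz/pixel).
#' @param epi_factor k-space lines acquired per echo per TR (1 = GRE).
#' @param etl_s readout train length per echo (s).
#' @param accel length-2 acceleration factors along (PE1, PE2).
#' @param caipi logical; stagger the undersampling lattice (CAIPI).
#' @param caipi_shift integer CAIPI kz shift per sampled ky row.
#' @param repetitions number of repetitions forming one scan.
#' @param gmax_mt_per_m maximum gradient amplitude (mT/m).
#' @param slew_mt_per_m_per_ms gradient slew rate (mT/m/ms).
#' @return An `epiqsm_protocol` object.
#' @export
new_protocol <- function(name, matrix, fov_mm, te_s, tr_s, flip_deg = 20,
                         bw_hz_per_px, epi_factor = 1L, etl_s,
                         accel = c(1L, 1L), caipi = FALSE, caipi_shift = 0L,
                         repetitions = 1L, gmax_mt_per_m = 40,
                         slew_mt_per_m_per_ms = 200) {
  te_s <- as.numeric(te_s)
  if (length(te_s) < 1 || any(diff(te_s) <= 0)) stop("te_s must be strictly increasing")
  if (epi_factor < 1) stop("epi_factor must be >= 1")
  if (repetitions < 1) stop("repetitions must be >= 1")
  structure(list(
    name = name, matrix = as.integer(as_len3(matrix, "matrix")),
    fov_mm = as_len3(fov_mm, "fov_mm"), te_s = te_s, tr_s = tr_s,
    flip_deg = flip_deg, bw_hz_per_px = bw_hz_per_px,
    epi_factor = as.integer(epi_factor), etl_s = etl_s,
    accel = as.integer(accel), caipi = isTRUE(caipi),
    caipi_shift = as.integer(caipi_shift),
    repetitions = as.integer(repetitions),
    gmax_mt_per_m = gmax_mt_per_m, slew_mt_per_m_per_ms = slew_mt_per_m_per_ms
  ), class = "epiqsm_protocol")
}

#' @export
print.epiqsm_protocol <- function(x, ...) {
  cat(sprintf("epiqsm protocol '%s': %s matrix, EPI factor %d, bw %g Hz/px, %d rep(s)\n",
              x$name, paste(x$matrix, collapse = "x"), x$epi_factor,
              x$bw_hz_per_px, x$repetitions))
  cat(sprintf("  TE %s ms, TR %g ms, accel %dx%d%s\n",
              paste(round(x$te_s * 1000, 1), collapse = "/"), x$tr_s * 1000,
              x$accel[1], x$accel[2], if (x$caipi) " CAIPI" else ""))
  invisible(x)
}

#' Rescale a protocol preset to a phantom grid
#'
#' Keeps all timing, bandwidth and acceleration parameters of a preset but
#' replaces the matrix and FOV by the phantom's grid, so full in-silico
#' studies can run at desk scale. Optionally overrides the acceleration.
#'
#' @param protocol an `epiqsm_protocol`.
#' @param phantom an `epiqsm_phantom` (or list with `m0` and `voxel_mm`).
#' @param accel optional length-2 acceleration override.
#' @return A rescaled `epiqsm_protocol`.
#' @export
desk_protocol <- function(protocol, phantom, accel = NULL) {
  protocol$matrix <- dim(phantom$m0)
  protocol$fov_mm <- dim(phantom$m0) * as_len3(phantom$voxel_mm, "voxel_mm")
  if (!is.null(accel)) protocol$accel <- as.integer(accel)
  protocol
}

#' CAIPI phase-encode sampling pattern
#'
#' Builds the regular (optionally CAIPI-staggered) undersampling lattice in
#' the (ky, kz) phase-encode plane: every `ry`-th ky row is kept, and within
#' a kept row the sampled kz positions are offset by
#' `caipi_shift * (row index mod rz)` modulo `rz`, producing the sheared
#' lattice that distributes aliasing in both directions. Lines are ordered
#' kz-major then ky.
#'
#' @param ny,nz phase-encode matrix sizes.
#' @param ry,rz acceleration factors (must divide `ny`, `nz`).
#' @param caipi_shift integer stagger (0 = plain regular lattice).
#' @return An `epiqsm_pattern`: list with integer matrix `lines` (columns
#'   `ky`, `kz`, 0-based), `ny`, `nz`, `accel`, `caipi_shift`.
#' @export
caipi_pattern <- function(ny, nz, ry = 1L, rz = 1L, caipi_shift = 0L) {
  if (ry < 1 || rz < 1) stop("acceleration factors must be >= 1")
  if (ny %% ry != 0 || nz %% rz != 0) {
    stop("matrix sizes must be divisible by the acceleration factors")
  }
  ky <- seq(0L, ny - 1L, by = ry)
  rows <- lapply(seq_along(ky), function(i) {
    off <- (caipi_shift * ((i - 1L) %% rz)) %% rz
    kz <- seq(0L + off, nz - 1L, by = rz)
    cbind(ky = rep(ky[i], length(kz)), kz = kz)
  })
  lines <- do.call(rbind, rows)
  lines <- lines[order(lines[, "kz"], lines[, "ky"]), , drop = FALSE]
  structure(list(lines = lines, ny = as.integer(ny), nz = as.integer(nz),
                 accel = as.integer(c(ry, rz)), caipi_shift = as.integer(caipi_shift)),
            class = "epiqsm_pattern")
}

#' @keywords internal
pattern_for_protocol <- function(protocol) {
  caipi_pattern(protocol$matrix[2], protocol$matrix[3],
                protocol$accel[1], protocol$accel[2],
                if (protocol$caipi) protocol$caipi_shift else 0L)
}

#' Group sampled lines into EPI shots
#'
#' Assigns every line of a sampling pattern to a shot of `epi_factor` lines
#' (one TR acquires `epi_factor` lines per echo). `sequential` groups
#' consecutive lines in pattern order; `interleaved` assigns line `i` to
#' shot `i mod n_shots`, giving maximally spaced lines within each shot.
#' A final partial shot is allowed and flagged.
#'
#' @param pattern an `epiqsm_pattern`.
#' @param epi_factor lines per shot (>= 1, <= number of lines).
#' @param ordering `"interleaved"` (default) or `"sequential"`.
#' @return List with `shot` (1-based shot index per line, in pattern line
#'   order), `n_shots`, and `partial` (logical per shot).
#' @export
segment_shots <- function(pattern, epi_factor, ordering = c("interleaved", "sequential")) {
  ordering <- match.arg(ordering)
  nl <- nrow(pattern$lines)
  epi_factor <- as.integer(epi_factor)
  if (epi_factor < 1) stop("epi_factor must be >= 1")
  if (epi_factor > nl) stop("epi_factor exceeds the number of sampled lines")
  n_shots <- ceiling(nl / epi_factor)
  idx <- seq_len(nl) - 1L
  shot <- if (ordering == "sequential") idx %/% epi_factor else idx %% n_shots
  shot <- shot + 1L
  counts <- tabulate(shot, n_shots)
  list(shot = shot, n_shots = as.integer(n_shots), partial = counts < epi_factor)
}

#' Bandwidth-scaled thermal noise level
#'
#' Predicts the complex thermal-noise standard deviation of a protocol from
#' a reference protocol's noise level: noise SD scales with the square root
#' of the readout bandwidth, `sigma = ref_sigma * sqrt(bw / ref_bw)`.
#'
#' @param bw_hz_per_px target readout bandwidth (Hz/pixel).
#' @param ref_sigma reference noise SD (per real/imaginary component).
#' @param ref_bw_hz_per_px reference bandwidth (Hz/pixel).
#' @return Noise SD at the target bandwidth.
#' @export
thermal_noise_sigma <- function(bw_hz_per_px, ref_sigma, ref_bw_hz_per_px) {
  if (bw_hz_per_px <= 0 || ref_bw_hz_per_px <= 0) stop("bandwidths must be positive")
  if (ref_sigma < 0) stop("ref_sigma must be non-negative")
  ref_sigma * sqrt(bw_hz_per_px / ref_bw_hz_per_px)
}

#' Navigator acquisition length in TRs
#'
#' Number of TRs needed to acquire one accelerated 3D navigator image when
#' `lines_per_tr` navigator k-space lines fit into each TR:
#' `ceil((PE1/accel1) * (PE2/accel2) / lines_per_tr)`.
#'
#' @param nav_matrix length-3 navigator matrix (readout, PE1, PE2).
#' @param accel length-2 acceleration along (PE1, PE2); must divide the
#'   corresponding matrix sizes.
#' @param lines_per_tr navigator lines acquired per TR.
#' @return Integer TR count.
#' @export
navigator_tr_count <- function(nav_matrix, accel, lines_per_tr) {
  nav_matrix <- as.integer(as_len3(nav_matrix, "nav_matrix"))
  accel <- as.integer(accel)
  if (lines_per_tr < 1) stop("lines_per_tr must be >= 1")
  if (nav_matrix[2] %% accel[1] != 0 || nav_matrix[3] %% accel[2] != 0) {
    stop("phase-encode sizes must be divisible by the acceleration factors")
  }
  as.integer(ceiling((nav_matrix[2] / accel[1]) * (nav_matrix[3] / accel[2]) / lines_per_tr))
}

#' Idealized readout train length
#'
#' The ramp-free readout train length per echo, `epi_factor / bw_hz_per_px`:
#' each line's flat sampling takes `1/bw` seconds. Vendor-reported train
#' lengths additionally include inter-line gradient ramp overheads, so
#' protocol tables can print slightly longer values than this ideal.
#'
#' @param bw_hz_per_px readout bandwidth (Hz/pixel).
#' @param epi_factor lines per echo train.
#' @return Train length in seconds.
#' @export
readout_train_length <- function(bw_hz_per_px, epi_factor = 1) {
  if (bw_hz_per_px <= 0) stop("bandwidth must be positive")
  epi_factor / bw_hz_per_px
}

#' Maximum feasible EPI factor under gradient limits
#'
#' How many k-space lines fit into one echo train of length `etl_s` for a
#' trapezoidal readout with flat-top-only sampling: the flat top must cover
#' the full k-space extent `n_readout / fov` at gradient amplitude `G`
#' (`flat = (n/fov) / (gamma * G)`), plus two ramps of duration `G / slew`.
#'
#' @param gmax_mt_per_m maximum gradient amplitude (mT/m).
#' @param slew_mt_per_m_per_ms slew rate (mT/m/ms).
#' @param fov_mm readout field of view (mm).
#' @param n_readout readout samples per line.
#' @param etl_s echo train length (s).
#' @return Integer maximum EPI factor (0 if one line does not fit).
#' @export
max_epi_factor <- function(gmax_mt_per_m, slew_mt_per_m_per_ms, fov_mm,
                           n_readout, etl_s) {
  if (any(c(gmax_mt_per_m, slew_mt_per_m_per_ms, fov_mm, n_readout, etl_s) <= 0)) {
    stop("all inputs must be positive")
  }
  g_t_per_m <- gmax_mt_per_m * 1e-3
  k_extent <- n_readout / (fov_mm * 1e-3)            # cycles/m
  flat_s <- k_extent / (GAMMA_HZ_PER_T * g_t_per_m)  # s
  ramp_s <- gmax_mt_per_m / slew_mt_per_m_per_ms * 1e-3
  line_s <- flat_s + 2 * ramp_s
  if (line_s > etl_s) return(0L)
  as.integer(floor(etl_s / line_s))
}
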