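#' Build a digital brain phantom
#'
#' Constructs a geometric digital phantom for multi-echo T2*-weighted
#' simulation: an ellipsoidal white-matter "brain" wrapped in a thin CSF
#' shell, containing five spherical deep grey-matter nuclei (substantia
#' nigra, red nucleus, putamen, globus pallidus, caudate nucleus) and three
#' white-matter ROI spheres (splenium, posterior limb of the internal
#' capsule, optic radiation). Tissue values (proton density `m0`, decay rate
#' `r2s` in 1/s, magnetic susceptibility `chi` in ppb) are literature-typical
#' for brain at 3 T; the geometry is analytic so every ROI has exact ground
#' truth. Outside the head support the signal, susceptibility and decay are
#' identically zero.
#'
#' ROI centres are jittered by up to one voxel using `seed`, so phantoms are
#' reproducible per seed but not identical across seeds.
#'
#' @param shape integer length-3 grid size (each dimension at least 32).
#' @param voxel_mm numeric length-3 (or scalar) voxel size in mm.
#' @param seed integer seed controlling ROI placement jitter.
#' @param b0_tesla main field strength in tesla.
#' @return An object of class `epiqsm_phantom`: a list with 3D arrays `m0`,
#'   `r2s`, `chi` (ppb), integer `labels`, logical `mask`, plus `voxel_mm`,
#'   `b0_tesla`, `label_names` and `seed`.
#' @examples
#' ph <- build_phantom(c(32, 32, 32), voxel_mm = 4, seed = 1)
#' table(ph$labels[ph$labels > 0])
#' @export
build_phantom <- function(shape = c(64, 64, 48), voxel_mm = c(3, 3, 3),
                          seed = 0, b0_tesla = 3) {
  shape <- as.integer(as_len3(shape, "shape"))
  voxel_mm <- as_len3(voxel_mm, "voxel_mm")
  if (any(shape < 32)) stop("each grid dimension must be >= 32")
  if (any(voxel_mm <= 0)) stop("voxel sizes must be positive")

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  x <- axis_mm(nx, voxel_mm[1])
  y <- axis_mm(ny, voxel_mm[2])
  z <- axis_mm(nz, voxel_mm[3])
  X <- array(rep(x, times = ny * nz), shape)
  Y <- array(rep(rep(y, each = nx), times = nz), shape)
  Z <- array(rep(z, each = nx * ny), shape)

  fov <- shape * voxel_mm
  # head (outer support incl. CSF) and brain semi-axes, mm
  head_ax <- fov / 2 * c(0.80, 0.82, 0.80)
  shell_mm <- max(2 * min(voxel_mm), 4)
  brain_ax <- head_ax - shell_mm

  in_ellipsoid <- function(cx, ax) {
    (X - cx[1])^2 / ax[1]^2 + (Y - cx[2])^2 / ax[2]^2 + (Z - cx[3])^2 / ax[3]^2 <= 1
  }
  head <- in_ellipsoid(c(0, 0, 0), head_ax)
  brain <- in_ellipsoid(c(0, 0, 0), brain_ax)
  csf <- head & !brain

  # tissue parameter table (chi in ppb, r2s in 1/s, m0 arbitrary units)
  rois <- data.frame(
    name = c("substantia_nigra", "red_nucleus", "putamen",
             "globus_pallidus", "caudate_nucleus",
             "splenium", "internal_capsule", "optic_radiation"),
    chi  = c(160, 130, 90, 180, 60, -40, -35, -25),
    r2s  = c(65, 55, 45, 75, 35, 24, 22, 20),
    m0   = c(0.80, 0.80, 0.80, 0.80, 0.80, 0.85, 0.85, 0.85),
    # nominal centres as fractions of the brain semi-axes
    fx   = c(-0.15, 0.15, -0.45, 0.42, -0.12, 0.00, 0.45, -0.40),
    fy   = c(-0.25, -0.25, 0.05, 0.05, 0.35, -0.45, -0.10, 0.30),
    fz   = c(-0.30, -0.30, 0.05, 0.05, 0.30, 0.25, 0.35, -0.35),
    r_mm = c(6, 6, 9, 7, 6, 6, 6, 6)
  )
  # keep ROI radii resolvable on coarse grids
  rois$r_mm <- pmax(rois$r_mm, 1.6 * max(voxel_mm))

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  jit <- matrix(stats::runif(3 * nrow(rois), -1, 1), ncol = 3) * rep(voxel_mm, each = nrow(rois))

  m0 <- array(0, shape); r2s <- array(0, shape); chi <- array(0, shape)
  labels <- array(0L, shape)

  m0[brain] <- 0.85; r2s[brain] <- 21; chi[brain] <- -30; labels[brain] <- 1L
  m0[csf] <- 1.0;  r2s[csf] <- 1;  chi[csf] <- 0;   labels[csf] <- 2L

  for (i in seq_len(nrow(rois))) {
    ctr <- c(rois$fx[i], rois$fy[i], rois$fz[i]) * brain_ax + jit[i, ]
    r <- rois$r_mm[i]
    # the whole sphere must fit inside the brain ellipsoid
    margin <- 1 - sum((abs(ctr) + r)^2 / brain_ax^2)
    if (margin < 0) {
      stop(sprintf("grid too small to place ROI '%s' inside the brain", rois$name[i]))
    }
    sph <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= r^2
    if (!any(sph)) stop(sprintf("grid too small to place ROI '%s' inside the brain", rois$name[i]))
    m0[sph] <- rois$m0[i]; r2s[sph] <- rois$r2s[i]; chi[sph] <- rois$chi[i]
    labels[sph] <- i + 2L
  }

  structure(list(
    m0 = m0, r2s = r2s, chi = chi, labels = labels, mask = brain,
    voxel_mm = voxel_mm, b0_tesla = b0_tesla,
    label_names = c(brain_wm = 1L, csf = 2L,
                    stats::setNames(seq_len(nrow(rois)) + 2L, rois$name)),
    seed = seed
  ), class = "epiqsm_phantom")
}

#' @export
print.epiqsm_phantom <- function(x, ...) {
  cat(sprintf("epiqsm phantom: %s grid, %.3g x %.3g x %.3g mm voxels, B0 = %g T\n",
              paste(dim(x$m0), collapse = "x"),
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3], x$b0_tesla))
  cat(sprintf("  brain mask fraction %.3f, %d labelled classes\n",
              mean(x$mask), length(unique(x$labels[x$labels > 0]))))
  invisible(x)
}

#' Susceptibility-induced off-resonance field (dipole forward model)
#'
#' Computes the B0 off-resonance field (Hz) generated by a susceptibility
#' distribution via the k-space dipole kernel
#' \deqn{D(k) = 1/3 - k_z^2 / |k|^2,\quad D(0) = 0,}
#' so that `field = B0 * gamma * 1e-9 * IFT[D(k) FT(chi_ppb)]` with the main
#' field along the third (z) axis. Setting the DC term to zero makes the
#' field zero-mean over the grid (the demodulated-scanner convention).
#'
#' @param phantom an `epiqsm_phantom`, or a list with `chi` (ppb),
#'   `voxel_mm`, `b0_tesla`.
#' @return An `epiqsm_fieldmap`: list with `hz` (3D array) and `voxel_mm`.
#' @export
chi_to_field <- function(phantom) {
  chi <- phantom$chi
  stopifnot_finite(chi, "chi")
  voxel_mm <- as_len3(phantom$voxel_mm, "voxel_mm")
  if (any(voxel_mm <= 0)) stop("voxel sizes must be positive")
  D <- dipole_kernel(dim(chi), voxel_mm)
  hz <- phantom$b0_tesla * GAMMA_HZ_PER_T * 1e-9 *
    Re(fft(fft(chi) * D, inverse = TRUE)) / length(chi)
  structure(list(hz = hz, voxel_mm = voxel_mm), class = "epiqsm_fieldmap")
}

# k-space dipole kernel D(k) = 1/3 - kz^2/|k|^2 on the DFT grid, with the
# physical k coordinates determined by the voxel size; D(0) := 0.
#' @keywords internal
dipole_kernel <- function(shape, voxel_mm) {
  kx <- kfreq(shape[1]) / (shape[1] * voxel_mm[1])
  ky <- kfreq(shape[2]) / (shape[2] * voxel_mm[2])
  kz <- kfreq(shape[3]) / (shape[3] * voxel_mm[3])
  KX2 <- array(rep(kx^2, times = shape[2] * shape[3]), shape)
  KY2 <- array(rep(rep(ky^2, each = shape[1]), times = shape[3]), shape)
  KZ2 <- array(rep(kz^2, each = shape[1] * shape[2]), shape)
  K2 <- KX2 + KY2 + KZ2
  D <- 1 / 3 - KZ2 / K2
  D[1, 1, 1] <- 0
  D
}

#' Sample a shot-resolved physiological timeline
#'
#' Draws the per-shot physiological state used by the acquisition simulator:
#' a global B0 offset (random-walk drift plus a sinusoidal respiratory
#' component), a spatially linear B0 gradient (per-axis random walks) and a
#' rigid translation (per-axis random walks). Shot `k` occurs at time
#' `k * tr_s` (0-based).
#'
#' @param n_shots number of shots (TRs) in the scan.
#' @param drift_sd_hz per-shot standard deviation of the global-frequency
#'   random-walk increment (Hz).
#' @param resp_amp_hz amplitude of the sinusoidal respiratory B0 term (Hz).
#' @param resp_period_s respiratory period (s).
#' @param tr_s repetition time (s).
#' @param grad_sd_hz_per_mm per-shot increment SD of the linear-gradient
#'   random walk, per axis (Hz/mm).
#' @param trans_sd_mm per-shot increment SD of the translation random walk (mm).
#' @param seed integer seed.
#' @return An `epiqsm_timeline`: list with `n_shots`, `global_hz` (length
#'   `n_shots`), `grad_hz_per_mm` (`n_shots` x 3), `trans_mm` (`n_shots` x 3).
#' @export
sample_physio_timeline <- function(n_shots, drift_sd_hz = 0.2, resp_amp_hz = 1,
                                   resp_period_s = 4, tr_s = 0.06,
                                   grad_sd_hz_per_mm = 0, trans_sd_mm = 0.02,
                                   seed = 0) {
  if (n_shots < 1) stop("n_shots must be >= 1")
  if (drift_sd_hz < 0 || grad_sd_hz_per_mm < 0 || trans_sd_mm < 0 || resp_amp_hz < 0) {
    stop("standard deviations and amplitudes must be non-negative")
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  walk <- function(sd) if (sd == 0) numeric(n_shots) else cumsum(stats::rnorm(n_shots, 0, sd))
  t_s <- (seq_len(n_shots) - 1) * tr_s
  global <- walk(drift_sd_hz) + resp_amp_hz * sin(2 * pi * t_s / resp_period_s)
  grad <- cbind(walk(grad_sd_hz_per_mm), walk(grad_sd_hz_per_mm), walk(grad_sd_hz_per_mm))
  trans <- cbind(walk(trans_sd_mm), walk(trans_sd_mm), walk(trans_sd_mm))
  structure(list(n_shots = as.integer(n_shots), global_hz = global,
                 grad_hz_per_mm = grad, trans_mm = trans, tr_s = tr_s, seed = seed),
            class = "epiqsm_timeline")
}

#' Null (motion- and fluctuation-free) timeline
#'
#' @param n_shots number of shots.
#' @return An `epiqsm_timeline` with all entries exactly zero.
#' @export
null_timeline <- function(n_shots) {
  structure(list(n_shots = as.integer(n_shots), global_hz = numeric(n_shots),
                 grad_hz_per_mm = matrix(0, n_shots, 3),
                 trans_mm = matrix(0, n_shots, 3), tr_s = NA_real_, seed = NA_integer_),
            class = "epiqsm_timeline")
}

#' @keywords internal
is_null_timeline <- function(tl) {
  all(tl$global_hz == 0) && all(tl$grad_hz_per_mm == 0) && all(tl$trans_mm == 0)
}
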