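# Internal numerical helpers: unitary DFTs, index conventions, spline shifts.
#
# Conventions used throughout the package:
#  * voxel indices are 0-based; the image-domain origin sits at index N/2
#    (even grids), so physical coordinate r_mm = (i - N/2) * voxel_mm;
#  * k-space arrays are stored in DFT layout (frequency j maps to the
#    centred integer frequency j for j < N/2 and j - N otherwise);
#  * all DFTs are unitary (1/sqrt(N) per axis), so white noise keeps its
#    standard deviation across the transform and Parseval holds exactly.

#' @keywords internal
ufft <- function(x) fft(x) / sqrt(length(x))

#' @keywords internal
uifft <- function(x) fft(x, inverse = TRUE) / sqrt(length(x))

# Centred integer frequency for each storage index of an axis of length n.
#' @keywords internal
kfreq <- function(n) {
  j <- 0:(n - 1)
  ifelse(j < n / 2, j, j - n)
}

# Physical image-domain coordinate (mm) for each voxel index of an axis.
#' @keywords internal
axis_mm <- function(n, voxel_mm) (0:(n - 1) - floor(n / 2)) * voxel_mm

# k-space phase factor implementing a translation by `shift_vox` voxels
# along one axis of length n (exact for band-limited periodic signals).
#' @keywords internal
shift_phase <- function(n, shift_vox) {
  exp(-2i * pi * kfreq(n) * shift_vox / n)
}

#' @keywords internal
stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
}

# --- cubic B-spline interpolation -------------------------------------------

# Prefilter a vector (or each column of a matrix) so that evaluating the
# cubic B-spline expansion at the sample points reproduces the data.
# boundary: "periodic" uses the exact circulant inverse via FFT;
# "mirror" solves the banded (1/6, 4/6, 1/6) system with reflected ends.
#' @keywords internal
bspline_prefilter <- function(x, boundary = c("periodic", "mirror")) {
  boundary <- match.arg(boundary)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) return(x)
  if (boundary == "periodic") {
    b <- numeric(n)
    b[1] <- 4 / 6
    b[2] <- 1 / 6
    b[n] <- 1 / 6
    fb <- fft(b)
    out <- apply(x, 2, function(col) Re(fft(fft(as.complex(col)) / fb, inverse = TRUE)) / n)
    return(matrix(out, n))
  }
  # mirror boundary: tridiagonal system with reflected first/last rows
  A <- diag(4 / 6, n)
  idx <- seq_len(n - 1)
  A[cbind(idx, idx + 1)] <- 1 / 6
  A[cbind(idx + 1, idx)] <- 1 / 6
  A[1, 2] <- 2 / 6
  A[n, n - 1] <- 2 / 6
  solve(A, x)
}

# Cubic B-spline basis weights for fractional offset t in [0, 1), taps at
# offsets -1, 0, 1, 2 relative to the floor of the sample position.
#' @keywords internal
bspline_weights <- function(t) {
  cbind((1 - t)^3 / 6,
        (4 - 6 * t^2 + 3 * t^3) / 6,
        (1 + 3 * t + 3 * t^2 - 3 * t^3) / 6,
        t^3 / 6)
}

# Evaluate a cubic-spline interpolant of a 1D signal at arbitrary sample
# positions (0-based). Positions are wrapped (periodic) or clamped (mirror).
#' @keywords internal
bspline_sample <- function(x, pos, boundary = c("periodic", "mirror")) {
  boundary <- match.arg(boundary)
  n <- length(x)
  c0 <- bspline_prefilter(matrix(x, ncol = 1), boundary)[, 1]
  i0 <- floor(pos)
  t <- pos - i0
  w <- bspline_weights(t)
  out <- numeric(length(pos))
  for (k in 0:3) {
    idx <- i0 + (k - 1)
    if (boundary == "periodic") {
      idx <- ((idx %% n) + n) %% n
    } else {
      idx <- pmin(pmax(idx, 0), n - 1)
    }
    out <- out + w[, k + 1] * c0[idx + 1]
  }
  out
}

# Shift a 3D volume by a constant sub-voxel offset per axis using separable
# cubic-spline interpolation (mirror boundaries). shift_vox gives, per axis,
# the displacement applied to the image content (positive = content moves
# toward larger indices).
#' @keywords internal
spline_shift3 <- function(vol, shift_vox) {
  dm <- dim(vol)
  out <- vol
  for (ax in 1:3) {
    s <- shift_vox[ax]
    if (s == 0) next
    n <- dm[ax]
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(out, perm), nrow = n)
    cm <- bspline_prefilter(m, "mirror")
    pos <- (0:(n - 1)) - s
    i0 <- floor(pos)
    t <- pos - i0
    w <- bspline_weights(t)
    res <- matrix(0, n, ncol(m))
    for (k in 0:3) {
      idx <- pmin(pmax(i0 + (k - 1), 0), n - 1)
      res <- res + w[, k + 1] * cm[idx + 1, , drop = FALSE]
    }
    out <- aperm(array(res, dm[perm]), order(perm))
  }
  out
}

#' @keywords internal
as_len3 <- function(x, what) {
  if (length(x) == 1) x <- rep(x, 3)
  if (length(x) != 3) stop(sprintf("%s must have length 3", what), call. = FALSE)
  as.numeric(x)
}

# Gyromagnetic ratio of the proton, Hz per tesla.
#' @keywords internal
GAMMA_HZ_PER_T <- 42.58e6

# mean over the 4th (echo) dimension of a 4D array, vectorized
#' @keywords internal
echo_mean <- function(x) {
  dm <- dim(x)
  array(rowMeans(matrix(x, ncol = dm[4])), dm[1:3])
}
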