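# R2* fitting, frequency mapping, phase unwrapping, background-field
# removal and dipole inversion.

test_that("mono-exponential fit recovers exact decays", {
  # two-point exact solution: ln(100/36.788)/0.05 = 20 / s
  mag <- array(c(100, 36.788), c(1, 1, 1, 2))
  fit <- fit_r2star(mag, c(0.010, 0.060), array(TRUE, c(1, 1, 1)))
  expect_equal(fit$r2s_hat[1, 1, 1], 20.0, tolerance = 1e-4)
  expect_equal(fit$s0_hat[1, 1, 1], 122.14, tolerance = 1e-3)

  # noiseless 4-echo decay at the GRE echo times
  te <- c(0.014, 0.025, 0.036, 0.047)
  r_true <- 30
  sig <- 80 * exp(-r_true * te)
  mag4 <- array(rep(sig, each = 50), c(50, 1, 1, 4))
  fit4 <- fit_r2star(mag4, te, array(TRUE, c(50, 1, 1)))
  expect_lt(max(abs(fit4$r2s_hat - r_true)), 1e-6)
  expect_true(all(fit4$diagnostics$converged))

  # scale equivariance: magnitudes x c leave R2* unchanged, scale S0
  fit_s <- fit_r2star(mag4 * 3.5, te, array(TRUE, c(50, 1, 1)))
  expect_equal(fit_s$r2s_hat, fit4$r2s_hat, tolerance = 1e-9)
  expect_equal(fit_s$s0_hat, fit4$s0_hat * 3.5, tolerance = 1e-6)

  # all-zero voxel inside the mask is flagged and excluded
  magz <- mag4
  magz[1, 1, 1, ] <- 0
  fitz <- fit_r2star(magz, te, array(TRUE, c(50, 1, 1)))
  expect_true(is.na(fitz$r2s_hat[1, 1, 1]))
  expect_equal(fitz$diagnostics$n_undefined, 1)
})

test_that("Gauss-Newton agrees with Levenberg-Marquardt on noisy voxels", {
  skip_if_not_installed("minpack.lm")
  te <- c(0.014, 0.025, 0.036, 0.047)
  set.seed(3)
  n <- 25
  r_true <- runif(n, 10, 60)
  s_true <- runif(n, 50, 150)
  mag <- t(vapply(seq_len(n), function(i) {
    pmax(s_true[i] * exp(-r_true[i] * te) + rnorm(4, 0, 2), 0.1)
  }, numeric(4)))
  fit <- fit_r2star(array(mag, c(n, 1, 1, 4)), te, array(TRUE, c(n, 1, 1)))
  ref <- vapply(seq_len(n), function(i) {
    y <- mag[i, ]
    out <- minpack.lm::nlsLM(y ~ S0 * exp(-R * te),
                             start = list(S0 = y[1], R = 20),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(out)[["R"]]
  }, numeric(1))
  expect_equal(as.vector(fit$r2s_hat), ref, tolerance = 1e-5)
})

test_that("R2* is nearly unbiased from Rician magnitudes at SNR 50", {
  te <- c(0.014, 0.025, 0.036, 0.047)
  r_true <- 20
  s0 <- 100
  sigma <- s0 * exp(-r_true * te[1]) / 50     # first-echo SNR 50
  set.seed(17)
  n <- 1e4
  clean <- s0 * exp(-outer(rep(1, n), r_true * te))
  mag <- sqrt((clean + matrix(rnorm(n * 4, 0, sigma), n))^2 +
                matrix(rnorm(n * 4, 0, sigma), n)^2)
  fit <- fit_r2star(array(mag, c(n, 1, 1, 4)), te, array(TRUE, c(n, 1, 1)))
  bias <- mean(fit$r2s_hat, na.rm = TRUE) - r_true
  expect_lt(abs(bias) / r_true, 0.02)
})

test_that("frequency mapping handles exact, wrapped and noisy phase", {
  te <- c(0.014, 0.025, 0.036, 0.047)
  dm <- c(10, 10, 1)
  mask <- array(TRUE, dm)
  mag <- array(1, c(dm, 4))

  mk_phase <- function(f) {
    ph <- array(0, c(dm, 4))
    for (e in 1:4) ph[, , , e] <- Arg(exp(1i * 2 * pi * f * te[e]))
    ph
  }
  # noiseless 4 Hz: exact
  f4 <- frequency_map(mk_phase(4), te, mag, mask)
  expect_equal(as.vector(f4), rep(4, prod(dm)), tolerance = 1e-9)

  # 25 Hz wraps beyond pi at the later echoes; temporal unwrapping fixes it
  f25 <- frequency_map(mk_phase(25), te, mag, mask)
  expect_equal(as.vector(f25), rep(25, prod(dm)), tolerance = 1e-6)

  expect_error(frequency_map(array(0, c(dm, 1)), te[1], mag, mask), "two echoes")

  # weighting by magnitude^2 TE reduces variance when phase noise scales
  # inversely with magnitude
  set.seed(5)
  nv <- 1000
  m_v <- matrix(runif(nv * 4, 0.2, 2), nv)
  err_w <- numeric(100); err_u <- numeric(100)
  for (tr in 1:100) {
    ph_v <- 2 * pi * 10 * outer(rep(1, nv), te) + rnorm(nv * 4, 0, 0.05) / m_v
    fw <- frequency_map(array(ph_v, c(nv, 1, 1, 4)), te,
                        array(m_v, c(nv, 1, 1, 4)), array(TRUE, c(nv, 1, 1)))
    fu <- frequency_map(array(ph_v, c(nv, 1, 1, 4)), te,
                        array(1, c(nv, 1, 1, 4)), array(TRUE, c(nv, 1, 1)))
    err_w[tr] <- stats::var(as.vector(fw) - 10)
    err_u[tr] <- stats::var(as.vector(fu) - 10)
  }
  expect_lt(mean(err_w), mean(err_u))
})

test_that("spatial unwrapping restores smooth phase modulo a global offset", {
  dm <- c(24, 24, 24)
  X <- array(rep(1:24, 24 * 24), dm)
  mask <- array(TRUE, dm)

  # wrap-free smooth phase is untouched
  smooth <- 0.02 * X
  expect_equal(spatial_unwrap(smooth, mask)$unwrapped, smooth)

  # 6 pi ramp across the mask: recovered up to one global 2 pi k
  truth <- 6 * pi * (X - 1) / 23
  wrapped <- Arg(exp(1i * truth))
  u <- spatial_unwrap(wrapped, mask)$unwrapped
  off <- 2 * pi * round((u[1, 1, 1] - truth[1, 1, 1]) / (2 * pi))
  expect_lt(max(abs(u - truth - off)), 1e-6)
  # modulo-2pi property holds exactly at every voxel
  expect_lt(max(abs(Arg(exp(1i * (u - wrapped))))), 1e-9)

  # disconnected components are unwrapped independently
  mask2 <- array(FALSE, dm)
  mask2[2:8, 2:8, 2:8] <- TRUE
  mask2[16:22, 16:22, 16:22] <- TRUE
  u2 <- spatial_unwrap(wrapped, mask2)
  expect_equal(u2$n_components, 2L)
  expect_lt(max(abs(Arg(exp(1i * (u2$unwrapped - wrapped))))), 1e-9)
})

test_that("V-SHARP removes external fields and keeps internal ones", {
  dm <- c(48, 48, 48)
  vox <- c(2, 2, 2)
  x <- (0:(dm[1] - 1) - 24) * 2
  X <- array(rep(x, times = 48 * 48), dm)
  Y <- array(rep(rep(x, each = 48), times = 48), dm)
  Z <- array(rep(x, each = 48 * 48), dm)
  r <- sqrt(X^2 + Y^2 + Z^2)
  mask <- r <= 36

  radii <- c(12, 8, 6, 4)
  # zero field -> zero output
  v0 <- vsharp_background_removal(array(0, dm), mask, radii, vox)
  expect_lt(max(abs(v0$f_tissue[v0$eroded_mask])), 1e-10)

  # source outside the mask: residual < 5% of the input RMS inside
  chi_out <- array(0, dm)
  chi_out[(abs(X - 42) <= 4) & (abs(Y) <= 6) & (abs(Z) <= 6)] <- 500
  f_out <- chi_to_field(list(chi = chi_out, voxel_mm = vox, b0_tesla = 3))$hz
  v1 <- vsharp_background_removal(f_out, mask, radii, vox)
  rms_in <- sqrt(mean(f_out[v1$eroded_mask]^2))
  rms_res <- sqrt(mean(v1$f_tissue[v1$eroded_mask]^2))
  expect_lt(rms_res, 0.05 * rms_in)

  # internal source far from the boundary: preserved (high-pass correlation)
  chi_in <- array(0, dm)
  chi_in[r <= 8] <- 100
  f_in <- chi_to_field(list(chi = chi_in, voxel_mm = vox, b0_tesla = 3))$hz
  v2 <- vsharp_background_removal(f_in, mask, radii, vox)
  sel <- v2$eroded_mask & r <= 20
  expect_gt(stats::cor(v2$f_tissue[sel], f_in[sel]), 0.95)

  expect_error(vsharp_background_removal(f_in, r <= 2, radii, vox), "smaller")
})

test_that("dipole inversion recovers sources and references the mean", {
  dm <- c(64, 64, 64)
  x <- (0:(dm[1] - 1)) - 32
  X <- array(rep(x, times = 64 * 64), dm)
  Y <- array(rep(rep(x, each = 64), times = 64), dm)
  Z <- array(rep(x, each = 64 * 64), dm)
  r <- sqrt(X^2 + Y^2 + Z^2)
  mask <- array(TRUE, dm)

  expect_lt(max(abs(dipole_inversion(array(0, dm), mask, 3))), 1e-12)

  sph <- r <= 6
  chi <- array(0, dm); chi[sph] <- 100
  f <- chi_to_field(list(chi = chi, voxel_mm = c(1, 1, 1), b0_tesla = 3))$hz
  ch <- dipole_inversion(f, mask, 3, c(1, 1, 1), "tkd", 0.2)
  # sphere mean recovered within 15% of 100 ppb (relative to background)
  expect_equal(mean(ch[sph]) - mean(ch[!sph]), 100, tolerance = 0.15)
  # referencing invariant: exact zero mean over the mask
  expect_lt(abs(mean(ch[mask])), 1e-10)

  cht <- dipole_inversion(f, mask, 3, c(1, 1, 1), "tikhonov", 0.001)
  expect_equal(mean(cht[sph]) - mean(cht[!sph]), 100, tolerance = 0.2)
  expect_error(dipole_inversion(f, array(FALSE, dm), 3), "empty mask")
  expect_error(dipole_inversion(f, mask, 3, c(1, 1, 1), "tkd", 1.5), "threshold")
})

test_that("noiseless quantification is an identity on the phantom", {
  ph <- small_phantom(c(32, 32, 32))
  pr <- small_protocol(ph)
  ideal <- ideal_image(ph, pr)
  q <- quantify_maps(ideal, ph$mask, what = c("r2s", "f"))
  expect_lt(max(abs(q$r2s_hat - ph$r2s)[ph$mask], na.rm = TRUE), 0.1)
  f_true <- chi_to_field(ph)$hz
  expect_lt(max(abs(q$f_hat - f_true)[ph$mask], na.rm = TRUE), 0.05)
})

test_that("dipole inversion contracts toward truth on the default phantom", {
  ph <- build_phantom(seed = 0)
  fm <- chi_to_field(ph)
  chh <- dipole_inversion(fm$hz, ph$mask, ph$b0_tesla, ph$voxel_mm, "tkd", 0.2)
  ker <- epiqsm:::smv_kernel(dim(ph$mask), ph$voxel_mm, 6)
  eroded <- epiqsm:::erode_mask_fft(ph$mask, ker)
  ctr <- ph$chi - mean(ph$chi[ph$mask])
  expect_gt(stats::cor(chh[eroded], ctr[eroded]), 0.9)
})
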