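# Reconstruction contracts: linearity, oracle-corrected recovery, corrected
# vs uncorrected behaviour, EPI odd/even phase correction, navigator
# timeline estimation, multi-coil CAIPI unaliasing.

test_that("reconstruction is linear in k-space and conserves energy", {
  ph <- small_phantom(c(32, 32, 32))
  pr <- small_protocol(ph)
  nl <- 32 * 32
  tl <- sample_physio_timeline(nl, tr_s = pr$tr_s, seed = 5)
  k1 <- simulate_scan(ph, pr, tl, noise_sigma = 0.05, seed = 1)
  k2 <- simulate_scan(ph, pr, tl, noise_sigma = 0.05, seed = 2)
  k3 <- k1
  for (e in seq_along(k1$echo_data)) {
    k3$echo_data[[e]] <- 2 * k1$echo_data[[e]] - 0.5 * k2$echo_data[[e]]
  }
  r1 <- reconstruct(k1, "corrected")$data
  r2 <- reconstruct(k2, "corrected")$data
  r3 <- reconstruct(k3, "corrected")$data
  expect_lt(rel_rmse(r3, 2 * r1 - 0.5 * r2), 1e-10)

  # unitary DFT: k-space energy equals image energy (full sampling, no
  # correction phases)
  k0 <- simulate_scan(ph, pr, null_timeline(nl), noise_sigma = 0, seed = 0)
  img <- reconstruct(k0, "uncorrected")
  for (e in c(1, 4)) {
    expect_equal(sum(Mod(k0$echo_data[[e]])^2), sum(Mod(img$data[, , , e])^2),
                 tolerance = 1e-10)
  }
})

test_that("oracle-corrected reconstruction recovers the ideal image", {
  ph <- small_phantom(c(32, 32, 32))
  pr <- small_protocol(ph)
  nl <- 32 * 32
  ideal <- ideal_image(ph, pr)

  # translation-free timeline (global + readout-direction gradient):
  # recovery to numerical precision
  tl <- sample_physio_timeline(nl, drift_sd_hz = 0.2, resp_amp_hz = 1,
                               tr_s = pr$tr_s, grad_sd_hz_per_mm = 0.002,
                               trans_sd_mm = 0, seed = 9)
  tl$grad_hz_per_mm[, 2:3] <- 0
  kd <- simulate_scan(ph, pr, tl, noise_sigma = 0, seed = 0)
  expect_lt(rel_rmse(reconstruct(kd, "corrected")$data, ideal$data), 1e-6)

  # with sub-voxel translations: conjugate Fourier shift undoes them
  tlt <- sample_physio_timeline(nl, drift_sd_hz = 0.2, resp_amp_hz = 1,
                                tr_s = pr$tr_s, grad_sd_hz_per_mm = 0,
                                trans_sd_mm = 0.05, seed = 10)
  tlt$trans_mm <- pmin(pmax(tlt$trans_mm, -3), 3)   # <= 0.5 voxel at 6 mm
  kdt <- simulate_scan(ph, pr, tlt, noise_sigma = 0, seed = 0)
  expect_lt(rel_rmse(reconstruct(kdt, "corrected")$data, ideal$data), 0.01)

  # null timeline: corrected and uncorrected agree exactly
  kd0 <- simulate_scan(ph, pr, null_timeline(nl), noise_sigma = 0, seed = 0)
  expect_equal(reconstruct(kd0, "corrected")$data,
               reconstruct(kd0, "uncorrected")$data)

  # constant global offset: uncorrected (scan mean) captures it fully
  tlc <- null_timeline(nl)
  tlc$global_hz <- rep(3.7, nl)
  kdc <- simulate_scan(ph, pr, tlc, noise_sigma = 0, seed = 0)
  expect_lt(rel_rmse(reconstruct(kdc, "uncorrected")$data,
                     reconstruct(kdc, "corrected")$data), 1e-12)
})

test_that("correction beats no correction under fluctuating physiology", {
  ph <- small_phantom(c(32, 32, 32))
  pr <- small_protocol(ph)
  nl <- 32 * 32
  ideal <- ideal_image(ph, pr)
  tl <- sample_physio_timeline(nl, tr_s = pr$tr_s, seed = 3)
  kd <- simulate_scan(ph, pr, tl, noise_sigma = 0, seed = 1)
  cor_img <- reconstruct(kd, "corrected")$data
  unc_img <- reconstruct(kd, "uncorrected")$data
  for (e in seq_along(pr$te_s)) {
    rms <- function(x) sqrt(mean(Mod(x[, , , e] - ideal$data[, , , e])[ph$mask]^2))
    expect_lt(rms(cor_img), rms(unc_img))
  }
})

test_that("EPI odd/even phase correction removes the injected ghost", {
  ph <- small_phantom(c(32, 32, 32))
  pr <- small_protocol(ph, "EPIx5")
  nl <- 32 * 32
  n_shots <- ceiling(nl / 5)
  tl <- null_timeline(n_shots)
  ideal <- ideal_image(ph, pr)

  # no injected error: correction with zero calibration is a no-op
  kd0 <- simulate_scan(ph, pr, tl, noise_sigma = 0, seed = 0)
  expect_identical(epi_phase_correction(kd0, c(0, 0))$echo_data, kd0$echo_data)

  # constant 0.3 rad on odd lines: ghost energy suppressed below 1%
  kde <- simulate_scan(ph, pr, tl, noise_sigma = 0, seed = 0,
                       odd_even_phase = c(0.3, 0))
  ghost_energy <- function(k) {
    img <- reconstruct(k, "uncorrected")$data
    sum(Mod(img - ideal$data)^2) / sum(Mod(ideal$data)^2)
  }
  expect_gt(ghost_energy(kde), 0.005)      # the error is visible before
  kdec <- epi_phase_correction(kde)        # calibration estimated from data
  expect_lt(ghost_energy(kdec), 0.01)

  # linear phase: recovered slope within 5%
  kdl <- simulate_scan(ph, pr, tl, noise_sigma = 0, seed = 0,
                       odd_even_phase = c(0, 0.01))
  est <- epiqsm:::estimate_oddeven_phase(kdl$calib$even, kdl$calib$odd)
  expect_equal(unname(est[2]), 0.01, tolerance = 0.05)
  expect_lt(ghost_energy(epi_phase_correction(kdl)), 0.01)

  kd_nocal <- kd0
  kd_nocal$calib <- NULL
  expect_error(epi_phase_correction(kd_nocal), "calibration")
})

test_that("navigator phase series yield the underlying timeline", {
  dm <- c(16, 14, 10)
  vox <- c(6, 6, 12)
  mask <- array(FALSE, dm)
  mask[4:13, 4:11, 3:8] <- TRUE
  nav_te <- 0.0039
  x <- (0:(dm[1] - 1) - dm[1] %/% 2) * vox[1]
  y <- (0:(dm[2] - 1) - dm[2] %/% 2) * vox[2]
  z <- (0:(dm[3] - 1) - dm[3] %/% 2) * vox[3]
  X <- array(rep(x, times = dm[2] * dm[3]), dm)

  # all-zero phase: null estimate
  nav0 <- array(0, c(dm, 4))
  tl0 <- estimate_timeline(nav0, nav_te, vox, mask)
  expect_true(all(tl0$global_hz == 0) && all(tl0$grad_hz_per_mm == 0))

  # exact linear model: a = 5 Hz, g = (0.1, 0, 0) Hz/mm
  f_true <- 5 + 0.1 * X
  nav <- array(rep(2 * pi * f_true * nav_te, 3), c(dm, 3))
  tl <- estimate_timeline(nav, nav_te, vox, mask)
  expect_equal(tl$global_hz, rep(5, 3), tolerance = 1e-6)
  expect_equal(tl$grad_hz_per_mm[, 1], rep(0.1, 3), tolerance = 1e-6)
  expect_lt(max(tl$residual_hz), 1e-6)

  # with 0.05 rad phase noise the global term is recovered within 0.5 Hz
  # in at least 95% of trials
  set.seed(99)
  err <- replicate(100, {
    navn <- nav[, , , 1] + array(stats::rnorm(prod(dm), 0, 0.05), dm)
    tln <- estimate_timeline(array(navn, c(dm, 1)), nav_te, vox, mask)
    abs(tln$global_hz[1] - 5)
  })
  expect_gte(mean(err < 0.5), 0.95)

  expect_error(estimate_timeline(nav0, nav_te, vox, array(FALSE, dm)),
               "degenerate")
})

test_that("multi-coil CAIPI data unaliases to the ideal image", {
  ph <- small_phantom(c(32, 32, 32))
  pr <- small_protocol(ph, "GRE", accel = c(2, 2))
  pr$te_s <- pr$te_s[1:2]
  sens <- synth_coil_sens(dim(ph$m0), n_coils = 8)
  nl <- 32 * 32 / 4
  kd <- simulate_scan(ph, pr, null_timeline(nl), noise_sigma = 0, seed = 0,
                      coil_sens = sens)
  img <- reconstruct(kd, "uncorrected", coil_sens = sens)
  ideal <- ideal_image(ph, pr)
  # compare within the head support (sensitivity-less exterior is noise)
  sup <- ph$labels > 0
  err <- Mod(img$data[, , , 1] - ideal$data[, , , 1])[sup]
  ref <- Mod(ideal$data[, , , 1])[sup]
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(ref^2)), 1e-6)
  expect_error(reconstruct(kd, "uncorrected"), "coil_sens")
})
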