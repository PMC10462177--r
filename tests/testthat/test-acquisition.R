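# Protocols, CAIPI sampling, shot segmentation, timing arithmetic and the
# k-space simulator's noise contracts.

test_that("protocol presets carry the study parameters", {
  pp <- protocol_presets()
  expect_named(pp, c("GRE", "EPIx3", "EPIx5"))

  gre <- pp$GRE
  expect_equal(gre$te_s, c(0.014, 0.025, 0.036, 0.047))
  expect_equal(gre$epi_factor, 1L)          # GRE = EPI factor 1
  expect_equal(gre$tr_s, 0.060)
  expect_equal(gre$bw_hz_per_px, 125)
  expect_equal(gre$etl_s, 0.008)
  expect_equal(gre$repetitions, 1L)
  expect_equal(gre$matrix, c(240L, 180L, 144L))
  expect_equal(gre$accel, c(2L, 2L))

  e3 <- pp$EPIx3
  expect_equal(e3$te_s, c(0.013, 0.025, 0.037, 0.049))
  expect_equal(e3$tr_s, 0.064)
  expect_equal(e3$bw_hz_per_px, 372)
  expect_equal(e3$epi_factor, 3L)
  expect_equal(e3$repetitions, 3L)

  e5 <- pp$EPIx5
  expect_equal(e5$te_s, c(0.013, 0.026, 0.039, 0.052))
  expect_equal(e5$bw_hz_per_px, 631)
  expect_equal(e5$epi_factor, 5L)
  expect_equal(e5$repetitions, 5L)
  for (p in pp) {
    expect_equal(p$flip_deg, 20)
    expect_equal(p$gmax_mt_per_m, 40)
    expect_equal(p$slew_mt_per_m_per_ms, 200)
    expect_true(all(diff(p$te_s) > 0))
    # repetitions x echo-train count arithmetic stays integral
    n_lines <- prod(p$matrix[2:3] / p$accel)
    expect_true(n_lines %% 1 == 0)
  }
  expect_error(new_protocol("bad", c(8, 8, 8), c(8, 8, 8), te_s = c(0.02, 0.01),
                            tr_s = 0.05, bw_hz_per_px = 100, etl_s = 0.008),
               "strictly increasing")
})

test_that("CAIPI lattices have the right size, coverage and stagger", {
  full <- caipi_pattern(8, 8, 1, 1, 0)
  expect_equal(nrow(full$lines), 64)
  expect_equal(nrow(unique(full$lines)), 64)

  st <- caipi_pattern(8, 8, 2, 2, 1)
  expect_equal(nrow(st$lines), 16)
  expect_true(all(st$lines[, "ky"] %% 2 == 0))
  # staggered rows: kz parity alternates with the sampled-row index
  for (i in seq(0, 6, 2)) {
    kzs <- st$lines[st$lines[, "ky"] == i, "kz"]
    expect_true(all(kzs %% 2 == (i / 2) %% 2))
  }
  reg <- caipi_pattern(8, 8, 2, 2, 0)
  expect_equal(nrow(reg$lines), 16)
  expect_false(identical(
    reg$lines[order(reg$lines[, 1], reg$lines[, 2]), ],
    st$lines[order(st$lines[, 1], st$lines[, 2]), ]))

  expect_error(caipi_pattern(9, 8, 2, 2, 0), "divisible")
})

test_that("shot segmentation conserves lines and flags partial shots", {
  # the study geometry: 180 x 144 phase encodes at 2x2 -> 6480 lines
  pat <- caipi_pattern(180, 144, 2, 2, 1)
  expect_equal(nrow(pat$lines), 6480)
  seg1 <- segment_shots(pat, 1)
  expect_equal(seg1$n_shots, 6480L)       # GRE: one line per TR
  seg5 <- segment_shots(pat, 5)
  expect_equal(seg5$n_shots, 1296L)
  expect_false(any(seg5$partial))
  # every line assigned exactly once, epi_factor lines per full shot
  expect_equal(sort(unique(tabulate(seg5$shot))), 5L)
  expect_equal(length(seg5$shot), 6480)

  pat10 <- caipi_pattern(10, 1, 1, 1, 0)
  seg3 <- segment_shots(pat10, 3, ordering = "sequential")
  expect_equal(seg3$n_shots, 4L)
  expect_equal(as.vector(tabulate(seg3$shot)), c(3L, 3L, 3L, 1L))
  expect_equal(which(seg3$partial), 4L)

  segi <- segment_shots(pat10, 3, ordering = "interleaved")
  expect_equal(segi$n_shots, 4L)
  expect_equal(sort(tabulate(segi$shot)), c(2L, 2L, 3L, 3L))

  expect_error(segment_shots(pat10, 11), "exceeds")
})

test_that("thermal noise scales with the square root of bandwidth", {
  expect_equal(thermal_noise_sigma(125, 1.7, 125), 1.7)
  expect_equal(thermal_noise_sigma(631, 1, 125), sqrt(631 / 125))
  expect_equal(thermal_noise_sigma(631, 1, 125), 2.246775, tolerance = 1e-6)
  expect_error(thermal_noise_sigma(-1, 1, 125), "positive")
})

test_that("navigator timing and readout train arithmetic match the protocol", {
  expect_equal(navigator_tr_count(c(40, 32, 12), c(4, 2), 8), 6L)
  expect_equal(navigator_tr_count(c(40, 32, 12), c(1, 1), 8), 48L)
  expect_equal(navigator_tr_count(c(40, 32, 12), c(4, 2), 7), 7L)
  expect_error(navigator_tr_count(c(40, 32, 12), c(3, 2), 8), "divisible")

  expect_equal(readout_train_length(125, 1), 0.008)
  expect_equal(readout_train_length(372, 3), 3 / 372)   # 8.06 ms, ramp-free
  expect_lt(readout_train_length(1e9, 5), 1e-8)
})

test_that("gradient limits bound the EPI factor", {
  expect_equal(max_epi_factor(40, 200, 240, 240, 0.010), 10L)
  expect_equal(max_epi_factor(20, 200, 240, 240, 0.010), 7L)
  expect_equal(max_epi_factor(40, 200, 240, 240, 0.020),
               2L * max_epi_factor(40, 200, 240, 240, 0.010))
  expect_equal(max_epi_factor(40, 200, 240, 240, 0.0005), 0L)
  expect_error(max_epi_factor(-40, 200, 240, 240, 0.01), "positive")
})

test_that("simulated k-space reproduces the ideal image and its noise model", {
  ph <- small_phantom()
  pr <- small_protocol(ph)
  nl <- prod(dim(ph$m0)[2:3])
  tl <- null_timeline(nl)

  # inverse-crime identity: noiseless full sampling reconstructs exactly
  kd <- simulate_scan(ph, pr, tl, noise_sigma = 0, seed = 0)
  img <- reconstruct(kd, "uncorrected")
  ideal <- ideal_image(ph, pr)
  expect_lt(rel_rmse(img$data, ideal$data), 1e-12)

  # constant global offset: phase differs by exactly 2 pi delta TE
  tlc <- null_timeline(nl)
  tlc$global_hz <- rep(2.5, nl)
  kdc <- simulate_scan(ph, pr, tlc, noise_sigma = 0, seed = 0)
  raw <- reconstruct(kdc, "corrected", timeline = null_timeline(nl))
  for (e in seq_along(pr$te_s)) {
    expected <- 2 * pi * 2.5 * pr$te_s[e]
    dphi <- Arg(raw$data[, , , e] * Conj(ideal$data[, , , e]))
    expect_lt(max(abs(dphi[ph$mask] - expected)), 1e-9)
  }

  # image-domain noise SD equals sigma under the unitary DFT (background)
  sigma <- 0.05
  kdn <- simulate_scan(ph, pr, tl, noise_sigma = sigma, seed = 11)
  imgn <- reconstruct(kdn, "uncorrected")
  bg <- ph$labels == 0
  noise_re <- Re(imgn$data[, , , 1])[bg]
  expect_gt(length(noise_re), 1e4)
  expect_equal(stats::sd(noise_re), sigma, tolerance = 0.05)

  # two seeds differ only by noise: difference is zero-mean complex
  # Gaussian with per-component SD sigma * sqrt(2)
  kdn2 <- simulate_scan(ph, pr, tl, noise_sigma = sigma, seed = 12)
  d <- unlist(lapply(1:4, function(e) as.vector(kdn$echo_data[[e]] - kdn2$echo_data[[e]])))
  expect_gt(length(d), 1e5)
  expect_lt(abs(mean(Re(d))), 5 * sigma * sqrt(2) / sqrt(length(d)))
  expect_equal(stats::sd(Re(d)), sigma * sqrt(2), tolerance = 0.05)
  expect_equal(stats::sd(Im(d)), sigma * sqrt(2), tolerance = 0.05)

  expect_error(simulate_scan(ph, pr, null_timeline(10)), "shots")
})

test_that("SNR matching: averaged EPI repetitions recover the GRE noise level", {
  ph <- small_phantom()
  gre <- small_protocol(ph, "GRE")
  e5 <- small_protocol(ph, "EPIx5")
  nl <- prod(dim(ph$m0)[2:3])
  sigma_gre <- 0.04
  sigma_e5 <- thermal_noise_sigma(e5$bw_hz_per_px, sigma_gre, gre$bw_hz_per_px)

  kd_g <- simulate_scan(ph, gre, null_timeline(nl), sigma_gre, seed = 21)
  g_img <- reconstruct(kd_g, "uncorrected")
  n_shots5 <- ceiling(nl / 5)
  acc <- 0
  for (r in 1:5) {
    kd_e <- simulate_scan(ph, e5, null_timeline(n_shots5), sigma_e5, seed = 30 + r)
    acc <- acc + reconstruct(kd_e, "uncorrected")$data / 5
  }
  bg <- ph$labels == 0
  sd_gre <- stats::sd(Re(g_img$data[, , , 1])[bg])
  sd_epi <- stats::sd(Re(acc[, , , 1])[bg])
  expect_gt(sum(bg), 1e4)
  expect_equal(sd_epi, sd_gre, tolerance = 0.05)
})
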