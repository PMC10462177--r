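#!/usr/bin/env Rscript
# EPI geometric distortion and T2* blurring at the protocol's scale:
# the pixel-shift model (150 Hz x 10 ms ETL = 1.5 px), the delta-function
# evaluation of the distortion-correction algorithm (effective voxel size
# and residual shift over true shifts 0..2 px), and the T2*-decay PSF FWHM
# across the echo train.
#
# Findings to expect: the effective voxel size varies between 1 and 2
# nominal voxels depending on the sub-pixel part of the shift; the
# corrected shift agrees with the prediction to a small fraction of a
# pixel; T2* of 10 ms across a 10 ms train blurs the PSF to < 1.2 voxels.

suppressPackageStartupMessages(library(epiqsm))

dir.create("results", showWarnings = FALSE)

cat(sprintf("pixel shift of 150 Hz at 10 ms ETL: %.2f px\n",
            pixel_shift(150, 0.010)))

ev <- evaluate_correction(seq(0, 2, by = 0.05), n = 256)
write.csv(ev, "results/distortion_correction_eval.csv", row.names = FALSE)
cat(sprintf("effective voxel size: max %.3f at shift %.2f px; residual shift max %.2g px\n",
            max(ev$effective_voxel),
            ev$shift_px[which.max(ev$effective_voxel)],
            max(abs(ev$residual_shift_px))))

t2_grid <- c(5, 10, 20, 40, 80) / 1000
fw <- vapply(t2_grid, function(t2) {
  f <- t2star_blur_fwhm(t2, 0.010, 256)
  c(discrete = as.numeric(f), sinc = attr(f, "fwhm_sinc_voxels"))
}, numeric(2))
psf <- data.frame(t2star_ms = t2_grid * 1000, fwhm_voxels = fw["discrete", ],
                  fwhm_sinc_voxels = fw["sinc", ])
write.csv(psf, "results/t2star_psf_fwhm.csv", row.names = FALSE)
print(psf, row.names = FALSE)
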