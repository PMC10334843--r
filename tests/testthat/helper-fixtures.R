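# Shared small fixtures, built in code at load time.

default_irf <- make_irf(170)

# A small projected image with hand-placed cells: one macrophage disk and one
# adipocyte rim, on a near-zero background. Returns the image plus the truth
# masks used to place the intensities.
tiny_projection <- function(n = 48, macro_val = c(nadh = 60, fad = 40, lipo = 300),
                            rim_val = c(nadh = 70, fad = 30, lipo = 0)) {
  arr <- array(0, dim = c(n, n, 3))
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  macro <- (yy - 12)^2 + (xx - 12)^2 <= 16
  d2 <- (yy - 32)^2 + (xx - 32)^2
  rim <- d2 <= 100 & d2 >= 49
  arr[, , 1][macro] <- macro_val[["nadh"]]; arr[, , 1][rim] <- rim_val[["nadh"]]
  arr[, , 2][macro] <- macro_val[["fad"]]; arr[, , 2][rim] <- rim_val[["fad"]]
  arr[, , 3][macro] <- macro_val[["lipo"]]
  proj <- structure(list(data = arr, channels = c("nadh", "fad", "lipofuscin"),
                         pixel_pitch_um = 1, mode = "sum"),
                    class = "projected_image")
  list(proj = proj, macro = macro, rim = rim)
}

# Decay image with every pixel drawing from one (a1, t1, t2) truth.
uniform_decay_image <- function(frame = 12, a1 = 0.7, t1 = 0.4, t2 = 2.5,
                                counts_per_pixel = 2000, seed = 1,
                                acq = flim_acq_config(frame = frame,
                                                      counts_per_pixel = counts_per_pixel)) {
  lam <- model_decay(a1, t1, t2, scale = counts_per_pixel, irf = acq$irf)
  counts <- withr::with_seed(seed, {
    array(rpois(frame * frame * acq$n_bins,
                rep(lam, each = frame * frame)),
          dim = c(frame, frame, acq$n_bins))
  })
  structure(list(counts = counts, irf = acq$irf,
                 bin_width_ps = acq$bin_width_ps, frame = frame,
                 owner = matrix(1L, frame, frame), acq = acq),
            class = "decay_image")
}
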