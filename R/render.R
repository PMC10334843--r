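#' Two-photon acquisition optics configuration
#'
#' Channel definitions and stack geometry for rendering multi-channel image
#' stacks. Defaults mirror a full-resolution acquisition: three channels
#' (NAD(P)H excited at 740 nm, emission 400-480 nm; FAD at 890 nm, 510-600 nm;
#' lipofuscin at 1040 nm, 604-679 nm), 11 z-planes covering 20 um at 2 um
#' steps, a 4096-pixel frame at 0.16 um pitch (655.36 um field of view).
#'
#' @param frame Frame side in pixels.
#' @param pixel_pitch_um Pixel pitch in micrometres.
#' @param z_planes Number of z planes (>= 1).
#' @param photon_scale Multiplier on all expected photon counts.
#' @param background Expected background counts per pixel summed over the
#'   stack, per channel (named).
#' @return A list of class `optics_config`.
#' @export
optics_config <- function(frame = 4096, pixel_pitch_um = 0.16, z_planes = 11,
                          photon_scale = 1,
                          background = c(nadh = 4, fad = 4, lipofuscin = 1.5)) {
  if (z_planes < 1) stop("z_planes must be >= 1", call. = FALSE)
  channels <- data.frame(
    name = c("nadh", "fad", "lipofuscin"),
    excitation_nm = c(740, 890, 1040),
    emission_lo_nm = c(400, 510, 604),
    emission_hi_nm = c(480, 600, 679), stringsAsFactors = FALSE)
  structure(list(frame = as.integer(frame), pixel_pitch_um = pixel_pitch_um,
                 z_planes = as.integer(z_planes), channels = channels,
                 photon_scale = photon_scale, background = background,
                 fov_um = frame * pixel_pitch_um,
                 z_depth_um = 20, z_step_um = 2),
            class = "optics_config")
}

# Expected stack-summed intensity per channel for a scene.
# Adipocyte rims and macrophages share a total NAD(P)H+FAD budget split by the
# cell's redox ratio (redox = FAD / (NAD(P)H + FAD)); the lipofuscin channel
# lights up only on macrophages, proportional to lipo_rel.
scene_expected_intensity <- function(scene, optics,
                                     cell_total = 330, lipo_base = 400) {
  n <- scene$frame
  bg <- optics$background
  e_nadh <- matrix(bg[["nadh"]], n, n)
  e_fad <- matrix(bg[["fad"]], n, n)
  e_lipo <- matrix(bg[["lipofuscin"]], n, n)
  cells <- scene$cells
  for (k in seq_len(nrow(cells))) {
    id <- cells$id[k]
    px <- if (cells$type[k] == "adipocyte") scene$adipo_labels == id
          else scene$macro_labels == id
    if (!any(px)) next
    e_fad[px] <- cells$redox[k] * cell_total
    e_nadh[px] <- (1 - cells$redox[k]) * cell_total
    if (cells$type[k] == "macrophage")
      e_lipo[px] <- cells$lipo_rel[k] * lipo_base
  }
  # lipid voids: near-dark interiors (below background haze)
  list(nadh = e_nadh * optics$photon_scale, fad = e_fad * optics$photon_scale,
       lipofuscin = e_lipo * optics$photon_scale)
}

#' Render a multi-channel z-stack from a tissue scene
#'
#' Converts per-cell ground truth into expected per-pixel photon counts
#' (split between the NAD(P)H and FAD channels by each cell's redox ratio,
#' with the lipofuscin channel bright only on macrophage masks) and draws
#' independent Poisson counts per pixel, channel and z plane. The expected
#' stack total is divided evenly across z planes, so a sum projection has the
#' configured expectation.
#'
#' @param scene A [generate_tissue_scene()] result.
#' @param optics An [optics_config()]; its frame must match the scene.
#' @param cell_total Expected NAD(P)H+FAD counts per cell pixel, summed over
#'   the stack.
#' @param lipo_base Expected lipofuscin counts per macrophage pixel (at
#'   relative intensity 1), summed over the stack.
#' @param seed Integer seed.
#' @return An `image_stack`: integer array `data` of dim (y, x, channel, z),
#'   channel table, pixel pitch, and acquisition metadata including the
#'   physical field-of-view width in micrometres.
#' @export
render_multichannel_stack <- function(scene, optics = optics_config(frame = scene$frame),
                                      cell_total = 330, lipo_base = 400,
                                      seed = NULL) {
  stopifnot(inherits(scene, "tissue_scene"), inherits(optics, "optics_config"))
  if (scene$frame != optics$frame)
    stop(sprintf("scene frame (%d) does not match optics frame (%d)",
                 scene$frame, optics$frame), call. = FALSE)
  exp_int <- scene_expected_intensity(scene, optics, cell_total, lipo_base)
  n <- scene$frame; nz <- optics$z_planes
  ch_names <- optics$channels$name
  with_local_seed(seed, {
    data <- array(0L, dim = c(n, n, length(ch_names), nz))
    for (ci in seq_along(ch_names)) {
      lam <- exp_int[[ch_names[ci]]] / nz
      for (z in seq_len(nz))
        data[, , ci, z] <- rpois(n * n, lam)
    }
    structure(list(data = data, channels = ch_names,
                   pixel_pitch_um = optics$pixel_pitch_um,
                   meta = list(fov_um = optics$fov_um,
                               z_planes = nz, z_step_um = optics$z_step_um,
                               channel_table = optics$channels,
                               cell_total = cell_total,
                               lipo_base = lipo_base)),
              class = "image_stack")
  })
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %dx%d px, %d channels (%s), %d z-planes, FOV %.2f um\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ","), d[4],
              x$meta$fov_um))
  invisible(x)
}

#' FLIM acquisition configuration
#'
#' Defaults describe a 256x256-pixel TCSPC acquisition with 256 time bins of
#' 48.8 ps (a 12.5 ns window), a Gaussian IRF of 170 ps FWHM, and a
#' per-pixel photon budget chosen so the median foreground pixel collects
#' comfortably more than 200 photons, the floor below which decay fits are
#' refused.
#'
#' @param frame FLIM frame side in pixels.
#' @param n_bins Number of TCSPC time bins.
#' @param bin_width_ps Bin width in picoseconds.
#' @param irf_fwhm_ps IRF full width at half maximum, picoseconds.
#' @param irf_center_ps Temporal position of the IRF peak.
#' @param counts_per_pixel Expected total photons per foreground pixel.
#' @param background_counts Expected total photons per background pixel.
#' @param min_counts Photon-count floor used downstream by the fitters.
#' @return A list of class `flim_acq_config` (includes the built `irf`).
#' @export
flim_acq_config <- function(frame = 256, n_bins = 256, bin_width_ps = 48.8,
                            irf_fwhm_ps = 170, irf_center_ps = 600,
                            counts_per_pixel = 400, background_counts = 1,
                            min_counts = 200) {
  if (bin_width_ps <= 0) stop("bin_width_ps must be > 0", call. = FALSE)
  if (irf_fwhm_ps <= 0) stop("irf_fwhm_ps must be > 0", call. = FALSE)
  irf <- make_irf(irf_fwhm_ps, bin_width_ps, n_bins, irf_center_ps)
  structure(list(frame = as.integer(frame), n_bins = as.integer(n_bins),
                 bin_width_ps = bin_width_ps, irf_fwhm_ps = irf_fwhm_ps,
                 irf_center_ps = irf_center_ps,
                 counts_per_pixel = counts_per_pixel,
                 background_counts = background_counts,
                 min_counts = min_counts, irf = irf),
            class = "flim_acq_config")
}

#' Render a per-pixel TCSPC decay image from a tissue scene
#'
#' Every FLIM pixel is mapped (nearest neighbour) onto the scene grid; pixels
#' inside a cell mask receive Poisson decay counts around the IRF-convolved
#' bi-exponential model of the owning cell's ground truth (a1, t1, t2) scaled
#' to the configured photon budget, background pixels receive a small
#' IRF-shaped count.
#'
#' @param scene A `tissue_scene`.
#' @param acq A [flim_acq_config()].
#' @param seed Integer seed.
#' @return A `decay_image`: integer `counts` array of dim (y, x, bin), the
#'   IRF, bin width, and the cell-ownership label matrix at FLIM resolution.
#' @export
render_flim_frame <- function(scene, acq = flim_acq_config(), seed = NULL) {
  stopifnot(inherits(scene, "tissue_scene"), inherits(acq, "flim_acq_config"))
  nf <- acq$frame
  if (scene$frame < nf)
    stop("scene frame smaller than FLIM frame", call. = FALSE)
  idx <- pmin(scene$frame, pmax(1L, round(seq_len(nf) * scene$frame / nf)))
  owner <- matrix(0L, nf, nf)
  lab_a <- scene$adipo_labels[idx, idx]
  lab_m <- scene$macro_labels[idx, idx]
  owner[lab_a > 0L] <- lab_a[lab_a > 0L]
  owner[lab_m > 0L] <- lab_m[lab_m > 0L]   # macrophage-first, as in the scene
  with_local_seed(seed, {
    counts <- array(0L, dim = c(nf, nf, acq$n_bins))
    bgp <- acq$background_counts * acq$irf$curve
    if (acq$background_counts > 0) {
      nbgl <- sum(owner == 0L)
      if (nbgl > 0)
        for (b in seq_len(acq$n_bins)) {
          sl <- counts[, , b]
          sl[owner == 0L] <- rpois(nbgl, bgp[b])
          counts[, , b] <- sl
        }
    }
    cells <- scene$cells
    for (k in seq_len(nrow(cells))) {
      px <- owner == cells$id[k]
      npx <- sum(px)
      if (npx == 0) next
      lam <- model_decay(cells$a1[k], cells$t1[k], cells$t2[k],
                         scale = acq$counts_per_pixel, irf = acq$irf)
      for (b in seq_len(acq$n_bins)) {
        sl <- counts[, , b]
        sl[px] <- rpois(npx, lam[b])
        counts[, , b] <- sl
      }
    }
    structure(list(counts = counts, irf = acq$irf,
                   bin_width_ps = acq$bin_width_ps, frame = nf,
                   owner = owner, acq = acq),
              class = "decay_image")
  })
}

#' @export
print.decay_image <- function(x, ...) {
  cat(sprintf("decay_image: %dx%d px, %d bins x %.1f ps\n", x$frame, x$frame,
              dim(x$counts)[3], x$bin_width_ps))
  invisible(x)
}

#' Ground-truth optical readout table for a set of scenes
#'
#' One row per field of view with the nine optical readouts, computed as means
#' of the scenes' per-cell ground truth: OR1 adipocyte redox ratio; OR2-OR4
#' adipocyte a1, t1, t2; OR5 macrophage redox ratio; OR6-OR8 macrophage a1,
#' t1, t2; OR9 macrophage relative lipofuscin intensity. Scenes missing a
#' cell type yield NA readouts for that type and are flagged incomplete.
#'
#' @param scenes A list of `tissue_scene` objects.
#' @return A data.frame with columns OR1..OR9, `group` (the stage label) and
#'   `incomplete`.
#' @export
readout_truth_table <- function(scenes) {
  if (inherits(scenes, "tissue_scene")) scenes <- list(scenes)
  rows <- lapply(scenes, function(sc) {
    a <- sc$cells[sc$cells$type == "adipocyte", ]
    m <- sc$cells[sc$cells$type == "macrophage", ]
    mn <- function(df, col) if (nrow(df) > 0) mean(df[[col]]) else NA_real_
    data.frame(OR1 = mn(a, "redox"), OR2 = mn(a, "a1"), OR3 = mn(a, "t1"),
               OR4 = mn(a, "t2"), OR5 = mn(m, "redox"), OR6 = mn(m, "a1"),
               OR7 = mn(m, "t1"), OR8 = mn(m, "t2"), OR9 = mn(m, "lipo_rel"),
               group = sc$stage, incomplete = nrow(a) == 0 || nrow(m) == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
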