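#' Stage-dependent metabolic ground truth
#'
#' Mean per-cell optical parameters for each disease stage. These are
#' simulator choices (the underlying study reports effect directions, not
#' per-cell values): in the prediabetic stage only adipocytes shift
#' (redox ratio down, free-NAD(P)H fraction a1 up, bound lifetime t2 down);
#' in the diabetic stage both cell types shift and macrophage lipofuscin
#' rises, most in crown-like-structure (CLS) macrophages, whose redox ratio
#' is configured below that of non-CLS macrophages.
#'
#' @param stage One of `"control"`, `"prediabetic"`, `"diabetic"`.
#' @return A list with `adipocyte` and `macrophage` mean-parameter lists and
#'   `sd` (cell-level) / `fov_sd` (field-level) noise scales.
#' @export
stage_truth <- function(stage = c("control", "prediabetic", "diabetic")) {
  stage <- match.arg(stage)
  adipo <- switch(stage,
    control     = list(redox = 0.45, a1 = 0.75, t1 = 0.40, t2 = 2.5),
    prediabetic = list(redox = 0.38, a1 = 0.82, t1 = 0.40, t2 = 2.2),
    diabetic    = list(redox = 0.35, a1 = 0.85, t1 = 0.40, t2 = 2.1))
  macro <- switch(stage,
    control     = list(redox = 0.42, redox_cls = 0.42, a1 = 0.72, t1 = 0.40,
                       t2 = 2.6, lipo = 1.0, lipo_cls = 1.0),
    prediabetic = list(redox = 0.42, redox_cls = 0.42, a1 = 0.72, t1 = 0.40,
                       t2 = 2.6, lipo = 1.0, lipo_cls = 1.0),
    diabetic    = list(redox = 0.38, redox_cls = 0.33, a1 = 0.80, t1 = 0.40,
                       t2 = 2.3, lipo = 1.5, lipo_cls = 2.2))
  list(stage = stage, adipocyte = adipo, macrophage = macro,
       sd = list(redox = 0.03, a1 = 0.03, t1 = 0.02, t2 = 0.12, lipo = 0.15),
       fov_sd = list(redox = 0.015, a1 = 0.015, t1 = 0.008, t2 = 0.06,
                     lipo = 0.08))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Rasterize a disk (r_in = 0) or annulus into an integer label matrix.
paint_annulus <- function(labels, cx, cy, r_in, r_out, id) {
  n <- nrow(labels)
  xs <- max(1L, floor(cx - r_out)):min(ncol(labels), ceiling(cx + r_out))
  ys <- max(1L, floor(cy - r_out)):min(n, ceiling(cy + r_out))
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  sel <- d2 <= r_out^2 & d2 >= r_in^2
  sub <- labels[ys, xs, drop = FALSE]
  sub[sel] <- id
  labels[ys, xs] <- sub
  labels
}

#' Generate a synthetic adipose-tissue scene with known ground truth
#'
#' Lays out unilocular adipocytes (dark lipid voids with thin bright cytoplasm
#' rims) and lipofuscin-laden macrophages (small disks) in a square field of
#' view, optionally arranging dense crowns of macrophages around chosen
#' adipocytes to emulate crown-like structures. Each cell carries a metabolic
#' ground truth (redox ratio, a1, t1, t2, relative lipofuscin intensity) drawn
#' around the stage means of [stage_truth()], plus a shared per-field random
#' effect. Geometry scales with the frame size so the same cell density is
#' kept at reduced resolutions.
#'
#' @param stage Disease stage label.
#' @param n_adipocytes,n_macrophages Requested counts (macrophages here are
#'   the scattered, non-CLS ones).
#' @param n_cls Number of crown-like structures; each is a ring of macrophages
#'   around one adipocyte. Defaults to 2 in the diabetic stage, 0 otherwise.
#' @param frame Frame side length in pixels.
#' @param pixel_pitch_um Pixel pitch in micrometres.
#' @param truth Output of [stage_truth()]; override to change effect sizes.
#' @param seed Integer seed.
#' @return An object of class `tissue_scene`: frame geometry, a `cells`
#'   data.frame of per-cell truth, and integer label images `adipo_labels`
#'   (cytoplasm rims) and `macro_labels`, disjoint by construction
#'   (macrophage-first where a rim and a macrophage would overlap).
#' @export
generate_tissue_scene <- function(stage = c("control", "prediabetic", "diabetic"),
                                  n_adipocytes = 12, n_macrophages = 15,
                                  n_cls = NULL, frame = 512,
                                  pixel_pitch_um = 655.36 / 512 * 512 / frame,
                                  truth = stage_truth(stage), seed = NULL) {
  stage <- match.arg(stage)
  if (is.null(n_cls)) n_cls <- if (stage == "diabetic") 2L else 0L
  if (n_cls > n_adipocytes)
    stop("n_cls cannot exceed n_adipocytes", call. = FALSE)
  with_local_seed(seed, {
    s <- frame / 512                      # geometry scale factor
    r_lo <- 22 * s; r_hi <- 34 * s
    rim_w <- max(2, round(3 * s))
    macro_r <- max(3, round(5 * s))
    gap <- 8 * s
    d_link <- 2 * (2 * macro_r)           # safety margin around CLS rings
    ring_pad <- 2 * macro_r + 2 * s

    # --- place adipocytes (CLS hosts first, with enlarged exclusion zones)
    radii <- runif(n_adipocytes, r_lo, r_hi)
    excl <- radii + ifelse(seq_len(n_adipocytes) <= n_cls, ring_pad + d_link, 0)
    cx <- cy <- numeric(n_adipocytes)
    for (i in seq_len(n_adipocytes)) {
      placed <- FALSE
      for (try in seq_len(4000)) {
        m <- excl[i] + 2
        if (frame - 2 * m <= 1) break
        x <- runif(1, m, frame - m); y <- runif(1, m, frame - m)
        if (i == 1 || all(sqrt((cx[seq_len(i - 1)] - x)^2 +
                               (cy[seq_len(i - 1)] - y)^2) >
                          excl[seq_len(i - 1)] + excl[i] + gap)) {
          cx[i] <- x; cy[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed)
        stop(sprintf("frame %d too small for %d adipocytes (placed %d)",
                     frame, n_adipocytes, i - 1L), call. = FALSE)
    }

    # --- macrophage centres: CLS rings then scattered singletons
    mx <- my <- numeric(0); m_cls <- integer(0)
    for (k in seq_len(n_cls)) {
      r_ring <- radii[k] + rim_w + macro_r + 2 * s
      n_ring <- max(5L, round(2 * pi * r_ring / (1.8 * 2 * macro_r)))
      th <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
      mx <- c(mx, cx[k] + r_ring * cos(th))
      my <- c(my, cy[k] + r_ring * sin(th))
      m_cls <- c(m_cls, rep(k, n_ring))
    }
    min_sep <- 3 * 2 * macro_r
    for (j in seq_len(n_macrophages)) {
      placed <- FALSE
      for (try in seq_len(4000)) {
        x <- runif(1, macro_r + 2, frame - macro_r - 2)
        y <- runif(1, macro_r + 2, frame - macro_r - 2)
        d_adipo <- sqrt((cx - x)^2 + (cy - y)^2)
        ok <- all(d_adipo > radii + rim_w + macro_r + 2)
        if (ok && n_cls > 0)
          ok <- all(d_adipo[seq_len(n_cls)] > excl[seq_len(n_cls)] + macro_r)
        if (ok && length(mx) > 0)
          ok <- all(sqrt((mx - x)^2 + (my - y)^2) > min_sep)
        if (ok) { mx <- c(mx, x); my <- c(my, y); m_cls <- c(m_cls, 0L)
                  placed <- TRUE; break }
      }
      if (!placed)
        stop(sprintf("frame %d too small for %d scattered macrophages",
                     frame, n_macrophages), call. = FALSE)
    }

    # --- per-cell truth draws around stage means plus a per-field effect
    sd <- truth$sd; fsd <- truth$fov_sd
    fov <- lapply(fsd, function(v) rnorm(1, 0, v))
    n_m <- length(mx)
    draw <- function(mu, s_, lo, hi, n, f) clamp(rnorm(n, mu + f, s_), lo, hi)
    a_tr <- truth$adipocyte
    adipo <- if (n_adipocytes > 0) data.frame(
      id = seq_len(n_adipocytes), type = "adipocyte",
      cls_id = c(seq_len(n_cls), rep(0L, n_adipocytes - n_cls)),
      cx = cx, cy = cy, r_in = radii, r_out = radii + rim_w,
      redox = draw(a_tr$redox, sd$redox, 0.01, 0.99, n_adipocytes, fov$redox),
      a1 = draw(a_tr$a1, sd$a1, 0.01, 0.99, n_adipocytes, fov$a1),
      t1 = draw(a_tr$t1, sd$t1, 0.1, 0.9, n_adipocytes, fov$t1),
      t2 = draw(a_tr$t2, sd$t2, 1.2, 5.5, n_adipocytes, fov$t2),
      lipo_rel = rep(0, n_adipocytes), stringsAsFactors = FALSE) else NULL
    m_tr <- truth$macrophage
    macro <- if (n_m > 0) {
      is_cls <- m_cls > 0
      data.frame(
        id = n_adipocytes + seq_len(n_m), type = "macrophage", cls_id = m_cls,
        cx = mx, cy = my, r_in = 0, r_out = macro_r,
        redox = clamp(rnorm(n_m, ifelse(is_cls, m_tr$redox_cls, m_tr$redox) +
                              fov$redox, sd$redox), 0.01, 0.99),
        a1 = draw(m_tr$a1, sd$a1, 0.01, 0.99, n_m, fov$a1),
        t1 = draw(m_tr$t1, sd$t1, 0.1, 0.9, n_m, fov$t1),
        t2 = draw(m_tr$t2, sd$t2, 1.2, 5.5, n_m, fov$t2),
        lipo_rel = clamp(rnorm(n_m, ifelse(is_cls, m_tr$lipo_cls, m_tr$lipo) +
                                 fov$lipo, sd$lipo), 0.05, 10),
        stringsAsFactors = FALSE)
    } else NULL
    cells <- rbind(adipo, macro)
    if (is.null(cells))
      cells <- data.frame(id = integer(0), type = character(0),
                          cls_id = integer(0), cx = numeric(0), cy = numeric(0),
                          r_in = numeric(0), r_out = numeric(0),
                          redox = numeric(0), a1 = numeric(0), t1 = numeric(0),
                          t2 = numeric(0), lipo_rel = numeric(0))

    # --- truth label images; macrophages win any rim/macrophage collision
    adipo_labels <- matrix(0L, frame, frame)
    macro_labels <- matrix(0L, frame, frame)
    if (n_adipocytes > 0)
      for (i in seq_len(n_adipocytes))
        adipo_labels <- paint_annulus(adipo_labels, cx[i], cy[i],
                                      radii[i], radii[i] + rim_w, i)
    if (n_m > 0)
      for (j in seq_len(n_m))
        macro_labels <- paint_annulus(macro_labels, mx[j], my[j],
                                      0, macro_r, n_adipocytes + j)
    adipo_labels[macro_labels > 0L] <- 0L

    structure(list(frame = as.integer(frame), pixel_pitch_um = pixel_pitch_um,
                   stage = stage, cells = cells, adipo_labels = adipo_labels,
                   macro_labels = macro_labels, truth = truth),
              class = "tissue_scene")
  })
}

#' @export
print.tissue_scene <- function(x, ...) {
  cat(sprintf("tissue_scene: %dx%d px (%.2f um/px), stage %s\n", x$frame,
              x$frame, x$pixel_pitch_um, x$stage))
  cat(sprintf("  %d adipocytes, %d macrophages (%d in %d CLS)\n",
              sum(x$cells$type == "adipocyte"),
              sum(x$cells$type == "macrophage"),
              sum(x$cells$type == "macrophage" & x$cells$cls_id > 0),
              length(unique(x$cells$cls_id[x$cells$cls_id > 0]))))
  invisible(x)
}
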