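# Dominant ground-truth cell id under a segmented mask (0 if none).
dominant_truth_id <- function(truth_labels, mask) {
  v <- truth_labels[mask]
  v <- v[v > 0L]
  if (length(v) == 0) return(0L)
  tb <- table(v)
  as.integer(names(tb)[which.max(tb)])
}

#' Segment one scene's rendered stack and extract intensity cell records
#'
#' Renders the multi-channel stack, sum-projects it, segments macrophages
#' (lipofuscin channel) and adipocyte cytoplasm rims (NAD(P)H + FAD), detects
#' crown-like structures, and returns per-cell records with mean channel
#' intensities, redox ratios, CLS flags, and the dominant ground-truth cell
#' id under each segmented mask (used downstream to source that cell's decay
#' photons).
#'
#' @param scene A `tissue_scene`.
#' @param optics An [optics_config()] matching the scene frame.
#' @param seed Integer seed for the rendering noise.
#' @return A cell-record data.frame with `truth_id` and `n_cls` attribute.
#' @export
measure_scene_intensity <- function(scene,
                                    optics = optics_config(frame = scene$frame),
                                    seed = NULL) {
  stack <- render_multichannel_stack(scene, optics, seed = seed)
  proj <- z_project(stack, "sum")
  seg_m <- segment_macrophages(proj)
  cls <- detect_cls(seg_m$labels)
  seg_a <- withCallingHandlers(
    segment_adipocyte_cytoplasm(proj, seg_m$labels),
    warning = function(w) invokeRestart("muffleWarning"))
  rec <- extract_cell_records(proj, seg_m$labels, seg_a$labels, cls)
  if (nrow(rec) > 0) {
    rec$truth_id <- vapply(seq_len(nrow(rec)), function(i) {
      lab <- if (rec$type[i] == "macrophage") seg_m$labels else seg_a$labels
      tru <- if (rec$type[i] == "macrophage") scene$macro_labels else
        scene$adipo_labels
      dominant_truth_id(tru, lab == rec$cell_id[i])
    }, 0L)
  } else rec$truth_id <- integer(0)
  attr(rec, "n_cls") <- cls$n_cls
  attr(rec, "stage") <- scene$stage
  rec
}

#' Add per-cell FLIM parameters by pooled-decay fitting
#'
#' For each segmented cell, a pooled TCSPC decay is drawn from the matched
#' ground-truth cell's decay model — the photon expectation scales with the
#' cell's area at FLIM resolution times the per-pixel budget (the pooled sum
#' of per-pixel Poisson decays is itself Poisson) — and fitted with
#' [fit_decay()]. Cells with no matched truth get NA parameters.
#'
#' @param records Output of [measure_scene_intensity()].
#' @param scene The scene the records came from.
#' @param acq A [flim_acq_config()].
#' @param seed Integer seed.
#' @param photon_cap Upper bound on pooled photons per cell.
#' @return `records` with `a1`, `t1`, `t2`, `flim_converged` columns.
#' @export
add_flim_fits <- function(records, scene, acq = flim_acq_config(),
                          seed = NULL, photon_cap = 2e5) {
  n <- nrow(records)
  records$a1 <- records$t1 <- records$t2 <- NA_real_
  records$flim_converged <- NA
  if (n == 0) return(records)
  scale2 <- (acq$frame / scene$frame)^2
  with_local_seed(seed, {
    for (i in seq_len(n)) {
      tid <- records$truth_id[i]
      if (tid == 0L) next
      tru <- scene$cells[scene$cells$id == tid, ]
      photons <- min(photon_cap,
                     max(2 * acq$min_counts,
                         records$area[i] * scale2 * acq$counts_per_pixel))
      h <- simulate_decay(tru$a1, tru$t1, tru$t2, photons, acq$irf)
      f <- fit_decay(h, min_counts = acq$min_counts)
      records$a1[i] <- f$a1; records$t1[i] <- f$t1; records$t2[i] <- f$t2
      records$flim_converged[i] <- f$converged
    }
  })
  records
}

#' Simulate and measure a full imaging study
#'
#' Generates `n_fov` fields of view per stage, runs the full measurement
#' pipeline on each (render, segment, redox, per-cell FLIM, field
#' aggregation), and assembles the measured readout table: OR1 adipocyte
#' redox; OR2-OR4 adipocyte a1/t1/t2; OR5 macrophage redox; OR6-OR8
#' macrophage a1/t1/t2; OR9 macrophage lipofuscin intensity relative to the
#' control-group field mean.
#'
#' @param n_fov Fields of view per stage.
#' @param stages Character vector of stages to simulate.
#' @param frame Scene/optics frame in pixels.
#' @param n_adipocytes,n_macrophages Per-scene cell counts.
#' @param optics,acq Acquisition configurations.
#' @param cells_per_point Cells averaged per field data point.
#' @param seed Integer seed (per-field substreams are derived from it).
#' @return A list: `readouts` (data.frame OR1..OR9 + `group`, `fov`,
#'   `n_cls`), `cells` (all per-cell records with `fov` and `group`).
#' @export
simulate_study <- function(n_fov = 30,
                           stages = c("control", "prediabetic", "diabetic"),
                           frame = 512, n_adipocytes = 12, n_macrophages = 15,
                           optics = optics_config(frame = frame),
                           acq = flim_acq_config(),
                           cells_per_point = 10, seed = 1) {
  all_cells <- list(); rows <- list(); k <- 0L
  for (st in stages) for (f in seq_len(n_fov)) {
    k <- k + 1L
    scene <- generate_tissue_scene(st, n_adipocytes = n_adipocytes,
                                   n_macrophages = n_macrophages,
                                   frame = frame,
                                   seed = child_seed(seed, 3L * k))
    rec <- measure_scene_intensity(scene, optics,
                                   seed = child_seed(seed, 3L * k + 1L))
    rec <- add_flim_fits(rec, scene, acq, seed = child_seed(seed, 3L * k + 2L))
    rec$fov <- k; rec$group <- st
    agg <- fov_aggregate(rec, cells_per_point)
    a <- agg[agg$type == "adipocyte", ]
    m <- agg[agg$type == "macrophage", ]
    g <- function(df, col) if (nrow(df) == 1) df[[col]] else NA_real_
    rows[[k]] <- data.frame(
      OR1 = g(a, "redox_ratio"), OR2 = g(a, "a1"), OR3 = g(a, "t1"),
      OR4 = g(a, "t2"), OR5 = g(m, "redox_ratio"), OR6 = g(m, "a1"),
      OR7 = g(m, "t1"), OR8 = g(m, "t2"), OR9 = g(m, "mean_lipofuscin"),
      group = st, fov = k, n_cls = attr(rec, "n_cls"),
      stringsAsFactors = FALSE)
    all_cells[[k]] <- rec
  }
  readouts <- do.call(rbind, rows)
  # express lipofuscin relative to the control-group field mean
  ctrl <- readouts$OR9[readouts$group == "control"]
  if (length(ctrl) > 0 && mean(ctrl, na.rm = TRUE) > 0)
    readouts$OR9 <- readouts$OR9 / mean(ctrl, na.rm = TRUE)
  list(readouts = readouts, cells = do.call(rbind, all_cells))
}

#' Fit and evaluate a binary diagnostic model between two groups
#'
#' Multivariable logistic regression on the chosen readouts (the integrated
#' diagnostic score is the fitted disease probability), with resubstitution
#' and leave-one-out cross-validated accuracies at cutoff 0.5 and the ROC /
#' AUC / Youden operating point of the fitted probabilities.
#'
#' @param readouts A readout table (from [simulate_study()] or
#'   [readout_truth_table()]).
#' @param group_a,group_b Group labels; `group_b` is the positive class.
#' @param features Readout columns to use.
#' @return A list: `model` (`logistic_model`), `accuracy`
#'   ([loocv_accuracy()] result), `roc` (resubstitution probabilities),
#'   `roc_cv` (ROC of the cross-validated probabilities, free of
#'   resubstitution optimism), `groups`, `features`, `n`.
#' @export
diagnose_groups <- function(readouts, group_a = "control",
                            group_b = "prediabetic",
                            features = c("OR1", "OR2", "OR4")) {
  sub <- readouts[readouts$group %in% c(group_a, group_b), , drop = FALSE]
  sub <- sub[stats::complete.cases(sub[features]), , drop = FALSE]
  y <- as.integer(sub$group == group_b)
  model <- suppressWarnings(logistic_fit(sub[features], y))
  acc <- suppressWarnings(loocv_accuracy(sub[features], y))
  roc <- roc_auc(model$fitted_prob, y)
  roc_cv <- roc_auc(acc$probabilities, y)
  list(model = model, accuracy = acc, roc = roc, roc_cv = roc_cv,
       groups = c(group_a, group_b), features = features, n = nrow(sub))
}
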