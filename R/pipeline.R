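#' Pipeline configuration
#'
#' Fully serializable configuration for [run_pipeline()]. Every run writes
#' the resolved configuration alongside its outputs.
#'
#' @param out_dir Output (run) directory.
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_fov Fields of view per group.
#' @param frame Scene/optics frame in pixels.
#' @param stages Stages to run, a subset of `simulate`, `segment`, `redox`,
#'   `flim_fit`, `readouts`, `diagnose`, `report` (run in pipeline order).
#' @param n_adipocytes,n_macrophages Per-scene cell counts.
#' @param adipocyte_features,macrophage_features Readout columns used in the
#'   diagnostic models.
#' @param cells_per_point Cells averaged per field data point.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("adipoflim_run_"), seed = 1,
                            n_fov = 10, frame = 256,
                            stages = c("simulate", "segment", "redox",
                                       "flim_fit", "readouts", "diagnose",
                                       "report"),
                            n_adipocytes = 8, n_macrophages = 10,
                            adipocyte_features = c("OR1", "OR2", "OR4"),
                            macrophage_features = c("OR5", "OR6", "OR8", "OR9"),
                            cells_per_point = 10) {
  order <- c("simulate", "segment", "redox", "flim_fit", "readouts",
             "diagnose", "report")
  bad <- setdiff(stages, order)
  if (length(bad) > 0)
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  structure(list(out_dir = out_dir, seed = seed, n_fov = n_fov, frame = frame,
                 stages = order[order %in% stages],
                 n_adipocytes = n_adipocytes, n_macrophages = n_macrophages,
                 adipocyte_features = adipocyte_features,
                 macrophage_features = macrophage_features,
                 cells_per_point = cells_per_point),
            class = "pipeline_config")
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the end-to-end pipeline
#'
#' Executes the stage chain simulate -> segment -> redox -> flim_fit ->
#' readouts -> diagnose -> report, writing every stage's outputs (CSV/JSON,
#' plus RDS for the scene intermediates) into the run directory together
#' with the resolved configuration and a machine-readable manifest. Runs are
#' idempotent given the seed. A stage failure aborts with a stage-named
#' error after writing the manifest of completed outputs.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with `out_dir`, `manifest`, and the in-memory
#'   stage products that were computed.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE)
  manifest <- list(config = "config.json")
  state <- new.env(parent = emptyenv())
  stages_all <- c("control", "prediabetic", "diabetic")

  path_of <- function(f) file.path(config$out_dir, f)
  need <- function(file, what) {
    p <- path_of(file)
    if (!file.exists(p))
      stop(sprintf("%s requires %s from an earlier stage", what, file),
           call. = FALSE)
    p
  }
  save_manifest <- function() jsonlite::write_json(
    manifest, path_of("manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  stage_fns <- list(
    simulate = function() {
      cohort <- simulate_cohort(cohort_config(seed = config$seed))
      manifest$cohort <<- basename(write_csv_plain(cohort, path_of("cohort.csv")))
      k <- 0L
      scenes <- list()
      for (st in stages_all) for (f in seq_len(config$n_fov)) {
        k <- k + 1L
        scenes[[k]] <- generate_tissue_scene(
          st, n_adipocytes = config$n_adipocytes,
          n_macrophages = config$n_macrophages, frame = config$frame,
          seed = child_seed(config$seed, 3L * k))
      }
      saveRDS(scenes, path_of("scenes.rds"))
      manifest$scenes <<- "scenes.rds"
      manifest$truth_readouts <<- basename(write_csv_plain(
        readout_truth_table(scenes), path_of("truth_readouts.csv")))
      state$scenes <- scenes
    },
    segment = function() {
      scenes <- state$scenes %||% readRDS(need("scenes.rds", "segment"))
      optics <- optics_config(frame = config$frame)
      recs <- list()
      for (k in seq_along(scenes)) {
        rec <- measure_scene_intensity(scenes[[k]], optics,
                                       seed = child_seed(config$seed, 3L * k + 1L))
        rec$fov <- k
        rec$group <- scenes[[k]]$stage
        rec$n_cls <- attr(rec, "n_cls")
        recs[[k]] <- rec
      }
      cells <- do.call(rbind, recs)
      manifest$cells_intensity <<- basename(write_csv_plain(
        cells, path_of("cells_intensity.csv")))
      state$cells <- cells
    },
    redox = function() {
      cells <- state$cells %||%
        utils::read.csv(need("cells_intensity.csv", "redox"))
      ctrl <- cells$mean_lipofuscin[cells$group == "control" &
                                    cells$type == "macrophage"]
      norm <- if (length(ctrl) > 0) mean(ctrl) else 1
      cells <- relative_lipofuscin_intensity(cells, norm)
      manifest$cells_redox <<- basename(write_csv_plain(
        cells, path_of("cells_redox.csv")))
      state$cells <- cells
    },
    flim_fit = function() {
      cells <- state$cells %||% utils::read.csv(need("cells_redox.csv", "flim_fit"))
      scenes <- state$scenes %||% readRDS(need("scenes.rds", "flim_fit"))
      acq <- flim_acq_config()
      out <- list()
      for (k in sort(unique(cells$fov))) {
        sub <- cells[cells$fov == k, , drop = FALSE]
        out[[length(out) + 1L]] <- add_flim_fits(
          sub, scenes[[k]], acq, seed = child_seed(config$seed, 3L * k + 2L))
      }
      cells <- do.call(rbind, out)
      manifest$cells_flim <<- basename(write_csv_plain(
        cells, path_of("cells_flim.csv")))
      state$cells <- cells
    },
    readouts = function() {
      cells <- state$cells %||% utils::read.csv(need("cells_flim.csv", "readouts"))
      rows <- lapply(sort(unique(cells$fov)), function(k) {
        sub <- cells[cells$fov == k, , drop = FALSE]
        agg <- fov_aggregate(sub, config$cells_per_point)
        a <- agg[agg$type == "adipocyte", ]; m <- agg[agg$type == "macrophage", ]
        g <- function(df, col) if (nrow(df) == 1) df[[col]] else NA_real_
        data.frame(OR1 = g(a, "redox_ratio"), OR2 = g(a, "a1"),
                   OR3 = g(a, "t1"), OR4 = g(a, "t2"),
                   OR5 = g(m, "redox_ratio"), OR6 = g(m, "a1"),
                   OR7 = g(m, "t1"), OR8 = g(m, "t2"),
                   OR9 = g(m, "lipofuscin_rel"), group = sub$group[1],
                   fov = k, n_cls = sub$n_cls[1], stringsAsFactors = FALSE)
      })
      readouts <- do.call(rbind, rows)
      manifest$readouts <<- basename(write_csv_plain(
        readouts, path_of("readouts.csv")))
      state$readouts <- readouts
    },
    diagnose = function() {
      ro <- state$readouts %||% utils::read.csv(need("readouts.csv", "diagnose"))
      zs <- zscore_table(ro, reference = "control")
      manifest$zscores <<- basename(write_csv_plain(zs$z, path_of("zscores.csv")))
      manifest$z_heat <<- basename(write_csv_plain(
        data.frame(group = rownames(zs$heat), zs$heat), path_of("z_heat.csv")))
      pca <- pca_fit(ro[stats::complete.cases(ro[readout_columns(ro)]), ])
      jsonlite::write_json(list(loadings = as.data.frame(pca$loadings),
                                prop_var = pca$prop_var),
                           path_of("pca.json"), auto_unbox = TRUE, digits = NA)
      manifest$pca <<- "pca.json"
      diags <- list(
        control_vs_prediabetic = diagnose_groups(
          ro, "control", "prediabetic", config$adipocyte_features),
        control_vs_diabetic = diagnose_groups(
          ro, "control", "diabetic",
          union(config$adipocyte_features, config$macrophage_features)))
      models <- lapply(diags, function(d) list(
        groups = d$groups, features = d$features, n = d$n,
        coefficients = as.list(d$model$coefficients),
        odds_ratios = as.list(d$model$or),
        auc = d$roc$auc, sensitivity = d$roc$sensitivity,
        specificity = d$roc$specificity,
        youden_threshold = d$roc$youden_threshold,
        accuracy_resubstitution = d$accuracy$resubstitution,
        accuracy_loocv = d$accuracy$loocv))
      jsonlite::write_json(models, path_of("models.json"), auto_unbox = TRUE,
                           digits = NA)
      manifest$models <<- "models.json"
      roc_rows <- do.call(rbind, lapply(names(diags), function(nm)
        cbind(contrast = nm, diags[[nm]]$roc$curve)))
      manifest$roc <<- basename(write_csv_plain(roc_rows, path_of("roc.csv")))
      state$models <- models
    },
    report = function() {
      models <- state$models %||%
        jsonlite::read_json(need("models.json", "report"), simplifyVector = FALSE)
      report <- list(
        seed = config$seed, n_fov_per_group = config$n_fov,
        frame = config$frame,
        auc = lapply(models, function(m) m$auc),
        accuracy_loocv = lapply(models, function(m) m$accuracy_loocv))
      jsonlite::write_json(report, path_of("report.json"), auto_unbox = TRUE,
                           digits = NA)
      manifest$report <<- "report.json"
    })

  for (st in config$stages) {
    res <- tryCatch(stage_fns[[st]](), error = function(e) e)
    if (inherits(res, "error")) {
      save_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", st,
                   conditionMessage(res)), call. = FALSE)
    }
  }
  save_manifest()
  invisible(list(out_dir = config$out_dir, manifest = manifest,
                 readouts = state$readouts, models = state$models))
}
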