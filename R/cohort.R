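#' Configure a simulated diet-induced diabetes mouse cohort
#'
#' Builds the parameter set for [simulate_cohort()]. The default values emulate
#' a C57BL/6 study design in which mice are fed normal chow (control), a
#' high-fat diet (HFD) or a high-fat-high-sucrose diet (HFHSD) for 16 weeks,
#' develop insulin resistance (elevated HOMA-IR relative to control) by week 5
#' and diabetic hyperglycemia (fasting glucose above 13 mmol/L in the diet
#' groups) by week 16.
#'
#' Group effects are additive weekly drifts on fasting glucose, fasting insulin
#' and body weight; a mouse's value at week `w` is
#' `baseline + drift * w + noise`. Setting every drift to zero yields three
#' statistically indistinguishable groups.
#'
#' @param n_per_group Mice per group (default 8, at least 2).
#' @param groups Character vector of group names; the first is the reference.
#' @param weeks Number of follow-up weeks (week 0 is baseline).
#' @param ir_onset_week Week from which diet-group mean HOMA-IR is expected to
#'   exceed control (default 5).
#' @param hyperglycemia_week Week at which diet-group mean fasting glucose is
#'   expected to exceed 13 mmol/L (default 16).
#' @param glucose_baseline_mean,glucose_baseline_sd Fasting glucose baseline,
#'   mmol/L.
#' @param insulin_baseline_mean,insulin_baseline_sd Fasting insulin baseline,
#'   uU/mL.
#' @param weight_baseline_mean,weight_baseline_sd Body weight baseline, g.
#' @param glucose_drift,insulin_drift,weight_drift Named numeric vectors of
#'   additive per-week drifts, one entry per group.
#' @param glucose_noise_sd,insulin_noise_sd,weight_noise_sd Week-to-week
#'   measurement noise standard deviations.
#' @param seed Integer seed used by [simulate_cohort()] when none is passed
#'   there.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 8,
                          groups = c("control", "HFD", "HFHSD"),
                          weeks = 16,
                          ir_onset_week = 5,
                          hyperglycemia_week = 16,
                          glucose_baseline_mean = 5.5,
                          glucose_baseline_sd = 0.4,
                          insulin_baseline_mean = 10,
                          insulin_baseline_sd = 1.5,
                          weight_baseline_mean = 22,
                          weight_baseline_sd = 1.2,
                          glucose_drift = c(control = 0.02, HFD = 0.58, HFHSD = 0.52),
                          insulin_drift = c(control = 0.05, HFD = 1.3, HFHSD = 1.15),
                          weight_drift = c(control = 0.25, HFD = 0.95, HFHSD = 0.9),
                          glucose_noise_sd = 0.35,
                          insulin_noise_sd = 1.2,
                          weight_noise_sd = 0.5,
                          seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  if (weeks < 1) stop("weeks must be >= 1", call. = FALSE)
  if (weeks < ir_onset_week)
    stop("weeks must be >= ir_onset_week", call. = FALSE)
  groups <- as.character(groups)
  if (anyDuplicated(groups)) stop("duplicate group names", call. = FALSE)
  for (d in list(glucose_drift, insulin_drift, weight_drift))
    if (!all(groups %in% names(d)))
      stop("each drift vector needs one named entry per group", call. = FALSE)
  sds <- c(glucose_baseline_sd, insulin_baseline_sd, weight_baseline_sd,
           glucose_noise_sd, insulin_noise_sd, weight_noise_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  structure(list(
    n_per_group = as.integer(n_per_group), groups = groups,
    weeks = as.integer(weeks), ir_onset_week = as.integer(ir_onset_week),
    hyperglycemia_week = as.integer(hyperglycemia_week),
    glucose_baseline_mean = glucose_baseline_mean,
    glucose_baseline_sd = glucose_baseline_sd,
    insulin_baseline_mean = insulin_baseline_mean,
    insulin_baseline_sd = insulin_baseline_sd,
    weight_baseline_mean = weight_baseline_mean,
    weight_baseline_sd = weight_baseline_sd,
    glucose_drift = glucose_drift, insulin_drift = insulin_drift,
    weight_drift = weight_drift,
    glucose_noise_sd = glucose_noise_sd, insulin_noise_sd = insulin_noise_sd,
    weight_noise_sd = weight_noise_sd, seed = seed
  ), class = "cohort_config")
}

#' Simulate a longitudinal diet-induced diabetes cohort
#'
#' Draws per-mouse baselines and weekly measurements of body weight, fasting
#' glucose (FPG, mmol/L) and fasting insulin (FINS, uU/mL) under the group
#' trajectories in `config`, and derives HOMA-IR = FPG x FINS / 22.5 for every
#' observation. Output is deterministic for a given seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A data.frame with one row per mouse per week: `id`, `group`,
#'   `week`, `body_weight`, `fasting_glucose`, `fasting_insulin`, `homa_ir`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(seed, {
    rows <- vector("list", length(config$groups))
    mouse_no <- 0L
    for (g in config$groups) {
      n <- config$n_per_group
      base_g <- pmax(0, rnorm(n, config$glucose_baseline_mean, config$glucose_baseline_sd))
      base_i <- pmax(0, rnorm(n, config$insulin_baseline_mean, config$insulin_baseline_sd))
      base_w <- pmax(0, rnorm(n, config$weight_baseline_mean, config$weight_baseline_sd))
      weeks <- 0:config$weeks
      per_mouse <- lapply(seq_len(n), function(i) {
        gl <- pmax(0, base_g[i] + config$glucose_drift[[g]] * weeks +
                     rnorm(length(weeks), 0, config$glucose_noise_sd))
        ins <- pmax(0, base_i[i] + config$insulin_drift[[g]] * weeks +
                      rnorm(length(weeks), 0, config$insulin_noise_sd))
        wt <- pmax(0, base_w[i] + config$weight_drift[[g]] * weeks +
                     rnorm(length(weeks), 0, config$weight_noise_sd))
        data.frame(id = sprintf("%s_%02d", g, i), group = g, week = weeks,
                   body_weight = wt, fasting_glucose = gl,
                   fasting_insulin = ins, stringsAsFactors = FALSE)
      })
      mouse_no <- mouse_no + n
      rows[[match(g, config$groups)]] <- do.call(rbind, per_mouse)
    }
    out <- do.call(rbind, rows)
    out$homa_ir <- homa_ir(out$fasting_glucose, out$fasting_insulin)
    rownames(out) <- NULL
    out
  })
}
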