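#' Homeostasis-model insulin-resistance index
#'
#' `HOMA-IR = FPG (mmol/L) x FINS (uU/mL) / 22.5`.
#'
#' @param fpg Fasting plasma glucose, mmol/L (>= 0).
#' @param fins Fasting insulin, uU/mL (>= 0).
#' @return The HOMA-IR index (vectorized).
#' @export
homa_ir <- function(fpg, fins) {
  if (any(fpg < 0) || any(fins < 0))
    stop("glucose and insulin must be non-negative", call. = FALSE)
  fpg * fins / 22.5
}

#' Bulk biochemical redox ratio
#'
#' `NAD(P)+ / (NAD(P)H + NAD(P)+)` from bulk-tissue coenzyme measurements.
#'
#' @param nad_plus,nadh Non-negative amounts, not both zero.
#' @return Ratio in \[0, 1\].
#' @export
bulk_redox_ratio <- function(nad_plus, nadh) {
  if (any(nad_plus < 0) || any(nadh < 0))
    stop("amounts must be non-negative", call. = FALSE)
  if (any(nad_plus + nadh == 0))
    stop("ratio undefined: both amounts are zero", call. = FALSE)
  nad_plus / (nadh + nad_plus)
}

#' Derived bioenergetic metrics from an extracellular-flux trace
#'
#' For an OCR (mito stress) trace with epochs baseline, oligomycin, FCCP and
#' Rot/AA: basal respiration = baseline - Rot/AA; ATP production = baseline -
#' oligomycin; maximal respiration = FCCP - Rot/AA. For an ECAR (glycolysis
#' stress) trace with epochs baseline, glucose, oligomycin, 2-DG: glycolysis
#' = rate after glucose; glycolytic capacity = rate after oligomycin;
#' glycolytic reserve = oligomycin - glucose. Epoch rates are the mean rate
#' within the epoch.
#'
#' @param trace A data.frame with columns `epoch` and `rate`.
#' @param kind `"OCR"` or `"ECAR"`.
#' @return A named list of derived metrics.
#' @export
seahorse_metrics <- function(trace, kind = c("OCR", "ECAR")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(trace), all(c("epoch", "rate") %in% names(trace)))
  need <- if (kind == "OCR") c("baseline", "oligomycin", "FCCP", "rot_aa")
          else c("baseline", "glucose", "oligomycin", "2-DG")
  missing_ep <- setdiff(need, unique(trace$epoch))
  if (length(missing_ep) > 0)
    stop(sprintf("missing epoch(s): %s", paste(missing_ep, collapse = ", ")),
         call. = FALSE)
  ep <- vapply(need, function(e) mean(trace$rate[trace$epoch == e]), 0)
  if (kind == "OCR")
    list(basal_respiration = ep[["baseline"]] - ep[["rot_aa"]],
         atp_production = ep[["baseline"]] - ep[["oligomycin"]],
         maximal_respiration = ep[["FCCP"]] - ep[["rot_aa"]])
  else
    list(glycolysis = ep[["glucose"]],
         glycolytic_capacity = ep[["oligomycin"]],
         glycolytic_reserve = ep[["oligomycin"]] - ep[["glucose"]])
}

readout_columns <- function(table) {
  grep("^OR[0-9]+$", names(table), value = TRUE)
}

#' Z-score a readout table against a reference group
#'
#' Each readout column is centred and scaled by the mean and standard
#' deviation of the reference group, giving the per-row Z-scores and the
#' per-group mean Z values used for heatmaps. Columns with zero reference SD
#' are flagged and returned as NA rather than silently dropped. The stored
#' `center`/`scale` make the transform invertible.
#'
#' @param table A readout table with columns `OR1..OR9` (any `OR<k>` set
#'   works) and `group`.
#' @param reference Name of the reference group (default `"control"`).
#' @return A list: `z` (Z-scored table with `group`), `heat` (group x readout
#'   matrix of mean Z), `center`, `scale`, `flagged` (zero-SD columns),
#'   `reference`.
#' @export
zscore_table <- function(table, reference = "control") {
  cols <- readout_columns(table)
  if (length(cols) == 0) stop("no OR columns found", call. = FALSE)
  if (!reference %in% table$group)
    stop(sprintf("reference group '%s' not present", reference), call. = FALSE)
  ref <- table[table$group == reference, cols, drop = FALSE]
  if (nrow(ref) < 2) stop("reference group needs >= 2 rows", call. = FALSE)
  center <- vapply(ref, mean, 0)
  scale <- vapply(ref, stats::sd, 0)
  flagged <- names(scale)[scale == 0]
  z <- table[cols]
  for (cn in cols)
    z[[cn]] <- if (scale[[cn]] == 0) NA_real_ else
      (table[[cn]] - center[[cn]]) / scale[[cn]]
  z$group <- table$group
  groups <- unique(table$group)
  heat <- matrix(NA_real_, length(groups), length(cols),
                 dimnames = list(groups, cols))
  for (g in groups) for (cn in cols)
    heat[g, cn] <- mean(z[[cn]][z$group == g])
  list(z = z, heat = heat, center = center, scale = scale,
       flagged = flagged, reference = reference)
}

#' Invert a Z-scored table
#' @param z Z-scored data (columns as in the `z` element of
#'   [zscore_table()]).
#' @param zs The [zscore_table()] result holding `center` and `scale`.
#' @return The table on the original scale.
#' @export
unzscore_table <- function(z, zs) {
  cols <- names(zs$center)
  out <- z[cols]
  for (cn in cols) out[[cn]] <- z[[cn]] * zs$scale[[cn]] + zs$center[[cn]]
  if ("group" %in% names(z)) out$group <- z$group
  out
}

#' Binomial logistic regression with odds ratios
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' [stats::glm()]) of a binary outcome on one or more features, reporting
#' per-variable odds ratios `exp(beta)`, Wald 95% confidence intervals and
#' p-values. Complete separation is detected (diverging coefficients or
#' saturated fitted probabilities), flagged, and the coefficients are capped
#' rather than returned infinite.
#'
#' @param features A data.frame or matrix of numeric predictors.
#' @param labels Binary outcome: logical, 0/1, or a two-level factor (second
#'   level = positive).
#' @param max_iter,tol IRLS control.
#' @param coef_cap Absolute cap applied to coefficients when separation is
#'   flagged.
#' @return A `logistic_model`: `coefficients` (incl. intercept), `or`, `ci`
#'   (2-column), `p`, `fitted_prob`, `fitted_class`, `separation`.
#' @export
logistic_fit <- function(features, labels, max_iter = 100, tol = 1e-10,
                         coef_cap = 15) {
  features <- as.data.frame(features)
  if (ncol(features) < 1) stop("need at least one feature", call. = FALSE)
  y <- to_binary(labels)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  df <- cbind(features, .y = y)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(maxit = max_iter, epsilon = tol)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (sep || any(abs(beta) > coef_cap)) {
    sep <- TRUE
    beta <- pmin(pmax(beta, -coef_cap), coef_cap)
    warning("possible complete separation: coefficients capped", call. = FALSE)
  }
  zval <- stats::coef(fit) / se
  p <- 2 * stats::pnorm(-abs(zval))
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  prob <- as.numeric(stats::predict(fit, type = "response"))
  structure(list(coefficients = beta, se = se, or = exp(beta), ci = ci,
                 p = p, fitted_prob = prob,
                 fitted_class = as.integer(prob >= 0.5),
                 separation = sep, glm = fit, n = length(y)),
            class = "logistic_model")
}

to_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have two levels", call. = FALSE)
    return(as.integer(labels == levels(labels)[2]))
  }
  if (is.character(labels)) return(to_binary(factor(labels)))
  if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
  as.integer(labels)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("logistic_model (n=%d%s)\n", x$n,
              if (x$separation) ", separation flagged" else ""))
  tab <- data.frame(beta = x$coefficients, OR = x$or, lower = x$ci[, 1],
                    upper = x$ci[, 2], p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Univariate logistic screen of readout columns
#'
#' One single-feature logistic fit per readout column, reporting the odds
#' ratio, Wald 95% CI and p-value, flagging columns with p < `alpha`. Raw
#' p-values drive the screen; a Benjamini-Hochberg adjusted column is
#' reported alongside. A degenerate column (e.g. constant) errors only for
#' that column, recorded in `error`, and leaves the others unaffected.
#'
#' @param table Readout table (columns `OR<k>`) or any numeric data.frame.
#' @param labels Binary outcome as in [logistic_fit()].
#' @param alpha Screening level (default 0.05).
#' @return A data.frame with one row per readout: `readout`, `or`, `ci_lo`,
#'   `ci_hi`, `p`, `p_bh`, `flagged`, `error`.
#' @export
univariate_screen <- function(table, labels, alpha = 0.05) {
  cols <- readout_columns(table)
  if (length(cols) == 0)
    cols <- names(table)[vapply(table, is.numeric, TRUE)]
  rows <- lapply(cols, function(cn) {
    res <- tryCatch({
      m <- suppressWarnings(logistic_fit(table[cn], labels))
      data.frame(readout = cn, or = m$or[[2]], ci_lo = m$ci[2, 1],
                 ci_hi = m$ci[2, 2], p = m$p[[2]], error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(readout = cn, or = NA_real_, ci_lo = NA_real_,
                 ci_hi = NA_real_, p = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- !is.na(out$p) & out$p < alpha
  out[c("readout", "or", "ci_lo", "ci_hi", "p", "p_bh", "flagged", "error")]
}

#' Resubstitution and leave-one-out cross-validated accuracy
#'
#' Fits a logistic model on all rows (resubstitution accuracy at probability
#' cutoff 0.5) and then refits with each row left out in turn, predicting the
#' held-out row (LOOCV accuracy). A fold whose training set loses one class
#' entirely is flagged and predicted with the training majority class.
#'
#' @param features Numeric data.frame or matrix.
#' @param labels Binary outcome.
#' @param threshold Probability cutoff (default 0.5).
#' @return A list: `resubstitution`, `loocv`, `predictions` (LOOCV class per
#'   row), `probabilities` (LOOCV predicted probability per row),
#'   `flagged_folds`.
#' @export
loocv_accuracy <- function(features, labels, threshold = 0.5) {
  features <- as.data.frame(features)
  y <- to_binary(labels)
  n <- length(y)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  full <- suppressWarnings(logistic_fit(features, y))
  resub <- mean(as.integer(full$fitted_prob >= threshold) == y)
  preds <- integer(n)
  probs <- numeric(n)
  flagged <- integer(0)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      flagged <- c(flagged, i)
      probs[i] <- mean(ytr)
      preds[i] <- as.integer(probs[i] >= 0.5)
      next
    }
    m <- suppressWarnings(logistic_fit(features[-i, , drop = FALSE], ytr))
    pr <- suppressWarnings(
      stats::predict(m$glm, newdata = features[i, , drop = FALSE],
                     type = "response"))
    probs[i] <- pr
    preds[i] <- as.integer(pr >= threshold)
  }
  list(resubstitution = resub, loocv = mean(preds == y),
       predictions = preds, probabilities = probs, flagged_folds = flagged)
}

#' ROC curve, AUC and Youden-optimal operating point
#'
#' Sweeps all distinct score thresholds (predicting positive for scores at or
#' above the threshold), traces the (FPR, TPR) curve from (0,0) to (1,1),
#' integrates the AUC by the trapezoid rule (tied scores contribute the
#' averaged diagonal step, so the AUC equals the normalized Mann-Whitney U
#' statistic), and reports the threshold maximizing Youden's
#' J = sensitivity + specificity - 1.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary outcome.
#' @return A `roc_result`: `curve` (data.frame `threshold`, `fpr`, `tpr`),
#'   `auc`, `youden_threshold`, `sensitivity`, `specificity`.
#' @export
roc_auc <- function(scores, labels) {
  y <- to_binary(labels)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n_neg, 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1)
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  j <- curve$tpr - curve$fpr
  best <- which.max(j)
  structure(list(curve = curve, auc = auc,
                 youden_threshold = curve$threshold[best],
                 sensitivity = curve$tpr[best],
                 specificity = 1 - curve$fpr[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC=%.3f, Youden threshold=%.4g (sens=%.2f, spec=%.2f)\n",
              x$auc, x$youden_threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Principal component analysis of a readout table
#'
#' PCA of the (by default) column-standardized data, treating each optical
#' readout as an independent dimension. Loadings are unit-norm with the sign
#' convention that each component's largest-magnitude entry is positive;
#' per-component proportion of variance is reported.
#'
#' @param table Numeric data.frame/matrix, or a readout table (OR columns
#'   are used and `group` ignored).
#' @param n_components Number of components to return.
#' @param standardize Z-score columns before decomposition (default TRUE).
#' @return A `pca_result`: `loadings` (columns PC1..), `prop_var`, `scores`,
#'   `center`, `scale`.
#' @export
pca_fit <- function(table, n_components = 2, standardize = TRUE) {
  cols <- readout_columns(as.data.frame(table))
  x <- if (length(cols) > 0) as.matrix(as.data.frame(table)[cols])
       else as.matrix(table)
  if (any(apply(x, 2, stats::sd) == 0))
    stop("zero-variance column", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  k <- min(n_components, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- scale(x, center = pc$center,
                  scale = if (standardize) pc$scale else FALSE) %*% load
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = load, prop_var = prop[seq_len(k)],
                 scores = scores, center = pc$center,
                 scale = if (standardize) pc$scale else NULL,
                 all_prop_var = prop), class = "pca_result")
}

#' Compare groups by t-test or one-way ANOVA with Tukey post hoc
#'
#' Two groups: two-sided unpaired Student's t-test (equal variances). Three
#' or more: one-way ANOVA followed by Tukey's honest significant differences.
#' Significance level 0.05.
#'
#' @param values Numeric response.
#' @param groups Group labels (length matching `values`).
#' @return A list: `method`, `p` (overall), `statistic`, and for ANOVA a
#'   `tukey` data.frame of pairwise comparisons.
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs >= 2 values", call. = FALSE)
  if (nlevels(groups) == 2) {
    tt <- stats::t.test(values ~ groups, var.equal = TRUE)
    list(method = "t-test", p = tt$p.value, statistic = unname(tt$statistic),
         df = unname(tt$parameter), estimate = diff(rev(tt$estimate)))
  } else {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    list(method = "anova+tukey", p = an[["Pr(>F)"]][1],
         statistic = an[["F value"]][1],
         df = c(an[["Df"]][1], an[["Df"]][2]),
         tukey = data.frame(comparison = rownames(tk), tk, row.names = NULL))
  }
}
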