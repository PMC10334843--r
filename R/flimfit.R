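#' Fit the IRF-convolved two-component decay model to one histogram
#'
#' Weighted least squares (Neyman weights `1/max(obs, 1)`, the TCSPC
#' convention) by Levenberg-Marquardt over `(a1, t1, t2, scale)`, with the
#' lifetime ordering `t1 < t2` enforced by the box constraints
#' `t1 in (0.05, 1]` ns and `t2 in (1, 6]` ns. A Poisson maximum-likelihood
#' objective (deviance) is available via `objective = "mle"`. Histograms with
#' fewer than `min_counts` photons are refused; non-convergence is reported
#' via the `converged` flag, not an error.
#'
#' @param hist A `decay_histogram` ([simulate_decay()]) or a numeric count
#'   vector (then `irf` must be given).
#' @param irf IRF to use when `hist` is a bare vector.
#' @param init Named start values for `a1`, `t1`, `t2` (ns).
#' @param lower,upper Box constraints for `(a1, t1, t2)`.
#' @param min_counts Photon-count floor below which the fit is refused.
#' @param objective `"wls"` (default) or `"mle"`.
#' @return A `flim_fit`: `a1`, `a2 = 1 - a1` (exactly), `t1`, `t2`, `scale`,
#'   `chi2r` (reduced chi-square), `converged`, `n_photons`.
#' @export
fit_decay <- function(hist, irf = NULL,
                      init = c(a1 = 0.7, t1 = 0.4, t2 = 2.5),
                      lower = c(a1 = 0, t1 = 0.05, t2 = 1),
                      upper = c(a1 = 1, t1 = 1, t2 = 6),
                      min_counts = 200, objective = c("wls", "mle")) {
  objective <- match.arg(objective)
  if (inherits(hist, "decay_histogram")) {
    counts <- hist$counts; irf <- hist$irf
  } else counts <- as.numeric(hist)
  if (is.null(irf)) stop("an IRF is required", call. = FALSE)
  n_photons <- sum(counts)
  if (n_photons < min_counts)
    stop(sprintf("total counts (%d) below min_counts (%d); fit refused",
                 round(n_photons), min_counts), call. = FALSE)
  par0 <- c(init[["a1"]], init[["t1"]], init[["t2"]], n_photons)
  lo <- c(lower[["a1"]], lower[["t1"]], lower[["t2"]], 1e-6)
  hi <- c(upper[["a1"]], upper[["t1"]], upper[["t2"]], Inf)
  model_of <- function(p) model_decay(p[1], p[2], p[3], scale = p[4], irf = irf)

  if (objective == "wls") {
    w <- 1 / sqrt(pmax(counts, 1))
    fit <- minpack.lm::nls.lm(
      par = par0, lower = lo, upper = hi,
      fn = function(p) (model_of(p) - counts) * w,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    par <- fit$par
    converged <- fit$info %in% 1:4
  } else {
    dev <- function(p) {
      lam <- pmax(model_of(p), 1e-12)
      2 * sum(lam - counts + ifelse(counts > 0, counts * log(counts / lam), 0))
    }
    fit <- stats::optim(par0, dev, method = "L-BFGS-B", lower = lo,
                        upper = pmin(hi, c(1, 1, 6, 1e12)),
                        control = list(maxit = 500))
    par <- fit$par
    converged <- fit$convergence == 0
  }
  expected <- model_of(par)
  chi2r <- tryCatch(reduced_chi2(counts, expected, n_params = 4),
                    error = function(e) NA_real_)
  structure(list(a1 = par[1], a2 = 1 - par[1], t1 = par[2], t2 = par[3],
                 scale = par[4], chi2r = chi2r, converged = converged,
                 n_photons = n_photons, objective = objective),
            class = "flim_fit")
}

#' @export
print.flim_fit <- function(x, ...) {
  cat(sprintf("flim_fit: a1=%.3f a2=%.3f t1=%.3f ns t2=%.3f ns chi2r=%.2f%s\n",
              x$a1, x$a2, x$t1, x$t2, x$chi2r,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Amplitude-weighted mean lifetime of a fit
#' @param fit A `flim_fit`.
#' @return `a1 * t1 + a2 * t2` in nanoseconds.
#' @export
mean_lifetime <- function(fit) fit$a1 * fit$t1 + fit$a2 * fit$t2

#' Reduced chi-square of an observed versus expected histogram
#'
#' Pearson statistic `sum((obs - exp)^2 / max(exp, eps))` over bins whose
#' expected count reaches `count_floor`, divided by the degrees of freedom
#' `n_used - n_params`.
#'
#' @param observed,expected Count vectors on the same grid.
#' @param n_params Number of fitted parameters.
#' @param count_floor Bins with expected counts below this are excluded.
#' @param eps Denominator guard.
#' @return The reduced chi-square (>= 0).
#' @export
reduced_chi2 <- function(observed, expected, n_params, count_floor = 1,
                         eps = 1e-12) {
  if (length(observed) != length(expected))
    stop("observed and expected must share a grid", call. = FALSE)
  use <- expected >= count_floor
  dof <- sum(use) - n_params
  if (dof <= 0) stop("non-positive degrees of freedom", call. = FALSE)
  sum((observed[use] - expected[use])^2 / pmax(expected[use], eps)) / dof
}

#' Fit the decay model across a FLIM frame
#'
#' Optionally aggregates the decay image over non-overlapping `binning` x
#' `binning` pixel blocks (raising per-fit photon counts), fits every block
#' whose total count reaches `min_counts`, and writes the fitted parameters
#' back to all pixels of the block. Below-threshold blocks are left missing
#' (NA).
#'
#' @param dimg A `decay_image` ([render_flim_frame()]).
#' @param binning Spatial binning factor (1 = per pixel).
#' @param init Start values passed to [fit_decay()].
#' @param min_counts Photon floor per fitted block.
#' @param objective Passed to [fit_decay()].
#' @return A list of matrices `a1`, `t1`, `t2`, `chi2r`, `converged` in the
#'   frame geometry, plus `n_fitted`.
#' @export
fit_flim_image <- function(dimg, binning = 1,
                           init = c(a1 = 0.7, t1 = 0.4, t2 = 2.5),
                           min_counts = NULL, objective = "wls") {
  stopifnot(inherits(dimg, "decay_image"))
  if (is.null(min_counts))
    min_counts <- dimg$acq$min_counts %||% 200
  nf <- dimg$frame; nb <- dim(dimg$counts)[3]
  if (nf == 0 || nb == 0) stop("empty decay image", call. = FALSE)
  b <- as.integer(binning)
  nby <- ceiling(nf / b); nbx <- ceiling(nf / b)
  blk_y <- (seq_len(nf) - 1L) %/% b + 1L
  blk_x <- blk_y
  maps <- lapply(1:5, function(i) matrix(NA_real_, nf, nf))
  names(maps) <- c("a1", "t1", "t2", "chi2r", "converged")
  n_fitted <- 0L
  for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
    ys <- which(blk_y == by); xs <- which(blk_x == bx)
    sub <- dimg$counts[ys, xs, , drop = FALSE]
    h <- apply(sub, 3, sum)
    if (sum(h) < min_counts) next
    f <- fit_decay(h, irf = dimg$irf, init = init, min_counts = min_counts,
                   objective = objective)
    n_fitted <- n_fitted + 1L
    maps$a1[ys, xs] <- f$a1; maps$t1[ys, xs] <- f$t1
    maps$t2[ys, xs] <- f$t2; maps$chi2r[ys, xs] <- f$chi2r
    maps$converged[ys, xs] <- as.numeric(f$converged)
  }
  c(maps, list(n_fitted = n_fitted, binning = b, min_counts = min_counts))
}

#' Pseudo-color rendering of fitted FLIM maps
#'
#' Clips each map to its configured display range and maps it through a
#' blue-green-yellow-red ramp; missing (unfitted) pixels render black. The
#' output is deterministic.
#'
#' @param maps Named list of numeric matrices (e.g. from
#'   [fit_flim_image()]).
#' @param ranges Named list of `c(min, max)` display ranges, one per map.
#' @param n_colors Number of ramp levels.
#' @return Named list of RGB arrays of dim (y, x, 3) with values in \[0, 1\].
#' @export
render_flim_maps <- function(maps, ranges, n_colors = 256) {
  ramp <- grDevices::colorRamp(c("#00007F", "#007FFF", "#00FF7F",
                                 "#FFFF00", "#FF0000"))
  out <- list()
  for (nm in names(ranges)) {
    m <- maps[[nm]]
    if (is.null(m)) stop(sprintf("no map named '%s'", nm), call. = FALSE)
    rg <- ranges[[nm]]
    if (rg[2] <= rg[1]) stop("inverted color range", call. = FALSE)
    v <- (pmin(pmax(m, rg[1]), rg[2]) - rg[1]) / (rg[2] - rg[1])
    miss <- is.na(v)
    v[miss] <- 0
    cols <- ramp(as.vector(v)) / 255
    rgb <- array(0, dim = c(nrow(m), ncol(m), 3))
    for (k in 1:3) {
      ch <- matrix(cols[, k], nrow(m), ncol(m))
      ch[miss] <- 0
      rgb[, , k] <- ch
    }
    out[[nm]] <- rgb
  }
  out
}
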