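#' Construct an assay curve
#'
#' @param kind `"decay"` (time in min vs residual activity %), `"t50"`
#'   (incubation temperature in C vs residual activity %), or `"melt"`
#'   (temperature in C vs 350/330 nm fluorescence ratio).
#' @param x,y Numeric vectors; `x` must be strictly increasing.
#' @param variant Variant label (metadata).
#' @param temperature Assay temperature in C for decay curves (metadata).
#' @return An `assay_curve` object.
#' @export
assay_curve <- function(kind = c("decay", "t50", "melt"), x, y,
                        variant = NA_character_, temperature = NA_real_) {
  kind <- match.arg(kind)
  if (length(x) != length(y))
    pc_error("x and y lengths differ", "validation_error")
  if (any(diff(x) <= 0))
    pc_error("x must be strictly increasing", "validation_error")
  if (length(x) < 4L)
    pc_error("need >= 4 points for any fit", "validation_error")
  if (kind %in% c("decay", "t50") && any(y > 120 | y < 0))
    pc_error("activity values must lie in [0, 120] percent", "validation_error")
  structure(list(kind = kind, x = as.numeric(x), y = as.numeric(y),
                 variant = variant, temperature = temperature),
            class = "assay_curve")
}

#' @export
print.assay_curve <- function(x, ...) {
  cat(sprintf("assay_curve (%s): %d points, x in [%g, %g]%s\n", x$kind,
              length(x$x), min(x$x), max(x$x),
              if (!is.na(x$variant)) paste0(", variant ", x$variant) else ""))
  invisible(x)
}

new_stability_result <- function(...) {
  structure(list(...), class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("stability_result:\n")
  for (nm in names(x)) if (is.numeric(x[[nm]]))
    cat(sprintf("  %s = %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Fit a first-order inactivation half-life
#'
#' Ordinary least squares of `ln(activity/100)` against incubation time over
#' the linear window; the half-life is `-ln(2)/k` with `k` the fitted slope.
#' The default window keeps points with activity at least `window_min_frac`
#' of the initial value, since near-zero activities dominate the noise in
#' log space; an explicit time window overrides it.
#'
#' @param curve A decay [assay_curve()].
#' @param window_min_frac Keep points with `y >= window_min_frac * y[1]`
#'   (default 0.05).
#' @param window Optional numeric `c(tmin, tmax)` explicit time window.
#' @return A `stability_result` with `k` (1/min), `t_half` (min), `fit_r2`,
#'   `n_used`.
#' @examples
#' cv <- assay_curve("decay", 0:6 * 10, 100 * exp(-0.0231 * 0:6 * 10))
#' fit_half_life(cv)$t_half  # 30.0
#' @export
fit_half_life <- function(curve, window_min_frac = 0.05, window = NULL) {
  stopifnot(inherits(curve, "assay_curve"), curve$kind == "decay")
  x <- curve$x; y <- curve$y
  if (any(y <= 0)) {
    pc_warning(sprintf("dropping %d points with activity <= 0", sum(y <= 0)),
               "data_warning")
    keep <- y > 0; x <- x[keep]; y <- y[keep]
  }
  if (!is.null(window)) {
    keep <- x >= window[1] & x <= window[2]
  } else {
    keep <- y >= window_min_frac * y[1]
  }
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L)
    pc_error("fewer than 4 usable points in the linear window", "validation_error")
  ly <- log(y / 100)
  fit <- stats::lm(ly ~ x)
  k <- unname(stats::coef(fit)[2])
  if (k >= 0)
    pc_error("non-negative slope: enzyme is not inactivating", "no_decay_error")
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
  new_stability_result(kind = "decay", k = k, t_half = -log(2) / k,
                       fit_r2 = r2, n_used = length(x), variant = curve$variant)
}

#' Fit T50 from a thermal-inactivation profile
#'
#' Nonlinear least squares of the Boltzmann sigmoid
#' `y(T) = A2 + (A1 - A2) / (1 + exp((T - T50)/dT))` to residual activity
#' versus incubation temperature. Activities are first normalized so the
#' lowest-temperature point reads 100%. T50 is the fitted inflection point:
#' the temperature at which a fixed-length incubation halves activity.
#'
#' @param curve A t50 [assay_curve()]. Must span both plateaus (normalized
#'   maximum > 80%, minimum < 20%).
#' @return A `stability_result` with `t50_15` (C), `dT` (C), `fit_r2`.
#' @export
fit_t50 <- function(curve) {
  stopifnot(inherits(curve, "assay_curve"), curve$kind == "t50")
  x <- curve$x
  y <- 100 * curve$y / curve$y[1]
  if (stats::cor(x, y) > 0)
    pc_error("activity rises with temperature; not an inactivation profile",
             "fit_error")
  if (max(y) <= 80 || min(y) >= 20)
    pc_error("curve does not span both plateaus (>80% and <20%)", "fit_error")
  start <- list(A1 = max(y), A2 = min(y),
                T50 = x[which.min(abs(y - (max(y) + min(y)) / 2))], dT = 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A2 + (A1 - A2) / (1 + exp((x - T50) / dT)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      cond <- errorCondition(paste0("Boltzmann fit failed: ",
                                    conditionMessage(e)),
                             class = c("fit_error", "phyloconsensus_error"))
      attr(cond, "residuals") <- y - mean(y)
      stop(cond)
    })
  co <- stats::coef(fit)
  resid <- stats::resid(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  new_stability_result(kind = "t50", t50_15 = unname(co["T50"]),
                       dT = unname(co["dT"]), fit_r2 = r2,
                       variant = curve$variant)
}

#' Fit a melting temperature from a nanoDSF ratio curve
#'
#' Least-squares polynomial fit (default degree 9) of the 350/330 nm
#' fluorescence ratio against temperature; Tm is the temperature of the
#' maximum of the fitted polynomial's first derivative, located by dense
#' evaluation on a fine grid. Because a single global polynomial cannot
#' track a sharp two-state transition across a full 20-95 C ramp, the
#' transition is first localized by the steepest finite-difference slope of
#' the (median-smoothed) raw signal and the polynomial is fitted within a
#' window around it (default +/- 15 C). A derivative maximum at a ramp
#' endpoint triggers a boundary warning (transition not captured).
#'
#' @param curve A melt [assay_curve()] with at least 20 points.
#' @param degree Polynomial degree (default 9).
#' @param grid_step Evaluation grid step in C (default 0.01).
#' @param window_halfwidth Half-width in C of the fitting window around the
#'   coarse transition estimate (default 15).
#' @return A `stability_result` with `tm` (C) and `fit_r2`.
#' @export
fit_tm <- function(curve, degree = 9, grid_step = 0.01, window_halfwidth = 15) {
  stopifnot(inherits(curve, "assay_curve"), curve$kind == "melt")
  x <- curve$x; y <- curve$y
  if (length(x) < 20L)
    pc_error("need >= 20 points across the thermal ramp", "validation_error")
  # coarse localization: steepest rise of the lightly smoothed raw signal
  ys <- stats::runmed(y, 3)
  slope0 <- diff(ys) / diff(x)
  t_coarse <- mean(x[which.max(slope0) + 0:1])
  lo <- max(min(x), t_coarse - window_halfwidth)
  hi <- min(max(x), t_coarse + window_halfwidth)
  keep <- x >= lo & x <= hi
  deg <- min(degree, sum(keep) - 2L)
  xw <- x[keep]; yw <- y[keep]
  fit <- stats::lm(yw ~ stats::poly(xw, deg))
  grid <- seq(min(xw), max(xw), by = grid_step)
  yy <- stats::predict(fit, newdata = data.frame(xw = grid))
  slope <- diff(yy) / grid_step
  imax <- which.max(slope)
  tm <- (grid[imax] + grid[imax + 1]) / 2
  # a genuine transition shows an interior, prominent derivative peak
  prominence <- slope[imax] - max(slope[1], slope[length(slope)])
  at_edge <- tm - min(x) < 2 * grid_step || max(x) - tm < 2 * grid_step
  if (at_edge || prominence <= 1e-3 * max(abs(slope[imax]), 1e-12))
    pc_warning("no interior derivative peak; transition not captured",
               "boundary_warning")
  sst <- sum((yw - mean(yw))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
  new_stability_result(kind = "melt", tm = tm, fit_r2 = r2,
                       variant = curve$variant)
}

#' Fold improvement of a variant over a reference
#'
#' @param variant_t_half,reference_t_half Half-lives in minutes (positive).
#' @return The exact ratio `variant / reference`. Use [round_fold()] for the
#'   conventional reported precision.
#' @export
fold_improvement <- function(variant_t_half, reference_t_half) {
  if (any(variant_t_half <= 0) || any(reference_t_half <= 0))
    pc_error("half-lives must be positive", "domain_error")
  variant_t_half / reference_t_half
}

#' Round a fold improvement to reported precision
#'
#' One decimal for folds of 10 or more, two decimals below 10 — the
#' convention used for variant tables.
#' @param fold Numeric fold improvement(s).
#' @return Rounded value(s).
#' @export
round_fold <- function(fold) {
  ifelse(fold >= 10, round(fold, 1), round(fold, 2))
}

#' Summarize variants against a reference
#'
#' Computes each variant's fold improvement in half-life over the reference
#' and the design success rate: the percentage of variants with fold > 1,
#' rounded to the nearest integer percent.
#'
#' @param records data.frame with columns `label`, `t_half`, and optionally
#'   `relative_activity`.
#' @param reference Label of the reference row in `records` (it is excluded
#'   from the variant count), or a numeric reference half-life.
#' @return A list with `table` (variants sorted by descending fold, with
#'   `fold` exact and `fold_reported` rounded), `n_variants`, `n_improved`,
#'   `success_rate` (integer percent), `reference_t_half`.
#' @export
summarize_variants <- function(records, reference) {
  stopifnot(is.data.frame(records), all(c("label", "t_half") %in% names(records)))
  if (is.character(reference)) {
    i <- match(reference, records$label)
    if (is.na(i))
      pc_error(sprintf("reference '%s' not found", reference), "config_error")
    ref <- records$t_half[i]
    records <- records[-i, , drop = FALSE]
  } else {
    ref <- as.numeric(reference)
    if (!is.finite(ref) || ref <= 0)
      pc_error("reference half-life must be positive", "config_error")
  }
  fold <- fold_improvement(records$t_half, ref)
  out <- records
  out$fold <- fold
  out$fold_reported <- round_fold(fold)
  out <- out[order(-out$fold), , drop = FALSE]
  rownames(out) <- NULL
  n_improved <- sum(fold > 1)
  list(table = out, n_variants = nrow(out), n_improved = n_improved,
       success_rate = round(100 * n_improved / nrow(out)),
       reference_t_half = ref)
}

#' Read assay curves from CSV
#'
#' Expects columns `x`, `y`, `variant`, `kind` (and optionally
#' `temperature`); returns one [assay_curve()] per variant/kind pair.
#'
#' @param path CSV path.
#' @return Named list of `assay_curve` objects.
#' @export
read_assay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "variant", "kind")
  if (!all(need %in% names(df)))
    pc_error(sprintf("assay CSV must have columns %s", paste(need, collapse = ", ")),
             "validation_error")
  sp <- split(df, paste(df$variant, df$kind, sep = ":"))
  lapply(sp, function(g) {
    g <- g[order(g$x), , drop = FALSE]
    assay_curve(g$kind[1], g$x, g$y, variant = g$variant[1],
                temperature = if ("temperature" %in% names(g)) g$temperature[1] else NA_real_)
  })
}
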