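# Doubling-time estimation: log-linear exponential fit on cell counts, and
# the colorimetric dilution-curve time-shift method (twofold culture dilutions
# reach the same optical density one doubling time apart).

#' Growth curve container
#'
#' @param times time points in minutes (strictly increasing).
#' @param values cell counts (cells/ml, CFU/ml) or OD units.
#' @param kind `"count"` or `"od"`.
#' @param dilution dilution factor of the series (1 = undiluted); used by the
#'   colorimetric method.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(times, values, kind = c("count", "od"), dilution = 1) {
  kind <- match.arg(kind)
  if (length(times) != length(values)) stop("times and values differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (kind == "count" && any(values <= 0)) stop("counts must be positive")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind, dilution = dilution),
            class = "growth_curve")
}

#' Doubling time by exponential fit
#'
#' Least-squares fit of `log2(count)` against time over an optional window;
#' the doubling time is the reciprocal of the slope.
#'
#' @param curve a [growth_curve()] of kind `"count"`.
#' @param window optional `c(t_min, t_max)` restricting the fit.
#' @return list with `dt_minutes`, `r_squared`, `n_points`.
#' @export
fit_doubling_time <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "growth_curve"))
  if (curve$kind != "count") stop("exponential fit requires a count curve")
  keep <- rep(TRUE, length(curve$times))
  if (!is.null(window)) keep <- curve$times >= window[1] & curve$times <= window[2]
  t <- curve$times[keep]; v <- curve$values[keep]
  if (length(t) < 3) stop("need at least 3 points in the fit window")
  if (any(v <= 0)) stop("non-positive counts in fit window")
  fit <- stats::lm(log2(v) ~ t)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("no growth: non-positive slope in log-linear fit")
  list(dt_minutes = 1 / slope, r_squared = r_squared(fit, log2(v)),
       n_points = length(t))
}

# R^2 of a fitted lm without summary.lm (which warns on perfect fits);
# a zero-variance response counts as perfectly fit.
r_squared <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / sst
}

# Longest contiguous run (>= min_points) whose linear fit reaches r2 >= r2_min;
# ties broken by higher r2. Exhaustive search over contiguous windows.
best_linear_segment <- function(times, values, r2_min = 0.999, min_points = 5L) {
  n <- length(times)
  if (n < min_points) stop("curve has fewer than ", min_points, " points")
  best <- NULL; best_r2_seen <- -Inf
  for (len in seq(n, min_points)) {
    for (i in seq_len(n - len + 1L)) {
      idx <- i:(i + len - 1L)
      if (diff(range(values[idx])) == 0) next  # flat plateau, not growth
      fit <- stats::lm(values[idx] ~ times[idx])
      if (stats::coef(fit)[2] == 0) next
      r2 <- r_squared(fit, values[idx])
      best_r2_seen <- max(best_r2_seen, r2)
      if (r2 >= r2_min) {
        if (is.null(best) || len > best$len ||
            (len == best$len && r2 > best$r2)) {
          co <- stats::coef(fit)
          best <- list(idx = idx, len = len, r2 = r2,
                       intercept = unname(co[1]), slope = unname(co[2]),
                       t_range = range(times[idx]))
        }
      }
    }
    if (!is.null(best)) break  # longer windows already exhausted
  }
  if (is.null(best)) {
    stop(sprintf("no contiguous segment of >= %d points reaches R^2 >= %g (best %.6f)",
                 min_points, r2_min, best_r2_seen))
  }
  best
}

#' Doubling time from twofold dilution OD curves
#'
#' For each dilution curve the maximal contiguous segment (at least
#' `min_points` points) whose linear fit achieves `R^2 >= r2_min` is selected.
#' The horizontal time offset between consecutive dilution curves is then
#' evaluated from the two regression equations at a matched OD (the mean OD of
#' the overlapping fitted ranges), and the doubling time is the mean offset
#' per twofold dilution step: `dt = offset / log2(dilution ratio)`.
#'
#' @param curves list of [growth_curve()] objects of kind `"od"`, each with a
#'   `dilution` factor; need not be sorted.
#' @param r2_min linearity threshold (default 0.999).
#' @param min_points minimal segment length.
#' @return list with `dt_minutes`, per-pair `offsets` (minutes per doubling),
#'   and the fitted `segments`.
#' @export
doubling_time_from_dilutions <- function(curves, r2_min = 0.999, min_points = 5L) {
  if (length(curves) < 2) stop("need at least 2 dilution curves")
  dil <- vapply(curves, function(c) c$dilution, numeric(1))
  ord <- order(dil)
  curves <- curves[ord]; dil <- dil[ord]
  segs <- lapply(curves, function(cu) {
    if (cu$kind != "od") stop("dilution method requires OD curves")
    best_linear_segment(cu$times, cu$values, r2_min, min_points)
  })
  offsets <- numeric(length(curves) - 1L)
  for (i in seq_len(length(curves) - 1L)) {
    s1 <- segs[[i]]; s2 <- segs[[i + 1L]]
    od1 <- range(s1$intercept + s1$slope * s1$t_range)
    od2 <- range(s2$intercept + s2$slope * s2$t_range)
    ov <- c(max(od1[1], od2[1]), min(od1[2], od2[2]))
    od_star <- if (ov[1] <= ov[2]) mean(ov) else mean(c(mean(od1), mean(od2)))
    t1 <- (od_star - s1$intercept) / s1$slope
    t2 <- (od_star - s2$intercept) / s2$slope
    step <- log2(dil[i + 1L] / dil[i])
    if (step <= 0) stop("dilution factors must increase between curves")
    offsets[i] <- (t2 - t1) / step
  }
  list(dt_minutes = mean(offsets), offsets = offsets, segments = segs)
}
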