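#' Area under a concentration-time curve by the linear trapezoid
#'
#' Linear trapezoidal rule over `[t1, t2]`, with linear interpolation of the
#' curve at the window edges when they fall between sampling times. AUC is
#' additive over adjacent windows.
#'
#' @param curve A data frame with columns `time` (h, strictly increasing)
#'   and `conc` (ng/mL, non-negative).
#' @param t1,t2 Window bounds, h; default to the curve's span. Must satisfy
#'   `t1 < t2` and lie within the span.
#' @return AUC in ng·h/mL.
#' @examples
#' auc_trapezoid(data.frame(time = 0:2, conc = c(0, 10, 0))) # 10
#' @export
auc_trapezoid <- function(curve, t1 = NULL, t2 = NULL) {
  .check_curve(curve)
  t1 <- t1 %||% min(curve$time)
  t2 <- t2 %||% max(curve$time)
  if (t1 >= t2 || t1 < min(curve$time) || t2 > max(curve$time)) {
    stop("invalid window: need t1 < t2 within the curve's span", call. = FALSE)
  }
  f <- stats::approxfun(curve$time, curve$conc)
  tt <- c(t1, curve$time[curve$time > t1 & curve$time < t2], t2)
  cc <- f(tt)
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' Peak concentration and its time
#'
#' Maximum sampled concentration and the time at which it occurs, optionally
#' restricted to a window (used to separate the immediate-release peak,
#' conventionally 0-4 h, from the extended-release peak, 4 h onward, in
#' biphasic profiles). Ties are broken by the earliest time.
#'
#' @inheritParams auc_trapezoid
#' @param window Optional `c(t1, t2)` restricting the search.
#' @return A tibble with `cmax` (ng/mL) and `tmax` (h).
#' @export
cmax_tmax <- function(curve, window = NULL) {
  .check_curve(curve)
  keep <- rep(TRUE, nrow(curve))
  if (!is.null(window)) {
    keep <- curve$time >= window[1] & curve$time <= window[2]
    if (!any(keep)) stop("empty window: no samples inside it", call. = FALSE)
  }
  tt <- curve$time[keep]; cc <- curve$conc[keep]
  i <- which.max(cc)  # which.max returns the first maximum: earliest-time tie-break
  tibble::tibble(cmax = cc[i], tmax = tt[i])
}

#' Standard summary metrics for a concentration curve
#'
#' Overall Cmax/Tmax and AUC to the last sample, plus windowed entries for
#' each requested window (default: the 0-4 h immediate-release window and
#' the 4 h-to-end extended-release window, when the curve extends past 4 h).
#'
#' @inheritParams auc_trapezoid
#' @param windows List of `c(t1, t2)` windows, or `NULL` for the defaults.
#' @return A tibble with one row per window (first row = full span):
#'   `window`, `t1`, `t2`, `cmax`, `tmax`, `auc`.
#' @export
pk_metrics <- function(curve, windows = NULL) {
  .check_curve(curve)
  span <- range(curve$time)
  if (is.null(windows)) {
    windows <- list()
    if (span[2] > 4 && span[1] < 4) {
      windows <- list(c(max(span[1], 0), 4), c(4, span[2]))
    }
  }
  all_w <- c(list(span), windows)
  labels <- c("overall", vapply(windows, function(w)
    sprintf("%g-%g h", w[1], w[2]), character(1)))
  purrr::map2_dfr(all_w, labels, function(w, lab) {
    pk <- cmax_tmax(curve, window = w)
    tibble::tibble(window = lab, t1 = w[1], t2 = w[2],
                   cmax = pk$cmax, tmax = pk$tmax,
                   auc = auc_trapezoid(curve, w[1], w[2]))
  })
}

#' Fold error between predicted and observed values
#'
#' `max(p/o, o/p)`: the symmetric ratio used for adequacy assessment. A
#' prediction is conventionally adequate when the fold error is strictly
#' below 2.
#'
#' @param predicted,observed Positive values. Vectorised.
#' @return Fold error (>= 1).
#' @export
fold_error <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("fold error requires strictly positive values", call. = FALSE)
  }
  pmax(predicted / observed, observed / predicted)
}

#' Point-by-point two-fold adequacy of a predicted curve
#'
#' Interpolates the predicted curve to the observed sampling times and
#' reports the fold error at each point and whether it falls strictly within
#' a factor of two. Observed rows with missing or non-positive means (e.g.
#' below the quantification limit) are dropped.
#'
#' @param predicted Data frame with `time` and `conc` (the model curve).
#' @param observed Data frame with `time` and `mean` (and optionally `sd`,
#'   carried through untouched).
#' @return A tibble `time`, `observed`, `predicted`, `fold`,
#'   `within_twofold`; the fraction of points within two-fold is attached as
#'   attribute `fraction_within` and is also returned by
#'   `summary()`-style use of `mean(x$within_twofold)`.
#' @export
two_fold_overlay <- function(predicted, observed) {
  .check_curve(predicted)
  obs <- observed[!is.na(observed$mean) & observed$mean > 0, ]
  if (any(obs$time < min(predicted$time) | obs$time > max(predicted$time))) {
    stop("observed times fall outside the predicted curve's span",
         call. = FALSE)
  }
  pred <- stats::approx(predicted$time, predicted$conc, xout = obs$time)$y
  out <- tibble::tibble(
    time = obs$time, observed = obs$mean, predicted = pred,
    fold = fold_error(pmax(pred, .Machine$double.xmin), obs$mean),
    within_twofold = NA
  )
  out$within_twofold <- out$fold < 2
  attr(out, "fraction_within") <- mean(out$within_twofold)
  out
}

.check_curve <- function(curve) {
  if (!all(c("time", "conc") %in% names(curve))) {
    stop("curve needs `time` and `conc` columns", call. = FALSE)
  }
  if (is.unsorted(curve$time, strictly = TRUE)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (any(curve$conc < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  invisible(curve)
}

#' Read / write an observed concentration table
#'
#' CSV dialect `time_h, mean, sd` (comma separator, period decimal, header
#' row), the format [generate_study()] emits and [two_fold_overlay()]
#' consumes.
#'
#' @param observed Data frame with columns `time`, `mean`, `sd`.
#' @param path File path.
#' @return `read_observed_curve()` returns a tibble with columns `time`,
#'   `mean`, `sd`; `write_observed_curve()` returns `path` invisibly.
#' @export
write_observed_curve <- function(observed, path) {
  out <- tibble::tibble(time_h = observed$time, mean = observed$mean,
                        sd = if ("sd" %in% names(observed)) observed$sd else NA)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_observed_curve
#' @export
read_observed_curve <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_h", "mean") %in% names(raw))) {
    stop("observed-curve CSV needs `time_h` and `mean` columns", call. = FALSE)
  }
  tibble::tibble(time = raw$time_h, mean = raw$mean,
                 sd = if ("sd" %in% names(raw)) raw$sd else NA_real_)
}
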