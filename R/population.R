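#' Default Monte Carlo distribution set for population simulations
#'
#' Builds the table of parameter distributions used for population
#' variability: blood flows and tissue volumes vary normally, while cardiac
#' output, partition coefficients, chemical/biochemical constants and GI
#' anatomy/physiology vary lognormally. Coefficients of variation: 9% for
#' cardiac output, 20% for partition coefficients, 10% for GI
#' anatomy/physiology, and 30% for the remaining parameters. All draws are
#' truncated at 1.96 standard deviations around the mean (on the log scale
#' for lognormal families). Body weight defaults to a normal 70 +/- 12 kg
#' unless overridden per study.
#'
#' Grouped parameters are renormalized after sampling to preserve balance:
#' fractional blood flows (group `"flow"`) are rescaled to their baseline
#' sum so perfusion still accounts for the whole cardiac output, and tissue
#' volumes (group `"volume"`) and gut-wall masses (group `"gi_mass"`) are
#' rescaled to their baseline sums to preserve body-mass balance.
#'
#' @param model An [mph_model()]; the distribution means are the model's
#'   current values.
#' @param bw_mean,bw_sd Body-weight distribution (kg).
#' @return A tibble `path`, `family`, `cv`, `group`.
#' @export
default_distribution_set <- function(model, bw_mean = 70, bw_sd = 12) {
  segs <- model$physiology$segment
  gi_paths <- function(col) paste("physiology", segs[-1], col, sep = ".")
  rows <- list(
    tibble::tibble(path = "subject.cardiac_output", family = "lognormal",
                   cv = 0.09, group = NA_character_),
    tibble::tibble(path = c("subject.P_liver", "subject.P_richly",
                            "subject.P_slowly", "drug.gut_partition"),
                   family = "lognormal", cv = 0.20, group = NA_character_),
    tibble::tibble(path = c("subject.flow_hepatic_artery",
                            "subject.flow_richly", "subject.flow_slowly",
                            gi_paths("flow_fraction")),
                   family = "normal", cv = 0.30, group = "flow"),
    tibble::tibble(path = c("subject.plasma_volume", "subject.liver_volume",
                            "subject.richly_volume", "subject.slowly_volume"),
                   family = "normal", cv = 0.30, group = "volume"),
    tibble::tibble(path = "subject.body_weight", family = "normal",
                   cv = bw_sd / bw_mean, group = NA_character_),
    tibble::tibble(path = c("drug.HPeff", "drug.S0",
                            paste0("metabolism.",
                                   names(metabolism_params()))),
                   family = "lognormal", cv = 0.30, group = NA_character_),
    tibble::tibble(path = c(gi_paths("pH"), gi_paths("transit_time"),
                            gi_paths("lumen_volume"),
                            gi_paths("surface_area"),
                            "physiology.stomach.pH",
                            "physiology.stomach.transit_time",
                            "physiology.stomach.lumen_volume"),
                   family = "lognormal", cv = 0.10, group = NA_character_),
    tibble::tibble(path = gi_paths("bile_conc"), family = "lognormal",
                   cv = 0.10, group = NA_character_),
    tibble::tibble(path = gi_paths("wall_mass_fraction"),
                   family = "lognormal", cv = 0.10, group = "gi_mass")
  )
  if (!is.null(model$formulation$weibull)) {
    rows <- c(rows, list(
      tibble::tibble(path = c("formulation.weibull.tlag",
                              "formulation.weibull.a",
                              "formulation.weibull.b"),
                     family = "lognormal", cv = 0.30, group = NA_character_)))
  }
  out <- dplyr::bind_rows(rows)
  # drop parameters whose baseline is zero (nothing to vary multiplicatively)
  base <- vapply(out$path, function(p) param_get(model, p), numeric(1))
  out[base > 0, ]
}

# one column of truncated draws; truncation at +/-1.96 SD via inverse-CDF
.sample_trunc <- function(n, mean, cv, family, truncate = TRUE) {
  mean <- unname(mean)
  z_lim <- if (truncate) 1.96 else Inf
  p_lo <- stats::pnorm(-z_lim); p_hi <- stats::pnorm(z_lim)
  z <- stats::qnorm(stats::runif(n, p_lo, p_hi))
  if (family == "normal") {
    mean * (1 + cv * z)
  } else {
    sigma <- sqrt(log(1 + cv^2))
    mu <- log(mean) - sigma^2 / 2     # preserves the arithmetic mean
    exp(mu + sigma * z)
  }
}

#' Draw parameter sets for a virtual population
#'
#' Samples `n` joint parameter draws from a distribution table (see
#' [default_distribution_set()]), applying truncation and the fractional
#' renormalization of grouped flows/volumes. Deterministic given `seed`.
#'
#' @param model Baseline [mph_model()].
#' @param distributions Distribution tibble (`path`, `family`, `cv`,
#'   `group`).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param truncate Apply the +/-1.96 SD truncation (disable only for
#'   sampling-statistics checks).
#' @return A tibble of `n` rows, one column per parameter path, with the
#'   baseline values attached as attribute `base`.
#' @export
sample_parameter_draws <- function(model, distributions, n, seed = 1,
                                   truncate = TRUE) {
  set.seed(seed)
  base <- vapply(distributions$path, function(p) param_get(model, p),
                 numeric(1))
  cols <- lapply(seq_len(nrow(distributions)), function(i) {
    .sample_trunc(n, base[i], distributions$cv[i], distributions$family[i],
                  truncate)
  })
  names(cols) <- distributions$path
  draws <- tibble::as_tibble(cols)
  # fractional renormalization within groups preserves blood/mass balance
  for (grp in unique(stats::na.omit(distributions$group))) {
    cols <- distributions$path[!is.na(distributions$group) &
                                 distributions$group == grp]
    target <- sum(base[cols])
    draw_sum <- rowSums(draws[, cols, drop = FALSE])
    draws[, cols] <- draws[, cols, drop = FALSE] * (target / draw_sum)
  }
  attr(draws, "base") <- base
  draws
}

# apply one draw (named numeric vector or one-row tibble) to a model
.apply_draw <- function(model, draw) {
  vals <- unlist(draw)
  for (p in names(vals)) model <- param_set(model, p, vals[[p]])
  model
}

#' Sample one virtual subject
#'
#' A single truncated, renormalized draw applied to the baseline model.
#'
#' @inheritParams sample_parameter_draws
#' @return An [mph_model()] with sampled parameter values.
#' @export
sample_subject <- function(model, distributions = default_distribution_set(model),
                           seed = 1) {
  .apply_draw(model, sample_parameter_draws(model, distributions, 1, seed)[1, ])
}

#' Monte Carlo population simulation
#'
#' Simulates `n` virtual subjects drawn from the parameter distributions and
#' summarises the plasma total-drug concentration band (pointwise mean and
#' 5th/95th percentiles, i.e. the 90% interval) together with per-subject
#' summary metrics (Cmax, Tmax, AUC to the horizon). A subject whose
#' integration fails is redrawn once; persistent failures are dropped and
#' counted.
#'
#' @inheritParams sample_parameter_draws
#' @param n Number of subjects.
#' @param t_end,dt_out,rtol,atol Passed to [simulate_mph()].
#' @return An object of class `mph_population`: `band` (time, mean, p5,
#'   p95), `metrics` (per subject), `metric_summary` (mean, sd, and for Tmax
#'   also the median), `n`, `n_failed`, `seed`.
#' @export
run_population <- function(model, n = 1000, seed = 1,
                           distributions = default_distribution_set(model),
                           t_end = 24, dt_out = 0.05,
                           rtol = 1e-8, atol = 1e-9) {
  stopifnot(n >= 1)
  draws <- sample_parameter_draws(model, distributions, n, seed)
  retry_seed <- seed + 1000003L
  conc <- NULL
  metrics <- vector("list", n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    sim <- tryCatch(
      simulate_mph(.apply_draw(model, draws[i, ]), t_end = t_end,
                   dt_out = dt_out, rtol = rtol, atol = atol),
      error = function(e) NULL)
    if (is.null(sim)) {
      redraw <- sample_parameter_draws(model, distributions, 1,
                                       seed = retry_seed + i)
      sim <- tryCatch(
        simulate_mph(.apply_draw(model, redraw[1, ]), t_end = t_end,
                     dt_out = dt_out, rtol = rtol, atol = atol),
        error = function(e) NULL)
    }
    if (is.null(sim)) {
      n_failed <- n_failed + 1L
      next
    }
    if (is.null(conc)) {
      conc <- matrix(NA_real_, nrow = length(sim$plasma$time), ncol = n)
      times <- sim$plasma$time
    }
    conc[, i] <- sim$plasma$conc_total
    curve <- data.frame(time = sim$plasma$time, conc = sim$plasma$conc_total)
    pk <- cmax_tmax(curve)
    metrics[[i]] <- tibble::tibble(
      subject = i, cmax = pk$cmax, tmax = pk$tmax,
      auc = auc_trapezoid(curve))
  }
  if (is.null(conc)) stop("all population iterations failed", call. = FALSE)
  ok <- colSums(is.na(conc)) == 0
  band <- tibble::tibble(
    time = times,
    mean = rowMeans(conc[, ok, drop = FALSE]),
    p5 = apply(conc[, ok, drop = FALSE], 1, stats::quantile, probs = 0.05),
    p95 = apply(conc[, ok, drop = FALSE], 1, stats::quantile, probs = 0.95)
  )
  metrics <- dplyr::bind_rows(metrics)
  metric_summary <- metrics |>
    tidyr::pivot_longer(-"subject", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     median = stats::median(.data$value), .groups = "drop")
  structure(list(band = band, metrics = metrics,
                 metric_summary = metric_summary,
                 n = n, n_failed = n_failed, seed = seed),
            class = "mph_population")
}

#' @export
print.mph_population <- function(x, ...) {
  cat(sprintf("<mph_population> n = %d (failed %d), seed %d\n",
              x$n, x$n_failed, x$seed))
  print(x$metric_summary)
  invisible(x)
}
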