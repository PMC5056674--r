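model_ir <- mph_model(builtin_formulation("IR-MPH"))

test_that("the default distribution set follows the stated families and CVs", {
  d <- default_distribution_set(model_ir)
  expect_equal(d$cv[d$path == "subject.cardiac_output"], 0.09)
  expect_equal(d$family[d$path == "subject.cardiac_output"], "lognormal")
  expect_true(all(d$cv[grepl("^subject.P_|gut_partition", d$path)] == 0.20))
  expect_equal(d$cv[d$path == "physiology.jejunum1.transit_time"], 0.10)
  expect_equal(d$family[d$path == "physiology.jejunum1.transit_time"],
               "lognormal")
  expect_true(all(d$family[d$group %in% c("flow", "volume")] == "normal"))
  expect_equal(d$cv[d$path == "metabolism.K5dC"], 0.30)
  # zero-valued parameters (colonic bile) are excluded
  expect_false("physiology.caecum.bile_conc" %in% d$path)
})

test_that("draws respect truncation and renormalization at n = 10^4", {
  d <- default_distribution_set(model_ir)
  draws <- sample_parameter_draws(model_ir, d, 10000, seed = 101)
  base <- attr(draws, "base")
  # lognormal truncation on the log scale
  for (p in c("subject.cardiac_output", "drug.HPeff")) {
    cv <- d$cv[d$path == p]
    sig <- sqrt(log(1 + cv^2))
    mu <- log(base[p]) - sig^2 / 2
    z <- (log(draws[[p]]) - mu) / sig
    expect_true(all(abs(z) <= 1.96 + 1e-9), label = p)
  }
  # normal truncation on the natural scale (pre-renormalization parameters)
  bw <- draws[["subject.body_weight"]]
  expect_true(all(bw >= 70 * (1 - 1.96 * 12 / 70) - 1e-9))
  expect_true(all(bw <= 70 * (1 + 1.96 * 12 / 70) + 1e-9))
  # renormalized flows and volumes preserve their baseline totals exactly
  for (grp in c("flow", "volume", "gi_mass")) {
    cols <- d$path[!is.na(d$group) & d$group == grp]
    expect_equal(rowSums(draws[, cols]), rep(sum(base[cols]), nrow(draws)),
                 tolerance = 1e-12)
  }
})

test_that("empirical CV matches the nominal CV without truncation", {
  d <- default_distribution_set(model_ir)
  draws <- sample_parameter_draws(model_ir, d, 10000, seed = 7,
                                  truncate = FALSE)
  for (p in c("drug.HPeff", "subject.cardiac_output")) {
    cv <- d$cv[d$path == p]
    x <- draws[[p]]
    expect_equal(stats::sd(x) / mean(x), cv, tolerance = 0.03)
  }
})

test_that("sampling and population runs are seed-reproducible", {
  d <- default_distribution_set(model_ir)
  expect_identical(sample_parameter_draws(model_ir, d, 50, seed = 3),
                   sample_parameter_draws(model_ir, d, 50, seed = 3))
  s1 <- sample_subject(model_ir, seed = 9)
  s2 <- sample_subject(model_ir, seed = 9)
  expect_identical(s1, s2)
  p1 <- run_population(model_ir, n = 4, seed = 5, dt_out = 0.25,
                       rtol = fast$rtol, atol = fast$atol)
  p2 <- run_population(model_ir, n = 4, seed = 5, dt_out = 0.25,
                       rtol = fast$rtol, atol = fast$atol)
  expect_identical(p1$band, p2$band)
  expect_identical(p1$metrics, p2$metrics)
})

test_that("a degenerate population reproduces the deterministic subject", {
  d <- default_distribution_set(model_ir)
  d$cv[] <- 1e-9
  pop <- run_population(model_ir, n = 1, seed = 2, distributions = d,
                        dt_out = 0.25, rtol = fast$rtol, atol = fast$atol)
  det <- simulate_mph(model_ir, dt_out = 0.25,
                      rtol = fast$rtol, atol = fast$atol)
  expect_equal(pop$band$mean, det$plasma$conc_total, tolerance = 1e-5)
})

test_that("the deterministic curve lies inside the population band", {
  pop <- run_population(model_ir, n = 16, seed = 11, dt_out = 0.25,
                        rtol = fast$rtol, atol = fast$atol)
  det <- simulate_mph(model_ir, dt_out = 0.25,
                      rtol = fast$rtol, atol = fast$atol)
  inside <- det$plasma$conc_total >= pop$band$p5 &
    det$plasma$conc_total <= pop$band$p95
  expect_gte(mean(inside), 0.95)
  # band ordering holds pointwise
  expect_true(all(pop$band$p5 <= pop$band$p95))
  gl <- glance(pop)
  expect_equal(gl$n, 16)
})
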