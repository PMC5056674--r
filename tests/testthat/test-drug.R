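props <- drug_properties()

test_that("unionized fraction follows Henderson-Hasselbalch", {
  expect_equal(unionized_fraction(8.77, 8.77), 0.5)
  expect_equal(unionized_fraction(30, 8.77), 1, tolerance = 1e-12)
  expect_equal(unionized_fraction(-30, 8.77), 0, tolerance = 1e-12)
  # hand evaluation: 1 / (1 + 10^(8.77 - 6.2)) = 1 / (1 + 371.535...)
  expect_equal(unionized_fraction(6.2, 8.77), 2.6845e-3, tolerance = 1e-4)
  # ionized and unionized fractions are complementary
  pH <- seq(1, 8, by = 0.5)
  ionized <- 1 - 1 / (1 + 10^(8.77 - pH))
  expect_equal(unionized_fraction(pH, 8.77) + ionized, rep(1, length(pH)))
})

test_that("aqueous solubility anchors and monotonicity hold", {
  # back-calculated intrinsic solubility reproduces the predicted anchor
  expect_equal(aqueous_solubility(10.58, props), 9250, tolerance = 1e-3)
  expect_equal(aqueous_solubility(8.77, props), 2 * props$S0)
  # strictly decreasing in pH
  s <- aqueous_solubility(seq(1, 12, by = 0.25), props)
  expect_true(all(diff(s) < 0))
  # gastric solubility is effectively unlimited
  expect_equal(aqueous_solubility(1.3, props),
               props$S0 * (1 + 10^(8.77 - 1.3)))
})

test_that("bile solubilization follows the micellar capacity model", {
  expect_equal(bile_solubility(6.5, 0, props), 0)
  # SR = 10^(0.606 * 0.20 + 2.234) = 10^2.3552, evaluated independently
  sr <- 10^2.3552
  expect_equal(sr, 226.57, tolerance = 1e-4)
  sw <- aqueous_solubility(6.5, props)
  expect_equal(bile_solubility(6.5, 2, props),
               sr * (sw * 18.015 / 233.3062 * 1e-6) * 233.3062 * 2)
  expect_error(bile_solubility(6.5, -1, props), "non-negative")
  # total solubility is additive and dominates the aqueous part
  pH <- c(5, 6, 7)
  expect_equal(total_solubility(pH, 2.8, props),
               aqueous_solubility(pH, props) + bile_solubility(pH, 2.8, props))
  expect_true(all(total_solubility(pH, 2.8, props) >=
                    aqueous_solubility(pH, props)))
})

test_that("dissolution rate matches the diffusion-layer arithmetic", {
  expect_equal(dissolution_rate(0, 1, 100, 50), 0)
  expect_equal(dissolution_rate(5, 100, 100, 50), 0)   # saturated
  # prefactor oracle: 3e-4 / (1 * 5e-4 * 30e-4 * 50) * 6000 = 24,000
  expect_equal(dissolution_rate(1, 0, 1, 50), 24000)
  # supersaturation reverses the sign (precipitation)
  expect_lt(dissolution_rate(1, 150, 100, 50), 0)
  expect_error(dissolution_rate(1, 0, 1, 0), "v_lumen")
})

test_that("closed-vessel dissolution approaches the saturation asymptote", {
  # one static compartment, no transit or absorption: the dissolved
  # concentration must rise monotonically to min(total/V, solubility)
  v <- 50; solub <- 10; total <- 1000  # solubility-limited case
  deriv <- function(t, y, p) {
    r <- dissolution_rate(y[1] / v, y[2] / v, solub, v)
    r <- min(r, 1e3 * y[1])           # same stiffness cap as the simulator
    list(c(-r, r))
  }
  out <- deSolve::lsoda(c(total, 0), seq(0, 2, 0.01), deriv, NULL,
                        rtol = 1e-8, atol = 1e-10)
  cdiss <- unname(out[, 3] / v)
  expect_true(all(diff(cdiss) >= -1e-6 * solub))
  expect_equal(cdiss[nrow(out)], solub, tolerance = 1e-3)
  # dose-limited case: everything dissolves
  total2 <- 100
  out2 <- deSolve::lsoda(c(total2, 0), seq(0, 2, 0.01), deriv, NULL,
                         rtol = 1e-8, atol = 1e-10)
  expect_equal(unname(out2[nrow(out2), 3] / v), total2 / v, tolerance = 1e-3)
})

test_that("permeability regression is monotone and distinct from the calibrated value", {
  # hand evaluation of 10^(0.86 + 0.92 * log10(24.7e-6))
  expect_equal(effective_permeability(24.7e-6), 4.181e-4, tolerance = 1e-3)
  expect_true(effective_permeability(5e-5) > effective_permeability(2e-5))
  # the calibrated simulation constant is NOT the regression output
  expect_gt(abs(effective_permeability(props$Papp) - props$HPeff) /
              props$HPeff, 1)
})

test_that("drug property invariants are enforced", {
  expect_error(drug_properties(pKa = -1), "pKa")
  expect_error(drug_properties(S0 = 0), "S0")
  expect_error(drug_properties(HPeff = 2), "HPeff")
  expect_error(dissolution_params(r_particle = -5), "positive")
})
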