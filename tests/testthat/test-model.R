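model_ir <- mph_model(builtin_formulation("IR-MPH"))

test_that("parameter paths address every component", {
  expect_equal(param_get(model_ir, "physiology.jejunum1.pH"), 6.2)
  expect_equal(param_get(model_ir, "metabolism.K5dC"), 0.79)
  expect_equal(param_get(model_ir, "drug.HPeff"), 0.963e-4)
  m2 <- param_set(model_ir, "physiology.caecum.transit_time", 5)
  expect_equal(param_get(m2, "physiology.caecum.transit_time"), 5)
  expect_equal(param_get(model_ir, "physiology.caecum.transit_time"), 4.5)
  m3 <- mph_model(builtin_formulation("MLR-MPH"))
  expect_equal(param_get(m3, "formulation.weibull.tlag"), 4)
  expect_error(param_get(model_ir, "physiology.pylorus.pH"), "unknown")
  expect_error(param_set(model_ir, "drug.nonexistent", 1), "unknown")
})

test_that("setting geometry recomputes the surface area", {
  m <- param_set(model_ir, "physiology.duodenum.radius", 3.2)
  expect_equal(param_get(m, "physiology.duodenum.surface_area"),
               surface_area(15, 3.2, "small"))
})

test_that("prandial state must be consistent between formulation and physiology", {
  fed_phys <- gi_physiology("fed")
  expect_error(mph_model(builtin_formulation("IR-MPH"), physiology = fed_phys),
               "fasted")
})

test_that("transit rates invert the transit times", {
  tr <- transit_rates(gi_physiology("fasted"))
  expect_equal(tr$rate[tr$segment == "stomach"], 4)
  expect_equal(tr$rate[tr$segment == "jejunum1"], 1 / 0.95)
  # a first-order emptying stomach retains exp(-t/tau) of a bolus
  expect_equal(exp(-4 * 0.5), 0.1353, tolerance = 1e-3)
  # mean residence times add up to the whole-gut transit time
  expect_equal(sum(1 / tr$rate), sum(gi_physiology("fasted")$transit_time))
  bad <- gi_physiology(); bad$transit_time[4] <- 0
  expect_error(transit_rates(bad), "positive")
})

test_that("absorption flux follows the permeability-area law", {
  phys <- gi_physiology("fasted")
  jej <- phys[phys$segment == "jejunum1", ]
  props <- drug_properties()
  expect_equal(absorption_flux(1, 1000, jej, props), 0)  # equilibrium
  # first-order lumen rate constant: 3600 HPeff ESA NI / V (about 0.41/h)
  ka <- absorption_flux(1, 0, jej, props) / jej$lumen_volume
  expect_equal(ka, 0.412, tolerance = 0.01)
  # flux reverses when the enterocyte concentration dominates
  expect_lt(absorption_flux(0.5, 1000, jej, props), 0)
  expect_error(absorption_flux(1, 0, phys[1, ], props), "stomach")
})

test_that("hepatic hydrolysis shows saturation and competitive inhibition", {
  met <- metabolism_params()
  bw75 <- 70^0.75
  # linear limit: clearance Vmax/Km per unit concentration
  v <- hepatic_hydrolysis_rates(1, 0, met, 70)
  expect_equal(v[["d"]], met$VmaxliverdC * bw75 / met$Kmliverd,
               tolerance = 1e-4)
  # half saturation at C = Km
  v2 <- hepatic_hydrolysis_rates(met$Kmliverd, 0, met, 70)
  expect_equal(v2[["d"]], met$VmaxliverdC * bw75 / 2)
  # l at its Km doubles d's apparent Km
  v3 <- hepatic_hydrolysis_rates(met$Kmliverd, met$Kmliverl, met, 70)
  expect_equal(v3[["d"]], met$VmaxliverdC * bw75 * met$Kmliverd /
                 (2 * met$Kmliverd + met$Kmliverd))
  expect_error(hepatic_hydrolysis_rates(-1, 0, met, 70), "non-negative")
})

test_that("subject physiology enforces flow and volume balance", {
  s <- subject_physiology()
  expect_equal(s$flow_hepatic_artery + 8 * gut_flow_fraction("male") +
                 s$flow_richly + s$flow_slowly, 1)
  expect_error(subject_physiology(flow_richly = 0.9), "sum to 1")
  expect_error(subject_physiology(plasma_volume = 100), "exceed")
  expect_equal(subject_physiology(body_weight = 70)$cardiac_output, 312)
})
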