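test_that("effective shear rate reproduces the measured flow estimate", {
  # v = 5.1 mm/s over the 15 um average width -> 680 1/s
  expect_equal(effectiveShearRate(5.1, 15), 680)
  expect_equal(effectiveShearRate(0, 15), 0)
  # degree-1 homogeneity in v, degree -1 in w
  expect_equal(effectiveShearRate(10.2, 15), 2 * effectiveShearRate(5.1, 15))
  expect_equal(effectiveShearRate(5.1, 30), effectiveShearRate(5.1, 15) / 2)
})

test_that("effective shear stress is eta * gamma with unit conversion", {
  g <- effectiveShearRate(5.1, 15)
  expect_equal(effectiveShearStress(1.5, g), 1.02)
  expect_equal(signif(effectiveShearStress(1.5, g), 2), 1.0)
  expect_equal(effectiveShearStress(1.5, 0), 0)
})

test_that("gamma -> tau -> gamma round-trips to machine precision", {
  g <- effectiveShearRate(3.7, 12)
  tau <- effectiveShearStress(2.1, g)
  expect_equal(tau / (2.1 * 1e-3), g, tolerance = 1e-12)
})

test_that("flow conditions bundle derives w_av from the channel openings", {
  fc <- flowConditions()
  expect_s4_class(fc, "FlowConditions")
  expect_equal(fc@wAvUm, 15)
  expect_equal(fc@gammaEffPerS, 680)
  expect_equal(signif(fc@tauEffPa, 2), 1.0)
  expect_error(flowConditions(vRbcMmPerS = -1), ">= 0|positive|> 0")
})
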