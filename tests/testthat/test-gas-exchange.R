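test_that("the gas-exchange transfer function and its variants are the printed models", {
  tf <- gas_exchange_tf()
  expect_identical(tf$num, c(20, 200, 62))
  expect_identical(tf$den, c(1, 110, 350, 67))
  expect_equal(dc_gain(tf), 62 / 67)
  expect_true(tf_is_stable(tf))
  expect_identical(gas_exchange_tf("model1")$num, c(10, 300, 62))
  expect_identical(gas_exchange_tf("model2")$num, c(20, 400, 62))
  expect_identical(gas_exchange_tf("model3")$num, c(20, 400, 52))
  expect_identical(gas_exchange_tf("model3")$den, c(1, 110, 350, 67))
})

test_that("compartment derivatives vanish at equilibrium and match direct substitution", {
  rates <- canonical_rates()
  expect_equal(unname(gas_exchange_derivatives(c(3, 3, 3), rates,
                                               v_in = 3, k_in = rates$k_AA)),
               c(0, 0, 0))
  d <- gas_exchange_derivatives(c(1, 0, 0), rates, v_in = 0, k_in = 0)
  expect_equal(unname(d), c(-rates$k_AA, rates$k_AT, 0))
})

test_that("the exchange network has the printed trace and the conservation null space", {
  rates <- canonical_rates()
  A <- gas_coupling_matrix(rates, k_in = 0)
  expect_equal(-sum(diag(A)),
               rates$k_AA + rates$k_AT + rates$k_TT + rates$k_BB)
  expect_equal(-sum(diag(A)), 109.75, tolerance = 1e-3)
  # s^2 coefficient of the printed third-order denominator is 110
  expect_equal(-sum(diag(A)), 110, tolerance = 0.005)
  # pure exchange conserves the weighted total: singular coupling matrix
  expect_lt(abs(det(A)), 1e-8 * prod(pmax(abs(diag(A)), 1)))
  expect_equal(unname(A %*% c(1, 1, 1)), matrix(0, 3, 1))
})

test_that("rate constants derived from the physical parameters match the printed blood-side rates", {
  p <- gas_exchange_params()
  r <- derive_rate_constants(p, scale = 0.1)
  expect_equal(r$k_TT, 15.87, tolerance = 1e-3)
  expect_equal(r$k_BB, 88.88, tolerance = 1e-3)
  r1 <- derive_rate_constants(p, scale = 1)
  expect_equal(r1$k_AA, 2.4e-12 / (2.5e-5 * 1.9e-7), tolerance = 1e-12)
  expect_equal(r1$k_AA, 0.505, tolerance = 1e-3)
  # doubling all volumes halves all rates
  p2 <- p
  p2$V_A <- 2 * p$V_A; p2$V_T <- 2 * p$V_T; p2$V_B <- 2 * p$V_B
  r2 <- derive_rate_constants(p2, scale = 1)
  for (nm in names(unclass(r1)))
    expect_equal(r2[[nm]], r1[[nm]] / 2)
})

test_that("with input coupling all compartments converge to the supply potential", {
  skip_if_not_installed("deSolve")
  rates <- canonical_rates()
  rhs <- function(t, s, parms)
    list(unname(gas_exchange_derivatives(s, rates, v_in = 5,
                                         k_in = rates$k_AA)))
  sol <- deSolve::ode(y = c(0, 0, 0), times = c(0, 60), func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  expect_equal(unname(sol[2, 2:4]), c(5, 5, 5), tolerance = 1e-4)
})

test_that("the composite patient model has order 11, DC gain 62/67, and carries the transport delay", {
  tp <- patient_model(intermediate_delay = 0.75)
  expect_equal(length(tp$den) - 1, 11)
  expect_equal(dc_gain(tp), 62 / 67)
  expect_equal(tp$dead_time, 0.75)
  tp0 <- patient_model()
  prod <- tf_series(airway_cascade("infected"), gas_exchange_tf())
  expect_identical(tp0$num, prod$num)
  expect_identical(tp0$den, prod$den)
  expect_identical(tp0$dead_time, 0)
})

test_that("the composite patient model is stable with positive Bode margins", {
  tp <- patient_model()
  expect_true(tf_is_stable(tp))
  mg <- stability_margins(tp)
  expect_gt(mg$gain_margin_db, 0)
  expect_gt(mg$phase_margin_deg, 0)  # Inf when the gain never reaches 0 dB
})

test_that("parameter ingest validates the diffusion-rate range and positivity", {
  p <- gas_exchange_params()
  expect_s3_class(p, "gas_exchange_params")
  expect_true(p$D_TB >= p$D_TB_range[1] && p$D_TB <= p$D_TB_range[2])
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("gas_exchange:", "  V_A: 1.9e-7", "  V_T: 4.2e-8",
               "  V_B: 7.5e-9", "  sigma_A: 2.5e-5", "  sigma_T: 1.2e-6",
               "  sigma_B: 1.2e-6", "  D_TA: 2.4e-12", "  D_TB: 5.0e-12",
               "  D_TB_range: [6.7e-12, 1.0e-11]"), tmp)
  expect_error(gas_exchange_params(tmp), "D_TB_range")
  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("gas_exchange:", "  V_A: -1"), tmp2)
  expect_error(gas_exchange_params(tmp2), "V_A")
})
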