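test_that("transfer-function arithmetic: construction, series product, DC gain", {
  expect_error(rtf(c(1, 0, 0), c(1, 1)), "improper")
  expect_error(rtf(1, c(1, 1), dead_time = -0.1), "dead_time")
  h <- tf_series(rtf(1, c(1, 1)), rtf(2, c(1, 3, 1), dead_time = 0.2))
  expect_equal(h$num, 2)
  expect_equal(h$den, c(1, 4, 4, 1))     # (s+1)(s^2+3s+1)
  expect_equal(h$dead_time, 0.2)
  expect_equal(dc_gain(h), 2)
})

test_that("oxygen-source lag has unity DC gain and the documented time constant", {
  tf <- cylinder_tf(0.5)
  expect_equal(tf$den, c(0.5, 1))
  expect_equal(dc_gain(tf), 1)
  expect_error(cylinder_tf(0), "positive")
  expect_error(cylinder_tf(-1), "positive")
  # discrete step response: closed form at t = tau, DC at large t
  blk <- discretize(tf, 1e-3)
  expect_equal(step_constant(blk, 1, 501), 1 - exp(-1), tolerance = 1e-3)
  blk <- discretize(tf, 1e-3)
  expect_equal(step_constant(blk, 1, 10001), 1, tolerance = 1e-3)
})

test_that("airway segment biquads carry the canonical coefficients", {
  expect_equal(segment_tf("trachea")$den, c(3.7e-4, 5.4e-3, 1))
  expect_equal(segment_tf("alveoli")$den, c(6.72e-8, 5.71e-4, 1))
  expect_equal(segment_tf("nasal")$den, c(2.7e-3, 2.165, 1))
  expect_equal(segment_tf("bronchi")$den, c(1.44e-5, 4.02e-4, 1))
  for (lab in segment_specs()$label)
    expect_equal(dc_gain(segment_tf(lab)), 1)
  expect_error(segment_tf("larynx"), "unknown segment")
})

test_that("the distressed-alveoli model is the printed biquad with ~672x stiffening", {
  tf <- infected_alveoli_tf()
  expect_identical(tf$den, c(1.0e-10, 1.15e-6, 1))
  expect_equal(segment_tf("alveoli")$den[1] / tf$den[1], 672)
  expect_equal(dc_gain(tf), 1)
})

test_that("RC products of the section R, L, C table agree with the printed column", {
  tab <- segment_specs("table")
  printed_RC <- c(nasal = 2.156, trachea = 0.0054, bronchi = 0.000402,
                  alveoli = 0.000571)
  ulp <- c(nasal = 1e-3, trachea = 1e-4, bronchi = 1e-6, alveoli = 1e-6)
  for (lab in names(printed_RC)) {
    got <- tab$RC[tab$label == lab]
    expect_lte(abs(got - printed_RC[[lab]]), ulp[[lab]] + 1e-12)
  }
  # the table-reconstruction path agrees with the canonical equation path
  eq <- segment_specs("equation")
  expect_equal(tab$RC, eq$RC, tolerance = 5e-3)
})

test_that("the airway cascade is an order-8 unity-DC product differing only in the alveolar factor", {
  inf <- airway_cascade("infected")
  hea <- airway_cascade("healthy")
  expect_equal(length(inf$den) - 1, 8)
  expect_equal(dc_gain(inf), 1)
  expect_equal(inf$den,
               tf_series(segment_tf("nasal"), segment_tf("trachea"),
                         segment_tf("bronchi"), infected_alveoli_tf())$den)
  expect_equal(hea$den,
               tf_series(segment_tf("nasal"), segment_tf("trachea"),
                         segment_tf("bronchi"), segment_tf("alveoli"))$den)
  expect_false(isTRUE(all.equal(inf$den, hea$den)))
})

test_that("every segment and cascade model is BIBO stable", {
  for (lab in segment_specs()$label)
    expect_true(tf_is_stable(segment_tf(lab)))
  expect_true(tf_is_stable(infected_alveoli_tf()))
  expect_true(tf_is_stable(airway_cascade("infected")))
  expect_true(tf_is_stable(airway_cascade("healthy")))
})

test_that("an uncontrolled step cannot reach a commanded level above the DC gain", {
  # open-loop settling value = DC gain (=1 for the cascade): a command > 1
  # is never reached without control action
  casc <- airway_cascade("infected")
  expect_lte(dc_gain(casc), 1 + 1e-12)
})

test_that("stability margins follow the classical conventions", {
  m1 <- stability_margins(rtf(1, c(1, 1)))
  expect_identical(m1$gain_margin_db, Inf)     # never reaches -180 deg
  expect_gt(m1$phase_margin_deg, 0)
  # integrator with a quarter-period delay sits exactly at the stability
  # boundary: |L| = 1 at 1 rad/s where the phase is -180 deg
  m2 <- stability_margins(rtf(1, c(1, 0), dead_time = pi / 2))
  expect_equal(m2$w_gain_crossover, 1, tolerance = 1e-6)
  expect_equal(m2$phase_margin_deg, 0, tolerance = 1e-6)
  # third-order lag with known margins: L = 1/(s+1)^3 reaches -180 deg at
  # sqrt(3) rad/s where |L| = 1/8 -> gain margin 18.06 dB
  m3 <- stability_margins(rtf(1, c(1, 3, 3, 1)))
  expect_equal(m3$w_phase_crossover, sqrt(3), tolerance = 1e-6)
  expect_equal(m3$gain_margin_db, 20 * log10(8), tolerance = 1e-6)
})

test_that("transfer functions round-trip through JSON", {
  tp <- patient_model(intermediate_delay = 0.75)
  tmp <- withr::local_tempfile(fileext = ".json")
  tf_to_json(tp, tmp)
  back <- tf_from_json(tmp)
  expect_equal(back$num, tp$num)
  expect_equal(back$den, tp$den)
  expect_equal(back$dead_time, 0.75)
})
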