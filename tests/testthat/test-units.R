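test_that("count/concentration conversions reproduce the reference values", {
  # 500 nm cube
  expect_equal(count_to_concentration(3000, 0.5^3), 39.867, tolerance = 1e-4)
  expect_equal(count_to_concentration(700, 0.5^3), 9.302, tolerance = 1e-4)
  expect_equal(count_to_concentration(0, 1), 0)
  # 1 x 1 x 2 um box at 5 uM
  expect_equal(count_to_concentration(6020, 2), 5.0, tolerance = 1e-3)
  # inverse round-trips
  for (v in c(0.125, 1, 2)) {
    n <- concentration_to_count(7.3, v, round = FALSE)
    expect_equal(count_to_concentration(n, v), 7.3)
  }
})

test_that("second-order rate conversion is consistent with the count scale", {
  # 1 uM^-1 s^-1 acting on 1 uM (=602 molecules/um^3) gives 1/s per molecule
  expect_equal(kon_to_volume_rate(1) * concentration_to_count(1, 1), 1,
               tolerance = 1e-12)
})
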