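test_that("binding radius calibration has the right limits", {
  expect_equal(binding_radius(0, 2.2e-6, 1e-6), 0)
  expect_error(binding_radius(NaN, 1e-6, 1e-6), "non-finite")
  # large-step (ballistic) limit: swept volume per step equals k' dt
  kon <- 100; dt <- 1e-6; D <- 2.3e-6
  sg <- binding_radius(kon, D, dt)                    # nm
  sg_ball <- (3 * kon_to_volume_rate(kon) * dt / (4 * pi))^(1 / 3) * 1e3
  expect_within(sg / sg_ball, 1, 0.05)
  # small-step limit: Smoluchowski diffusion-limited rate
  sg_um <- 4e-3
  expect_equal(simulated_binding_rate(sg_um, D, 1e-10),
               4 * pi * sg_um * D_to_um2(D), tolerance = 1e-6)
  # forward relation is the inverse of the calibration
  expect_within(simulated_binding_rate(sg * 1e-3, D, dt) /
                  kon_to_volume_rate(kon), 1, 0.02)
})

test_that("a well-mixed simulation at the calibrated radius reproduces
           mass-action kinetics", {
  m <- ab_model(kf = 50, kb = 0)
  cm <- compile_model(m, 1e-6)
  fr <- sapply(1:3, function(s) {
    r <- simulate_model(m, t_end = 0.006, dt = 1e-6, seed = s,
                        events = FALSE, cm = cm)
    r$counts$freeA
  })
  vol <- 0.4^3
  c0 <- count_to_concentration(800, vol)
  tt <- seq(0, 0.006, 1e-3)
  analytic <- concentration_to_count(c0 / (1 + 50 * c0 * tt), vol,
                                     round = FALSE)
  rel <- abs(rowMeans(fr)[-1] - analytic[-1]) / analytic[-1]
  # calibration contract: mass-action within 2%, allow Monte-Carlo noise
  expect_lt(mean(rel), 0.03)
})
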