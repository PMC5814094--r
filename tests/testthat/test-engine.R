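test_that("identical seeds reproduce bit-identical event logs", {
  pr <- build_preset("model1_scaled")
  cm <- compile_model(pr$model, 1e-6)
  r1 <- simulate_model(pr$model, t_end = 0.01, dt = 1e-6, seed = 7, cm = cm)
  r2 <- simulate_model(pr$model, t_end = 0.01, dt = 1e-6, seed = 7, cm = cm)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
  r3 <- simulate_model(pr$model, t_end = 0.01, dt = 1e-6, seed = 8, cm = cm)
  expect_false(identical(r1$events, r3$events))
})

test_that("structural invariants hold at every record in debug mode", {
  pr <- build_preset("model3_scaled")
  r <- run_preset(pr, seed = 41, t_end = 0.01, debug = TRUE)
  # debug mode stops on any bond/site/colocation violation; reaching here
  # plus exact conservation is the assertion
  expect_equal(unname(r$ledger$final["cam"]), unname(r$ledger$initial["cam"]))
  expect_equal(unname(r$ledger$final["K"]), unname(r$ledger$initial["K"]))
  expect_true(r$ledger$balanced)
  # phosphorylation never decreases (no phosphatase in the model)
  expect_true(all(diff(r$counts$p_subunits) >= 0))
})

test_that("the SSA and the spatial engine agree on the closed network", {
  pr <- build_preset("model3_scaled")
  cmL <- compile_model(pr$model, 1e-6)
  cmS <- compile_model(pr$model, radii = FALSE)
  sp <- sapply(1:3, function(s) {
    r <- simulate_model(pr$model, t_end = 0.02, dt = 1e-6, seed = s,
                        events = FALSE, cm = cmL)
    c(bound = utils::tail(r$counts$cam_bound, 1),
      p = utils::tail(r$counts$p_subunits, 1))
  })
  ws <- sapply(1:6, function(s) {
    r <- ssa_simulate(pr$model, t_end = 0.02, seed = 50 + s, events = FALSE,
                      cm = cmS)
    c(bound = utils::tail(r$counts$cam_bound, 1),
      p = utils::tail(r$counts$p_subunits, 1))
  })
  for (k in 1:2) {
    se <- sqrt(stats::var(sp[k, ]) / 3 + stats::var(ws[k, ]) / 6)
    expect_within(mean(sp[k, ]), mean(ws[k, ]), 4 * se + 2)
  }
})

test_that("halving the time step leaves the equilibrium within Monte-Carlo
           error", {
  m <- ab_model(kf = 50, kb = 500, nA = 500, nB = 500, side = 0.3)
  cm1 <- compile_model(m, 1e-6)
  cm2 <- compile_model(m, 5e-7)
  b1 <- vapply(1:5, function(s)
    mean(utils::tail(simulate_model(m, 0.015, 1e-6, seed = s, events = FALSE,
                                    cm = cm1)$counts$boundA, 5)), numeric(1))
  b2 <- vapply(1:5, function(s)
    mean(utils::tail(simulate_model(m, 0.015, 5e-7, seed = 50 + s,
                                    events = FALSE,
                                    cm = cm2)$counts$boundA, 5)), numeric(1))
  se <- sqrt(stats::var(b1) / 5 + stats::var(b2) / 5)
  expect_within(mean(b1), mean(b2), 2 * max(se, 2))
})
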