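test_that("the default rate set passes the reversibility audit", {
  rates <- default_rates()
  # derived context constants follow the linkage construction
  expect_equal(unname(rates["koff_C1_K"]), unname(rates["koff_C1"] / rates["g_K"]))
  expect_equal(unname(rates["koff_cam_K_2_2"]),
               unname(rates["kon_cam_K"] * rates["Kd0_cam_K"] / rates["g_K"]^4))
  pr <- build_preset("reduced_fig13_scaled")
  audit <- check_reversibility(pr$model)
  expect_true(audit$ok)
  expect_gt(audit$n_cycles, 0)
})

test_that("the full monomeric network is detailed-balanced", {
  # monomer variant expands to the complete two-layer network
  rates <- default_rates()
  mols <- camkii_molecules()
  rules <- parse_rule_file(lines = network_rules("monomer", phospho = FALSE),
                           molecules = mols)
  m <- hs_model("full_monomer", mols, rules, rates,
                box_geometry(c(1, 1, 1)),
                init = list(list(type = "ca", count = 10),
                            list(type = "cam", count = 10),
                            list(type = "K", count = 10)))
  audit <- check_reversibility(m)
  expect_true(audit$ok)
  expect_gt(audit$n_cycles, 10)
})

test_that("a perturbed loop is reported with the perturbation residual", {
  ok <- check_reversibility(square_loop_model(koff_b1 = 20))
  expect_true(ok$ok)
  expect_equal(ok$n_cycles, 1L)
  bad <- check_reversibility(square_loop_model(koff_b1 = 22))  # +10% on koff
  expect_false(bad$ok)
  expect_equal(nrow(bad$violations), 1L)
  expect_within(bad$violations$residual[1], 0.1, 0.02)
})

test_that("presets build, are closed under conservation, and validate
           overrides", {
  for (nm in list_presets()) {
    pr <- build_preset(nm)
    expect_s3_class(pr, "hs_preset")
    expect_true(all(pr$model$geometry$L > 0))
  }
  expect_error(build_preset("no_such_model"), "unknown preset")
  expect_error(build_preset("model1_scaled", overrides = list(cam_uM = -2)),
               "invalid override")
  # prototype counts at full scale
  pf <- build_preset("prototype_full")
  counts <- vapply(pf$model$init, function(e)
    if (!is.null(e$ring)) e$ring$n * e$count else e$count, numeric(1))
  types <- vapply(pf$model$init, function(e)
    if (!is.null(e$ring)) e$ring$type else e$type, character(1))
  expect_equal(unname(counts[types == "cam"]), 6020)
  expect_equal(unname(counts[types == "K"]), 12036)
  expect_equal(pf$model$geometry$L, c(1, 1, 2))
  # CaMKII immobilized
  expect_false(pf$model$molecules$K$mobile)
  # reduced network: monomeric subunits, 1/s phosphorylation, 5 pulses
  rf <- build_preset("reduced_fig13")
  expect_equal(unname(rf$model$rates["kp_reduced"]), 1)
  expect_equal(rf$influx_spec$n_pulses, 5)
  phr <- Filter(function(r) r$order == 1 && !r$reversible, rf$model$rules)
  expect_true(any(vapply(phr, function(r) r$label == "KN1C2~p", logical(1))))
})

test_that("the restricted schemes keep matched phosphorylation rates", {
  s1 <- build_preset("scheme1")
  labs1 <- vapply(s1$model$rules, `[[`, character(1), "label")
  expect_true(any(grepl("^KN0C2~p", labs1)))
  expect_false(any(grepl("^KN2C0~p", labs1)))
  s2 <- build_preset("scheme2")
  labs2 <- vapply(s2$model$rules, `[[`, character(1), "label")
  expect_true(any(grepl("^KN2C0~p", labs2)))
  expect_false(any(grepl("^KN0C2~p", labs2)))
  r <- default_rates()
  expect_equal(unname(r["kp_20"]), unname(r["kp_02"]))
  expect_equal(unname(r["kp_21"]), unname(r["kp_12"]))
  expect_error(build_preset("scheme1",
                            overrides = list(rates = c(kp_20 = 9))))
})

test_that("influx specs materialize and multipliers preserve the mean", {
  pr <- build_preset("reduced_fig13_scaled")
  pl <- preset_influx(pr$influx_spec)
  expect_equal(pl$times, (0:4) / 5)
  expect_equal(pl$ions, rep(2000, 5))
  set.seed(1)
  th <- preset_influx(list(kind = "theta", freq = 10, channels = 16,
                           multiplier = 0.1))
  expect_s3_class(th, "influx_trace")
  expect_gt(attr(th, "total"), 0)
})

test_that("equilibration returns a stationary snapshot consistent with the
           SSA equilibrium", {
  # zero-rate closed system: the initial state is already stationary
  m0 <- ab_model(kf = 0, kb = 0, nA = 50, nB = 50)
  eq0 <- suppressWarnings(equilibrate(
    structure(list(model = m0, sim = list(dt = 1e-6, record_interval = 1e-3)),
              class = "hs_preset"), n_trials = 2, t_eq = 0.002))
  expect_equal(as.integer(table(eq0$state$ptype)), c(50L, 50L))
  # reversible pair: spatial equilibrium matches the well-mixed oracle
  m <- ab_model(kf = 50, kb = 500, nA = 400, nB = 400, side = 0.3)
  pr <- structure(list(model = m, sim = list(dt = 1e-6,
                                             record_interval = 1e-3)),
                  class = "hs_preset")
  eq <- equilibrate(pr, n_trials = 3, t_eq = 0.01, seed = 2)
  cmS <- compile_model(m, radii = FALSE)
  ssa_eq <- mean(vapply(1:5, function(s)
    mean(utils::tail(ssa_simulate(m, t_end = 0.01, seed = 10 + s,
                                  events = FALSE,
                                  cm = cmS)$counts$boundA, 3)),
    numeric(1)))
  # key observable here is boundA (first observable is freeA): compare the
  # complementary count
  expect_within(eq$bound_cam, 400 - ssa_eq, 4 * sqrt(ssa_eq) / sqrt(3) + 8)
  expect_true(eq$stationary)
})
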