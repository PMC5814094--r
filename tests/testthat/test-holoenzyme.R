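test_that("ring geometry places subunits with the stated spacing", {
  # 6 subunits on a radius-8 circle: neighbour chord equals the radius
  p6 <- build_ring(ring_template(6, 8), c(0.5, 0.5, 0.5))
  d6 <- sqrt(sum((p6[1, ] - p6[2, ])^2))
  expect_equal(d6 * 1e3, 8, tolerance = 1e-9)
  # dimers sit diametrically opposed
  p2 <- build_ring(ring_template(2, 8), c(0.5, 0.5, 0.5))
  expect_equal(sqrt(sum((p2[1, ] - p2[2, ])^2)) * 1e3, 16, tolerance = 1e-9)
  # the radius sweep keeps chord = radius at n = 6
  p15 <- build_ring(ring_template(6, 15), c(0.5, 0.5, 0.5))
  expect_equal(sqrt(sum((p15[1, ] - p15[2, ])^2)) * 1e3, 15, tolerance = 1e-9)
  expect_error(ring_template(1, 8))
  expect_error(ring_template(6, 8, mobile = TRUE), "immobilized")
})

test_that("ring placement respects the box and the left/right convention", {
  m <- build_preset("model2_scaled", overrides = list(n_subunits = 6))$model
  set.seed(2)
  st <- build_world(m)
  L <- m$geometry$L
  expect_true(all(st$pos >= 0 & st$pos <= matrix(L, nrow(st$pos), 3,
                                                 byrow = TRUE)))
  # right(left(i)) == i around every ring
  expect_equal(st$right[st$left + 1], seq_along(st$left) - 1L)
  mbig <- m
  mbig$init[[1]]$ring <- ring_template(6, 8)
  mbig$geometry <- box_geometry(c(0.01, 0.01, 0.01))
  expect_error(build_world(mbig), "does not fit")
})

test_that("phosphorylation eligibility follows the kinase rule variants", {
  # isolated dimer, both CaM-bound, none phosphorylated: both eligible
  expect_true(phospho_condition(c(TRUE, TRUE), c(FALSE, FALSE), 1))
  expect_true(phospho_condition(c(TRUE, TRUE), c(FALSE, FALSE), 2))
  # no-phospho-kinase variant: one phosphorylated dimer partner blocks the
  # other forever (absorbing at one half)
  expect_false(phospho_condition(c(TRUE, TRUE), c(TRUE, FALSE), 2,
                                 "ml_no_phospho_kinase"))
  # default variant accepts an autonomous (phosphorylated, CaM-free) left
  # neighbour
  expect_true(phospho_condition(c(FALSE, TRUE), c(TRUE, FALSE), 2))
  # scheme restrictions on the bound CaM state
  expect_false(phospho_condition(c(TRUE, TRUE), c(FALSE, FALSE), 1,
                                 "scheme2_N2Cx_only",
                                 cam_state = c("N0C2", "N0C2")))
  expect_true(phospho_condition(c(TRUE, TRUE), c(FALSE, FALSE), 1,
                                "scheme1_NxC2_only",
                                cam_state = c("N0C2", "N0C2")))
})

test_that("the exact jamming fractions match the known sequence", {
  expect_equal(ring_phospho_steady_fraction(2), 1 / 2)
  expect_equal(ring_phospho_steady_fraction(3), 2 / 3)
  # the sequence rises from one half, peaks at the trimer value and then
  # converges (non-monotonically) to 1 - 1/e
  ns <- c(2, 3, 4, 6, 8, 12, 16)
  fr <- vapply(ns, ring_phospho_steady_fraction, numeric(1))
  expect_true(all(fr >= 1 / 2 & fr <= 2 / 3))
  err <- abs(fr - (1 - exp(-1)))
  expect_true(all(diff(err[-(1:2)]) <= 0))   # converging for n >= 4
  expect_within(fr[length(fr)], 1 - exp(-1), 0.002)
  set.seed(20)
  expect_within(sample_ring_jam(64, 300), 1 - exp(-1), 0.01)
})

test_that("simulated saturated rings converge to the exact jamming oracle", {
  for (n in c(2, 3, 6, 12)) {
    pr <- build_preset("model2_scaled", overrides = list(n_subunits = n))
    r <- run_preset(pr, seed = n)
    total <- r$counts$n_K[1]
    frac <- utils::tail(r$counts$p_subunits, 1) / total
    exact <- ring_phospho_steady_fraction(n)
    expect_within(frac, exact, 3 * sqrt(exact * (1 - exact) / (total / n)))
    # the phosphorylation level is nondecreasing (no dephosphorylation)
    expect_true(all(diff(r$counts$p_subunits) >= 0))
  }
})
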