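test_that("network expansion closes over the reachable species", {
  m <- square_loop_model()
  net <- expand_network(m)
  # M, MX(a), MX(b), MX(ab), X: five species
  expect_length(net$species, 5)
  expect_true(all(c("bindA0", "bindA1", "bindB0", "bindB1") %in%
                    net$reactions$label))
  expect_error(expand_network(m, max_species = 2), "guard")
})

test_that("ODE trajectories conserve moieties and honour detailed balance", {
  pr <- build_preset("model1_scaled")
  net <- expand_network(pr$model)
  vol <- prod(pr$model$geometry$L)
  y0 <- c(N0C0 = count_to_concentration(88, vol),
          ca = count_to_concentration(375, vol))
  tr <- ode_trajectories(net, y0, c(0, 0.05, 5))
  # all rates 0 -> constant trajectories
  m0 <- pr$model
  m0$rules <- resolve_rates(m0$rules, stats::setNames(
    rep(0, length(default_rates())), names(default_rates())))
  for (i in seq_along(m0$rules)) { m0$rules[[i]]$kf <- 0; m0$rules[[i]]$kb <- 0 }
  tr0 <- ode_trajectories(expand_network(m0), y0, c(0, 1))
  expect_equal(unlist(tr0[1, -1]), unlist(tr0[2, -1]), tolerance = 1e-10)
  # detailed balance at equilibrium: each reversible pair's net flux is zero
  eqr <- unlist(tr[3, -1])
  rates <- default_rates()
  # N1 site on CaM with an empty N2: ratio of adjacent states = kon*ca/koff
  for (pair in list(c("N0C0", "N1C0", "kon_N1", "koff_N1"),
                    c("N0C1", "N0C2", "kon_C2", "koff_C2"),
                    c("N1C2", "N2C2", "kon_N2", "koff_N2"))) {
    Keq <- rates[[pair[3]]] / rates[[pair[4]]]
    expect_equal(eqr[[pair[2]]] / (eqr[[pair[1]]] * eqr[["ca"]]), Keq,
                 tolerance = 1e-5)
  }
})

test_that("SSA matches the first-order closed form and the ODE mean", {
  mols <- list(A = molecule_type("A", c(f = "flag"), diffusion = 0,
                                 mobile = FALSE))
  rules <- parse_rule_file(lines = "A{f==0} -> A{f=1} kf=1 label=conv",
                           molecules = mols)
  m <- hs_model("ab1", mols, rules, geometry = box_geometry(c(1, 1, 1)),
                init = list(list(type = "A", count = 1000)),
                observables = list(B = list(type = "A", conds = data.frame(
                  target = "self", via = NA_character_, site = "f",
                  value = 1L, stringsAsFactors = FALSE))))
  res <- sapply(1:60, function(s)
    ssa_simulate(m, t_end = 1, seed = s, rec_dt = 0.5,
                 events = FALSE)$counts$B)
  expected <- 1000 * (1 - exp(-c(0, 0.5, 1)))
  z <- (rowMeans(res) - expected) /
    (apply(res, 1, stats::sd) / sqrt(60) + 1e-9)
  expect_true(all(abs(z[-1]) < 3))
  # zero-propensity system produces no events
  m0 <- m
  m0$rules[[1]]$kf <- 0
  r0 <- ssa_simulate(m0, t_end = 1, seed = 1)
  expect_equal(nrow(r0$events), 0)
})

test_that("SSA mean converges to the ODE solution as counts grow", {
  devs <- vapply(c(100, 1000, 10000), function(n0) {
    m <- ab_model(kf = 50, kb = 100, nA = n0, nB = n0, side = 0.4)
    cm <- compile_model(m, radii = FALSE)
    fr <- vapply(1:8, function(s)
      utils::tail(ssa_simulate(m, t_end = 0.01, seed = s, events = FALSE,
                               cm = cm)$counts$boundA, 1) / n0, numeric(1))
    vol <- 0.4^3
    c0 <- count_to_concentration(n0, vol)
    Kd <- 2
    x <- ((2 * c0 + Kd) - sqrt((2 * c0 + Kd)^2 - 4 * c0^2)) / 2
    abs(mean(fr) - x / c0)
  }, numeric(1))
  # relative sampling deviation shrinks roughly like 1/sqrt(n0)
  expect_lt(devs[3], 0.02)
  expect_lt(devs[3], devs[1] + 0.02)
})

test_that("regime classification implements the rate decomposition", {
  # k_enc -> infinity leaves k_a = k_on
  r <- regime_classify(10, 1e-2, sigma_enc = 5)
  expect_equal(r$k_a, 10, tolerance = 1e-4)
  # plain arithmetic: 1/(1/10 - 1/1000)
  D_for_kenc <- function(kenc_uM) {
    kenc_uM * kon_to_volume_rate(1) / (4 * pi * 5e-3) / 1e8
  }
  r2 <- regime_classify(10, D_for_kenc(1000))
  expect_equal(r2$k_a, 1 / (1 / 10 - 1 / 1000), tolerance = 1e-6)
  expect_equal(r2$classification, "activation-limited")
  # beyond the encounter rate: diffusion-limited flag
  r3 <- regime_classify(10, D_for_kenc(5))
  expect_equal(r3$classification, "diffusion-limited")
  expect_true(is.na(r3$k_a))
})

test_that("every network reaction is activation-limited, also at half
           diffusion", {
  pr <- build_preset("model1_scaled")
  for (sc in c(1, 0.5)) {
    rep <- regime_report(pr$model, sigma_enc = 5, D_scale = sc)
    expect_true(all(rep$classification == "activation-limited"))
    expect_true(all(rep$ratio < 10))
  }
  full <- build_preset("model3_scaled")
  repf <- regime_report(full$model)
  expect_true(all(repf$classification == "activation-limited"))
})
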