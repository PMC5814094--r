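test_that("free diffusion obeys the Einstein relation", {
  mols <- list(ca = molecule_type("ca", c(b = "binding"), diffusion = 2.2e-6))
  m <- hs_model("d", mols, rules = list(),
                geometry = box_geometry(c(100, 100, 100)),
                init = list(list(type = "ca", count = 4000)),
                observables = list())
  set.seed(42)
  st <- build_world(m)
  st$pos[] <- 50
  cm <- compile_model(m, 1e-6)
  simp <- list(dt = 1e-6, nsteps = 500L, record_every = 500L, t0 = 0,
               debug = FALSE, collect_events = FALSE,
               influx_counts = integer(0), influx_type = 0L,
               influx_pos = c(0, 0, 0))
  res <- holosim:::engine_run(cm, st, simp)
  disp <- res$state$pos - 50
  t <- 500e-6; D <- 220
  msd <- mean(rowSums(disp^2))
  expect_within(msd / (6 * D * t), 1, 4 * sqrt(2 / 3 / 4000) * 3)
  # per-axis displacements are Gaussian with sd sqrt(2 D t)
  z <- as.vector(disp) / sqrt(2 * D * t)
  expect_within(sd(z), 1, 0.03)
  expect_within(mean(z), 0, 4 / sqrt(length(z)))
})

test_that("immobile species and anchored complexes never move", {
  mols <- list(K = molecule_type("K", c(cam = "binding", p = "flag"),
                                 diffusion = 0, mobile = FALSE))
  m <- hs_model("im", mols, rules = list(),
                geometry = box_geometry(c(1, 1, 1)),
                init = list(list(ring = ring_template(6, 8, "K"), count = 5)),
                observables = list())
  set.seed(1)
  st <- build_world(m)
  cm <- compile_model(m, 1e-6)
  simp <- list(dt = 1e-6, nsteps = 100L, record_every = 100L, t0 = 0,
               debug = TRUE, collect_events = FALSE,
               influx_counts = integer(0), influx_type = 0L,
               influx_pos = c(0, 0, 0))
  res <- holosim:::engine_run(cm, st, simp)
  expect_equal(res$state$pos, st$pos)
})

test_that("bound molecules co-locate and diffuse with the slower partner", {
  # high-affinity pair: once bound, positions must stay identical and the
  # cluster must move with the smaller diffusion coefficient
  m <- ab_model(kf = 200, kb = 0, nA = 200, nB = 200, side = 0.3, D = 1e-6)
  m$molecules$B$diffusion_coeff <- 1e-7   # B is the big, slow molecule
  r <- simulate_model(m, t_end = 0.01, dt = 1e-6, seed = 2, debug = TRUE)
  st <- r$state
  bonds <- which(st$bondp[, 1] >= 0)
  expect_gt(length(bonds), 50)
  for (i in utils::head(bonds, 20)) {
    j <- st$bondp[i, 1] + 1
    expect_equal(st$pos[i, ], st$pos[j, ], tolerance = 1e-12)
  }
})

test_that("a molecule bound to an anchored complex stops moving", {
  mols <- list(
    L = molecule_type("L", c(s = "binding"), diffusion = 1e-6),
    K = molecule_type("K", c(s = "binding"), diffusion = 0, mobile = FALSE))
  rules <- parse_rule_file(
    lines = "L{} + K{} <-> L~K{L.s=1} kf=500 kb=0 label=lk",
    molecules = mols)
  m <- hs_model("anch", mols, rules, geometry = box_geometry(c(0.3, 0.3, 0.3)),
                init = list(list(type = "L", count = 300),
                            list(type = "K", count = 300)),
                observables = list())
  r1 <- simulate_model(m, t_end = 0.005, dt = 1e-6, seed = 3, events = FALSE)
  st <- r1$state
  bound <- which(st$bondp[, 1] >= 0 & st$ptype == 0L)
  expect_gt(length(bound), 20)
  pos0 <- st$pos
  r2 <- simulate_model(m, t_end = 0.001, dt = 1e-6, seed = 4,
                       events = FALSE, init_state = st)
  # bound L sits on its K and does not move over the continuation run
  moved <- rowSums((r2$state$pos[bound, ] - pos0[bound, ])^2)
  expect_true(all(moved == 0))
})

test_that("reflective boundaries conserve particles; absorption ledger
           balances exactly", {
  m <- ab_model(kf = 0, kb = 0, nA = 500, nB = 0, side = 0.3)
  r <- simulate_model(m, t_end = 0.005, dt = 1e-6, seed = 5, events = FALSE)
  expect_true(r$ledger$balanced)
  expect_equal(unname(r$ledger$final["A"]), 500)
  # absorption coefficient 0 behaves as pure reflection
  m2 <- ab_model(kf = 0, nA = 500, nB = 0, side = 0.3)
  m2$geometry <- box_geometry(c(0.3, 0.3, 0.3),
                              zlo = absorbing_face("A", prob = 0))
  r2 <- simulate_model(m2, t_end = 0.005, dt = 1e-6, seed = 6, events = FALSE)
  expect_equal(unname(r2$ledger$final["A"]), 500)
  # full absorption at the bottom removes walkers and the ledger tracks it
  m3 <- ab_model(kf = 0, nA = 500, nB = 0, side = 0.3)
  m3$geometry <- box_geometry(c(0.3, 0.3, 0.3),
                              zlo = absorbing_face("A", prob = 1))
  r3 <- simulate_model(m3, t_end = 0.005, dt = 1e-6, seed = 7, events = FALSE)
  expect_gt(unname(r3$ledger$absorbed["A"]), 0)
  expect_true(r3$ledger$balanced)
})

test_that("absorbing-boundary flux matches the half-space solution", {
  # pure diffusion from a uniform column against a perfectly absorbing
  # plane: survival fraction is the integral of erf(x / sqrt(4 D t))
  mols <- list(ca = molecule_type("ca", c(b = "binding"), diffusion = 2.2e-6))
  m <- hs_model("hs", mols, rules = list(),
                geometry = box_geometry(c(0.5, 0.5, 20),
                                        zlo = absorbing_face("ca", 1)),
                init = list(list(type = "ca", count = 8000)),
                observables = list())
  t_end <- 2e-4; D <- 220; L <- 20
  r <- simulate_model(m, t_end = t_end, dt = 1e-6, seed = 8, events = FALSE)
  surv <- unname(r$ledger$final["ca"]) / 8000
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  expected <- mean(erf(((1:2000) / 2000 * L) / sqrt(4 * D * t_end)))
  expect_within(surv / expected, 1, 0.05)
})

test_that("unbinding survival times are exponential at the declared rate", {
  m <- ab_model(kf = 100, kb = 400, nA = 600, nB = 600, side = 0.3)
  r <- simulate_model(m, t_end = 0.025, dt = 1e-6, seed = 9)
  # only episodes starting well before the end of the run, so censoring of
  # long survival times cannot bias the sample
  ev <- r$events
  # pair up consecutive bind/unbind events per A particle
  binds <- ev[ev$dir == 1, ]; unbinds <- ev[ev$dir == -1, ]
  expect_gt(nrow(unbinds), 800)
  durations <- numeric(0)
  for (p in unique(binds$p1)) {
    tb <- sort(binds$time[binds$p1 == p])
    tu <- sort(unbinds$time[unbinds$p1 == p])
    k <- min(length(tb), length(tu))
    if (k > 0) {
      keep <- tb[seq_len(k)] < 0.012
      durations <- c(durations, (tu[seq_len(k)] - tb[seq_len(k)])[keep])
    }
  }
  durations <- durations[durations > 0]
  expect_within(mean(durations) * 400, 1, 0.1)
  ks <- stats::ks.test(durations, "pexp", rate = 400)
  expect_gt(ks$p.value, 0.001)
})

test_that("reflective and periodic side walls give equivalent kinetics", {
  pr <- build_preset("model1_scaled")
  m2 <- pr$model
  m2$geometry <- box_geometry(m2$geometry$L, xlo = "periodic",
                              xhi = "periodic", ylo = "periodic",
                              yhi = "periodic")
  cm1 <- compile_model(pr$model, 1e-6)
  cm2 <- compile_model(m2, 1e-6)
  f1 <- sapply(1:8, function(s)
    utils::tail(simulate_model(pr$model, 0.02, 1e-6, seed = s,
                               events = FALSE, cm = cm1)$counts$N2C2, 1))
  f2 <- sapply(1:8, function(s)
    utils::tail(simulate_model(m2, 0.02, 1e-6, seed = 100 + s,
                               events = FALSE, cm = cm2)$counts$N2C2, 1))
  expect_gt(stats::t.test(f1, f2)$p.value, 0.01)
})

test_that("a too-large time step is rejected under the strict flag", {
  m <- ab_model(kf = 10, kb = 5000)
  expect_error(simulate_model(m, 1e-3, dt = 1e-4, seed = 1), "time step")
  expect_warning(check_timestep(m, 1e-4, strict = FALSE), "time step")
  expect_silent(check_timestep(m, 1e-6))
})
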