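test_that("steady-state activation and time constant match closed forms", {
  expect_equal(n_inf(-15), 0.5)
  expect_equal(n_inf(-7), 1 / (1 + exp(-1)))
  expect_equal(tau_n(-15), 0.06 + 4 * 0.75 * 0.45 * 0.55 / 2)
  expect_equal(tau_n(-15), 0.43125)
})

test_that("gating is a two-state chain with the right stationary law", {
  set.seed(11)
  expect_identical(gate_step(c(TRUE, FALSE), -15, 0), c(TRUE, FALSE))
  # at V = V_half the rates are symmetric: long-run open fraction 1/2
  open <- rep(FALSE, 200)
  fr <- replicate(400, mean(open <<- gate_step(open, -15, 0.2)))
  expect_within(mean(fr[-(1:50)]), 0.5, 0.02)
  # stationary open fraction matches the exact discrete-chain law and
  # tracks n_inf for small steps
  for (V in c(-30, -20, -10, 0, 10)) {
    dt <- 0.1
    open <- rep(FALSE, 300)
    fr <- replicate(300, mean(open <<- gate_step(open, V, dt)))
    po <- 1 - exp(-n_inf(V) / tau_n(V) * dt)
    pc <- 1 - exp(-(1 - n_inf(V)) / tau_n(V) * dt)
    pi_exact <- po / (po + pc)
    n_eff <- 300 * 250 / (1 + 2 * tau_n(V) / dt)
    expect_within(mean(fr[-(1:50)]), pi_exact,
                  4 * sqrt(pi_exact * (1 - pi_exact) / n_eff) + 0.01)
  }
})

test_that("single-channel and GHK currents have the right limits and signs", {
  p <- current_params()
  expect_equal(single_channel_current(-1.91, V_s = -1.91), -0.06)
  expect_lt(abs(single_channel_current(200, V_s = -1.91)), 1e-4)
  V <- seq(-100, 60, 5)
  expect_true(all(single_channel_current(V, -1.91) < 0))  # always inward
  # GHK at V=0 reduces to P z F ([Ca]i - [Ca]o) over the patch
  FARADAY <- 96485
  lim <- p$P_cm_s * p$z * FARADAY *
    (p$Ca_in_nM * 1e-12 - p$Ca_out_mM * 1e-6) * 1e-8 * 1e12
  expect_equal(ghk_current(0), lim, tolerance = 1e-9)
  expect_equal(ghk_current(1e-7), lim, tolerance = 1e-4)
})

test_that("the GHK fit recovers the channel count and offset potential", {
  f <- fit_channel_number()
  expect_equal(f$N, 16)
  expect_within(f$V_s, -1.91, 0.3)
  # doubling the permeability doubles the channel count: exactly for the
  # unconstrained fit, within rounding for the integer one
  p2 <- current_params(); p2$P_cm_s <- 2 * p2$P_cm_s
  f2 <- fit_channel_number(p2)
  expect_equal(f2$N_free, 2 * f$N_free, tolerance = 1e-6)
  expect_lte(abs(f2$N - 2 * f$N), 1)
  # degenerate fit is reported
  p0 <- current_params(); p0$P_cm_s <- 0
  expect_error(fit_channel_number(p0), "degenerate")
})

test_that("ion counts per step are stochastically rounded with exact mean", {
  expect_equal(ions_per_step(0, 1e-3), 0L)
  set.seed(3)
  n <- ions_per_step(rep(-0.06, 4000), 1e-3)
  mu <- 0.06e-12 * 1e-3 / (2 * 1.602176634e-19)   # ~187.3
  expect_within(mean(n), mu, 0.05)
  expect_true(all(n %in% c(floor(mu), ceiling(mu))))
  # conservation: totals are sums of the per-step counts
  expect_equal(sum(n), sum(as.numeric(n)))
})

test_that("theta-burst voltage traces have the prescribed spike pattern", {
  vt <- generate_voltage_trace(burst_freq = 5)
  # 25 spikes grouped 5 x 5
  peaks <- which(diff(sign(diff(vt$V_mV))) == -2) + 1
  peaks <- peaks[vt$V_mV[peaks] > 0]
  expect_equal(length(peaks), 25)
  gaps <- diff(vt$time_ms[peaks])
  expect_equal(sum(gaps > 50), 4)    # 4 inter-burst intervals at 5 Hz
  expect_equal(sum(gaps < 15), 20)   # 100 Hz within bursts
  # flat trace -> only spontaneous baseline influx
  set.seed(5)
  vt0 <- generate_voltage_trace(burst_freq = 5, amplitude = 0)
  tr0 <- generate_influx_trace(vt0, n_channels = 16)
  vt1 <- generate_voltage_trace(burst_freq = 5)
  tr1 <- generate_influx_trace(vt1, n_channels = 16)
  # spontaneous (resting) openings contribute, but the bursts dominate
  expect_lt(attr(tr0, "total"), 0.7 * attr(tr1, "total"))
  expect_gt(attr(tr0, "total"), 0)   # spontaneous influx exists
})

test_that("ensemble generation returns a total-matched trace pair", {
  set.seed(42)
  ens <- generate_influx_ensemble(n_trials = 40)
  expect_lt(ens$rel_diff, 0.001)
  expect_s3_class(ens[["5Hz"]], "influx_trace")
  expect_s3_class(ens[["10Hz"]], "influx_trace")
  expect_equal(attr(ens[["5Hz"]], "total"), ens$totals[1])
})

test_that("traces survive a plain-text round trip", {
  set.seed(8)
  vt <- generate_voltage_trace(burst_freq = 10, t_end_ms = 100)
  p <- tempfile(fileext = ".txt")
  write_trace(vt, p, header = c(seed = "8", kind = "voltage"))
  back <- read_trace(p, "voltage")
  expect_equal(back$V_mV, vt$V_mV, tolerance = 1e-8)
  expect_true(any(grepl("^# seed: 8", readLines(p))))
})
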