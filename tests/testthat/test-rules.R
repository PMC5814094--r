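mols_cal <- read_molecules(system.file("extdata", "molecules_cal.yaml",
                                       package = "holosim"))
mols_net <- camkii_molecules()

test_that("the rule dialect parses the channel gating and inert rules", {
  r <- parse_rule("CaL{gate==0} <-> CaL{gate=1} kf=ro kb=rc", mols_cal)
  expect_equal(r$order, 1)
  expect_true(r$reversible)
  expect_equal(r$conditions$site, "gate")
  expect_equal(r$conditions$value, 0L)
  expect_equal(r$assignments$value, 1L)
  expect_identical(r$kf, "ro")  # symbolic until resolved

  r2 <- parse_rule("cam{C1==0} + ca{} <-> cam~ca{cam.C1=1} kf=0 kb=0",
                   mols_net)
  expect_equal(r2$order, 2)
  expect_equal(unname(r2$bond["cam"]), "C1")
  expect_equal(unname(r2$bond["ca"]), "b")   # implicit single binding site
  expect_equal(r2$kf, 0)
})

test_that("syntax and semantic errors are rejected with line information", {
  expect_error(parse_rule("cam{C1=0} + ca{} <-> cam~ca{cam.C1=1} kf=1 kb=1",
                          mols_net, line = 7), "line 7")
  expect_error(parse_rule("cam{C1==0} <-> cam{C1==1} kf=1 kb=1", mols_net),
               "'=='")
  expect_error(parse_rule("zz{a==0} <-> zz{a=1} kf=1 kb=1", mols_net),
               "unknown molecule")
  expect_error(parse_rule("cam{Q7==0} <-> cam{Q7=1} kf=1 kb=1", mols_net),
               "unknown site")
  expect_error(parse_rule_file(lines = c(
    "cam{C1==0} + ca{} <-> cam~ca{cam.C1=1} kf=1 kb=1 label=x",
    "cam{C2==0} + ca{} <-> cam~ca{cam.C2=1} kf=1 kb=1 label=x"),
    molecules = mols_net), "duplicate")
})

test_that("serialization round-trips to the identical canonical rule", {
  lines <- c(model1_rules(), network_rules("default"))
  rules <- parse_rule_file(lines = lines, molecules = mols_net)
  for (r in rules) {
    txt <- serialize_rule(r)
    r2 <- parse_rule(txt, mols_net)
    r2$label <- r$label
    expect_equal(serialize_rule(r2), txt)
  }
})

test_that("the shipped rule files match their generators", {
  f <- function(p) readLines(system.file("extdata", p, package = "holosim"))
  expect_equal(f("rules_model1.rules"), model1_rules())
  expect_equal(f("rules_network_default.rules"), network_rules("default"))
  expect_equal(f("rules_reduced.rules"), reduced_rules(clearance = TRUE))
})

test_that("the sequential CaM scheme reaches exactly the 9 lobe states", {
  pr <- build_preset("model1_scaled")
  net <- expand_network(pr$model)
  nm <- species_names(net)
  cam_states <- setdiff(nm, "ca")
  expect_setequal(cam_states,
                  sprintf("N%dC%d", rep(0:2, each = 3), rep(0:2, 3)))
  # 4 reversible rules = 8 directed ones
  expect_length(directed_rules(pr$model$rules, pr$model$molecules), 8)
})

test_that("hash-table lookup equals the brute-force condition scan", {
  pr <- build_preset("model1_scaled")
  tab <- build_table(pr$model$rules, pr$model$molecules)
  # one particle per reachable CaM state plus one free ion
  states <- expand.grid(x = 0:2, y = 0:2)
  n <- nrow(states) + 1
  st <- list(ptype = c(rep(1L, nrow(states)), 0L),
             state = c(with(states,
                            as.integer(x >= 1) + 2L * as.integer(x >= 2) +
                              4L * as.integer(y >= 1) + 8L * as.integer(y >= 2)),
                       0L),
             bondp = matrix(-1L, n, 5), left = rep(-1L, n),
             right = rep(-1L, n))
  w <- world_view(st, pr$model)
  ca_id <- n
  for (i in seq_len(nrow(states))) {
    hash <- lookup_rules(tab, w, i, ca_id)
    brute <- lookup_brute(tab, w, i, ca_id)
    expect_identical(vapply(hash, `[[`, character(1), "label"),
                     vapply(brute, `[[`, character(1), "label"),
                     info = sprintf("state N%dC%d", states$x[i], states$y[i]))
    # branching examples: apoCaM has two candidate sites, a full CaM none
    nfree <- (states$x[i] < 2) + (states$y[i] < 2)
    expect_length(hash, nfree)
  }
})

test_that("combined rates add and branch selection follows the partition", {
  cand <- list(list(rate = 5), list(rate = 15))
  expect_equal(combined_rate(cand), 20)
  expect_equal(combined_rate(list()), 0)
  expect_equal(combined_rate(list(list(rate = 7))), 7)
  expect_equal(combined_rate(list(list(rate = 1), list(rate = 2),
                                  list(rate = 3))), 6)
  eq <- list(list(rate = 1, id = 1), list(rate = 1, id = 2))
  expect_equal(select_branch(eq, 0.4)$id, 1)
  expect_equal(select_branch(eq, 0.6)$id, 2)
  expect_equal(select_branch(list(list(rate = 3, id = 9)), 0.99)$id, 9)
  expect_null(select_branch(list(list(rate = 0)), 0.5))
})

test_that("branch frequencies converge to the rate proportions", {
  cand <- list(list(rate = 1, id = 1), list(rate = 3, id = 2))
  set.seed(101)
  u <- runif(1e5)
  picks <- vapply(u, function(ui) select_branch(cand, ui)$id, numeric(1))
  tab <- table(picks)
  chi <- chisq.test(tab, p = c(0.25, 0.75))
  expect_gt(chi$p.value, 0.01)
  # 3-sigma binomial envelope
  expect_within(mean(picks == 1), 0.25, 3 * sqrt(0.25 * 0.75 / 1e5))
})
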