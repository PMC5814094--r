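# Small fixture models built in code.

# two-species reversible binder A + B <-> AB
ab_model <- function(kf = 50, kb = 0, nA = 800, nB = 800, side = 0.4,
                     D = 1e-6) {
  mols <- list(
    A = molecule_type("A", c(s = "binding"), diffusion = D),
    B = molecule_type("B", c(s = "binding"), diffusion = D))
  rules <- parse_rule_file(
    lines = sprintf("A{} + B{} <-> A~B{A.s=1} kf=%g kb=%g label=ab", kf, kb),
    molecules = mols)
  hs_model("ab", mols, rules, geometry = box_geometry(rep(side, 3)),
           init = list(list(type = "A", count = nA),
                       list(type = "B", count = nB)),
           observables = list(
             freeA = list(type = "A", conds = data.frame(
               target = "self", via = NA_character_, site = "s", value = 0L,
               stringsAsFactors = FALSE)),
             boundA = list(type = "A", conds = data.frame(
               target = "self", via = NA_character_, site = "s", value = 1L,
               stringsAsFactors = FALSE))))
}

# detailed-balance toy square: X binds at two sites of M; the b-site rate
# is state-resolved so one edited constant can break exactly one loop
square_loop_model <- function(koff_b1 = 20) {
  mols <- list(
    M = molecule_type("M", c(a = "binding", b = "binding"), diffusion = 1e-7),
    X = molecule_type("X", c(s = "binding"), diffusion = 1e-6))
  lines <- c(
    "M{a==0,b==0} + X{} <-> M~X{M.a=1} kf=10 kb=100 label=bindA0",
    "M{a==0,b==1} + X{} <-> M~X{M.a=1} kf=10 kb=100 label=bindA1",
    "M{b==0,a==0} + X{} <-> M~X{M.b=1} kf=2 kb=20 label=bindB0",
    sprintf("M{b==0,a==1} + X{} <-> M~X{M.b=1} kf=2 kb=%g label=bindB1",
            koff_b1))
  rules <- parse_rule_file(lines = lines, molecules = mols)
  hs_model("square", mols, rules, geometry = box_geometry(c(1, 1, 1)),
           init = list(list(type = "M", count = 100),
                       list(type = "X", count = 500)))
}

expect_within <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("%g within %g of %g", x, tol, target))
}
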