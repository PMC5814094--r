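# The Ca2+/CaM/CaMKII rule-set family: molecule declarations, the default
# rate set, and generators for the rule files of each network tier.
#
# CaM carries four Ca2+ sites (N1, N2, C1, C2; binding within a lobe is
# sequential/cooperative, lobes are independent) plus a CaMKII-binding site
# k. A CaMKII subunit K carries a CaM-binding site and a phosphorylation
# flag p. Ca2+ binding kinetics depend on CaM's context: free, bound to an
# unphosphorylated subunit (K...), or to a phosphorylated one (Kp...).

#' Molecule declarations of the Ca2+/CaM/CaMKII family
#'
#' @param D_ca,D_cam diffusion coefficients, cm^2/s. CaMKII subunits are
#'   immobilized (cytoskeleton-attached).
#' @return named list of [molecule_type()]
#' @export
camkii_molecules <- function(D_ca = 2.2e-6, D_cam = 1.0e-7) {
  list(
    ca = molecule_type("ca", c(b = "binding"), diffusion = D_ca),
    cam = molecule_type("cam", c(N1 = "binding", N2 = "binding",
                                 C1 = "binding", C2 = "binding",
                                 k = "binding"), diffusion = D_cam),
    K = molecule_type("K", c(cam = "binding", p = "flag"), diffusion = 0,
                      mobile = FALSE))
}

#' Default rate set (primitives plus derived constants)
#'
#' Reads the editable primitive constants (uM^-1 s^-1 / s^-1) and derives the
#' context-dependent constants by thermodynamic linkage: Ca2+ affinity per
#' occupied site is increased by `g_K` on subunit-bound CaM and by `g_Kp` on
#' phosphorylated-subunit-bound CaM, so CaM-subunit dissociation scales as
#' `Kd0 / g^(x+y)`; the resulting network satisfies microscopic reversibility
#' by construction (audited by [check_reversibility()]).
#'
#' @param path YAML file of primitive constants; defaults to the shipped file
#' @return named numeric vector of all rate constants
#' @export
default_rates <- function(path = system.file("extdata", "rates_default.yaml",
                                             package = "holosim")) {
  p <- unlist(yaml::read_yaml(path))
  r <- p
  for (s in c("N1", "N2", "C1", "C2")) {
    r[paste0("koff_", s, "_K")] <- p[[paste0("koff_", s)]] / p[["g_K"]]
    r[paste0("koff_", s, "_Kp")] <- p[[paste0("koff_", s)]] / p[["g_Kp"]]
  }
  for (x in 0:2) for (y in 0:2) {
    n <- x + y
    r[sprintf("koff_cam_K_%d_%d", x, y)] <-
      p[["kon_cam_K"]] * p[["Kd0_cam_K"]] / p[["g_K"]]^n
    r[sprintf("koff_cam_Kp_%d_%d", x, y)] <-
      p[["kon_cam_Kp"]] * p[["Kd0_cam_Kp"]] / p[["g_Kp"]]^n
  }
  r
}

# state-pin conditions for CaM in state NxCy
.cam_pin <- function(x, y) {
  sprintf("N1==%d,N2==%d,C1==%d,C2==%d",
          as.integer(x >= 1), as.integer(x >= 2),
          as.integer(y >= 1), as.integer(y >= 2))
}

.ctx_pin <- c(free = "k==0", K = "k==1,partner(k).p==0",
              Kp = "k==1,partner(k).p==1")
.ctx_lab <- c(free = "", K = "K", Kp = "Kp")
.ctx_suffix <- c(free = "", K = "_K", Kp = "_Kp")
.vertex <- function(ctx, x, y) sprintf("%sN%dC%d", .ctx_lab[[ctx]], x, y)

#' Generate the rule lines of the Ca2+-CaM sequential-binding network
#'
#' The four reversible site rules of the 9-state CaM scheme (N2 requires N1,
#' C2 requires C1; unbinding of an inner site is blocked while the outer one
#' is occupied). Used as the basic simulator test model.
#'
#' @return character vector of rule lines
#' @export
model1_rules <- function() {
  c("# Ca2+ binding to free CaM: sequential within each lobe",
    "cam{N1==0,N2==0} + ca{} <-> cam~ca{cam.N1=1} kf=kon_N1 kb=koff_N1 label=N1~ca",
    "cam{N1==1,N2==0} + ca{} <-> cam~ca{cam.N2=1} kf=kon_N2 kb=koff_N2 label=N2~ca",
    "cam{C1==0,C2==0} + ca{} <-> cam~ca{cam.C1=1} kf=kon_C1 kb=koff_C1 label=C1~ca",
    "cam{C1==1,C2==0} + ca{} <-> cam~ca{cam.C2=1} kf=kon_C2 kb=koff_C2 label=C2~ca")
}

# Ca2+-site rule for one directed edge of the two-layer network, pinned to
# its origin vertex so event labels resolve the edge exactly
.ca_edge_rule <- function(site, x, y, ctx) {
  pin <- .cam_pin(x, y)
  cond <- paste(c(pin, .ctx_pin[[ctx]]), collapse = ",")
  lab <- sprintf("%s%s~ca@%s", .ctx_lab[[ctx]], site, .vertex(ctx, x, y))
  sprintf("cam{%s} + ca{} <-> cam~ca{cam.%s=1} kf=kon_%s kb=koff_%s%s label=%s",
          cond, site, site, site, .ctx_suffix[[ctx]], lab)
}

#' Generate the full two-layer Ca2+-CaM-CaMKII network rules
#'
#' State-resolved rules for: Ca2+ binding to CaM in all three contexts
#' (free / K-bound / Kp-bound), CaM binding to unphosphorylated and
#' phosphorylated subunits from every NxCy state, and neighbour-conditional
#' subunit autophosphorylation with a rate set by the bound CaM's state.
#'
#' @param variant phosphorylation eligibility: `"default"` (left neighbour
#'   activated: CaM-bound or autonomous), `"ml"` (left neighbour CaM-bound
#'   and unphosphorylated), `"scheme1"` (only NxC2-bound subunits
#'   phosphorylate), `"scheme2"` (only N2Cx), `"monomer"` (no neighbour
#'   condition)
#' @param phospho include phosphorylation rules
#' @return character vector of rule lines
#' @export
network_rules <- function(variant = c("default", "ml", "scheme1", "scheme2",
                                      "monomer"),
                          phospho = TRUE) {
  variant <- match.arg(variant)
  out <- c("# Layer 1 and Layer 2 Ca2+-CaM edges (state-resolved)")
  for (ctx in c("free", "K", "Kp")) {
    for (x in 0:2) for (y in 0:2) {
      if (x < 2) out <- c(out, .ca_edge_rule(if (x == 0) "N1" else "N2",
                                             x, y, ctx))
      if (y < 2) out <- c(out, .ca_edge_rule(if (y == 0) "C1" else "C2",
                                             x, y, ctx))
    }
  }
  out <- c(out, "# CaM binding to CaMKII subunits (per CaM state)")
  for (x in 0:2) for (y in 0:2) {
    pin <- .cam_pin(x, y)
    out <- c(out, sprintf(
      "cam{%s} + K{p==0} <-> cam~K{cam.k=1} kf=kon_cam_K kb=koff_cam_K_%d_%d label=K~N%dC%d",
      pin, x, y, x, y))
    out <- c(out, sprintf(
      "cam{%s} + K{p==1} <-> cam~K{cam.k=1} kf=kon_cam_Kp kb=koff_cam_Kp_%d_%d label=Kp~N%dC%d",
      pin, x, y, x, y))
  }
  if (phospho) {
    out <- c(out, "# neighbour-conditional autophosphorylation")
    states <- expand.grid(x = 0:2, y = 0:2)
    keep <- switch(variant,
                   scheme1 = states$y == 2,
                   scheme2 = states$x == 2,
                   rep(TRUE, nrow(states)))
    for (i in which(keep)) {
      x <- states$x[i]; y <- states$y[i]
      campin <- gsub("(N1|N2|C1|C2)==", "partner(cam).\\1==", .cam_pin(x, y))
      base <- sprintf("K{p==0,cam==1,%s%%s} -> K{p=1} kf=kp_%d%d label=KN%dC%d~p%%s",
                      campin, x, y, x, y)
      if (variant == "monomer") {
        out <- c(out, sprintf(base, "", ""))
      } else if (variant == "ml") {
        out <- c(out, sprintf(base, ",left.cam==1,left.p==0", ""))
      } else {
        out <- c(out, sprintf(base, ",left.cam==1", ".a"))
        out <- c(out, sprintf(base, ",left.cam==0,left.p==1", ".b"))
      }
    }
  }
  out
}

#' Generate the reduced (monomeric) network used for the frequency-reversal
#' analysis
#'
#' The entry steps of the full network only: sequential C-lobe loading of
#' free CaM, one N-site step from N0C2, CaM(N0C2)/CaM(N1C2) binding to
#' monomeric subunits, Ca2+ binding on subunit-bound CaM, and subunit
#' phosphorylation at a fixed rate while CaM N1C2 is bound. An optional
#' first-order Ca2+ clearance stands in for diffusive escape in well-mixed
#' runs.
#'
#' @param clearance include the `ca` removal rule (for SSA runs; spatial runs
#'   use the partially absorbing boundary instead)
#' @return character vector of rule lines
#' @export
reduced_rules <- function(clearance = FALSE) {
  out <- c(
    "# reduced network: C-lobe loading, one N step, subunit binding, phosphorylation",
    "cam{N1==0,N2==0,C1==0,C2==0,k==0} + ca{} <-> cam~ca{cam.C1=1} kf=kon_C1 kb=koff_C1 label=C1~ca@N0C0",
    "cam{N1==0,N2==0,C1==1,C2==0,k==0} + ca{} <-> cam~ca{cam.C2=1} kf=kon_C2 kb=koff_C2 label=C2~ca@N0C1",
    "cam{N1==0,N2==0,C1==1,C2==1,k==0} + ca{} <-> cam~ca{cam.N1=1} kf=kon_N1 kb=koff_N1 label=N1~ca@N0C2",
    "cam{N1==0,N2==0,C1==1,C2==1} + K{p==0} <-> cam~K{cam.k=1} kf=kon_cam_K kb=koff_cam_K_0_2 label=K~N0C2",
    "cam{N1==1,N2==0,C1==1,C2==1} + K{p==0} <-> cam~K{cam.k=1} kf=kon_cam_K kb=koff_cam_K_1_2 label=K~N1C2",
    "cam{N1==0,N2==0,C1==1,C2==1,k==1,partner(k).p==0} + ca{} <-> cam~ca{cam.N1=1} kf=kon_N1 kb=koff_N1_K label=KN1~ca@KN0C2",
    "K{p==0,cam==1,partner(cam).N1==1,partner(cam).N2==0,partner(cam).C1==1,partner(cam).C2==1} -> K{p=1} kf=kp_reduced label=KN1C2~p")
  if (clearance)
    out <- c(out, "ca{b==0} -> 0 kf=k_clear label=ca~clear")
  out
}

#' Rule lines for the saturated-ring phosphorylation test model
#'
#' Subunits with CaM permanently bound (saturating CaM abstracted as a flag
#' defaulting to 1); the only dynamics is neighbour-conditional
#' phosphorylation under the no-phosphorylated-kinase rule, whose steady
#' state is the jamming fraction computed by
#' [ring_phospho_steady_fraction()].
#'
#' @return character vector with one rule line
#' @export
jam_rules <- function() {
  c("# saturated ring: left neighbour must be CaM-bound and unphosphorylated",
    "K{cam==1,p==0,left.cam==1,left.p==0} -> K{p=1} kf=kp_jam label=jam~p")
}

#' Molecule declaration for the saturated-ring test model
#' @return named list with the jam-model subunit type
#' @export
jam_molecules <- function() {
  list(K = molecule_type("K", c(cam = "flag", p = "flag"), diffusion = 0,
                         mobile = FALSE, defaults = c(cam = 1L)))
}

#' Edge metadata for the two-layer network
#'
#' Maps every rule label to its network edge: origin and destination vertex
#' (CaM-centric: each edge moves one CaM between vertices), reaction family,
#' and layer (1 = free-CaM edges including CaM-subunit binding, 2 =
#' subunit-bound-CaM edges including phosphorylation).
#'
#' @param variant as in [network_rules()]
#' @return data.frame: `label`, `from`, `to`, `family`, `layer`
#' @export
network_edge_map <- function(variant = "default") {
  rows <- list()
  add <- function(label, from, to, family, layer)
    rows[[length(rows) + 1]] <<- data.frame(label = label, from = from,
                                            to = to, family = family,
                                            layer = layer,
                                            stringsAsFactors = FALSE)
  for (ctx in c("free", "K", "Kp")) {
    lay <- if (ctx == "free") 1L else 2L
    for (x in 0:2) for (y in 0:2) {
      if (x < 2) {
        s <- if (x == 0) "N1" else "N2"
        fam <- sprintf("%s%s~ca", .ctx_lab[[ctx]], s)
        add(sprintf("%s@%s", fam, .vertex(ctx, x, y)),
            .vertex(ctx, x, y), .vertex(ctx, x + 1, y), fam, lay)
      }
      if (y < 2) {
        s <- if (y == 0) "C1" else "C2"
        fam <- sprintf("%s%s~ca", .ctx_lab[[ctx]], s)
        add(sprintf("%s@%s", fam, .vertex(ctx, x, y)),
            .vertex(ctx, x, y), .vertex(ctx, x, y + 1), fam, lay)
      }
    }
  }
  for (x in 0:2) for (y in 0:2) {
    add(sprintf("K~N%dC%d", x, y), .vertex("free", x, y), .vertex("K", x, y),
        "K~NxCy", 1L)
    add(sprintf("Kp~N%dC%d", x, y), .vertex("free", x, y), .vertex("Kp", x, y),
        "Kp~NxCy", 1L)
    base <- sprintf("KN%dC%d~p", x, y)
    sufs <- if (variant %in% c("monomer", "ml")) "" else c(".a", ".b")
    for (sf in sufs)
      add(paste0(base, sf), .vertex("K", x, y), .vertex("Kp", x, y),
          "KNxCy~p", 2L)
  }
  do.call(rbind, rows)
}

#' Vertex observables of the two-layer network
#'
#' One engine observable per vertex (`NxCy`, `KNxCy`, `KpNxCy`), plus the
#' phosphorylated-subunit count and the bound-CaM count.
#'
#' @return named list of observable specs for [hs_model()]
#' @export
network_observables <- function() {
  obs <- list()
  pin_df <- function(x, y, ctx) {
    df <- data.frame(
      target = "self", via = NA_character_,
      site = c("N1", "N2", "C1", "C2", "k"),
      value = c(as.integer(x >= 1), as.integer(x >= 2),
                as.integer(y >= 1), as.integer(y >= 2),
                as.integer(ctx != "free")),
      stringsAsFactors = FALSE)
    if (ctx != "free")
      df <- rbind(df, data.frame(target = "partner", via = "k", site = "p",
                                 value = as.integer(ctx == "Kp"),
                                 stringsAsFactors = FALSE))
    df
  }
  for (ctx in c("free", "K", "Kp"))
    for (x in 0:2) for (y in 0:2)
      obs[[.vertex(ctx, x, y)]] <- list(type = "cam", conds = pin_df(x, y, ctx))
  obs[["p_subunits"]] <- list(type = "K", conds = data.frame(
    target = "self", via = NA_character_, site = "p", value = 1L,
    stringsAsFactors = FALSE))
  obs[["cam_bound"]] <- list(type = "cam", conds = data.frame(
    target = "self", via = NA_character_, site = "k", value = 1L,
    stringsAsFactors = FALSE))
  obs
}
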