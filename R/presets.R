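# Ready-to-run model presets: the simulator test models, the full prototype,
# the reduced frequency-reversal network and the scheme variants, each with
# desk-scale counterparts (volume and counts scaled at fixed concentrations)
# so validation runs finish in minutes.

.preset_names <- c("model1_ca_cam", "model1_scaled",
                   "model2_ml_test", "model2_scaled",
                   "model3_closed_network", "model3_scaled",
                   "prototype_full", "prototype_scaled",
                   "reduced_fig13", "reduced_fig13_scaled",
                   "scheme1", "scheme2", "radius_sweep")

#' List available presets
#' @return character vector of preset names
#' @export
list_presets <- function() .preset_names

# observables for the 9 free-CaM states (no subunits in the model)
.cam9_observables <- function() {
  obs <- list()
  for (x in 0:2) for (y in 0:2) {
    obs[[sprintf("N%dC%d", x, y)]] <- list(type = "cam", conds = data.frame(
      target = "self", via = NA_character_,
      site = c("N1", "N2", "C1", "C2"),
      value = c(as.integer(x >= 1), as.integer(x >= 2),
                as.integer(y >= 1), as.integer(y >= 2)),
      stringsAsFactors = FALSE))
  }
  obs$free_ca <- list(type = "ca", conds = data.frame(
    target = "self", via = NA_character_, site = "b", value = 0L,
    stringsAsFactors = FALSE))
  obs
}

#' Build a ready-to-run preset configuration
#'
#' Returns the model plus its simulation defaults. Overrides layer onto the
#' defaults; supported overrides: `cam_uM`, `ca_uM`, `D_ca`, `D_cam`
#' (cm^2/s), `ring_radius_nm` (5..15), `n_subunits`, `influx_multiplier`,
#' `absorb_prob`, `variant`, `rates` (named vector merged over the default
#' rate set).
#'
#' @param name one of [list_presets()]
#' @param overrides named list of overrides
#' @return an `hs_preset`: list(`model`, `sim`, `influx_spec`)
#' @export
build_preset <- function(name, overrides = list()) {
  if (!name %in% .preset_names) stop("unknown preset: ", name)
  for (key in setdiff(names(overrides), "rates")) {
    v <- overrides[[key]]
    if (is.numeric(v) && any(v < 0)) stop("invalid override ", key, ": ", v)
  }
  ov <- function(key, default) overrides[[key]] %||% default
  rates <- default_rates()
  if (!is.null(overrides$rates)) rates[names(overrides$rates)] <- overrides$rates
  D_ca <- ov("D_ca", 2.2e-6)
  D_cam <- ov("D_cam", 1.0e-7)
  absorb <- ov("absorb_prob", 1)
  mk <- function(model, sim, influx_spec = NULL)
    structure(list(model = model, sim = sim, influx_spec = influx_spec,
                   name = name, overrides = overrides), class = "hs_preset")

  if (name %in% c("model1_ca_cam", "model1_scaled")) {
    scaled <- name == "model1_scaled"
    side <- if (scaled) 0.25 else 0.5
    n_ca <- ov("n_ca", if (scaled) 375 else 3000)
    n_cam <- ov("n_cam", if (scaled) 88 else 700)
    mols <- camkii_molecules(D_ca, D_cam)[c("ca", "cam")]
    rules <- parse_rule_file(lines = model1_rules(), molecules = mols)
    model <- hs_model(name, mols, rules, rates,
                      box_geometry(rep(side, 3)),
                      init = list(list(type = "ca", count = n_ca),
                                  list(type = "cam", count = n_cam)),
                      observables = .cam9_observables())
    return(mk(model, sim = list(dt = 1e-6,
                                t_end = if (scaled) 0.05 else 0.1,
                                record_interval = 1e-3)))
  }

  if (name %in% c("model2_ml_test", "model2_scaled")) {
    n_sub <- ov("n_subunits", 6)
    total <- ov("total_subunits", if (name == "model2_scaled") 600 else 6000)
    n_rings <- floor(total / n_sub)
    mols <- jam_molecules()
    rules <- parse_rule_file(lines = jam_rules(), molecules = mols)
    model <- hs_model(name, mols, rules, c(kp_jam = 1),
                      box_geometry(c(1, 1, 1)),
                      init = list(list(
                        ring = ring_template(n_sub,
                                             ov("ring_radius_nm", 8), "K"),
                        count = n_rings)),
                      observables = list(
                        p_subunits = list(type = "K", conds = data.frame(
                          target = "self", via = NA_character_, site = "p",
                          value = 1L, stringsAsFactors = FALSE))))
    return(mk(model, sim = list(dt = 0.05, t_end = 30,
                                record_interval = 0.5)))
  }

  if (name %in% c("model3_closed_network", "model3_scaled",
                  "prototype_full", "prototype_scaled",
                  "scheme1", "scheme2", "radius_sweep")) {
    proto <- name %in% c("prototype_full", "prototype_scaled", "scheme1",
                         "scheme2", "radius_sweep")
    scaled <- name %in% c("model3_scaled", "prototype_scaled", "scheme1",
                          "scheme2", "radius_sweep")
    variant <- ov("variant", switch(name, scheme1 = "scheme1",
                                    scheme2 = "scheme2", "default"))
    if (variant %in% c("scheme1", "scheme2")) {
      # the two schemes must use matched phosphorylation rates
      stopifnot(rates[["kp_20"]] == rates[["kp_02"]],
                rates[["kp_21"]] == rates[["kp_12"]])
    }
    L <- if (proto) {
      if (scaled) c(1 / sqrt(10), 1 / sqrt(10), 2) else c(1, 1, 2)
    } else {
      if (scaled) c(0.5, 0.5, 0.5) else c(1, 1, 1)
    }
    vol <- prod(L)
    cam_uM <- ov("cam_uM", 5)
    n_cam <- concentration_to_count(cam_uM, vol)
    n_sub_target <- concentration_to_count(ov("camkii_uM", 10), vol)
    n_rings <- floor(n_sub_target / 6)
    mols <- camkii_molecules(D_ca, D_cam)
    rules <- parse_rule_file(lines = network_rules(variant),
                             molecules = mols)
    geom <- if (proto)
      box_geometry(L, zlo = absorbing_face("ca", absorb))
    else box_geometry(L)
    init <- list(list(type = "cam", count = n_cam),
                 list(ring = ring_template(6, ov("ring_radius_nm", 8), "K"),
                      count = n_rings))
    if (!proto) init <- c(init, list(list(
      type = "ca", count = concentration_to_count(ov("ca_uM", 10), vol))))
    obs <- network_observables()
    obs$free_ca <- list(type = "ca", conds = data.frame(
      target = "self", via = NA_character_, site = "b", value = 0L,
      stringsAsFactors = FALSE))
    model <- hs_model(name, mols, rules, rates, geom, init = init,
                      observables = obs,
                      edge_map = network_edge_map(variant))
    influx_spec <- if (proto)
      list(kind = "theta", freq = ov("freq", 5), channels = 16,
           multiplier = ov("influx_multiplier", if (scaled) 0.1 else 1))
    return(mk(model,
              sim = list(dt = 1e-6,
                         t_end = if (proto) { if (scaled) 1.3 else 2.2 }
                         else { if (scaled) 0.1 else 1 },
                         record_interval = 1e-3),
              influx_spec = influx_spec))
  }

  if (name %in% c("reduced_fig13", "reduced_fig13_scaled")) {
    scaled <- name == "reduced_fig13_scaled"
    L <- if (scaled) c(1 / sqrt(10), 1 / sqrt(10), 2) else c(1, 1, 2)
    vol <- prod(L)
    rates <- c(rates, kp_reduced = 1,
               k_clear = unname(ov("k_clear", 2 * D_to_um2(D_ca) / 2^2)))
    mols <- camkii_molecules(D_ca, D_cam)
    # spatial runs clear Ca2+ through the absorbing bottom; the SSA variant
    # uses the first-order clearance rule instead
    rules_sp <- parse_rule_file(lines = reduced_rules(clearance = FALSE),
                                molecules = mols)
    obs <- list(
      p_subunits = list(type = "K", conds = data.frame(
        target = "self", via = NA_character_, site = "p", value = 1L,
        stringsAsFactors = FALSE)),
      KN1C2 = list(type = "cam", conds = data.frame(
        target = c(rep("self", 5)), via = NA_character_,
        site = c("N1", "N2", "C1", "C2", "k"),
        value = c(1L, 0L, 1L, 1L, 1L), stringsAsFactors = FALSE)),
      free_ca = list(type = "ca", conds = data.frame(
        target = "self", via = NA_character_, site = "b", value = 0L,
        stringsAsFactors = FALSE)))
    n_cam <- concentration_to_count(ov("cam_uM", 5), vol)
    n_k <- concentration_to_count(ov("camkii_uM", 10), vol)
    model <- hs_model(name, mols, rules_sp, rates,
                      box_geometry(L, zlo = absorbing_face("ca", absorb)),
                      init = list(list(type = "cam", count = n_cam),
                                  list(type = "K", count = n_k)),
                      observables = obs)
    model_ssa <- hs_model(paste0(name, "_ssa"), mols,
                          parse_rule_file(lines = reduced_rules(TRUE),
                                          molecules = mols),
                          rates, box_geometry(L),
                          init = model$init, observables = obs)
    pr <- mk(model,
             sim = list(dt = 2e-6, t_end = 1.3, record_interval = 1e-3),
             influx_spec = list(kind = "pulses",
                                freq = ov("freq", 5), n_pulses = 5,
                                ions_per_pulse = ov("ions_per_pulse",
                                                    if (scaled) 2000 else 20000)))
    pr$model_ssa <- model_ssa
    return(pr)
  }
  stop("unhandled preset ", name)
}

#' @export
print.hs_preset <- function(x, ...) {
  cat("<hs_preset>", x$name, "\n")
  print(x$model)
  cat("  sim: dt =", x$sim$dt, "s, t_end =", x$sim$t_end, "s\n")
  invisible(x)
}

#' Materialize a preset's influx specification into pulse times or a trace
#'
#' Theta-burst specs generate a synthetic voltage trace and a stochastic
#' channel influx trace (consuming the current RNG stream); pulse specs
#' return instantaneous additions. Multipliers are applied by binomial
#' thinning (multiplier < 1) or stochastic-rounded scaling.
#'
#' @param spec a preset's `influx_spec`
#' @return `NULL`, an `influx_trace`, or `list(times=, ions=)`
#' @export
preset_influx <- function(spec) {
  if (is.null(spec)) return(NULL)
  if (spec$kind == "pulses") {
    tt <- (seq_len(spec$n_pulses) - 1) / spec$freq
    return(list(times = tt, ions = rep(spec$ions_per_pulse, spec$n_pulses)))
  }
  if (spec$kind == "theta") {
    vt <- generate_voltage_trace(burst_freq = spec$freq)
    tr <- generate_influx_trace(vt, n_channels = spec$channels)
    m <- spec$multiplier %||% 1
    if (m != 1) {
      mu <- tr$ions * m
      fl <- floor(mu)
      tr$ions <- as.integer(fl + (stats::runif(length(mu)) < mu - fl))
      attr(tr, "total") <- sum(tr$ions)
    }
    return(tr)
  }
  stop("unknown influx spec kind: ", spec$kind)
}

#' Run a preset end-to-end
#'
#' Seeds one RNG stream, materializes the influx, and runs the requested
#' engine with the preset's simulation defaults.
#'
#' @param preset an `hs_preset` from [build_preset()]
#' @param seed RNG seed
#' @param engine `"spatial"` or `"ssa"`
#' @param t_end,dt optional overrides of the preset defaults
#' @param ... passed to [simulate_model()] / [ssa_simulate()]
#' @return an `hs_run`
#' @export
run_preset <- function(preset, seed = 1, engine = c("spatial", "ssa"),
                       t_end = NULL, dt = NULL, ...) {
  engine <- match.arg(engine)
  set.seed(seed)
  influx <- preset_influx(preset$influx_spec)
  t_end <- t_end %||% preset$sim$t_end
  if (engine == "spatial") {
    run <- simulate_model(preset$model, t_end = t_end,
                          dt = dt %||% preset$sim$dt, seed = NULL,
                          record_interval = preset$sim$record_interval,
                          influx = influx, ...)
    run$manifest$seed <- seed
    return(run)
  } else {
    model <- preset$model_ssa %||% preset$model
    pulses <- if (!is.null(influx) && !inherits(influx, "influx_trace"))
      influx else if (inherits(influx, "influx_trace"))
        list(times = influx$time_ms[influx$ions > 0] * 1e-3,
             ions = influx$ions[influx$ions > 0]) else NULL
    run <- ssa_simulate(model, t_end = t_end, seed = NULL,
                        rec_dt = preset$sim$record_interval, pulses = pulses,
                        ...)
    run$manifest$seed <- seed
    run
  }
}

#' Pre-run a closed preset to its binding equilibrium
#'
#' Runs `n_trials` independent pre-runs without influx, tests stationarity of
#' the bound-CaM count over the last 40% of each run (difference of the last
#' two 20% windows against their pooled spread), and returns the final
#' snapshot for use as `init_state` of a stimulated run, together with the
#' equilibrium bound-CaM report.
#'
#' @param preset an `hs_preset`
#' @param n_trials number of pre-run trials (default 5)
#' @param t_eq pre-run length, s
#' @param seed RNG seed
#' @param engine `"spatial"` or `"ssa"`
#' @return list: `state` (snapshot), `bound_cam` (mean over trials),
#'   `bound_sd`, `stationary` (logical), `trials`
#' @export
equilibrate <- function(preset, n_trials = 5, t_eq = 0.2, seed = 1,
                        engine = "spatial") {
  key <- if ("cam_bound" %in% names(preset$model$observables)) "cam_bound"
  else names(preset$model$observables)[1]
  vals <- numeric(n_trials); stat <- logical(n_trials); state <- NULL
  cm <- if (engine == "spatial") compile_model(preset$model, preset$sim$dt)
  else compile_model(preset$model, preset$sim$dt, radii = FALSE)
  for (k in seq_len(n_trials)) {
    run <- if (engine == "spatial")
      simulate_model(preset$model, t_end = t_eq, dt = preset$sim$dt,
                     seed = seed + k - 1, events = FALSE, cm = cm)
    else ssa_simulate(preset$model, t_end = t_eq, seed = seed + k - 1,
                      events = FALSE, cm = cm)
    y <- run$counts[[key]]
    n <- length(y)
    w1 <- y[seq(floor(0.6 * n) + 1, floor(0.8 * n))]
    w2 <- y[seq(floor(0.8 * n) + 1, n)]
    spread <- stats::sd(c(w1, w2))
    stat[k] <- abs(mean(w2) - mean(w1)) <=
      3 * max(spread, 1) / sqrt(length(w2)) + 1
    vals[k] <- mean(w2)
    state <- run$state
  }
  if (!all(stat))
    warning("bound-CaM count still drifting in ", sum(!stat), " of ",
            n_trials, " trials; increase t_eq")
  list(state = state, bound_cam = mean(vals), bound_sd = stats::sd(vals),
       stationary = all(stat), trials = vals)
}
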