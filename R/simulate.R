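# Running compiled models: initial-state construction, the spatial engine
# front end, and the well-mixed SSA front end.

# cheap stable content hash (FNV-1a over the serialized object)
.config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Build the initial particle state of a model
#'
#' Free molecules are placed uniformly at random in the box; ring complexes
#' are placed with their full extent inside the box, at a random orientation
#' about the z axis. Site states start at the molecule's declared defaults.
#' Uses the current RNG stream.
#'
#' @param model an [hs_model()]
#' @return an engine state list (internal format)
#' @export
build_world <- function(model) {
  mols <- model$molecules
  tidx <- stats::setNames(seq_along(mols) - 1L, names(mols))
  sidx <- .site_index(mols)
  L <- model$geometry$L
  default_state <- vapply(mols, function(m)
    sum(bitwShiftL(1L, which(m$sites$default == 1L) - 1L)), integer(1))

  ptype <- integer(0); state <- integer(0); anchored <- integer(0)
  left <- integer(0); right <- integer(0)
  pos <- matrix(numeric(0), ncol = 3)
  for (entry in model$init) {
    if (!is.null(entry$ring)) {
      tpl <- entry$ring
      r <- tpl$radius_nm * 1e-3
      if (2 * r >= min(L[1], L[2]))
        stop("ring of radius ", tpl$radius_nm, " nm does not fit the box")
      for (k in seq_len(entry$count)) {
        ctr <- c(stats::runif(1, r, L[1] - r), stats::runif(1, r, L[2] - r),
                 stats::runif(1, 0, L[3]))
        ring_pos <- build_ring(tpl, ctr, phase = stats::runif(1, 0, 2 * pi))
        base <- length(ptype)
        n <- tpl$n
        ptype <- c(ptype, rep(tidx[[tpl$type]], n))
        state <- c(state, rep(default_state[[tpl$type]], n))
        anchored <- c(anchored, rep(1L, n))
        left <- c(left, base + ((seq_len(n) - 2L) %% n))
        right <- c(right, base + (seq_len(n) %% n))
        pos <- rbind(pos, ring_pos)
      }
    } else {
      n <- entry$count
      if (n == 0) next
      ptype <- c(ptype, rep(tidx[[entry$type]], n))
      state <- c(state, rep(default_state[[entry$type]], n))
      anchored <- c(anchored, rep(0L, n))
      left <- c(left, rep(-1L, n)); right <- c(right, rep(-1L, n))
      pos <- rbind(pos, cbind(stats::runif(n, 0, L[1]),
                              stats::runif(n, 0, L[2]),
                              stats::runif(n, 0, L[3])))
    }
  }
  n <- length(ptype)
  maxS <- max(vapply(mols, function(m) nrow(m$sites), integer(1)))
  list(ptype = as.integer(ptype), pos = pos, state = as.integer(state),
       bondp = matrix(-1L, n, maxS), bonds = matrix(-1L, n, maxS),
       left = as.integer(left), right = as.integer(right),
       anchored = as.integer(anchored), alive = rep(1L, n))
}

# map an influx spec onto the engine step grid
.influx_steps <- function(influx, dt, nsteps) {
  if (is.null(influx)) return(integer(0))
  counts <- integer(nsteps)
  if (inherits(influx, "influx_trace")) {
    stp <- pmin(nsteps - 1L, pmax(0L, as.integer(floor(
      influx$time_ms * 1e-3 / dt))))
    for (i in which(influx$ions > 0))
      counts[stp[i] + 1L] <- counts[stp[i] + 1L] + influx$ions[i]
  } else if (is.list(influx) && !is.null(influx$times)) {
    stp <- pmin(nsteps - 1L, pmax(0L, as.integer(floor(influx$times / dt))))
    for (i in seq_along(stp))
      counts[stp[i] + 1L] <- counts[stp[i] + 1L] + influx$ions[i]
  } else stop("unrecognized influx spec")
  counts
}

#' Run the spatial stochastic engine
#'
#' One iteration per time step: diffusion of free particles and bound
#' clusters (rigid, at the slowest member's coefficient), boundary handling,
#' collision detection through cell lists, rule lookup and branch selection
#' for colliding pairs, then first-order rules at `p = 1 - exp(-k dt)`.
#' Events are appended to the reaction log as they occur.
#'
#' @param model an [hs_model()]
#' @param t_end simulated time, s
#' @param dt time step, s (default 1 us; see [check_timestep()])
#' @param seed RNG seed (single stream drives gating, diffusion and reactions)
#' @param record_interval recording interval for species counts, s
#' @param influx `NULL`, an `influx_trace` (ions per trace step entering at
#'   the source point), or `list(times=, ions=)` for instantaneous pulses
#' @param influx_species molecule type entering (default `"ca"`)
#' @param events collect the reaction-event log
#' @param debug run structural invariant checks at every record point
#' @param strict abort (rather than warn) when `k*dt > 0.1` or the rms step
#'   exceeds a tenth of the smallest box dimension
#' @param init_state optional engine state (e.g. from [equilibrate()] or a
#'   previous run's `$state`)
#' @param cm optional precompiled model (from [compile_model()]) to reuse
#' @return an `hs_run`: list with `counts` (data.frame), `events`
#'   (data.frame), `ledger`, `state`, `manifest`
#' @export
simulate_model <- function(model, t_end, dt = 1e-6, seed = NULL,
                           record_interval = 1e-3, influx = NULL,
                           influx_species = "ca", events = TRUE,
                           debug = FALSE, strict = TRUE, init_state = NULL,
                           cm = NULL) {
  t_start <- Sys.time()
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cm)) cm <- compile_model(model, dt)
  check_timestep(model, dt, strict = strict, cm = cm)
  nsteps <- as.integer(round(t_end / dt))
  record_every <- max(1L, as.integer(round(record_interval / dt)))
  influx_counts <- .influx_steps(influx, dt, nsteps)
  state0 <- if (is.null(init_state)) build_world(model) else init_state
  L <- model$geometry$L
  simp <- list(dt = dt, nsteps = nsteps, record_every = record_every,
               t0 = 0, debug = debug, collect_events = events,
               influx_counts = as.integer(influx_counts),
               influx_type = if (influx_species %in% cm$type_names)
                 match(influx_species, cm$type_names) - 1L else 0L,
               influx_pos = c(L[1] / 2, L[2] / 2, L[3] - 1e-3))
  res <- engine_run(cm, state0, simp)
  .wrap_run(res, model, cm, state0, influx_type = simp$influx_type,
            manifest = list(engine = "spatial", seed = seed, dt = dt,
                            t_end = t_end, record_interval = record_interval,
                            model = model$name,
                            config_hash = .config_hash(
                              list(model, dt, t_end, influx)),
                            version = as.character(
                              utils::packageVersion("holosim")),
                            wall_s = as.numeric(difftime(Sys.time(), t_start,
                                                         units = "secs"))))
}

#' Run the well-mixed stochastic simulation algorithm on the same rules
#'
#' Statistically exact Gillespie sampling that reuses the compiled rule set
#' without positions: propensities are per-rule products of match-set sizes
#' maintained incrementally (network-free; no species enumeration).
#'
#' @inheritParams simulate_model
#' @param rec_dt recording grid, s
#' @param pulses `NULL` or `list(times=, ions=)`: instantaneous additions of
#'   `pulse_species`
#' @param pulse_species molecule type injected by pulses
#' @return an `hs_run`
#' @export
ssa_simulate <- function(model, t_end, seed = NULL, rec_dt = 1e-3,
                         pulses = NULL, pulse_species = "ca", events = TRUE,
                         init_state = NULL, cm = NULL) {
  t_start <- Sys.time()
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cm)) cm <- compile_model(model, dt = 1e-6, radii = FALSE)
  state0 <- if (is.null(init_state)) build_world(model) else init_state
  simp <- list(t_end = t_end, rec_dt = rec_dt,
               volume = prod(model$geometry$L),
               pulse_t = if (is.null(pulses)) numeric(0) else pulses$times,
               pulse_n = if (is.null(pulses)) integer(0) else
                 as.integer(pulses$ions),
               pulse_type = if (pulse_species %in% cm$type_names)
                 match(pulse_species, cm$type_names) - 1L else 0L,
               collect_events = events)
  res <- ssa_run(cm, state0, simp)
  .wrap_run(res, model, cm, state0, influx_type = simp$pulse_type,
            manifest = list(engine = "ssa", seed = seed, t_end = t_end,
                            model = model$name,
                            config_hash = .config_hash(
                              list(model, t_end, pulses)),
                            version = as.character(
                              utils::packageVersion("holosim")),
                            wall_s = as.numeric(difftime(Sys.time(), t_start,
                                                         units = "secs"))))
}

.wrap_run <- function(res, model, cm, state0, manifest, influx_type = NULL) {
  counts <- as.data.frame(res$counts)
  names(counts) <- c(cm$obs_names, paste0("n_", cm$type_names))
  counts <- cbind(time = res$times, counts)
  ev <- res$events
  events <- data.frame(time = ev$time, label = cm$labels[ev$label + 1L],
                       dir = ev$dir, p1 = ev$p1, p2 = ev$p2,
                       stringsAsFactors = FALSE)
  led <- res$ledger
  names(led$absorbed) <- cm$type_names
  names(led$removed) <- cm$type_names
  init_n <- tabulate(state0$ptype + 1L, nbins = cm$T)
  final_n <- tabulate(res$state$ptype[res$state$alive == 1L] + 1L,
                      nbins = cm$T)
  led$initial <- stats::setNames(init_n, cm$type_names)
  led$final <- stats::setNames(final_n, cm$type_names)
  influx_by_type <- stats::setNames(numeric(cm$T), cm$type_names)
  if (!is.null(influx_type) && led$influx_added > 0)
    influx_by_type[influx_type + 1L] <- led$influx_added
  led$influx <- influx_by_type
  # exact conservation: initial + influx - absorbed - removed = final
  led$balance <- led$initial + led$influx - led$absorbed - led$removed -
    led$final
  led$balanced <- all(led$balance == 0)
  structure(list(counts = counts, events = events, ledger = led,
                 state = res$state, model = model, cm = cm,
                 manifest = manifest),
            class = "hs_run")
}

#' @export
print.hs_run <- function(x, ...) {
  cat("<hs_run>", x$manifest$model, sprintf("(%s engine)", x$manifest$engine),
      "\n  t:", utils::tail(x$counts$time, 1), "s;",
      nrow(x$events), "events;",
      "ledger", if (isTRUE(x$ledger$balanced)) "balanced" else "IMBALANCED",
      "\n")
  invisible(x)
}

#' Validate the time step against the model's rates and geometry
#'
#' A usable step requires every first-order `k * dt <= 0.1` and an rms
#' diffusive step no larger than a tenth of the smallest box dimension.
#'
#' @param model an [hs_model()]
#' @param dt candidate time step, s
#' @param strict abort on violation instead of warning
#' @param cm optional precompiled model
#' @return invisibly, a list with the two margins
#' @export
check_timestep <- function(model, dt, strict = TRUE, cm = NULL) {
  if (is.null(cm)) cm <- compile_model(model, dt, radii = FALSE)
  kmax <- if (length(cm$o1_rate)) max(cm$o1_rate) else 0
  rms <- sqrt(2 * max(cm$D) * dt)
  Lmin <- min(model$geometry$L)
  bad <- character(0)
  if (kmax * dt > 0.1)
    bad <- c(bad, sprintf("k*dt = %.3g > 0.1 (k = %.3g/s)", kmax * dt, kmax))
  if (rms > Lmin / 10)
    bad <- c(bad, sprintf("rms step %.3g um > box/10 = %.3g um", rms, Lmin / 10))
  if (length(bad)) {
    msg <- paste("time step too large:", paste(bad, collapse = "; "))
    if (strict) stop(msg) else warning(msg)
  }
  invisible(list(k_dt = kmax * dt, rms_um = rms))
}

#' Functional view over an engine state for rule-table queries
#'
#' Wraps a state list in the accessor interface used by [lookup_rules()] /
#' [lookup_brute()] (1-based particle ids).
#'
#' @param state an engine state list
#' @param model the owning [hs_model()]
#' @return list of accessor closures
#' @export
world_view <- function(state, model) {
  tnames <- names(model$molecules)
  sidx <- .site_index(model$molecules)
  list(
    type = function(pid) tnames[state$ptype[pid] + 1L],
    site = function(pid, name) {
      ty <- tnames[state$ptype[pid] + 1L]
      bitwAnd(bitwShiftR(state$state[pid], sidx[[ty]][[name]]), 1L)
    },
    partner = function(pid, via) {
      ty <- tnames[state$ptype[pid] + 1L]
      j <- state$bondp[pid, sidx[[ty]][[via]] + 1L]
      if (j < 0) NA_integer_ else j + 1L
    },
    neighbor = function(pid, side) {
      j <- if (side == "left") state$left[pid] else state$right[pid]
      if (j < 0) NA_integer_ else j + 1L
    })
}

#' Run a pulsed protocol with phase-dependent time steps
#'
#' Instantaneous influx pulses create short-lived steep gradients near the
#' source, which need a fine time step; between pulses the tracked ion is
#' essentially cleared and the remaining dynamics (first-order transitions
#' and free diffusion with mirror reflection, which is exact at any step) are
#' insensitive to the step, so a coarser step is used there. Binding radii
#' are recalibrated for each step size. One RNG stream spans all phases, and
#' the chained segments are returned as a single run.
#'
#' @inheritParams simulate_model
#' @param pulses `list(times=, ions=)` instantaneous additions at the source
#' @param t_end total simulated time, s
#' @param dt_active,dt_quiet time steps during/after a pulse and between
#'   pulses, s
#' @param active_window length of the fine-step window after each pulse, s
#' @param cms optional list of two precompiled models (active, quiet)
#' @return an `hs_run`
#' @export
simulate_pulsed <- function(model, pulses, t_end, dt_active = 4e-6,
                            dt_quiet = 2e-5, active_window = 0.06,
                            seed = NULL, record_interval = 1e-3,
                            influx_species = "ca", events = TRUE,
                            cms = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cms))
    cms <- list(active = compile_model(model, dt_active),
                quiet = compile_model(model, dt_quiet, radii = TRUE))
  # phase boundaries: [pulse, pulse+active_window] fine; else coarse
  bounds <- sort(unique(c(0, pulses$times,
                          pmin(pulses$times + active_window, t_end), t_end)))
  bounds <- bounds[bounds <= t_end]
  state <- build_world(model)
  runs <- list()
  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    active <- any(pulses$times <= t0 + 1e-12 &
                    t0 < pulses$times + active_window - 1e-12)
    dt <- if (active) dt_active else dt_quiet
    cm <- if (active) cms$active else cms$quiet
    seg_pulse <- pulses$times >= t0 - 1e-12 & pulses$times < t0 + dt
    influx <- if (any(seg_pulse))
      list(times = rep(0, sum(seg_pulse)), ions = pulses$ions[seg_pulse])
    else NULL
    seg <- simulate_model(model, t_end = t1 - t0, dt = dt, seed = NULL,
                          record_interval = record_interval, influx = influx,
                          influx_species = influx_species, events = events,
                          init_state = state, cm = cm, strict = FALSE)
    seg$counts$time <- seg$counts$time + t0
    seg$events$time <- seg$events$time + t0
    state <- seg$state
    runs[[k]] <- seg
  }
  out <- runs[[length(runs)]]
  out$counts <- do.call(rbind, lapply(seq_along(runs), function(k)
    if (k == 1) runs[[k]]$counts else runs[[k]]$counts[-1, , drop = FALSE]))
  out$events <- do.call(rbind, lapply(runs, `[[`, "events"))
  led <- runs[[1]]$ledger
  for (k in 2:length(runs)) {
    led$influx_added <- led$influx_added + runs[[k]]$ledger$influx_added
    led$absorbed <- led$absorbed + runs[[k]]$ledger$absorbed
    led$removed <- led$removed + runs[[k]]$ledger$removed
    led$influx <- led$influx + runs[[k]]$ledger$influx
  }
  led$final <- runs[[length(runs)]]$ledger$final
  led$balance <- led$initial + led$influx - led$absorbed - led$removed -
    led$final
  led$balanced <- all(led$balance == 0)
  out$ledger <- led
  out$manifest$engine <- "spatial-pulsed"
  out
}
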