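#' Default gating parameters for the voltage-gated Ca2+ channel
#'
#' Hodgkin-Huxley style activation with half-activation voltage -15 mV and
#' slope 8 mV; the time-constant expression uses the coefficient set
#' (0.06 base; 4, 0.75, 0.45, 0.55) with tau in milliseconds.
#' @return list with `V_half` (mV), `slope` (mV) and tau coefficients
#' @export
gating_params <- function() {
  list(V_half = -15, slope = 8,
       tau_base = 0.06, tau_num = 4 * 0.75 * 0.45 * 0.55,
       tau_a = 0.55, tau_b = 0.45)
}

#' Steady-state activation of the Ca2+ channel
#'
#' `n_inf(V) = 1 / (1 + exp(-(V - V_half)/slope))`.
#'
#' @param V membrane potential, mV (vectorised)
#' @param params gating parameters, see [gating_params()]
#' @return dimensionless activation in (0, 1)
#' @export
n_inf <- function(V, params = gating_params()) {
  1 / (1 + exp(-(V - params$V_half) / params$slope))
}

#' Voltage-dependent activation time constant
#'
#' `tau_n(V) = 0.06 + 0.7425 / (exp((V - V_half) * 0.55 / slope) +
#' exp(-(V - V_half) * 0.45 / slope))` in milliseconds.
#'
#' @inheritParams n_inf
#' @return time constant in ms
#' @examples
#' tau_n(-15)  # 0.43125 ms
#' @export
tau_n <- function(V, params = gating_params()) {
  u <- V - params$V_half
  params$tau_base + params$tau_num /
    (exp(u * params$tau_a / params$slope) + exp(-u * params$tau_b / params$slope))
}

#' Advance a bank of two-state channels by one time step
#'
#' Each channel opens with probability `1 - exp(-rate_open * dt)` and closes
#' with probability `1 - exp(-rate_close * dt)`, where
#' `rate_open = n_inf / tau_n` and `rate_close = (1 - n_inf) / tau_n`.
#'
#' @param open logical vector of current channel states (TRUE = open)
#' @param V membrane potential at this step, mV
#' @param dt time step in ms (same unit as `tau_n`)
#' @param params gating parameters
#' @return updated logical vector
#' @export
gate_step <- function(open, V, dt, params = gating_params()) {
  stopifnot(dt >= 0)
  ni <- n_inf(V, params); tn <- tau_n(V, params)
  p_open <- 1 - exp(-(ni / tn) * dt)
  p_close <- 1 - exp(-((1 - ni) / tn) * dt)
  u <- stats::runif(length(open))
  ifelse(open, u >= p_close, u < p_open)
}

#' Default single-channel / GHK current parameters
#'
#' Single-channel conductance 5 pS with RT/zF = 12 mV; GHK permeability
#' 0.241e-3 cm/s over a 1 um^2 membrane patch, [Ca]out = 2 mM,
#' [Ca]in = 50 nM, valence 2.
#' @return list of parameters
#' @export
current_params <- function() {
  list(g_pS = 5, RT_zF = 12, P_cm_s = 0.241e-3,
       Ca_out_mM = 2, Ca_in_nM = 50, area_um2 = 1, z = 2)
}

#' Single-channel Ca2+ current
#'
#' `i_ca(V) = -g (V - Vs) exp(-(V-Vs)/(RT/zF)) / (1 - exp(-(V-Vs)/(RT/zF)))`
#' in pA, with the removable singularity at `V = Vs` evaluated by its limit
#' `-g * RT/zF`.
#'
#' @param V membrane potential, mV (vectorised)
#' @param V_s offset potential, mV
#' @param params current parameters, see [current_params()]
#' @return current in pA (negative = inward)
#' @export
single_channel_current <- function(V, V_s = -1.91, params = current_params()) {
  u <- (V - V_s) / params$RT_zF
  out <- -params$g_pS * 1e-3 * (V - V_s) * exp(-u) / (1 - exp(-u))
  out[abs(u) < 1e-9] <- -params$g_pS * 1e-3 * params$RT_zF
  out
}

#' Goldman-Hodgkin-Katz Ca2+ current for a membrane patch
#'
#' Constant-field current density
#' `P z^2 F^2 V / (RT) * ([Ca]in - [Ca]out exp(-zVF/RT)) / (1 - exp(-zVF/RT))`
#' scaled to the patch area. The exponent `zVF/RT` is expressed through the
#' same RT/zF (mV) as the single-channel expression.
#'
#' @inheritParams single_channel_current
#' @return total current over the patch in pA
#' @export
ghk_current <- function(V, params = current_params()) {
  FARADAY <- 96485
  u <- V / params$RT_zF
  cai <- params$Ca_in_nM * 1e-9 * 1e-3   # mol/cm^3
  cao <- params$Ca_out_mM * 1e-3 * 1e-3
  dens <- params$P_cm_s * params$z * FARADAY * u *
    (cai - cao * exp(-u)) / (1 - exp(-u))      # A/cm^2
  dens[abs(u) < 1e-9] <- params$P_cm_s * params$z * FARADAY * (cai - cao)
  dens * params$area_um2 * 1e-8 * 1e12         # pA over the patch
}

#' Fit the number of channels and offset potential to the GHK current
#'
#' Fits `N * i_ca(V; Vs)` to the GHK patch current by least squares with `N`
#' constrained to an integer: for each candidate `N` the offset `Vs` is
#' profiled out by one-dimensional optimisation, and the `N` with the smallest
#' residual sum of squares is reported. The default voltage range spans the
#' physiological excursion from strong hyperpolarization to the action
#' potential peak; the fitted `Vs` is range-sensitive (see the methods
#' vignette) while `N` is stable.
#'
#' @param params current parameters, see [current_params()]
#' @param V_range fit range in mV, default `c(-100, 50)`
#' @param dV voltage grid spacing, mV
#' @param N_max largest channel count considered
#' @return list with integer `N`, `V_s` (mV), the real-valued unconstrained
#'   `N_free`, and the residual sum of squares `sse`
#' @export
fit_channel_number <- function(params = current_params(),
                               V_range = c(-100, 50), dV = 1, N_max = 100) {
  V <- seq(V_range[1], V_range[2], by = dV)
  I <- ghk_current(V, params)
  if (max(abs(I)) < 1e-12) stop("degenerate fit: GHK current is flat over the range")
  sse_for <- function(N) {
    o <- stats::optimize(function(Vs)
      sum((I - N * single_channel_current(V, Vs, params))^2), c(-40, 40))
    c(o$objective, o$minimum)
  }
  # unconstrained profile fit for reference
  o_free <- stats::optimize(function(Vs) {
    b <- single_channel_current(V, Vs, params)
    sum((I - (sum(I * b) / sum(b * b)) * b)^2)
  }, c(-40, 40))
  b <- single_channel_current(V, o_free$minimum, params)
  N_free <- sum(I * b) / sum(b * b)
  cand <- max(1, floor(N_free - 3)):min(N_max, ceiling(N_free + 3))
  fits <- vapply(cand, sse_for, numeric(2))
  best <- which.min(fits[1, ])
  list(N = cand[best], V_s = fits[2, best], N_free = N_free, sse = fits[1, best])
}

#' Ions entering through an open channel in one time step
#'
#' Expected count `|i_ca| * dt / (z e)` converted to an integer by stochastic
#' rounding (floor plus a Bernoulli draw on the fractional part), so the mean
#' equals the expectation exactly.
#'
#' @param i_ca single-channel current, pA (scalar or vector)
#' @param dt time step in seconds
#' @param z ion valence (2 for Ca2+)
#' @return integer ion count(s)
#' @export
ions_per_step <- function(i_ca, dt, z = 2) {
  stopifnot(dt > 0)
  e_charge <- 1.602176634e-19
  mu <- abs(i_ca) * 1e-12 * dt / (z * e_charge)
  fl <- floor(mu)
  as.integer(fl + (stats::runif(length(mu)) < (mu - fl)))
}

#' Generate a synthetic theta-burst voltage trace
#'
#' A stereotyped action-potential waveform (biexponential spike from a resting
#' potential to a fixed peak, ~2 ms width) placed at theta-burst times:
#' `n_pulses` spikes at `intra_freq` within a burst, `n_bursts` bursts at
#' `burst_freq`. This is a synthetic stand-in for a compartmental-model soma
#' recording.
#'
#' @param burst_freq burst repetition frequency, Hz (5 or 10 for theta-burst)
#' @param n_bursts number of bursts (default 5)
#' @param n_pulses spikes per burst (default 5)
#' @param intra_freq within-burst spike frequency, Hz (default 100)
#' @param dt_ms trace resolution, ms
#' @param t_end_ms trace duration, ms (default: covers all bursts + 200 ms tail)
#' @param V_rest resting potential, mV
#' @param V_peak spike peak, mV
#' @param amplitude spike amplitude scale in \[0, 1\] (0 = no spikes)
#' @return data.frame with columns `time_ms`, `V_mV`; class `voltage_trace`
#' @export
generate_voltage_trace <- function(burst_freq = 5, n_bursts = 5, n_pulses = 5,
                                   intra_freq = 100, dt_ms = 0.1, t_end_ms = NULL,
                                   V_rest = -65, V_peak = 30, amplitude = 1) {
  burst_t <- (seq_len(n_bursts) - 1) * 1000 / burst_freq
  spike_t <- as.vector(outer((seq_len(n_pulses) - 1) * 1000 / intra_freq, burst_t, `+`))
  if (is.null(t_end_ms)) t_end_ms <- max(spike_t) + 200
  tt <- seq(0, t_end_ms, by = dt_ms)
  V <- rep(V_rest, length(tt))
  # biexponential AP template: fast rise (0.2 ms), slower decay (0.8 ms)
  tau_r <- 0.2; tau_d <- 0.8
  tpl_t <- seq(0, 6, by = dt_ms)
  tpl <- exp(-tpl_t / tau_d) - exp(-tpl_t / tau_r)
  tpl <- tpl / max(tpl)
  for (ts in spike_t) {
    i0 <- which.min(abs(tt - ts))
    idx <- i0:min(length(tt), i0 + length(tpl) - 1L)
    V[idx] <- pmax(V[idx], V_rest + amplitude * (V_peak - V_rest) * tpl[seq_along(idx)])
  }
  structure(data.frame(time_ms = tt, V_mV = V), class = c("voltage_trace", "data.frame"))
}

#' Generate a stochastic Ca2+ influx trace from a voltage trace
#'
#' Runs `n_channels` independent two-state channels along the voltage trace
#' ([gate_step()]) and draws ion entries per open channel and step
#' ([ions_per_step()]).
#'
#' @param vtrace a `voltage_trace` (data.frame `time_ms`, `V_mV`)
#' @param n_channels number of co-located channels (default 16)
#' @param V_s offset potential for the single-channel current, mV
#' @param gparams,cparams gating / current parameter lists
#' @return data.frame `time_ms`, `ions`; class `influx_trace`, attribute
#'   `total` = sum of entries
#' @export
generate_influx_trace <- function(vtrace, n_channels = 16, V_s = -1.91,
                                  gparams = gating_params(), cparams = current_params()) {
  tt <- vtrace$time_ms; V <- vtrace$V_mV
  dt_ms <- tt[2] - tt[1]
  open <- rep(FALSE, n_channels)
  ions <- integer(length(tt))
  for (i in seq_along(tt)) {
    open <- gate_step(open, V[i], dt_ms, gparams)
    n_open <- sum(open)
    if (n_open > 0) {
      ica <- single_channel_current(V[i], V_s, cparams)
      ions[i] <- sum(ions_per_step(rep(ica, n_open), dt_ms * 1e-3))
    }
  }
  structure(data.frame(time_ms = tt, ions = ions),
            class = c("influx_trace", "data.frame"), total = sum(ions))
}

#' Generate matched influx trace pairs for two burst frequencies
#'
#' Draws `n_trials` stochastic influx traces for each of two theta-burst
#' frequencies and returns the cross-frequency pair whose total ion counts
#' are closest, so frequency comparisons are not confounded by total influx.
#'
#' @param freqs the two burst frequencies, Hz (default `c(5, 10)`)
#' @param n_trials trials per frequency (default 40)
#' @param n_channels channels per trace
#' @param ... further arguments to [generate_voltage_trace()]
#' @return list with elements named by frequency (`influx_trace`s), plus
#'   `totals` and `rel_diff` (relative total mismatch)
#' @export
generate_influx_ensemble <- function(freqs = c(5, 10), n_trials = 40,
                                     n_channels = 16, ...) {
  stopifnot(length(freqs) == 2)
  # equal observation windows for both frequencies, so the spontaneous
  # (resting) influx contributes equally and totals are comparable
  t_end <- max(vapply(freqs, function(f)
    (5 - 1) * 1000 / f + (5 - 1) * 10 + 200, numeric(1)))
  traces <- lapply(freqs, function(f) {
    vt <- generate_voltage_trace(burst_freq = f, t_end_ms = t_end, ...)
    lapply(seq_len(n_trials), function(i) generate_influx_trace(vt, n_channels))
  })
  tot1 <- vapply(traces[[1]], attr, numeric(1), "total")
  tot2 <- vapply(traces[[2]], attr, numeric(1), "total")
  d <- abs(outer(tot1, tot2, `-`))
  ij <- arrayInd(which.min(d), dim(d))
  pick <- list(traces[[1]][[ij[1]]], traces[[2]][[ij[2]]])
  names(pick) <- paste0(freqs, "Hz")
  pick$totals <- c(tot1[ij[1]], tot2[ij[2]])
  pick$rel_diff <- abs(diff(pick$totals)) / max(pick$totals)
  pick
}

#' Write / read two-column plain-text traces
#'
#' Traces are stored as two whitespace-separated columns (time in ms, value)
#' with `#`-prefixed header lines carrying provenance (seed, parameters).
#'
#' @param trace a `voltage_trace` or `influx_trace`
#' @param path output file
#' @param header named character vector written as `# key: value` lines
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header)) writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  utils::write.table(trace, con, row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param what `"voltage"` or `"influx"`
#' @export
read_trace <- function(path, what = c("voltage", "influx")) {
  what <- match.arg(what)
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  cls <- if (what == "voltage") "voltage_trace" else "influx_trace"
  out <- structure(df, class = c(cls, "data.frame"))
  if (what == "influx") attr(out, "total") <- sum(df[[2]])
  out
}
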