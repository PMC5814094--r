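# Binding-radius calibration for fixed-time-step Brownian dynamics.
#
# A second-order rule fires when a reactant pair falls within its binding
# radius sigma_b after a diffusion step. The steady-state rate constant of
# that algorithm depends on sigma_b, the mutual diffusion coefficient and the
# time step; sigma_b is chosen by numerically inverting that relation so the
# simulation reproduces the requested mass-action k_on.
#
# Dimensional reduction: with s = sqrt(2 D dt) (per-axis rms of the relative
# coordinate) the absorbed volume per step is sigma^3 * f(s/sigma), so the
# dimensionless function f is computed once per step-ratio and cached.

.radius_cache <- new.env(parent = emptyenv())

# steady-state absorbed volume per step for sigma = 1, rms step x (>= 0.2):
# radial pair density iterated under Gaussian propagation + absorption inside
# r < 1, far field clamped to density 1.
.reduced_absorption <- function(x, tol = 1e-5, max_iter = 4000) {
  key <- sprintf("f%.6g", x)
  if (!is.null(.radius_cache[[key]])) return(.radius_cache[[key]])
  s <- x
  R1 <- 1 + 5 * s          # clamp zone start
  R2 <- 1 + 8 * s          # outer edge
  dr <- min(s, 1) / 8
  r <- seq(dr / 2, R2, by = dr)
  n <- length(r)
  # radial propagator: probability that a pair at radius r_j is at r_i after
  # one step (mass form, rows = destination)
  M <- outer(r, r, function(ri, rj)
    (ri / (rj * s * sqrt(2 * pi))) *
      (exp(-(ri - rj)^2 / (2 * s^2)) - exp(-(ri + rj)^2 / (2 * s^2)))) * dr
  shell <- 4 * pi * r^2 * dr
  inside <- r < 1
  clamp <- r >= R1
  m <- shell
  m[inside] <- 0
  absorbed_prev <- -1
  absorbed <- 0
  for (it in seq_len(max_iter)) {
    m <- as.vector(M %*% m)
    absorbed <- sum(m[inside])
    m[inside] <- 0
    m[clamp] <- shell[clamp]
    if (absorbed_prev > 0 &&
        abs(absorbed - absorbed_prev) < tol * absorbed) break
    absorbed_prev <- absorbed
  }
  .radius_cache[[key]] <- absorbed
  absorbed
}

# the reduced function is smooth in log-log space; evaluating it on a fixed
# logarithmic grid (16 nodes per decade) and interpolating keeps radius
# inversion cheap no matter how many rates are calibrated
.reduced_absorption_interp <- function(x) {
  k <- floor(16 * log10(x))
  x1 <- 10^(k / 16); x2 <- 10^((k + 1) / 16)
  f1 <- .reduced_absorption(x1); f2 <- .reduced_absorption(x2)
  w <- (log(x) - log(x1)) / (log(x2) - log(x1))
  exp((1 - w) * log(f1) + w * log(f2))
}

# absorbed volume per step at binding radius sigma (um), rms step s (um)
.absorbed_volume <- function(sigma, s) {
  x <- s / sigma
  if (x > 60) {
    # ballistic limit: the sphere interior is refilled every step
    (4 / 3) * pi * sigma^3
  } else {
    sigma^3 * .reduced_absorption_interp(x)
  }
}

#' Effective mass-action rate of the fixed-step binding algorithm
#'
#' The steady-state rate constant (um^3/s) realised by a simulation that binds
#' any reactant pair closer than `sigma` after a Gaussian displacement step.
#' Used by [binding_radius()] for inversion; exposed for calibration checks.
#' In the small-step limit it approaches the Smoluchowski diffusion-limited
#' rate `4 pi sigma D`; in the large-step limit it approaches
#' `(4/3) pi sigma^3 / dt`.
#'
#' @param sigma binding radius, um
#' @param D_mutual mutual diffusion coefficient (sum over the pair), cm^2/s
#' @param dt time step, s
#' @return rate constant in um^3 s^-1
#' @export
simulated_binding_rate <- function(sigma, D_mutual, dt) {
  stopifnot(sigma >= 0, D_mutual >= 0, dt > 0)
  if (sigma == 0) return(0)
  D <- D_to_um2(D_mutual)
  s <- sqrt(2 * D * dt)
  if (s < 0.2 * sigma) return(4 * pi * sigma * D)  # diffusion-limited regime
  .absorbed_volume(sigma, s) / dt
}

#' Calibrate the binding radius for a second-order rate constant
#'
#' Numerically inverts the reduced-rate relation of the fixed-time-step
#' binding algorithm so that a well-mixed simulation using the returned radius
#' reproduces mass-action kinetics at rate `k_on`.
#'
#' @param k_on second-order rate constant, uM^-1 s^-1
#' @param D_mutual mutual diffusion coefficient of the pair, cm^2/s
#' @param dt simulation time step, s
#' @return binding radius in nm
#' @examples
#' binding_radius(0, 2.2e-6, 1e-6)  # 0
#' @export
binding_radius <- function(k_on, D_mutual, dt) {
  if (!all(is.finite(c(k_on, D_mutual, dt)))) stop("non-finite inputs")
  stopifnot(k_on >= 0, D_mutual >= 0, dt > 0)
  if (k_on == 0) return(0)
  kv <- kon_to_volume_rate(k_on)           # um^3/s
  sigma0 <- (3 * kv * dt / (4 * pi))^(1 / 3)  # ballistic-limit guess
  D <- D_to_um2(D_mutual)
  if (D == 0) return(sigma0 * 1e3)
  if (kv >= 4 * pi * sigma0 * D) {
    # requested rate at or beyond the diffusion limit for this radius scale
    sigma0 <- max(sigma0, kv / (4 * pi * D))
  }
  f <- function(sg) simulated_binding_rate(sg, D_mutual, dt) - kv
  lo <- sigma0 / 4
  hi <- sigma0 * 4
  while (f(lo) > 0 && lo > sigma0 / 64) lo <- lo / 2
  while (f(hi) < 0 && hi < sigma0 * 64) hi <- hi * 2
  sg <- stats::uniroot(f, c(lo, hi), tol = sigma0 * 1e-4)$root
  sg * 1e3                                  # nm
}
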