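#' Avogadro constant used throughout the package
#'
#' `6.02e23`, the value that reproduces the standard count/concentration
#' conversions for femtolitre-scale reaction volumes (e.g. 3000 molecules in a
#' 500 nm cube = 39.867 uM).
#' @export
AVOGADRO <- 6.02e23

# molecules per um^3 at 1 uM, with AVOGADRO as above (= 602.0)
.per_um3_per_uM <- AVOGADRO * 1e-6 / 1e15

#' Convert a molecule count to a concentration
#'
#' @param count number of molecules (>= 0)
#' @param volume reaction volume in um^3
#' @return concentration in uM
#' @examples
#' count_to_concentration(3000, 0.5^3)  # 39.867 uM
#' @export
count_to_concentration <- function(count, volume) {
  stopifnot(all(count >= 0), volume > 0)
  count / (volume * .per_um3_per_uM)
}

#' Convert a concentration to a molecule count
#'
#' @param conc concentration in uM
#' @param volume reaction volume in um^3
#' @param round round to the nearest integer count (default TRUE)
#' @return molecule count
#' @export
concentration_to_count <- function(conc, volume, round = TRUE) {
  stopifnot(all(conc >= 0), volume > 0)
  n <- conc * volume * .per_um3_per_uM
  if (round) round(n) else n
}

#' Convert a second-order rate constant to volume units
#'
#' `uM^-1 s^-1` to `um^3 s^-1` (per molecule pair), the unit the particle
#' engine and SSA propensities work in.
#' @param k_uMs rate constant in uM^-1 s^-1
#' @return rate in um^3 s^-1
#' @export
kon_to_volume_rate <- function(k_uMs) k_uMs / .per_um3_per_uM

#' Convert a diffusion coefficient from cm^2/s to um^2/s
#' @param D_cm2 diffusion coefficient, cm^2/s
#' @return um^2/s
#' @export
D_to_um2 <- function(D_cm2) D_cm2 * 1e8
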