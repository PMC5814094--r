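# Reaction-regime classification: decomposition of a measured on-rate into
# encounter and activation steps, 1/k_on = 1/k_enc + 1/k_a.

#' Classify a second-order reaction as activation- or diffusion-limited
#'
#' The encounter rate is the Smoluchowski rate at the encounter radius,
#' `k_enc = 4 pi sigma_enc D_mutual`; the intrinsic activation rate follows
#' from `1/k_on = 1/k_enc + 1/k_a`. A reaction is activation-limited when
#' the activation step is rate-limiting (`k_a / k_on` below the threshold);
#' `k_on >= k_enc` leaves `k_a` undefined and flags the reaction
#' diffusion-limited.
#'
#' @param k_on measured on-rate, uM^-1 s^-1
#' @param D_mutual mutual diffusion coefficient of the pair, cm^2/s
#' @param sigma_enc encounter radius, nm (default 5, a typical protein
#'   encounter distance; configurable)
#' @param threshold classification threshold on `k_a / k_on` (default 10)
#' @return list: `k_on`, `k_enc` (uM^-1 s^-1), `k_a`, `ratio`,
#'   `classification`
#' @export
regime_classify <- function(k_on, D_mutual, sigma_enc = 5, threshold = 10) {
  stopifnot(k_on >= 0, D_mutual >= 0, sigma_enc > 0)
  k_enc_vol <- 4 * pi * (sigma_enc * 1e-3) * D_to_um2(D_mutual)  # um^3/s
  k_enc <- k_enc_vol / kon_to_volume_rate(1)                     # uM^-1 s^-1
  if (k_on >= k_enc) {
    return(list(k_on = k_on, k_enc = k_enc, k_a = NA_real_, ratio = Inf,
                classification = "diffusion-limited"))
  }
  k_a <- if (k_on == 0) 0 else 1 / (1 / k_on - 1 / k_enc)
  ratio <- if (k_on == 0) 1 else k_a / k_on
  list(k_on = k_on, k_enc = k_enc, k_a = k_a, ratio = ratio,
       classification = if (ratio < threshold) "activation-limited"
       else "intermediate")
}

#' Regime report for every second-order rule of a model
#'
#' @param model an [hs_model()]
#' @param sigma_enc encounter radius, nm
#' @param D_scale multiplier on all diffusion coefficients (e.g. 0.5 to test
#'   the halved-diffusion condition)
#' @return data.frame: one row per directed binding rule
#' @export
regime_report <- function(model, sigma_enc = 5, D_scale = 1) {
  o2 <- Filter(function(r) r$order == 2L,
               directed_rules(model$rules, model$molecules))
  rows <- lapply(o2, function(r) {
    Dm <- D_scale * (model$molecules[[r$typeA]]$diffusion_coeff +
                       model$molecules[[r$typeB]]$diffusion_coeff)
    cl <- regime_classify(r$rate, Dm, sigma_enc)
    data.frame(label = r$label, k_on = cl$k_on, k_enc = cl$k_enc,
               k_a = cl$k_a, ratio = cl$ratio,
               classification = cl$classification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
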