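# Ring complexes (holoenzymes): geometry, neighbour-conditional
# phosphorylation eligibility, and the exact steady-state oracle for the
# directed ring phosphorylation (jamming) process.

#' Declare a ring-complex template
#'
#' Subunits are placed equally spaced on a circle of the given radius, in the
#' xy-plane. With the default 6-subunit ring the chord between adjacent
#' subunits equals the radius, so "radius 8 nm, neighbours separated by 8 nm"
#' holds exactly; for other subunit counts the neighbour spacing follows from
#' the circle geometry. The left neighbour of subunit `i` is subunit
#' `(i - 1) mod n` (phosphorylation direction is fixed left-to-right).
#'
#' @param n_subunits number of subunits (>= 2)
#' @param radius_nm ring radius in nm (default 8)
#' @param type subunit molecule type name
#' @param mobile rings are immobilized by default (cytoskeleton-attached)
#' @return a `ring_template`
#' @export
ring_template <- function(n_subunits, radius_nm = 8, type = "K",
                          mobile = FALSE) {
  stopifnot(n_subunits >= 2, radius_nm > 0)
  if (mobile) stop("mobile ring complexes are not supported; holoenzymes are ",
                   "modeled as immobilized")
  structure(list(n = as.integer(n_subunits), radius_nm = radius_nm,
                 type = type, mobile = mobile), class = "ring_template")
}

#' Subunit positions for one ring instance
#'
#' @param template a [ring_template()]
#' @param center ring centre, um (length 3)
#' @param phase rotation angle about the z axis, radians
#' @return n x 3 matrix of positions in um
#' @export
build_ring <- function(template, center, phase = 0) {
  r <- template$radius_nm * 1e-3
  th <- phase + 2 * pi * (seq_len(template$n) - 1) / template$n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th),
        rep(center[3], template$n))
}

#' Phosphorylation eligibility of a ring subunit
#'
#' @param cam_bound,phos logical vectors over the ring's subunits (CaM bound;
#'   phosphorylated), in ring index order
#' @param i subunit index (1-based)
#' @param variant kinase rule variant: `"default_neighbor"` (left neighbour
#'   activated = CaM-bound or autonomously phosphorylated),
#'   `"ml_no_phospho_kinase"` (left neighbour must be CaM-bound and
#'   unphosphorylated), `"scheme1_NxC2_only"` / `"scheme2_N2Cx_only"` (as
#'   default but the bound CaM state must lie in the scheme's set; supply
#'   `cam_state`)
#' @param cam_state optional character vector of bound-CaM states (`"NxCy"`)
#'   used by the scheme variants
#' @return logical: can subunit `i` be phosphorylated now
#' @export
phospho_condition <- function(cam_bound, phos, i,
                              variant = c("default_neighbor",
                                          "ml_no_phospho_kinase",
                                          "scheme1_NxC2_only",
                                          "scheme2_N2Cx_only"),
                              cam_state = NULL) {
  variant <- match.arg(variant)
  n <- length(cam_bound)
  li <- ((i - 2) %% n) + 1   # left neighbour
  self_ok <- cam_bound[i] && !phos[i]
  if (!self_ok) return(FALSE)
  left_ok <- switch(variant,
    ml_no_phospho_kinase = cam_bound[li] && !phos[li],
    cam_bound[li] || phos[li])
  if (!left_ok) return(FALSE)
  if (variant == "scheme1_NxC2_only")
    return(grepl("^N[012]C2$", cam_state[i]))
  if (variant == "scheme2_N2Cx_only")
    return(grepl("^N2C[012]$", cam_state[i]))
  TRUE
}

#' Exact steady-state phosphorylated fraction of a saturated ring
#'
#' Under saturating CaM with the no-phosphorylated-kinase rule, subunit `i`
#' can be phosphorylated only while its left neighbour is still
#' unphosphorylated; the process jams when no eligible subunit remains. All
#' eligible subunits fire at the same rate, so the embedded jump chain picks
#' uniformly among them. This computes the exact expected final fraction by
#' dynamic programming over the 2^n ring configurations (n <= 16), the
#' quantity a closed-system multi-subunit simulation must converge to
#' (1/2 for dimers, 2/3 for trimers, approaching 1 - exp(-1)).
#'
#' @param n number of subunits (2..16 for the exact mode)
#' @return expected phosphorylated fraction at steady state
#' @export
ring_phospho_steady_fraction <- function(n) {
  stopifnot(n >= 2)
  if (n > 16) stop("exact mode limited to n <= 16; use sample_ring_jam()")
  memo <- rep(NA_real_, bitwShiftL(1L, n))
  left_of <- c(n, seq_len(n - 1))          # left neighbour of i
  bit <- bitwShiftL(1L, 0:(n - 1))
  rec <- function(mask) {
    got <- memo[mask + 1]
    if (!is.na(got)) return(got)
    elig <- which(bitwAnd(mask, bit) == 0L &
                    bitwAnd(mask, bit[left_of]) == 0L)
    if (length(elig) == 0) {
      v <- sum(bitwAnd(mask, bit) > 0) / n
    } else {
      v <- mean(vapply(elig, function(i) rec(bitwOr(mask, bit[i])),
                       numeric(1)))
    }
    memo[mask + 1] <<- v
    v
  }
  rec(0L)
}

#' Monte-Carlo jamming fraction for large rings
#'
#' Samples the directed ring phosphorylation process (uniform choice among
#' eligible subunits until jammed) for rings too large for the exact DP.
#'
#' @param n ring size
#' @param n_rings number of independent rings sampled
#' @return mean phosphorylated fraction across rings
#' @export
sample_ring_jam <- function(n, n_rings = 100) {
  left_of <- c(n, seq_len(n - 1))
  fr <- vapply(seq_len(n_rings), function(rep) {
    p <- logical(n)
    repeat {
      elig <- which(!p & !p[left_of])
      if (length(elig) == 0) return(mean(p))
      p[elig[sample.int(length(elig), 1)]] <- TRUE
    }
  }, numeric(1))
  mean(fr)
}
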