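#' Count rotationally distinct ring states (necklaces)
#'
#' Number of equivalence classes of length-`n` strings over `k` symbols under
#' rotation, computed with Burnside's lemma:
#' \deqn{N(n,k) = \frac{1}{n} \sum_{d | n} \varphi(d)\, k^{n/d}.}
#' For a ring-shaped holoenzyme of `n` subunits with `k` states per subunit
#' this is the number of distinct species the ring can form.
#'
#' @param n number of beads (ring subunits), >= 1
#' @param k number of colours (states per subunit), >= 1
#' @return integer-valued count (as a double; exact for counts below 2^53)
#' @examples
#' necklace_count(6, 4)   # 700
#' necklace_count(6, 20)  # 10668140
#' @export
necklace_count <- function(n, k) {
  stopifnot(length(n) == 1, length(k) == 1)
  if (n < 1 || k < 1 || n != round(n) || k != round(k))
    stop("n and k must be positive integers")
  divs <- which((n %% seq_len(n)) == 0)
  tot <- sum(vapply(divs, function(d) .euler_phi(d) * k^(n / d), numeric(1)))
  tot / n
}

.euler_phi <- function(d) {
  sum(vapply(seq_len(d), function(i) as.numeric(.gcd(i, d) == 1L), numeric(1)))
}

.gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Enumerate canonical ring species
#'
#' Lists one representative (the lexicographically minimal rotation) per
#' rotational equivalence class of length-`n` strings over colours
#' `0..k-1`. Serves as a brute-force cross-check of [necklace_count()]; the
#' enumeration is guarded to small state spaces.
#'
#' @param n ring length
#' @param k number of colours
#' @return character vector of canonical representatives, length
#'   `necklace_count(n, k)`
#' @examples
#' enumerate_ring_species(2, 2)  # "00" "01" "11"
#' @export
enumerate_ring_species <- function(n, k) {
  stopifnot(n >= 1, k >= 1)
  if (k^n > 1e7) stop("state space k^n exceeds enumeration guard (1e7)")
  digits <- as.matrix(expand.grid(rep(list(0:(k - 1)), n))[, n:1, drop = FALSE])
  canon <- apply(digits, 1, function(s) {
    rots <- vapply(seq_len(n), function(i)
      paste(s[((seq_len(n) + i - 2L) %% n) + 1L], collapse = ","), character(1))
    min(rots)
  })
  reps <- sort(unique(canon))
  if (k <= 10) gsub(",", "", reps, fixed = TRUE) else reps
}
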