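# Model assembly: molecules + rules + rates + geometry + initial contents.

#' Box geometry with per-face boundary behaviour
#'
#' The box has its origin at a corner; `z = Lz` is the "top" (membrane) face.
#' Each face is `"reflect"`, `"periodic"` (must be paired with the opposite
#' face) or a partial-absorption spec created with [absorbing_face()].
#'
#' @param L box dimensions `c(Lx, Ly, Lz)` in um
#' @param xlo,xhi,ylo,yhi,zlo,zhi face behaviours
#' @return a `geometry` list
#' @export
box_geometry <- function(L, xlo = "reflect", xhi = "reflect",
                         ylo = "reflect", yhi = "reflect",
                         zlo = "reflect", zhi = "reflect") {
  stopifnot(length(L) == 3, all(L > 0))
  faces <- list(xlo = xlo, xhi = xhi, ylo = ylo, yhi = yhi,
                zlo = zlo, zhi = zhi)
  for (d in c("x", "y", "z")) {
    lo <- faces[[paste0(d, "lo")]]; hi <- faces[[paste0(d, "hi")]]
    if (identical(lo, "periodic") != identical(hi, "periodic"))
      stop("periodic faces must be paired on axis ", d)
  }
  structure(list(L = as.numeric(L), faces = faces), class = "geometry")
}

#' @rdname box_geometry
#' @param species character vector of molecule types the face absorbs; all
#'   other species reflect there
#' @param prob per-crossing absorption probability in \[0, 1\]
#' @export
absorbing_face <- function(species, prob = 1) {
  stopifnot(prob >= 0, prob <= 1)
  list(type = "absorb", species = species, prob = prob)
}

#' Assemble a runnable model
#'
#' @param name model name
#' @param molecules named list of [molecule_type()]
#' @param rules list of parsed rules (symbolic rates allowed)
#' @param rates named numeric vector resolving symbolic rate constants
#' @param geometry a [box_geometry()]
#' @param init list of initial-content entries: `list(type=, count=)` for
#'   uniformly placed free molecules, or `list(ring=, count=)` with a
#'   [ring_template()] for ring complexes
#' @param observables named list; each entry `list(type=, conds=)` with a
#'   condition data.frame (`target`, `via`, `site`, `value`)
#' @param edge_map optional data.frame (`label`, `from`, `to`, `family`,
#'   `layer`) mapping rule labels to network edges for history analysis
#' @return an `hs_model`
#' @export
hs_model <- function(name, molecules, rules, rates = numeric(), geometry,
                     init = list(), observables = list(), edge_map = NULL) {
  rules <- resolve_rates(rules, rates)
  structure(list(name = name, molecules = molecules, rules = rules,
                 rates = rates, geometry = geometry, init = init,
                 observables = observables, edge_map = edge_map),
            class = "hs_model")
}

#' @export
print.hs_model <- function(x, ...) {
  cat("<hs_model>", x$name, "\n")
  cat("  molecules:", paste(names(x$molecules), collapse = ", "), "\n")
  cat("  rules:", length(x$rules), " box:",
      paste(signif(x$geometry$L, 3), collapse = " x "), "um\n")
  invisible(x)
}

# observable condition helper
obs_conds <- function(...) {
  terms <- list(...)
  do.call(rbind, lapply(terms, function(t)
    data.frame(target = t[[1]], via = if (length(t) == 4) t[[2]] else NA_character_,
               site = t[[length(t) - 1]], value = as.integer(t[[length(t)]]),
               stringsAsFactors = FALSE)))
}

# resolve which molecule type binds at (type, site); needed to map partner
# condition site names to bit indices
partner_type_of <- function(directed, type, site) {
  o2 <- Filter(function(r) r$order == 2L, directed)
  cand <- unique(unlist(lapply(o2, function(r) {
    out <- character(0)
    if (r$typeA == type && r$bondA == site) out <- c(out, r$typeB)
    if (r$typeB == type && r$bondB == site) out <- c(out, r$typeA)
    out
  })))
  if (length(cand) == 0) return(NA_character_)
  if (length(cand) > 1)
    stop("site ", type, ".", site, " binds multiple types; partner conditions ",
         "would be ambiguous")
  cand
}
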