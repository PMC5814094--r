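# Expansion of a rule set into an explicit species/reaction network, for the
# well-mixed ODE oracle and the microscopic-reversibility audit. The expansion
# is what the particle engine avoids doing; it is guarded against the
# combinatorial explosion (max 1e4 species) and refuses ring complexes.

# cluster = list(mol = data.frame(type, state), bonds = data.frame(i, si, j, sj))
.cluster_singleton <- function(type, state) {
  list(mol = data.frame(type = type, state = as.integer(state),
                        stringsAsFactors = FALSE),
       bonds = data.frame(i = integer(0), si = integer(0), j = integer(0),
                          sj = integer(0)))
}

# canonical string of a (tree-shaped) cluster
.canon <- function(cl) {
  n <- nrow(cl$mol)
  if (n == 1)
    return(paste0(cl$mol$type[1], "[", cl$mol$state[1], "]"))
  adj <- vector("list", n)
  for (b in seq_len(nrow(cl$bonds))) {
    i <- cl$bonds$i[b]; j <- cl$bonds$j[b]
    adj[[i]] <- rbind(adj[[i]], c(cl$bonds$si[b], j))
    adj[[j]] <- rbind(adj[[j]], c(cl$bonds$sj[b], i))
  }
  rec <- function(v, parent) {
    kids <- character(0)
    if (!is.null(adj[[v]])) {
      for (r in seq_len(nrow(adj[[v]]))) {
        w <- adj[[v]][r, 2]
        if (w == parent) next
        kids <- c(kids, paste0(adj[[v]][r, 1], ":", rec(w, v)))
      }
    }
    paste0(cl$mol$type[v], "[", cl$mol$state[v], "]",
           if (length(kids)) paste0("(", paste(sort(kids), collapse = ","), ")")
           else "")
  }
  min(vapply(seq_len(n), function(v) rec(v, 0L), character(1)))
}

.site_bit <- function(sidx, type, site) sidx[[type]][[site]]

# evaluate a parse-format condition df for molecule m of a cluster
.cl_eval <- function(cl, m, conds, sidx) {
  if (is.null(conds) || nrow(conds) == 0) return(TRUE)
  for (i in seq_len(nrow(conds))) {
    tg <- conds$target[i]
    if (tg %in% c("left", "right")) return(FALSE)  # rings not expandable
    q <- m
    if (tg == "partner") {
      via <- .site_bit(sidx, cl$mol$type[m], conds$via[i])
      hit <- which((cl$bonds$i == m & cl$bonds$si == via) |
                     (cl$bonds$j == m & cl$bonds$sj == via))
      if (length(hit) == 0) {
        if (conds$value[i] != 0) return(FALSE)
        next
      }
      q <- if (cl$bonds$i[hit] == m) cl$bonds$j[hit] else cl$bonds$i[hit]
    }
    sb <- .site_bit(sidx, cl$mol$type[q], conds$site[i])
    if (bitwAnd(bitwShiftR(cl$mol$state[q], sb), 1L) != conds$value[i])
      return(FALSE)
  }
  TRUE
}

.setbit <- function(state, bit, v)
  if (v) bitwOr(state, bitwShiftL(1L, bit)) else
    bitwAnd(state, bitwNot(bitwShiftL(1L, bit)))

# split a cluster into connected components (after an unbind)
.components <- function(cl) {
  n <- nrow(cl$mol)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (b in seq_len(nrow(cl$bonds))) {
      i <- cl$bonds$i[b]; j <- cl$bonds$j[b]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(cc) {
    keep <- which(comp == cc)
    remap <- match(seq_len(n), keep)
    bsel <- cl$bonds$i %in% keep & cl$bonds$j %in% keep
    list(mol = cl$mol[keep, , drop = FALSE],
         bonds = data.frame(i = remap[cl$bonds$i[bsel]],
                            si = cl$bonds$si[bsel],
                            j = remap[cl$bonds$j[bsel]],
                            sj = cl$bonds$sj[bsel]))
  })
}

#' Expand a rule set into an explicit reaction network
#'
#' Breadth-first closure over reachable species (bonded clusters in canonical
#' form) under the model's directed rules. Refuses models with ring-neighbour
#' conditions and stops at `max_species` (the guard against the combinatorial
#' explosion the particle engine is designed to avoid).
#'
#' @param model an [hs_model()] without ring complexes
#' @param max_species expansion guard (default 1e4)
#' @return list with `species` (canonical names), `reactions` (data.frame:
#'   `r1`, `r2`, products `p1`, `p2`, `rate`, `label`, `dir`, `mult`),
#'   `composition` (species x molecule-type count matrix)
#' @export
expand_network <- function(model, max_species = 1e4) {
  mols <- model$molecules
  sidx <- .site_index(mols)
  directed <- directed_rules(model$rules, mols)
  default_state <- vapply(mols, function(m)
    sum(bitwShiftL(1L, which(m$sites$default == 1L) - 1L)), integer(1))

  species <- list(); names_vec <- character(0)
  add_species <- function(cl) {
    nm <- .canon(cl)
    id <- match(nm, names_vec)
    if (!is.na(id)) return(id)
    if (length(names_vec) >= max_species)
      stop("species expansion guard exceeded (", max_species, ")")
    species[[length(species) + 1]] <<- cl
    names_vec <<- c(names_vec, nm)
    length(names_vec)
  }
  for (entry in model$init) {
    if (!is.null(entry$ring)) stop("ring complexes cannot be expanded")
    add_species(.cluster_singleton(entry$type, default_state[[entry$type]]))
  }
  # species that only enter later (influx/pulses) must still be seeded
  for (t in names(mols))
    add_species(.cluster_singleton(t, default_state[[t]]))

  rx <- NULL
  # one full pass over the current species set; reactions are rebuilt from
  # scratch each pass, so the final (closed) pass yields exact multiplicities
  one_pass <- function() {
    acc <- new.env(parent = emptyenv())
    add_rx <- function(r1, r2, prods, rate, label, dir) {
      key <- paste(r1, r2, paste(sort(prods), collapse = "/"), label, dir)
      if (!is.null(acc[[key]])) acc[[key]]$mult <- acc[[key]]$mult + 1L
      else acc[[key]] <- list(r1 = r1, r2 = r2,
                              p1 = if (length(prods) >= 1) prods[1] else NA,
                              p2 = if (length(prods) > 1) prods[2] else NA,
                              rate = rate, label = label, dir = dir, mult = 1L)
    }
    n_now <- length(species)
    for (s1 in seq_len(n_now)) {
      cl1 <- species[[s1]]
      for (r in directed) {
        if (r$order == 1L) {
          for (m in which(cl1$mol$type == r$owner)) {
            if (!.cl_eval(cl1, m, r$conds, sidx)) next
            if (r$kind == "flag") {
              cl2 <- cl1
              cl2$mol$state[m] <- .setbit(cl2$mol$state[m],
                                          .site_bit(sidx, r$owner, r$site),
                                          r$value)
              add_rx(s1, NA, add_species(cl2), r$rate, r$label, r$dir)
            } else if (r$kind == "remove") {
              if (nrow(cl1$mol) == 1)
                add_rx(s1, NA, integer(0), r$rate, r$label, r$dir)
            } else if (r$kind == "unbind") {
              via <- .site_bit(sidx, r$owner, r$site)
              hit <- which((cl1$bonds$i == m & cl1$bonds$si == via) |
                             (cl1$bonds$j == m & cl1$bonds$sj == via))
              if (length(hit) != 1) next
              cl2 <- cl1
              q <- if (cl2$bonds$i[hit] == m) cl2$bonds$j[hit] else
                cl2$bonds$i[hit]
              qs <- if (cl2$bonds$i[hit] == m) cl2$bonds$sj[hit] else
                cl2$bonds$si[hit]
              cl2$mol$state[m] <- .setbit(cl2$mol$state[m], via, 0L)
              cl2$mol$state[q] <- .setbit(cl2$mol$state[q], qs, 0L)
              cl2$bonds <- cl2$bonds[-hit, , drop = FALSE]
              prods <- vapply(.components(cl2), add_species, integer(1))
              add_rx(s1, NA, prods, r$rate, r$label, r$dir)
            }
          }
        } else {
          for (s2 in seq_len(n_now)) {
            cl2 <- species[[s2]]
            for (a in which(cl1$mol$type == r$typeA)) {
              if (!.cl_eval(cl1, a, r$condA, sidx)) next
              for (b in which(cl2$mol$type == r$typeB)) {
                if (!.cl_eval(cl2, b, r$condB, sidx)) next
                if (s1 == s2) stop("self-pair reactions are not supported")
                merged <- list(
                  mol = rbind(cl1$mol, cl2$mol),
                  bonds = rbind(cl1$bonds,
                                data.frame(i = cl2$bonds$i + nrow(cl1$mol),
                                           si = cl2$bonds$si,
                                           j = cl2$bonds$j + nrow(cl1$mol),
                                           sj = cl2$bonds$sj)))
                bA <- .site_bit(sidx, r$typeA, r$bondA)
                bB <- .site_bit(sidx, r$typeB, r$bondB)
                merged$bonds <- rbind(merged$bonds,
                                      data.frame(i = a, si = bA,
                                                 j = b + nrow(cl1$mol),
                                                 sj = bB))
                merged$mol$state[a] <- .setbit(merged$mol$state[a], bA, 1L)
                merged$mol$state[b + nrow(cl1$mol)] <-
                  .setbit(merged$mol$state[b + nrow(cl1$mol)], bB, 1L)
                add_rx(s1, s2, add_species(merged), r$rate, r$label, r$dir)
              }
            }
          }
        }
      }
    }
    list(n_before = n_now, rx = as.list(acc))
  }
  repeat {
    pass <- one_pass()
    if (length(species) == pass$n_before) { rx <- pass$rx; break }
  }

  reactions <- do.call(rbind, lapply(rx, function(x)
    data.frame(r1 = x$r1, r2 = if (is.na(x$r2)) NA_integer_ else x$r2,
               p1 = if (length(x$p1) && !is.na(x$p1)) x$p1 else NA_integer_,
               p2 = if (!is.na(x$p2)) x$p2 else NA_integer_,
               rate = x$rate, label = x$label, dir = x$dir, mult = x$mult,
               stringsAsFactors = FALSE)))
  rownames(reactions) <- NULL
  comp <- t(vapply(species, function(cl)
    vapply(names(mols), function(t) sum(cl$mol$type == t), numeric(1)),
    numeric(length(mols))))
  colnames(comp) <- names(mols)
  list(species = names_vec, clusters = species, reactions = reactions,
       composition = comp, model = model)
}

#' Human-readable species names for expanded networks
#'
#' For clusters built from the Ca2+/CaM/CaMKII molecule family this produces
#' the field's `NxCy` / `KNxCy` / `KpNxCy` notation; other clusters keep their
#' canonical strings.
#'
#' @param net an expanded network from [expand_network()]
#' @return character vector parallel to `net$species`
#' @export
species_names <- function(net) {
  mols <- net$model$molecules
  sidx <- .site_index(mols)
  vapply(seq_along(net$clusters), function(i) {
    cl <- net$clusters[[i]]
    cams <- which(cl$mol$type == "cam")
    if (length(cams) == 1 && all(c("N1", "C1") %in% names(sidx$cam))) {
      st <- cl$mol$state[cams]
      x <- sum(bitwAnd(bitwShiftR(st, c(sidx$cam[["N1"]], sidx$cam[["N2"]])), 1L))
      y <- sum(bitwAnd(bitwShiftR(st, c(sidx$cam[["C1"]], sidx$cam[["C2"]])), 1L))
      ks <- which(cl$mol$type == "K")
      pre <- ""
      if (length(ks) == 1) {
        kst <- cl$mol$state[ks]
        ph <- bitwAnd(bitwShiftR(kst, sidx$K[["p"]]), 1L)
        pre <- if (ph) "Kp" else "K"
      }
      return(sprintf("%sN%dC%d", pre, x, y))
    }
    if (nrow(cl$mol) == 1 && cl$mol$type[1] == "ca") return("ca")
    if (nrow(cl$mol) == 1 && cl$mol$type[1] == "K") {
      ph <- bitwAnd(bitwShiftR(cl$mol$state[1], sidx$K[["p"]]), 1L)
      return(if (ph) "Kp_free" else "K_free")
    }
    net$species[i]
  }, character(1))
}

#' Deterministic mass-action trajectories of an expanded network
#'
#' Stiff-safe integration (lsoda) of the ODE system implied by the expanded
#' reaction network; the well-mixed deterministic oracle the particle engine
#' is validated against in the activation-limited regime.
#'
#' @param net an expanded network from [expand_network()]
#' @param y0 named initial concentrations in uM (names from `net$species` or
#'   [species_names()]); unnamed species start at 0
#' @param t_grid output times, s
#' @return data.frame: `time` plus one column per species (uM), named via
#'   [species_names()]
#' @export
ode_trajectories <- function(net, y0, t_grid) {
  nm <- species_names(net)
  n <- length(nm)
  y <- stats::setNames(numeric(n), nm)
  for (k in names(y0)) {
    id <- which(nm == k | net$species == k)
    if (length(id) == 0) stop("unknown species in y0: ", k)
    y[id] <- y0[[k]]
  }
  rex <- net$reactions
  deriv <- function(t, y, parms) {
    dy <- numeric(n)
    for (i in seq_len(nrow(rex))) {
      flux <- rex$rate[i] * rex$mult[i] * y[rex$r1[i]]
      if (!is.na(rex$r2[i])) flux <- flux * y[rex$r2[i]]
      dy[rex$r1[i]] <- dy[rex$r1[i]] - flux
      if (!is.na(rex$r2[i])) dy[rex$r2[i]] <- dy[rex$r2[i]] - flux
      if (!is.na(rex$p1[i])) dy[rex$p1[i]] <- dy[rex$p1[i]] + flux
      if (!is.na(rex$p2[i])) dy[rex$p2[i]] <- dy[rex$p2[i]] + flux
    }
    list(dy)
  }
  out <- deSolve::lsoda(y, t_grid, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  df <- as.data.frame(out)
  names(df) <- c("time", nm)
  # conservation audit of every molecular moiety
  tot0 <- as.numeric(y %*% net$composition)
  totT <- as.numeric(as.matrix(df[nrow(df), -1]) %*% net$composition)
  rel <- abs(totT - tot0) / pmax(abs(tot0), 1e-30)
  if (any(tot0 > 0 & rel > 1e-8))
    warning("moiety conservation drift above 1e-8: ",
            paste(colnames(net$composition)[rel > 1e-8], collapse = ", "))
  df
}

#' Audit microscopic reversibility of a rate set
#'
#' Expands the network, pairs forward/backward reactions by label, and checks
#' that the product of equilibrium constants around every independent
#' thermodynamic cycle equals one. Cycles are the left-null basis of the
#' reaction incidence matrix; a cycle's residual is `|prod(K_eq) - 1|`.
#'
#' @param model an [hs_model()] (monomeric rule set)
#' @param tol relative residual tolerance (default 1e-6)
#' @return list with `violations` (data.frame: cycle id, residual, labels of
#'   member reactions), `n_cycles`, and `ok`
#' @export
check_reversibility <- function(model, tol = 1e-6) {
  net <- expand_network(model)
  rex <- net$reactions
  # reversible pairs: same label, opposite dir
  fw <- rex[rex$dir == 1 & rex$rate > 0, , drop = FALSE]
  logK <- numeric(0); inc <- NULL; labs <- character(0)
  n <- length(net$species)
  for (i in seq_len(nrow(fw))) {
    bw <- rex[rex$label == fw$label[i] & rex$dir == -1, , drop = FALSE]
    # match the reverse by species: products of fw are reactants of bw
    pf <- sort(stats::na.omit(c(fw$p1[i], fw$p2[i])))
    bw <- bw[vapply(seq_len(nrow(bw)), function(j)
      identical(sort(stats::na.omit(c(bw$r1[j], bw$r2[j]))), pf) &&
        identical(sort(stats::na.omit(c(bw$p1[j], bw$p2[j]))),
                  sort(stats::na.omit(c(fw$r1[i], fw$r2[i])))),
      logical(1)), , drop = FALSE]
    if (nrow(bw) != 1 || bw$rate[1] <= 0) next
    v <- numeric(n)
    for (s in stats::na.omit(c(fw$r1[i], fw$r2[i]))) v[s] <- v[s] + 1
    for (s in stats::na.omit(c(fw$p1[i], fw$p2[i]))) v[s] <- v[s] - 1
    inc <- rbind(inc, v)
    logK <- c(logK, log(fw$rate[i] * fw$mult[i]) -
                log(bw$rate[1] * bw$mult[1]))
    labs <- c(labs, fw$label[i])
  }
  if (is.null(inc) || nrow(inc) < 2)
    return(list(violations = data.frame(), n_cycles = 0L, ok = TRUE))
  # thermodynamic cycles = left-null space of the reaction incidence matrix
  sv <- svd(inc, nu = nrow(inc))
  rank <- sum(sv$d > 1e-10 * max(sv$d))
  if (rank >= nrow(inc))
    return(list(violations = data.frame(), n_cycles = 0L, ok = TRUE))
  basis <- sv$u[, (rank + 1):nrow(inc), drop = FALSE]
  basis <- sweep(basis, 2, apply(abs(basis), 2, max), "/")
  viol <- list()
  for (c in seq_len(ncol(basis))) {
    resid <- abs(exp(sum(basis[, c] * logK)) - 1)
    if (resid > tol) {
      members <- labs[abs(basis[, c]) > 1e-8]
      viol[[length(viol) + 1]] <- data.frame(
        cycle = c, residual = resid,
        members = paste(members, collapse = " | "))
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else data.frame()
  list(violations = violations, n_cycles = ncol(basis),
       ok = nrow(violations) == 0)
}
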