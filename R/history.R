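# Reaction-history analysis: the event log is turned into accumulated net
# occurrences per network edge (bindings minus unbindings per bin,
# cumulative), split into the two network layers, and walked greedily to
# extract the preferred pathway.

#' Accumulate net reaction occurrences per edge
#'
#' For each rule label, events are binned (default 10 ms), unbindings are
#' subtracted from bindings within each bin, and the running cumulative sum
#' is returned; a negative value means unbinding has dominated so far.
#'
#' @param events event data.frame (`time`, `label`, `dir`) from an `hs_run`,
#'   or a list of them (trials are summed)
#' @param bin bin width, s (default 0.01)
#' @param t0,t1 analysis window, s (defaults: 0 to the last event)
#' @return data.frame: `label`, `time` (bin end), `net` (per bin),
#'   `cumulative`
#' @export
accumulate_edges <- function(events, bin = 0.01, t0 = 0, t1 = NULL) {
  if (is.data.frame(events)) events <- list(events)
  ev <- data.table::rbindlist(lapply(events, function(e)
    e[, c("time", "label", "dir")]))
  if (is.null(t1)) t1 <- if (nrow(ev)) max(ev$time) else t0 + bin
  breaks <- seq(t0, t1 + bin * (1 - 1e-9), by = bin)
  if (utils::tail(breaks, 1) < t1) breaks <- c(breaks, t1)
  ev <- ev[ev$time >= t0 & ev$time <= t1 + 1e-12, ]
  labels <- sort(unique(ev$label))
  grid <- data.table::CJ(label = labels, time = breaks[-1])
  if (nrow(ev)) {
    ev$time_bin <- breaks[pmin(length(breaks) - 1,
                               findInterval(ev$time, breaks,
                                            left.open = TRUE,
                                            rightmost.closed = TRUE)) + 1]
    net <- data.table::as.data.table(ev)[, list(net = sum(dir)),
                                         by = c("label", "time_bin")]
    data.table::setnames(net, "time_bin", "time")
    out <- merge(grid, net, by = c("label", "time"), all.x = TRUE)
  } else {
    out <- grid; out$net <- 0L
  }
  out$net[is.na(out$net)] <- 0L
  data.table::setorderv(out, c("label", "time"))
  out[, "cumulative" := cumsum(net), by = "label"]
  as.data.frame(out)
}

#' Classify an edge label into its layer and reaction family
#'
#' Layer 1 holds the free-CaM edges (`Nx~ca`, `Cx~ca`, `K~NxCy`, `Kp~NxCy`);
#' Layer 2 holds the subunit-bound-CaM edges (`KNx~ca`, `KCx~ca`,
#' `KpNx~ca`, `KpCx~ca`, `KNxCy~p`).
#'
#' @param label an edge label (origin-vertex suffix after `@` allowed)
#' @return list with `layer` (1 or 2) and `family`
#' @export
classify_edge <- function(label) {
  fam <- sub("@.*$", "", label)
  fam <- sub("\\.[ab]$", "", fam)
  if (grepl("^K~N[012]C[012]$", fam))
    return(list(layer = 1L, family = "K~NxCy"))
  if (grepl("^Kp~N[012]C[012]$", fam))
    return(list(layer = 1L, family = "Kp~NxCy"))
  if (grepl("^[NC][12]~ca$", fam))
    return(list(layer = 1L, family = fam))
  if (grepl("^Kp?[NC][12]~ca$", fam))
    return(list(layer = 2L, family = fam))
  if (grepl("^KN[012]C[012]~p$", fam))
    return(list(layer = 2L, family = "KNxCy~p"))
  stop("unknown edge label: ", label)
}

#' Extract the preferred pathway from accumulated edge fluxes
#'
#' Greedy walk over the network graph: starting from `start` (apoCaM by
#' default), at each vertex follow the outgoing edge with the largest final
#' cumulative net count; the walk ends at a phosphorylation edge, on a
#' revisit, or when no outgoing edge has positive net flux. Ties are
#' reported, never broken silently.
#'
#' @param edge_series output of [accumulate_edges()]
#' @param edge_map edge metadata (label, from, to, family) such as
#'   [network_edge_map()]
#' @param start starting vertex (default `"N0C0"`)
#' @return list: `path` (vertices), `edges` (chosen edge labels per step),
#'   `values` (their final cumulative nets), `ties` (per-step list of
#'   co-maximal alternatives), `complete` (reached a phosphorylation edge)
#' @export
preferred_path <- function(edge_series, edge_map, start = "N0C0") {
  finals <- stats::aggregate(cumulative ~ label, data = edge_series,
                             FUN = function(x) utils::tail(x, 1))
  if (nrow(finals) == 0 || all(finals$cumulative == 0))
    return(list(path = character(0), edges = character(0),
                values = numeric(0), ties = list(), complete = FALSE,
                note = "no net flux recorded"))
  em <- merge(edge_map, finals, by = "label", all.x = TRUE)
  em$cumulative[is.na(em$cumulative)] <- 0
  # aggregate labels sharing an edge (e.g. the two activation disjuncts)
  em <- stats::aggregate(cumulative ~ from + to + family, data = em, FUN = sum)
  path <- start; edges <- character(0); values <- numeric(0); ties <- list()
  v <- start
  repeat {
    out <- em[em$from == v & em$cumulative > 0, , drop = FALSE]
    if (nrow(out) == 0) break
    best <- max(out$cumulative)
    hit <- out[out$cumulative == best, , drop = FALSE]
    ties[[length(ties) + 1]] <- if (nrow(hit) > 1)
      paste(hit$family, "->", hit$to) else character(0)
    step <- hit[1, ]
    edges <- c(edges, paste0(step$family, "@", v))
    values <- c(values, step$cumulative)
    if (step$family == "KNxCy~p") {
      path <- c(path, step$to)
      return(list(path = path, edges = edges, values = values, ties = ties,
                  complete = TRUE))
    }
    if (step$to %in% path) { path <- c(path, step$to); break }
    path <- c(path, step$to)
    v <- step$to
  }
  list(path = path, edges = edges, values = values, ties = ties,
       complete = FALSE)
}

#' Structural ledger identity between event log and species counts
#'
#' For every network vertex, the initial count plus the cumulative inflow
#' nets minus the cumulative outflow nets must equal the recorded count at
#' every bin boundary, exactly. This ties the event log to the state and is
#' the main integrity check of the history analysis.
#'
#' @param run an `hs_run` whose model carries an `edge_map` and per-vertex
#'   observables
#' @param bin ledger bin width, s (default 0.01; must be a multiple of the
#'   recording interval)
#' @return list: `ok` (all deviations zero), `max_abs_dev`, `table`
#'   (vertex x time deviations)
#' @export
ledger_check <- function(run, bin = 0.01) {
  em <- run$model$edge_map
  if (is.null(em)) stop("model has no edge_map")
  counts <- run$counts
  rec_times <- counts$time
  t1 <- max(rec_times)
  bts <- seq(0, t1 + 1e-12, by = bin)
  bts <- bts[vapply(bts, function(b)
    any(abs(rec_times - b) < 1e-9), logical(1))]
  es <- accumulate_edges(run$events, bin = bin, t0 = 0, t1 = t1)
  verts <- intersect(unique(c(em$from, em$to)), names(counts))
  dev <- matrix(0, length(verts), length(bts),
                dimnames = list(verts, sprintf("%.3f", bts)))
  for (vi in seq_along(verts)) {
    v <- verts[vi]
    inflow <- em$label[em$to == v]
    outflow <- em$label[em$from == v]
    n0 <- counts[[v]][1]
    for (bi in seq_along(bts)) {
      b <- bts[bi]
      cum_at <- function(labs) {
        if (length(labs) == 0) return(0)
        sel <- es[es$label %in% labs & es$time <= b + 1e-9, , drop = FALSE]
        if (nrow(sel) == 0) return(0)
        sum(vapply(split(sel, sel$label), function(d)
          utils::tail(d$cumulative, 1), numeric(1)))
      }
      predicted <- n0 + cum_at(inflow) - cum_at(outflow)
      actual <- counts[[v]][which.min(abs(rec_times - b))]
      dev[vi, bi] <- actual - predicted
    }
  }
  list(ok = all(dev == 0), max_abs_dev = max(abs(dev)), table = dev)
}
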