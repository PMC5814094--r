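# Site-level reaction rules and the lookup table that replaces network
# expansion.
#
# Molecules are declared with named binary sites (binding sites carry bonds;
# flag sites carry marks such as phosphorylation). Rules are written in a
# small text dialect, one per line:
#
#   A{cond,...} + B{cond,...} <-> A~B{assign,...} kf=V kb=V label=NAME
#   A{cond,...} <-> A{assign,...} kf=V kb=V label=NAME
#   A{cond,...} -> 0 kf=V label=NAME              (removal / clearance)
#
# Conditions use `==` (state tests), assignments use `=`. A condition term
# may address the molecule's own sites (`C1==0`), the molecule bound at one
# of its sites (`partner(k).p==0`), or the left/right ring neighbour
# (`left.cam==1`). `<->` declares a reversible rule stored as two directed
# rules sharing the label; `->` is forward-only.

#' Declare a molecule type
#'
#' @param name identifier
#' @param sites named character vector mapping site name to kind
#'   (`"binding"` or `"flag"`)
#' @param diffusion diffusion coefficient, cm^2/s
#' @param mobile logical; `FALSE` forces the effective diffusion to zero
#' @param defaults named integer vector of default site states (default all 0)
#' @return a `molecule_type` list
#' @export
molecule_type <- function(name, sites, diffusion = 0, mobile = diffusion > 0,
                          defaults = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  kinds <- match.arg(unname(sites), c("binding", "flag"), several.ok = TRUE)
  if (anyDuplicated(names(sites))) stop("site names must be unique within ", name)
  if (diffusion < 0) stop("diffusion_coeff must be >= 0")
  def <- stats::setNames(rep(0L, length(sites)), names(sites))
  if (!is.null(defaults)) def[names(defaults)] <- as.integer(defaults)
  structure(list(name = name,
                 sites = data.frame(name = names(sites), kind = kinds,
                                    default = unname(def),
                                    stringsAsFactors = FALSE),
                 diffusion_coeff = if (mobile) diffusion else 0,
                 mobile = mobile && diffusion > 0),
            class = "molecule_type")
}

#' Read molecule declarations from a YAML config
#'
#' @param path YAML file with a top-level `molecules:` map; each entry has
#'   `sites` (map site -> binding|flag), `diffusion` (cm^2/s) and optionally
#'   `mobile`, `defaults`
#' @return named list of `molecule_type`
#' @export
read_molecules <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$molecules)) stop("no 'molecules' section in ", path)
  out <- lapply(names(cfg$molecules), function(nm) {
    m <- cfg$molecules[[nm]]
    molecule_type(nm, unlist(m$sites), diffusion = m$diffusion %||% 0,
                  mobile = m$mobile %||% ((m$diffusion %||% 0) > 0),
                  defaults = unlist(m$defaults))
  })
  stats::setNames(out, names(cfg$molecules))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- parsing ---------------------------------------------------------------

.parse_term <- function(txt, op, mol_names, line, col0) {
  # one `ref==v` or `ref=v` term; returns list(target, via, site, value, mol)
  pat <- if (op == "==") "==" else "(?<![=<>!])=(?!=)"
  parts <- strsplit(txt, pat, perl = TRUE)[[1]]
  if (length(parts) != 2)
    stop(sprintf("rule syntax error at line %d, near '%s': expected single '%s'",
                 line, txt, op), call. = FALSE)
  ref <- trimws(parts[1]); val <- trimws(parts[2])
  if (op == "==" && grepl("(?<![=<>!])=(?!=)", txt, perl = TRUE) &&
      !grepl("==", txt, fixed = TRUE))
    stop(sprintf("line %d: '=' used on left side (use '==')", line), call. = FALSE)
  if (!val %in% c("0", "1"))
    stop(sprintf("line %d: state value must be 0 or 1, got '%s'", line, val),
         call. = FALSE)
  mol <- NA_character_; target <- "self"; via <- NA_character_
  toks <- strsplit(ref, ".", fixed = TRUE)[[1]]
  if (length(toks) > 1 && toks[1] %in% mol_names) {
    mol <- toks[1]; toks <- toks[-1]
  }
  if (length(toks) == 2 && toks[1] %in% c("left", "right")) {
    target <- toks[1]; toks <- toks[-1]
  } else if (length(toks) == 2 && grepl("^partner\\(", toks[1])) {
    target <- "partner"
    via <- sub("^partner\\(([^)]+)\\)$", "\\1", toks[1])
    toks <- toks[-1]
  }
  if (length(toks) != 1)
    stop(sprintf("line %d: cannot parse site reference '%s'", line, ref),
         call. = FALSE)
  list(mol = mol, target = target, via = via, site = toks[1],
       value = as.integer(val))
}

.split_terms <- function(braces) {
  body <- trimws(braces)
  if (body == "") character(0) else trimws(strsplit(body, ",", fixed = TRUE)[[1]])
}

.term_df <- function(terms, op, default_mol, mol_names, line) {
  if (length(terms) == 0)
    return(data.frame(mol = character(0), target = character(0),
                      via = character(0), site = character(0),
                      value = integer(0), stringsAsFactors = FALSE))
  rows <- lapply(terms, function(t) {
    if (op == "==" && grepl("(?<![=<>!])=(?!=)", t, perl = TRUE))
      stop(sprintf("line %d: '=' used on left side in '%s' (use '==')", line, t),
           call. = FALSE)
    if (op == "=" && grepl("==", t, fixed = TRUE))
      stop(sprintf("line %d: '==' used on right side in '%s' (use '=')", line, t),
           call. = FALSE)
    p <- .parse_term(t, op, mol_names, line, 0)
    if (is.na(p$mol)) p$mol <- default_mol
    as.data.frame(p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.parse_rate <- function(kv, key, line) {
  m <- regmatches(kv, regexec(paste0(key, "=([^ ]+)"), kv))[[1]]
  if (length(m) < 2) return(NULL)
  v <- suppressWarnings(as.numeric(m[2]))
  if (is.na(v)) m[2] else v   # symbolic rate kept as character
}

#' Parse one rule from the rule dialect
#'
#' @param text a single rule line, e.g.
#'   `"cam{C1==0} + ca{} <-> cam~ca{cam.C1=1} kf=5 kb=10 label=C1~ca"`
#' @param molecules named list of [molecule_type()] declarations
#' @param line line number used in error messages
#' @return a `reaction_rule` list (order, reactants, conditions, assignments,
#'   bond, kf, kb, label, reversible)
#' @export
parse_rule <- function(text, molecules, line = 1L) {
  mol_names <- names(molecules)
  raw <- trimws(sub("#.*$", "", text))
  if (raw == "") return(NULL)
  rev_arrow <- grepl("<->", raw, fixed = TRUE)
  arrow <- if (rev_arrow) "<->" else "->"
  halves <- strsplit(raw, arrow, fixed = TRUE)[[1]]
  if (length(halves) != 2)
    stop(sprintf("rule syntax error at line %d, column %d: expected one '%s'",
                 line, regexpr("[-<]", raw), arrow), call. = FALSE)
  lhs <- trimws(halves[1])
  rhs_all <- trimws(halves[2])
  # rates/label tail after the last closing brace (or after '0' for removal)
  tail_start <- regexpr("k[fb]=", rhs_all)
  if (tail_start < 0) stop(sprintf("line %d: missing kf=", line), call. = FALSE)
  rhs <- trimws(substr(rhs_all, 1, tail_start - 1))
  kv <- substr(rhs_all, tail_start, nchar(rhs_all))
  kf <- .parse_rate(kv, "kf", line)
  kb <- .parse_rate(kv, "kb", line)
  label <- regmatches(kv, regexec("label=([^ ]+)", kv))[[1]]
  label <- if (length(label) >= 2) label[2] else NA_character_
  if (is.null(kf)) stop(sprintf("line %d: missing kf=", line), call. = FALSE)
  if (rev_arrow && is.null(kb))
    stop(sprintf("line %d: reversible rule missing kb=", line), call. = FALSE)

  spec_pat <- "^([A-Za-z_][A-Za-z0-9_]*)\\{([^}]*)\\}$"
  parse_side <- function(s) {
    m <- regmatches(s, regexec(spec_pat, s))[[1]]
    if (length(m) < 3)
      stop(sprintf("rule syntax error at line %d near '%s' (expected name{...})",
                   line, s), call. = FALSE)
    list(mol = m[2], body = m[3])
  }

  lhs_parts <- strsplit(lhs, "+", fixed = TRUE)[[1]]
  order <- length(lhs_parts)
  if (!order %in% 1:2)
    stop(sprintf("line %d: rules are first or second order", line), call. = FALSE)
  sides <- lapply(trimws(lhs_parts), parse_side)
  types <- vapply(sides, `[[`, character(1), "mol")
  for (ty in types) if (!ty %in% mol_names)
    stop(sprintf("line %d: unknown molecule '%s'", line, ty), call. = FALSE)

  conds <- do.call(rbind, lapply(seq_along(sides), function(i)
    .term_df(.split_terms(sides[[i]]$body), "==", types[i], mol_names, line)))

  removal <- rhs == "0" || rhs == "null"
  if (removal) {
    if (order != 1) stop(sprintf("line %d: removal must be first order", line),
                         call. = FALSE)
    assigns <- .term_df(character(0), "=", types[1], mol_names, line)
  } else {
    if (order == 2) {
      m <- regmatches(rhs, regexec("^([A-Za-z_][A-Za-z0-9_]*)~([A-Za-z_][A-Za-z0-9_]*)\\{([^}]*)\\}$", rhs))[[1]]
      if (length(m) < 4)
        stop(sprintf("line %d: second-order product must be A~B{...}", line),
             call. = FALSE)
      if (!setequal(c(m[2], m[3]), types))
        stop(sprintf("line %d: product molecules must match reactants", line),
             call. = FALSE)
      body <- m[4]
    } else {
      m <- regmatches(rhs, regexec(spec_pat, rhs))[[1]]
      if (m[2] != types[1])
        stop(sprintf("line %d: product molecule must match reactant", line),
             call. = FALSE)
      body <- m[3]
    }
    assigns <- .term_df(.split_terms(body), "=", types[1], mol_names, line)
    if (order == 2 && nrow(assigns)) {
      amb <- is.na(match(assigns$mol, types))
      if (any(amb)) stop(sprintf("line %d: ambiguous assignment target", line),
                         call. = FALSE)
    }
  }

  # validate site names
  chk <- rbind(conds, assigns)
  for (i in seq_len(nrow(chk))) {
    mt <- molecules[[chk$mol[i]]]
    ref_mol <- if (chk$target[i] %in% c("left", "right")) mt else mt
    if (chk$target[i] == "partner") {
      if (!chk$via[i] %in% mt$sites$name)
        stop(sprintf("line %d: unknown site '%s' on %s", line, chk$via[i],
                     mt$name), call. = FALSE)
      # the partner's site is validated at model assembly (partner type
      # depends on the bond); accept here
    } else if (!chk$site[i] %in% mt$sites$name) {
      stop(sprintf("line %d: unknown site '%s' on %s", line, chk$site[i],
                   mt$name), call. = FALSE)
    }
  }

  bond <- NULL
  if (order == 2) {
    bsite <- lapply(types, function(ty) {
      mt <- molecules[[ty]]
      a <- assigns[assigns$mol == ty & assigns$target == "self" &
                     assigns$value == 1 &
                     assigns$site %in% mt$sites$name[mt$sites$kind == "binding"], ]
      if (nrow(a) == 1) return(a$site)
      if (nrow(a) > 1)
        stop(sprintf("line %d: a binding rule must set exactly one bond per reactant",
                     line), call. = FALSE)
      bs <- mt$sites$name[mt$sites$kind == "binding"]
      if (length(bs) == 1) return(bs)   # implicit single binding site
      stop(sprintf("line %d: bond site on '%s' is ambiguous; assign it explicitly",
                   line, ty), call. = FALSE)
    })
    bond <- stats::setNames(unlist(bsite), types)
  }

  structure(list(order = order, types = types, conditions = conds,
                 assignments = assigns, bond = bond,
                 kf = kf, kb = if (rev_arrow) kb else NULL,
                 reversible = rev_arrow, removal = removal,
                 label = label, line = line),
            class = "reaction_rule")
}

#' Serialize a rule back to the rule dialect
#'
#' `parse_rule(serialize_rule(r))` is the identity on canonical rules.
#' @param rule a `reaction_rule`
#' @return single-line character string
#' @export
serialize_rule <- function(rule) {
  fmt_terms <- function(df, op, with_mol) {
    if (nrow(df) == 0) return("")
    ref <- vapply(seq_len(nrow(df)), function(i) {
      base <- switch(df$target[i],
                     self = df$site[i],
                     partner = sprintf("partner(%s).%s", df$via[i], df$site[i]),
                     left = paste0("left.", df$site[i]),
                     right = paste0("right.", df$site[i]))
      if (with_mol) paste0(df$mol[i], ".", base) else base
    }, character(1))
    paste0(ref, op, df$value, collapse = ",")
  }
  rate_str <- function(v) if (is.character(v)) v else format(v, digits = 15)
  lab <- if (!is.na(rule$label)) paste0(" label=", rule$label) else ""
  if (rule$order == 2) {
    lh <- paste(vapply(seq_along(rule$types), function(i) {
      d <- rule$conditions[rule$conditions$mol == rule$types[i], , drop = FALSE]
      sprintf("%s{%s}", rule$types[i], fmt_terms(d, "==", FALSE))
    }, character(1)), collapse = " + ")
    rh <- sprintf("%s~%s{%s}", rule$types[1], rule$types[2],
                  fmt_terms(rule$assignments, "=", TRUE))
    sprintf("%s <-> %s kf=%s kb=%s%s", lh, rh, rate_str(rule$kf),
            rate_str(rule$kb), lab)
  } else if (rule$removal) {
    sprintf("%s{%s} -> 0 kf=%s%s", rule$types[1],
            fmt_terms(rule$conditions, "==", FALSE), rate_str(rule$kf), lab)
  } else {
    arrow <- if (rule$reversible) "<->" else "->"
    tail <- if (rule$reversible) sprintf(" kb=%s", rate_str(rule$kb)) else ""
    sprintf("%s{%s} %s %s{%s} kf=%s%s%s", rule$types[1],
            fmt_terms(rule$conditions, "==", FALSE), arrow, rule$types[1],
            fmt_terms(rule$assignments, "=", FALSE), rate_str(rule$kf), tail, lab)
  }
}

#' Parse a rule file
#'
#' UTF-8 text, one rule per line, `#` comments. Rules without labels get
#' positional labels `r<line>`.
#'
#' @param path file path (or a character vector of lines via `lines=`)
#' @param molecules named list of [molecule_type()]
#' @param lines optional character vector overriding `path`
#' @return list of `reaction_rule`
#' @export
parse_rule_file <- function(path = NULL, molecules, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path, warn = FALSE)
  rules <- list()
  for (i in seq_along(lines)) {
    r <- parse_rule(lines[i], molecules, line = i)
    if (is.null(r)) next
    if (is.na(r$label)) r$label <- paste0("r", i)
    rules[[length(rules) + 1L]] <- r
  }
  labs <- vapply(rules, `[[`, character(1), "label")
  if (anyDuplicated(labs))
    stop("duplicate rule labels: ", paste(unique(labs[duplicated(labs)]),
                                          collapse = ", "))
  rules
}

#' Resolve symbolic rate constants against a named rate set
#'
#' Rule files may reference rates by name (e.g. `kf=kon_C1`); this replaces
#' every symbol with its numeric value.
#' @param rules list of parsed rules
#' @param rates named numeric vector
#' @return the rules with numeric `kf`/`kb`
#' @export
resolve_rates <- function(rules, rates) {
  lapply(rules, function(r) {
    for (f in c("kf", "kb")) {
      v <- r[[f]]
      if (is.character(v)) {
        if (!v %in% names(rates)) stop("unknown rate symbol '", v, "'")
        r[[f]] <- unname(rates[[v]])
      }
    }
    if (!is.null(r$kf) && r$kf < 0) stop("negative rate in rule ", r$label)
    if (!is.null(r$kb) && r$kb < 0) stop("negative rate in rule ", r$label)
    r
  })
}

# ---- directed expansion ----------------------------------------------------

#' Expand reversible declarations into directed rules
#'
#' A reversible declaration is stored as two directed rules sharing the label
#' (direction +1 forward / -1 backward) so event logs can net bindings against
#' unbindings. The backward rule of a binding is a first-order unbinding owned
#' by reactant 1, with the forward conditions carried over (conditions on the
#' bond sites replaced by bound-state requirements, and reactant-2 self
#' conditions rewritten as partner conditions through the bond).
#' @param rules list of parsed rules (numeric rates)
#' @param molecules named list of [molecule_type()]
#' @return list of directed rule records
#' @export
directed_rules <- function(rules, molecules) {
  out <- list()
  add <- function(x) out[[length(out) + 1L]] <<- x
  for (r in rules) {
    if (r$order == 2) {
      tA <- r$types[1]; tB <- r$types[2]
      if (tA == tB) stop("identical reactant types are not supported: ", r$label)
      cond <- r$conditions
      # implicit: bond sites free
      cond <- rbind(cond,
                    data.frame(mol = c(tA, tB), target = "self",
                               via = NA_character_,
                               site = unname(r$bond[c(tA, tB)]), value = 0L,
                               stringsAsFactors = FALSE))
      cond <- unique(cond)
      add(list(order = 2L, kind = "bind", typeA = tA, typeB = tB,
               condA = cond[cond$mol == tA, , drop = FALSE],
               condB = cond[cond$mol == tB, , drop = FALSE],
               bondA = unname(r$bond[tA]), bondB = unname(r$bond[tB]),
               rate = r$kf, label = r$label, dir = 1L))
      if (r$reversible) {
        # unbinding: owner = typeA, break bond at bondA
        ca <- cond[cond$mol == tA, , drop = FALSE]
        ca$value[ca$target == "self" & ca$site == r$bond[[tA]]] <- 1L
        cb <- cond[cond$mol == tB, , drop = FALSE]
        cb <- cb[!(cb$target == "self" & cb$site == r$bond[[tB]]), , drop = FALSE]
        if (nrow(cb)) {
          if (any(cb$target != "self"))
            stop("reactant-2 conditions must be on its own sites: ", r$label)
          cb$target <- "partner"; cb$via <- r$bond[[tA]]; cb$mol <- tA
        }
        add(list(order = 1L, kind = "unbind", owner = tA,
                 site = unname(r$bond[tA]),
                 conds = rbind(ca, cb), rate = r$kb, label = r$label,
                 dir = -1L, partner_type = tB, partner_site = unname(r$bond[tB])))
      }
    } else if (r$removal) {
      add(list(order = 1L, kind = "remove", owner = r$types[1],
               conds = r$conditions, rate = r$kf, label = r$label, dir = -1L))
    } else {
      a <- r$assignments
      if (nrow(a) != 1 || a$target != "self")
        stop("first-order state rules must assign exactly one own site: ",
             r$label)
      add(list(order = 1L, kind = "flag", owner = r$types[1], site = a$site,
               value = a$value, conds = r$conditions, rate = r$kf,
               label = r$label, dir = 1L))
      if (r$reversible) {
        cb <- r$conditions
        hit <- cb$target == "self" & cb$site == a$site
        cb$value[hit] <- a$value
        if (!any(hit))
          cb <- rbind(cb, data.frame(mol = r$types[1], target = "self",
                                     via = NA_character_, site = a$site,
                                     value = a$value, stringsAsFactors = FALSE))
        add(list(order = 1L, kind = "flag", owner = r$types[1], site = a$site,
                 value = 1L - a$value, conds = cb, rate = r$kb,
                 label = r$label, dir = -1L))
      }
    }
  }
  out
}

# ---- rule table ------------------------------------------------------------

#' Build the reaction lookup table
#'
#' Stores all second-order rules keyed by the (unordered) reactant type pair
#' plus a condition signature over the sites any rule of that pair examines,
#' so that collision-time lookup of any concrete state pair returns exactly
#' the rules whose conditions hold. First-order rules are indexed by owner
#' type.
#'
#' @param rules list of `reaction_rule` (numeric rates; see [resolve_rates()])
#' @param molecules named list of [molecule_type()]
#' @return a `rule_table`
#' @export
build_table <- function(rules, molecules) {
  dr <- directed_rules(rules, molecules)
  labs <- vapply(dr, function(x) paste0(x$label, c("-", "+", "+")[x$dir + 2L]),
                 character(1))
  if (anyDuplicated(labs)) stop("duplicate directed rule: ",
                                labs[duplicated(labs)][1])
  o2 <- dr[vapply(dr, function(x) x$order == 2L, logical(1))]
  o1 <- dr[vapply(dr, function(x) x$order == 1L, logical(1))]
  pair_key <- vapply(o2, function(x) paste(x$typeA, x$typeB, sep = "|"),
                     character(1))
  groups <- lapply(split(seq_along(o2), pair_key), function(idx) {
    rs <- o2[idx]
    probes <- unique(do.call(rbind, lapply(rs, function(r) {
      rbind(cbind(who = "A", r$condA[c("target", "via", "site")]),
            cbind(who = "B", r$condB[c("target", "via", "site")]))
    })))
    rownames(probes) <- NULL
    if (nrow(probes) > 20) stop("condition signature too wide for pair ",
                                rs[[1]]$typeA, "+", rs[[1]]$typeB)
    # per rule: required (mask, value) over probe bits
    mv <- lapply(rs, function(r) {
      cd <- rbind(cbind(who = "A", r$condA), cbind(who = "B", r$condB))
      idx2 <- match(paste(cd$who, cd$target, cd$via, cd$site),
                    paste(probes$who, probes$target, probes$via, probes$site))
      mask <- sum(2^(idx2 - 1))
      val <- sum(2^(idx2 - 1) * cd$value)
      c(mask = mask, val = val)
    })
    nsig <- 2^nrow(probes)
    sig_sets <- lapply(0:(nsig - 1), function(sig) {
      hit <- vapply(mv, function(x)
        bitwAnd(sig, x["mask"]) == x["val"], logical(1))
      which(hit)
    })
    list(typeA = rs[[1]]$typeA, typeB = rs[[1]]$typeB, rules = rs,
         probes = probes, sig_sets = sig_sets)
  })
  structure(list(molecules = molecules, directed = dr, order2 = o2,
                 order1 = o1, groups = groups),
            class = "rule_table")
}

# probe a concrete particle context: `world` functions give states
.probe_bit <- function(world, pid, target, via, site) {
  q <- pid
  if (target %in% c("left", "right")) {
    q <- world$neighbor(pid, target)
    if (is.na(q)) return(NA_integer_)
  }
  if (target == "partner") {
    q <- world$partner(q, via)
    if (is.na(q)) return(0L)   # unbound partner probes read as 0
  }
  world$site(q, site)
}

#' Look up candidate rules for a colliding pair
#'
#' Evaluates the condition signature of the two concrete molecule states and
#' returns the matching second-order rules in deterministic (label) order.
#' `lookup_brute` performs the equivalent full condition scan without the
#' signature table; the two must agree for every reachable state pair.
#'
#' @param table a `rule_table`
#' @param world a context list with functions `site(pid, name)`,
#'   `partner(pid, via)`, `neighbor(pid, side)` and `type(pid)`
#' @param a,b particle ids of the colliding pair
#' @return list of matching directed binding rules (possibly empty)
#' @export
lookup_rules <- function(table, world, a, b) {
  ta <- world$type(a); tb <- world$type(b)
  key <- NULL
  for (k in names(table$groups)) {
    g <- table$groups[[k]]
    if (g$typeA == ta && g$typeB == tb) { key <- k; swap <- FALSE; break }
    if (g$typeA == tb && g$typeB == ta) { key <- k; swap <- TRUE; break }
  }
  if (is.null(key)) return(list())
  if (isTRUE(swap)) { tmp <- a; a <- b; b <- tmp }
  g <- table$groups[[key]]
  bits <- vapply(seq_len(nrow(g$probes)), function(i) {
    pid <- if (g$probes$who[i] == "A") a else b
    bit <- .probe_bit(world, pid, g$probes$target[i], g$probes$via[i],
                      g$probes$site[i])
    if (is.na(bit)) 0L else bit
  }, integer(1))
  sig <- sum(bits * 2^(seq_along(bits) - 1))
  rs <- g$rules[g$sig_sets[[sig + 1]]]
  rs[order(vapply(rs, `[[`, character(1), "label"))]
}

#' @rdname lookup_rules
#' @export
lookup_brute <- function(table, world, a, b) {
  ta <- world$type(a); tb <- world$type(b)
  hits <- Filter(function(r) {
    if (!(r$typeA == ta && r$typeB == tb) &&
        !(r$typeA == tb && r$typeB == ta)) return(FALSE)
    if (r$typeA == tb && r$typeB == ta) { x <- b; y <- a } else { x <- a; y <- b }
    ok <- function(cond, pid) {
      all(vapply(seq_len(nrow(cond)), function(i) {
        bit <- .probe_bit(world, pid, cond$target[i], cond$via[i], cond$site[i])
        !is.na(bit) && bit == cond$value[i]
      }, logical(1)))
    }
    ok(r$condA, x) && ok(r$condB, y)
  }, table$order2)
  hits[order(vapply(hits, `[[`, character(1), "label"))]
}

#' Combined forward rate of branching candidates
#'
#' For second-order rules sharing the same reactant pair the branches act as
#' one equivalent reaction with `kf = sum(kf_i)`; the binding radius is
#' computed from the sum and the branch is then chosen proportionally.
#'
#' @param candidates list of directed rules (or parsed rules with `$rate`/`$kf`)
#' @return total forward rate (0 for an empty list)
#' @export
combined_rate <- function(candidates) {
  if (length(candidates) == 0) return(0)
  sum(vapply(candidates, function(r) r$rate %||% r$kf, numeric(1)))
}

#' Choose a reaction branch from a uniform draw
#'
#' Partitions (0, 1] proportionally to the candidates' forward rates and
#' returns the candidate whose subinterval contains `u`.
#'
#' @param candidates nonempty list of rules
#' @param u a uniform(0, 1] draw
#' @return the selected rule
#' @export
select_branch <- function(candidates, u) {
  stopifnot(length(candidates) >= 1, u > 0, u <= 1)
  ks <- vapply(candidates, function(r) r$rate %||% r$kf, numeric(1))
  tot <- sum(ks)
  if (tot <= 0) return(NULL)   # no-reaction signal
  cum <- cumsum(ks) / tot
  candidates[[which(u <= cum + 1e-15)[1]]]
}
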