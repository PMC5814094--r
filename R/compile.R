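# Compilation of an hs_model into the flat integer/double tables the C++
# engine consumes: directed rules, per-type-pair condition-signature tables
# (the collision-time hash table), calibrated binding radii, observables and
# geometry codes.

.target_code <- c(self = 0L, partner = 1L, left = 2L, right = 3L)

# site index lookup (0-based) per molecule type
.site_index <- function(molecules) {
  lapply(molecules, function(m)
    stats::setNames(seq_len(nrow(m$sites)) - 1L, m$sites$name))
}

# encode a condition data.frame relative to an owner type
.code_conds <- function(df, owner, molecules, sidx, directed) {
  n <- if (is.null(df)) 0L else nrow(df)
  out <- data.frame(target = integer(n), via = integer(n), site = integer(n),
                    val = integer(n))
  if (n == 0) return(out)
  for (i in seq_len(n)) {
    tg <- df$target[i]
    out$target[i] <- .target_code[[tg]]
    if (tg == "partner") {
      via <- df$via[i]
      if (!via %in% names(sidx[[owner]]))
        stop("unknown via-site ", via, " on ", owner)
      out$via[i] <- sidx[[owner]][[via]]
      pt <- partner_type_of(directed, owner, via)
      if (is.na(pt)) stop("site ", owner, ".", via, " never binds; ",
                          "partner condition is unsatisfiable")
      if (!df$site[i] %in% names(sidx[[pt]]))
        stop("unknown site ", df$site[i], " on partner type ", pt)
      out$site[i] <- sidx[[pt]][[df$site[i]]]
    } else {
      # left/right neighbours share the owner's type (ring of one subunit type)
      if (!df$site[i] %in% names(sidx[[owner]]))
        stop("unknown site ", df$site[i], " on ", owner)
      out$via[i] <- 0L
      out$site[i] <- sidx[[owner]][[df$site[i]]]
    }
    out$val[i] <- df$value[i]
  }
  out
}

.flatten_conds <- function(cond_list) {
  off <- c(0L, cumsum(vapply(cond_list, nrow, integer(1))))
  all <- if (length(cond_list)) do.call(rbind, cond_list) else
    data.frame(target = integer(0), via = integer(0), site = integer(0),
               val = integer(0))
  list(off = as.integer(off), target = as.integer(all$target),
       via = as.integer(all$via), site = as.integer(all$site),
       val = as.integer(all$val))
}

#' Compile a model for the simulation engine
#'
#' Expands reversible declarations into directed rules, builds the per-pair
#' condition-signature lookup tables, calibrates binding radii for every
#' candidate subset via [binding_radius()] (combined-rate radii for branching
#' schemes), and encodes observables and geometry.
#'
#' @param model an [hs_model()]
#' @param dt simulation time step, s (fixes the binding radii)
#' @param radii compute binding radii (`FALSE` for well-mixed SSA use)
#' @return a compiled model list (internal format)
#' @export
compile_model <- function(model, dt = 1e-6, radii = TRUE) {
  mols <- model$molecules
  Tn <- length(mols)
  tname <- names(mols)
  tidx <- stats::setNames(seq_len(Tn) - 1L, tname)
  sidx <- .site_index(mols)
  nsites <- vapply(mols, function(m) nrow(m$sites), integer(1))
  maxS <- max(nsites)
  skind <- matrix(0L, Tn, maxS)
  for (t in seq_len(Tn))
    skind[t, seq_len(nsites[t])] <-
      as.integer(mols[[t]]$sites$kind == "binding")

  directed <- directed_rules(model$rules, mols)
  o2 <- Filter(function(r) r$order == 2L, directed)
  o1 <- Filter(function(r) r$order == 1L, directed)

  labels <- unique(vapply(directed, `[[`, character(1), "label"))
  lab_id <- stats::setNames(seq_along(labels) - 1L, labels)

  radius_cache <- new.env(parent = emptyenv())
  get_radius <- function(kf_total, Dm) {
    if (!radii || kf_total <= 0) return(0)
    key <- sprintf("%.8g|%.8g", kf_total, Dm)
    if (is.null(radius_cache[[key]]))
      radius_cache[[key]] <- binding_radius(kf_total, Dm, dt) * 1e-3  # um
    radius_cache[[key]]
  }

  # ---- order-2 groups -------------------------------------------------------
  pair_key <- vapply(o2, function(r) paste(sort(c(r$typeA, r$typeB)),
                                           collapse = "|"), character(1))
  pairgroup <- matrix(-1L, Tn, Tn)
  groups <- list()
  o2_bsA <- integer(0); o2_bsB <- integer(0); o2_label <- integer(0)
  o2_kv <- numeric(0); o2_ta <- integer(0); o2_tb <- integer(0)
  o2_condA <- list(); o2_condB <- list()
  gsplit <- split(seq_along(o2), pair_key)
  for (gk in names(gsplit)) {
    rs <- o2[gsplit[[gk]]]
    ord <- order(vapply(rs, `[[`, character(1), "label"))
    rs <- rs[ord]
    ta <- rs[[1]]$typeA; tb <- rs[[1]]$typeB
    if (!all(vapply(rs, function(r) r$typeA == ta && r$typeB == tb, logical(1))))
      stop("inconsistent reactant orientation within pair ", gk)
    gid_rids <- integer(0)
    for (r in rs) {
      rid <- length(o2_bsA)
      o2_bsA <- c(o2_bsA, sidx[[ta]][[r$bondA]])
      o2_bsB <- c(o2_bsB, sidx[[tb]][[r$bondB]])
      o2_label <- c(o2_label, lab_id[[r$label]])
      o2_kv <- c(o2_kv, kon_to_volume_rate(r$rate))
      o2_ta <- c(o2_ta, tidx[[ta]]); o2_tb <- c(o2_tb, tidx[[tb]])
      o2_condA[[rid + 1]] <- .code_conds(r$condA, ta, mols, sidx, directed)
      o2_condB[[rid + 1]] <- .code_conds(r$condB, tb, mols, sidx, directed)
      gid_rids <- c(gid_rids, rid)
    }
    # probes: union of coded conditions over the group, tagged by side
    probe_df <- unique(do.call(rbind, lapply(seq_along(rs), function(i) {
      rid <- gid_rids[i]
      rbind(cbind(who = 0L, o2_condA[[rid + 1]][c("target", "via", "site")]),
            cbind(who = 1L, o2_condB[[rid + 1]][c("target", "via", "site")]))
    })))
    rownames(probe_df) <- NULL
    P <- nrow(probe_df)
    if (P > 20) stop("condition signature too wide for pair ", gk)
    probe_key <- paste(probe_df$who, probe_df$target, probe_df$via,
                       probe_df$site)
    mask <- integer(length(rs)); val <- integer(length(rs))
    for (i in seq_along(rs)) {
      rid <- gid_rids[i]
      cd <- rbind(cbind(who = 0L, o2_condA[[rid + 1]]),
                  cbind(who = 1L, o2_condB[[rid + 1]]))
      pk <- paste(cd$who, cd$target, cd$via, cd$site)
      bits <- match(pk, probe_key) - 1L
      mask[i] <- sum(bitwShiftL(1L, bits))
      val[i] <- sum(bitwShiftL(1L, bits) * cd$val)
    }
    nsig <- bitwShiftL(1L, P)
    subsets <- list(); subset_key <- character(0)
    sig2subset <- integer(nsig)
    for (sig in 0:(nsig - 1)) {
      hit <- which(bitwAnd(sig, mask) == val)
      if (length(hit) == 0) { sig2subset[sig + 1] <- -1L; next }
      key <- paste(hit, collapse = ",")
      id <- match(key, subset_key)
      if (is.na(id)) {
        subsets[[length(subsets) + 1]] <- hit
        subset_key <- c(subset_key, key)
        id <- length(subsets)
      }
      sig2subset[sig + 1] <- id - 1L
    }
    Dm <- mols[[ta]]$diffusion_coeff + mols[[tb]]$diffusion_coeff
    sub_off <- 0L; sub_rule <- integer(0); sub_cum <- numeric(0)
    sub_tot <- numeric(0); sub_r2 <- numeric(0)
    for (ss in subsets) {
      ks <- vapply(ss, function(i) rs[[i]]$rate, numeric(1))
      sub_rule <- c(sub_rule, gid_rids[ss])
      sub_cum <- c(sub_cum, cumsum(ks))
      sub_off <- c(sub_off, length(sub_rule))
      sub_tot <- c(sub_tot, sum(ks))
      rr <- get_radius(sum(ks), Dm)
      sub_r2 <- c(sub_r2, rr^2)
    }
    groups[[length(groups) + 1]] <- list(
      ta = tidx[[ta]], tb = tidx[[tb]],
      p_who = as.integer(probe_df$who), p_target = as.integer(probe_df$target),
      p_via = as.integer(probe_df$via), p_site = as.integer(probe_df$site),
      sig2subset = as.integer(sig2subset), sub_off = as.integer(sub_off),
      sub_rule = as.integer(sub_rule), sub_cum = sub_cum, sub_tot = sub_tot,
      sub_r2 = sub_r2, maxr = sqrt(max(sub_r2, 0)))
    gid <- length(groups) - 1L
    pairgroup[tidx[[ta]] + 1, tidx[[tb]] + 1] <- gid
    pairgroup[tidx[[tb]] + 1, tidx[[ta]] + 1] <- gid
  }

  # ---- order-1 rules --------------------------------------------------------
  kinds <- c(flag = 0L, unbind = 1L, remove = 2L)
  o1_owner <- integer(0); o1_kind <- integer(0); o1_site <- integer(0)
  o1_val <- integer(0); o1_rate <- numeric(0); o1_urad <- numeric(0)
  o1_label <- integer(0); o1_dir <- integer(0)
  o1_ptype <- integer(0); o1_psite <- integer(0)
  o1_conds <- list()
  fwd_kf <- stats::setNames(
    vapply(o2, `[[`, numeric(1), "rate"),
    vapply(o2, `[[`, character(1), "label"))
  for (r in o1) {
    o1_owner <- c(o1_owner, tidx[[r$owner]])
    o1_kind <- c(o1_kind, kinds[[r$kind]])
    o1_site <- c(o1_site, if (!is.null(r$site)) sidx[[r$owner]][[r$site]] else 0L)
    o1_val <- c(o1_val, if (!is.null(r$value)) r$value else 0L)
    o1_rate <- c(o1_rate, r$rate)
    ur <- 0
    if (r$kind == "unbind" && r$label %in% names(fwd_kf)) {
      Dm <- mols[[r$owner]]$diffusion_coeff +
        mols[[r$partner_type]]$diffusion_coeff
      ur <- get_radius(fwd_kf[[r$label]], Dm)
    }
    o1_urad <- c(o1_urad, ur)
    o1_label <- c(o1_label, lab_id[[r$label]])
    o1_dir <- c(o1_dir, r$dir)
    o1_ptype <- c(o1_ptype, if (!is.null(r$partner_type))
      tidx[[r$partner_type]] else -1L)
    o1_psite <- c(o1_psite, if (!is.null(r$partner_site))
      sidx[[r$partner_type]][[r$partner_site]] else -1L)
    # evaluation order: cheapest, most-discriminating conditions first (the
    # bond-site test of an unbinding rule, then own sites, then neighbours,
    # then bond-partner probes)
    cnd <- r$conds
    if (!is.null(cnd) && nrow(cnd)) {
      key <- ifelse(cnd$target == "self", 1L,
                    ifelse(cnd$target %in% c("left", "right"), 2L, 3L))
      if (r$kind == "unbind" && !is.null(r$site))
        key[cnd$target == "self" & cnd$site == r$site] <- 0L
      cnd <- cnd[order(key), , drop = FALSE]
    }
    o1_conds[[length(o1_conds) + 1]] <-
      .code_conds(cnd, r$owner, mols, sidx, directed)
  }
  fc <- .flatten_conds(o1_conds)

  # ---- observables ----------------------------------------------------------
  obs_names <- names(model$observables)
  obs_type <- integer(0); obs_conds_coded <- list()
  for (ob in model$observables) {
    obs_type <- c(obs_type, tidx[[ob$type]])
    obs_conds_coded[[length(obs_conds_coded) + 1]] <-
      .code_conds(ob$conds, ob$type, mols, sidx, directed)
  }
  oc <- .flatten_conds(obs_conds_coded)

  # ---- SSA side conditions --------------------------------------------------
  fa <- .flatten_conds(o2_condA)
  fb <- .flatten_conds(o2_condB)

  # ---- geometry -------------------------------------------------------------
  g <- model$geometry
  face_order <- c("xlo", "xhi", "ylo", "yhi", "zlo", "zhi")
  bc <- integer(6); aprob <- numeric(6); amask <- integer(6)
  for (f in seq_along(face_order)) {
    fd <- g$faces[[face_order[f]]]
    if (identical(fd, "reflect")) bc[f] <- 0L
    else if (identical(fd, "periodic")) bc[f] <- 1L
    else if (is.list(fd) && identical(fd$type, "absorb")) {
      bc[f] <- 2L; aprob[f] <- fd$prob
      amask[f] <- sum(bitwShiftL(1L, tidx[fd$species]))
    } else stop("unknown boundary spec on face ", face_order[f])
  }

  list(T = Tn, maxS = as.integer(maxS), nsites = as.integer(nsites),
       mobile = as.integer(vapply(mols, `[[`, logical(1), "mobile")),
       participates = as.integer((seq_len(Tn) - 1L) %in% c(o2_ta, o2_tb)),
       D = vapply(mols, function(m) D_to_um2(m$diffusion_coeff), numeric(1)),
       skind = as.integer(t(skind)),
       pairgroup = as.integer(t(pairgroup)),
       groups = groups,
       o2_bsA = as.integer(o2_bsA), o2_bsB = as.integer(o2_bsB),
       o2_label = as.integer(o2_label), o2_kv = o2_kv,
       o2_ta = as.integer(o2_ta), o2_tb = as.integer(o2_tb),
       o2A_coff = fa$off, a_target = fa$target, a_via = fa$via,
       a_site = fa$site, a_val = fa$val,
       o2B_coff = fb$off, b_target = fb$target, b_via = fb$via,
       b_site = fb$site, b_val = fb$val,
       o1_owner = as.integer(o1_owner), o1_kind = as.integer(o1_kind),
       o1_site = as.integer(o1_site), o1_val = as.integer(o1_val),
       o1_rate = o1_rate, o1_urad = o1_urad,
       o1_label = as.integer(o1_label), o1_dir = as.integer(o1_dir),
       o1_ptype = as.integer(o1_ptype), o1_psite = as.integer(o1_psite),
       o1_coff = fc$off, c_target = fc$target, c_via = fc$via,
       c_site = fc$site, c_val = fc$val,
       obs_type = as.integer(obs_type),
       obs_coff = oc$off, oc_target = oc$target, oc_via = oc$via,
       oc_site = oc$site, oc_val = oc$val,
       L = g$L, bc = bc, absorb_prob = aprob, absorb_mask = amask,
       # R-side metadata
       labels = labels, obs_names = obs_names, type_names = tname,
       dt = dt)
}
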