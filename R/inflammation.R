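# Inflammatory cell agents: resident inactive monocytes (seeded sparsely at
# initialization), and neutrophils and macrophages recruited at abstracted
# blood-vessel sites. Active cells chemotax along their guidance species
# (neutrophils: TLR4 ligand; macrophages: IFN-gamma), phagocytose necrotic
# debris, secrete cytokines, and expire after a bounded lifespan. Multiple
# inflammatory cells may share a patch with epithelial agents.

IM_MONO <- 1L; IM_MAC <- 2L; IM_NEU <- 3L

#' Recruit inflammatory cells at vessel sites
#'
#' At each blood-vessel patch, neutrophils and macrophages arrive with a
#' probability that saturates (Hill coefficient 1) in the local
#' pro-inflammatory signal (TLR4 ligand + TNF-alpha), preventing unbounded
#' influx during long insults. Resident inactive monocytes activate into
#' macrophages where local IFN-gamma exceeds its threshold. With no signal
#' anywhere, nothing is recruited (quiescence).
#'
#' @param state A `cv_state` (modified in place).
#' @return Number of cells recruited or activated, invisibly.
#' @export
recruit_inflammatory <- function(state) {
  q <- state$cfg$inflammation
  vs <- rep(state$topo$vessel_sites, q$recruit_burst)
  C <- state$f$TLR4_LIGAND[vs] + state$f$TNFA[vs]
  sat <- C / (C + q$recruit_K)
  new_pid <- integer(0); new_ty <- integer(0); new_life <- numeric(0)
  rec_n <- vs[stats::runif(length(vs)) < q$r_neutrophil * sat]
  rec_m <- vs[stats::runif(length(vs)) < q$r_macrophage * sat]
  if (length(rec_n)) {
    new_pid <- c(new_pid, rec_n)
    new_ty <- c(new_ty, rep(IM_NEU, length(rec_n)))
    new_life <- c(new_life, rep(q$neutrophil_life, length(rec_n)))
  }
  if (length(rec_m)) {
    new_pid <- c(new_pid, rec_m)
    new_ty <- c(new_ty, rep(IM_MAC, length(rec_m)))
    new_life <- c(new_life, rep(q$macrophage_life, length(rec_m)))
  }
  n_act <- 0L
  inact <- which(state$im$itype == IM_MONO)
  if (length(inact)) {
    go <- state$f$IFNG[state$im$pid[inact]] >= q$ifng_activation
    if (any(go)) {
      idx <- inact[go]
      state$im$itype[idx] <- IM_MAC
      state$im$act[idx] <- 1
      state$im$life[idx] <- q$macrophage_life
      n_act <- length(idx)
    }
  }
  if (length(new_pid)) {
    state$im$pid <- c(state$im$pid, new_pid)
    state$im$itype <- c(state$im$itype, new_ty)
    state$im$act <- c(state$im$act, rep(1, length(new_pid)))
    state$im$life <- c(state$im$life, new_life)
  }
  invisible(length(new_pid) + n_act)
}

#' Chemotax active inflammatory cells
#'
#' Each activated cell moves one patch per tick to the 4-neighbor with the
#' highest concentration of its guidance species (macrophages: IFN-gamma;
#' neutrophils: TLR4 ligand), with an exploratory random step with
#' probability `chemotax_noise`. When the local gradient is flat (below the
#' flatness threshold) the cell takes a uniform random step. Cells standing
#' on necrotic debris hold position (they are busy phagocytosing); inactive
#' monocytes do not move.
#'
#' @param state A `cv_state` (modified in place).
#' @return Number of cells that moved, invisibly.
#' @export
chemotax_cells <- function(state) {
  q <- state$cfg$inflammation
  act <- which(state$im$itype > IM_MONO)
  if (!length(act)) return(invisible(0L))
  pid <- state$im$pid[act]
  busy <- state$debris[pid]
  act <- act[!busy]; pid <- pid[!busy]
  if (!length(act)) return(invisible(0L))
  moved <- 0L
  for (step in seq_len(q$steps_per_tick)) {
    pid <- state$im$pid[act]
    busy2 <- state$debris[pid]
    nb <- cbind(state$up_i[pid], state$down_i[pid],
                state$left_i[pid], state$right_i[pid])
    is_mac <- state$im$itype[act] == IM_MAC
    for (grp_mac in c(TRUE, FALSE)) {
      grp <- (is_mac == grp_mac) & !busy2
      if (!any(grp)) next
      # primary guidance; macrophages fall back to the DAMP gradient when
      # IFN-gamma is locally flat (late-phase mop-up)
      guides <- if (grp_mac) c("IFNG", "TLR4_LIGAND") else "TLR4_LIGAND"
      nbg <- nb[grp, , drop = FALSE]
      n_g <- nrow(nbg)
      pick <- rep(NA_integer_, n_g)
      for (sp in guides) {
        g <- c(state$f[[sp]], -Inf)  # sentinel: boundary never chosen
        vals <- matrix(g[nbg], ncol = 4)
        best <- max.col(vals, ties.method = "first")
        bestv <- vals[cbind(seq_len(n_g), best)]
        follow <- is.na(pick) & bestv > state$f[[sp]][pid[grp]] + q$chemotax_eps
        pick[follow] <- best[follow]
      }
      rnd <- sample.int(4L, n_g, replace = TRUE)
      # noisy chemotaxis: exploratory random steps break up the pile-up at
      # the plume maximum so laggard debris off the gradient path is found
      explore <- stats::runif(n_g) < q$chemotax_noise
      pick[is.na(pick) | explore] <- rnd[is.na(pick) | explore]
      tgt <- nbg[cbind(seq_len(n_g), pick)]
      ok <- tgt <= state$n  # a random step into a boundary stays put
      idx <- act[grp][ok]
      state$im$pid[idx] <- tgt[ok]
      moved <- moved + sum(ok)
    }
  }
  invisible(moved)
}

#' Phagocytose necrotic debris
#'
#' Every activated macrophage or neutrophil co-located with necrotic debris
#' clears one debris unit this tick; the patch permanently stops emitting
#' DAMPs and damaging its neighbors.
#'
#' @param state A `cv_state` (modified in place).
#' @return Number of debris patches cleared, invisibly.
#' @export
phagocytose <- function(state) {
  act <- which(state$im$itype > IM_MONO)
  if (!length(act)) return(invisible(0L))
  pids <- unique(state$im$pid[act])
  hit <- pids[state$debris[pids]]
  if (length(hit)) {
    state$debris[hit] <- FALSE
    state$counts["cleared"] <- state$counts["cleared"] + length(hit)
  }
  invisible(length(hit))
}

#' Age and remove inflammatory cells
#'
#' Lifespans count down each tick and the cell is removed at zero;
#' anti-inflammatory tone (local IL-10) accelerates neutrophil expiry
#' (resolution). Resident inactive monocytes persist.
#'
#' @param state A `cv_state` (modified in place).
#' @return Number of cells removed, invisibly.
#' @export
expire_inflammatory <- function(state) {
  q <- state$cfg$inflammation
  ty <- state$im$itype
  if (!length(ty)) return(invisible(0L))
  dec <- rep(state$dt, length(ty))
  neu <- ty == IM_NEU
  if (any(neu))
    dec[neu] <- state$dt *
      (1 + q$il10_life_factor * state$f$IL10[state$im$pid[neu]])
  dec[ty == IM_MONO] <- 0
  state$im$life <- state$im$life - dec
  drop <- state$im$life <= 0
  if (any(drop)) {
    for (fld in c("pid", "itype", "act", "life"))
      state$im[[fld]] <- state$im[[fld]][!drop]
  }
  invisible(sum(drop))
}

# cytokine secretion by inflammatory agents -> next tick's field sources
secrete_inflammatory <- function(st) {
  q <- st$cfg$inflammation$secrete
  st$cyto <- NULL
  mac <- which(st$im$itype == IM_MAC)
  neu <- which(st$im$itype == IM_NEU)
  cyto <- list()
  if (length(mac)) {
    pid <- st$im$pid[mac]; a <- st$im$act[mac]
    cyto$TNFA <- list(ids = pid, rate = q$tnfa * a)
    cyto$IL6 <- list(ids = pid, rate = q$il6 * a)
    cyto$IL13 <- list(ids = pid, rate = rep(q$il13, length(pid)))
    cyto$IL15 <- list(ids = pid, rate = rep(q$il15, length(pid)))
    deb_p <- c(as.numeric(st$debris), 0)
    near <- deb_p[pid] + deb_p[st$up_i[pid]] + deb_p[st$down_i[pid]] +
      deb_p[st$left_i[pid]] + deb_p[st$right_i[pid]]
    calm <- near == 0
    if (any(calm))  # resolution phase: debris locally cleared
      cyto$IL10 <- list(ids = pid[calm], rate = rep(q$il10, sum(calm)))
  }
  if (length(neu)) {
    pid <- st$im$pid[neu]
    deb_p <- c(as.numeric(st$debris), 0)
    near <- deb_p[pid] + deb_p[st$up_i[pid]] + deb_p[st$down_i[pid]] +
      deb_p[st$left_i[pid]] + deb_p[st$right_i[pid]]
    eng <- near > 0
    if (any(eng))  # engaged neutrophils flag the site for macrophages
      cyto$IFNG <- list(ids = pid[eng], rate = rep(q$ifng, sum(eng)))
  }
  st$cyto <- if (length(cyto)) cyto else NULL
  invisible(NULL)
}

# slow enzymatic breakdown of isolated debris (autolysis); phagocytosis
# does the real work, this guarantees stragglers eventually resolve
autolyze_debris <- function(st) {
  deb <- which(st$debris)
  if (!length(deb)) return(invisible(0L))
  gone <- deb[stats::runif(length(deb)) < st$cfg$inflammation$debris_autolysis]
  if (length(gone)) {
    st$debris[gone] <- FALSE
    st$counts["autolyzed"] <- st$counts["autolyzed"] + length(gone)
  }
  invisible(length(gone))
}

# inflammation phase of a tick (skipped entirely while the tissue is quiet)
step_inflammation <- function(st) {
  quiet <- !any(st$debris) && all(st$im$itype == IM_MONO) &&
    max(st$f$TLR4_LIGAND) < 1e-9
  if (quiet) { st$cyto <- NULL; return(invisible(NULL)) }
  recruit_inflammatory(st)
  chemotax_cells(st)
  phagocytose(st)
  autolyze_debris(st)
  secrete_inflammatory(st)
  expire_inflammatory(st)
  invisible(NULL)
}
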