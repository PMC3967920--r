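# Gut epithelial cell (GEC) agents: stem, transit-amplifying (TA) and
# mature enterocytes on the unwrapped lattice. Transport is division-driven
# column displacement (a daughter pushes the contiguous stack above it one
# row towards the tip) plus a constant-rate upward drift into gaps opened by
# cell loss. Stem cells live in the niche (bottom crypt rows), divide
# asymmetrically and never migrate.

#' Differentiate beta-catenin-depleted cells
#'
#' A cell whose destruction complex is active (local Wnt lost for longer
#' than the activation delay) differentiates to an enterocyte once its
#' beta-catenin falls below the depletion threshold: its maturation clock
#' starts at zero and Hedgehog production begins with the elevated internal
#' Hh of a freshly differentiated cell.
#'
#' @param state A `cv_state` (modified in place).
#' @return Patch ids of cells that differentiated, invisibly.
#' @export
differentiate_cells <- function(state) {
  p <- state$cfg$signaling
  ids_d <- which((state$type == CV_STEM | state$type == CV_TA) &
                   state$dc & state$bcat < p$theta_diff)
  if (length(ids_d)) {
    state$type[ids_d] <- CV_ENT
    state$age_diff_min[ids_d] <- 0
    state$hh_int[ids_d] <- p$hh_diff_spike
  }
  invisible(ids_d)
}

#' Remove enterocytes by apoptosis
#'
#' Hazard per tick from [apoptosis_hazard()]: bound BMP (maturation clock),
#' Akt loss and received Hedgehog raise it; NF-kB suppresses it. Apoptotic
#' cells are removed instantly and cleanly (no debris, no DAMP release) —
#' physiological loss at the villus tip is this hazard catching cells at
#' the top of their maturation ramp.
#'
#' @param state A `cv_state` (modified in place).
#' @return Patch ids removed, invisibly.
#' @export
apoptose_cells <- function(state) {
  ids_e <- which(state$type == CV_ENT)
  if (!length(ids_e)) return(invisible(integer(0)))
  p <- state$cfg$signaling
  bmpb <- bmp_activity(state$f$BMP_FREE[ids_e], state$age_diff_min[ids_e], p)
  hh_sig <- state$hh_sig %||%
    (mean(state$f$HH) * (1 - state$mod$hh_block) / p$hh_ref)
  h <- apoptosis_hazard(bmpb, state$akt[ids_e], hh_sig,
                        state$nfkb[ids_e], state$dt, p)
  # trophic collapse: with the proliferative compartment extinct (no live
  # cell retains active Wnt signaling), survival support is lost tissue-wide
  if (max(state$bcat[state$type > 0L]) < p$theta_prolif)
    h <- pmax(h, p$h_collapse * state$dt / 15)
  dead <- ids_e[stats::runif(length(ids_e)) < h]
  if (length(dead)) {
    state$counts["apoptoses"] <- state$counts["apoptoses"] + length(dead)
    reset_cells(state, dead)
  }
  invisible(dead)
}

#' Necrose cells
#'
#' Cells whose RIP damage accumulator crosses the necrosis threshold (stem
#' cells are niche-protected by a higher threshold), or an explicitly forced
#' set, become necrotic debris in place: the patch keeps emitting TLR4
#' ligand (DAMPs) and damaging its 4-neighbors until inflammatory cells
#' clear it.
#'
#' @param state A `cv_state` (modified in place).
#' @param ids Optional patch ids to force into necrosis (e.g. a wound);
#'   default: all cells past their RIP threshold.
#' @return Patch ids necrosed, invisibly.
#' @export
necrose_cells <- function(state, ids = NULL) {
  p <- state$cfg$signaling
  if (is.null(ids)) {
    thr <- ifelse(state$type == CV_STEM,
                  p$rip_theta * p$rip_theta_stem_factor, p$rip_theta)
    ids <- which(state$type > 0L & state$rip >= thr)
  } else {
    ids <- ids[state$type[ids] > 0L]
  }
  make_debris(state, ids)
  invisible(ids)
}

# unconditional division with column displacement; daughter TA one row up
# (asymmetric stem division: the daughter is inserted above the whole stem
# stack so no stem is ever displaced out of the niche)
do_division_at <- function(st, id) {
  r <- st$row_of[id]; cc <- st$col_of[id]
  cid <- st$ids[, cc]
  while (r < st$R && st$type[cid[r + 1L]] == CV_STEM) r <- r + 1L
  if (r >= st$R) return(invisible(NULL))  # no room above the lattice
  above <- st$type[cid[(r + 1L):st$R]] == 0L
  gap <- which(above)[1]
  if (is.na(gap)) {  # column full: tip-most cell is displaced off the lattice
    st$counts["tip_exits"] <- st$counts["tip_exits"] + 1
    reset_cells(st, cid[st$R])
    er <- st$R
  } else er <- r + gap
  if (er > r + 1L) {
    src <- cid[(r + 1L):(er - 1L)]
    dst <- cid[(r + 2L):er]
    for (v in CELL_VECS) st[[v]][dst] <- st[[v]][src]
  }
  d <- cid[r + 1L]
  for (v in c("bcat", "wnt_free_min", "dc", "pten", "hh_int", "akt",
              "tlr4", "chronic", "nfkb", "ros", "jak", "ifabp"))
    st[[v]][d] <- st[[v]][id]   # I-FABP load partitions to the daughter
  st$type[d] <- CV_TA
  st$age_min[d] <- 0; st$age_diff_min[d] <- NA_real_
  st$rip[d] <- 0; st$dose[d] <- 0
  st$label[d] <- FALSE
  st$counts["births"] <- st$counts["births"] + 1
  invisible(d)
}

#' Attempt one cell division
#'
#' A stem or TA cell with active Wnt signaling (beta-catenin above the
#' proliferation threshold) divides with its per-tick probability. The
#' daughter is a TA cell placed one row towards the tip, displacing the
#' contiguous column of cells above it; if the column reaches the top of
#' the lattice the tip-most cell is shed. Stem divisions are asymmetric:
#' the stem stays in the niche. Enterocytes never divide.
#'
#' @param state A `cv_state` (modified in place).
#' @param patch_id Patch of the candidate mother cell.
#' @return Patch id of the daughter, or `NULL` if no division occurred.
#' @export
attempt_division <- function(state, patch_id) {
  ty <- state$type[patch_id]
  if (!(ty %in% c(CV_STEM, CV_TA))) return(NULL)
  p <- state$cfg
  if (state$bcat[patch_id] < p$signaling$theta_prolif) return(NULL)
  pr <- if (ty == CV_STEM) p$cells$p_stem else p$cells$p_div
  if (stats::runif(1) >= pr) return(NULL)
  d <- do_division_at(state, patch_id)
  if (is.null(d)) NULL else d
}

divide_all <- function(st) {
  p <- st$cfg
  elig <- which((st$type == CV_STEM | st$type == CV_TA) &
                  st$bcat >= p$signaling$theta_prolif)
  if (!length(elig)) return(invisible(NULL))
  pr <- ifelse(st$type[elig] == CV_STEM, p$cells$p_stem, p$cells$p_div)
  chosen <- elig[stats::runif(length(elig)) < pr]
  if (length(chosen) > 1L) chosen <- sample(chosen)  # shuffled update order
  for (id in chosen) do_division_at(st, id)
  invisible(NULL)
}

#' Migrate cells towards the villus tip
#'
#' Non-stem cells step one row up with the drift probability, but only into
#' an unoccupied patch — the drift closes gaps opened by cell death while
#' net column transport is set by the division flux. Cells cross the crypt
#' rim onto the linked villus base. Necrotic debris is patch-bound and may
#' be co-occupied by a migrating live cell.
#'
#' @param state A `cv_state` (modified in place).
#' @return Number of cells moved, invisibly.
#' @export
migrate_cells <- function(state) {
  ty_p <- c(state$type, 1L)  # sentinel blocks moving off-lattice
  movers <- which(state$type == CV_TA | state$type == CV_ENT)
  if (!length(movers)) return(invisible(0L))
  up <- state$up_i[movers]
  ok <- ty_p[up] == 0L
  movers <- movers[ok]; up <- up[ok]
  go <- stats::runif(length(movers)) < state$cfg$cells$p_move
  movers <- movers[go]; up <- up[go]
  if (length(movers)) {
    for (v in CELL_VECS) {
      state[[v]][up] <- state[[v]][movers]
    }
    reset_cells(state, movers)
  }
  invisible(length(movers))
}

#' Apply reperfusion commitments (sloughing vs necrosis)
#'
#' During ischemia every live cell accrues I-FABP (linear in time, scaled
#' by the axial severity gradient) and an accelerating ischemic-injury
#' dose. At reperfusion, enterocytes whose I-FABP load exceeds the
#' sloughing threshold — equivalently, whose severity exceeds a threshold
#' that falls with the log of the ischemic duration, so longer ischemia
#' sloughs a deeper band of the villus — are shed cleanly into the lumen
#' (removed; no debris, no DAMP release) when sloughing is enabled.
#' Otherwise those impending-necrotic cells die in place as debris.
#' Undifferentiated cells past the (much higher) necrotic commitment dose
#' become debris regardless.
#'
#' @param state A `cv_state` (modified in place).
#' @param sloughing_enabled Logical.
#' @return List of patch ids: `sloughed`, `necrosed`, invisibly.
#' @export
slough_cells <- function(state, sloughing_enabled = TRUE) {
  p <- state$cfg$cells
  d <- state$dose
  t_isch <- state$t - state$mod$isch_t0
  sev_thr <- p$slough_sev0 -
    p$slough_sev_slope * log2(pmax(1, t_isch / 30))
  ent <- which(state$type == CV_ENT & state$sev >= sev_thr & d > 0)
  sloughed <- integer(0); necro <- integer(0); apop <- integer(0)
  if (length(ent)) {
    if (sloughing_enabled) {
      sloughed <- ent
      state$counts["sloughs"] <- state$counts["sloughs"] + length(ent)
      reset_cells(state, ent)
    } else necro <- ent
  }
  # graded ischemic death of the proliferative compartment: moderate doses
  # kill cleanly (apoptosis), extreme doses leave necrotic debris in place;
  # stem cells have their own, shallower vulnerability curve (partial ISC
  # death at intermediate ischemia)
  und <- which((state$type == CV_STEM | state$type == CV_TA) & d > 0)
  if (length(und)) {
    stem <- state$type[und] == CV_STEM
    th <- ifelse(stem, p$stem_isch_theta, p$ta_isch_theta)
    wd <- ifelse(stem, p$stem_isch_width, p$ta_isch_width)
    die <- und[stats::runif(length(und)) < stats::plogis((d[und] - th) / wd)]
    if (length(die)) {
      pr_nec <- stats::plogis((d[die] - p$necro_commit_theta) /
                                p$necro_commit_width)
      nec2 <- die[stats::runif(length(die)) < pr_nec]
      apop <- setdiff(die, nec2)
      necro <- c(necro, nec2)
      if (length(apop)) {
        state$counts["apoptoses"] <- state$counts["apoptoses"] + length(apop)
        reset_cells(state, apop)
      }
    }
  }
  make_debris(state, necro)
  invisible(list(sloughed = sloughed, necrosed = necro, apoptosed = apop))
}

# physical-action phase of a tick
step_epithelium <- function(st) {
  differentiate_cells(st)
  necrose_cells(st)
  apoptose_cells(st)
  if (!st$mod$ischemic) {
    divide_all(st)
    migrate_cells(st)
  }
  invisible(NULL)
}
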