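# Engine: discrete-time scheduler binding geometry, fields, signaling,
# epithelium, inflammation, scenarios and metrics. The tissue state is an
# environment holding per-patch vectors indexed by geometry patch id; all
# per-tick updates are vectorized over patches. One global RNG stream
# (seeded once per run) drives every stochastic decision, so a fixed seed
# and config give byte-identical output.

# cell types
CV_EMPTY <- 0L; CV_STEM <- 1L; CV_TA <- 2L; CV_ENT <- 3L

# per-cell attribute vectors moved together on division pushes / migration
CELL_VECS <- c("type", "bcat", "wnt_free_min", "dc", "age_min",
               "age_diff_min", "pten", "hh_int", "akt", "tlr4", "chronic",
               "nfkb", "rip", "ros", "jak", "ifabp", "dose", "label")

METRIC_COLS <- c("time_min", "crypt_alive", "villus_alive", "total_alive",
                 "necrotic", "neutrophils", "macrophages", "monocytes",
                 "wnt_total", "crypt_depth_um", "villus_height_um", "ratio",
                 "junction_row", "births", "apoptoses", "necroses",
                 "sloughs", "tip_exits", "cleared", "debris_formed",
                 "labeled_alive")

#' Create a fresh tissue state
#'
#' Builds the lattice, precomputes diffusion operators and neighbor index
#' tables, and seeds a near-homeostatic cell layout (stem niche in the
#' bottom crypt rows, transit-amplifying cells above it, an enterocyte
#' column with a maturation-age gradient). Fields start empty and
#' equilibrate during burn-in. Resident inactive monocytes are scattered
#' sparsely. Consumes RNG draws (monocyte placement), so seed beforehand or
#' use [simulate_tissue()].
#'
#' @param config A `cv_config`.
#' @return A `cv_state` environment.
#' @export
new_state <- function(config = default_config()) {
  validate_config(config)
  g <- config$geometry
  topo <- build_tissue(g)
  st <- new.env(parent = emptyenv())
  st$cfg <- config
  st$topo <- topo
  Hc <- g$crypt_rows; Hv <- g$villus_rows
  R <- Hc + Hv; W <- g$crypt_width
  n <- topo$n_patches
  st$R <- R; st$W <- W; st$Hc <- Hc; st$n <- n
  st$patch_um <- g$patch_um

  # combined (row, col) -> patch id; geometry orders crypt unit then villus,
  # column-major within each unit
  ids <- matrix(0L, nrow = R, ncol = W)
  for (j in seq_len(W)) {
    ids[seq_len(Hc), j] <- (j - 1L) * Hc + seq_len(Hc)
    ids[Hc + seq_len(Hv), j] <- W * Hc + (j - 1L) * Hv + seq_len(Hv)
  }
  st$ids <- ids
  st$row_of <- integer(n); st$col_of <- integer(n)
  st$row_of[as.vector(ids)] <- rep(seq_len(R), times = W)
  st$col_of[as.vector(ids)] <- rep(seq_len(W), each = R)
  st$axial <- topo$patches$axial_pos

  # padded neighbor indices (n + 1 is a zero-valued sentinel)
  pad <- function(v) ifelse(is.na(v), n + 1L, v)
  st$up_i <- pad(topo$adj[, "up"]); st$down_i <- pad(topo$adj[, "down"])
  st$left_i <- pad(topo$adj[, "left"]); st$right_i <- pad(topo$adj[, "right"])

  dt <- config$engine$dt_cell
  st$dt <- dt
  st$ops <- lapply(CV_SPECIES, function(sp) {
    fp <- config$fields[[sp]]
    if (fp$D == 0 && fp$k == 0) NULL
    else make_field_operator(topo, fp$D, fp$k, dt)
  })
  names(st$ops) <- CV_SPECIES
  st$f <- lapply(CV_SPECIES, function(sp) numeric(n))
  names(st$f) <- CV_SPECIES
  st$f$BMP_FREE <- rep(config$fields$BMP_FREE$uniform, n)
  st$wnt_src_ids <- as.vector(ids[seq_len(config$fields$wnt_source_rows), ])

  # cell vectors (dc and label are numeric 0/1 so block moves stay uniform)
  for (v in CELL_VECS) st[[v]] <- numeric(n)
  st$type <- integer(n)
  st$debris <- logical(n)
  st$age_diff_min <- rep(NA_real_, n)
  st$sev <- numeric(n)

  # near-homeostatic seed layout (burn-in settles fields and the junction)
  p <- config$cells; s <- config$signaling
  flux <- p$stem_rows * p$p_stem + 10 * p$p_div      # rows per tick
  hom_junction <- 12L
  hom_tip <- min(R, hom_junction + round(flux * s$bmp_ramp_min *
                                           s$apop_theta / dt))
  for (r in seq_len(min(hom_tip, R))) {
    row_ids <- ids[r, ]
    if (r <= p$stem_rows) {
      st$type[row_ids] <- CV_STEM; st$bcat[row_ids] <- 1
    } else if (r <= hom_junction) {
      st$type[row_ids] <- CV_TA; st$bcat[row_ids] <- 1
    } else {
      st$type[row_ids] <- CV_ENT
      st$bcat[row_ids] <- s$theta_diff / 2
      st$age_diff_min[row_ids] <- (r - hom_junction) / flux * dt
      st$wnt_free_min[row_ids] <- s$dc_delay_min + 1
      st$dc[row_ids] <- TRUE
    }
    st$pten[row_ids] <- 1; st$hh_int[row_ids] <- 1; st$akt[row_ids] <- 1
  }

  # resident inactive monocytes (itype 1), sparse
  n_mono <- max(1L, floor(n / config$inflammation$resident_per_patches))
  mono_ids <- sample.int(n, n_mono)
  st$im <- list(pid = mono_ids, itype = rep(1L, n_mono),
                act = numeric(n_mono), life = rep(Inf, n_mono))
  st$cyto <- NULL  # inflammatory secretion sources, rebuilt each tick

  st$mod <- list(sfrp1_ext = 0, hh_block = 0, pten_block = 0,
                 chronic_ligand = 0, ischemic = FALSE, isch_t0 = NA_real_,
                 slough_enabled = TRUE)
  st$t <- 0
  st$counts <- c(births = 0, apoptoses = 0, necroses = 0, sloughs = 0,
                 tip_exits = 0, cleared = 0, autolyzed = 0,
                 debris_formed = 0)
  class(st) <- c("cv_state", "environment")
  st
}

alive_mask <- function(st) st$type > 0L

reset_cells <- function(st, ids_rm) {
  for (v in CELL_VECS) st[[v]][ids_rm] <- 0
  st$type[ids_rm] <- CV_EMPTY
  st$dc[ids_rm] <- FALSE
  st$label[ids_rm] <- FALSE
  st$age_diff_min[ids_rm] <- NA_real_
}

make_debris <- function(st, ids_nec) {
  if (!length(ids_nec)) return(invisible(NULL))
  st$counts["necroses"] <- st$counts["necroses"] + length(ids_nec)
  # a cell dying on an already-debris patch merges with it (one unit/patch)
  st$counts["debris_formed"] <- st$counts["debris_formed"] +
    sum(!st$debris[ids_nec])
  reset_cells(st, ids_nec)
  st$debris[ids_nec] <- TRUE
  invisible(NULL)
}

# ---- tick phases ----------------------------------------------------------

step_fields_engine <- function(st) {
  dt <- st$dt
  cfg <- st$cfg
  n <- st$n
  ent <- which(st$type == CV_ENT)
  deb <- which(st$debris)

  src <- list()
  src$WNT <- list(ids = st$wnt_src_ids,
                  rate = rep(cfg$fields$wnt_source_rate,
                             length(st$wnt_src_ids)))
  if (length(ent)) {
    sec <- hh_sfrp1_production(TRUE, st$hh_int[ent],
                               st$f$HH[ent] * (1 - st$mod$hh_block),
                               cfg$signaling)
    src$HH <- list(ids = ent, rate = sec$hh)
    src$SFRP1 <- list(ids = ent, rate = sec$sfrp1)
  }
  if (length(deb))
    src$TLR4_LIGAND <- list(ids = deb,
                            rate = rep(cfg$fields$debris_damp_rate,
                                       length(deb)))
  for (sp in c("WNT", "SFRP1", "HH", "TLR4_LIGAND", "TNFA", "IFNG",
               "IL6", "IL10", "IL13", "IL15")) {
    conc <- st$f[[sp]]
    s1 <- src[[sp]]
    cy <- st$cyto[[sp]]
    active <- !is.null(s1) || !is.null(cy) || any(conc > 1e-12)
    if (sp == "SFRP1" && st$mod$sfrp1_ext > 0) {
      conc <- conc + st$mod$sfrp1_ext * dt
      active <- TRUE
    }
    if (!active) next
    if (!is.null(s1)) conc[s1$ids] <- conc[s1$ids] + s1$rate * dt
    if (!is.null(cy)) conc[cy$ids] <- conc[cy$ids] + cy$rate * dt
    st$f[[sp]] <- as.numeric(st$ops[[sp]] %*% conc)
  }
  # SFRP1 neutralizes Wnt by stoichiometric annihilation on contact
  m <- pmin(st$f$WNT, st$f$SFRP1)
  if (any(m > 0)) {
    st$f$WNT <- st$f$WNT - m
    st$f$SFRP1 <- st$f$SFRP1 - m
  }
  invisible(NULL)
}

step_signaling_engine <- function(st) {
  dt <- st$dt
  p <- st$cfg$signaling
  a <- which(st$type > 0L)
  if (!length(a)) return(invisible(NULL))

  wb <- wnt_bcat_update(st$bcat[a], st$wnt_free_min[a], st$f$WNT[a], dt, p)
  st$bcat[a] <- wb$bcat
  st$wnt_free_min[a] <- wb$wnt_free_min
  st$dc[a] <- wb$dc_active

  # tissue-level Hedgehog signal (hormone-like readout of villus mass)
  st$hh_sig <- mean(st$f$HH) * (1 - st$mod$hh_block) / p$hh_ref
  px <- pten_axis_update(st$pten[a], st$hh_int[a], st$hh_sig, st$chronic[a],
                         dt, p, pten_block = st$mod$pten_block)
  st$pten[a] <- px$pten; st$hh_int[a] <- px$hh_internal; st$akt[a] <- px$akt

  debn_p <- c(as.numeric(st$debris), 0)
  nb_debris <- debn_p[st$up_i[a]] + debn_p[st$down_i[a]] +
    debn_p[st$left_i[a]] + debn_p[st$right_i[a]]
  lig <- st$f$TLR4_LIGAND[a] + st$mod$chronic_ligand
  ia <- inflammatory_axis_update(st$tlr4[a], st$chronic[a], st$nfkb[a],
                                 st$rip[a], st$ros[a], st$jak[a],
                                 ligand = lig, debris_neighbors = nb_debris,
                                 ifabp = st$ifabp[a],
                                 il6 = st$f$IL6[a], il10 = st$f$IL10[a],
                                 dt = dt, p = p)
  st$tlr4[a] <- ia$tlr4; st$chronic[a] <- ia$chronic; st$nfkb[a] <- ia$nfkb
  st$rip[a] <- ia$rip; st$ros[a] <- ia$ros; st$jak[a] <- ia$jak

  if (st$mod$ischemic) {
    t_is <- st$t - st$mod$isch_t0
    sv <- st$sev[a]
    st$dose[a] <- st$dose[a] + sv * ((t_is + dt)^2 - t_is^2) / 240
    st$ifabp[a] <- st$ifabp[a] + sv * dt
  } else {
    st$ifabp[a] <- st$ifabp[a] * exp(-dt / st$cfg$cells$ifabp_tau)
  }

  st$age_min[a] <- st$age_min[a] + dt
  st$age_diff_min[a] <- st$age_diff_min[a] + dt  # NA stays NA
  invisible(NULL)
}

# rows' majority composition -> junction, depth, height (internal fast path)
architecture_rows <- function(st) {
  und <- st$type == CV_STEM | st$type == CV_TA
  ent <- st$type == CV_ENT
  und_rows <- tabulate(st$row_of[und], nbins = st$R)
  ent_rows <- tabulate(st$row_of[ent], nbins = st$R)
  occ <- und_rows + ent_rows
  maj_und <- which(occ > 0 & und_rows >= ent_rows)
  junction <- if (length(maj_und)) max(maj_und) else 0L
  ent_major <- which(ent_rows >= ceiling(st$W / 2))
  ent_major <- ent_major[ent_major > junction]
  tip <- if (length(ent_major)) max(ent_major) else junction
  list(junction = junction, tip = tip,
       und_rows = und_rows, ent_rows = ent_rows)
}

append_metrics <- function(st, k) {
  ar <- architecture_rows(st)
  j <- ar$junction
  alive_rows <- ar$und_rows + ar$ent_rows
  crypt_alive <- if (j > 0) sum(alive_rows[seq_len(j)]) else 0
  total_alive <- sum(alive_rows)
  villus_alive <- total_alive - crypt_alive
  height <- max(0, (ar$tip - j)) * st$patch_um
  depth <- j * st$patch_um
  it <- st$im$itype
  st$metrics[k, ] <- c(st$t, crypt_alive, villus_alive, total_alive,
                       sum(st$debris), sum(it == 3L), sum(it == 2L),
                       sum(it == 1L), sum(st$f$WNT),
                       depth, height,
                       if (height > 0) depth / height else NA_real_,
                       j, st$counts[["births"]], st$counts[["apoptoses"]],
                       st$counts[["necroses"]], st$counts[["sloughs"]],
                       st$counts[["tip_exits"]],
                       st$counts[["cleared"]] + st$counts[["autolyzed"]],
                       st$counts[["debris_formed"]],
                       sum(st$label))
  st$counts[] <- 0
  invisible(NULL)
}

cv_tick <- function(st, scenario_events = NULL) {
  step_fields_engine(st)
  step_signaling_engine(st)
  step_epithelium(st)
  step_inflammation(st)
  st$t <- st$t + st$dt
  if (!is.null(scenario_events)) apply_due_events(st, scenario_events)
  invisible(NULL)
}

#' Run the simulator
#'
#' Advances a tissue state (fresh, or a supplied checkpoint) for a given
#' simulated duration under an optional perturbation scenario. Each 15-min
#' tick performs, in order: field substeps; signaling updates with
#' delayed-effect delivery for every live cell; physical cell actions
#' (differentiation, necrosis, apoptosis, division with column displacement,
#' migration); inflammatory-cell actions (recruitment, chemotaxis,
#' phagocytosis, expiry); scenario schedule; metrics. A fixed seed and
#' config give a bit-identical run.
#'
#' @param config A `cv_config`; ignored when `init` is given.
#' @param days,minutes Simulated duration (supply one).
#' @param seed Integer seed, or `NULL` to continue the current RNG stream
#'   (e.g. straight after restoring a checkpoint).
#' @param scenario A scenario from one of the `scenario_*()` constructors,
#'   or `NULL` for baseline.
#' @param init Optional `cv_state` to continue from (it is copied, not
#'   mutated).
#' @param label_at_start Mark all currently-alive non-stem cells so their
#'   disappearance can be tracked (`labeled_alive` metric column); used for
#'   renewal measurement.
#' @return A `cv_run`: list with `metrics` (tibble, one row per tick),
#'   `state` (final `cv_state`), `config`, `scenario`, `seed`.
#' @export
simulate_tissue <- function(config = default_config(), days = NULL,
                            minutes = NULL, seed = 1L, scenario = NULL,
                            init = NULL, label_at_start = FALSE) {
  if (is.null(minutes)) {
    if (is.null(days)) stop("supply days or minutes", call. = FALSE)
    minutes <- days * 1440
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  st <- if (is.null(init)) new_state(config) else copy_state(init)
  if (label_at_start) label_cells(st)
  n_ticks <- max(0L, floor(minutes / st$dt))
  st$metrics <- matrix(NA_real_, nrow = n_ticks, ncol = length(METRIC_COLS),
                       dimnames = list(NULL, METRIC_COLS))
  ev <- prepare_events(st, scenario)
  if (n_ticks > 0) {
    apply_due_events(st, ev)  # events scheduled at t = 0
    for (k in seq_len(n_ticks)) {
      cv_tick(st, ev)
      append_metrics(st, k)
    }
  }
  st$rng_state <- get(".Random.seed", envir = globalenv())
  out <- list(metrics = tibble::as_tibble(as.data.frame(st$metrics)),
              state = st, config = st$cfg, scenario = scenario, seed = seed)
  st$metrics <- NULL
  class(out) <- "cv_run"
  out
}

#' @export
print.cv_run <- function(x, ...) {
  m <- x$metrics
  k <- nrow(m)
  cat("<cv_run> ", k, " ticks (", signif(m$time_min[k] / 1440, 3),
      " days), scenario: ",
      if (is.null(x$scenario)) "baseline" else x$scenario$name, "\n",
      "  final: crypt ", m$crypt_alive[k], ", villus ", m$villus_alive[k],
      ", necrotic ", m$necrotic[k],
      ", ratio ", signif(m$ratio[k], 3), "\n", sep = "")
  invisible(x)
}

#' Label all alive non-stem cells
#'
#' Stem cells are permanent niche residents and are excluded. The
#' `labeled_alive` metric column then tracks the cohort's disappearance.
#'
#' @param state A `cv_state` (modified in place).
#' @return Number of cells labeled, invisibly.
#' @export
label_cells <- function(state) {
  ids_l <- which(state$type == CV_TA | state$type == CV_ENT)
  state$label[ids_l] <- TRUE
  invisible(length(ids_l))
}

# deep copy of a state environment (vectors copy on assignment)
copy_state <- function(st) {
  st2 <- new.env(parent = emptyenv())
  for (nm in ls(st, all.names = TRUE)) st2[[nm]] <- st[[nm]]
  class(st2) <- c("cv_state", "environment")
  st2
}

#' Burn a fresh tissue in to homeostasis and return the state
#'
#' Every perturbation scenario starts from such a checkpoint so that
#' responses are not confounded by initialization transients. Results are
#' memoized per (config, seed, burn-in) within the session.
#'
#' @param config A `cv_config`.
#' @param seed Integer seed.
#' @param burn_in_days Simulated days of burn-in.
#' @param cache Reuse a previously computed checkpoint for the same key.
#' @return A `cv_state` at homeostasis (RNG state stored in the state).
#' @export
homeostatic_checkpoint <- function(config = default_config(), seed = 1L,
                                   burn_in_days = config$engine$burn_in_days,
                                   cache = TRUE) {
  key <- rlang::hash(list(config, seed, burn_in_days))
  if (cache && !is.null(.cv_cache[[key]])) return(copy_state(.cv_cache[[key]]))
  run <- simulate_tissue(config, days = burn_in_days, seed = seed)
  stx <- run$state
  stx$rng_state <- .Random.seed
  if (cache) .cv_cache[[key]] <- copy_state(stx)
  stx
}

.cv_cache <- new.env(parent = emptyenv())

#' Save / restore a checkpoint
#'
#' The full state (cell vectors, fields, inflammatory agents, scenario
#' modifiers, counters and RNG stream position) is written as a plain-text
#' file (base64-wrapped serialization), which round-trips every value
#' exactly:
#' restoring and continuing reproduces the uninterrupted run bit for bit.
#' Diffusion operators and index tables are rebuilt from the config on
#' restore.
#'
#' @param state A `cv_state`.
#' @param path File path.
#' @return `save_checkpoint`: the path, invisibly. `restore_checkpoint`:
#'   a `cv_state`.
#' @export
save_checkpoint <- function(state, path) {
  keep <- c(CELL_VECS, "debris", "sev", "t", "counts", "mod", "im")
  payload <- list(config = unclass_config(state$cfg),
                  rng = if (!is.null(state$rng_state)) state$rng_state
                        else .Random.seed,
                  fields = state$f)
  for (nm in keep) payload[[nm]] <- state[[nm]]
  writeLines(c("cryptvillus-checkpoint-v1",
               jsonlite::base64_enc(serialize(payload, NULL))), path)
  invisible(path)
}

unclass_config <- function(cfg) {
  cfg2 <- unclass(cfg); cfg2$geometry <- unclass(cfg2$geometry); cfg2
}

#' @rdname save_checkpoint
#' @export
restore_checkpoint <- function(path) {
  payload <- tryCatch({
    ln <- readLines(path, warn = FALSE)
    stopifnot(ln[1] == "cryptvillus-checkpoint-v1")
    unserialize(jsonlite::base64_dec(paste(ln[-1], collapse = "")))
  }, error = function(e)
    stop("corrupted or unreadable checkpoint: ",
         conditionMessage(e), call. = FALSE))
  need <- c("config", "rng", "fields", "type", "t", "mod")
  if (!is.list(payload) || !all(need %in% names(payload)))
    stop("corrupted checkpoint: missing fields", call. = FALSE)
  geo <- do.call(tissue_config, payload$config$geometry[
    c("n_villi", "crypts_per_villus", "crypt_width", "crypt_rows",
      "villus_rows", "patch_um")])
  blocks <- payload$config[setdiff(names(payload$config),
                                   c("geometry", "class"))]
  cfg <- do.call(default_config, c(list(geometry = geo), blocks))
  st <- new_state(cfg)   # consumes monocyte placement draws; overwritten below
  for (nm in c(CELL_VECS, "debris", "sev", "t")) st[[nm]] <- payload[[nm]]
  st$counts <- payload$counts
  st$mod <- payload$mod
  st$im <- payload$im
  st$f <- payload$fields
  st$rng_state <- payload$rng
  st
}

#' Resume the RNG stream stored in a checkpoint
#'
#' @param state A `cv_state` with a stored RNG position.
#' @return Invisibly, TRUE.
#' @export
resume_rng <- function(state) {
  if (is.null(state$rng_state)) stop("state has no stored RNG", call. = FALSE)
  assign(".Random.seed", as.integer(state$rng_state), envir = globalenv())
  invisible(TRUE)
}
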