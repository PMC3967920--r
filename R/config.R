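#' Default model parameters
#'
#' All rates are per minute unless stated otherwise; concentrations are in
#' arbitrary units with homeostatic intracellular baselines of 1. The
#' defaults are the package's calibrated study conditions: they place the
#' emergent crypt-villus junction so that crypt depth is ~1/4 of a ~1 mm
#' villus, give whole-epithelium renewal of ~5 days, and let a villus-wide
#' wound clear within ~24 h. See the methods vignette for the calibration
#' rationale of each block.
#'
#' @format A named list of parameter blocks: `engine`, `fields`, `signaling`,
#'   `cells`, `inflammation`, `metrics`.
#' @export
cv_defaults <- list(
  engine = list(
    dt_cell = 15,            # minutes per physical-action tick (~10^3 s)
    burn_in_days = 7
  ),
  fields = list(
    WNT         = list(D = 0.30, k = 0.010),
    BMP_FREE    = list(D = 0,    k = 0,     uniform = 1.0),
    SFRP1       = list(D = 0.50, k = 0.004),
    HH          = list(D = 0.40, k = 0.010),
    TLR4_LIGAND = list(D = 0.30, k = 0.020),
    TNFA        = list(D = 0.30, k = 0.020),
    IFNG        = list(D = 0.30, k = 0.020),
    IL6         = list(D = 0.30, k = 0.020),
    IL10        = list(D = 0.30, k = 0.020),
    IL13        = list(D = 0.15, k = 0.020),
    IL15        = list(D = 0.15, k = 0.020),
    wnt_source_rate = 1.0,   # emission per source patch per min
    wnt_source_rows = 2L,    # bottom crypt rows that emit Wnt
    debris_damp_rate = 6.0   # TLR4-ligand emission per debris patch per min
  ),
  signaling = list(
    wnt_eps = 3.5,           # Wnt activity threshold (a.u.)
    dc_delay_min = 30,       # destruction-complex activation delay
    tau_bcat_up = 60,        # beta-catenin accumulation time constant
    tau_bcat_down = 120,     # beta-catenin decay once complex is active
    theta_diff = 0.30,       # beta-catenin depletion -> differentiation
    theta_prolif = 0.50,     # beta-catenin needed to divide
    bmp_ramp_min = 5250,     # receptor-availability ramp (maturation clock)
    bmp_ramp_shape = 1.0,    # concavity of the receptor ramp (<= 1)
    hh_secretion_rate = 0.010,
    sfrp1_secretion_rate = 0.060,
    sfrp1_hh_sat = 0.80,     # receptor saturation of the Hh->SFRP1 response
    hh_ref = 0.40,           # homeostatic tissue-mean extracellular Hh
    hh_diff_spike = 1,       # internal Hh of a freshly differentiated cell
    tau_hh = 240,
    tau_pten = 240,
    hh_pten_slope = 0.4,     # strength of PTEN inhibition of internal Hh
    akt_max = 1.3,           # PI3K capacity bound on Akt
    tlr4_pten_gain = 2,      # chronic TLR4 tone -> PTEN up-regulation
    tau_tlr4 = 30,
    tau_chronic = 720,       # slow filter: acute spikes barely move PTEN
    tau_nfkb = 120,
    tau_ros = 120,
    tau_jak = 120,
    tlr4_K = 8,              # ligand half-saturation for TLR4 activation
    rip_contact_rate = 0.0012,  # RIP gain per adjacent debris patch per min
    rip_ligand_basal = 0.006,   # ungated RIP gain per supra-floor TLR4
    rip_ligand_rate = 0.020,    # extra gain per unit ischemic sensitization
                                # (ischemia-sensitized cells only)
    rip_tlr4_floor = 0.6,       # low-grade activation does not engage RIP
    rip_tlr4_floor_sens = 0.45, # ischemia-primed cells respond to less ligand
    tau_rip = 720,           # slow resolution of sub-threshold RIP damage
    sens_K = 12,             # I-FABP scale of ischemic sensitization (quadratic)
    sens_cap = 30,           # max ischemic sensitization multiplier
    rip_theta = 1,           # necrosis threshold (TA/enterocyte)
    rip_theta_stem_factor = 10,   # stem-niche protection multiplier
    w_akt = 1, w_hh = 1,     # weights of the two apoptotic arms
    drive_beta = 2.60,       # exponent of the Akt-loss arm
    apop_theta = 0.8,        # apoptotic-drive threshold
    apop_width = 0.05,
    h_base = 2e-4,           # baseline hazard per 15-min tick
    h_max = 0.6,             # hazard above threshold per 15-min tick
    h_collapse = 0.03,       # hazard floor once no proliferative cells remain
    nfkb_protect = 1
  ),
  cells = list(
    p_stem = 0.0025,         # asymmetric stem division prob per tick
    p_div = 0.025,           # TA division prob per tick
    p_move = 0.30,           # gap-filling upward step prob per tick
    stem_rows = 2L,          # niche: bottom crypt rows
    ifabp_tau = 1440,        # I-FABP clearance time constant post-ischemia
    slough_sev0 = 0.85,      # severity sloughed after a 30-min ischemia
    slough_sev_slope = 0.10, # threshold drop per doubling of ischemic time
    ta_isch_theta = 140,     # TA ischemic-death dose (clean, apoptotic)
    ta_isch_width = 6,
    stem_isch_theta = 140,   # stem ischemic-death dose (shallower curve)
    stem_isch_width = 10,
    necro_commit_theta = 200,  # extreme dose: necrosis in place instead
    necro_commit_width = 3,
    sev_floor = 0.36         # ischemia severity at the crypt base
  ),
  inflammation = list(
    resident_per_patches = 50,  # one inactive monocyte per this many patches
    recruit_burst = 3L,      # arrival slots per vessel per tick and type
    r_neutrophil = 0.9,      # max recruit prob per arrival slot
    r_macrophage = 0.6,
    recruit_K = 2,           # half-saturation of recruitment (ligand + TNFa)
    ifng_activation = 0.3,   # IFN-gamma threshold activating monocytes
    chemotax_eps = 1e-8,     # gradient below this is "flat" (random step)
    chemotax_noise = 0.35,   # exploratory (non-gradient) step probability
    steps_per_tick = 3L,     # chemotaxis moves per tick (~4 um/min)
    neutrophil_life = 2880,  # minutes
    macrophage_life = 5760,
    debris_autolysis = 0.005,   # per-tick spontaneous breakdown of debris
    il10_life_factor = 2,    # IL-10 shortens neutrophil lifespan
    secrete = list(tnfa = 0.2, il6 = 0.2, ifng = 0.5, il10 = 0.5,
                   il13 = 0.01, il15 = 0.01)
  ),
  metrics = list(
    recovery_band = 0.10,    # +/- band around baseline for "recovered"
    eval_window_min = 1440   # final window used for outcome classification
                             # (after the standard 72-h I/R follow-up)
  )
)

#' Build a full simulation configuration
#'
#' Merges overrides into [cv_defaults] and attaches the lattice geometry.
#' Overrides are given per block, e.g.
#' `default_config(cells = list(p_div = 0.012))`.
#'
#' @param geometry A `cv_geometry` (see [tissue_config()]).
#' @param ... Named parameter blocks with entries to override.
#' @return A `cv_config` list.
#' @export
default_config <- function(geometry = tissue_config(), ...) {
  cfg <- cv_defaults
  over <- list(...)
  for (blk in names(over)) {
    if (!blk %in% names(cfg))
      stop("unknown config block: ", blk, call. = FALSE)
    for (nm in names(over[[blk]])) {
      if (!nm %in% names(cfg[[blk]]))
        stop("unknown parameter: ", blk, "$", nm, call. = FALSE)
      cfg[[blk]][[nm]] <- over[[blk]][[nm]]
    }
  }
  cfg$geometry <- geometry
  class(cfg) <- "cv_config"
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks field paths and reports the offending entry on failure: positive
#' rates, thresholds in range, diffusion stable under the tick substepping,
#' and a single-complex geometry (the engine simulates one crypt-villus
#' unit; the geometry module itself supports more).
#'
#' @param config A `cv_config`.
#' @return The config, invisibly, or an error naming the bad field.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "cv_config"))
  validate_geometry(config$geometry)
  chk <- function(val, path, lo = 0, hi = Inf, strict = FALSE) {
    bad <- !is.numeric(val) || length(val) != 1 || is.na(val) ||
      val < lo || val > hi || (strict && val <= lo)
    if (bad) stop("config error at ", path, ": must be in [", lo, ", ", hi,
                  "]", if (strict) " (exclusive lower)", call. = FALSE)
  }
  chk(config$engine$dt_cell, "engine$dt_cell", 0, 120, strict = TRUE)
  for (sp in CV_SPECIES) {
    fp <- config$fields[[sp]]
    if (is.null(fp)) stop("config error at fields$", sp, ": missing", call. = FALSE)
    chk(fp$D, paste0("fields$", sp, "$D"), 0, 10)
    chk(fp$k, paste0("fields$", sp, "$k"), 0, 1)
  }
  s <- config$signaling
  chk(s$theta_diff, "signaling$theta_diff", 0, 1)
  chk(s$theta_prolif, "signaling$theta_prolif", 0, 1)
  chk(s$h_max, "signaling$h_max", 0, 1)
  ce <- config$cells
  chk(ce$p_stem, "cells$p_stem", 0, 1); chk(ce$p_div, "cells$p_div", 0, 1)
  chk(ce$p_move, "cells$p_move", 0, 1)
  if (config$geometry$n_villi != 1L || config$geometry$crypts_per_villus != 1L)
    stop("config error at geometry: the engine runs a single crypt-villus ",
         "complex (n_villi = 1, crypts_per_villus = 1)", call. = FALSE)
  invisible(config)
}

#' Read a configuration from YAML
#'
#' Layered configuration: the file's blocks override [cv_defaults]; the
#' geometry block (if present) is passed to [tissue_config()].
#'
#' @param path YAML file path.
#' @return A `cv_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  geo <- if (!is.null(y$geometry)) do.call(tissue_config, y$geometry)
         else tissue_config()
  y$geometry <- NULL
  do.call(default_config, c(list(geometry = geo), y))
}
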