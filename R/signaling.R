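#' Intracellular signaling
#'
#' The per-cell network is evaluated as time-delayed rules: in the time a
#' cell takes to perform a physical action (~10^3 s), the signaling
#' consequences of its local environment are assumed to have played out, so
#' each pathway is advanced by an exact exponential relaxation towards an
#' environment-determined target, with explicit timers for the genuinely
#' delayed switches (beta-catenin destruction-complex activation). All
#' functions here are vectorized over cells: scalars in, scalars out; vectors
#' in, vectors out. Levels are arbitrary units with homeostatic baselines of
#' 1; no level can go negative under any update order.
#'
#' @name signaling
NULL

# exact integrator of x' = (target - x)/tau over dt (constant target)
relax_to <- function(x, target, tau, dt) {
  x + (1 - exp(-dt / tau)) * (target - x)
}

#' Wnt/beta-catenin arm of the signaling network
#'
#' While local Wnt is at or above the activity threshold, the destruction
#' complex is inactive and beta-catenin accumulates (saturating at 1). When
#' Wnt falls below the threshold, a timer starts; after the activation delay
#' the destruction complex switches on and beta-catenin decays
#' exponentially — it is non-increasing until Wnt returns. Differentiation is
#' triggered elsewhere when beta-catenin falls below the depletion threshold.
#'
#' @param bcat Beta-catenin level(s), in `[0, 1]`.
#' @param wnt_free_min Minutes the cell has been without Wnt (0 when Wnt is
#'   present).
#' @param wnt_local Local Wnt concentration(s).
#' @param dt Minutes.
#' @param p Signaling parameter list (see [cv_defaults]).
#' @return A list: `bcat`, `wnt_free_min`, `dc_active` (destruction complex).
#' @export
wnt_bcat_update <- function(bcat, wnt_free_min, wnt_local, dt,
                            p = cv_defaults$signaling) {
  has_wnt <- wnt_local >= p$wnt_eps
  wnt_free_min <- ifelse(has_wnt, 0, wnt_free_min + dt)
  dc_active <- !has_wnt & wnt_free_min >= p$dc_delay_min
  up <- relax_to(bcat, 1, p$tau_bcat_up, dt)
  down <- bcat * exp(-dt / p$tau_bcat_down)
  bcat <- ifelse(has_wnt, up, ifelse(dc_active, down, bcat))
  list(bcat = pmax(bcat, 0), wnt_free_min = wnt_free_min, dc_active = dc_active)
}

#' BMP receptor binding (BMP activity)
#'
#' Free BMP is spatially uniform; the junction-to-tip gradient of BMP
#' *activity* arises because receptor availability ramps with time since
#' differentiation (a cell-intrinsic maturation clock). Undifferentiated
#' cells have zero availability; a just-differentiated cell starts near zero
#' and availability rises (optionally concavely, shape exponent <= 1) to saturate at 1 after `bmp_ramp_min` minutes, so bound BMP is
#' monotone non-decreasing in time since differentiation.
#'
#' @param bmp_free Local free-BMP concentration(s).
#' @param age_diff_min Minutes since differentiation (`NA` or negative for
#'   undifferentiated cells).
#' @param p Signaling parameter list.
#' @return Bound-BMP level(s).
#' @export
bmp_activity <- function(bmp_free, age_diff_min, p = cv_defaults$signaling) {
  x <- pmax(0, ifelse(is.na(age_diff_min), 0, age_diff_min)) / p$bmp_ramp_min
  avail <- pmin(1, x)^p$bmp_ramp_shape
  pmax(0, bmp_free) * avail
}

#' Hedgehog and SFRP1 secretion by differentiated cells
#'
#' Differentiated, alive enterocytes secrete Hedgehog in proportion to their
#' internal Hh level and secrete the Wnt inhibitor SFRP1 in proportion to the
#' Hedgehog signal they themselves receive (so loss of the villus collapses
#' SFRP1 production and releases Wnt). Undifferentiated and dead cells
#' secrete neither.
#'
#' @param differentiated Logical: alive differentiated enterocyte?
#' @param hh_internal Internal Hh level(s).
#' @param hh_env Received (extracellular) Hh signal(s), after any inhibitor
#'   block.
#' @param p Signaling parameter list.
#' @return List of per-minute secretion rates: `hh`, `sfrp1`.
#' @export
hh_sfrp1_production <- function(differentiated, hh_internal, hh_env,
                                p = cv_defaults$signaling) {
  on <- as.numeric(differentiated)
  # SFRP1 output saturates at the homeostatic Hh operating point: losing
  # Hh collapses SFRP1, but excess Hh cannot push it much further up
  list(hh = on * p$hh_secretion_rate * pmax(0, hh_internal),
       sfrp1 = on * p$sfrp1_secretion_rate *
         pmin(pmax(0, hh_env), p$sfrp1_hh_sat))
}

#' PTEN/PI3K/Akt axis with the inflammation-morphogenesis crosstalk
#'
#' PTEN and Hedgehog mutually inhibit each other (both targets are
#' `2/(1 + other)`, so the unperturbed fixed point is 1 for both), and
#' chronic TLR4 tone up-regulates PTEN with a long delay. PTEN suppresses
#' PI3K->Akt survival signaling (`akt = 2/(1 + pten)`), so elevated PTEN
#' lowers Akt and raises the apoptosis hazard, while PTEN inhibition lets
#' internal Hh rise (the compensatory spike seen after PTEN blockade).
#'
#' @param pten PTEN level(s).
#' @param hh_internal Internal Hh level(s).
#' @param hh_signal Received Hedgehog signal (normalized to its homeostatic
#'   mean; after any inhibitor block).
#' @param chronic Slow-filtered TLR4 activation (chronic inflammatory tone).
#' @param dt Minutes.
#' @param p Signaling parameter list.
#' @param pten_block Fraction of PTEN activity clamped away (1 = full
#'   inhibition).
#' @return List: `pten`, `hh_internal`, `akt`.
#' @export
pten_axis_update <- function(pten, hh_internal, hh_signal, chronic, dt,
                             p = cv_defaults$signaling, pten_block = 0) {
  pten_target <- (1 + p$tlr4_pten_gain * pmax(0, chronic)) *
    2 / (1 + pmax(0, hh_signal))
  pten <- relax_to(pten, pten_target, p$tau_pten, dt) * (1 - pten_block)
  hh_target <- (1 + p$hh_pten_slope) / (1 + p$hh_pten_slope * pten)
  hh_internal <- relax_to(hh_internal, hh_target, p$tau_hh, dt)
  # PI3K capacity bounds Akt: losing PTEN lifts survival signaling only so far
  akt <- pmin(p$akt_max, 2 / (1 + pten))
  list(pten = pmax(pten, 0), hh_internal = pmax(hh_internal, 0), akt = akt)
}

#' TLR4/NF-kB/RIP inflammatory arm
#'
#' TLR4 activation tracks local DAMP/ligand exposure with fast saturating
#' kinetics; a slow filter of that activation is the chronic tone feeding the
#' PTEN axis (acute spikes barely move it, sustained stimulation does).
#' NF-kB follows activation (anti-apoptotic); RIP integrates membrane damage
#' with slow resolution: contact with necrotic debris (scaled by ischemic
#' sensitization, i.e. I-FABP load) and, for sensitized cells only, high
#' ambient DAMP exposure add to it, and necrosis fires
#' when RIP crosses the cell's threshold. ROS and JAK/STAT3 are tracked
#' (activation- and IL-6/IL-10-driven) but drive no behavior.
#'
#' @param tlr4,chronic,nfkb,rip,ros,jak Current levels.
#' @param ligand Local TLR4-ligand concentration (plus any scenario-imposed
#'   exposure).
#' @param debris_neighbors Number of adjacent necrotic-debris patches.
#' @param ifabp I-FABP load (ischemic sensitization).
#' @param il6,il10 Local interleukin concentrations.
#' @param dt Minutes.
#' @param p Signaling parameter list.
#' @return List: `tlr4`, `chronic`, `nfkb`, `rip`, `ros`, `jak`.
#' @export
inflammatory_axis_update <- function(tlr4, chronic, nfkb, rip, ros, jak,
                                     ligand, debris_neighbors, ifabp,
                                     il6 = 0, il10 = 0, dt,
                                     p = cv_defaults$signaling) {
  act_target <- pmax(0, ligand) / (pmax(0, ligand) + p$tlr4_K)
  tlr4 <- relax_to(tlr4, act_target, p$tau_tlr4, dt)
  chronic <- relax_to(chronic, tlr4, p$tau_chronic, dt)
  nfkb <- relax_to(nfkb, tlr4, p$tau_nfkb, dt)
  sens <- pmin(p$sens_cap, (1 + pmax(0, ifabp) / p$sens_K)^2)
  rip <- rip * exp(-dt / p$tau_rip) + dt *
    (p$rip_contact_rate * sens * debris_neighbors +
       p$rip_ligand_basal * pmax(0, tlr4 - p$rip_tlr4_floor) +
       p$rip_ligand_rate * (sens - 1) *
         pmax(0, tlr4 - p$rip_tlr4_floor_sens))
  ros <- relax_to(ros, tlr4, p$tau_ros, dt)
  jak <- relax_to(jak, (il6 + il10) / (il6 + il10 + 1), p$tau_jak, dt)
  list(tlr4 = tlr4, chronic = chronic, nfkb = nfkb, rip = rip,
       ros = ros, jak = jak)
}

#' Apoptosis hazard of an enterocyte
#'
#' The hazard is a steep sigmoid in the apoptotic drive
#' `bmp_bound * (w_akt * (akt0/akt)^beta + w_hh * hh_signal) / (w_akt + w_hh)`,
#' rising with bound BMP, with loss of Akt survival signaling and with
#' received Hedgehog; NF-kB suppresses it multiplicatively, bounded below at
#' 0.1x. Because PTEN and received Hh enter symmetrically, inhibiting either
#' one alone leaves the drive near baseline (the redundancy between the two
#' apoptotic arms), while chronic PTEN elevation plus Hh loss (metaplasia)
#' raises it.
#'
#' @param bmp_bound Bound-BMP level(s) (from [bmp_activity()]).
#' @param akt Akt level(s) (baseline 1).
#' @param hh_signal Received Hh normalized to its homeostatic mean.
#' @param nfkb NF-kB level(s).
#' @param dt Minutes.
#' @param p Signaling parameter list.
#' @return Per-tick death probability(ies).
#' @export
apoptosis_hazard <- function(bmp_bound, akt, hh_signal, nfkb, dt,
                             p = cv_defaults$signaling) {
  akt_term <- pmin(4, pmax(0.25, 1 / pmax(akt, 1e-6)))^p$drive_beta
  drive <- pmax(0, bmp_bound) *
    (p$w_akt * akt_term + p$w_hh * pmax(0, hh_signal)) / (p$w_akt + p$w_hh)
  nfkb_fac <- pmax(0.1, 1 / (1 + p$nfkb_protect * pmax(0, nfkb)))
  h <- p$h_base + p$h_max * stats::plogis((drive - p$apop_theta) / p$apop_width)
  pmin(1, nfkb_fac * h * dt / 15)   # rates are per 15-min reference tick
}

# ---------------------------------------------------------------------------
# Generic time-delayed rule engine (per-cell semantics)
# ---------------------------------------------------------------------------

#' Construct a time-delayed rule
#'
#' A rule has a trigger predicate over `(state, env)`, a delay in minutes, a
#' target state field and a rate. While the trigger holds at time `t`, each
#' evaluation schedules one effect of magnitude `rate(state, env) * dt` (or
#' `rate * dt` for a constant) to be applied to `target` at `t + delay`.
#' Scheduled effects are applied exactly once, in due-time order. As
#' `dt -> 0` this discretization converges to the corresponding delayed
#' differential equation.
#'
#' @param trigger `function(state, env) -> logical`.
#' @param delay Delay in minutes (>= 0).
#' @param target Name of the state field the effect adds to.
#' @param rate Constant, or `function(state, env) -> numeric` evaluated at
#'   scheduling time.
#' @return A `cv_rule`.
#' @export
delayed_rule <- function(trigger, delay, target, rate) {
  stopifnot(is.function(trigger), delay >= 0, is.character(target))
  r <- list(trigger = trigger, delay = delay, target = target, rate = rate)
  class(r) <- "cv_rule"
  r
}

#' A single cell's signal state for the delayed-rule engine
#'
#' Named numeric levels plus a queue of pending `(due, target, amount)`
#' effects kept ordered by due time. Levels are clamped at zero when effects
#' are applied, so no level ever goes negative under any firing order.
#'
#' @param ... Named numeric levels.
#' @return A `cv_cell_state`.
#' @export
cell_signal_state <- function(...) {
  s <- list(levels = c(...), pending = data.frame(due = numeric(0),
                                                  target = character(0),
                                                  amount = numeric(0)))
  class(s) <- "cv_cell_state"
  s
}

#' Evaluate delayed rules for one cell over one step
#'
#' Applies all pending effects due by `t`, then evaluates each rule's
#' trigger against `(state, env)` and schedules its effect at `t + delay`.
#'
#' @param state A `cv_cell_state`.
#' @param env Named list/vector of local environment samples.
#' @param t Current time (minutes).
#' @param dt Step (minutes).
#' @param rules List of `cv_rule`.
#' @return The updated `cv_cell_state`.
#' @export
step_rules <- function(state, env, t, dt, rules) {
  stopifnot(inherits(state, "cv_cell_state"))
  due <- state$pending$due <= t + 1e-12
  if (any(due)) {
    for (i in which(due)) {
      tg <- state$pending$target[i]
      state$levels[tg] <- max(0, state$levels[tg] + state$pending$amount[i])
    }
    state$pending <- state$pending[!due, , drop = FALSE]
  }
  for (r in rules) {
    if (isTRUE(r$trigger(state, env))) {
      amt <- if (is.function(r$rate)) r$rate(state, env) * dt else r$rate * dt
      state$pending <- rbind(state$pending,
                             data.frame(due = t + r$delay, target = r$target,
                                        amount = amt))
    }
  }
  state$pending <- state$pending[order(state$pending$due), , drop = FALSE]
  state
}

#' Integrate a production-decay pair of delayed rules
#'
#' Convenience driver for the rule engine: constant production `a` and
#' linear decay `-b * x`, both with the same delay, integrated from `x0`
#' over `T_min` at step `dt`. With zero delay the trajectory converges to
#' the analytic solution `x(t) = a/b + (x0 - a/b) exp(-b t)` as `dt -> 0`.
#'
#' @param a Production rate per minute.
#' @param b Decay rate per minute.
#' @param x0 Initial level.
#' @param T_min Total time, minutes.
#' @param dt Step, minutes.
#' @param delay Delay applied to both rules, minutes.
#' @return Tibble with `time` and `x`.
#' @export
integrate_rule_chain <- function(a, b, x0, T_min, dt, delay = 0) {
  rules <- list(
    delayed_rule(function(s, e) TRUE, delay, "x", a),
    delayed_rule(function(s, e) TRUE, delay, "x",
                 function(s, e) -b * s$levels[["x"]]))
  st <- cell_signal_state(x = x0)
  times <- seq(0, T_min, by = dt)
  out <- numeric(length(times)); out[1] <- x0
  for (i in seq_along(times)[-1]) {
    st <- step_rules(st, list(), times[i - 1], dt, rules)
    st <- step_rules(st, list(), times[i], 0, list())  # apply what came due
    out[i] <- st$levels[["x"]]
  }
  tibble::tibble(time = times, x = out)
}
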