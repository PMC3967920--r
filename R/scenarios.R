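# Scenario library: the perturbation experiments expressed as declarative
# schedules applied to a running simulation. A scenario with all strengths
# zero consumes no extra randomness and leaves the trajectory bit-identical
# to baseline under the same seed.

new_scenario <- function(name, events) {
  s <- list(name = name, events = events)
  class(s) <- "cv_scenario"
  s
}

ev <- function(t_min, type, ...) list(t_min = t_min, type = type,
                                      args = list(...))

#' Scenario constructors
#'
#' Each constructor returns a declarative schedule for [simulate_tissue()]
#' or [run_scenario()]; times are minutes relative to the start of the run
#' (which normally starts from a homeostatic checkpoint).
#'
#' * `scenario_baseline()`: no perturbation.
#' * `scenario_wnt_inhibition(strength)`: a uniform SFRP1-equivalent source
#'   of the given strength from `at_min` onward (a strong inhibitor
#'   eliminates all Wnt activity; proliferation stops, the crypt is lost
#'   first, then the villus).
#' * `scenario_hh_inhibition(strength)`: blocks the fraction `strength` of
#'   Hedgehog signal reception (SFRP1 production collapses, Wnt extends
#'   upward, the crypt deepens while the villus returns to near normal).
#' * `scenario_pten_inhibition(strength)`: clamps away the fraction
#'   `strength` of PTEN in all GECs (transient Hh spike and crypt
#'   shrinkage, then return to near-baseline architecture).
#' * `scenario_wound(at_min)`: villus-wide necrosis — every live cell above
#'   the current junction becomes necrotic debris at `at_min`.
#' * `scenario_ischemia_reperfusion(ischemia_min, sloughing)`: ischemia
#'   from `at_min` (division and migration suspended; I-FABP and an
#'   axially-graded injury dose accrue), then reperfusion applies sloughing
#'   or in-place necrosis commitments and inflammation responds.
#' * `scenario_chronic_tlr4(level)`: continuous low-grade TLR4 stimulation
#'   of all GECs from `at_min` (the chronic inflammatory milieu that
#'   remodels the tissue towards the colonic phenotype).
#'
#' @param strength Non-negative perturbation strength (0 = no-op; 1 = full
#'   inhibition for the blockade scenarios).
#' @param at_min Start time, minutes from the beginning of the run.
#' @param ischemia_min Ischemic interval, minutes.
#' @param sloughing Is I-FABP-mediated sloughing active at reperfusion?
#' @param level Chronic TLR4 ligand-equivalent exposure level.
#' @return A `cv_scenario`.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_baseline <- function() new_scenario("baseline", list())

#' @rdname scenarios
#' @export
scenario_wnt_inhibition <- function(strength = 1, at_min = 0) {
  stopifnot(strength >= 0)
  new_scenario("wnt_inhibition",
               list(ev(at_min, "wnt_inhibition", strength = strength)))
}

#' @rdname scenarios
#' @export
scenario_hh_inhibition <- function(strength = 1, at_min = 0) {
  stopifnot(strength >= 0, strength <= 1)
  new_scenario("hh_inhibition",
               list(ev(at_min, "hh_inhibition", strength = strength)))
}

#' @rdname scenarios
#' @export
scenario_pten_inhibition <- function(strength = 1, at_min = 0) {
  stopifnot(strength >= 0, strength <= 1)
  new_scenario("pten_inhibition",
               list(ev(at_min, "pten_inhibition", strength = strength)))
}

#' @rdname scenarios
#' @export
scenario_wound <- function(at_min = 0) {
  new_scenario("wound", list(ev(at_min, "wound")))
}

#' @rdname scenarios
#' @export
scenario_ischemia_reperfusion <- function(ischemia_min, sloughing = TRUE,
                                          at_min = 0) {
  stopifnot(ischemia_min >= 0)
  evs <- if (ischemia_min > 0)
    list(ev(at_min, "ischemia_on", sloughing = sloughing),
         ev(at_min + ischemia_min, "reperfusion"))
  else list()
  new_scenario("ischemia_reperfusion", evs)
}

#' @rdname scenarios
#' @export
scenario_chronic_tlr4 <- function(level = 1, at_min = 0) {
  stopifnot(level >= 0)
  new_scenario("chronic_tlr4", list(ev(at_min, "chronic_tlr4", level = level)))
}

# ---- direct perturbation operators (also used by the event dispatcher) ----

#' Apply perturbations to a running state
#'
#' These operators implement the scenario effects directly on a `cv_state`
#' and can be used interactively; the scenario schedule calls the same
#' functions. Zero-strength applications are exact no-ops.
#'
#' @param state A `cv_state` (modified in place).
#' @param strength,level See [scenarios].
#' @return The state, invisibly.
#' @name perturbations
NULL

#' @rdname perturbations
#' @export
apply_wnt_inhibition <- function(state, strength) {
  state$mod$sfrp1_ext <- strength
  invisible(state)
}

#' @rdname perturbations
#' @export
apply_hh_inhibition <- function(state, strength) {
  state$mod$hh_block <- strength
  invisible(state)
}

#' @rdname perturbations
#' @export
apply_pten_inhibition <- function(state, strength) {
  state$mod$pten_block <- strength
  invisible(state)
}

#' @rdname perturbations
#' @export
apply_chronic_tlr4 <- function(state, level) {
  state$mod$chronic_ligand <- level
  invisible(state)
}

#' Induce a necrotic wound
#'
#' All live cells in the region (default: every patch above the current
#' crypt-villus junction, i.e. the whole villus) die simultaneously by
#' necrosis, leaving DAMP-emitting debris in place.
#'
#' @param state A `cv_state` (modified in place).
#' @param region Optional patch ids; `NULL` wounds the villus.
#' @return Patch ids necrosed, invisibly.
#' @export
induce_wound <- function(state, region = NULL) {
  if (is.null(region)) {
    j <- architecture_rows(state)$junction
    region <- which(state$type > 0L & state$row_of > j)
  }
  invisible(necrose_cells(state, region))
}

start_ischemia <- function(st, sloughing) {
  ar <- architecture_rows(st)
  tip_ax <- max(st$axial[st$ids[max(ar$tip, 1L), 1L]], st$patch_um)
  p <- st$cfg$cells
  st$sev <- p$sev_floor + (1 - p$sev_floor) * pmin(1, st$axial / tip_ax)
  st$mod$ischemic <- TRUE
  st$mod$isch_t0 <- st$t
  st$mod$slough_enabled <- isTRUE(sloughing)
  invisible(NULL)
}

end_ischemia <- function(st) {
  slough_cells(st, st$mod$slough_enabled)
  st$mod$ischemic <- FALSE
  st$dose[] <- 0
  invisible(NULL)
}

prepare_events <- function(st, scenario) {
  if (is.null(scenario) || !length(scenario$events)) return(NULL)
  e <- new.env(parent = emptyenv())
  e$events <- lapply(scenario$events, function(x) {
    x$t_min <- st$t + x$t_min; x$done <- FALSE; x
  })
  e
}

apply_due_events <- function(st, ev_env) {
  if (is.null(ev_env)) return(invisible(NULL))
  for (i in seq_along(ev_env$events)) {
    x <- ev_env$events[[i]]
    if (x$done || x$t_min > st$t + 1e-9) next
    switch(x$type,
           wnt_inhibition = apply_wnt_inhibition(st, x$args$strength),
           hh_inhibition = apply_hh_inhibition(st, x$args$strength),
           pten_inhibition = apply_pten_inhibition(st, x$args$strength),
           chronic_tlr4 = apply_chronic_tlr4(st, x$args$level),
           wound = induce_wound(st),
           ischemia_on = start_ischemia(st, x$args$sloughing),
           reperfusion = end_ischemia(st),
           stop("unknown scenario event: ", x$type, call. = FALSE))
    ev_env$events[[i]]$done <- TRUE
  }
  invisible(NULL)
}

#' Run a scenario from a homeostatic checkpoint
#'
#' @param checkpoint A `cv_state` from [homeostatic_checkpoint()].
#' @param scenario A `cv_scenario`.
#' @param days Simulated days to run.
#' @param seed Seed for the run's RNG stream.
#' @return A `cv_run`.
#' @export
run_scenario <- function(checkpoint, scenario, days, seed = 1L) {
  simulate_tissue(days = days, seed = seed, scenario = scenario,
                  init = checkpoint)
}

#' Ischemia/reperfusion experiment
#'
#' Runs ischemia of the given duration from a homeostatic checkpoint,
#' reperfuses (with or without I-FABP-mediated sloughing) and continues
#' for `post_hours` of recovery.
#'
#' @param checkpoint A `cv_state`.
#' @param ischemia_minutes Ischemic interval, minutes.
#' @param sloughing_enabled Logical.
#' @param post_hours Simulated recovery hours after reperfusion (the
#'   outcome classification uses the final day of this follow-up).
#' @param seed Seed.
#' @return A `cv_run`.
#' @export
run_ischemia_reperfusion <- function(checkpoint, ischemia_minutes,
                                     sloughing_enabled = TRUE,
                                     post_hours = 72, seed = 1L) {
  sc <- scenario_ischemia_reperfusion(ischemia_minutes,
                                      sloughing = sloughing_enabled)
  simulate_tissue(minutes = ischemia_minutes + post_hours * 60, seed = seed,
                  scenario = sc, init = checkpoint)
}
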