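# Observables and outcome classification.

#' Measure the crypt-villus architecture
#'
#' The junction is the highest axial row whose majority occupant (by
#' circumferential vote among live cells) is undifferentiated (stem/TA).
#' Crypt depth is the axial extent up to the junction; villus height is the
#' extent above it up to the highest row still majority-occupied by live
#' enterocytes. Lengths are rows times patch size, in micrometres; the
#' ratio is depth/height and is undefined (NA) for an empty villus.
#'
#' @param state A `cv_state`.
#' @return A tibble with `crypt_depth_um`, `villus_height_um`, `ratio`,
#'   `junction_row`, `tip_row`.
#' @export
measure_architecture <- function(state) {
  ar <- architecture_rows(state)
  depth <- ar$junction * state$patch_um
  height <- max(0, ar$tip - ar$junction) * state$patch_um
  tibble::tibble(crypt_depth_um = depth, villus_height_um = height,
                 ratio = if (height > 0) depth / height else NA_real_,
                 junction_row = ar$junction, tip_row = ar$tip)
}

#' Measure whole-epithelium renewal time
#'
#' Labels every live non-stem cell at the start (stem cells are permanent
#' residents and excluded), advances the baseline simulation, and returns
#' the elapsed time until at least `frac` of the labeled cohort is gone.
#'
#' @param checkpoint A homeostatic `cv_state`.
#' @param max_days Upper bound on the follow-up.
#' @param frac Replacement fraction defining renewal (default 0.99).
#' @param seed Seed.
#' @return Renewal time in days (NA if not reached within `max_days`).
#' @export
measure_renewal <- function(checkpoint, max_days = 10, frac = 0.99,
                            seed = 1L) {
  run <- simulate_tissue(days = max_days, seed = seed, init = checkpoint,
                         label_at_start = TRUE)
  m <- run$metrics
  lab <- m$labeled_alive
  n0 <- lab[1]
  if (n0 == 0) return(0)
  hit <- which(lab <= (1 - frac) * n0)
  if (!length(hit)) return(NA_real_)
  t_start <- m$time_min[1] - run$state$dt
  (m$time_min[hit[1]] - t_start) / 1440
}

#' Summarize a baseline run for outcome classification
#'
#' Means of the crypt and villus populations over the final day of a
#' baseline run — the reference for the recovery band.
#'
#' @param run A baseline `cv_run`.
#' @param window_min Averaging window (from the end), minutes.
#' @return List with `crypt_mean`, `villus_mean`.
#' @export
baseline_stats <- function(run, window_min = 1440) {
  m <- run$metrics
  w <- m$time_min > max(m$time_min) - window_min
  list(crypt_mean = mean(m$crypt_alive[w]),
       villus_mean = mean(m$villus_alive[w]))
}

#' Classify the outcome of a perturbation trajectory
#'
#' DEAD if the live cell population reaches zero (loss of the stem niche is
#' unrecoverable); RECOVERED if, over the final evaluation window, the mean
#' of each compartment population is within the recovery band of its
#' baseline mean and no necrotic debris remains (window means: the discrete
#' junction row makes instantaneous compartment counts jump by a whole
#' circumference); otherwise PERSISTENT_ALTERATION.
#' Deterministic given a trajectory.
#'
#' @param metrics A `cv_run` metrics tibble (or the run itself).
#' @param baseline A list from [baseline_stats()].
#' @param window_min Evaluation window at the end of the trajectory, minutes.
#' @param band Relative recovery band (default the configured 10%).
#' @return One of `"RECOVERED"`, `"PERSISTENT_ALTERATION"`, `"DEAD"`.
#' @export
classify_outcome <- function(metrics, baseline,
                             window_min = cv_defaults$metrics$eval_window_min,
                             band = cv_defaults$metrics$recovery_band) {
  if (inherits(metrics, "cv_run")) metrics <- metrics$metrics
  if (any(metrics$total_alive == 0)) return("DEAD")
  w <- metrics$time_min > max(metrics$time_min) - window_min
  okc <- abs(mean(metrics$crypt_alive[w]) - baseline$crypt_mean) <=
    band * baseline$crypt_mean
  okv <- abs(mean(metrics$villus_alive[w]) - baseline$villus_mean) <=
    band * baseline$villus_mean
  if (okc && okv && all(metrics$necrotic[w] == 0)) "RECOVERED"
  else "PERSISTENT_ALTERATION"
}

#' Circumferentially averaged axial profile
#'
#' Mean level per axial row, from crypt base to villus tip, of either a
#' field (a `cv_field` or raw per-patch vector) or a per-patch signal.
#'
#' @param x A `cv_field`, or numeric vector of length `n_patches`.
#' @param topology The matching `cv_topology`.
#' @return Tibble with `row`, `axial_pos` (um) and `mean_level`.
#' @export
gradient_profile <- function(x, topology) {
  v <- if (inherits(x, "cv_field")) x$conc else as.numeric(x)
  stopifnot(length(v) == topology$n_patches)
  g <- topology$config
  rows_total <- g$crypt_rows + g$villus_rows
  combined_row <- ifelse(topology$patches$kind == "crypt",
                         topology$patches$row,
                         g$crypt_rows + topology$patches$row)
  mean_level <- as.numeric(tapply(v, combined_row, mean, na.rm = TRUE))
  tibble::tibble(row = sort(unique(combined_row)),
                 axial_pos = (sort(unique(combined_row)) - 0.5) * g$patch_um,
                 mean_level = mean_level)
}

#' Bound-BMP per-patch levels of a state
#'
#' Convenience accessor: bound BMP (receptor activity) for every patch,
#' zero where there is no live enterocyte.
#'
#' @param state A `cv_state`.
#' @param empty Value reported for patches without a live enterocyte (use
#'   `NA` to average over occupied patches only in [gradient_profile()]).
#' @return Numeric vector of length `n_patches`.
#' @export
bmp_bound_levels <- function(state, empty = 0) {
  out <- rep(as.numeric(empty), state$n)
  e <- which(state$type == CV_ENT)
  out[e] <- bmp_activity(state$f$BMP_FREE[e], state$age_diff_min[e],
                         state$cfg$signaling)
  out
}

#' EphB positional readout
#'
#' A monotone function of beta-catenin (the crypt-base-high gradient),
#' tracked as a positional readout only: it drives no behavior.
#'
#' @param state A `cv_state`.
#' @return Numeric vector of length `n_patches`.
#' @export
ephb_readout <- function(state) {
  state$bcat / (1 + state$bcat)
}
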