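# Shared fixtures. Expensive objects (homeostatic checkpoint, baseline
# reference run) are computed once per test session and reused across files.

.fx <- new.env(parent = emptyenv())

tiny_topo <- function(w = 4, hc = 4, hv = 4, patch = 20) {
  build_tissue(tissue_config(crypt_width = w, crypt_rows = hc,
                             villus_rows = hv, patch_um = patch))
}

# states are environments; give each test its own copy
copy_state_for_test <- function(st) {
  st2 <- new.env(parent = emptyenv())
  for (nm in ls(st, all.names = TRUE)) st2[[nm]] <- st[[nm]]
  class(st2) <- class(st)
  st2
}

fx_checkpoint <- function() {
  if (is.null(.fx$chk)) .fx$chk <- homeostatic_checkpoint(seed = 1)
  copy_state_for_test(.fx$chk)
}

fx_baseline_stats <- function() {
  if (is.null(.fx$bs)) {
    run <- run_scenario(fx_checkpoint(), scenario_baseline(), days = 6,
                        seed = 99)
    .fx$bs <- baseline_stats(run, window_min = 2880)
    .fx$base_run <- run
  }
  .fx$bs
}

fx_baseline_run <- function() {
  fx_baseline_stats()
  .fx$base_run
}

# relative time axis (minutes since the run started) for scenario runs
rel_time <- function(m) m$time_min - (m$time_min[1] - 15)

# brute-force neighbor computation on the unwrapped lattice by coordinate
# arithmetic only (independent of the package's adjacency table)
brute_neighbors <- function(topo, pid) {
  p <- topo$patches[topo$patches$patch_id == pid, ]
  g <- topo$config
  same_unit <- topo$patches[topo$patches$unit_id == p$unit_id, ]
  w <- if (p$kind == "crypt") g$crypt_width
       else g$crypt_width * g$crypts_per_villus
  at <- function(row, circ) {
    same_unit$patch_id[same_unit$row == row &
                         same_unit$circ_index == (circ %% w)]
  }
  out <- c(at(p$row, p$circ_index - 1), at(p$row, p$circ_index + 1))
  if (p$row > 1) out <- c(out, at(p$row - 1, p$circ_index))
  h <- if (p$kind == "crypt") g$crypt_rows else g$villus_rows
  if (p$row < h) out <- c(out, at(p$row + 1, p$circ_index))
  lk <- topo$links
  if (p$kind == "crypt" && p$row == g$crypt_rows)
    out <- c(out, lk$villus_patch[lk$crypt_patch == pid])
  if (p$kind == "villus" && p$row == 1)
    out <- c(out, lk$crypt_patch[lk$villus_patch == pid])
  sort(unique(out))
}
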