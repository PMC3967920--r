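# a small quiet state for unit-level cell mechanics: stems + a TA column
mech_state <- function() {
  set.seed(123)
  st <- new_state(default_config())
  st
}

test_that("division is restricted to Wnt-active stem/TA cells and the
           daughter is a TA one row up", {
  st <- mech_state()
  # enterocytes never divide
  ent <- which(st$type == 3)[1]
  set.seed(1)
  expect_null(attempt_division(st, ent))
  # stem with high beta-catenin: daughter is TA placed above the niche
  stem <- st$ids[1, 3]
  st$bcat[stem] <- 1
  before <- st$type
  set.seed(2)
  d <- NULL
  for (i in 1:2000) { d <- attempt_division(st, stem); if (!is.null(d)) break }
  expect_false(is.null(d))
  expect_equal(st$type[d], 2L)                       # TA daughter
  expect_equal(st$type[stem], 1L)                    # stem stays in niche
  expect_gt(st$row_of[d], st$cfg$cells$stem_rows)    # above the whole niche
  # TA below the proliferation threshold does not divide
  ta <- st$ids[5, 1]
  st$bcat[ta] <- 0.1
  set.seed(3)
  expect_null(attempt_division(st, ta))
})

test_that("expected daughter count over many trials matches the division
           probability (binomial check)", {
  st <- mech_state()
  p <- st$cfg$cells$p_div
  ta <- st$ids[5, 2]
  st$bcat[ta] <- 1
  set.seed(11)
  n <- 1000
  hits <- 0
  for (i in 1:n) {
    st2 <- copy_state_for_test(st)
    if (!is.null(attempt_division(st2, ta))) hits <- hits + 1
  }
  expect_lt(abs(hits - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
})

test_that("column displacement pushes the contiguous stack and sheds at the
           lattice top", {
  st <- mech_state()
  cc <- 4
  col_ids <- st$ids[, cc]
  # fill the whole column so a division must shed the tip-most cell
  empty <- col_ids[st$type[col_ids] == 0]
  st$type[empty] <- 3L
  st$age_diff_min[empty] <- 1000
  top_before <- st$type[col_ids[st$R]]
  expect_gt(top_before, 0)
  n_before <- sum(st$type[col_ids] > 0)
  cryptvillus:::do_division_at(st, st$ids[5, cc])
  expect_equal(sum(st$type[col_ids] > 0), n_before)  # +1 born, -1 shed
  expect_equal(unname(st$counts["tip_exits"]), 1)
  expect_equal(unname(st$counts["births"]), 1)
})

test_that("migration drifts non-stem cells up into gaps only", {
  st <- mech_state()
  # stems never move
  stems <- which(st$type == 1L)
  rows0 <- st$row_of[stems]
  set.seed(5)
  migrate_cells(st)
  expect_identical(st$row_of[which(st$type == 1L)], rows0)
  # a lone TA below an empty patch moves up with probability p_move
  st2 <- mech_state()
  st2$type[] <- 0L
  lone <- st2$ids[10, 1]
  st2$type[lone] <- 2L
  set.seed(9)
  n <- 600; moved <- 0
  for (i in 1:n) {
    s3 <- copy_state_for_test(st2)
    if (migrate_cells(s3) > 0) moved <- moved + 1
  }
  pm <- st2$cfg$cells$p_move
  expect_lt(abs(moved - n * pm), 3 * sqrt(n * pm * (1 - pm)))
})

test_that("differentiation fires at beta-catenin depletion and starts the
           maturation clock", {
  st <- mech_state()
  p <- st$cfg$signaling
  ta <- st$ids[8, 1]
  st$type[ta] <- 2L
  st$dc[ta] <- 1
  st$bcat[ta] <- p$theta_diff + 0.01
  differentiate_cells(st)
  expect_equal(st$type[ta], 2L)                 # above threshold: unchanged
  st$bcat[ta] <- p$theta_diff - 0.001
  differentiate_cells(st)
  expect_equal(st$type[ta], 3L)                 # boundary crossing
  expect_equal(st$age_diff_min[ta], 0)
  expect_equal(st$hh_int[ta], p$hh_diff_spike)  # Hh production begins
})

test_that("necrotic debris emits DAMPs and raises neighbor TLR4 until
           cleared", {
  st <- mech_state()
  mid <- st$ids[30, 5]
  below <- st$ids[29, 5]
  necrose_cells(st, mid)
  expect_true(st$debris[mid])
  expect_equal(st$type[mid], 0L)
  rip0 <- st$rip[below]
  for (k in 1:8) cryptvillus:::cv_tick(st)
  expect_gt(st$f$TLR4_LIGAND[mid], 0)           # DAMP emission
  expect_gt(st$rip[below], rip0)                # neighbor damage accrues
  expect_gt(st$tlr4[below], 0)
  # removal stops emission: ligand decays away
  st$debris[mid] <- FALSE
  lig1 <- st$f$TLR4_LIGAND[mid]
  for (k in 1:20) cryptvillus:::cv_tick(st)
  expect_lt(st$f$TLR4_LIGAND[mid], lig1 / 2)
})

test_that("reperfusion sloughing sheds the most ischemic enterocytes cleanly
           and spares unexposed cells", {
  st <- mech_state()
  st$mod$isch_t0 <- st$t
  st$t <- st$t + 30                      # 30 min of ischemia
  tip <- st$ids[60, 1]; low <- st$ids[20, 1]
  st$type[c(tip, low)] <- 3L
  st$sev[tip] <- 0.95; st$sev[low] <- 0.5
  st$dose[c(tip, low)] <- c(10, 2)
  st$ifabp[c(tip, low)] <- c(28, 15)
  res <- slough_cells(st, sloughing_enabled = TRUE)
  expect_true(tip %in% res$sloughed)
  expect_equal(st$type[tip], 0L)
  expect_false(st$debris[tip])           # clean loss: no debris, no DAMPs
  expect_equal(st$type[low], 3L)         # below threshold: stays alive
  # same history without sloughing: the committed cell necroses in place
  st2 <- mech_state()
  st2$mod$isch_t0 <- st2$t; st2$t <- st2$t + 30
  tip2 <- st2$ids[60, 1]
  st2$type[tip2] <- 3L; st2$sev[tip2] <- 0.95; st2$dose[tip2] <- 10
  res2 <- slough_cells(st2, sloughing_enabled = FALSE)
  expect_true(tip2 %in% res2$necrosed)
  expect_true(st2$debris[tip2])
  # ifabp = 0 (never ischemic) always stays alive
  st3 <- mech_state()
  st3$mod$isch_t0 <- st3$t; st3$t <- st3$t + 30
  alive0 <- sum(st3$type > 0)
  slough_cells(st3, TRUE)
  expect_equal(sum(st3$type > 0), alive0)
})

test_that("the population-balance ledger is exact every tick", {
  chk <- fx_checkpoint()
  run <- run_scenario(chk, scenario_wound(), days = 1.5, seed = 77)
  m <- run$metrics
  d_alive <- diff(m$total_alive)
  flux <- (m$births - m$apoptoses - m$necroses - m$sloughs -
             m$tip_exits)[-1]
  expect_identical(d_alive, flux)
})

test_that("crypt and villus populations are stationary at homeostasis", {
  run <- simulate_tissue(days = 12, seed = 2)
  m <- run$metrics
  day <- floor(m$time_min / 1440)
  keep <- day >= 5                       # post burn-in
  vm <- tapply(m$villus_alive[keep], day[keep], mean)
  cm <- tapply(m$crypt_alive[keep], day[keep], mean)
  drift <- function(x) abs(unname(coef(lm(as.numeric(x) ~
                                            seq_along(x)))[2])) / mean(x)
  expect_lt(drift(vm), 0.02)             # < 2% per day trend
  expect_lt(drift(cm), 0.02)
})

test_that("a labeled cohort is almost fully replaced within the renewal
           horizon", {
  chk <- fx_checkpoint()
  resume_rng(chk)
  run <- simulate_tissue(days = 7, seed = NULL, init = chk,
                         label_at_start = TRUE)
  lab <- run$metrics$labeled_alive
  expect_lt(lab[length(lab)], 0.01 * lab[1])   # >= 99% replaced by 7 d
})
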