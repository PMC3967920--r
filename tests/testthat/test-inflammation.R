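quiet_state <- function() {
  set.seed(55)
  new_state(default_config())
}

test_that("the inflammatory compartment is quiescent without necrosis", {
  run <- simulate_tissue(days = 4, seed = 4)
  m <- run$metrics
  expect_true(all(m$neutrophils == 0))
  expect_true(all(m$macrophages == 0))
  # resident inactive monocytes persist at their seeded density
  expect_equal(length(unique(m$monocytes)), 1)
  expect_gt(m$monocytes[1], 0)
})

test_that("recruitment is zero without cytokines and saturating with them", {
  st <- quiet_state()
  set.seed(1)
  expect_equal(recruit_inflammatory(st), 0)
  # fixed ligand at the vessel: arrivals follow the saturating rate
  q <- st$cfg$inflammation
  lig <- 6
  st$f$TLR4_LIGAND[st$topo$vessel_sites] <- lig
  sat <- lig / (lig + q$recruit_K)
  p_n <- q$r_neutrophil * sat
  n_slots <- length(st$topo$vessel_sites) * q$recruit_burst
  set.seed(2)
  neus <- 0
  for (i in 1:500) {
    st2 <- copy_state_for_test(st)
    st2$im <- list(pid = integer(0), itype = integer(0), act = numeric(0),
                   life = numeric(0))
    recruit_inflammatory(st2)
    neus <- neus + sum(st2$im$itype == 3L)
  }
  expn <- 500 * n_slots * p_n
  expect_lt(abs(neus - expn), 3 * sqrt(expn))
  # monocytes activate into macrophages where IFN-gamma is high
  st3 <- quiet_state()
  st3$f$IFNG[] <- 1
  set.seed(3)
  recruit_inflammatory(st3)
  expect_true(all(st3$im$itype != 1L))
})

test_that("chemotaxis on a flat field is an unbiased random walk", {
  st <- quiet_state()
  cfg0 <- st$cfg
  start <- st$ids[40, 8]
  set.seed(8)
  disp <- replicate(800, {
    st$im <- list(pid = start, itype = 3L, act = 1, life = 1e5)
    chemotax_cells(st)
    st$row_of[st$im$pid] - 40
  })
  expect_lt(abs(mean(disp)), 0.25)   # mean displacement ~ 0
})

test_that("a neutrophil tracks the DAMP gradient to a lone debris patch", {
  # noise-free chemotaxis: greedy ascent reaches the source quickly
  set.seed(12)
  st <- new_state(default_config(inflammation = list(chemotax_noise = 0)))
  target <- st$ids[40, 8]
  st$debris[target] <- TRUE
  # let the plume establish
  for (k in 1:20) cryptvillus:::cv_tick(st)
  st$im <- list(pid = st$ids[20, 8], itype = 3L, act = 1, life = 1e5)
  manhattan <- 20
  steps <- 0
  for (k in 1:manhattan) {
    chemotax_cells(st)
    steps <- steps + 1
    if (st$im$pid == target) break
  }
  # 3 lattice moves per tick: well within the Manhattan bound in ticks
  expect_identical(st$im$pid[1], target)
})

test_that("phagocytosis clears one debris per engaged cell per tick and the
           ledger balances", {
  st <- quiet_state()
  d1 <- st$ids[30, 2]; d2 <- st$ids[30, 3]
  necrose_cells(st, c(d1, d2))
  st$im <- list(pid = d1, itype = 2L, act = 1, life = 1e5)
  expect_equal(phagocytose(st), 1)
  expect_false(st$debris[d1])
  expect_true(st$debris[d2])       # not co-located: untouched
  expect_equal(phagocytose(st), 0) # nothing under the cell now
  # debris conservation over a whole wound episode:
  # formed = cleared (incl. autolyzed) + remaining, and a cell dying onto
  # existing debris merges rather than duplicating a unit
  chk <- fx_checkpoint()
  run <- run_scenario(chk, scenario_wound(), days = 1, seed = 13)
  m <- run$metrics
  expect_equal(sum(m$debris_formed), sum(m$cleared) + m$necrotic[nrow(m)])
  expect_gte(sum(m$necroses), sum(m$debris_formed))
})

test_that("wound debris decline is eventually monotone as clearance
           overtakes propagation", {
  chk <- fx_checkpoint()
  run <- run_scenario(chk, scenario_wound(), days = 1.5, seed = 14)
  nec <- run$metrics$necrotic
  peak <- which.max(nec)
  after <- nec[seq(peak + 8, length(nec), by = 8)]
  expect_true(all(diff(after) <= 0))
})

test_that("inflammatory cells expire on schedule and IL-10 shortens
           neutrophil survival", {
  st <- quiet_state()
  st$im <- list(pid = st$ids[5, 1], itype = 3L, act = 1, life = 10)
  expire_inflammatory(st)
  expect_equal(length(st$im$pid), 0)   # lifespan hit zero: removed
  # cohort statistic: high ambient IL-10 cuts neutrophil survival time
  lifespan_under <- function(il10) {
    s <- quiet_state()
    s$f$IL10[] <- il10
    s$debris[s$ids[40, 1]] <- TRUE     # keep the compartment non-quiet
    n0 <- 200
    s$im <- list(pid = rep(s$ids[30, 2], n0), itype = rep(3L, n0),
                 act = rep(1, n0), life = rep(s$cfg$inflammation$neutrophil_life, n0))
    ticks <- 0
    while (sum(s$im$itype == 3L) > n0 / 2 && ticks < 2000) {
      expire_inflammatory(s)
      ticks <- ticks + 1
    }
    ticks
  }
  t_hi <- lifespan_under(1)
  t_lo <- lifespan_under(0)
  expect_lt(t_hi, t_lo * 0.55)         # roughly halved under strong IL-10
})
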