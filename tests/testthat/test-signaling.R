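p_sig <- cv_defaults$signaling

test_that("beta-catenin follows the destruction-complex switching rules", {
  # zero Wnt: the complex activates after its delay, then bcat decays
  st <- list(bcat = 1, timer = 0)
  traj <- numeric(10); active <- logical(10)
  for (i in 1:10) {
    r <- wnt_bcat_update(st$bcat, st$timer, wnt_local = 0, dt = 15, p_sig)
    st <- list(bcat = r$bcat, timer = r$wnt_free_min)
    traj[i] <- r$bcat; active[i] <- r$dc_active
  }
  expect_false(active[1])           # still within the activation delay
  expect_true(all(active[3:10]))
  expect_true(all(diff(traj) <= 0)) # non-increasing without Wnt
  # hand-iterated oracle: delay of dc_delay_min, then exponential decay
  n_decay <- sum(active)
  expect_equal(traj[10], 1 * exp(-15 * n_decay / p_sig$tau_bcat_down),
               tolerance = 1e-12)

  # constant Wnt: saturating accumulation matches the closed form
  x <- 0.1
  for (i in 1:10) x <- wnt_bcat_update(x, 0, wnt_local = 10, dt = 15,
                                       p_sig)$bcat
  expect_equal(x, 1 - (1 - 0.1) * exp(-10 * 15 / p_sig$tau_bcat_up),
               tolerance = 1e-12)

  # all-zero state in an all-zero environment stays at zero
  r0 <- wnt_bcat_update(0, 1e6, 0, 15, p_sig)
  expect_equal(r0$bcat, 0)
})

test_that("BMP activity ramps with time since differentiation", {
  expect_equal(bmp_activity(1, NA, p_sig), 0)       # undifferentiated
  expect_equal(bmp_activity(1, -5, p_sig), 0)
  early <- bmp_activity(1, 15, p_sig)
  expect_gt(early, 0); expect_lt(early, 0.05)       # just-differentiated
  expect_equal(bmp_activity(1, p_sig$bmp_ramp_min * 2, p_sig), 1)  # saturated
  ages <- seq(0, 2 * p_sig$bmp_ramp_min, by = 120)
  expect_true(all(diff(bmp_activity(1, ages, p_sig)) >= 0))  # monotone
  expect_equal(bmp_activity(0.5, p_sig$bmp_ramp_min, p_sig), 0.5)
})

test_that("only live differentiated cells secrete Hh and SFRP1", {
  r <- hh_sfrp1_production(FALSE, 1, 1, p_sig)   # stem/TA
  expect_equal(r$hh, 0); expect_equal(r$sfrp1, 0)
  h <- 1.7
  r2 <- hh_sfrp1_production(TRUE, h, 0.8, p_sig)
  expect_equal(r2$hh, p_sig$hh_secretion_rate * h)
  expect_equal(r2$sfrp1, p_sig$sfrp1_secretion_rate * 0.8)
})

test_that("the PTEN axis reaches the analytic fixed point under chronic tone", {
  # iterate the update map to convergence at sustained low TLR4 tone
  S <- 0.5
  pten <- 1; hh <- 1
  for (i in 1:4000) {
    r <- pten_axis_update(pten, hh, hh_signal = hh, chronic = S, dt = 15,
                          p_sig)
    pten <- r$pten; hh <- r$hh_internal
  }
  # independent oracle: solve the coupled fixed-point equations directly
  a <- p_sig$hh_pten_slope
  fp <- uniroot(function(h) {
    pt <- (1 + p_sig$tlr4_pten_gain * S) * 2 / (1 + h)
    (1 + a) / (1 + a * pt) - h
  }, c(1e-6, 1))$root
  expect_equal(hh, fp, tolerance = 1e-6)
  expect_gt(pten, 1)   # PTEN above baseline under chronic stimulation
  r <- pten_axis_update(pten, hh, hh, S, 15, p_sig)
  expect_lt(r$akt, 1)  # Akt below baseline
  # no chronic tone, baseline levels: everything stays at baseline
  r0 <- pten_axis_update(1, 1, 1, 0, 15, p_sig)
  expect_equal(r0$pten, 1, tolerance = 1e-12)
  expect_equal(r0$akt, 1, tolerance = 1e-12)
})

test_that("PTEN inhibition releases internal Hh (the compensatory spike)", {
  pten <- 1; hh <- 1
  for (i in 1:40) {   # ~10 h
    r <- pten_axis_update(pten, hh, hh_signal = 1, chronic = 0, dt = 15,
                          p_sig, pten_block = 1)
    pten <- r$pten; hh <- r$hh_internal
  }
  expect_equal(pten, 0)
  expect_gt(hh, 1.3)  # rises towards (1 + slope) with PTEN clamped
})

test_that("TLR4 activation, NF-kB and RIP respect the necrosis threshold", {
  # ligand just below saturating levels: NF-kB rises, RIP stays at zero
  s <- list(tlr4 = 0, chronic = 0, nfkb = 0, rip = 0, ros = 0, jak = 0)
  for (i in 1:200) {
    s <- inflammatory_axis_update(s$tlr4, s$chronic, s$nfkb, s$rip, s$ros,
                                  s$jak, ligand = 8, debris_neighbors = 0,
                                  ifabp = 0, dt = 15, p = p_sig)
  }
  expect_equal(s$tlr4, 0.5, tolerance = 1e-6)   # 8 / (8 + K), K = 8
  expect_gt(s$nfkb, 0.45)                       # anti-apoptotic arm engaged
  expect_equal(s$rip, 0)                        # below the RIP floor
  # zero ligand: nothing moves
  z <- inflammatory_axis_update(0, 0, 0, 0, 0, 0, 0, 0, 0, dt = 15, p = p_sig)
  expect_true(all(unlist(z) == 0))
  # massive exposure: RIP crosses the necrosis threshold
  s2 <- list(tlr4 = 1, rip = 0)
  for (i in 1:200) {
    r <- inflammatory_axis_update(s2$tlr4, 0, 0, s2$rip, 0, 0,
                                  ligand = 1000, debris_neighbors = 2,
                                  ifabp = 100, dt = 15, p = p_sig)
    s2$tlr4 <- r$tlr4; s2$rip <- r$rip
  }
  expect_gt(s2$rip, p_sig$rip_theta)
  # acute vs chronic: the slow filter barely moves on a 2 h spike
  ch <- 0; tl <- 0
  for (i in 1:8) {
    r <- inflammatory_axis_update(tl, ch, 0, 0, 0, 0, 100, 0, 0, dt = 15,
                                  p = p_sig)
    tl <- r$tlr4; ch <- r$chronic
  }
  expect_lt(ch, 0.15)
})

test_that("apoptosis hazard is monotone in its inputs and NF-kB-bounded", {
  h0 <- apoptosis_hazard(0, 1, 1, 0, 15, p_sig)
  expect_equal(h0, p_sig$h_base, tolerance = 1e-2)  # no BMP activity
  b <- seq(0, 1, by = 0.1)
  hb <- apoptosis_hazard(b, 1, 1, 0, 15, p_sig)
  expect_true(all(diff(hb) >= 0))                   # rises with bound BMP
  expect_gt(apoptosis_hazard(0.9, 0.5, 1, 0, 15, p_sig),
            apoptosis_hazard(0.9, 1, 1, 0, 15, p_sig))   # Akt loss
  expect_gt(apoptosis_hazard(0.9, 1, 2, 0, 15, p_sig),
            apoptosis_hazard(0.9, 1, 1, 0, 15, p_sig))   # Hh signal
  # NF-kB suppression is multiplicative and bounded below at 0.1x
  hi <- apoptosis_hazard(1, 1, 1, 1e6, 15, p_sig)
  expect_gte(hi, 0.1 * apoptosis_hazard(1, 1, 1, 0, 15, p_sig) - 1e-12)
})

test_that("no signaling level goes negative under any update order", {
  set.seed(7)
  for (rep in 1:50) {
    b <- wnt_bcat_update(runif(1), runif(1, 0, 500), runif(1, 0, 40), 15,
                         p_sig)
    px <- pten_axis_update(runif(1, 0, 3), runif(1, 0, 3), runif(1, 0, 3),
                           runif(1), 15, p_sig, pten_block = runif(1))
    ia <- inflammatory_axis_update(runif(1), runif(1), runif(1), runif(1),
                                   runif(1), runif(1), runif(1, 0, 100),
                                   sample(0:4, 1), runif(1, 0, 200),
                                   runif(1), runif(1), 15, p_sig)
    expect_true(all(c(b$bcat, px$pten, px$hh_internal, px$akt,
                      unlist(ia)) >= 0))
  }
})

test_that("delayed rules apply scheduled effects once, in due-time order", {
  fired <- delayed_rule(function(s, e) s$levels[["x"]] < 1, delay = 30,
                        target = "x", rate = 2)
  st <- cell_signal_state(x = 0)
  st <- step_rules(st, list(), t = 0, dt = 15, list(fired))
  expect_equal(st$levels[["x"]], 0)          # effect pending, not applied
  expect_equal(nrow(st$pending), 1)
  expect_equal(st$pending$due, 30)
  st <- step_rules(st, list(), t = 15, dt = 15, list(fired))
  expect_equal(st$levels[["x"]], 0)          # still before due time
  st <- step_rules(st, list(), t = 30, dt = 15, list(fired))
  expect_equal(st$levels[["x"]], 30)         # rate * dt applied exactly once
  expect_true(!is.unsorted(st$pending$due))
  # negative effects clamp at zero
  drain <- delayed_rule(function(s, e) TRUE, 0, "x", -1e6)
  st2 <- cell_signal_state(x = 5)
  st2 <- step_rules(st2, list(), 0, 1, list(drain))
  st2 <- step_rules(st2, list(), 1, 1, list(drain))
  expect_gte(st2$levels[["x"]], 0)
})

test_that("the delayed-rule discretization converges to the analytic
           exponential as dt shrinks", {
  a <- 0.2; b <- 0.05; x0 <- 0; T_min <- 120
  exact <- a / b + (x0 - a / b) * exp(-b * T_min)
  errs <- sapply(c(4, 2, 1), function(dt) {
    tr <- integrate_rule_chain(a, b, x0, T_min, dt)
    abs(tr$x[nrow(tr)] - exact)
  })
  expect_true(all(diff(errs) < 0))      # error decreases with dt
  expect_lt(errs[3], 0.01 * exact)      # and is small at the finest step
})
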