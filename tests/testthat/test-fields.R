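test_that("a quiet field stays quiet and a zero field samples zero", {
  topo <- tiny_topo(5, 3, 2)
  f <- new_field(topo, "WNT", D = 0.3, k_decay = 0.01)
  f2 <- step_field(f, topo, dt = 15)
  expect_equal(f2$conc, rep(0, topo$n_patches))
  expect_identical(sample_field(f, 1), 0)
  # with D = 0, k = 0 and no sources the field is constant in time
  g <- new_field(topo, "BMP_FREE", D = 0, k_decay = 0, conc = 1.7)
  g2 <- step_field(g, topo, dt = 15)
  expect_equal(g2$conc, rep(1.7, topo$n_patches))
})

test_that("mass is conserved without decay over many steps (closed box)", {
  topo <- tiny_topo(5, 3, 2)  # 25-patch lattice
  f <- new_field(topo, "WNT", D = 0.4, k_decay = 0)
  f <- deposit(f, 13, 1)      # unit mass at one patch
  for (k in 1:1000) f <- step_field(f, topo, dt = 15)
  expect_lt(abs(sum(f$conc) - 1), 1e-9)
  expect_true(all(f$conc >= 0))
})

test_that("a decay-only field decreases geometrically", {
  topo <- tiny_topo(3, 2, 2)
  k <- 0.01; dt <- 15
  f <- new_field(topo, "IL6", D = 0, k_decay = k, conc = 2)
  f1 <- step_field(f, topo, dt)
  expect_equal(f1$conc, rep(2 * exp(-k * dt), topo$n_patches),
               tolerance = 1e-12)
  # after a deposit at p (D = 0), the next tick retains exp(-k dt) of it
  f <- deposit(f, 5, 3)
  fs <- step_field(f, topo, dt)
  expect_equal(sample_field(fs, 5), (2 + 3) * exp(-k * dt), tolerance = 1e-12)
})

test_that("constant source with decay reaches the brute-force steady profile", {
  # 1 x 30 strip: crypt 1 x 10 joined to villus 1 x 20
  topo <- build_tissue(tissue_config(crypt_width = 1, crypt_rows = 10,
                                     villus_rows = 20))
  # a short tick keeps the deposit-then-relax discretization close to the
  # continuous-source steady state it is compared against
  D <- 0.3; k <- 0.01; dt <- 1
  f <- new_field(topo, "WNT", D = D, k_decay = k,
                 sources = stats::setNames(1, "1"))
  for (i in 1:2000) f <- step_field(f, topo, dt)
  # independent oracle: steady state solves (k I - D L) c = s
  L <- as.matrix(cryptvillus:::lattice_laplacian(topo))
  s <- numeric(topo$n_patches); s[1] <- 1
  c_star <- solve(k * diag(topo$n_patches) - D * L, s)
  ord <- order(topo$patches$axial_pos)
  expect_equal(f$conc[ord], c_star[ord], tolerance = 2e-2)
  expect_true(all(diff(f$conc[ord]) < 0))  # strictly decreasing from source
})

test_that("explicit-scheme stability violations are a config error", {
  topo <- tiny_topo()
  f <- new_field(topo, "WNT", D = 1, k_decay = 0)
  expect_error(step_field(f, topo, dt = 15, dt_sub = 5), "unstable")
  expect_error(new_field(topo, "WNT", D = -1), "D must be")
  expect_error(sample_field(f, 999), "unknown patch")
  expect_error(deposit(f, 0, 1), "unknown patch")
})

test_that("stepping is deterministic and uniform sources stay uniform", {
  topo <- tiny_topo()
  mk <- function() {
    f <- new_field(topo, "HH", D = 0.4, k_decay = 0.01,
                   conc = rep(0.5, topo$n_patches))
    for (i in 1:20) f <- step_field(f, topo, 15)
    f$conc
  }
  expect_identical(mk(), mk())
  # uniform field with no sinks stays uniform under diffusion + decay
  f <- new_field(topo, "BMP_FREE", D = 0.2, k_decay = 0.005, conc = 1)
  for (i in 1:50) f <- step_field(f, topo, 15)
  expect_lt(diff(range(f$conc)), 1e-12)
})

test_that("the homeostatic Wnt profile check accepts the real pattern only", {
  chk <- fx_checkpoint()
  arch <- measure_architecture(chk)
  wf <- new_field(chk$topo, "WNT")
  wf$conc <- chk$f$WNT
  expect_true(wnt_profile_check(wf, chk$topo,
                                arch$junction_row * chk$patch_um))
  uf <- new_field(chk$topo, "WNT", conc = 1)  # uniform field: no gradient
  expect_false(wnt_profile_check(uf, chk$topo,
                                 arch$junction_row * chk$patch_um))
})
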