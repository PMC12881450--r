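# Inhibition functions, dimensionless/dimensional right-hand sides, the
# scale map between them, and structural miRNA variants.

test_that("inhibition functions are the expected squares and sums", {
  s <- c(A1 = 0, A2 = 1, A3 = 2, R1 = 1, R2 = 1, R3 = 1, T = 1, S = 1)
  G <- inhibition_terms(s)
  expect_equal(unname(G), c(0, 1, 4, 3, 3))
  s2 <- c(A1 = 1, A2 = 1, A3 = 1, R1 = 2, R2 = 0, R3 = 0, T = 1, S = 1)
  expect_equal(inhibition_terms(s2)[["G4"]], 4)
  expect_error(inhibition_terms(replace(s, 1, -0.1)), "non-negative")
})

test_that("inhibition functions are strictly increasing in their arguments", {
  base <- random_state(seed = 1)
  for (v in c("A1", "A2", "A3", "R1", "R2", "R3")) {
    lo <- base
    hi <- base
    hi[v] <- hi[v] + 0.5
    gl <- inhibition_terms(lo)
    gh <- inhibition_terms(hi)
    dep <- switch(v, A1 = "G1", A2 = "G2", A3 = "G3",
                  R1 = c("G4", "G5"), R2 = c("G4", "G5"), R3 = c("G4", "G5"))
    expect_true(all(gh[dep] > gl[dep]))
    expect_true(all(gh[setdiff(names(gh), dep)] == gl[setdiff(names(gl), dep)]))
  }
})

test_that("dimensionless derivatives reduce to the expected closed forms", {
  p <- model_parameters()
  s <- random_state(seed = 2)
  d <- rhs_dimensionless(-1, s, p)
  # antagomirs: pure first-order decay
  expect_equal(d[["A1"]], -p$mu_A1 * s[["A1"]])
  expect_equal(d[["A2"]], -p$mu_A2 * s[["A2"]])
  expect_equal(d[["A3"]], -p$mu_A3 * s[["A3"]])
  # alpha = 0: the Hill denominator cancels and autocatalysis saturates at k1
  p0 <- model_parameters(alpha = 0, base = p)
  d0 <- rhs_dimensionless(-1, s, p0)
  expect_equal(d0[["R1"]], p$lam_R1 + p$k1 - p$mu_R1 * s[["R1"]])
  # SE induction multiplies the miRNA sources for t >= 0
  dse <- rhs_dimensionless(0, s, p)
  expect_equal(dse[["R1"]] - d[["R1"]],
               (p$se_source_multiplier - 1) * p$lam_R1)
  # derivative vanishes at the closed-form equilibrium
  eq <- steady_state(p, A_const = c(0, 0, 0), se_phase = FALSE)
  deq <- rhs_dimensionless(-1, eq$state, p)
  expect_lt(max(abs(deq[4:8])), 1e-12)
})

test_that("masked-out branches are frozen and removed from the cascade", {
  p <- model_parameters()
  mask <- mirna_mask(TRUE, FALSE, FALSE)
  s <- random_state(seed = 3)
  d <- rhs_dimensionless(-1, s, p, mask)
  expect_identical(d[["R2"]], 0)
  expect_identical(d[["R3"]], 0)
  # excluded branches contribute nothing to the T/S denominators
  s0 <- s
  s0[c("R2", "R3")] <- 0
  dref <- rhs_dimensionless(-1, s0, p)
  expect_equal(d[["T"]], dref[["T"]])
  expect_equal(d[["S"]], dref[["S"]])
})

test_that("model_variant zeroes exactly the excluded branch parameters", {
  p <- model_parameters()
  expect_identical(model_variant(p, mirna_mask()), p)
  v <- model_variant(p, mirna_mask(TRUE, FALSE, FALSE))
  expect_identical(unname(unlist(v[c("eps", "zeta", "theta", "kappa",
                                     "lam_R2", "lam_R3")])), rep(0, 6))
  expect_identical(v$delta, p$delta)
  expect_identical(v$lam_R1, p$lam_R1)
})

test_that("the scale map is the identity at unit scales and scales quadratically", {
  dp <- random_dim_params(seed = 4)
  for (nm in c("A1s", "A2s", "A3s", "R1s", "R2s", "R3s", "Ts", "Ss"))
    dp[[nm]] <- 1
  p <- nondimensionalize(dp)
  expect_equal(p$k1, dp$tau1)
  expect_equal(p$alpha, dp$ups1)
  expect_equal(p$lam_R1, dp$f_miR21)
  expect_equal(p$lam, dp$lambda_TGFb)
  expect_equal(p$mu_S, dp$mu_SMAD)
  expect_equal(p$se_source_multiplier, 1)
  dp$A1s <- 2
  dp$ups1 <- 0.5
  expect_equal(nondimensionalize(dp)$alpha, 2)
})

test_that("dimensional and dimensionless systems agree under the scale map", {
  # Trajectories of the barred system, rescaled by the characteristic
  # concentrations, must match trajectories of the dimensionless system.
  scales <- function(dp) unlist(dp[c("A1s", "A2s", "A3s", "R1s", "R2s",
                                     "R3s", "Ts", "Ss")])
  for (seed in 1:10) {
    dp <- random_dim_params(seed = 100 + seed)
    p <- nondimensionalize(dp)
    sc <- scales(dp)
    y0 <- random_state(seed = 200 + seed)
    f_dim <- function(t, y, parms) list(rhs_dimensional(t, y, dp))
    f_nd <- function(t, y, parms) list(rhs_dimensionless(t, y, p))
    tt <- seq(0, 10, by = 1)
    sol_dim <- deSolve::lsoda(y0 * sc, tt, f_dim, NULL, rtol = 1e-10, atol = 1e-12)
    sol_nd <- deSolve::lsoda(y0, tt, f_nd, NULL, rtol = 1e-10, atol = 1e-12)
    rescaled <- sweep(sol_dim[, -1], 2, sc, "/")
    expect_lt(max(abs(rescaled - sol_nd[, -1])), 1e-6)
  }
})

test_that("trajectories stay non-negative and bounded for random systems", {
  for (seed in 1:8) {
    p <- random_params(seed = 300 + seed)
    y0 <- random_state(seed = 400 + seed)
    f <- function(t, y, parms) list(rhs_dimensionless(t, y, p))
    sol <- deSolve::lsoda(y0, seq(-24, 100, by = 2), f, NULL,
                          rtol = 1e-8, atol = 1e-10)
    expect_true(all(sol[, -1] > -1e-8))
    m <- p$se_source_multiplier
    t_max <- (p$lam_T + p$k7) / p$mu_T
    bounds <- c(rep(max(y0[1:3]), 3),
                (c(p$lam_R1, p$lam_R2, p$lam_R3) * m + c(p$k1, p$k3, p$k5)) /
                  c(p$mu_R1, p$mu_R2, p$mu_R3),
                t_max,
                (p$lam_S + p$lam * t_max + p$k9) / p$mu_S)
    lim <- 10 * pmax(bounds, y0)
    expect_true(all(sweep(sol[, -1], 2, lim, "<=")))
  }
})

test_that("parameter validation rejects invalid fields", {
  expect_error(model_parameters(mu_T = 0), "strictly positive")
  expect_error(model_parameters(k2 = -1), "strictly positive")
  expect_error(model_parameters(alpha = -5), "non-negative")
  expect_error(model_parameters(se_source_multiplier = 0.5), ">= 1")
  expect_error(model_parameters(nonsense = 1), "unknown parameter")
})
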