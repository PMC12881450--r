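# Equilibria, Jacobian structure, stability, nullclines and vector fields.

test_that("the closed-form equilibrium has the expected limits", {
  p <- model_parameters()
  eq0 <- steady_state(p, A_const = c(0, 0, 0), se_phase = FALSE)
  expect_equal(eq0$state[["R1"]], (p$lam_R1 + p$k1) / p$mu_R1)
  # saturated inhibition: autocatalysis fully suppressed
  eq_inf <- steady_state(p, A_const = rep(1e9, 3), se_phase = FALSE)
  expect_equal(eq_inf$state[["R1"]], p$lam_R1 / p$mu_R1, tolerance = 1e-6)
  expect_lt(eq0$residual, 1e-9)
  expect_error(steady_state(p, A_const = c(-1, 0, 0)), "non-negative")
})

test_that("long integration converges to the closed-form equilibrium", {
  p <- model_parameters()
  eq <- steady_state(p, A_const = c(0, 0, 0))
  traj <- simulate_protocol(p, dosing_protocol("control"), t_end = 500,
                            grid = seq(-24, 500, by = 4))
  final <- traj$states[nrow(traj$states), ]
  expect_lt(max(abs(final[4:8] - eq$state[4:8])), 1e-6)
})

test_that("the Jacobian matches finite differences and is triangular", {
  for (seed in 1:5) {
    p <- random_params(seed = 500 + seed)
    st <- random_state(seed = 600 + seed)
    J <- model_jacobian(p, st)
    f0 <- rhs_dimensionless(-1, st, p)
    fd <- matrix(0, 8, 8)
    hstep <- 1e-6
    for (j in 1:8) {
      s2 <- st
      s2[j] <- s2[j] + hstep
      fd[, j] <- (rhs_dimensionless(-1, s2, p) - f0) / hstep
    }
    expect_lt(max(abs(J - fd)), 1e-4)
    expect_true(all(J[upper.tri(J)] == 0))
  }
})

test_that("eigenvalues equal the negated decay rates for random systems", {
  for (seed in 1:100) {
    p <- random_params(seed = 700 + seed)
    st <- random_state(seed = 800 + seed)
    ev <- sort(Re(eigen(model_jacobian(p, st), only.values = TRUE)$values))
    mus <- sort(-unlist(p[c("mu_A1", "mu_A2", "mu_A3", "mu_R1", "mu_R2",
                            "mu_R3", "mu_T", "mu_S")]))
    expect_equal(ev, unname(mus), tolerance = 1e-12)
  }
})

test_that("every equilibrium of a valid system is a stable node", {
  for (seed in 1:20) {
    p <- random_params(seed = 900 + seed)
    A <- runif(3, 0, 2)
    eq <- steady_state(p, A_const = A)
    expect_equal(eq$classification, "stable_node")
    expect_lt(eq$residual, 1e-9)
  }
})

test_that("random starts are attracted to the unique equilibrium", {
  p <- model_parameters()
  eq <- steady_state(p, A_const = c(0, 0, 0))
  f <- function(t, y, parms) list(rhs_dimensionless(t, y, p))
  set.seed(12)
  finals <- t(sapply(1:50, function(i) {
    y0 <- runif(8, 0, 3)
    names(y0) <- state_names()
    y0[1:3] <- 0  # constant (zero) antagomir levels
    sol <- deSolve::lsoda(y0, c(0, 500), f, NULL, rtol = 1e-10, atol = 1e-12)
    sol[2, -1]
  }))
  expect_lt(max(abs(sweep(finals[, 4:8], 2, eq$state[4:8], "-"))), 1e-5)
})

test_that("steady state under a pairwise variant lies below both singles", {
  p <- model_parameters()
  masks <- list(R1 = mirna_mask(TRUE, FALSE, FALSE),
                R2 = mirna_mask(FALSE, TRUE, FALSE),
                R3 = mirna_mask(FALSE, FALSE, TRUE))
  pairs <- list(c("R1", "R2"), c("R1", "R3"), c("R2", "R3"))
  singles <- lapply(masks, function(m)
    steady_state(model_variant(p, m), mask = m)$state)
  for (pr in pairs) {
    m2 <- mirna_mask("R1" %in% pr, "R2" %in% pr, "R3" %in% pr)
    st2 <- steady_state(model_variant(p, m2), mask = m2)$state
    for (one in pr) {
      expect_lt(st2[["T"]], singles[[one]][["T"]])
      expect_lt(st2[["S"]], singles[[one]][["S"]])
    }
  }
})

test_that("steady-state suppression is monotone in antagomir and strengths", {
  p <- model_parameters()
  # R* non-increasing in the clamped antagomir level
  Rstars <- sapply(seq(0, 2, by = 0.25), function(a)
    steady_state(p, A_const = rep(a, 3))$state[["R1"]])
  expect_true(all(diff(Rstars) <= 1e-12))
  # T* non-increasing in each TGF-beta inhibition strength
  for (nm in c("delta", "eps", "zeta")) {
    Ts <- sapply(seq(0.5, 3, by = 0.5), function(v) {
      pp <- model_parameters(base = p)
      pp[[nm]] <- v
      steady_state(pp)$state[["T"]]
    })
    expect_true(all(diff(Ts) <= 1e-12))
  }
  # S* non-increasing in each SMAD inhibition strength
  for (nm in c("eta", "theta", "kappa")) {
    Ss <- sapply(seq(0.5, 3, by = 0.5), function(v) {
      pp <- model_parameters(base = p)
      pp[[nm]] <- v
      steady_state(pp)$state[["S"]]
    })
    expect_true(all(diff(Ss) <= 1e-12))
  }
})

test_that("nullclines intersect at the equilibrium and zero the derivatives", {
  p <- model_parameters()
  for (A in list(c(0, 0, 0), c(1, 1, 1))) {
    for (pair in list(c("R1", "T"), c("R3", "S"))) {
      nc <- nullclines_2d(p, pair = pair, A_const = A)
      eq <- steady_state(p, A_const = A)
      expect_equal(unname(nc$intersection[1]), unname(eq$state[[pair[1]]]),
                   tolerance = 1e-8)
      expect_equal(unname(nc$intersection[2]), unname(eq$state[[pair[2]]]),
                   tolerance = 1e-8)
      # every sampled point of the explicit curve zeroes its own derivative
      resid <- apply(nc$var2_nullcline, 1, function(row) {
        st <- nc$background
        st[[pair[1]]] <- row[1]
        st[[pair[2]]] <- row[2]
        rhs_dimensionless(0, st, p)[[pair[2]]]
      })
      expect_lt(max(abs(resid)), 1e-8)
    }
  }
})

test_that("without TGF-beta inhibition the T-nullcline is flat", {
  p <- model_parameters(delta = 0, eps = 0, zeta = 0)
  nc <- nullclines_2d(p, pair = c("R1", "T"))
  expect_equal(unique(round(nc$var2_nullcline$T, 12)),
               round((p$lam_T + p$k7) / p$mu_T, 12))
})

test_that("the vector field vanishes at equilibrium and flips across the nullcline", {
  p <- model_parameters()
  eq <- steady_state(p, A_const = c(0, 0, 0))
  g <- list(R1 = c(eq$state[["R1"]], 0.5, 2.5), T = c(eq$state[["T"]], 0.3, 2))
  vf <- vector_field_2d(p, c("R1", "T"), background = eq$state, grid = g)
  expect_lt(abs(vf$d1[1, 1]), 1e-9)
  expect_lt(abs(vf$d2[1, 1]), 1e-9)
  # dT/dt changes sign across the T-nullcline along a vertical transect
  nc <- nullclines_2d(p, pair = c("R1", "T"), A_const = c(0, 0, 0))
  r_fix <- 1.0
  t_null <- nc$var2_nullcline$T[which.min(abs(nc$var2_nullcline$R1 - r_fix))]
  g2 <- list(R1 = r_fix, T = c(t_null - 0.2, t_null + 0.2))
  vf2 <- vector_field_2d(p, c("R1", "T"), background = eq$state, grid = g2)
  expect_gt(vf2$d2[1, 1], 0)
  expect_lt(vf2$d2[1, 2], 0)
})

test_that("field arrows are tangent to a simulated trajectory", {
  p <- model_parameters(se_source_multiplier = 1)
  traj <- simulate_protocol(p, dosing_protocol("control"), t_end = 24,
                            grid = seq(-24, 24, by = 0.1))
  idx <- which(traj$times > -23 & traj$times < -18)  # transient, far from rest
  cosims <- sapply(idx, function(i) {
    d <- rhs_dimensionless(traj$times[i], traj$states[i, ], p)
    v_traj <- (traj$states[i + 1, ] - traj$states[i - 1, ]) /
      (traj$times[i + 1] - traj$times[i - 1])
    u <- c(d[["R1"]], d[["T"]])
    w <- c(v_traj[["R1"]], v_traj[["T"]])
    sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  })
  expect_true(all(cosims > 0.99))
})
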