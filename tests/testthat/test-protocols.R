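# Dosing-protocol construction, event semantics and trajectory simulation.

test_that("protocol builders produce the documented impulse schedules", {
  b <- dosing_protocol("bolus", dose = 1.0)
  ev <- protocol_events(b)
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$time == -24))
  expect_true(all(ev$amount == 1.0))

  m1 <- dosing_protocol("multidose", dose = 1.0, n_injections = 1)
  expect_equal(protocol_events(m1), protocol_events(b))

  m4 <- dosing_protocol("multidose", dose = 1.0, n_injections = 4)
  ev4 <- protocol_events(m4)
  expect_equal(sort(unique(ev4$time)), c(-24, -18, -12, -6))
  expect_true(all(ev4$amount == 0.25))

  expect_equal(nrow(protocol_events(dosing_protocol("control"))), 0)
  expect_equal(nrow(protocol_events(dosing_protocol("infusion", dose = 0.25))), 0)

  expect_error(dosing_protocol("bolus", dose = -1), "non-negative")
  expect_error(dosing_protocol("control", dose = 0.5), "dose = 0")
  expect_error(dosing_protocol("multidose", dose = 1, n_injections = 0),
               "positive integer")
})

test_that("the antagomir closed form obeys decay identities", {
  expect_equal(antagomir_closed_form(1, 0, 0, 17), 1)
  mu <- 0.3
  expect_equal(antagomir_closed_form(1, mu, 0, log(2) / mu), 0.5)
  expect_error(antagomir_closed_form(1, mu, 0, -1), "precedes")
})

test_that("simulated antagomir channels match the analytic superposition", {
  p <- model_parameters()
  for (proto in list(dosing_protocol("bolus", dose = 0.8),
                     dosing_protocol("multidose", dose = 1.0, n_injections = 4))) {
    traj <- simulate_protocol(p, proto, t_end = 24)
    ev <- protocol_events(proto)
    ev1 <- ev[ev$channel == "A1", ]
    expected <- rowSums(sapply(seq_len(nrow(ev1)), function(j) {
      out <- numeric(length(traj$times))
      on <- traj$times >= ev1$time[j]
      out[on] <- antagomir_closed_form(ev1$amount[j], p$mu_A1, ev1$time[j],
                                       traj$times[on])
      out
    }))
    expect_lt(max(abs(traj$states[, "A1"] - expected)), 1e-8)
  }
})

test_that("impulses jump A exactly while R, T, S stay continuous", {
  p <- model_parameters()
  proto <- dosing_protocol("multidose", dose = 1.0, n_injections = 4)
  fine <- seq(-24, 24, by = 0.01)
  traj <- simulate_protocol(p, proto, t_end = 24, grid = fine)
  for (t_imp in c(-18, -12, -6)) {
    i <- which(traj$times == t_imp)
    before <- traj$states[i - 1, ]
    at <- traj$states[i, ]
    # A jumps by ~dose/4 (0.01 h of decay notwithstanding)
    expect_equal(unname(at["A1"] - before["A1"]), 0.25, tolerance = 1e-2)
    # downstream species move only by O(dt)
    expect_lt(max(abs(at[4:8] - before[4:8])), 0.02)
  }
})

test_that("infusion clamps the antagomir level then releases it to decay", {
  p <- model_parameters()
  proto <- dosing_protocol("infusion", dose = 0.25)
  traj <- simulate_protocol(p, proto, t_end = 24)
  inwin <- traj$times >= -24 & traj$times <= 0
  expect_true(all(abs(traj$states[inwin, "A2"] - 0.25) < 1e-10))
  post <- traj$times > 0
  expect_equal(traj$states[post, "A2"],
               0.25 * exp(-p$mu_A2 * traj$times[post]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("with all production switched off a bolus decays in closed form", {
  p <- model_parameters(lam_R1 = 0, lam_R2 = 0, lam_R3 = 0, lam_T = 0,
                        lam_S = 0, k1 = 0, k3 = 0, k5 = 0, k7 = 0, k9 = 0,
                        lam = 0, se_source_multiplier = 1)
  d <- 0.7
  traj <- simulate_protocol(p, dosing_protocol("bolus", dose = d), t_end = 24)
  expect_equal(traj$states[, "A1"], d * exp(-p$mu_A1 * (traj$times + 24)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # R also decays in closed form from its initial 1.0
  expect_equal(traj$states[, "R1"], exp(-p$mu_R1 * (traj$times + 24)),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("a control run started at equilibrium stays constant", {
  p <- model_parameters(se_source_multiplier = 1)
  eq <- steady_state(p, A_const = c(0, 0, 0), se_phase = FALSE)
  traj <- simulate_protocol(p, dosing_protocol("control"), t_end = 24,
                            init = eq$state)
  drift <- sweep(traj$states, 2, eq$state, "-")
  expect_lt(max(abs(drift)), 1e-7)
})

test_that("tightening integrator tolerances barely moves the solution", {
  p <- model_parameters()
  proto <- dosing_protocol("bolus", dose = 1.0)
  g <- seq(-24, 24, by = 0.5)
  a <- simulate_protocol(p, proto, grid = g, rtol = 1e-8, atol = 1e-10)
  b <- simulate_protocol(p, proto, grid = g, rtol = 5e-9, atol = 5e-11)
  rel <- abs(a$states - b$states) / (abs(a$states) + 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("the fast batch integrator matches the adaptive reference", {
  p <- model_parameters()
  for (proto in list(dosing_protocol("control"),
                     dosing_protocol("bolus", dose = 1.0),
                     dosing_protocol("infusion", dose = 0.25),
                     dosing_protocol("multidose", dose = 1.0, n_injections = 8))) {
    ref <- simulate_protocol(p, proto, t_end = 24)
    fast <- mirseize:::.sim_fast(p, proto, times_out = c(0, 24), h = 0.05)
    for (k in 1:2) {
      t_k <- c(0, 24)[k]
      i <- which(ref$times == t_k)
      expect_lt(max(abs(ref$states[i, 4:8] - fast$states[1, , k])), 1e-6)
      # adaptive solver vs closed form on the antagomir channels
      expect_lt(max(abs(ref$states[i, 1:3] - fast$A[k, ])), 1e-7)
    }
  }
})

test_that("higher infusion levels dominate pointwise", {
  p <- model_parameters()
  doses <- c(0.1, 0.2, 0.4)
  trajs <- lapply(doses, function(d)
    simulate_protocol(p, dosing_protocol("infusion", dose = d), t_end = 24))
  for (i in 1:2) {
    lo <- trajs[[i]]$states
    hi <- trajs[[i + 1]]$states
    expect_true(all(hi[, "R1"] <= lo[, "R1"] + 1e-9))
    expect_true(all(hi[, "T"] >= lo[, "T"] - 1e-9))
    expect_true(all(hi[, "S"] >= lo[, "S"] - 1e-9))
  }
})

test_that("splitting a fixed total dose more finely raises chronic T and S", {
  p <- model_parameters()
  lvl <- sapply(c(1, 2, 4, 8), function(n) {
    traj <- simulate_protocol(
      p, dosing_protocol("multidose", dose = 1.0, n_injections = n),
      t_end = 24, grid = seq(-24, 24, by = 0.5))
    traj$states[nrow(traj$states), c("T", "S")]
  })
  expect_true(all(diff(lvl["T", ]) > -1e-9))
  expect_true(all(diff(lvl["S", ]) > -1e-9))
})
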