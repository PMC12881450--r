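# Antagomir administration strategies and trajectory simulation.

#' Declare an antagomir administration strategy
#'
#' Four strategies are supported, all acting on the three antagomir channels
#' during the control phase (default window \[-24, 0\] hours, SE induction at
#' t = 0): `control` (scrambled control, no antagomir), `bolus` (a single
#' impulse of size `dose` at `window_start`), `infusion` (channels clamped at
#' `dose` throughout the window, free first-order decay afterwards), and
#' `multidose` (the total `dose` split into `n_injections` equal impulses at
#' equal intervals starting at `window_start`; successive impulses add to the
#' current level).
#'
#' @param kind One of `"control"`, `"bolus"`, `"infusion"`, `"multidose"`.
#' @param dose Per-antagomir amount in FC over control (total dose for
#'   `multidose`; clamp level for `infusion`).
#' @param n_injections Number of equal impulses (`multidose` only).
#' @param window Numeric length-2, administration window in hours.
#' @param per_antagomir Optional length-3 numeric of per-channel doses
#'   overriding `dose`.
#' @return A list of class `mirseize_protocol`.
#' @export
dosing_protocol <- function(kind = c("control", "bolus", "infusion", "multidose"),
                            dose = 0, n_injections = 1L, window = c(-24, 0),
                            per_antagomir = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(dose) || length(dose) != 1 || !is.finite(dose) || dose < 0)
    stop("dose must be a single non-negative finite number")
  n_injections <- as.integer(n_injections)
  if (is.na(n_injections) || n_injections < 1L)
    stop("n_injections must be a positive integer")
  if (length(window) != 2 || !all(is.finite(window)) || window[1] >= window[2])
    stop("window must be c(start, end) with start < end")
  if (kind == "control" && dose != 0)
    stop("control protocol requires dose = 0")
  if (kind == "multidose" &&
      (window[2] - window[1]) / n_injections <= .Machine$double.eps)
    stop("multidose injection spacing collapses to zero")
  doses <- if (is.null(per_antagomir)) rep(dose, 3) else as.numeric(per_antagomir)
  if (length(doses) != 3 || any(!is.finite(doses)) || any(doses < 0))
    stop("per_antagomir must be 3 non-negative finite values")
  structure(list(kind = kind, dose = dose, n_injections = n_injections,
                 window_start = window[1], window_end = window[2],
                 doses = doses),
            class = "mirseize_protocol")
}

#' @export
print.mirseize_protocol <- function(x, ...) {
  cat(sprintf("<mirseize_protocol> %s, dose %g on [%g, %g] h", x$kind,
              x$dose, x$window_start, x$window_end))
  if (x$kind == "multidose") cat(sprintf(" in %d injections", x$n_injections))
  cat("\n")
  invisible(x)
}

#' Impulse events implied by a protocol
#'
#' @param protocol A `mirseize_protocol`.
#' @return Data frame with columns `time`, `channel` (`"A1".."A3"`) and
#'   `amount`; empty for `control` and `infusion` (the clamp is not an
#'   impulse).
#' @export
protocol_events <- function(protocol) {
  stopifnot(inherits(protocol, "mirseize_protocol"))
  empty <- data.frame(time = numeric(), channel = character(), amount = numeric())
  if (protocol$kind %in% c("control", "infusion")) return(empty)
  times <- if (protocol$kind == "bolus") protocol$window_start else
    protocol$window_start + (seq_len(protocol$n_injections) - 1) *
      (protocol$window_end - protocol$window_start) / protocol$n_injections
  amounts <- if (protocol$kind == "bolus") protocol$doses else
    protocol$doses / protocol$n_injections
  data.frame(
    time = rep(times, each = 3),
    channel = rep(c("A1", "A2", "A3"), times = length(times)),
    amount = rep(amounts, times = length(times))
  )
}

#' Closed-form antagomir level after an impulse
#'
#' Analytic companion of the antagomir decay equations: an impulse of size
#' `dose` at `t0` decays exponentially, `dose * exp(-mu * (t - t0))`.
#' Multi-impulse protocols are superpositions of these responses.
#'
#' @param dose Impulse size (FC over control).
#' @param mu Decay rate (1/hour).
#' @param t0 Impulse time (hours).
#' @param t Evaluation time(s), all `>= t0`.
#' @return Numeric vector of levels.
#' @export
antagomir_closed_form <- function(dose, mu, t0, t) {
  if (any(t < t0)) stop("evaluation time precedes the impulse time")
  dose * exp(-mu * (t - t0))
}

# Per-channel analytic antagomir level under a protocol (vectorized in t).
.antagomir_level <- function(protocol, mu3, t) {
  ws <- protocol$window_start; we <- protocol$window_end
  out <- matrix(0, length(t), 3)
  if (protocol$kind == "control") {
  } else if (protocol$kind == "infusion") {
    for (i in 1:3) {
      lvl <- numeric(length(t))
      inwin <- t >= ws & t <= we
      lvl[inwin] <- protocol$doses[i]
      post <- t > we
      lvl[post] <- protocol$doses[i] * exp(-mu3[i] * (t[post] - we))
      out[, i] <- lvl
    }
  } else {
    ev <- protocol_events(protocol)
    for (i in 1:3) {
      ch <- ev[ev$channel == c("A1", "A2", "A3")[i], ]
      lvl <- numeric(length(t))
      for (j in seq_len(nrow(ch))) {
        on <- t >= ch$time[j]
        lvl[on] <- lvl[on] + ch$amount[j] * exp(-mu3[i] * (t[on] - ch$time[j]))
      }
      out[, i] <- lvl
    }
  }
  colnames(out) <- c("A1", "A2", "A3")
  out
}

#' Simulate the model under a dosing protocol
#'
#' Integrates the dimensionless system piecewise between event boundaries
#' (impulse times, infusion window edges, SE induction at t = 0) with an
#' adaptive implicit-capable solver (`deSolve::lsoda`). At an impulse the
#' integration stops, the dose is added to the antagomir channels, and
#' integration restarts; during an infusion clamp the antagomir derivatives
#' are overridden to zero and the levels held at the clamp value. States at
#' an event time report the post-event value.
#'
#' @param params A `mirseize_params` object.
#' @param protocol A `mirseize_protocol`.
#' @param t_end Final time in hours (must be `>= window_end`).
#' @param grid Output time grid; defaults to 0.1-hour spacing from the
#'   protocol window start to `t_end`.
#' @param mask A `mirseize_mask`.
#' @param init Initial 8-component state; defaults to 1.0 FC over control for
#'   all species, antagomir channels set by the protocol (0 before the first
#'   event), masked miRNA branches frozen at 0.
#' @param rtol,atol Integrator tolerances.
#' @return A `mirseize_trajectory`: list with `times`, `states` (matrix with
#'   one row per time), `events`, `protocol`, `params`, and a `phenotype`
#'   slot filled by [classify_trajectory()].
#' @export
simulate_protocol <- function(params, protocol, t_end = 24, grid = NULL,
                              mask = mirna_mask(), init = NULL,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "mirseize_params"),
            inherits(protocol, "mirseize_protocol"))
  if (t_end < protocol$window_end)
    stop("t_end must not precede the protocol window end")
  if (is.null(grid)) grid <- seq(protocol$window_start, t_end, by = 0.1)
  t0 <- grid[1]
  if (any(diff(grid) <= 0)) stop("grid times must be strictly increasing")
  if (t0 > protocol$window_start)
    stop("grid must start at or before the protocol window start")
  times_out <- sort(unique(c(grid[grid <= t_end], t_end)))

  if (is.null(init)) {
    init <- c(0, 0, 0, 1, 1, 1, 1, 1)
    names(init) <- state_names()
  } else {
    init <- .as_state(init)
    if (any(init < 0)) stop("initial state must be non-negative")
  }
  init[4:6][!as.logical(mask)] <- 0

  ev <- protocol_events(protocol)
  # the clamp applies per integration segment (segments never straddle the
  # window edges), so the solver cannot sample a mixed-regime derivative
  clamp_seg <- FALSE
  derivs <- function(t, y, parms) {
    d <- rhs_dimensionless(t, y, params, mask)
    if (clamp_seg) d[1:3] <- 0
    list(d)
  }

  breaks <- sort(unique(c(t0, ev$time, 0,
                          if (protocol$kind == "infusion")
                            c(protocol$window_start, protocol$window_end),
                          t_end)))
  breaks <- breaks[breaks >= t0 & breaks <= t_end]

  y <- init
  out_t <- numeric(0)
  out_s <- NULL
  record <- function(tt, ss) {
    out_t <<- c(out_t, tt)
    out_s <<- rbind(out_s, ss)
  }

  apply_events_at <- function(y, tt) {
    sel <- ev[abs(ev$time - tt) < 1e-12, ]
    for (j in seq_len(nrow(sel)))
      y[sel$channel[j]] <- y[sel$channel[j]] + sel$amount[j]
    if (protocol$kind == "infusion" && abs(tt - protocol$window_start) < 1e-12)
      y[1:3] <- protocol$doses
    y
  }

  y <- apply_events_at(y, t0)
  if (t0 %in% times_out) record(t0, y)

  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]; b <- breaks[i + 1]
    clamp_seg <- protocol$kind == "infusion" &&
      a >= protocol$window_start - 1e-12 && b <= protocol$window_end + 1e-12
    seg_times <- sort(unique(c(a, times_out[times_out > a & times_out <= b], b)))
    sol <- deSolve::lsoda(y = y, times = seg_times, func = derivs, parms = NULL,
                          rtol = rtol, atol = atol, hmax = 0.1)
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[, -1])))
      stop(sprintf("integration failed on [%g, %g] h", a, b))
    y <- sol[nrow(sol), -1]
    names(y) <- state_names()
    keep <- sol[, 1] %in% times_out & sol[, 1] > a & sol[, 1] < b
    if (any(keep)) record(sol[keep, 1], sol[keep, -1, drop = FALSE])
    y <- apply_events_at(y, b)
    if (b %in% times_out) record(b, y)
  }

  states <- matrix(out_s, ncol = 8, dimnames = list(NULL, state_names()))
  states[states < 0 & states > -1e-12] <- 0
  if (any(states < 0)) stop("negative state encountered; positivity violated")
  structure(list(times = out_t, states = states, events = ev,
                 protocol = protocol, params = params, mask = mask,
                 phenotype = NULL),
            class = "mirseize_trajectory")
}

#' @export
print.mirseize_trajectory <- function(x, ...) {
  cat(sprintf("<mirseize_trajectory> %s protocol, %d time points on [%g, %g] h\n",
              x$protocol$kind, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.mirseize_trajectory <- function(x, ...) {
  df <- data.frame(t = x$times, x$states, check.names = FALSE)
  df$phenotype <- if (is.null(x$phenotype)) NA_character_ else
    as.character(x$phenotype)
  df
}

# ---------------------------------------------------------------------------
# Fast fixed-step batch integrator.
#
# Integrates only (R1, R2, R3, T, S); the antagomir channels have closed-form
# solutions under every protocol and are evaluated analytically inside the
# right-hand side. Many parameter sets are propagated simultaneously as rows
# of a matrix (classic RK4, piecewise between event boundaries), which is what
# makes the eFAST sweeps and the repeated least-squares fits affordable.
# Antagomir decay rates must be shared across rows (they are never varied in
# those sweeps).

.sim_fast <- function(params, protocol, overrides = NULL,
                      times_out = c(0, 24), h = 0.05,
                      init = c(1, 1, 1, 1, 1), t_start = NULL) {
  stopifnot(inherits(params, "mirseize_params"),
            inherits(protocol, "mirseize_protocol"))
  pv <- lapply(unclass(params), as.numeric)
  B <- 1L
  if (!is.null(overrides)) {
    overrides <- as.matrix(overrides)
    if (is.null(colnames(overrides)))
      stop("overrides must have parameter-named columns")
    if (any(grepl("^mu_A", colnames(overrides))))
      stop("antagomir decay rates cannot be varied in the batch integrator")
    B <- nrow(overrides)
    for (nm in colnames(overrides)) pv[[nm]] <- overrides[, nm]
  }
  mu3 <- c(pv$mu_A1[1], pv$mu_A2[1], pv$mu_A3[1])
  t0 <- if (is.null(t_start)) min(protocol$window_start, times_out, 0) else t_start
  if (any(times_out < t0)) stop("times_out must not precede the start time")

  ev_df <- protocol_events(protocol)

  # Hill inhibition factors for precomputed antagomir levels; A rows are
  # stage-time levels, so each factor is a scalar per stage.
  rhs <- function(A, y, m) {
    dR1 <- pv$lam_R1 * m + pv$k1 * pv$k2^2 / (pv$k2^2 + pv$alpha * A[1]^2) - pv$mu_R1 * y[, 1]
    dR2 <- pv$lam_R2 * m + pv$k3 * pv$k4^2 / (pv$k4^2 + pv$beta * A[2]^2) - pv$mu_R2 * y[, 2]
    dR3 <- pv$lam_R3 * m + pv$k5 * pv$k6^2 / (pv$k6^2 + pv$gamma * A[3]^2) - pv$mu_R3 * y[, 3]
    dT <- pv$lam_T + pv$k7 * pv$k8^2 /
      (pv$k8^2 + pv$delta * y[, 1]^2 + pv$eps * y[, 2]^2 + pv$zeta * y[, 3]^2) -
      pv$mu_T * y[, 4]
    dS <- pv$lam_S + pv$lam * y[, 4] + pv$k9 * pv$k10^2 /
      (pv$k10^2 + pv$eta * y[, 1]^2 + pv$theta * y[, 2]^2 + pv$kappa * y[, 3]^2) -
      pv$mu_S * y[, 5]
    cbind(dR1, dR2, dR3, dT, dS)
  }

  ev_times <- unique(ev_df$time)
  breaks <- sort(unique(c(t0, ev_times,
                          if (protocol$kind == "infusion")
                            c(protocol$window_start, protocol$window_end),
                          0, times_out)))
  breaks <- breaks[breaks >= t0]

  y <- matrix(rep(as.numeric(init), each = B), nrow = B)
  out <- array(NA_real_, c(B, 5, length(times_out)),
               dimnames = list(NULL, c("R1", "R2", "R3", "T", "S"), NULL))
  rec <- function(tt) {
    k <- which(abs(times_out - tt) < 1e-9)
    if (length(k)) out[, , k[1]] <<- y
  }
  rec(t0)
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]; b <- breaks[i + 1]
    m <- if (a >= 0) pv$se_source_multiplier else 1
    n <- max(1L, ceiling((b - a) / h))
    dt <- (b - a) / n
    # antagomir levels at all RK4 stage times, precomputed per segment;
    # levels at the segment end use the left limit (pre-impulse, pre-clamp)
    stage_t <- a + (0:(2 * n)) * dt / 2
    Amat <- .antagomir_level(protocol, mu3, stage_t)
    at_end <- stage_t >= b - 1e-12
    if (any(at_end)) {
      sel <- ev_df[abs(ev_df$time - b) < 1e-12, ]
      for (j in seq_len(nrow(sel))) {
        ci <- match(sel$channel[j], c("A1", "A2", "A3"))
        Amat[at_end, ci] <- Amat[at_end, ci] - sel$amount[j]
      }
      if (protocol$kind == "infusion" &&
          abs(b - protocol$window_start) < 1e-12)
        Amat[at_end, ] <- 0
    }
    for (s in seq_len(n)) {
      j0 <- 2 * (s - 1) + 1
      k1m <- rhs(Amat[j0, ], y, m)
      k2m <- rhs(Amat[j0 + 1, ], y + dt / 2 * k1m, m)
      k3m <- rhs(Amat[j0 + 1, ], y + dt / 2 * k2m, m)
      k4m <- rhs(Amat[j0 + 2, ], y + dt * k3m, m)
      y <- y + dt / 6 * (k1m + 2 * k2m + 2 * k3m + k4m)
    }
    rec(b)
  }
  A_out <- .antagomir_level(protocol, mu3, times_out)
  list(times = times_out, states = out, A = A_out)
}
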