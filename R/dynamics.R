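# Equilibria, Jacobian, stability, nullclines and phase-plane fields.

#' Closed-form equilibrium under constant antagomir levels
#'
#' With the antagomir channels held at constant levels the system is a
#' feed-forward cascade, so its unique equilibrium has the explicit form
#' `R_i* = (lam_Ri * m + k_odd k_even^2 / (k_even^2 + strength * A_i^2)) / mu_Ri`,
#' then `T*` and `S*` by substituting the `R_i*` into their own balances.
#' `m` is the SE source multiplier when `se_phase = TRUE` (the chronic
#' phase), otherwise 1.
#'
#' @param params A `mirseize_params`.
#' @param A_const Length-3 constant antagomir levels.
#' @param mask A `mirseize_mask`; excluded branches sit at 0.
#' @param se_phase Logical; apply the SE source multiplier (default TRUE).
#' @return List of class `mirseize_equilibrium` with `state` (8 components),
#'   `eigenvalues` (of the active subsystem's Jacobian), `classification`
#'   (`"stable_node"` or `"other"`), and `residual` (max |rhs| over the
#'   non-antagomir active components, antagomirs treated as clamped).
#' @export
steady_state <- function(params, A_const = c(0, 0, 0), mask = mirna_mask(),
                         se_phase = TRUE) {
  stopifnot(inherits(params, "mirseize_params"))
  if (length(A_const) != 3 || any(!is.finite(A_const)) || any(A_const < 0))
    stop("A_const must be 3 non-negative finite levels")
  p <- params
  m <- if (se_phase) p$se_source_multiplier else 1
  inc <- as.logical(mask)
  R <- c(
    (p$lam_R1 * m + p$k1 * p$k2^2 / (p$k2^2 + p$alpha * A_const[1]^2)) / p$mu_R1,
    (p$lam_R2 * m + p$k3 * p$k4^2 / (p$k4^2 + p$beta * A_const[2]^2)) / p$mu_R2,
    (p$lam_R3 * m + p$k5 * p$k6^2 / (p$k6^2 + p$gamma * A_const[3]^2)) / p$mu_R3
  )
  R[!inc] <- 0
  Tst <- (p$lam_T + p$k7 * p$k8^2 /
            (p$k8^2 + p$delta * R[1]^2 + p$eps * R[2]^2 + p$zeta * R[3]^2)) / p$mu_T
  Sst <- (p$lam_S + p$lam * Tst + p$k9 * p$k10^2 /
            (p$k10^2 + p$eta * R[1]^2 + p$theta * R[2]^2 + p$kappa * R[3]^2)) / p$mu_S
  state <- c(A_const, R, Tst, Sst)
  names(state) <- state_names()
  tt <- if (se_phase) 0 else -1
  resid <- rhs_dimensionless(tt, state, p, mask)
  active <- c(rep(FALSE, 3), inc, TRUE, TRUE)  # antagomirs clamped
  residual <- max(abs(resid[active]))
  J <- model_jacobian(p, state, mask)
  keep <- c(rep(TRUE, 3), inc, TRUE, TRUE)
  ev <- eigen(J[keep, keep, drop = FALSE], only.values = TRUE)$values
  stable <- all(Re(ev) < -1e-12) && all(abs(Im(ev)) < 1e-12)
  structure(list(state = state, eigenvalues = ev,
                 classification = if (stable) "stable_node" else "other",
                 residual = residual),
            class = "mirseize_equilibrium")
}

#' @export
print.mirseize_equilibrium <- function(x, ...) {
  cat("<mirseize_equilibrium>", x$classification,
      sprintf("(residual %.2e)\n", x$residual))
  print(x$state, ...)
  invisible(x)
}

#' Analytic Jacobian of the dimensionless system
#'
#' Under the state ordering (A1, A2, A3, R1, R2, R3, T, S) the Jacobian is
#' block lower-triangular (each species depends only on itself and upstream
#' species), so its eigenvalues are exactly the diagonal entries, the negated
#' decay rates. Rows of masked-out miRNA branches are zero (their state is
#' frozen).
#'
#' @param params A `mirseize_params`.
#' @param state 8-component state at which to evaluate.
#' @param mask A `mirseize_mask`.
#' @return An 8x8 matrix with dimnames `state_names()`.
#' @export
model_jacobian <- function(params, state, mask = mirna_mask()) {
  p <- params
  s <- .as_state(state)
  inc <- as.logical(mask)
  J <- matrix(0, 8, 8, dimnames = list(state_names(), state_names()))
  J["A1", "A1"] <- -p$mu_A1
  J["A2", "A2"] <- -p$mu_A2
  J["A3", "A3"] <- -p$mu_A3
  hill_dA <- function(k_odd, k_even, strength, A)
    -k_odd * k_even^2 * 2 * strength * A / (k_even^2 + strength * A^2)^2
  if (inc[1]) {
    J["R1", "A1"] <- hill_dA(p$k1, p$k2, p$alpha, s[["A1"]])
    J["R1", "R1"] <- -p$mu_R1
  }
  if (inc[2]) {
    J["R2", "A2"] <- hill_dA(p$k3, p$k4, p$beta, s[["A2"]])
    J["R2", "R2"] <- -p$mu_R2
  }
  if (inc[3]) {
    J["R3", "A3"] <- hill_dA(p$k5, p$k6, p$gamma, s[["A3"]])
    J["R3", "R3"] <- -p$mu_R3
  }
  r <- ifelse(inc, s[c("R1", "R2", "R3")], 0)
  denT <- p$k8^2 + p$delta * r[1]^2 + p$eps * r[2]^2 + p$zeta * r[3]^2
  denS <- p$k10^2 + p$eta * r[1]^2 + p$theta * r[2]^2 + p$kappa * r[3]^2
  strT <- c(p$delta, p$eps, p$zeta)
  strS <- c(p$eta, p$theta, p$kappa)
  for (i in 1:3) if (inc[i]) {
    J["T", c("R1", "R2", "R3")[i]] <- -p$k7 * p$k8^2 * 2 * strT[i] * r[i] / denT^2
    J["S", c("R1", "R2", "R3")[i]] <- -p$k9 * p$k10^2 * 2 * strS[i] * r[i] / denS^2
  }
  J["T", "T"] <- -p$mu_T
  J["S", "T"] <- p$lam
  J["S", "S"] <- -p$mu_S
  J
}

#' Nullclines of a 2-D projection of the phase plane
#'
#' For a pair (R_i, V) with V one of T or S, holding the six remaining
#' variables at fixed background values: the V-nullcline is the explicit
#' curve V(R_i) obtained by zeroing V's balance, and the R_i-nullcline is the
#' vertical line `R_i = R_i*` at the background antagomir level. Their
#' intersection is the projection of the closed-form equilibrium.
#'
#' @param params A `mirseize_params`.
#' @param pair Character length-2, e.g. `c("R1", "T")`; first element one of
#'   `R1/R2/R3`, second `T` or `S`.
#' @param background Named 8-component state supplying the fixed variables;
#'   defaults to the equilibrium at `A_const`.
#' @param A_const Background antagomir levels (used for the default
#'   background and the R_i-nullcline).
#' @param ranges List with per-variable `c(lo, hi)` plotting ranges.
#' @param n_samples Points per curve (>= 2).
#' @param se_phase Passed to [steady_state()].
#' @return List of class `mirseize_nullclines` with the two sampled curves
#'   (`var1_nullcline`, `var2_nullcline` as data frames), the background and
#'   the `intersection` point.
#' @export
nullclines_2d <- function(params, pair = c("R1", "T"), background = NULL,
                          A_const = c(0, 0, 0),
                          ranges = list(), n_samples = 201, se_phase = TRUE) {
  v1 <- pair[1]; v2 <- pair[2]
  if (!v1 %in% c("R1", "R2", "R3") || !v2 %in% c("T", "S"))
    stop("pair must combine one of R1/R2/R3 with T or S")
  if (n_samples < 2) stop("n_samples must be >= 2")
  eq <- steady_state(params, A_const = A_const, se_phase = se_phase)
  if (is.null(background)) background <- eq$state
  background <- .as_state(background)
  p <- params
  r_range <- if (!is.null(ranges[[v1]])) ranges[[v1]] else
    c(0, max(2 * eq$state[[v1]], 1))
  v_range <- if (!is.null(ranges[[v2]])) ranges[[v2]] else
    c(0, max(2 * eq$state[[v2]], 1))
  r_grid <- seq(r_range[1], r_range[2], length.out = n_samples)

  v2_of_r <- function(r) {
    st <- background
    st[[v1]] <- r
    rr <- st[c("R1", "R2", "R3")]
    if (v2 == "T") {
      (p$lam_T + p$k7 * p$k8^2 /
         (p$k8^2 + p$delta * rr[1]^2 + p$eps * rr[2]^2 + p$zeta * rr[3]^2)) / p$mu_T
    } else {
      (p$lam_S + p$lam * st[["T"]] + p$k9 * p$k10^2 /
         (p$k10^2 + p$eta * rr[1]^2 + p$theta * rr[2]^2 + p$kappa * rr[3]^2)) / p$mu_S
    }
  }
  curve_v2 <- data.frame(v1 = r_grid, v2 = vapply(r_grid, v2_of_r, numeric(1)))
  names(curve_v2) <- pair
  r_star <- eq$state[[v1]]
  curve_v1 <- data.frame(v1 = rep(r_star, n_samples),
                         v2 = seq(v_range[1], v_range[2], length.out = n_samples))
  names(curve_v1) <- pair
  intersection <- c(r_star, v2_of_r(r_star))
  names(intersection) <- pair
  structure(list(pair = pair, var1_nullcline = curve_v1,
                 var2_nullcline = curve_v2, background = background,
                 A_const = A_const, intersection = intersection),
            class = "mirseize_nullclines")
}

#' Phase-plane vector field on a 2-D grid
#'
#' Evaluates the two projected derivative components on a grid, holding the
#' remaining six variables at background values. The field vanishes at the
#' nullcline intersection.
#'
#' @param params A `mirseize_params`.
#' @param pair As in [nullclines_2d()].
#' @param background Named 8-component background state.
#' @param grid List with numeric vectors named after the two pair variables.
#' @param se_phase Evaluate with the SE source multiplier (t >= 0) if TRUE.
#' @return List with the grid and matrices `d1`, `d2` of the derivatives
#'   (rows index the first variable's grid).
#' @export
vector_field_2d <- function(params, pair = c("R1", "T"), background,
                            grid, se_phase = TRUE) {
  v1 <- pair[1]; v2 <- pair[2]
  if (!v1 %in% c("R1", "R2", "R3") || !v2 %in% c("T", "S"))
    stop("pair must combine one of R1/R2/R3 with T or S")
  g1 <- grid[[v1]]; g2 <- grid[[v2]]
  if (any(g1 < 0) || any(g2 < 0)) stop("grid must lie in the non-negative quadrant")
  background <- .as_state(background)
  tt <- if (se_phase) 0 else -1
  d1 <- matrix(0, length(g1), length(g2))
  d2 <- matrix(0, length(g1), length(g2))
  for (i in seq_along(g1)) for (j in seq_along(g2)) {
    st <- background
    st[[v1]] <- g1[i]
    st[[v2]] <- g2[j]
    d <- rhs_dimensionless(tt, st, params)
    d1[i, j] <- d[[v1]]
    d2[i, j] <- d[[v2]]
  }
  list(pair = pair, grid = list(g1, g2), d1 = d1, d2 = d2)
}
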