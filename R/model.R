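# Right-hand sides of the dimensional and dimensionless governing equations.

.as_state <- function(state) {
  s <- unlist(state)
  if (length(s) != 8) stop("state must have 8 components (A1..A3, R1..R3, T, S)")
  if (is.null(names(s)) || !all(state_names() %in% names(s))) names(s) <- state_names()
  s <- s[state_names()]
  if (any(!is.finite(s))) stop("state components must be finite")
  s
}

#' Hill-denominator inhibition functions G1..G5
#'
#' The inhibition processes are quadratic: each antagomir inhibits its target
#' miRNA through the square of its own level (`G1 = A1^2`, `G2 = A2^2`,
#' `G3 = A3^2`), and the three miRNAs jointly suppress TGF-beta and SMAD
#' through the sum of their squares (`G4 = G5 = R1^2 + R2^2 + R3^2`). Each
#' function is non-negative and strictly increasing in every argument it
#' depends on, which is what makes the antagomir -| miRNA -| TGF-beta/SMAD
#' cascade monotone.
#'
#' @param state A state vector (named or in `state_names()` order).
#' @return Named numeric vector `c(G1, G2, G3, G4, G5)`.
#' @export
inhibition_terms <- function(state) {
  s <- .as_state(state)
  if (any(s < 0)) stop("state components must be non-negative")
  rsq <- s[["R1"]]^2 + s[["R2"]]^2 + s[["R3"]]^2
  c(G1 = s[["A1"]]^2, G2 = s[["A2"]]^2, G3 = s[["A3"]]^2, G4 = rsq, G5 = rsq)
}

#' Time derivative of the dimensionless system
#'
#' Implements the dimensionless governing equations: antagomirs decay
#' first-order; each miRNA has a constant source (multiplied by
#' `se_source_multiplier` for t >= 0, the status-epilepticus induction
#' surrogate), an autocatalytic production term inhibited by its antagomir
#' through a Hill-type denominator, and first-order decay; TGF-beta and SMAD
#' have sources, miRNA-inhibited autocatalysis, decay, and SMAD is
#' additionally activated by TGF-beta at rate `lam`. miRNA branches excluded
#' by `mask` have zero derivative and contribute nothing downstream.
#'
#' @param t Time in hours (SE induction at t = 0).
#' @param state State vector in FC over control.
#' @param params A `mirseize_params` object.
#' @param mask A `mirseize_mask` selecting active miRNA branches.
#' @return Named derivative vector (per hour).
#' @export
rhs_dimensionless <- function(t, state, params, mask = mirna_mask()) {
  s <- .as_state(state)
  p <- params
  m <- if (t >= 0) p$se_source_multiplier else 1
  inc <- as.logical(mask)
  r1 <- if (inc[1]) s[["R1"]] else 0
  r2 <- if (inc[2]) s[["R2"]] else 0
  r3 <- if (inc[3]) s[["R3"]] else 0
  dA <- c(-p$mu_A1 * s[["A1"]], -p$mu_A2 * s[["A2"]], -p$mu_A3 * s[["A3"]])
  dR <- c(
    p$lam_R1 * m + p$k1 * p$k2^2 / (p$k2^2 + p$alpha * s[["A1"]]^2) - p$mu_R1 * r1,
    p$lam_R2 * m + p$k3 * p$k4^2 / (p$k4^2 + p$beta * s[["A2"]]^2) - p$mu_R2 * r2,
    p$lam_R3 * m + p$k5 * p$k6^2 / (p$k6^2 + p$gamma * s[["A3"]]^2) - p$mu_R3 * r3
  )
  dR[!inc] <- 0
  dT <- p$lam_T + p$k7 * p$k8^2 /
    (p$k8^2 + p$delta * r1^2 + p$eps * r2^2 + p$zeta * r3^2) - p$mu_T * s[["T"]]
  dS <- p$lam_S + p$lam * s[["T"]] + p$k9 * p$k10^2 /
    (p$k10^2 + p$eta * r1^2 + p$theta * r2^2 + p$kappa * r3^2) - p$mu_S * s[["S"]]
  d <- c(dA, dR, dT, dS)
  names(d) <- state_names()
  d
}

#' Time derivative of the dimensional (barred) system
#'
#' Mass balances for the eight concentrations in their original units: each
#' species has a constant source `f_*`, the antagomirs decay first-order, and
#' the autocatalytic terms `tau_i * phi_i^2 / (phi_i^2 + ups_i * G_i)` carry
#' the quadratic inhibition functions. SMAD is activated by TGF-beta at rate
#' `lambda_TGFb`.
#'
#' @param t Time in hours (unused; the dimensional system is autonomous).
#' @param state Dimensional concentration vector (A1..A3, R1..R3, T, S).
#' @param params A `mirseize_dim_params` object.
#' @return Named derivative vector.
#' @export
rhs_dimensional <- function(t, state, params) {
  s <- .as_state(state)
  p <- params
  G <- inhibition_terms(pmax(s, 0))
  if (any(s < 0)) stop("state components must be non-negative")
  d <- c(
    -p$mu_antimiR21 * s[["A1"]],
    -p$mu_antimiR142 * s[["A2"]],
    -p$mu_antimiR10 * s[["A3"]],
    p$f_miR21 + p$tau1 * p$phi1^2 / (p$phi1^2 + p$ups1 * G[["G1"]]) - p$mu_miR21 * s[["R1"]],
    p$f_miR142 + p$tau2 * p$phi2^2 / (p$phi2^2 + p$ups2 * G[["G2"]]) - p$mu_miR142 * s[["R2"]],
    p$f_miR10 + p$tau3 * p$phi3^2 / (p$phi3^2 + p$ups3 * G[["G3"]]) - p$mu_miR10 * s[["R3"]],
    p$f_TGFb + p$tau4 * p$phi4^2 / (p$phi4^2 + p$ups4 * G[["G4"]]) - p$mu_TGFb * s[["T"]],
    p$f_SMAD + p$lambda_TGFb * s[["T"]] +
      p$tau5 * p$phi5^2 / (p$phi5^2 + p$ups5 * G[["G5"]]) - p$mu_SMAD * s[["S"]]
  )
  names(d) <- state_names()
  d
}
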