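# Shared fixtures: random valid parameter sets and small simulation helpers.

random_params <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model_parameters(
    lam_R1 = runif(1, 0, 1), lam_R2 = runif(1, 0, 1), lam_R3 = runif(1, 0, 1),
    lam_T = runif(1, 0, 0.5), lam_S = runif(1, 0, 0.5),
    k1 = runif(1, 0, 1), k2 = runif(1, 0.2, 2),
    k3 = runif(1, 0, 1), k4 = runif(1, 0.2, 2),
    k5 = runif(1, 0, 1), k6 = runif(1, 0.2, 2),
    k7 = runif(1, 0, 1), k8 = runif(1, 0.2, 2),
    k9 = runif(1, 0, 1), k10 = runif(1, 0.2, 2),
    alpha = runif(1, 0, 50), beta = runif(1, 0, 50), gamma = runif(1, 0, 50),
    delta = runif(1, 0, 3), eps = runif(1, 0, 3), zeta = runif(1, 0, 3),
    eta = runif(1, 0, 3), theta = runif(1, 0, 3), kappa = runif(1, 0, 3),
    lam = runif(1, 0, 0.2),
    mu_A1 = runif(1, 0.02, 0.2), mu_A2 = runif(1, 0.02, 0.2),
    mu_A3 = runif(1, 0.02, 0.2),
    mu_R1 = runif(1, 0.1, 1), mu_R2 = runif(1, 0.1, 1), mu_R3 = runif(1, 0.1, 1),
    mu_T = runif(1, 0.05, 0.5), mu_S = runif(1, 0.05, 0.5),
    se_source_multiplier = runif(1, 1, 2)
  )
}

random_dim_params <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # the scale map carries the activation rate over unchanged, which is exact
  # only for a shared TGF-beta/SMAD scale
  ts_shared <- runif(1, 0.5, 2)
  dimensional_parameters(
    f_miR21 = runif(1, 0, 1), f_miR142 = runif(1, 0, 1), f_miR10 = runif(1, 0, 1),
    f_TGFb = runif(1, 0, 0.5), f_SMAD = runif(1, 0, 0.5),
    tau1 = runif(1, 0, 1), tau2 = runif(1, 0, 1), tau3 = runif(1, 0, 1),
    tau4 = runif(1, 0, 1), tau5 = runif(1, 0, 1),
    phi1 = runif(1, 0.2, 2), phi2 = runif(1, 0.2, 2), phi3 = runif(1, 0.2, 2),
    phi4 = runif(1, 0.2, 2), phi5 = runif(1, 0.2, 2),
    ups1 = runif(1, 0, 5), ups2 = runif(1, 0, 5), ups3 = runif(1, 0, 5),
    ups4 = runif(1, 0, 5), ups5 = runif(1, 0, 5),
    mu_antimiR21 = runif(1, 0.02, 0.2), mu_antimiR142 = runif(1, 0.02, 0.2),
    mu_antimiR10 = runif(1, 0.02, 0.2),
    mu_miR21 = runif(1, 0.1, 1), mu_miR142 = runif(1, 0.1, 1),
    mu_miR10 = runif(1, 0.1, 1),
    mu_TGFb = runif(1, 0.05, 0.5), mu_SMAD = runif(1, 0.05, 0.5),
    lambda_TGFb = runif(1, 0, 0.2),
    A1s = runif(1, 0.5, 2), A2s = runif(1, 0.5, 2), A3s = runif(1, 0.5, 2),
    R1s = runif(1, 0.5, 2), R2s = runif(1, 0.5, 2), R3s = runif(1, 0.5, 2),
    Ts = ts_shared, Ss = ts_shared
  )
}

# Ishigami benchmark and its analytic variance decomposition (derived by
# integrating the function's square over the uniform cube: the sin^2 term
# contributes a^2/8 first-order, the x3^4 sin(x1) term splits between x1's
# first-order share and the x1:x3 interaction).
ishigami <- function(X) sin(X[, 1]) + 7 * sin(X[, 2])^2 +
  0.1 * X[, 3]^4 * sin(X[, 1])

ishigami_truth <- function(a = 7, b = 0.1) {
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  S1 <- c((0.5 * (1 + b * pi^4 / 5)^2) / V, (a^2 / 8) / V, 0)
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  ST <- c(S1[1] + V13 / V, S1[2], V13 / V)
  list(S1 = S1, ST = ST)
}

random_state <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- runif(8, 0, 3)
  names(s) <- state_names()
  s
}
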