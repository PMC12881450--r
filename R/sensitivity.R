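# Extended Fourier Amplitude Sensitivity Test (eFAST).
#
# Variance-based global sensitivity: each parameter is driven along a
# space-filling search curve at its own frequency; Fourier amplitudes of the
# model output at the focal parameter's frequency (and harmonics) give the
# first-order index S1, and one minus the variance carried by the
# complementary low-frequency band gives the total-order index ST.

#' Specify an eFAST experiment
#'
#' @param parameters Character vector of parameter names to analyse
#'   (a subset of the nine inhibition strengths by default).
#' @param ranges Named list of `c(lo, hi)` per parameter; defaults to
#'   0.5x-1.5x of the calibrated nominal values.
#' @param N Samples per search curve (>= 65 so at least one harmonic set
#'   fits under the Nyquist limit).
#' @param M Interference factor: number of focal-frequency harmonics summed.
#' @param NR Number of resampling curves (independent random phase shifts).
#' @param seed Integer seed controlling the phase draws.
#' @param outputs Model outputs to record (`R1`, `R2`, `R3`, `T`, `S`).
#' @param arm `"control"` (scrambled control) or `"antagomir"` (bolus 1.0
#'   pre-injection).
#' @param eval_time Evaluation time in hours (default 24, the Western-blot
#'   analysis point).
#' @return A list of class `mirseize_efast_spec`.
#' @export
efast_spec <- function(parameters = c("alpha", "beta", "gamma", "delta", "eps",
                                      "zeta", "eta", "theta", "kappa"),
                       ranges = NULL, N = 1000, M = 4, NR = 5, seed = 1,
                       outputs = c("R1", "R2", "R3", "T", "S"),
                       arm = c("control", "antagomir"), eval_time = 24) {
  arm <- match.arg(arm)
  if (N < 65) stop("N must be >= 65")
  if (M < 1 || NR < 1) stop("M and NR must be >= 1")
  if (is.null(ranges)) {
    nom <- unlist(.default_param_values()[parameters])
    ranges <- lapply(seq_along(parameters),
                     function(i) c(0.5, 1.5) * nom[i])
    names(ranges) <- parameters
  }
  if (!all(parameters %in% names(ranges)))
    stop("ranges must cover every parameter")
  for (nm in parameters) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2])
      stop("invalid range for ", nm)
  }
  omega_max <- floor((N - 1) / (2 * M))
  if (omega_max < 1) stop("N violates the Nyquist condition for this M")
  outputs <- match.arg(outputs, several.ok = TRUE)
  structure(list(parameters = parameters, ranges = ranges, N = as.integer(N),
                 M = as.integer(M), NR = as.integer(NR), seed = as.integer(seed),
                 outputs = outputs, arm = arm, eval_time = eval_time,
                 omega_max = omega_max),
            class = "mirseize_efast_spec")
}

# Complementary-set frequencies: distinct integers spread over a low band.
# Two competing failure modes constrain the band: clustering the frequencies
# at 1, 2, 3, ... makes pairs commensurate (the search curve then fails to
# fill the complementary subspace and the variance estimate swings with the
# random phases), while pushing them up to omega_max / (2M) lets their order-M
# harmonics leak past the omega_max / 2 cutoff used for the total-order index.
# Spreading over half that bound keeps harmonics in-band with good filling.
.efast_complementary_freqs <- function(k_other, omega_max, M) {
  cmax <- max(1, floor(omega_max / (2 * M)))
  if (k_other == 0) return(integer(0))
  if (k_other > cmax) return(rep_len(seq_len(cmax), k_other))
  band <- min(cmax, max(k_other, floor(cmax / 2)))
  fr <- unique(round(seq(1, band, length.out = k_other)))
  extra <- setdiff(seq_len(cmax), fr)
  sort(c(fr, extra[seq_len(k_other - length(fr))]))
}

#' Generate the eFAST design
#'
#' For each focal parameter and each of the `NR` resampling curves, builds an
#' `N x k` matrix of parameter values along the search curve
#' `x_j(s) = lo_j + (hi_j - lo_j) (1/2 + arcsin(sin(omega_j s + phi_j)) / pi)`
#' over `N` equispaced `s` in (-pi, pi]. The focal parameter carries the
#' maximal frequency permitted by the Nyquist condition
#' `N >= 2 M omega_max + 1`; the others carry distinct low frequencies.
#' Phases are drawn from the seeded generator, so a fixed seed reproduces the
#' design exactly.
#'
#' @param spec A `mirseize_efast_spec`.
#' @return List of class `mirseize_efast_design`: per focal parameter, a list
#'   of `NR` design matrices, each with attribute `omega` (the frequency
#'   vector).
#' @export
efast_sample <- function(spec) {
  stopifnot(inherits(spec, "mirseize_efast_spec"))
  k <- length(spec$parameters)
  s <- -pi + 2 * pi * seq_len(spec$N) / spec$N
  lo <- vapply(spec$ranges[spec$parameters], `[`, numeric(1), 1)
  hi <- vapply(spec$ranges[spec$parameters], `[`, numeric(1), 2)
  comp <- .efast_complementary_freqs(k - 1, spec$omega_max, spec$M)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  design <- vector("list", k)
  names(design) <- spec$parameters
  for (i in seq_len(k)) {
    omega <- numeric(k)
    omega[i] <- spec$omega_max
    omega[-i] <- comp
    curves <- vector("list", spec$NR)
    for (r in seq_len(spec$NR)) {
      phi <- stats::runif(k, 0, 2 * pi)
      X <- matrix(NA_real_, spec$N, k, dimnames = list(NULL, spec$parameters))
      for (j in seq_len(k)) {
        u <- 0.5 + asin(sin(omega[j] * s + phi[j])) / pi
        X[, j] <- lo[j] + (hi[j] - lo[j]) * u
      }
      attr(X, "omega") <- omega
      curves[[r]] <- X
    }
    design[[i]] <- curves
  }
  structure(design, class = "mirseize_efast_design", spec = spec)
}

.Random.seed_save <- function()
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Single-curve spectral decomposition -> c(S1, ST, D_total).
.efast_single <- function(y, omega_focal, M) {
  N <- length(y)
  q <- floor((N - 1) / 2)
  amp2 <- (Mod(stats::fft(y))[2:(q + 1)] / N)^2
  D <- 2 * sum(amp2)
  if (D <= 1e-14 * max(1, mean(y)^2))
    return(c(S1 = 0, ST = 0, D = 0))
  harm <- omega_focal * seq_len(M)
  harm <- harm[harm <= q]
  Di <- 2 * sum(amp2[harm])
  cmax <- floor(omega_focal / 2)
  Dc <- 2 * sum(amp2[seq_len(min(cmax, q))])
  c(S1 = min(1, max(0, Di / D)), ST = min(1, max(0, 1 - Dc / D)), D = D)
}

#' Compute eFAST indices from model responses
#'
#' @param responses A list (one element per focal parameter, in
#'   `spec$parameters` order) of `N x NR` matrices of model outputs along the
#'   resampling curves.
#' @param spec The `mirseize_efast_spec` used to build the design.
#' @return Data frame of class `mirseize_efast_result` with one row per
#'   parameter: point estimates `S1`, `ST` (means over resampling curves),
#'   95% percentile confidence bounds `S1_lo/S1_hi/ST_lo/ST_hi`, and a
#'   `degenerate` flag (zero output variance).
#' @export
efast_indices <- function(responses, spec) {
  stopifnot(inherits(spec, "mirseize_efast_spec"))
  k <- length(spec$parameters)
  if (length(responses) != k) stop("need one response matrix per focal parameter")
  rows <- lapply(seq_len(k), function(i) {
    Y <- as.matrix(responses[[i]])
    if (nrow(Y) != spec$N || ncol(Y) != spec$NR)
      stop("response matrix must be N x NR")
    per <- t(vapply(seq_len(ncol(Y)),
                    function(r) .efast_single(Y[, r], spec$omega_max, spec$M),
                    numeric(3)))
    colnames(per) <- c("S1", "ST", "D")
    degenerate <- all(per[, "D"] == 0)
    data.frame(
      parameter = spec$parameters[i],
      S1 = mean(per[, "S1"]), ST = mean(per[, "ST"]),
      S1_lo = unname(stats::quantile(per[, "S1"], 0.025)),
      S1_hi = unname(stats::quantile(per[, "S1"], 0.975)),
      ST_lo = unname(stats::quantile(per[, "ST"], 0.025)),
      ST_hi = unname(stats::quantile(per[, "ST"], 0.975)),
      degenerate = degenerate
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mirseize_efast_result", class(out))
  out
}

#' Evaluate the model along an eFAST design
#'
#' For every design row the listed inhibition-strength parameters overwrite
#' the base set, the chosen treatment arm is simulated from t = -24 h, and
#' the requested species are recorded at `eval_time`. Uses the package's
#' fixed-step batch integrator so a full N x NR x k sweep stays affordable.
#'
#' @param spec A `mirseize_efast_spec`.
#' @param params_base Base parameter set (defaults to the calibrated set).
#' @param design Optional pre-built design from [efast_sample()].
#' @param protocol Optional protocol overriding the arm default
#'   (control arm: no antagomir; antagomir arm: bolus 1.0 at -24 h).
#' @param h Integrator step (hours).
#' @return List: per output species, the list of `N x NR` response matrices
#'   (one per focal parameter) ready for [efast_indices()].
#' @export
efast_model_response <- function(spec, params_base = model_parameters(),
                                 design = NULL, protocol = NULL, h = 0.1) {
  stopifnot(inherits(spec, "mirseize_efast_spec"))
  if (is.null(design)) design <- efast_sample(spec)
  if (is.null(protocol))
    protocol <- if (spec$arm == "antagomir")
      dosing_protocol("bolus", dose = 1.0) else dosing_protocol("control")
  k <- length(spec$parameters)
  big <- do.call(rbind, unlist(design, recursive = FALSE))
  sim <- .sim_fast(params_base, protocol, overrides = big,
                   times_out = spec$eval_time, h = h)
  out <- vector("list", length(spec$outputs))
  names(out) <- spec$outputs
  for (sp in spec$outputs) {
    vals <- sim$states[, sp, 1]
    if (any(!is.finite(vals))) stop("non-finite model response in eFAST sweep")
    per_focal <- vector("list", k)
    idx <- 0
    for (i in seq_len(k)) {
      Y <- matrix(NA_real_, spec$N, spec$NR)
      for (r in seq_len(spec$NR)) {
        Y[, r] <- vals[idx + seq_len(spec$N)]
        idx <- idx + spec$N
      }
      per_focal[[i]] <- Y
    }
    names(per_focal) <- spec$parameters
    out[[sp]] <- per_focal
  }
  out
}

#' Run a full eFAST analysis of the seizure model
#'
#' Convenience wrapper: builds the design, evaluates the model for the chosen
#' arm, and returns the indices for every requested output species.
#'
#' @inheritParams efast_model_response
#' @return Named list of `mirseize_efast_result` data frames, one per output.
#' @export
run_efast <- function(spec, params_base = model_parameters(), h = 0.1,
                      protocol = NULL) {
  design <- efast_sample(spec)
  resp <- efast_model_response(spec, params_base, design = design,
                               protocol = protocol, h = h)
  lapply(resp, efast_indices, spec = spec)
}
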