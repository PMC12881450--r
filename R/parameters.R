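# Parameter containers and the non-dimensionalisation map.

#' Names of the state-vector components
#'
#' Eight concentrations, all expressed in fold change (FC) over the untreated
#' control baseline: three antagomirs (`A1` = anti-miR-21a-5p, `A2` =
#' anti-miR-142a-5p, `A3` = anti-miR-10a-5p), three seizure-modifying miRNAs
#' (`R1` = miR-21a-5p, `R2` = miR-142a-5p, `R3` = miR-10a-5p), the TGF-beta
#' receptor-complex activity `T` and the SMAD transcriptional activity `S`.
#'
#' @return Character vector of length 8.
#' @export
state_names <- function() c("A1", "A2", "A3", "R1", "R2", "R3", "T", "S")

.param_names <- c(
  "lam_R1", "lam_R2", "lam_R3", "lam_T", "lam_S",
  paste0("k", 1:10),
  "alpha", "beta", "gamma", "delta", "eps", "zeta", "eta", "theta", "kappa",
  "lam",
  "mu_A1", "mu_A2", "mu_A3", "mu_R1", "mu_R2", "mu_R3", "mu_T", "mu_S",
  "se_source_multiplier"
)

.strength_names <- c("alpha", "beta", "gamma", "delta", "eps", "zeta",
                     "eta", "theta", "kappa")

#' Construct and validate a dimensionless model parameter set
#'
#' Holds every rate and strength of the dimensionless governing equations:
#' miRNA/TGF-beta/SMAD source rates (`lam_R1..3`, `lam_T`, `lam_S`),
#' autocatalytic production rates (odd `k1,k3,k5,k7,k9`) with their Hill-type
#' saturation constants (even `k2,k4,k6,k8,k10`), antagomir-on-miRNA
#' inhibition strengths (`alpha`, `beta`, `gamma`), miRNA-on-TGF-beta
#' strengths (`delta`, `eps`, `zeta`), miRNA-on-SMAD strengths (`eta`,
#' `theta`, `kappa`), the TGF-beta-to-SMAD activation rate `lam`, first-order
#' decay rates `mu_*` (1/hour) and the status-epilepticus source multiplier
#' `se_source_multiplier` applied to `lam_R1..3` for t >= 0.
#'
#' @param ... Named numeric overrides of the default (calibrated) values.
#' @param base Optional existing `mirseize_params` object to start from.
#' @return A named list of class `mirseize_params`.
#' @export
model_parameters <- function(..., base = NULL) {
  p <- if (is.null(base)) .default_param_values() else unclass(base)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), .param_names)
    if (length(unknown))
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- lapply(dots, as.numeric)
  }
  p <- p[.param_names]
  class(p) <- "mirseize_params"
  validate_parameters(p)
  p
}

# Calibrated nominal set: satisfies the bolus (0.6, 1.0] and infusion
# (0.125, 0.25] sustainment bounds together with the qualitative two-arm
# behavior (control arm switches to seizure after SE induction, antagomir
# bolus 1.0 arm stays anti-seizure).
.default_param_values <- function() {
  list(
    lam_R1 = 0.35, lam_R2 = 0.35, lam_R3 = 0.35, lam_T = 0.02, lam_S = 0.01,
    k1 = 0.25, k2 = 1, k3 = 0.25, k4 = 1, k5 = 0.25, k6 = 1,
    k7 = 0.82, k8 = 1, k9 = 0.536, k10 = 1,
    alpha = 60, beta = 60, gamma = 60,
    delta = 1.2, eps = 0.9, zeta = 2.4,
    eta = 0.9, theta = 0.6, kappa = 2.0,
    lam = 0.03,
    mu_A1 = log(4) / 24, mu_A2 = log(4) / 24, mu_A3 = log(4) / 24,
    mu_R1 = 0.5, mu_R2 = 0.5, mu_R3 = 0.5,
    mu_T = 0.12, mu_S = 0.12,
    se_source_multiplier = 1.5
  )
}

#' Validate a dimensionless parameter set
#'
#' Checks finiteness, strict positivity of decay rates and even-index Hill
#' constants, non-negativity of sources and inhibition strengths, and
#' `se_source_multiplier >= 1`.
#'
#' @param p A `mirseize_params` object.
#' @return Invisibly, `p` (errors on violation).
#' @export
validate_parameters <- function(p) {
  v <- unlist(p[.param_names])
  if (length(v) != length(.param_names) || any(!is.finite(v)))
    stop("parameter set must contain all ", length(.param_names),
         " finite fields")
  mus <- v[grep("^mu_", names(v))]
  if (any(mus <= 0)) stop("all decay rates mu_* must be strictly positive")
  kev <- v[c("k2", "k4", "k6", "k8", "k10")]
  if (any(kev <= 0)) stop("Hill saturation constants k2,k4,k6,k8,k10 must be strictly positive")
  nn <- v[c("lam_R1", "lam_R2", "lam_R3", "lam_T", "lam_S", "lam",
            "k1", "k3", "k5", "k7", "k9", .strength_names)]
  if (any(nn < 0)) stop("source rates, autocatalytic rates and inhibition strengths must be non-negative")
  if (v["se_source_multiplier"] < 1)
    stop("se_source_multiplier must be >= 1")
  invisible(p)
}

#' @export
print.mirseize_params <- function(x, ...) {
  cat("<mirseize_params> dimensionless model parameter set\n")
  print(unlist(unclass(x)), ...)
  invisible(x)
}

#' Construct and validate a dimensional parameter set
#'
#' The dimensional (barred) mass-balance system uses source rates `f_*`
#' (concentration/hour), autocatalytic rates `tau1..tau5`
#' (concentration/hour), Hill saturation constants `phi1..phi5`
#' (concentration), inhibition scaling coefficients `ups1..ups5`
#' (1/concentration^2), first-order decay rates `mu_*` (1/hour), the
#' TGF-beta-to-SMAD activation rate `lambda_TGFb` (1/hour) and the
#' characteristic concentration scales `A1s..Ss` used to map onto the
#' dimensionless system.
#'
#' @param ... Named numeric fields (all required unless a default exists);
#'   scales default to 1.
#' @return A named list of class `mirseize_dim_params`.
#' @export
dimensional_parameters <- function(...) {
  defaults <- list(A1s = 1, A2s = 1, A3s = 1, R1s = 1, R2s = 1, R3s = 1,
                   Ts = 1, Ss = 1)
  req <- c("f_miR21", "f_miR142", "f_miR10", "f_TGFb", "f_SMAD",
           paste0("tau", 1:5), paste0("phi", 1:5), paste0("ups", 1:5),
           "mu_antimiR21", "mu_antimiR142", "mu_antimiR10",
           "mu_miR21", "mu_miR142", "mu_miR10", "mu_TGFb", "mu_SMAD",
           "lambda_TGFb")
  dots <- list(...)
  missing <- setdiff(req, names(dots))
  if (length(missing))
    stop("missing dimensional parameter field(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(dots), c(req, names(defaults)))
  if (length(unknown))
    stop("unknown dimensional parameter field(s): ", paste(unknown, collapse = ", "))
  p <- c(lapply(dots, as.numeric),
         defaults[setdiff(names(defaults), names(dots))])
  v <- unlist(p)
  if (any(!is.finite(v))) stop("all dimensional parameter fields must be finite")
  if (any(v[grep("^mu_", names(v))] <= 0)) stop("decay rates must be strictly positive")
  if (any(v[names(defaults)] <= 0)) stop("concentration scales must be strictly positive")
  if (any(v[setdiff(names(v), c(grep("^mu_", names(v), value = TRUE), names(defaults)))] < 0))
    stop("dimensional rate/strength fields must be non-negative")
  class(p) <- "mirseize_dim_params"
  p
}

#' Map a dimensional parameter set onto the dimensionless one
#'
#' Applies the characteristic-scale substitution: each source rate is divided
#' by its species scale, autocatalytic rates by the target species scale,
#' saturation constants carry over, and each inhibition coefficient is
#' multiplied by the square of the scale of the species whose squared
#' concentration it multiplies (`alpha = ups1 * A1s^2`, ...,
#' `kappa = ups5 * R3s^2`). Decay rates and the activation rate rename
#' one-to-one; `se_source_multiplier` is set to 1 (the dimensional system
#' carries no status-epilepticus term).
#'
#' Carrying the TGF-beta-to-SMAD activation rate over unchanged is exact only
#' when the TGF-beta and SMAD characteristic scales coincide (`Ts == Ss`),
#' which the scale map implicitly assumes; a warning is issued otherwise
#' (the cross-activation term then picks up a factor `Ts/Ss` that the
#' dimensionless system does not represent).
#'
#' @param dp A `mirseize_dim_params` object.
#' @return A `mirseize_params` object.
#' @export
nondimensionalize <- function(dp) {
  stopifnot(inherits(dp, "mirseize_dim_params"))
  if (abs(dp$Ts - dp$Ss) > 1e-12 * max(dp$Ts, dp$Ss))
    warning("TGF-beta and SMAD scales differ (Ts != Ss); the activation ",
            "rate mapping is only exact for a shared scale")
  model_parameters(
    lam_R1 = dp$f_miR21 / dp$R1s, k1 = dp$tau1 / dp$R1s, k2 = dp$phi1,
    alpha = dp$ups1 * dp$A1s^2,
    lam_R2 = dp$f_miR142 / dp$R2s, k3 = dp$tau2 / dp$R2s, k4 = dp$phi2,
    beta = dp$ups2 * dp$A2s^2,
    lam_R3 = dp$f_miR10 / dp$R3s, k5 = dp$tau3 / dp$R3s, k6 = dp$phi3,
    gamma = dp$ups3 * dp$A3s^2,
    lam_T = dp$f_TGFb / dp$Ts, k7 = dp$tau4 / dp$Ts, k8 = dp$phi4,
    delta = dp$ups4 * dp$R1s^2, eps = dp$ups4 * dp$R2s^2, zeta = dp$ups4 * dp$R3s^2,
    lam_S = dp$f_SMAD / dp$Ss, k9 = dp$tau5 / dp$Ss, k10 = dp$phi5,
    lam = dp$lambda_TGFb,
    eta = dp$ups5 * dp$R1s^2, theta = dp$ups5 * dp$R2s^2, kappa = dp$ups5 * dp$R3s^2,
    mu_A1 = dp$mu_antimiR21, mu_A2 = dp$mu_antimiR142, mu_A3 = dp$mu_antimiR10,
    mu_R1 = dp$mu_miR21, mu_R2 = dp$mu_miR142, mu_R3 = dp$mu_miR10,
    mu_T = dp$mu_TGFb, mu_S = dp$mu_SMAD,
    se_source_multiplier = 1
  )
}

#' Select which miRNA branches exist in a model variant
#'
#' Structural model variants keep only a subset of the three miRNA branches,
#' to dissect the individual and pairwise contributions of miR-21a-5p,
#' miR-142a-5p and miR-10a-5p to TGF-beta/SMAD suppression. Excluded branches
#' have their state frozen at 0 and contribute nothing to the inhibition
#' denominators; the 8-component state layout is shared by all variants.
#'
#' @param include_R1,include_R2,include_R3 Logical flags.
#' @return A logical vector of class `mirseize_mask`.
#' @export
mirna_mask <- function(include_R1 = TRUE, include_R2 = TRUE, include_R3 = TRUE) {
  m <- c(R1 = isTRUE(include_R1), R2 = isTRUE(include_R2), R3 = isTRUE(include_R3))
  class(m) <- "mirseize_mask"
  m
}

#' Zero out parameters of excluded miRNA branches
#'
#' Returns a parameter set in which the source rates and the TGF-beta/SMAD
#' inhibition strengths of every excluded miRNA branch are set to zero;
#' included branches are untouched. Used to build the single- and
#' pairwise-miRNA model variants.
#'
#' @param params A `mirseize_params` object.
#' @param mask A `mirseize_mask`.
#' @return A `mirseize_params` object.
#' @export
model_variant <- function(params, mask = mirna_mask()) {
  stopifnot(inherits(params, "mirseize_params"), inherits(mask, "mirseize_mask"))
  zero <- list(
    R1 = c("lam_R1", "delta", "eta"),
    R2 = c("lam_R2", "eps", "theta"),
    R3 = c("lam_R3", "zeta", "kappa")
  )
  for (br in names(zero)) if (!mask[[br]]) params[zero[[br]]] <- 0
  validate_parameters(params)
  params
}
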