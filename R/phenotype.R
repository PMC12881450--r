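# Seizure / anti-seizure phenotype classification and critical doses.

#' Phenotypic thresholds on TGF-beta and SMAD
#'
#' The (T, S) plane is partitioned by two strictly positive thresholds:
#' the state is *anti-seizure* when both `T > th_T` and `S > th_S`, *seizure*
#' when both are strictly below, and *transitional* otherwise (including
#' exact equality on either threshold). Defaults are the calibrated values
#' shipped with the package (see [calibrate()]).
#'
#' @param th_T,th_S Threshold concentrations in FC over control.
#' @return A list of class `mirseize_thresholds`.
#' @export
phenotype_thresholds <- function(th_T = .default_thresholds()[["th_T"]],
                                 th_S = .default_thresholds()[["th_S"]]) {
  if (!is.finite(th_T) || !is.finite(th_S) || th_T <= 0 || th_S <= 0)
    stop("thresholds must be strictly positive and finite")
  structure(list(th_T = th_T, th_S = th_S), class = "mirseize_thresholds")
}

# Calibrated jointly with the default parameter set: centred between the
# chronic-phase minima of the discriminating dosing arms (see calibrate()).
.default_thresholds <- function() c(th_T = 0.935, th_S = 0.993)

.phenotype_levels <- c("seizure", "transitional", "anti_seizure")

#' Classify (T, S) pairs into phenotype labels
#'
#' @param T,S TGF-beta and SMAD levels (FC over control, non-negative);
#'   vectorized.
#' @param thresholds A `mirseize_thresholds`.
#' @return Factor with levels `seizure`, `transitional`, `anti_seizure`.
#' @export
classify_state <- function(T, S, thresholds = phenotype_thresholds()) {
  if (any(!is.finite(T)) || any(!is.finite(S)) || any(T < 0) || any(S < 0))
    stop("T and S must be finite and non-negative")
  lab <- ifelse(T > thresholds$th_T & S > thresholds$th_S, "anti_seizure",
                ifelse(T < thresholds$th_T & S < thresholds$th_S, "seizure",
                       "transitional"))
  factor(lab, levels = .phenotype_levels)
}

#' Classify a trajectory and summarise its chronic-phase phenotype
#'
#' Labels every time point and summarises the phase window (default the
#' chronic phase \[0, 24\] h): occupancy fraction of each label, the first
#' time within the window at which the trajectory is not anti-seizure
#' (`NA` if it never leaves), and whether the anti-seizure state is
#' *sustained*, i.e. holds at every grid point of the window.
#'
#' @param traj A `mirseize_trajectory`.
#' @param thresholds A `mirseize_thresholds`.
#' @param phase_window Numeric length-2 window in hours.
#' @return The trajectory with its `phenotype` slot filled and a `summary`
#'   list (`occupancy`, `first_switch_time`, `sustained_anti_seizure`).
#' @export
classify_trajectory <- function(traj, thresholds = phenotype_thresholds(),
                                phase_window = c(0, 24)) {
  stopifnot(inherits(traj, "mirseize_trajectory"))
  if (phase_window[1] >= phase_window[2]) stop("empty phase window")
  if (min(traj$times) > phase_window[1] || max(traj$times) < phase_window[2])
    stop("trajectory does not cover the phase window")
  labels <- classify_state(traj$states[, "T"], traj$states[, "S"], thresholds)
  inwin <- traj$times >= phase_window[1] & traj$times <= phase_window[2]
  wl <- labels[inwin]
  occupancy <- as.list(table(wl) / length(wl))
  not_anti <- which(wl != "anti_seizure")
  first_switch <- if (length(not_anti)) traj$times[inwin][not_anti[1]] else NA_real_
  traj$phenotype <- labels
  traj$summary <- list(
    phase_window = phase_window,
    occupancy = occupancy,
    first_switch_time = first_switch,
    sustained_anti_seizure = length(not_anti) == 0
  )
  traj
}

#' Is the anti-seizure state sustained under a given dose?
#'
#' Convenience wrapper: simulates one arm and reports whether every
#' chronic-phase grid point is anti-seizure.
#'
#' @param params A `mirseize_params`.
#' @param dose Per-antagomir dose level.
#' @param kind `"bolus"` or `"infusion"`.
#' @param thresholds A `mirseize_thresholds`.
#' @param phase_window Chronic-phase window.
#' @param ... Passed to [simulate_protocol()].
#' @return Logical.
#' @export
dose_sustains <- function(params, dose, kind = c("bolus", "infusion"),
                          thresholds = phenotype_thresholds(),
                          phase_window = c(0, 24), ...) {
  kind <- match.arg(kind)
  proto <- if (dose == 0) dosing_protocol("control") else
    dosing_protocol(kind, dose = dose)
  traj <- simulate_protocol(params, proto, t_end = phase_window[2], ...)
  classify_trajectory(traj, thresholds, phase_window)$summary$sustained_anti_seizure
}

#' Locate the critical antagomir dose by bisection
#'
#' Finds the smallest dose whose trajectory stays anti-seizure at every
#' chronic-phase grid point, assuming the sustained outcome is monotone in
#' dose. The monotonicity assumption is checked on a 9-point ladder across
#' the bracket before bisecting; the bracket endpoints must straddle the
#' outcome (`lo` not sustained, `hi` sustained).
#'
#' @param params A `mirseize_params`.
#' @param thresholds A `mirseize_thresholds`.
#' @param kind `"bolus"` or `"infusion"`.
#' @param bracket Numeric `c(lo, hi)` dose bracket.
#' @param tol Bracket width at which bisection stops (> 0).
#' @param ladder_n Number of ladder points for the monotonicity check.
#' @param ... Passed to [dose_sustains()].
#' @return List with `dose` (smallest sustaining dose found), `bracket`
#'   (final `c(lo, hi)`), and `ladder` (the checked dose/outcome table).
#' @export
critical_dose <- function(params, thresholds = phenotype_thresholds(),
                          kind = c("bolus", "infusion"),
                          bracket = c(0, 2), tol = 0.01, ladder_n = 9, ...) {
  kind <- match.arg(kind)
  if (tol <= 0) stop("tol must be > 0")
  lo <- bracket[1]; hi <- bracket[2]
  if (!(lo < hi) || lo < 0) stop("invalid bracket")
  f <- function(d) dose_sustains(params, d, kind, thresholds, ...)
  if (f(lo)) return(list(dose = lo, bracket = c(lo, lo),
                         ladder = data.frame(dose = lo, sustained = TRUE)))
  if (!f(hi)) stop("outcome at the upper bracket end is not sustained")
  ladder_d <- seq(lo, hi, length.out = ladder_n)
  ladder_s <- vapply(ladder_d, f, logical(1))
  if (is.unsorted(ladder_s))  # FALSE < TRUE: must be non-decreasing
    stop("non-monotone sustained outcome on the dose ladder: ",
         paste(sprintf("%g=%s", ladder_d, ladder_s), collapse = ", "))
  lo <- max(ladder_d[!ladder_s]); hi <- min(ladder_d[ladder_s])
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid)) hi <- mid else lo <- mid
  }
  list(dose = hi, bracket = c(lo, hi),
       ladder = data.frame(dose = ladder_d, sustained = ladder_s))
}
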