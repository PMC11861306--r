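#' Proportional controller drive
#'
#' The bidirectional activation/deactivation drive that moves motor units
#' between the resting and active pools so that developed force tracks the
#' target load: `C = L * min(TL - MA, MR)`. The drive is positive
#' (activation) while demand exceeds the active pool and resting units are
#' available, and negative (deactivation) when the active pool overshoots
#' demand.
#'
#' @param TL target load, fraction of current maximal capacity in `[0, 1]`.
#' @param MA active motor-unit fraction in `[0, 1]`.
#' @param MR resting motor-unit fraction in `[0, 1]`.
#' @param L controller gain (> 0).
#' @return Signed activation rate (1/s). Vectorized over `TL`, `MA`, `MR`.
#' @examples
#' controller_drive(TL = 1, MA = 0, MR = 1, L = 20)   # 20: step-on, rested
#' controller_drive(TL = 0, MA = 0.3, MR = 0.5, L = 20) # -6: deactivation
#' @export
controller_drive <- function(TL, MA, MR, L = 20) {
  if (any(!is.finite(TL)) || any(TL < 0) || any(TL > 1))
    stop("target load TL must lie in [0, 1]")
  if (any(MA < 0) || any(MA > 1) || any(MR < 0) || any(MR > 1))
    stop("compartment fractions MA, MR must lie in [0, 1]")
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("controller gain L must be a single positive number")
  L * pmin(TL - MA, MR)
}

#' Velocity-dependent fatigue rate coefficients
#'
#' Splits the fatigue flow out of the active pool between the peripheral and
#' central pathways as a function of joint angular velocity `V`:
#' `FP = FP0 * (1 - exp(-k*V))` and `FC = FC0 * exp(-k*V)`. At `V = 0` all
#' fatigue is central (`FP = 0`, `FC = FC0`); as `V` grows the peripheral
#' share rises towards `FP0` while the central share decays to zero.
#'
#' @param V joint angular velocity in degree/s, `>= 0` (the model is stated
#'   for concentric agonist action, so negative velocities are rejected).
#' @param params a [fatigue_parameters] object.
#' @return A list with components `FP` and `FC` (1/s), vectorized over `V`.
#' @export
fatigue_coefficients <- function(V, params) {
  stopifnot(inherits(params, "fatigue_parameters"))
  if (any(!is.finite(V)) || any(V < 0))
    stop("velocity V must be >= 0 (concentric agonist convention)")
  e <- exp(-params$k * V)
  list(FP = params$FP0 * (1 - e), FC = params$FC0 * e)
}

#' Load-dependent recovery rate coefficients
#'
#' Peripheral recovery proceeds at the constant rate `RP0` throughout.
#' Central recovery runs at the baseline `RC0` while the muscle is loaded and
#' is boosted by the rest multiplier `r` when the target load is zero
#' (`r_at_rest = TRUE`, the enhanced-recovery convention). Set
#' `r_at_rest = FALSE` to apply the multiplier under load instead, for
#' sensitivity analysis of that modelling choice.
#'
#' @param TL target load fraction in `[0, 1]`.
#' @param params a [fatigue_parameters] object.
#' @param r_at_rest logical; apply `r` when `TL == 0` (default) or when
#'   `TL > 0`.
#' @return A list with components `RP` and `RC` (1/s), vectorized over `TL`.
#' @export
recovery_coefficients <- function(TL, params, r_at_rest = TRUE) {
  stopifnot(inherits(params, "fatigue_parameters"))
  if (any(!is.finite(TL)) || any(TL < 0) || any(TL > 1))
    stop("target load TL must lie in [0, 1]")
  boosted <- if (r_at_rest) TL == 0 else TL > 0
  list(RP = rep(params$RP0, length(TL)),
       RC = ifelse(boosted, params$r * params$RC0, params$RC0))
}

#' Compartment state constructor
#'
#' A state of the four-compartment pool: fractions of all motor units that
#' are active (`MA`), resting (`MR`), peripherally fatigued (`MFP`) and
#' centrally fatigued (`MFC`). Fractions must each lie in `[0, 1]` and sum
#' to 1 within `1e-9`.
#'
#' @param MA,MR,MFP,MFC compartment fractions.
#' @return A named numeric vector of class `compartment_state`.
#' @export
compartment_state <- function(MA = 0, MR = 1, MFP = 0, MFC = 0) {
  s <- c(MA = MA, MR = MR, MFP = MFP, MFC = MFC)
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("compartment fractions must lie in [0, 1]")
  if (abs(sum(s) - 1) > 1e-9)
    stop("compartment fractions must sum to 1 (tolerance 1e-9), got ",
         format(sum(s), digits = 12))
  structure(s, class = "compartment_state")
}

#' Time derivatives of the 4CCr compartments
#'
#' Evaluates the governing equations of the four-compartment controller
#' model at one state: fatigue drains the active pool through the peripheral
#' and central pathways, recovery returns fatigued units to rest, and the
#' controller drive [controller_drive] exchanges units between rest and
#' activity. The four derivatives sum to zero — motor units are conserved.
#'
#' @param state a [compartment_state] (or named vector with `MA`, `MR`,
#'   `MFP`, `MFC`).
#' @param TL target load fraction in `[0, 1]`.
#' @param V joint angular velocity (degree/s, >= 0).
#' @param params a [fatigue_parameters] object.
#' @param r_at_rest see [recovery_coefficients].
#' @return Named numeric vector `(MA, MR, MFP, MFC)` of derivatives (1/s).
#' @export
compartment_derivatives <- function(state, TL, V, params, r_at_rest = TRUE) {
  if (!inherits(state, "compartment_state"))
    state <- compartment_state(state[["MA"]], state[["MR"]],
                               state[["MFP"]], state[["MFC"]])
  fc <- fatigue_coefficients(V, params)
  rc <- recovery_coefficients(TL, params, r_at_rest = r_at_rest)
  C <- controller_drive(TL, state[["MA"]], state[["MR"]], params$L)
  MA <- state[["MA"]]; MFP <- state[["MFP"]]; MFC <- state[["MFC"]]
  c(MA  = -fc$FP * MA - fc$FC * MA + C,
    MR  =  rc$RP * MFP + rc$RC * MFC - C,
    MFP = -rc$RP * MFP + fc$FP * MA,
    MFC = -rc$RC * MFC + fc$FC * MA)
}
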