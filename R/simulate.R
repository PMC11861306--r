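# per-segment rate coefficients for the cpp core
.segment_rates <- function(profile, params, r_at_rest = TRUE) {
  seg <- profile$segments
  fc <- fatigue_coefficients(seg$V, params)
  rc <- recovery_coefficients(seg$TL, params, r_at_rest = r_at_rest)
  list(t0 = seg$t0, t1 = seg$t1, TL = seg$TL,
       FP = fc$FP, FC = fc$FC, RP = rc$RP, RC = rc$RC)
}

# residual capacity of the 4CCr model at the requested times only
# (no full-grid recording); used heavily by the fitting objective
.rc_at_times <- function(profile, params, times, dt = 0.01, order = 4L,
                         r_at_rest = TRUE) {
  sr <- .segment_rates(profile, params, r_at_rest)
  ord <- order(times)
  out <- .integrate_ccr_cpp(sr$t0, sr$t1, sr$TL, sr$FP, sr$FC, sr$RP, sr$RC,
                            params$L, c(0, 1, 0, 0), dt, as.integer(order),
                            times[ord], FALSE)
  rc <- 1 - out$state[, 3] - out$state[, 4]
  rc[order(ord)]
}

#' Simulate the 4CCr model over a task profile
#'
#' Integrates the four-compartment equations over a piecewise-constant
#' `(TL, V)` profile with a fixed-step solver. The integration grid is the
#' union of uniform `dt` steps and the profile breakpoints, so steps never
#' straddle a discontinuity of the inputs. States are clipped to `[0, 1]`
#' and renormalized when conservation drift exceeds `1e-12`; an excursion
#' beyond `1e-6` outside `[0, 1]` aborts with a step-size diagnostic.
#'
#' The default fourth-order (RK4) method at `dt = 0.01` s resolves the
#' controller time constant `1/L = 0.05` s comfortably; the first-order
#' (Euler) method exists as an independent cross-check of the integration.
#'
#' @param profile a `task_profile` (see [intermittent_profile],
#'   [experiment_protocol]).
#' @param params a [fatigue_parameters] object.
#' @param dt integration step (s).
#' @param method `"rk4"` (default) or `"euler"`.
#' @param init initial [compartment_state]; the default is fully rested
#'   (`MR = 1`), appropriate for sessions separated by >= 48 h of rest.
#' @param r_at_rest see [recovery_coefficients].
#' @param verbose if `TRUE`, log each phase transition (label, start time,
#'   load and velocity) as a message.
#' @return An object of class `ccr_trajectory`: a data frame with columns
#'   `time`, `MA`, `MR`, `MFP`, `MFC`, `residual_capacity`
#'   (`= MA + MR = 1 - MFP - MFC`), `TL`, `V`. If the profile carries MVIC
#'   sample times, the sampled residual capacities are attached as attribute
#'   `"mvic"` (a data frame with `time`, `phase_index`, `stop_deg`,
#'   `residual_capacity`).
#' @examples
#' pars <- fatigue_parameters(FC0 = 0.00912, FP0 = 0.0145, RC0 = 0.00094,
#'                            RP0 = 1.2e-5, r = 7.5, k = 0.0086)
#' traj <- ccr_simulate(intermittent_profile(1, 0.5, 10, 6), pars)
#' tail(traj, 1)
#' @export
ccr_simulate <- function(profile, params, dt = 0.01,
                         method = c("rk4", "euler"),
                         init = compartment_state(), r_at_rest = TRUE,
                         verbose = FALSE) {
  stopifnot(inherits(profile, "task_profile"),
            inherits(params, "fatigue_parameters"))
  method <- match.arg(method)
  if (verbose) {
    t0 <- 0
    for (ph in profile$phases) {
      message(sprintf("t = %7.2f s  %-8s (TL = %g, DC = %g, CT = %g, V = %g)",
                      t0, ph$label %||% ph$kind, ph$TL, ph$DC, ph$CT,
                      ph$velocity))
      t0 <- t0 + ph$duration
    }
  }
  order <- if (method == "rk4") 4L else 1L
  sr <- .segment_rates(profile, params, r_at_rest)
  out <- .integrate_ccr_cpp(sr$t0, sr$t1, sr$TL, sr$FP, sr$FC, sr$RP, sr$RC,
                            params$L, as.numeric(init), dt, order,
                            numeric(0), TRUE)
  seg <- profile$segments
  i <- findInterval(pmin(out$time, profile$duration - 1e-12), seg$t0)
  i[i < 1L] <- 1L
  traj <- data.frame(time = out$time,
                     MA = out$state[, 1], MR = out$state[, 2],
                     MFP = out$state[, 3], MFC = out$state[, 4],
                     residual_capacity = 1 - out$state[, 3] - out$state[, 4],
                     TL = seg$TL[i], V = seg$V[i])
  class(traj) <- c("ccr_trajectory", "data.frame")
  attr(traj, "params") <- params
  attr(traj, "dt") <- dt
  attr(traj, "method") <- method
  attr(traj, "profile") <- profile
  if (!is.null(profile$mvic)) {
    mv <- profile$mvic
    mv$residual_capacity <- residual_capacity_at(traj, mv$time)
    attr(traj, "mvic") <- mv
  }
  traj
}

#' Residual capacity at arbitrary times
#'
#' Linear interpolation of `1 - MFP - MFC` on the trajectory grid; times on
#' a grid point return the grid value exactly.
#'
#' @param traj a `ccr_trajectory` (or 3-compartment reference trajectory).
#' @param times times within the simulated range (s).
#' @return Numeric vector of residual-capacity fractions.
#' @export
residual_capacity_at <- function(traj, times) {
  if (any(times < min(traj$time) - 1e-9 | times > max(traj$time) + 1e-9))
    stop("times outside the simulated range")
  approx(traj$time, traj$residual_capacity, xout = times, rule = 1)$y
}

#' Simulate the three-compartment (3CCr) reference model
#'
#' The enhanced-recovery three-compartment controller model: a single
#' fatigued pool `MF` fed from the active pool at rate `F` and recovering at
#' rate `R` (boosted by `r` at rest), with the same proportional controller.
#' The four-compartment model collapses onto this model when the velocity is
#' zero everywhere (then `FP = 0` and the peripheral pool never fills), which
#' makes this implementation the equivalence oracle for that property.
#'
#' @param profile a `task_profile`.
#' @param params3 list with elements `F` (fatigue rate, 1/s), `R` (recovery
#'   rate, 1/s), `r` (rest multiplier) and `L` (controller gain).
#' @inheritParams ccr_simulate
#' @return A data frame of class `ccr3_trajectory` with columns `time`,
#'   `MA`, `MR`, `MF`, `residual_capacity`, `TL`, `V`.
#' @export
reference_3ccr <- function(profile, params3, dt = 0.01,
                           method = c("rk4", "euler"), r_at_rest = TRUE) {
  stopifnot(inherits(profile, "task_profile"),
            all(c("F", "R", "r", "L") %in% names(params3)))
  method <- match.arg(method)
  order <- if (method == "rk4") 4L else 1L
  seg <- profile$segments
  boosted <- if (r_at_rest) seg$TL == 0 else seg$TL > 0
  Reff <- ifelse(boosted, params3$r * params3$R, params3$R)
  out <- .integrate_ccr_cpp(seg$t0, seg$t1, seg$TL,
                            rep(0, nrow(seg)), rep(params3$F, nrow(seg)),
                            rep(0, nrow(seg)), Reff,
                            params3$L, c(0, 1, 0), dt, order,
                            numeric(0), TRUE)
  i <- findInterval(pmin(out$time, profile$duration - 1e-12), seg$t0)
  i[i < 1L] <- 1L
  traj <- data.frame(time = out$time,
                     MA = out$state[, 1], MR = out$state[, 2],
                     MF = out$state[, 3],
                     residual_capacity = 1 - out$state[, 3],
                     TL = seg$TL[i], V = seg$V[i])
  class(traj) <- c("ccr3_trajectory", "data.frame")
  traj
}

#' @export
print.ccr_trajectory <- function(x, ...) {
  cat(sprintf("4CCr trajectory: %d grid points over %g s (dt = %g, %s)\n",
              nrow(x), max(x$time), attr(x, "dt"), attr(x, "method")))
  cat(sprintf("  final state: MA = %.4f MR = %.4f MFP = %.4f MFC = %.4f\n",
              x$MA[nrow(x)], x$MR[nrow(x)], x$MFP[nrow(x)], x$MFC[nrow(x)]))
  cat(sprintf("  final residual capacity: %.4f\n",
              x$residual_capacity[nrow(x)]))
  invisible(x)
}

#' Plot a simulated trajectory
#'
#' Compartment fractions and residual capacity against time, with the target
#' load shown as a light step trace.
#'
#' @param x a `ccr_trajectory`.
#' @param ... passed to [graphics::matplot].
#' @export
plot.ccr_trajectory <- function(x, ...) {
  matplot(x$time, cbind(x$MA, x$MR, x$MFP, x$MFC, x$residual_capacity),
          type = "l", lty = c(1, 1, 1, 1, 2),
          col = c("firebrick", "forestgreen", "darkorange", "purple",
                  "black"),
          xlab = "time (s)", ylab = "fraction of motor-unit pool", ...)
  lines(x$time, x$TL, col = "grey80")
  legend("topright", bty = "n", lty = c(1, 1, 1, 1, 2),
         col = c("firebrick", "forestgreen", "darkorange", "purple",
                 "black"),
         legend = c("MA", "MR", "MFP", "MFC", "residual capacity"))
  invisible(x)
}

# first MVIC time of each isometric phase (the phase "anchor"); strengths
# recovered from the data pipeline are compared to residual capacity here
.phase_anchor_times <- function(profile) {
  stopifnot(!is.null(profile$mvic))
  mv <- profile$mvic
  vapply(split(mv$time, mv$phase_index), min, 0)
}
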