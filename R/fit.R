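#' Build fitting sessions from processed strengths
#'
#' Converts rows of a processed strengths table (see
#' [process_torque_data]) into the session objects consumed by
#' [ccr_objective] and [ccr_fit]: one session per participant x muscle
#' group x velocity, carrying the five phase-normalized strengths, the
#' number of MVIC samples per phase, and the session's task profile.
#'
#' @param strengths output of [process_torque_data] (typically filtered to
#'   one muscle group).
#' @param joint a [joint_spec] or standard joint name for the sessions'
#'   protocol.
#' @return A list of sessions; each is a list with `participant`,
#'   `muscle_group`, `velocity`, `strengths` (length 5, first element 1),
#'   `n_samples`, `protocol`.
#' @export
fatigue_sessions <- function(strengths, joint) {
  joint <- .resolve_joint(joint)
  key <- interaction(strengths$participant, strengths$muscle_group,
                     strengths$velocity_deg_s, drop = TRUE)
  protocols <- list()
  lapply(split(strengths, key), function(d) {
    d <- d[order(d$phase), ]
    v <- d$velocity_deg_s[1]
    pv <- as.character(v)
    if (is.null(protocols[[pv]]))
      protocols[[pv]] <<- experiment_protocol(joint, v)
    list(participant = d$participant[1], muscle_group = d$muscle_group[1],
         velocity = v, strengths = d$strength_norm,
         n_samples = d$n_stops[1], protocol = protocols[[pv]])
  })
}

#' Least-squares misfit of candidate velocity parameters
#'
#' For a candidate triple `(k, RP0, FP0)` — the parameters that are new in
#' the four-compartment model — simulates each session's protocol under the
#' fixed central-side parameters and sums, over sessions and isometric
#' phases, the squared difference between the model's residual capacity at
#' the phase anchor (first MVIC onset) and the measured phase-normalized
#' strength, weighting each phase by its number of MVIC samples (the
#' measured strength is a constant repeated at every sample time of the
#' phase). Sessions sharing a protocol are simulated once. A candidate that
#' destabilizes the integrator is penalized with `Inf`.
#'
#' @param candidate named vector or list with `k` (s/degree), `RP0` (1/s),
#'   `FP0` (1/s).
#' @param sessions list of sessions from [fatigue_sessions].
#' @param fixed list with the zero-velocity parameters `FC0`, `RC0`, `r`
#'   and optionally `L` (default 20).
#' @param dt integration step (s).
#' @param r_at_rest see [recovery_coefficients].
#' @return Non-negative misfit (sum of weighted squared errors).
#' @export
ccr_objective <- function(candidate, sessions, fixed, dt = 0.01,
                          r_at_rest = TRUE) {
  params <- fatigue_parameters(
    FC0 = fixed$FC0, FP0 = candidate[["FP0"]], RC0 = fixed$RC0,
    RP0 = candidate[["RP0"]], r = fixed$r, k = candidate[["k"]],
    L = fixed$L %||% 20)
  keys <- vapply(sessions, function(s)
    paste(s$protocol$joint$joint %||% "custom", s$velocity), "")
  pred <- new.env(parent = emptyenv())
  total <- 0
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    if (is.null(pred[[keys[i]]])) {
      phi <- tryCatch(
        .rc_at_times(s$protocol, params, .phase_anchor_times(s$protocol),
                     dt = dt, r_at_rest = r_at_rest),
        error = function(e) NULL)
      pred[[keys[i]]] <- if (is.null(phi)) NA else phi
    }
    phi <- pred[[keys[i]]]
    if (anyNA(phi)) return(Inf)
    total <- total + s$n_samples * sum((phi - s$strengths)^2)
  }
  total
}

#' Default search bounds for the velocity parameters
#'
#' Bounds bracketing all published calibrations of `(k, RP0, FP0)` by a
#' factor of three or more on each side.
#'
#' @return A list of length-2 numeric vectors `k`, `RP0`, `FP0`.
#' @export
ccr_bounds <- function() {
  list(k = c(0, 0.1), RP0 = c(1e-7, 1e-3), FP0 = c(1e-4, 1))
}

#' Search control settings
#'
#' Settings of the seeded population-based global search used by
#' [ccr_fit]: a differential-evolution population iterated until the
#' average improvement of the best misfit over the last
#' `stall_generations` generations falls to `tolerance` (mirroring a
#' stall-based genetic-algorithm stopping rule) or `max_generations` is
#' reached, followed by a derivative-free local polish.
#'
#' @param population population size.
#' @param max_generations generation cap.
#' @param stall_generations window for the stall-based stopping rule.
#' @param tolerance average per-generation improvement below which the
#'   search stalls.
#' @param seed integer seed; equal seeds give identical fits.
#' @param de_f,de_cr differential-evolution mutation factor and crossover
#'   rate.
#' @param polish logical; run a Nelder-Mead refinement from the best
#'   population member.
#' @param dt integration step used inside the objective (s).
#' @return A list of class `ccr_control`.
#' @export
ccr_control <- function(population = 30, max_generations = 200,
                        stall_generations = 50, tolerance = 1e-12,
                        seed = 1, de_f = 0.7, de_cr = 0.9, polish = TRUE,
                        dt = 0.01) {
  stopifnot(population >= 5, max_generations >= 1, stall_generations >= 2)
  structure(list(population = population,
                 max_generations = max_generations,
                 stall_generations = stall_generations,
                 tolerance = tolerance, seed = seed, de_f = de_f,
                 de_cr = de_cr, polish = polish, dt = dt),
            class = "ccr_control")
}

# search coordinates: k linear, RP0/FP0 in log10 (they range over decades)
.to_z <- function(x, bounds)
  c(x[1], log10(x[2]), log10(x[3]))
.from_z <- function(z, bounds)
  c(k = z[1], RP0 = 10^z[2], FP0 = 10^z[3])
.z_bounds <- function(bounds)
  rbind(lo = c(bounds$k[1], log10(bounds$RP0[1]), log10(bounds$FP0[1])),
        hi = c(bounds$k[2], log10(bounds$RP0[2]), log10(bounds$FP0[2])))

#' Estimate the velocity-dependent 4CCr parameters
#'
#' Fits the three parameters introduced by the peripheral pathway — the
#' velocity coefficient `k`, the peripheral recovery rate `RP0` and the
#' peripheral fatigue rate `FP0` — to measured strength-decline sessions by
#' minimizing [ccr_objective] with a seeded differential-evolution search
#' over box bounds (rates searched on a log scale), with stall-based
#' stopping and an optional Nelder-Mead polish. Equal seeds give identical
#' results.
#'
#' Sessions at zero velocity carry no information about the peripheral
#' pathway (`FP = FP0 * (1 - exp(-k*0)) = 0`); if no session has a positive
#' velocity the fit is flagged non-identifiable with a warning.
#'
#' @param sessions list of sessions from [fatigue_sessions].
#' @param fixed list with `FC0`, `RC0`, `r` and optionally `L`; these
#'   zero-velocity constants come from a three-compartment calibration and
#'   are not estimated here.
#' @param bounds see [ccr_bounds].
#' @param control see [ccr_control].
#' @param r_at_rest see [recovery_coefficients].
#' @return An object of class `ccr_fit` with components `estimates`
#'   (named `k`, `RP0`, `FP0`), `objective`, `evaluations`, `trace`
#'   (best misfit per generation), `converged` (stall rule met),
#'   `identifiable`, `seed`, plus the inputs, fitted phase strengths and
#'   residuals. Supports `coef`, `print`, `summary`, `predict`, `plot`,
#'   `residuals` and `simulate` methods.
#' @export
ccr_fit <- function(sessions, fixed, bounds = ccr_bounds(),
                    control = ccr_control(), r_at_rest = TRUE) {
  if (length(sessions) == 0) stop("no sessions supplied")
  stopifnot(inherits(control, "ccr_control"))
  for (nm in c("k", "RP0", "FP0"))
    if (bounds[[nm]][2] <= bounds[[nm]][1])
      stop("degenerate bounds for ", nm)
  identifiable <- any(vapply(sessions, `[[`, 0, "velocity") > 0)
  if (!identifiable)
    warning("all sessions have zero velocity: FP0 and k are not ",
            "identifiable from these data")

  zb <- .z_bounds(bounds)
  nd <- 3L
  evals <- 0L
  fn <- function(z) {
    if (any(z < zb["lo", ] - 1e-12) || any(z > zb["hi", ] + 1e-12))
      return(Inf)
    evals <<- evals + 1L
    ccr_objective(.from_z(z, bounds), sessions, fixed, dt = control$dt,
                  r_at_rest = r_at_rest)
  }

  res <- .with_seed(control$seed, {
    NP <- control$population
    pop <- sapply(seq_len(nd), function(j)
      runif(NP, zb["lo", j], zb["hi", j]))
    fit <- apply(pop, 1, fn)
    trace <- numeric(0)
    converged <- FALSE
    for (gen in seq_len(control$max_generations)) {
      for (i in seq_len(NP)) {
        idx <- sample(setdiff(seq_len(NP), i), 3)
        donor <- pop[idx[1], ] +
          control$de_f * (pop[idx[2], ] - pop[idx[3], ])
        donor <- pmin(pmax(donor, zb["lo", ]), zb["hi", ])
        cross <- runif(nd) < control$de_cr
        cross[sample.int(nd, 1)] <- TRUE
        trial <- ifelse(cross, donor, pop[i, ])
        ft <- fn(trial)
        if (ft <= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- ft
        }
      }
      trace[gen] <- min(fit)
      sg <- control$stall_generations
      if (gen >= sg) {
        avg_change <- (trace[gen - sg + 1] - trace[gen]) / (sg - 1)
        if (avg_change <= control$tolerance) {
          converged <- TRUE
          break
        }
      }
    }
    zbest <- pop[which.min(fit), ]
    fbest <- min(fit)
    if (control$polish) {
      pol <- optim(zbest, fn, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-14))
      if (pol$value <= fbest) {
        zbest <- pol$par
        fbest <- pol$value
      }
    }
    list(zbest = zbest, fbest = fbest, trace = trace,
         converged = converged)
  })

  estimates <- .from_z(res$zbest, bounds)
  params <- fatigue_parameters(FC0 = fixed$FC0, FP0 = estimates[["FP0"]],
                               RC0 = fixed$RC0, RP0 = estimates[["RP0"]],
                               r = fixed$r, k = estimates[["k"]],
                               L = fixed$L %||% 20)
  fitted <- .predict_sessions(sessions, params, dt = control$dt,
                              r_at_rest = r_at_rest)
  structure(list(estimates = estimates, objective = res$fbest,
                 evaluations = evals, trace = res$trace,
                 converged = res$converged, identifiable = identifiable,
                 seed = control$seed, bounds = bounds, fixed = fixed,
                 control = control, params = params, sessions = sessions,
                 fitted = fitted, r_at_rest = r_at_rest),
            class = "ccr_fit")
}

# phase-strength predictions for a list of sessions under given parameters
.predict_sessions <- function(sessions, params, dt = 0.01,
                              r_at_rest = TRUE) {
  keys <- vapply(sessions, function(s)
    paste(s$protocol$joint$joint %||% "custom", s$velocity), "")
  cache <- new.env(parent = emptyenv())
  out <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    if (is.null(cache[[keys[i]]]))
      cache[[keys[i]]] <-
        .rc_at_times(s$protocol, params, .phase_anchor_times(s$protocol),
                     dt = dt, r_at_rest = r_at_rest)
    data.frame(participant = s$participant,
               muscle_group = s$muscle_group %||% NA_character_,
               velocity = s$velocity, phase = 1:5,
               predicted = cache[[keys[i]]], measured = s$strengths,
               n_samples = s$n_samples, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation between predicted and measured strengths
#'
#' Standard Pearson correlation for aligned series of predicted and measured
#' strengths; series must be non-constant (a constant series makes the
#' coefficient undefined, reported as `NA` with a warning).
#'
#' @param predicted,measured equal-length numeric series, length >= 3.
#' @return Correlation coefficient in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_validation <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("series must be aligned (equal length)")
  if (length(predicted) < 3) stop("need at least 3 points")
  if (sd(predicted) == 0 || sd(measured) == 0) {
    warning("constant series: correlation undefined")
    return(NA_real_)
  }
  cor(predicted, measured)
}

#' Per-session validation correlations
#'
#' For each session, expands the per-phase predicted and measured strengths
#' to one value per MVIC sample time (the measured strength is constant
#' within a phase) and computes the Pearson correlation.
#'
#' @param sessions list of sessions from [fatigue_sessions].
#' @param params a [fatigue_parameters] object to predict with.
#' @param dt integration step (s).
#' @param r_at_rest see [recovery_coefficients].
#' @return A data frame with `participant`, `muscle_group`, `velocity`, `r`.
#' @export
session_validation <- function(sessions, params, dt = 0.01,
                               r_at_rest = TRUE) {
  pred <- .predict_sessions(sessions, params, dt = dt,
                            r_at_rest = r_at_rest)
  key <- interaction(pred$participant, pred$muscle_group, pred$velocity,
                     drop = TRUE)
  out <- lapply(split(pred, key), function(d) {
    data.frame(participant = d$participant[1],
               muscle_group = d$muscle_group[1],
               velocity = d$velocity[1],
               r = pearson_validation(rep(d$predicted, d$n_samples),
                                      rep(d$measured, d$n_samples)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
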