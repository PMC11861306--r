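# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards (seed = NULL uses the current stream)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Smooth unimodal torque-angle shape
#'
#' A Gaussian bell standing in for the empirical variation of normalized
#' isometric strength over joint angle: strength peaks at `peak_angle`,
#' falls off with characteristic `width`, and stays strictly positive, so
#' the curve lies in `(0, 1]` with value 1 at the peak.
#'
#' @param angle joint angle(s) in degrees.
#' @param peak_angle angle of maximal strength (degrees).
#' @param width bell width (degrees, > 0).
#' @param rom_range optional length-2 vector; angles outside it error.
#' @return Relative torque fraction(s) in `(0, 1]`.
#' @export
torque_angle_shape <- function(angle, peak_angle, width, rom_range = NULL) {
  if (width <= 0) stop("width must be positive")
  if (!is.null(rom_range) &&
      any(angle < min(rom_range) - 1e-9 | angle > max(rom_range) + 1e-9))
    stop("angle outside the joint's range of motion")
  exp(-((angle - peak_angle) / width)^2)
}

#' Specification for synthetic dynamometer sessions
#'
#' Bundles the ground truth from which synthetic torque datasets are
#' generated: the true 4CCr parameters (shared or per direction), the joint
#' protocol, the torque-angle shape, a maximum torque amplitude, and the
#' multiplicative measurement-noise level.
#'
#' @param params a [fatigue_parameters] object used for both directions, or
#'   a named list `list(flexion = ..., extension = ...)`.
#' @param joint a [joint_spec] or standard joint name.
#' @param amplitude peak torque amplitude in N·m (scalar or named list per
#'   direction).
#' @param peak_angle,width torque-angle bell parameters (scalar or named
#'   list per direction); the bell must be strictly positive over all ROM
#'   stops (it is, being Gaussian).
#' @param sigma multiplicative measurement noise standard deviation
#'   (fraction, >= 0).
#' @param strength_sampling `"phase"` (default): measured strength within an
#'   isometric phase is the model's residual capacity at the phase's first
#'   MVIC onset, held constant over the phase's stops — the convention under
#'   which the processing pipeline recovers strengths exactly. `"stop"`
#'   samples residual capacity at each individual MVIC time instead.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(params, joint, amplitude = 100,
                           peak_angle = NULL, width = NULL, sigma = 0,
                           strength_sampling = c("phase", "stop")) {
  joint <- .resolve_joint(joint)
  strength_sampling <- match.arg(strength_sampling)
  if (sigma < 0) stop("noise sigma must be >= 0")
  per_dir <- function(x, default) {
    if (is.null(x)) x <- default
    if (!is.list(x)) x <- list(flexion = x, extension = x)
    stopifnot(all(c("flexion", "extension") %in% names(x)))
    x
  }
  mid <- (max(joint$stops) + min(joint$stops)) / 2
  span <- max(joint$stops) - min(joint$stops)
  if (inherits(params, "fatigue_parameters"))
    params <- list(flexion = params, extension = params)
  stopifnot(all(c("flexion", "extension") %in% names(params)),
            all(vapply(params, inherits, TRUE, "fatigue_parameters")))
  amplitude <- per_dir(amplitude, 100)
  peak_angle <- per_dir(peak_angle, mid)
  width <- per_dir(width, span * 0.8)
  if (any(unlist(amplitude) <= 0)) stop("amplitude must be positive")
  structure(list(params = params, joint = joint, amplitude = amplitude,
                 peak_angle = peak_angle, width = width, sigma = sigma,
                 strength_sampling = strength_sampling),
            class = "synthetic_spec")
}

#' Generate one synthetic dynamometer session
#'
#' Simulates the alternating isometric/isokinetic protocol for the spec's
#' joint at the given velocity under the true parameters, then emits the
#' long-format peak-torque records a dynamometer session would produce: for
#' each isometric phase, ROM stop and direction,
#' `peak torque = amplitude * shape(stop) * strength * (1 + eps)` with
#' `eps ~ N(0, sigma)`, where `strength` is the model's residual capacity
#' sampled according to the spec's `strength_sampling` convention.
#'
#' @param spec a [synthetic_spec].
#' @param velocity isokinetic velocity for the session (degree/s, > 0).
#' @param participant participant id string.
#' @param seed integer seed for the noise draws (the caller's RNG state is
#'   left untouched); `NULL` uses the current stream.
#' @param dt integration step (s).
#' @return A list with `data` (long-format torque data frame, see
#'   [process_torque_data]) and `truth` (anchor times, per-direction sampled
#'   residual capacities and parameters, velocity, sigma, seed).
#' @export
generate_session <- function(spec, velocity, participant = "P01",
                             seed = NULL, dt = 0.01) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (velocity <= 0) stop("session velocity must be positive")
  protocol <- experiment_protocol(spec$joint, velocity)
  mv <- protocol$mvic
  anchors <- .phase_anchor_times(protocol)
  dirs <- c("flexion", "extension")
  rc <- lapply(dirs, function(d) {
    p <- spec$params[[d]]
    if (spec$strength_sampling == "phase") {
      phi <- .rc_at_times(protocol, p, anchors, dt = dt)
      phi[mv$phase_index]
    } else {
      .rc_at_times(protocol, p, mv$time, dt = dt)
    }
  })
  names(rc) <- dirs
  rows <- .with_seed(seed, {
    out <- lapply(dirs, function(d) {
      shape <- torque_angle_shape(mv$stop_deg, spec$peak_angle[[d]],
                                  spec$width[[d]])
      eps <- rnorm(nrow(mv), 0, spec$sigma)
      data.frame(participant = participant, joint = spec$joint$joint,
                 direction = d, velocity_deg_s = velocity,
                 phase = mv$phase_index, stop_deg = mv$stop_deg,
                 peak_torque_Nm = spec$amplitude[[d]] * shape * rc[[d]] *
                   (1 + eps),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  rows <- rows[order(rows$phase, match(rows$stop_deg, spec$joint$stops),
                     rows$direction), ]
  rownames(rows) <- NULL
  phase_rc <- lapply(dirs, function(d)
    if (spec$strength_sampling == "phase")
      rc[[d]][match(1:5, mv$phase_index)]
    else .rc_at_times(protocol, spec$params[[d]], anchors, dt = dt))
  names(phase_rc) <- dirs
  list(data = rows,
       truth = list(velocity = velocity, anchor_times = anchors,
                    phase_rc = phase_rc, params = spec$params,
                    sigma = spec$sigma, seed = seed,
                    strength_sampling = spec$strength_sampling))
}

#' Generate a full-factorial synthetic study
#'
#' Emulates the complete study design: every participant performs one
#' session per joint x tested velocity, with flexors and extensors measured
#' in each session as independent muscle groups. With the four standard
#' joints this yields 8 muscle groups x 5 velocities; counting the 5
#' isometric phases as strength iterations gives 200 strength distributions,
#' and the 4 inter-phase declines give 160 fatigue-rate cells.
#'
#' @param specs list of [synthetic_spec] objects, one per joint.
#' @param participants number of synthetic participants (ids `"P01"`, ...).
#' @param seed master integer seed; per-session seeds are drawn from it, so
#'   the whole study is reproducible.
#' @param dt integration step (s).
#' @return A list with `data` (row-bound torque records of all sessions) and
#'   `truths` (per-session ground truth, named `participant.joint.velocity`).
#' @export
generate_study <- function(specs, participants = 2, seed = 1, dt = 0.01) {
  stopifnot(all(vapply(specs, inherits, TRUE, "synthetic_spec")))
  grid <- do.call(rbind, lapply(seq_along(specs), function(i)
    expand.grid(spec = i, velocity = specs[[i]]$joint$velocities,
                participant = sprintf("P%02d", seq_len(participants)))))
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1,
                                       nrow(grid)))
  sessions <- lapply(seq_len(nrow(grid)), function(j) {
    generate_session(specs[[grid$spec[j]]], grid$velocity[j],
                     participant = as.character(grid$participant[j]),
                     seed = seeds[j], dt = dt)
  })
  data <- do.call(rbind, lapply(sessions, `[[`, "data"))
  rownames(data) <- NULL
  names(sessions) <- paste(grid$participant,
                           vapply(grid$spec, function(i)
                             specs[[i]]$joint$joint, ""),
                           grid$velocity, sep = ".")
  list(data = data, truths = lapply(sessions, `[[`, "truth"))
}

#' Summarize a processed study's design cardinality
#'
#' Counts the muscle groups, velocities, strength distributions (muscle
#' group x velocity x isometric phase) and fatigue-rate cells (muscle group
#' x velocity x isokinetic iteration) present in a processed strengths
#' table.
#'
#' @param strengths output of [process_torque_data].
#' @return A list with `n_groups`, `n_velocities`,
#'   `strength_distributions`, `rate_cells`.
#' @export
study_design_summary <- function(strengths) {
  gv <- unique(strengths[, c("muscle_group", "velocity_deg_s")])
  list(n_groups = length(unique(strengths$muscle_group)),
       n_velocities = length(unique(strengths$velocity_deg_s)),
       strength_distributions =
         nrow(unique(strengths[, c("muscle_group", "velocity_deg_s",
                                   "phase")])),
       rate_cells = 4L * nrow(gv))
}
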