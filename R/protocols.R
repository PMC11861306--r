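#' Joint specification for the dynamometer protocol
#'
#' Describes the tested range of motion of a joint: the ROM span, the fixed
#' joint angles (ROM stops) at which maximal voluntary isometric contractions
#' (MVICs) are measured, and the isokinetic velocities tested.
#'
#' @param joint joint name (e.g. `"knee"`).
#' @param rom range of motion in degrees.
#' @param stops vector of 5 or 6 ROM stop angles (degrees), in measurement
#'   order; the span `max(stops) - min(stops)` must equal `rom`.
#' @param velocities vector of tested isokinetic velocities (degree/s, > 0).
#' @return An object of class `joint_spec`.
#' @export
joint_spec <- function(joint, rom, stops, velocities) {
  rom <- as.numeric(rom)
  stops <- as.numeric(stops)
  velocities <- as.numeric(velocities)
  if (!length(stops) %in% c(5L, 6L))
    stop("a joint is measured at 5 or 6 ROM stops, got ", length(stops))
  if (any(velocities <= 0)) stop("tested velocities must be positive")
  if (abs((max(stops) - min(stops)) - rom) > 1e-9)
    stop("ROM stop span (", max(stops) - min(stops),
         ") inconsistent with stated ROM (", rom, ")")
  structure(list(joint = joint, rom = rom, stops = stops,
                 velocities = velocities),
            class = "joint_spec")
}

#' Standard joint specifications
#'
#' The four joints of the alternating isometric/isokinetic dynamometer
#' protocol, with their ROM stop angles and tested isokinetic velocities.
#' Elbow and knee use 6 stops; shoulder has 5; hip has 6.
#'
#' @return A named list of [joint_spec] objects
#'   (`elbow`, `shoulder`, `hip`, `knee`).
#' @export
standard_joints <- function() {
  list(
    elbow    = joint_spec("elbow",    75,  c(15, 30, 45, 60, 75, 90),
                          c(20, 30, 45, 60, 90)),
    shoulder = joint_spec("shoulder", 120, c(60, 90, 120, 150, 180),
                          c(20, 30, 45, 60, 75)),
    hip      = joint_spec("hip",      90,  c(0, 15, 30, 60, 75, 90),
                          c(30, 45, 60, 90, 120)),
    knee     = joint_spec("knee",     75,  c(90, 75, 60, 45, 30, 15),
                          c(30, 60, 90, 120, 150))
  )
}

.resolve_joint <- function(joint) {
  if (inherits(joint, "joint_spec")) return(joint)
  std <- standard_joints()
  if (is.character(joint) && joint %in% names(std)) return(std[[joint]])
  stop("unknown joint: supply a joint_spec or one of ",
       paste(names(std), collapse = ", "))
}

#' Phase specification
#'
#' One phase of a task protocol in the `(TL, DC, CT)` coding: a target load
#' held for a duty-cycle fraction `DC` of each cycle of length `CT`, repeated
#' `n_cycles` times, at a constant joint velocity (0 for isometric phases).
#'
#' @param kind `"isometric"` or `"isokinetic"`.
#' @param TL target load fraction in `[0, 1]`.
#' @param DC duty cycle fraction in `(0, 1]`.
#' @param CT cycle time (s, > 0).
#' @param n_cycles number of cycles (>= 1); ignored if `duration` is given.
#' @param velocity joint velocity (degree/s); must be 0 exactly for
#'   isometric phases and positive for isokinetic ones.
#' @param duration optional fixed phase duration (s); complete cycles are
#'   laid down and a final partial cycle is truncated, active portion first
#'   (the dynamometer enforces fixed-length isokinetic phases).
#' @param label phase label used in profiles (e.g. `"ISOM1"`).
#' @return An object of class `phase_spec`.
#' @export
phase_spec <- function(kind = c("isometric", "isokinetic"), TL, DC, CT,
                       n_cycles = NULL, velocity = 0, duration = NULL,
                       label = NULL) {
  kind <- match.arg(kind)
  TL <- as.numeric(TL); DC <- as.numeric(DC); CT <- as.numeric(CT)
  velocity <- as.numeric(velocity)
  if (!is.null(duration)) duration <- as.numeric(duration)
  if (TL < 0 || TL > 1) stop("TL must lie in [0, 1]")
  if (DC <= 0 || DC > 1) stop("DC must lie in (0, 1]")
  if (CT <= 0) stop("CT must be positive")
  if (velocity < 0) stop("velocity must be >= 0")
  if ((velocity == 0) != (kind == "isometric"))
    stop("velocity must be 0 iff the phase is isometric")
  if (is.null(duration)) {
    if (is.null(n_cycles) || n_cycles < 1 || n_cycles != round(n_cycles))
      stop("n_cycles must be a positive integer when no duration is given")
    duration <- n_cycles * CT
  } else {
    if (duration <= 0) stop("duration must be positive")
    n_cycles <- ceiling(duration / CT)
  }
  structure(list(kind = kind, TL = TL, DC = DC, CT = CT,
                 n_cycles = as.integer(n_cycles), velocity = velocity,
                 duration = duration, label = label),
            class = "phase_spec")
}

# segments of one phase starting at t_start; active portion leads each cycle.
# Cycle boundaries are computed as t_start + i * CT (not accumulated) so that
# consecutive segments share bit-identical breakpoints.
.phase_segments <- function(ph, t_start) {
  t_end <- t_start + ph$duration
  segs <- list()
  i <- 0L
  repeat {
    cyc0 <- t_start + i * ph$CT
    if (cyc0 >= t_end - 1e-9) break
    cyc1 <- min(t_start + (i + 1L) * ph$CT, t_end)
    on_end <- if (ph$DC >= 1) cyc1 else min(cyc0 + ph$DC * ph$CT, cyc1)
    segs[[length(segs) + 1L]] <-
      data.frame(t0 = cyc0, t1 = on_end, TL = ph$TL, V = ph$velocity,
                 phase = ph$label %||% ph$kind)
    if (cyc1 > on_end + 1e-9)
      segs[[length(segs) + 1L]] <-
        data.frame(t0 = on_end, t1 = cyc1, TL = 0, V = ph$velocity,
                   phase = ph$label %||% ph$kind)
    i <- i + 1L
  }
  do.call(rbind, segs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.new_task_profile <- function(phases, mvic = NULL, joint = NULL,
                              velocity = NULL) {
  t <- 0
  segs <- vector("list", length(phases))
  for (i in seq_along(phases)) {
    segs[[i]] <- .phase_segments(phases[[i]], t)
    t <- t + phases[[i]]$duration
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  structure(list(segments = segments, duration = t, phases = phases,
                 mvic = mvic, joint = joint, velocity = velocity),
            class = "task_profile")
}

#' Intermittent task profile
#'
#' Builds a piecewise-constant task profile from the `(TL, DC, CT)` coding:
#' each cycle is active (load `TL`, velocity `velocity`) for `DC * CT`
#' seconds, then at rest (`TL = 0`) for the remainder of the cycle. The
#' active portion leads each cycle. The velocity is held at the nominal
#' value for the whole phase (rest half-cycles included); for isokinetic
#' phases the exertion alternation is carried by `TL`, not by `V`.
#'
#' @inheritParams phase_spec
#' @return A `task_profile` object with fields `segments`
#'   (data frame `t0, t1, TL, V, phase`), `duration`, and the generating
#'   `phases`.
#' @examples
#' p <- intermittent_profile(TL = 1, DC = 0.2, CT = 15, n_cycles = 6)
#' p$duration  # 90 s
#' @export
intermittent_profile <- function(TL, DC, CT, n_cycles = NULL, velocity = 0,
                                 duration = NULL, label = NULL) {
  kind <- if (velocity == 0) "isometric" else "isokinetic"
  ph <- phase_spec(kind, TL = TL, DC = DC, CT = CT, n_cycles = n_cycles,
                   velocity = velocity, duration = duration,
                   label = label %||% toupper(kind))
  .new_task_profile(list(ph))
}

#' Build a task profile from a list of phase specifications
#'
#' @param phases list of [phase_spec] objects, executed back to back from
#'   time 0.
#' @return A `task_profile`.
#' @export
build_task_profile <- function(phases) {
  stopifnot(length(phases) >= 1, all(vapply(phases, inherits, TRUE,
                                            "phase_spec")))
  .new_task_profile(phases)
}

#' The alternating isometric/isokinetic experimental protocol
#'
#' Encodes one dynamometer test session as a task profile: five isometric
#' measurement phases (`ISOM1` .. `ISOM5`) alternate with four one-minute
#' isokinetic fatiguing phases (`ISOK1` .. `ISOK4`). Each isometric phase is
#' coded `(TL, DC, CT) = (1, 0.2, 15 s)` with one cycle per ROM stop (a 3 s
#' MVIC followed by 12 s of repositioning rest); each isokinetic phase is
#' coded `(1, 0.5, 2 * ROM / velocity)` and lasts 60 s, with any partial
#' final cycle truncated. MVIC sample times — the onset of each isometric
#' active cycle, when a stop's MVIC begins — are recorded together with the
#' stop angles. For a 6-stop joint the session lasts
#' `5 * 90 + 4 * 60 = 690` s.
#'
#' @param joint a [joint_spec] or a standard joint name (see
#'   [standard_joints]).
#' @param velocity isokinetic phase velocity (degree/s). A velocity outside
#'   the joint's tested set triggers a warning (the model extrapolates), not
#'   an error.
#' @return A `task_profile` whose `mvic` field is a data frame with columns
#'   `time`, `phase_index` (1..5), `label`, `stop_index`, `stop_deg`.
#' @examples
#' pr <- experiment_protocol("knee", 90)
#' pr$duration  # 690
#' @export
experiment_protocol <- function(joint, velocity) {
  joint <- .resolve_joint(joint)
  if (velocity <= 0) stop("isokinetic velocity must be positive")
  if (!velocity %in% joint$velocities)
    warning(sprintf("velocity %g not among tested velocities for the %s (%s)",
                    velocity, joint$joint,
                    paste(joint$velocities, collapse = ", ")))
  n_stops <- length(joint$stops)
  ct_isok <- 2 * joint$rom / velocity
  phases <- list()
  mvic <- list()
  t <- 0
  for (p in 1:5) {
    lab <- paste0("ISOM", p)
    phases[[length(phases) + 1L]] <-
      phase_spec("isometric", TL = 1, DC = 0.2, CT = 15, n_cycles = n_stops,
                 label = lab)
    mvic[[p]] <- data.frame(time = t + (seq_len(n_stops) - 1) * 15,
                            phase_index = p, label = lab,
                            stop_index = seq_len(n_stops),
                            stop_deg = joint$stops)
    t <- t + n_stops * 15
    if (p < 5) {
      phases[[length(phases) + 1L]] <-
        phase_spec("isokinetic", TL = 1, DC = 0.5, CT = ct_isok,
                   velocity = velocity, duration = 60,
                   label = paste0("ISOK", p))
      t <- t + 60
    }
  }
  .new_task_profile(phases, mvic = do.call(rbind, mvic), joint = joint,
                    velocity = velocity)
}

#' @export
print.task_profile <- function(x, ...) {
  cat(sprintf("task profile: %d phase(s), %d segments, duration %g s\n",
              length(x$phases), nrow(x$segments), x$duration))
  labs <- vapply(x$phases, function(p) p$label %||% p$kind, "")
  cat("  phases:", paste(labs, collapse = " "), "\n")
  if (!is.null(x$mvic))
    cat(sprintf("  %d MVIC sample times\n", nrow(x$mvic)))
  invisible(x)
}

#' Evaluate a task profile at given times
#'
#' @param profile a `task_profile`.
#' @param t times in `[0, duration]`; values on a segment boundary take the
#'   right-hand (incoming) segment, the profile being right-continuous.
#' @return A data frame with columns `t`, `TL`, `V`.
#' @export
profile_value <- function(profile, t) {
  stopifnot(inherits(profile, "task_profile"))
  if (any(t < 0 | t > profile$duration + 1e-9))
    stop("times outside [0, duration]")
  i <- findInterval(pmin(t, profile$duration - 1e-12), profile$segments$t0)
  i[i < 1L] <- 1L
  data.frame(t = t, TL = profile$segments$TL[i], V = profile$segments$V[i])
}

#' Write / read a task profile as a phase-list JSON config
#'
#' The profile is serialized as its generating phase list (plus joint
#' metadata when present) and rebuilt on read, so a round trip reproduces
#' identical breakpoints.
#'
#' @param profile a `task_profile`.
#' @param path output path (`.json`).
#' @return `write_task_profile` returns `path` invisibly;
#'   `read_task_profile` returns a `task_profile`.
#' @export
write_task_profile <- function(profile, path) {
  stopifnot(inherits(profile, "task_profile"))
  ph <- lapply(profile$phases, function(p)
    p[c("kind", "TL", "DC", "CT", "n_cycles", "velocity", "duration",
        "label")])
  obj <- list(phases = ph)
  if (!is.null(profile$joint))
    obj$joint <- profile$joint[c("joint", "rom", "stops", "velocities")]
  obj$velocity <- profile$velocity
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_task_profile
#' @export
read_task_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!is.null(obj$joint) && !is.null(obj$velocity)) {
    js <- joint_spec(obj$joint$joint, obj$joint$rom,
                     unlist(obj$joint$stops), unlist(obj$joint$velocities))
    return(experiment_protocol(js, obj$velocity))
  }
  phases <- lapply(obj$phases, function(p)
    phase_spec(p$kind, TL = p$TL, DC = p$DC, CT = p$CT,
               n_cycles = p$n_cycles, velocity = p$velocity,
               duration = p$duration, label = p$label))
  build_task_profile(phases)
}
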