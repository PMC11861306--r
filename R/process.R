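#' Normalize one isometric phase's peak torques
#'
#' Divides the peak MVIC torques measured at each ROM stop of one isometric
#' phase by the maximum across all stops in that phase, yielding the phase's
#' normalized torque-angle curve (values in `(0, 1]`, maximum exactly 1).
#'
#' @param torques positive peak torques (N·m), one per ROM stop, >= 2 stops.
#' @return Normalized values.
#' @examples
#' normalize_phase(c(40, 50, 45, 35, 30, 25))
#' @export
normalize_phase <- function(torques) {
  if (length(torques) < 2) stop("need at least 2 ROM stops")
  if (any(!is.finite(torques)) || any(torques <= 0))
    stop("peak torques must be positive (flag and exclude sensor artifacts ",
         "before normalization)")
  torques / max(torques)
}

#' Average normalized phase curves into a subject curve
#'
#' Each test session yields five normalized torque-angle curves (one per
#' isometric phase) over a common set of ROM stops; their per-stop arithmetic
#' mean is the subject's normalized torque-angle curve for that session.
#'
#' @param curves a matrix (phases x stops) or list of equal-length numeric
#'   vectors of normalized torques.
#' @return Per-stop mean curve, values in `(0, 1]`.
#' @export
subject_curve <- function(curves) {
  if (is.list(curves)) {
    if (length(unique(lengths(curves))) != 1)
      stop("phase curves have mismatched stop sets")
    curves <- do.call(rbind, curves)
  }
  if (any(curves <= 0) || any(curves > 1 + 1e-12))
    stop("curves must be normalized to (0, 1]")
  colMeans(curves)
}

#' Representative strength scale for one isometric phase
#'
#' Scales the subject's normalized torque-angle curve to fit a simple
#' majority of the phase's raw peak torques: of the `n` ROM stops, every
#' subset of `m = ceiling((n + 1) / 2)` points is evaluated with the
#' closed-form least-squares scale
#' `s = sum(y_i * c_i) / sum(c_i^2)` over the subset, and the scale of the
#' subset with the smallest summed squared residuals is returned. Using a
#' majority subset makes the representative strength robust to individual
#' submaximal or artifactual MVICs. Ties are broken deterministically in
#' favour of the lexicographically lowest stop-index subset; subsets on
#' which the curve is identically zero are excluded.
#'
#' @param curve normalized torque-angle curve (length `n >= 3`).
#' @param raw_phase raw peak torques of one phase over the same `n` stops.
#' @return A list with `scale` (N·m), `subset` (chosen stop indices) and
#'   `ssr` (summed squared residuals on the subset).
#' @examples
#' cv <- c(0.8, 1, 0.9, 0.7, 0.6, 0.5)
#' representative_scale(cv, 55 * cv)$scale  # 55, exactly proportional
#' @export
representative_scale <- function(curve, raw_phase) {
  n <- length(curve)
  if (n < 3) stop("need at least 3 ROM stops")
  if (length(raw_phase) != n)
    stop("curve and raw phase must cover the same stops")
  m <- ceiling((n + 1) / 2)
  subsets <- combn(n, m)
  nsub <- ncol(subsets)
  scales <- rep(NA_real_, nsub)
  ssrs <- rep(Inf, nsub)
  for (j in seq_len(nsub)) {
    S <- subsets[, j]
    cs <- curve[S]; ys <- raw_phase[S]
    denom <- sum(cs^2)
    if (denom == 0) next
    scales[j] <- sum(ys * cs) / denom
    ssrs[j] <- sum((ys - scales[j] * cs)^2)
  }
  if (!any(is.finite(ssrs)))
    stop("curve degenerate (zero on every candidate subset)")
  # ties (within rounding of the torques' scale) break to the first, i.e.
  # lexicographically lowest, subset
  tol <- 1e-10 * sum(raw_phase^2)
  j <- which(ssrs <= min(ssrs) + tol)[1]
  list(scale = scales[j], subset = subsets[, j], ssr = ssrs[j])
}

#' Per-iteration fatigue rates from a strength series
#'
#' The drop between consecutive isometric phases' representative scales
#' measures the strength lost during the intervening isokinetic bout
#' (recovery within the short isometric phases being treated as negligible).
#' Scales are first normalized by the first phase's scale so rates read as
#' percent of session-baseline MVIC per minute of isokinetic activity.
#'
#' @param scales the 5 representative scale factors, phases 1..5.
#' @param isok_minutes duration of each isokinetic bout in minutes
#'   (default 1).
#' @return 4 declines in %MVC/min (negative values — gains — are preserved).
#' @examples
#' fatigue_rates(c(1.0, 0.9, 0.85, 0.82, 0.80))  # 10 5 3 2
#' @export
fatigue_rates <- function(scales, isok_minutes = 1) {
  if (length(scales) != 5) stop("expected 5 phase scales")
  s <- scales / scales[1]
  100 * (s[-5] - s[-1]) / isok_minutes
}

.required_cols <- c("participant", "joint", "direction", "velocity_deg_s",
                    "phase", "stop_deg", "peak_torque_Nm")

#' Validate a long-format torque dataset
#'
#' Checks the schema of a peak-torque table (columns `participant`, `joint`,
#' `direction`, `velocity_deg_s`, `phase`, `stop_deg`, `peak_torque_Nm`),
#' that every session has exactly 5 isometric phases over a common stop set,
#' and that torques are positive. Non-positive torques are sensor artifacts:
#' they are dropped with a warning naming the offending rows
#' (`on_invalid = "exclude"`) or raise an error (`on_invalid = "error"`).
#'
#' @param data a data frame in long format.
#' @param on_invalid `"exclude"` or `"error"`.
#' @return The validated (possibly row-filtered) data frame.
#' @export
validate_torque_data <- function(data, on_invalid = c("exclude", "error")) {
  on_invalid <- match.arg(on_invalid)
  missing <- setdiff(.required_cols, names(data))
  if (length(missing))
    stop("torque data missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(data$peak_torque_Nm) | data$peak_torque_Nm <= 0)
  if (length(bad)) {
    msg <- paste0("non-positive peak torque in row(s) ",
                  paste(bad, collapse = ", "))
    if (on_invalid == "error") stop(msg)
    # drop the affected stop from every phase of its session so the
    # session keeps a common stop set across phases
    drop <- rep(FALSE, nrow(data))
    for (b in bad)
      drop <- drop | (data$participant == data$participant[b] &
                      data$joint == data$joint[b] &
                      data$direction == data$direction[b] &
                      data$velocity_deg_s == data$velocity_deg_s[b] &
                      data$stop_deg == data$stop_deg[b])
    warning(msg, "; the affected stop(s) excluded from their session(s)")
    data <- data[!drop, , drop = FALSE]
  }
  key <- interaction(data$participant, data$joint, data$direction,
                     data$velocity_deg_s, drop = TRUE)
  for (k in levels(key)) {
    d <- data[key == k, ]
    if (!setequal(unique(d$phase), 1:5))
      stop("session ", k, " does not have exactly phases 1..5")
    stops_by_phase <- lapply(split(d$stop_deg, d$phase), sort)
    if (length(unique(stops_by_phase)) != 1)
      stop("session ", k, " has inconsistent stop sets across phases")
  }
  data
}

#' Process a torque dataset into per-phase representative strengths
#'
#' Runs the full strength-extraction pipeline for every session (participant
#' x joint x direction x velocity): per-phase normalization
#' ([normalize_phase]), five-curve averaging ([subject_curve]) and
#' combinatorial least-squares scaling ([representative_scale]).
#'
#' @inheritParams validate_torque_data
#' @return A data frame with one row per session x phase: `participant`,
#'   `joint`, `direction`, `muscle_group`, `velocity_deg_s`, `phase`,
#'   `scale` (N·m), `strength_norm` (scale relative to phase 1), `ssr`,
#'   `subset` (chosen stop indices, comma-separated), `n_stops`.
#' @export
process_torque_data <- function(data, on_invalid = c("exclude", "error")) {
  data <- validate_torque_data(data, on_invalid)
  key <- interaction(data$participant, data$joint, data$direction,
                     data$velocity_deg_s, drop = TRUE)
  out <- lapply(split(data, key), function(d) {
    stops <- unique(d$stop_deg[d$phase == 1])
    raw <- sapply(1:5, function(p) {
      dp <- d[d$phase == p, ]
      dp$peak_torque_Nm[match(stops, dp$stop_deg)]
    })  # stops x phases
    norm <- apply(raw, 2, normalize_phase)
    curve <- subject_curve(t(norm))
    fits <- lapply(1:5, function(p) representative_scale(curve, raw[, p]))
    scales <- vapply(fits, `[[`, 0, "scale")
    data.frame(
      participant = d$participant[1], joint = d$joint[1],
      direction = d$direction[1],
      muscle_group = paste(d$joint[1],
                           ifelse(d$direction[1] == "flexion",
                                  "flexors", "extensors")),
      velocity_deg_s = d$velocity_deg_s[1], phase = 1:5,
      scale = scales, strength_norm = scales / scales[1],
      ssr = vapply(fits, `[[`, 0, "ssr"),
      subset = vapply(fits, function(f)
        paste(f$subset, collapse = ","), ""),
      n_stops = length(stops), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-session fatigue rates in long format
#'
#' @param strengths output of [process_torque_data].
#' @param isok_minutes see [fatigue_rates].
#' @return A data frame with one row per session x iteration (`iteration`
#'   1..4 labels the isokinetic bout between phases `iteration` and
#'   `iteration + 1`) and column `rate` in %MVC/min.
#' @export
session_fatigue_rates <- function(strengths, isok_minutes = 1) {
  key <- interaction(strengths$participant, strengths$muscle_group,
                     strengths$velocity_deg_s, drop = TRUE)
  out <- lapply(split(strengths, key), function(d) {
    d <- d[order(d$phase), ]
    data.frame(participant = d$participant[1],
               muscle_group = d$muscle_group[1],
               joint = d$joint[1], direction = d$direction[1],
               velocity_deg_s = d$velocity_deg_s[1], iteration = 1:4,
               rate = fatigue_rates(d$scale, isok_minutes),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-level fatigue-rate table
#'
#' Averages per-session fatigue rates across participants within each
#' muscle group x velocity x iteration cell.
#'
#' @param rates output of [session_fatigue_rates].
#' @return A data frame with `muscle_group`, `velocity_deg_s`, `iteration`,
#'   `mean_rate`, `sd_rate`, `n`.
#' @export
fatigue_rate_table <- function(rates) {
  agg <- aggregate(rate ~ muscle_group + velocity_deg_s + iteration,
                   data = rates,
                   FUN = function(x) c(mean = mean(x), sd = sd(x),
                                       n = length(x)))
  out <- data.frame(muscle_group = agg$muscle_group,
                    velocity_deg_s = agg$velocity_deg_s,
                    iteration = agg$iteration,
                    mean_rate = agg$rate[, "mean"],
                    sd_rate = agg$rate[, "sd"], n = agg$rate[, "n"],
                    stringsAsFactors = FALSE)
  out[order(out$muscle_group, out$velocity_deg_s, out$iteration), ]
}

#' Simple linear regression of fatigue rate on velocity
#'
#' Ordinary least squares of mean fatigue rate against isokinetic velocity
#' for one muscle group x iteration, with a t-based 95% confidence interval
#' and two-sided p-value for the slope. The slope's units are
#' %MVC·s/(degree·min): change in normalized fatigue rate per unit change in
#' angular velocity.
#'
#' @param rates data frame with columns `velocity_deg_s` and `mean_rate`
#'   (or `rate`) at >= 3 distinct velocities.
#' @return A list with `slope`, `intercept`, `ci` (length-2), `p_value`,
#'   `n`, and the underlying `lm` fit.
#' @export
velocity_regression <- function(rates) {
  y <- if ("mean_rate" %in% names(rates)) rates$mean_rate else rates$rate
  v <- rates$velocity_deg_s
  if (length(unique(v)) < 3)
    stop("need at least 3 distinct velocities for a regression")
  fit <- lm(y ~ v)
  # a perfect fit triggers a benign precision warning in summary/confint
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(unname(confint(fit)["v", ]))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       ci = ci,
       p_value = unname(sm$coefficients["v", "Pr(>|t|)"]),
       n = length(y), fit = fit)
}

#' Velocity-regression table across muscle groups and iterations
#'
#' Applies [velocity_regression] within every muscle group x iteration cell
#' of a group-level fatigue-rate table.
#'
#' @param rate_table output of [fatigue_rate_table].
#' @return A data frame with one row per muscle group x iteration:
#'   `slope`, `ci_low`, `ci_high`, `p_value`, `n_velocities`.
#' @export
velocity_regression_table <- function(rate_table) {
  key <- interaction(rate_table$muscle_group, rate_table$iteration,
                     drop = TRUE)
  out <- lapply(split(rate_table, key), function(d) {
    vr <- velocity_regression(d)
    data.frame(muscle_group = d$muscle_group[1], iteration = d$iteration[1],
               slope = vr$slope, ci_low = vr$ci[1], ci_high = vr$ci[2],
               p_value = vr$p_value, n_velocities = vr$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$muscle_group, res$iteration), ]
}
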