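#' @export
print.ccr_fit <- function(x, ...) {
  cat("4CCr velocity-parameter fit\n")
  cat(sprintf("  k   = %.5g s/deg\n  RP0 = %.5g 1/s\n  FP0 = %.5g 1/s\n",
              x$estimates[["k"]], x$estimates[["RP0"]],
              x$estimates[["FP0"]]))
  cat(sprintf("  objective %.6g after %d evaluations (%s, seed %d)\n",
              x$objective, x$evaluations,
              if (x$converged) "stall rule met" else "generation cap",
              x$seed))
  if (!x$identifiable)
    cat("  WARNING: zero-velocity sessions only; k, FP0 not identifiable\n")
  invisible(x)
}

#' @export
coef.ccr_fit <- function(object, ...) object$estimates

#' @export
summary.ccr_fit <- function(object, ...) {
  res <- residuals(object)
  val <- session_validation(object$sessions, object$params,
                            dt = object$control$dt,
                            r_at_rest = object$r_at_rest)
  structure(list(fit = object, rmse = sqrt(mean(res^2)),
                 validation = val,
                 n_sessions = length(object$sessions),
                 velocities = sort(unique(vapply(object$sessions, `[[`,
                                                 0, "velocity")))),
            class = "summary.ccr_fit")
}

#' @export
print.summary.ccr_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d session(s) at velocities %s deg/s\n", x$n_sessions,
              paste(x$velocities, collapse = ", ")))
  cat(sprintf("  phase-strength RMSE %.4g\n", x$rmse))
  cat(sprintf("  Pearson r: median %.4f (range %.4f..%.4f)\n",
              median(x$validation$r), min(x$validation$r),
              max(x$validation$r)))
  invisible(x)
}

#' Predict phase strengths or trajectories from a fit
#'
#' @param object a `ccr_fit`.
#' @param newdata optional list of sessions (see [fatigue_sessions]);
#'   defaults to the fitted sessions.
#' @param type `"strength"` for per-phase strength predictions,
#'   `"trajectory"` for full residual-capacity trajectories (one per unique
#'   protocol).
#' @param ... unused.
#' @export
predict.ccr_fit <- function(object, newdata = NULL,
                            type = c("strength", "trajectory"), ...) {
  type <- match.arg(type)
  sessions <- newdata %||% object$sessions
  if (type == "strength")
    return(.predict_sessions(sessions, object$params,
                             dt = object$control$dt,
                             r_at_rest = object$r_at_rest))
  keys <- unique(vapply(sessions, function(s)
    paste(s$protocol$joint$joint %||% "custom", s$velocity), ""))
  prots <- sessions[match(keys, vapply(sessions, function(s)
    paste(s$protocol$joint$joint %||% "custom", s$velocity), ""))]
  setNames(lapply(prots, function(s)
    ccr_simulate(s$protocol, object$params, dt = object$control$dt,
                 r_at_rest = object$r_at_rest)), keys)
}

#' @export
residuals.ccr_fit <- function(object, ...) {
  object$fitted$measured - object$fitted$predicted
}

#' @export
fitted.ccr_fit <- function(object, ...) object$fitted$predicted

#' Diagnostic plots for a fit
#'
#' Left: best misfit per search generation (log scale). Right: measured
#' against predicted phase strengths with the identity line.
#'
#' @param x a `ccr_fit`.
#' @param ... unused.
#' @export
plot.ccr_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(seq_along(x$trace), pmax(x$trace, .Machine$double.xmin),
       type = "l", log = "y", xlab = "generation", ylab = "best misfit")
  plot(x$fitted$predicted, x$fitted$measured,
       xlab = "predicted strength", ylab = "measured strength",
       col = factor(x$fitted$velocity))
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate strength series from a fitted model
#'
#' Regenerates per-phase strength observations for the fitted sessions:
#' model-predicted phase strengths perturbed by multiplicative Gaussian
#' noise whose standard deviation is estimated from the fit residuals.
#'
#' @param object a `ccr_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed (caller's RNG state is preserved).
#' @param ... unused.
#' @return A list of `nsim` data frames shaped like `object$fitted` with a
#'   simulated `measured` column.
#' @export
simulate.ccr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  base <- object$fitted
  sdn <- sd(residuals(object) / base$predicted)
  if (!is.finite(sdn)) sdn <- 0
  .with_seed(seed, lapply(seq_len(nsim), function(i) {
    out <- base
    out$measured <- base$predicted * (1 + rnorm(nrow(base), 0, sdn))
    out
  }))
}
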