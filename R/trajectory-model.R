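# Logistic remission-curve model for per-session VAS pain trajectories.
#
# A patient's pain during a course of physiotherapy is modelled as a
# decreasing logistic curve between two asymptotes: the upper asymptote K is
# anchored 1.2 VAS points (one minimal clinically significant difference)
# above the first pain rating, and the lower asymptote defaults to 0 (no
# pain).  The two free parameters a (onset location) and b (descent rate)
# are estimated per patient by bounded least squares.

#' Construct a VAS trajectory
#'
#' Bundles one patient's session-indexed visual analogue scale (VAS) pain
#' ratings. Sessions are the treatment time points (1, 2, ..., 10 in a full
#' ten-session course); ratings are on the 0--10 VAS.
#'
#' @param patient_id Identifier (coerced to character).
#' @param sessions Integer vector of session indices, strictly increasing,
#'   length at least 2.
#' @param vas Numeric vector of VAS scores in `[0, 10]`, same length as
#'   `sessions`.
#' @return An object of class `"vas_trajectory"`: a list with elements
#'   `patient_id`, `sessions` and `vas`.
#' @examples
#' vas_trajectory("p1", 1:10, c(7, 6.8, 6.1, 5, 3.6, 2.4, 1.7, 1.2, 1, 0.9))
#' @export
vas_trajectory <- function(patient_id, sessions, vas) {
  sessions <- as.numeric(sessions)
  vas <- as.numeric(vas)
  if (length(sessions) != length(vas)) {
    stop("`sessions` and `vas` must have the same length", call. = FALSE)
  }
  if (length(sessions) < 2L) {
    stop("a trajectory needs at least 2 measurements", call. = FALSE)
  }
  if (anyNA(sessions) || anyNA(vas)) {
    stop("missing values in trajectory", call. = FALSE)
  }
  if (any(diff(sessions) <= 0)) {
    stop("`sessions` must be strictly increasing", call. = FALSE)
  }
  if (any(vas < 0 | vas > 10)) {
    stop("VAS scores must lie in [0, 10]", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id)[1L],
         sessions = sessions, vas = vas),
    class = "vas_trajectory"
  )
}

#' @export
print.vas_trajectory <- function(x, ...) {
  cat("VAS trajectory for patient", x$patient_id, "-",
      length(x$sessions), "sessions\n")
  print(stats::setNames(x$vas, x$sessions))
  invisible(x)
}

#' Upper asymptote of the remission curve
#'
#' The upper asymptote K of the logistic remission curve is placed one
#' minimal clinically significant difference (1.2 VAS points) above the
#' first pain rating, capped at the top of the scale: K = vas1 + 1.2 when
#' vas1 < 8.8, and K = 10 otherwise.
#'
#' @param vas1 First-session VAS score(s) in `[0, 10]`; vectorised.
#' @param mcsd Minimal clinically significant difference in VAS points
#'   (default 1.2).
#' @return The upper asymptote(s) K, never exceeding 10.
#' @examples
#' compute_upper_asymptote(5.0) # 6.2
#' compute_upper_asymptote(9.5) # 10
#' @export
compute_upper_asymptote <- function(vas1, mcsd = 1.2) {
  if (anyNA(vas1) || any(vas1 < 0 | vas1 > 10)) {
    stop("first VAS score must lie in [0, 10]", call. = FALSE)
  }
  ifelse(vas1 >= 10 - mcsd, 10, vas1 + mcsd)
}

#' Decreasing logistic remission curve
#'
#' Evaluates `lower + H / (1 + exp(a + b * x))` with `H = K - lower`: a
#' sigmoid falling from the upper asymptote K (as x -> -Inf) to `lower`
#' (as x -> +Inf) when b >= 0. The inflection sits at x = -a/b, where the
#' curve crosses the midpoint between the asymptotes. Overflow saturates
#' to the asymptotes.
#'
#' @param x Session index (vectorised).
#' @param K Upper asymptote, VAS units.
#' @param a Location parameter (dimensionless); -a/b is the onset/inflection
#'   session.
#' @param b Descent-rate parameter per session, non-negative for a
#'   remission (decreasing) curve.
#' @param lower Lower asymptote, VAS units (default 0).
#' @return Curve value(s) in `[lower, K]`.
#' @examples
#' logistic_curve(1:10, K = 8, a = -3, b = 0.6)
#' @export
logistic_curve <- function(x, K, a, b, lower = 0) {
  H <- K - lower
  # plogis(-(a+bx)) = 1/(1+exp(a+bx)), numerically stable at both tails
  lower + H * stats::plogis(-(a + b * x))
}

sse_logistic <- function(par, x, y, K, lo) {
  sum((y - logistic_curve(x, K, par[1L], par[2L], lo))^2)
}

grad_sse_logistic <- function(par, x, y, K, lo) {
  H <- K - lo
  p <- stats::plogis(-(par[1L] + par[2L] * x))
  f <- lo + H * p
  common <- 2 * (f - y) * (-H * p * (1 - p))
  c(sum(common), sum(common * x))
}

#' Fit the remission curve to one patient
#'
#' Estimates the location and rate parameters (a, b) of the logistic
#' remission curve by bounded least squares, with the upper asymptote fixed
#' by [compute_upper_asymptote()] on the first rating and the lower
#' asymptote fixed (default 0). The optimiser is L-BFGS-B on the sum of
#' squared residuals with analytic gradient, bounds b in `[0, 10]`,
#' a in `[-50, 50]`, and a deterministic start: b0 = 0.5,
#' a0 = -b0 * x_mid where x_mid is the session whose score lies nearest the
#' midpoint between the asymptotes. For two-point trajectories the exact
#' interpolating parameters are also tried as a start and the fit is
#' flagged `exact_fit`. The returned parameters never have a larger sum of
#' squared errors than the starting point; on optimiser failure the best
#' iterate is returned with `converged = FALSE`.
#'
#' @param traj A [vas_trajectory()] with at least 2 points.
#' @param lower Lower asymptote, VAS units (default 0; fixed, not
#'   estimated).
#' @param mcsd MCSD used in the asymptote rule (default 1.2).
#' @param control Optional list overriding optimiser settings:
#'   `b_bounds` (default `c(0, 10)`), `a_bounds` (default `c(-50, 50)`),
#'   `maxit` (default 1000).
#' @return An object of class `"curve_fit"`: list with `patient_id`, `K`,
#'   `lower`, `H`, `a`, `b`, `sessions`, `observed`, `fitted`, `residuals`,
#'   `sse`, `ss_tot`, `r2`, `n`, `converged`, `exact_fit`.
#' @seealso [fit_truncated()], [r_squared_patient()], [r_squared_global()]
#' @examples
#' y <- logistic_curve(1:10, K = 8, a = -3, b = 0.6)
#' fit <- fit_patient(vas_trajectory("p1", 1:10, y))
#' c(fit$a, fit$b)  # recovers -3, 0.6
#' @export
fit_patient <- function(traj, lower = 0, mcsd = 1.2, control = list()) {
  if (!inherits(traj, "vas_trajectory")) {
    stop("`traj` must be a vas_trajectory", call. = FALSE)
  }
  x <- traj$sessions
  y <- traj$vas
  n <- length(x)
  if (n < 2L) stop("at least 2 points are required to fit", call. = FALSE)

  K <- compute_upper_asymptote(y[1L], mcsd = mcsd)
  H <- K - lower
  ctl <- utils::modifyList(
    list(b_bounds = c(0, 10), a_bounds = c(-50, 50), maxit = 1000L),
    control
  )

  clip_par <- function(par) {
    c(max(ctl$a_bounds[1L], min(ctl$a_bounds[2L], par[1L])),
      max(ctl$b_bounds[1L], min(ctl$b_bounds[2L], par[2L])))
  }
  # deterministic starts: onset at the session closest to the midpoint
  # between the asymptotes (fallback: mid-course, 5.5) combined with slow,
  # moderate and fast trial rates; the SSE surface has a flat basin along
  # b = 0 (constant curve at the asymptote) that a single start can fall
  # into, so the best of several deterministic starts is kept
  mid <- lower + H / 2
  x_mid <- if (all(!is.finite(y))) 5.5 else x[which.min(abs(y - mid))]
  starts <- lapply(c(0.1, 0.5, 1.5), function(b0) clip_par(c(-b0 * x_mid, b0)))

  # chord start: solve a + b x = log(H / (y - lower) - 1) exactly through
  # the first and last interior observations; for two-point trajectories
  # this interpolates both points outright
  interior <- which(y > lower & y < K)
  exact_fit <- n == 2L
  if (length(interior) >= 2L) {
    i1 <- interior[1L]
    i2 <- interior[length(interior)]
    eta <- log(H / (y[c(i1, i2)] - lower) - 1)
    b_ch <- (eta[2L] - eta[1L]) / (x[i2] - x[i1])
    a_ch <- eta[1L] - b_ch * x[i1]
    if (is.finite(a_ch) && is.finite(b_ch)) {
      starts <- c(starts, list(clip_par(c(a_ch, b_ch))))
    }
  }

  best_par <- starts[[1L]]
  best_sse <- sse_logistic(best_par, x, y, K, lower)
  converged <- FALSE
  for (st in starts) {
    st_sse <- sse_logistic(st, x, y, K, lower)
    if (st_sse < best_sse) {
      best_par <- st
      best_sse <- st_sse
    }
    opt <- tryCatch(
      stats::optim(
        st, sse_logistic, gr = grad_sse_logistic,
        x = x, y = y, K = K, lo = lower,
        method = "L-BFGS-B",
        lower = c(ctl$a_bounds[1L], ctl$b_bounds[1L]),
        upper = c(ctl$a_bounds[2L], ctl$b_bounds[2L]),
        control = list(maxit = ctl$maxit, factr = 10, pgtol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (!is.null(opt) && is.finite(opt$value) && opt$value <= best_sse) {
      best_par <- opt$par
      best_sse <- opt$value
      converged <- converged || opt$convergence == 0L
    }
  }

  fitted <- logistic_curve(x, K, best_par[1L], best_par[2L], lower)
  ss_tot <- sum((y - mean(y))^2)
  fit <- structure(
    list(patient_id = traj$patient_id,
         K = K, lower = lower, H = H,
         a = best_par[1L], b = best_par[2L],
         sessions = x, observed = y,
         fitted = fitted, residuals = y - fitted,
         sse = best_sse, ss_tot = ss_tot, r2 = NA_real_,
         n = n, converged = converged, exact_fit = exact_fit),
    class = "curve_fit"
  )
  fit$r2 <- r_squared_patient(fit)
  fit
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf(
    "Remission-curve fit, patient %s (n = %d)\n  K = %.3f, a = %.4f, b = %.4f, SSE = %.4g, R2 = %s%s\n",
    x$patient_id, x$n, x$K, x$a, x$b, x$sse,
    if (is.na(x$r2)) "undefined" else sprintf("%.4f", x$r2),
    if (!x$converged) " [not converged]" else ""
  ))
  invisible(x)
}

#' Per-patient coefficient of determination
#'
#' `R2 = 1 - SS_res / SS_tot`, with the total sum of squares taken about the
#' patient's own mean observed score. Undefined (returned as `NA`) when the
#' observed series is constant (`SS_tot = 0`).
#'
#' @param fit A `"curve_fit"` from [fit_patient()].
#' @return R-squared, or `NA_real_` when undefined.
#' @export
r_squared_patient <- function(fit) {
  if (!inherits(fit, "curve_fit")) stop("`fit` must be a curve_fit", call. = FALSE)
  if (fit$ss_tot <= 0) return(NA_real_)
  1 - fit$sse / fit$ss_tot
}

#' Global (pooled) coefficient of determination
#'
#' Pools residual and total sums of squares over all patients before
#' dividing: `R2_global = 1 - sum(SS_res) / sum(SS_tot)`. This is not the
#' mean of per-patient R-squared values; the pooled definition weights
#' each patient by the variability of their own series.
#'
#' @param fits List of `"curve_fit"` objects.
#' @return Pooled R-squared.
#' @export
r_squared_global <- function(fits) {
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  sse <- vapply(fits, function(f) f$sse, numeric(1))
  sst <- vapply(fits, function(f) f$ss_tot, numeric(1))
  if (sum(sst) <= 0) stop("all series are constant; pooled R2 undefined", call. = FALSE)
  1 - sum(sse) / sum(sst)
}
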