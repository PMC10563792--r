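#' Perturbation protocol specification
#'
#' A constant extra torque applied on top of the steady-state actuation:
#' by default 20% of the peak steady-state actuator moment, held for half a
#' cycle period, starting at a positive-going zero crossing of the angle
#' after five settled cycles.
#'
#' @param magnitude_fraction Perturbation torque as a fraction of the peak
#'   steady-state actuation moment (default 0.20).
#' @param duration Duration in seconds; `NULL` (default) means half the
#'   cycle period of the context it is applied to.
#' @param onset Onset time in seconds; `NULL` (default) means five full
#'   cycles, which is a positive-going zero crossing of the prescribed
#'   sinusoid.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(magnitude_fraction = 0.20, duration = NULL,
                              onset = NULL) {
  if (!is.numeric(magnitude_fraction) || length(magnitude_fraction) != 1L ||
      magnitude_fraction < 0) {
    stop("magnitude_fraction must be a single non-negative number")
  }
  if (!is.null(duration) && (duration <= 0)) stop("duration must be > 0")
  structure(list(magnitude_fraction = magnitude_fraction,
                 duration = duration, onset = onset),
            class = "perturbation_spec")
}

#' Forward-simulate the limb under steady actuation and a perturbation
#'
#' Integrates \eqn{J_{eff}\ddot\theta = -c_{eff}\dot\theta - k_{eff}\theta +
#' M(t) + M_p(t)} where \eqn{M(t)} is the inverse-dynamics moment that
#' produces the target sinusoid (so the pre-perturbation motion is the
#' steady state exactly) and \eqn{M_p} is the constant perturbation torque
#' over `[onset, onset + duration]`.  Uses an adaptive implicit Runge–Kutta
#' integrator with dense output (Radau IIA, deSolve's `radau`; rel. tol
#' 1e-8, abs. tol 1e-10).  Stance runs
#' whose angle exceeds \eqn{\pi/2} are truncated and flagged unstable (the
#' animal falls); swing runs are never truncated, since a hanging pendulum
#' may pass \eqn{\pi/2} harmlessly.
#'
#' @param ctx A [phase_context()].
#' @param spec A [perturbation_spec()].
#' @param n_cycles Number of cycles to simulate (>= 10).
#' @param nonlinear_gravity If TRUE, gravity enters as \eqn{\sin\theta}
#'   instead of its linearisation (useful for sweeps beyond 30 degrees).
#' @param samples_per_cycle Output sampling density.
#'
#' @return An object of class `limb_trajectory`: list with `t`, `theta`,
#'   `theta_dot`, `cycle_maxima` (data.frame `cycle`, `max_angle`),
#'   `classification` (`"stable_overdamped"`, `"stable_underdamped"` or
#'   `"unstable"`, from [classify_response()] for linear runs or the angle
#'   bound when truncated), `truncated`, plus the echoed `ctx` and `spec`.
#' @export
#' @examples
#' ctx <- phase_context("swing", T_cycle = 1, L = 0.005)
#' traj <- simulate_perturbation(ctx, perturbation_spec(), n_cycles = 12)
#' traj$classification
simulate_perturbation <- function(ctx, spec = perturbation_spec(),
                                  n_cycles = 20L, nonlinear_gravity = FALSE,
                                  samples_per_cycle = 128L) {
  stopifnot(inherits(ctx, "phase_context"), inherits(spec, "perturbation_spec"))
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 10L) stop("n_cycles must be at least 10")
  co <- effective_coefficients(ctx)
  p <- ctx$params
  w <- ctx$omega; Th <- ctx$theta_amplitude; Tc <- ctx$T
  onset <- if (is.null(spec$onset)) 5 * Tc else spec$onset
  duration <- if (is.null(spec$duration)) Tc / 2 else spec$duration
  if (duration > 5 * Tc) stop("perturbation duration must not exceed 5 cycle periods")
  M_peak <- sqrt((co$k_eff - co$J_eff * w^2)^2 + (co$c_eff * w)^2) * Th
  M_pert <- spec$magnitude_fraction * M_peak
  # split k_eff into the gravity part (possibly nonlinear) and the rest
  grav <- if (ctx$phase_of_gait == "swing") p$k_r_grav_swing else -p$k_r_grav_stance
  k_rest <- co$k_eff - grav
  grav_torque <- if (nonlinear_gravity) {
    function(th) -grav * sin(th)
  } else {
    function(th) -grav * th
  }
  deriv <- function(t, y, parms) {
    M <- co$J_eff * (-Th * w^2 * sin(w * t)) +
      co$c_eff * (Th * w * cos(w * t)) +
      co$k_eff * (Th * sin(w * t))
    if (t >= onset && t < onset + duration) M <- M + M_pert
    acc <- (-co$c_eff * y[2L] - k_rest * y[1L] + grav_torque(y[1L]) + M) / co$J_eff
    list(c(y[2L], acc))
  }
  # the pi/2 "falling over" bound only makes sense for stance (inverted
  # pendulum); a stable swing transient may exceed pi/2 harmlessly
  rootfun <- if (ctx$phase_of_gait == "stance") {
    function(t, y, parms) abs(y[1L]) - pi / 2
  } else {
    NULL
  }
  # resolve the limb's own ringing even when the drive period is much
  # longer than the natural period (only underdamped responses ring)
  zeta <- damping_ratio(ctx)
  if (is.finite(zeta) && zeta < 1) {
    T_nat <- 2 * pi / sqrt(co$k_eff / co$J_eff)
    samples_per_cycle <- min(65536L,
                             max(samples_per_cycle,
                                 as.integer(ceiling(32 * Tc / T_nat))))
  }
  times <- seq(0, n_cycles * Tc, by = Tc / samples_per_cycle)
  sol <- deSolve::radau(y = c(theta = 0, theta_dot = Th * w), times = times,
                        func = deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-10,
                        rootfunc = rootfun)
  t_out <- sol[, 1L]; theta <- sol[, 2L]; theta_dot <- sol[, 3L]
  truncated <- length(t_out) < length(times)
  cyc <- floor(t_out / Tc)
  cyc[cyc == n_cycles] <- n_cycles - 1L        # final endpoint belongs to last cycle
  completed <- seq_len(max(cyc[length(cyc)] + ifelse(truncated, 0L, 1L), 1L)) - 1L
  maxima <- vapply(completed, function(k) {
    sel <- cyc == k
    if (any(sel)) max(theta[sel]) else NA_real_
  }, numeric(1))
  classification <- if (truncated) "unstable" else classify_response(ctx)
  structure(list(t = t_out, theta = theta, theta_dot = theta_dot,
                 cycle_maxima = data.frame(cycle = completed, max_angle = maxima),
                 classification = classification, truncated = truncated,
                 onset = onset, duration = duration, M_pert = M_pert,
                 ctx = ctx, spec = spec),
            class = "limb_trajectory")
}

#' @export
print.limb_trajectory <- function(x, ...) {
  cat(sprintf("Limb trajectory: %s (%s, L = %.4g m, T = %.4g s)%s\n",
              x$classification, x$ctx$phase_of_gait, x$ctx$params$L, x$ctx$T,
              if (x$truncated) " [truncated: |theta| reached pi/2]" else ""))
  invisible(x)
}

#' Analytic classification of the perturbation response
#'
#' From the effective linear coefficients alone: a non-positive effective
#' stiffness means the posture diverges (`"unstable"`); otherwise the
#' damping ratio \eqn{\zeta = c_{eff} / (2\sqrt{J_{eff} k_{eff}})}
#' discriminates `"stable_underdamped"` (\eqn{\zeta < 1}, ringing over
#' multiple cycles) from `"stable_overdamped"` (\eqn{\zeta \ge 1},
#' monotonic decay).
#'
#' @param ctx A [phase_context()].
#' @return Character classification.
#' @export
classify_response <- function(ctx) {
  co <- effective_coefficients(ctx)
  if (co$k_eff <= 0) return("unstable")
  zeta <- co$c_eff / (2 * sqrt(co$J_eff * co$k_eff))
  if (zeta < 1) "stable_underdamped" else "stable_overdamped"
}

#' Classify a perturbation response from the simulated trace alone
#'
#' Model-free counterpart of [classify_response()]: looks only at the
#' deviation \eqn{\delta(t) = \theta(t) - \Theta\sin(\omega t)} after the
#' perturbation ends.  A truncated run (angle bound reached) or a deviation
#' whose magnitude grows over the observation window is `"unstable"`; a
#' decaying deviation that re-crosses zero at least twice (ringing) is
#' `"stable_underdamped"`; a decay with at most one sign change is
#' `"stable_overdamped"`.  Sign changes are counted only while the
#' deviation exceeds 5% of its post-perturbation maximum, so the window
#' should cover a few natural periods of the limb.
#'
#' @param traj A `limb_trajectory` from [simulate_perturbation()].
#' @return Character classification, or `NA` if the perturbation left no
#'   measurable deviation.
#' @export
classify_from_trajectory <- function(traj) {
  stopifnot(inherits(traj, "limb_trajectory"))
  if (traj$truncated) return("unstable")
  ctx <- traj$ctx
  post <- traj$t >= traj$onset + traj$duration
  delta <- traj$theta[post] -
    ctx$theta_amplitude * sin(ctx$omega * traj$t[post])
  A <- max(abs(delta))
  if (A < 1e-9 * ctx$theta_amplitude) return(NA_character_)
  n <- length(delta)
  q <- max(2L, n %/% 4L)
  if (mean(abs(delta[(n - q + 1L):n])) > mean(abs(delta[seq_len(q)]))) {
    return("unstable")
  }
  s <- sign(delta[abs(delta) > 0.05 * A])
  crossings <- sum(diff(s) != 0)
  if (crossings >= 2L) "stable_underdamped" else "stable_overdamped"
}

#' Damping ratio of the effective dynamics
#'
#' @param ctx A [phase_context()].
#' @return \eqn{\zeta = c_{eff}/(2\sqrt{J_{eff} k_{eff}})}, or `NA` when
#'   `k_eff <= 0` (no oscillatory restoring force).
#' @export
damping_ratio <- function(ctx) {
  co <- effective_coefficients(ctx)
  if (co$k_eff <= 0) return(NA_real_)
  co$c_eff / (2 * sqrt(co$J_eff * co$k_eff))
}

#' Passive stance stability boundary
#'
#' The unique limb length at which the rotational elastic stiffness
#' (\eqn{\propto L^3}) equals the destabilising gravitational stiffness of
#' stance (\eqn{\propto L^4}).  Below it an animal can stand without any
#' muscle activity; above it static posture is passively unstable.  The
#' boundary involves no frequency, so it is independent of cycle period.
#' Found by bisection in \eqn{\log L} to relative tolerance 1e-6.
#'
#' @param laws Allometric laws.
#' @param interval Search interval in metres.
#' @return Boundary length (m).
#' @export
#' @examples
#' passive_stability_boundary()   # 1 cm at the calibrated defaults
passive_stability_boundary <- function(laws = default_laws(),
                                       interval = c(1e-5, 1e2)) {
  f <- function(logL) {
    p <- derive_params(10^logL, laws)
    p$k_r_elas - p$k_r_grav_stance
  }
  lo <- log10(interval[1L]); hi <- log10(interval[2L])
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) {
    stop("no passive stability boundary in [", interval[1L], ", ",
         interval[2L], "] m: elastic and gravitational stiffness do not cross")
  }
  while ((hi - lo) > 1e-6 / log(10)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) { lo <- mid; hi <- mid; break }
    if (flo * fm < 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  10^((lo + hi) / 2)
}

#' Monotone spline through per-cycle maxima
#'
#' Diagnostic envelope used when plotting perturbation responses: a
#' monotone piecewise-cubic (Hyman-filtered) interpolant through the maximum
#' angle reached in each cycle.
#'
#' @param traj A `limb_trajectory`.
#' @param n Number of interpolation points.
#' @return data.frame with `t` (cycle-centre times, s) and `envelope` (rad).
#' @export
cycle_maxima_spline <- function(traj, n = 200L) {
  stopifnot(inherits(traj, "limb_trajectory"))
  cm <- traj$cycle_maxima
  ok <- is.finite(cm$max_angle)
  if (sum(ok) < 2L) return(data.frame(t = numeric(0), envelope = numeric(0)))
  tc <- (cm$cycle[ok] + 0.5) * traj$ctx$T
  sp <- stats::splinefun(tc, cm$max_angle[ok], method = "monoH.FC")
  tt <- seq(min(tc), max(tc), length.out = n)
  data.frame(t = tt, envelope = sp(tt))
}
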