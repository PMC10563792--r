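#' Inverse-dynamics moment for prescribed sinusoidal kinematics
#'
#' Samples the actuator moment required to drive
#' \eqn{\theta(t) = \Theta\sin(\omega t)} through the effective second-order
#' dynamics of the gait phase: \eqn{M(t) = J_{eff}\ddot\theta +
#' c_{eff}\dot\theta + k_{eff}\theta}.  The sampling is exact (closed-form
#' derivatives, no integration error).
#'
#' @param ctx A [phase_context()].
#' @param t_samples Sample times (s).
#' @return Numeric vector of moments (N m), one per sample time.
#' @export
inverse_dynamics_moment <- function(ctx, t_samples) {
  stopifnot(inherits(ctx, "phase_context"))
  co <- effective_coefficients(ctx)
  w <- ctx$omega; Th <- ctx$theta_amplitude
  th <- Th * sin(w * t_samples)
  thd <- Th * w * cos(w * t_samples)
  thdd <- -Th * w^2 * sin(w * t_samples)
  co$J_eff * thdd + co$c_eff * thd + co$k_eff * th
}

#' Steady-state work loop for one cycle
#'
#' Samples one full cycle of the prescribed sinusoid and its
#' inverse-dynamics moment.  Plotted as moment versus angle this is the
#' joint-level work loop: area swept below the curve is energy added to the
#' body, area enclosed by the loop is energy dissipated by joint viscosity
#' per cycle.
#'
#' @param ctx A [phase_context()].
#' @param n_samples Samples per cycle (default 1024, minimum 64).
#' @return An object of class `work_loop`: a list with vectors `t`, `theta`
#'   (rad), `moment` (N m) — the first sample repeated at `t = T` so the
#'   loop closes — and the `energy_partition` record of
#'   [energy_partition()].
#' @export
#' @examples
#' wl <- work_loop(phase_context("swing", T_cycle = 0.5, L = 0.02))
#' wl$energy_partition$dissipated
work_loop <- function(ctx, n_samples = 1024L) {
  stopifnot(inherits(ctx, "phase_context"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 64L) stop("need at least 64 samples per cycle")
  t <- seq(0, ctx$T, length.out = n_samples + 1L)   # closed loop
  theta <- ctx$theta_amplitude * sin(ctx$omega * t)
  moment <- inverse_dynamics_moment(ctx, t)
  loop <- structure(list(t = t, theta = theta, moment = moment,
                         n_samples = n_samples,
                         energy_partition = NULL),
                    class = "work_loop")
  loop$energy_partition <- energy_partition(loop, ctx)
  loop
}

#' Per-cycle energy partition of a work loop
#'
#' Splits the actuator work of one steady-state cycle into where it goes:
#' \itemize{
#'   \item `dissipated`: net work per cycle, equal to the enclosed loop area
#'     \eqn{\oint M\,d\theta} (trapezoid-integrated) and, in closed form,
#'     \eqn{\pi c_{eff} \omega \Theta^2}; the conservative terms net to zero
#'     over a cycle;
#'   \item `peak_kinetic` \eqn{= \tfrac12 J_{eff}\omega^2\Theta^2},
#'   \item `peak_elastic` \eqn{= \tfrac12 k_{r,elas}\Theta^2},
#'   \item `peak_gravitational` \eqn{= \pm\tfrac12 k_{r,grav}\Theta^2}
#'     (negative when gravity destabilises, i.e. in stance).
#' }
#' `fractions` normalises the four magnitudes by their absolute sum, giving
#' the shading proportions of the work-loop figures: deep in the kinetic
#' region the kinetic fraction approaches 1, deep in the viscous region the
#' dissipated fraction approaches 1.
#'
#' @param loop A [work_loop()] (or any list with closed `t`, `theta`,
#'   `moment` traces over one cycle).
#' @param ctx The [phase_context()] that produced it.
#' @return A list with `dissipated`, `dissipated_closed_form`,
#'   `peak_kinetic`, `peak_elastic`, `peak_gravitational` (J) and
#'   `fractions` (named numeric, sums to 1).
#' @export
energy_partition <- function(loop, ctx) {
  stopifnot(inherits(ctx, "phase_context"))
  theta <- loop$theta; moment <- loop$moment
  n <- length(theta)
  if (n < 3L) stop("loop traces too short")
  tol <- 1e-6 * max(abs(theta), abs(moment), 1e-300)
  if (abs(theta[1L] - theta[n]) > tol || abs(moment[1L] - moment[n]) > tol) {
    stop("work loop is not closed: trace must cover exactly one full cycle")
  }
  co <- effective_coefficients(ctx)
  p <- ctx$params
  w <- ctx$omega; Th <- ctx$theta_amplitude
  # trapezoid integration of the enclosed (signed) area
  area <- sum((moment[-n] + moment[-1L]) / 2 * diff(theta))
  closed <- pi * co$c_eff * w * Th^2
  grav <- if (ctx$phase_of_gait == "swing") p$k_r_grav_swing else p$k_r_grav_stance
  sign_grav <- if (ctx$phase_of_gait == "swing") 1 else -1
  comps <- c(dissipated = closed,
             kinetic = 0.5 * co$J_eff * w^2 * Th^2,
             elastic = 0.5 * p$k_r_elas * Th^2,
             gravitational = 0.5 * grav * Th^2)
  list(dissipated = area,
       dissipated_closed_form = closed,
       peak_kinetic = comps[["kinetic"]],
       peak_elastic = comps[["elastic"]],
       peak_gravitational = sign_grav * comps[["gravitational"]],
       fractions = comps / sum(abs(comps)))
}

#' @export
print.work_loop <- function(x, ...) {
  ep <- x$energy_partition
  cat(sprintf("Work loop: %d samples/cycle, dissipated %.4g J/cycle\n",
              x$n_samples, ep$dissipated))
  fr <- ep$fractions
  cat(sprintf("  energy fractions: kinetic %.3f | elastic %.3f | grav %.3f | dissipated %.3f\n",
              fr[["kinetic"]], fr[["elastic"]], fr[["gravitational"]],
              fr[["dissipated"]]))
  invisible(x)
}

#' @export
plot.work_loop <- function(x, ...) {
  graphics::plot(x$theta, x$moment, type = "l",
                 xlab = "joint angle (rad)", ylab = "actuator moment (N m)",
                 main = "Work loop", ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
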