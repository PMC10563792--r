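#' Kinematic and mechanical context for one oscillatory joint motion
#'
#' Fixes everything needed to evaluate the joint moment for the prescribed
#' sinusoid \eqn{\theta(t) = \Theta \sin(\omega t)}: the gait phase (swing =
#' hanging pendulum, stance = inverted pendulum carrying the body), the limb
#' parameters, the cycle period and the sweep semi-amplitude.
#'
#' @param phase_of_gait `"swing"` or `"stance"`.
#' @param params A [derive_params()] object, or `NULL` to derive from `L`
#'   and `laws`.
#' @param T_cycle Cycle period in seconds.
#' @param L Limb length (m), used when `params` is `NULL`.
#' @param laws Allometric laws used when `params` is `NULL`.
#' @param theta_amplitude Sweep semi-amplitude \eqn{\Theta} in radians;
#'   default 0.5 (a 1-radian sweep, about 60 degrees).  Values above
#'   \eqn{\pi/6} stretch the small-angle treatment of gravity and trigger a
#'   warning.
#'
#' @return An object of class `phase_context` with fields `phase_of_gait`,
#'   `params`, `T`, `omega` (\eqn{2\pi/T}) and `theta_amplitude`.
#' @export
#' @examples
#' ctx <- phase_context("stance", T_cycle = 0.7, L = 5e-3)
#' phase_shift(ctx)$phi_deg    # 45 degrees at the calibrated defaults
phase_context <- function(phase_of_gait = c("swing", "stance"), params = NULL,
                          T_cycle = 1, L = NULL, laws = default_laws(),
                          theta_amplitude = 0.5) {
  phase_of_gait <- match.arg(phase_of_gait)
  if (is.null(params)) {
    if (is.null(L)) stop("supply either params or a limb length L")
    params <- derive_params(L, laws)
  }
  if (!inherits(params, "limb_params")) stop("params must come from derive_params()")
  if (!is.numeric(T_cycle) || length(T_cycle) != 1L || !is.finite(T_cycle) ||
      T_cycle <= 0) {
    stop("cycle period T_cycle must be a single positive number")
  }
  if (!is.numeric(theta_amplitude) || length(theta_amplitude) != 1L ||
      theta_amplitude <= 0) {
    stop("theta_amplitude must be a single positive number")
  }
  if (theta_amplitude > pi / 6 + 1e-12) {
    warning("theta_amplitude exceeds pi/6; the linearised gravity terms lose accuracy")
  }
  structure(list(phase_of_gait = phase_of_gait, params = params,
                 T = T_cycle, omega = 2 * pi / T_cycle,
                 theta_amplitude = theta_amplitude),
            class = "phase_context")
}

#' Effective second-order coefficients for a gait phase
#'
#' Collapses the limb model onto \eqn{M = J_{eff}\ddot\theta +
#' c_{eff}\dot\theta + k_{eff}\theta}.  Gravity is stabilising in swing
#' (added to the elastic stiffness) and destabilising in stance (subtracted),
#' so `k_eff` may be negative in stance: static posture is then passively
#' unstable.
#'
#' @param ctx A [phase_context()].
#' @return A list with `J_eff` (kg m^2), `c_eff` (N m s rad^-1) and `k_eff`
#'   (N m rad^-1).
#' @export
effective_coefficients <- function(ctx) {
  stopifnot(inherits(ctx, "phase_context"))
  p <- ctx$params
  if (ctx$phase_of_gait == "swing") {
    list(J_eff = p$J_swing, c_eff = p$c_r,
         k_eff = p$k_r_elas + p$k_r_grav_swing)
  } else {
    list(J_eff = p$J_stance, c_eff = p$c_r,
         k_eff = p$k_r_elas - p$k_r_grav_stance)
  }
}

dominance_priority <- c("inertial", "gravitational", "elastic", "viscous")

#' Phase shift between actuator moment and joint angle
#'
#' For the prescribed sinusoid \eqn{\theta = \Theta\sin(\omega t)} the
#' required moment is \eqn{M = J_{eff}\ddot\theta + c_{eff}\dot\theta +
#' k_{eff}\theta}, itself sinusoidal, leading the angle by
#' \deqn{\phi = \mathrm{atan2}(c_{eff}\,\omega,\; k_{eff} - J_{eff}\omega^2)}
#' folded into \eqn{[0^\circ, 180^\circ]}.  \eqn{\phi \to 0^\circ} for
#' elastically dominated (quasi-static) motion, \eqn{90^\circ} for viscously
#' dominated motion and \eqn{180^\circ} for inertially or
#' destabilising-gravitationally dominated (kinetic) motion, making the phase
#' shift a single dimensionless readout of the dominant force.
#'
#' @param ctx A [phase_context()].
#' @return An object of class `phase_result`: a list with `phi_deg`
#'   (degrees in `[0, 180]`), the four moment-term amplitudes `A_inertial`
#'   (\eqn{J\omega^2\Theta}), `A_viscous` (\eqn{c\omega\Theta}), `A_elastic`
#'   (\eqn{k_{elas}r^2\Theta}) and `A_grav` (\eqn{k_{grav}\Theta}),
#'   `grav_destabilizing` (TRUE in stance), `dominant` (which amplitude is
#'   largest; ties broken inertial > gravitational > elastic > viscous) and
#'   `region` (see [classify_region()]), plus `L`, `T`, `phase_of_gait`.
#' @export
#' @examples
#' swing <- phase_context("swing", T_cycle = 1, L = 1)
#' phase_shift(swing)
phase_shift <- function(ctx) {
  stopifnot(inherits(ctx, "phase_context"))
  co <- effective_coefficients(ctx)
  p <- ctx$params
  w <- ctx$omega
  Th <- ctx$theta_amplitude
  denom <- co$k_eff - co$J_eff * w^2
  if (co$c_eff == 0 &&
      abs(denom) <= 1e-9 * (abs(co$k_eff) + co$J_eff * w^2)) {
    stop("degenerate context: undamped system driven exactly at resonance ",
         "(c_eff = 0 and k_eff = J_eff * omega^2); phase shift undefined")
  }
  phi <- atan2(co$c_eff * w, denom)          # in [0, pi] since c_eff >= 0
  grav <- if (ctx$phase_of_gait == "swing") p$k_r_grav_swing else p$k_r_grav_stance
  amps <- c(inertial = co$J_eff * w^2 * Th,
            viscous = co$c_eff * w * Th,
            elastic = p$k_r_elas * Th,
            gravitational = grav * Th)
  # which.max keeps the first maximum, so ordering by priority breaks ties
  dominant <- dominance_priority[which.max(amps[dominance_priority])]
  res <- structure(list(
    phi_deg = phi * 180 / pi,
    A_inertial = amps[["inertial"]], A_viscous = amps[["viscous"]],
    A_elastic = amps[["elastic"]], A_grav = amps[["gravitational"]],
    grav_destabilizing = ctx$phase_of_gait == "stance",
    dominant = dominant,
    L = p$L, T = ctx$T, phase_of_gait = ctx$phase_of_gait,
    region = NA_character_
  ), class = "phase_result")
  res$region <- classify_region(res)
  res
}

#' @export
print.phase_result <- function(x, ...) {
  cat(sprintf("Phase shift: %.2f deg  (%s, L = %.4g m, T = %.4g s)\n",
              x$phi_deg, x$phase_of_gait, x$L, x$T))
  cat(sprintf("  amplitudes (N m): inertial %.4g | viscous %.4g | elastic %.4g | grav %.4g (%s)\n",
              x$A_inertial, x$A_viscous, x$A_elastic, x$A_grav,
              if (x$grav_destabilizing) "destabilising" else "stabilising"))
  cat(sprintf("  dominant: %s  ->  region %s\n", x$dominant, x$region))
  invisible(x)
}

#' Classify the dominant-force region of a phase result
#'
#' Region I (kinetic): inertial or destabilising gravitational moments
#' dominate; phase shift near 180 degrees.  Region II (quasi-static): elastic
#' or stabilising gravitational moments dominate; phase shift near 0.
#' Region III (viscous): joint damping dominates; phase shift near 90.
#'
#' @param result A `phase_result` from [phase_shift()].
#' @return One of `"I_kinetic"`, `"II_quasistatic"`, `"III_viscous"`.
#' @export
classify_region <- function(result) {
  stopifnot(inherits(result, "phase_result"))
  switch(result$dominant,
         inertial = "I_kinetic",
         viscous = "III_viscous",
         elastic = "II_quasistatic",
         gravitational = if (result$grav_destabilizing) "I_kinetic" else "II_quasistatic",
         stop("unknown dominant label: ", result$dominant))
}

#' Phase-shift landscape over a (length, period) grid
#'
#' Evaluates [phase_shift()] at every combination of limb length and cycle
#' period.  Log-spaced grids spanning `L` from 1e-4 to 10 m and `T` from
#' 1e-3 to 100 s cover walking animals from fruit fly to horse; the
#' landscape then shows three plateaus near 0, 90 and 180 degrees.
#'
#' @param L_grid Strictly increasing vector of limb lengths (m).
#' @param T_grid Strictly increasing vector of cycle periods (s).
#' @param phase_of_gait `"swing"` or `"stance"`.
#' @param laws Allometric laws.
#' @param theta_amplitude Sweep semi-amplitude (rad).
#'
#' @return A long-format data.frame of class `phase_landscape` with columns
#'   `length_m`, `period_s`, `phase_of_gait`, `phi_deg`, `A_inertial`,
#'   `A_viscous`, `A_elastic`, `A_grav`, `dominant`, `region` (one row per
#'   grid cell, `T` varying fastest).
#' @export
#' @examples
#' ls <- phase_landscape(10^seq(-3, 0, length.out = 5),
#'                       10^seq(-2, 1, length.out = 5), "swing")
#' table(ls$region)
phase_landscape <- function(L_grid, T_grid,
                            phase_of_gait = c("swing", "stance"),
                            laws = default_laws(), theta_amplitude = 0.5) {
  phase_of_gait <- match.arg(phase_of_gait)
  if (length(L_grid) < 1L || length(T_grid) < 1L) {
    stop("L_grid and T_grid must be non-empty")
  }
  if (is.unsorted(L_grid, strictly = TRUE) || is.unsorted(T_grid, strictly = TRUE)) {
    stop("grids must be strictly increasing")
  }
  rows <- vector("list", length(L_grid) * length(T_grid))
  i <- 0L
  for (L in L_grid) {
    params <- derive_params(L, laws)
    for (Tc in T_grid) {
      ctx <- phase_context(phase_of_gait, params = params, T_cycle = Tc,
                           theta_amplitude = theta_amplitude)
      r <- phase_shift(ctx)
      i <- i + 1L
      rows[[i]] <- data.frame(length_m = L, period_s = Tc,
                              phase_of_gait = phase_of_gait,
                              phi_deg = r$phi_deg,
                              A_inertial = r$A_inertial,
                              A_viscous = r$A_viscous,
                              A_elastic = r$A_elastic,
                              A_grav = r$A_grav,
                              dominant = r$dominant, region = r$region,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("phase_landscape", "data.frame")
  out
}

#' @export
plot.phase_landscape <- function(x, levels = seq(10, 170, by = 10), ...) {
  Ls <- sort(unique(x$length_m)); Ts <- sort(unique(x$period_s))
  z <- matrix(x$phi_deg[order(x$length_m, x$period_s)],
              nrow = length(Ls), byrow = TRUE)
  graphics::filled.contour(
    log10(Ls), log10(Ts), z, levels = c(0, levels, 180),
    color.palette = function(n) grDevices::hcl.colors(n, "YlOrRd", rev = TRUE),
    xlab = "log10 limb length (m)", ylab = "log10 cycle period (s)",
    main = sprintf("Phase shift (deg), %s", x$phase_of_gait[1L]), ...)
  invisible(x)
}

# per-amplitude accessor used by find_crossover; each term is the amplitude
# of its moment contribution divided by theta_amplitude
amplitude_terms <- function(L, T_cycle, phase_of_gait, laws) {
  ctx <- phase_context(phase_of_gait, T_cycle = T_cycle, L = L, laws = laws)
  co <- effective_coefficients(ctx)
  p <- ctx$params
  grav <- if (phase_of_gait == "swing") p$k_r_grav_swing else p$k_r_grav_stance
  c(inertial = co$J_eff * ctx$omega^2,
    viscous = co$c_eff * ctx$omega,
    elastic = p$k_r_elas,
    gravitational = grav)
}

crossover_balances <- list(
  elastic_viscous_vs_grav_inertial = list(c("elastic", "viscous"),
                                          c("gravitational", "inertial")),
  elastic_vs_gravitational = list("elastic", "gravitational"),
  elastic_vs_inertial = list("elastic", "inertial"),
  elastic_vs_viscous = list("elastic", "viscous"),
  viscous_vs_inertial = list("viscous", "inertial")
)

#' Crossover limb length between two moment-amplitude groups
#'
#' Finds the limb length at which two named groups of moment amplitudes
#' balance, at a fixed cycle period: e.g. where the joint-intrinsic
#' elastic+viscous moments (scaling as \eqn{L^3}) hand over to the
#' mass-driven gravitational+inertial moments (\eqn{L^4}, \eqn{L^5}).  The
#' root of the amplitude-difference function is bracketed and refined by
#' bisection in \eqn{\log L} to a relative tolerance of 1e-6.
#'
#' @param T_fixed Cycle period (s).
#' @param phase_of_gait `"swing"` or `"stance"`.
#' @param laws Allometric laws.
#' @param balance One of `r paste0('\x60"', names(crossover_balances), '"\x60', collapse = ", ")`.
#' @param interval Search interval for `L` in metres.
#'
#' @return The crossover length `L_star` (m).  If the difference does not
#'   change sign over `interval`, an error of class
#'   `limbphase_no_crossover` is thrown.
#' @export
#' @examples
#' find_crossover(1, "swing")    # 0.2 m at the calibrated defaults
find_crossover <- function(T_fixed, phase_of_gait = c("swing", "stance"),
                           laws = default_laws(),
                           balance = names(crossover_balances),
                           interval = c(1e-4, 10)) {
  phase_of_gait <- match.arg(phase_of_gait)
  balance <- match.arg(balance)
  groups <- crossover_balances[[balance]]
  f <- function(logL) {
    a <- amplitude_terms(10^logL, T_fixed, phase_of_gait, laws)
    sum(a[groups[[1L]]]) - sum(a[groups[[2L]]])
  }
  lo <- log10(interval[1L]); hi <- log10(interval[2L])
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    stop(structure(class = c("limbphase_no_crossover", "error", "condition"),
                   list(message = sprintf(
                     "no crossover of '%s' in [%g, %g] m at T = %g s (%s)",
                     balance, interval[1L], interval[2L], T_fixed, phase_of_gait),
                     call = sys.call(-1L))))
  }
  # bisection on log10(L) until the bracket is tighter than 1e-6 relative
  while ((hi - lo) > 1e-6 / log(10)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) { lo <- mid; hi <- mid; break }
    if (flo * fm < 0) { hi <- mid } else { lo <- mid; flo <- fm }
  }
  10^((lo + hi) / 2)
}

#' Classical two-force dimensionless numbers
#'
#' The Froude number \eqn{Fr = v^2/(gL)} (inertial centripetal vs
#' gravitational force) and the Reynolds number \eqn{Re = \rho v L / \mu}
#' (inertial vs viscous force in a fluid).  Their level curves run parallel
#' to the kinetic/quasi-static and kinetic/viscous region boundaries of the
#' phase-shift landscape, which is why each classical number works only
#' where its two forces dominate.
#'
#' @param v Speed (m s^-1).
#' @param L Characteristic length (m).
#' @param g Gravitational acceleration (m s^-2).
#' @param rho Fluid density (kg m^-3).
#' @param mu Dynamic viscosity (Pa s).
#' @return A dimensionless number (vectorised).
#' @export
froude <- function(v, L, g = 9.81) {
  stopifnot(all(v > 0), all(L > 0), all(g > 0))
  v^2 / (g * L)
}

#' @rdname froude
#' @export
reynolds <- function(v, L, rho, mu) {
  stopifnot(all(v > 0), all(L > 0), all(rho > 0), all(mu > 0))
  rho * v * L / mu
}

#' Extract the phase shift from sampled moment and angle traces
#'
#' Estimates \eqn{\phi} by circular cross-correlation of a measured (or
#' simulated) moment trace against the angle trace over an integer number of
#' cycles, with parabolic interpolation of the correlation peak.  Serves as
#' an independent, measurement-style estimator: an experimentalist moving a
#' limb sinusoidally can obtain the dominant-force regime from recorded
#' traces without knowing any model coefficient.
#'
#' @param theta Joint-angle samples over exactly one cycle (uniform spacing,
#'   endpoint not repeated).
#' @param moment Moment samples on the same grid.
#' @return Phase shift in degrees, folded into `[0, 180]`.
#' @export
#' @examples
#' n <- 512; tau <- seq(0, 1 - 1/n, length.out = n)
#' phase_from_traces(sin(2*pi*tau), sin(2*pi*tau + pi/3))  # ~60 degrees
phase_from_traces <- function(theta, moment) {
  n <- length(theta)
  if (n < 16L || length(moment) != n) {
    stop("theta and moment must be equal-length vectors (>= 16 samples/cycle)")
  }
  th <- theta - mean(theta)
  mo <- moment - mean(moment)
  # circular cross-correlation via FFT
  cc <- Re(stats::fft(stats::fft(mo) * Conj(stats::fft(th)), inverse = TRUE))
  k <- which.max(cc) - 1L
  # parabolic interpolation around the peak
  ym <- cc[((k - 1L) %% n) + 1L]; y0 <- cc[k + 1L]; yp <- cc[((k + 1L) %% n) + 1L]
  denom <- ym - 2 * y0 + yp
  delta <- if (denom != 0) 0.5 * (ym - yp) / denom else 0
  lag <- (k + delta) %% n
  phi <- 360 * lag / n
  if (phi > 180) phi <- 360 - phi
  phi
}
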