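#' Gait specification for one stride
#'
#' Stance and swing durations, sweep amplitude, limb length and the
#' electromechanical lead used when converting predicted joint torque into
#' muscle activation envelopes.
#'
#' @param T_stance Stance duration (s).
#' @param T_swing Swing duration (s).
#' @param sweep_amplitude Semi-amplitude \eqn{\Theta} of the joint sweep
#'   (rad); default 0.5, i.e. a 1-radian sweep.
#' @param L Limb length (m).
#' @param label Free-text label.
#' @param emg_lead Electromechanical delay between muscle activation and
#'   force production (s); predicted activations are advanced by this much
#'   relative to the computed torque.  Default 0.050 s.
#' @return An object of class `gait_spec`.
#' @export
gait_spec <- function(T_stance, T_swing, sweep_amplitude = 0.5, L,
                      label = "", emg_lead = 0.050) {
  if (T_stance <= 0 || T_swing <= 0) stop("stance and swing durations must be > 0")
  if (sweep_amplitude <= 0) stop("sweep_amplitude must be > 0")
  if (L <= 0) stop("limb length L must be > 0")
  if (emg_lead < 0) stop("emg_lead must be >= 0")
  structure(list(T_stance = T_stance, T_swing = T_swing,
                 sweep_amplitude = sweep_amplitude, L = L, label = label,
                 emg_lead = emg_lead,
                 T_stride = T_stance + T_swing,
                 duty_factor = T_stance / (T_stance + T_swing)),
            class = "gait_spec")
}

#' Walking-gait presets
#'
#' `horse_gait()`: mean walking stance 0.74 s and swing 0.44 s from averaged
#' thoroughbred recordings, at a 1-m foreleg.  `stick_insect_gait()`: 1-Hz
#' stepping with 70% of the stride in stance, at a 1-cm limb.  Both sweep
#' 1 radian and use the default 50-ms electromechanical lead.
#'
#' @param L Limb length override (m).
#' @param ... Passed on to [gait_spec()].
#' @return A `gait_spec`.
#' @export
horse_gait <- function(L = 1, ...) {
  gait_spec(T_stance = 0.74, T_swing = 0.44, L = L, label = "horse", ...)
}

#' @rdname horse_gait
#' @export
stick_insect_gait <- function(L = 0.01, ...) {
  gait_spec(T_stance = 0.7, T_swing = 0.3, L = L, label = "stick_insect", ...)
}

# quintic (minimum-jerk) unit profile and derivatives on tau in [0, 1]
quintic_s <- function(tau) 6 * tau^5 - 15 * tau^4 + 10 * tau^3
quintic_sd <- function(tau) 30 * tau^4 - 60 * tau^3 + 30 * tau^2
quintic_sdd <- function(tau) 120 * tau^3 - 180 * tau^2 + 60 * tau

#' Joint kinematics over one stride
#'
#' A smooth stride: the joint retracts monotonically from \eqn{+\Theta} to
#' \eqn{-\Theta} during stance and protracts back during swing, each half
#' following a minimum-jerk (quintic) profile so that velocity and
#' acceleration vanish at touch-down and lift-off — no impulsive torque
#' artefacts at the phase transitions.
#'
#' @param spec A [gait_spec()].
#' @param n Number of samples over the stride (stride-periodic grid; the
#'   point at `t = T_stride` is not repeated).
#' @return data.frame with `t` (s), `stride_fraction`, `phase`
#'   (`"stance"`/`"swing"`), `theta` (rad), `theta_dot`, `theta_ddot`.
#' @export
gait_kinematics <- function(spec, n = 2048L) {
  stopifnot(inherits(spec, "gait_spec"))
  n <- as.integer(n)
  t <- seq(0, spec$T_stride, length.out = n + 1L)[-(n + 1L)]
  Th <- spec$sweep_amplitude
  stance <- t < spec$T_stance
  tau <- ifelse(stance, t / spec$T_stance,
                (t - spec$T_stance) / spec$T_swing)
  dur <- ifelse(stance, spec$T_stance, spec$T_swing)
  dirn <- ifelse(stance, -1, 1)      # stance retracts (+Th -> -Th), swing protracts
  theta <- ifelse(stance, Th, -Th) + dirn * 2 * Th * quintic_s(tau)
  theta_dot <- dirn * 2 * Th * quintic_sd(tau) / dur
  theta_ddot <- dirn * 2 * Th * quintic_sdd(tau) / dur^2
  data.frame(t = t, stride_fraction = t / spec$T_stride,
             phase = ifelse(stance, "stance", "swing"),
             theta = theta, theta_dot = theta_dot, theta_ddot = theta_ddot,
             stringsAsFactors = FALSE)
}

# circular shift of a stride-periodic envelope by an integer number of
# samples corresponding to `lead` seconds (positive lead = earlier in time)
shift_envelope <- function(x, lead, dt) {
  k <- as.integer(round(lead / dt)) %% length(x)
  if (k == 0L) return(x)
  c(x[(k + 1L):length(x)], x[1L:k])
}

#' Predict protractor/retractor activation envelopes for one stride
#'
#' Piecewise inverse dynamics: during stance the joint moment is computed
#' with the inverted-pendulum coefficients (body mass carried, gravity
#' destabilising), during swing with the hanging-pendulum coefficients; the
#' gravity/geometry swap at touch-down and lift-off is instantaneous.  The
#' moment is split by sign into two non-overlapping channels — torque in the
#' retraction direction is assigned to the retractor muscle, torque in the
#' protraction direction to the protractor (no cocontraction) — and each
#' channel is advanced circularly by the electromechanical lead and
#' normalised to its own stride maximum.
#'
#' With `ablate = TRUE` the joint's elastic and viscous properties are
#' removed (\eqn{c_r = 0}, \eqn{k_{r,elas} = 0}): at horse scale this barely
#' changes the prediction, while at stick-insect scale it abolishes the
#' late-stance/early-swing retractor burst that prevents the unloaded
#' elastic joint from snapping the leg forward.
#'
#' @param spec A [gait_spec()].
#' @param laws Allometric laws.
#' @param ablate Remove elastic and viscous joint properties.
#' @param n Samples per stride.
#' @return Object of class `emg_prediction`: data.frame-like list with `t`,
#'   `stride_fraction`, `phase`, `torque` (N m, unshifted), `retractor` and
#'   `protractor` (non-negative, peak-normalised, lead-advanced), plus
#'   `spec`, `ablate` and `raw_channels` (pre-normalisation, pre-shift).
#' @export
#' @examples
#' pred <- predict_emg(stick_insect_gait())
#' pattern_features(pred)$retractor$n_bursts
predict_emg <- function(spec, laws = default_laws(), ablate = FALSE,
                        n = 2048L) {
  stopifnot(inherits(spec, "gait_spec"))
  p <- derive_params(spec$L, laws)
  kin <- gait_kinematics(spec, n)
  c_r <- if (ablate) 0 else p$c_r
  k_elas <- if (ablate) 0 else p$k_r_elas
  stance <- kin$phase == "stance"
  J <- ifelse(stance, p$J_stance, p$J_swing)
  k_eff <- ifelse(stance, k_elas - p$k_r_grav_stance, k_elas + p$k_r_grav_swing)
  torque <- J * kin$theta_ddot + c_r * kin$theta_dot + k_eff * kin$theta
  # sign split: protraction is the +theta direction, so positive torque is
  # protractor, negative torque retractor
  protractor_raw <- pmax(torque, 0)
  retractor_raw <- pmax(-torque, 0)
  dt <- spec$T_stride / n
  normalise <- function(x) if (max(x) > 0) x / max(x) else x
  structure(list(t = kin$t, stride_fraction = kin$stride_fraction,
                 phase = kin$phase, torque = torque,
                 retractor = normalise(shift_envelope(retractor_raw,
                                                      spec$emg_lead, dt)),
                 protractor = normalise(shift_envelope(protractor_raw,
                                                       spec$emg_lead, dt)),
                 raw_channels = list(retractor = retractor_raw,
                                     protractor = protractor_raw),
                 spec = spec, ablate = ablate, dt = dt),
            class = "emg_prediction")
}

#' @export
print.emg_prediction <- function(x, ...) {
  cat(sprintf("EMG prediction for %s (L = %.4g m, stride %.3g s, duty %.2f)%s\n",
              x$spec$label, x$spec$L, x$spec$T_stride, x$spec$duty_factor,
              if (x$ablate) " [ablated: c_r = k_r,elas = 0]" else ""))
  f <- pattern_features(x)
  cat(sprintf("  retractor: %d burst(s); protractor: %d burst(s)\n",
              f$retractor$n_bursts, f$protractor$n_bursts))
  invisible(x)
}

#' @export
plot.emg_prediction <- function(x, ...) {
  graphics::plot(x$stride_fraction, x$retractor, type = "l", col = "blue",
                 ylim = c(0, 1), xlab = "stride fraction",
                 ylab = "normalised activation",
                 main = sprintf("Predicted EMG (%s)", x$spec$label), ...)
  graphics::lines(x$stride_fraction, x$protractor, col = "red")
  graphics::abline(v = x$spec$duty_factor, lty = 2, col = "grey50")
  graphics::legend("topright", c("retractor", "protractor"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}

# contiguous above-threshold runs on a circular stride, merged across the
# wrap point; returns onsets/offsets as stride fractions
find_bursts <- function(x, frac, threshold) {
  above <- x >= threshold
  if (!any(above)) {
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  }
  if (all(above)) {
    return(data.frame(onset = 0, offset = 1))
  }
  n <- length(x)
  # rotate so the trace starts below threshold, then find runs
  start <- which(!above)[1L]
  idx <- ((seq_len(n) + start - 2L) %% n) + 1L
  a <- above[idx]
  r <- rle(a)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  keep <- which(r$values)
  onset_i <- idx[begins[keep]]
  offset_i <- idx[ends[keep]]
  data.frame(onset = frac[onset_i], offset = frac[offset_i])
}

#' Quantitative burst features of a predicted EMG pattern
#'
#' Detects bursts per channel by thresholding at 10% of the channel peak
#' (circularly over the stride) and reports burst onsets/offsets as stride
#' fractions, burst counts and the fraction of stance and swing time each
#' channel is active — the operational versions of the qualitative pattern
#' descriptions (e.g. "bimodal protractor activity straddling the
#' stance-swing transition").
#'
#' @param pred An [predict_emg()] result.
#' @param threshold_fraction Burst threshold as a fraction of the channel
#'   peak (default 0.10).
#' @return A list with one record per channel (`retractor`, `protractor`):
#'   `bursts` (data.frame `onset`, `offset` in stride fractions), `n_bursts`,
#'   `stance_active_fraction`, `swing_active_fraction`; plus `duty_factor`.
#' @export
pattern_features <- function(pred, threshold_fraction = 0.10) {
  stopifnot(inherits(pred, "emg_prediction"))
  duty <- pred$spec$duty_factor
  channel_features <- function(x) {
    pk <- max(x)
    if (pk <= 0) {
      return(list(bursts = data.frame(onset = numeric(0), offset = numeric(0)),
                  n_bursts = 0L, stance_active_fraction = 0,
                  swing_active_fraction = 0))
    }
    thr <- threshold_fraction * pk
    b <- find_bursts(x, pred$stride_fraction, thr)
    active <- x >= thr
    stance <- pred$phase == "stance"
    list(bursts = b, n_bursts = nrow(b),
         stance_active_fraction = mean(active[stance]),
         swing_active_fraction = mean(active[!stance]))
  }
  list(retractor = channel_features(pred$retractor),
       protractor = channel_features(pred$protractor),
       duty_factor = duty)
}
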