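#' Allometric scaling laws for a one-segment limb
#'
#' Bundles the coefficient/exponent pairs that express every mechanical
#' property of a limb as a power law of its length \eqn{L}:
#' \itemize{
#'   \item limb mass \eqn{m_L = a_m L^3} (mass scales with volume),
#'   \item centre of mass \eqn{l_{com} = f_{com} L},
#'   \item moment of inertia \eqn{J_L = m_L (f_{gyr} L)^2},
#'   \item linear actuator stiffness \eqn{k_{elas} = a_k L},
#'   \item linear actuator damping \eqn{c = a_c L^{d}} (default \eqn{d = 1}),
#'   \item moment arm \eqn{r = f_r L},
#'   \item body mass carried in stance \eqn{m_B = \rho_B m_L}.
#' }
#' Linear actuator properties become rotational joint properties through the
#' principle of virtual work (multiplication by \eqn{r^2}); see
#' [derive_params()].
#'
#' @param mass_coeff Density-like mass prefactor \eqn{a_m} (kg m^-3).
#' @param com_fraction Centre-of-mass position as a fraction of \eqn{L};
#'   default 0.5 (uniform rod).
#' @param gyration_fraction Radius of gyration about the hip as a fraction of
#'   \eqn{L}; default \eqn{1/\sqrt{3}} (uniform rod pivoting at its end).
#' @param stiffness_coeff Linear stiffness prefactor \eqn{a_k} (N m^-1 per m).
#' @param damping_coeff Linear damping prefactor \eqn{a_c}
#'   (N s m^-1 per m^`damping_exp`).
#' @param damping_exp Exponent of the damping-versus-length power law;
#'   default 1 (damping, like stiffness, scales proportional to length).
#' @param moment_arm_fraction Actuator moment arm as a fraction of \eqn{L},
#'   treated as constant over sweeps below about 30 degrees.
#' @param body_mass_ratio Body mass supported by the limb in stance, as a
#'   multiple of the limb's own mass.
#' @param g Gravitational acceleration (m s^-2).
#'
#' @details Coefficients not supplied default to the calibrated values of
#' [default_laws()].
#'
#' @return An object of class `allometric_laws` (a named list of the nine
#'   fields above).
#' @seealso [default_laws()], [derive_params()], [load_laws_config()]
#' @export
#' @examples
#' laws <- allometric_laws()          # calibrated defaults
#' derive_params(0.1, laws)$m_L       # mass of a 10-cm limb
allometric_laws <- function(mass_coeff = NULL, com_fraction = NULL,
                            gyration_fraction = NULL, stiffness_coeff = NULL,
                            damping_coeff = NULL, damping_exp = NULL,
                            moment_arm_fraction = NULL, body_mass_ratio = NULL,
                            g = NULL) {
  base <- calibrated_defaults()
  supplied <- list(mass_coeff = mass_coeff, com_fraction = com_fraction,
                   gyration_fraction = gyration_fraction,
                   stiffness_coeff = stiffness_coeff,
                   damping_coeff = damping_coeff, damping_exp = damping_exp,
                   moment_arm_fraction = moment_arm_fraction,
                   body_mass_ratio = body_mass_ratio, g = g)
  for (nm in names(supplied)) {
    if (!is.null(supplied[[nm]])) base[[nm]] <- as.numeric(supplied[[nm]])
  }
  validate_laws(base)
}

#' @rdname allometric_laws
#' @export
default_laws <- function() allometric_laws()

# Closed-form calibration of the free prefactors.
#
# The limb geometry is a uniform rod (com_fraction 1/2, gyration 1/sqrt(3)),
# damping scales proportional to length, and the three prefactors that the
# geometry does not fix -- stiffness, damping, and the body-to-limb mass
# ratio -- are obtained by solving the linear system pinned by three
# phase-landscape landmarks:
#   (1) the passive stance stability boundary k_r,elas = k_r,grav,stance
#       sits at L = 1e-2 m (which is also the stance quasi-static -> kinetic
#       dominance transition at T = 1 s);
#   (2) the stance phase shift at L = 5e-3 m, T = 0.7 s equals 45 degrees;
#   (3) the swing (elastic+viscous) vs (gravitational+inertial) moment
#       balance at T = 1 s sits at L = 2e-1 m.
# Only the ratios u_k = a_k r^2 / a_m and u_c = a_c r^2 / a_m enter any
# phase shift, crossover, classification or normalised envelope; mass_coeff
# and moment_arm_fraction set absolute units and are fixed at physically
# reasonable values (20 kg m^-3; r = L/10).
calibrated_defaults <- function() {
  g <- 9.81
  f_com <- 0.5
  f_gyr2 <- 1 / 3
  L_bound <- 1e-2                 # stance stability boundary (m)
  L_t3 <- 5e-3                    # 45-degree stance anchor: length (m)
  w3 <- 2 * pi / 0.7              # ... and angular frequency (rad/s)
  L_sw <- 2e-1                    # swing group-balance crossover at T = 1 s
  w1 <- 2 * pi
  # unknowns x = (u_k, u_c, body_mass_ratio)
  A <- rbind(c(1, 0, -g * L_bound),
             c(-1, w3, g * L_t3 + L_t3^2 * w3^2),
             c(1, w1, 0))
  b <- c(g * f_com * L_bound,
         -g * f_com * L_t3 - f_gyr2 * L_t3^2 * w3^2,
         g * f_com * L_sw + f_gyr2 * L_sw^2 * w1^2)
  x <- solve(A, b)
  a_m <- 20
  f_r <- 0.1
  list(mass_coeff = a_m,
       com_fraction = f_com,
       gyration_fraction = sqrt(f_gyr2),
       stiffness_coeff = x[[1]] * a_m / f_r^2,
       damping_coeff = x[[2]] * a_m / f_r^2,
       damping_exp = 1,
       moment_arm_fraction = f_r,
       body_mass_ratio = x[[3]],
       g = g)
}

validate_laws <- function(laws) {
  need <- c("mass_coeff", "com_fraction", "gyration_fraction",
            "stiffness_coeff", "damping_coeff", "damping_exp",
            "moment_arm_fraction", "body_mass_ratio", "g")
  missing <- setdiff(need, names(laws))
  if (length(missing)) {
    stop("allometric_laws is missing fields: ", paste(missing, collapse = ", "))
  }
  for (nm in need) {
    v <- laws[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("allometric_laws field '", nm, "' must be a single finite number")
    }
  }
  pos <- c("mass_coeff", "com_fraction", "gyration_fraction",
           "stiffness_coeff", "damping_coeff", "moment_arm_fraction",
           "body_mass_ratio", "g")
  for (nm in pos) {
    if (laws[[nm]] <= 0) stop("allometric_laws field '", nm, "' must be > 0")
  }
  if (laws$com_fraction > 1) stop("com_fraction must lie in (0, 1]")
  if (laws$moment_arm_fraction > 1) stop("moment_arm_fraction must lie in (0, 1]")
  structure(laws[need], class = "allometric_laws")
}

#' @export
print.allometric_laws <- function(x, ...) {
  cat("Allometric scaling laws for a one-segment limb\n")
  cat(sprintf("  limb mass       m_L = %.4g * L^3 kg\n", x$mass_coeff))
  cat(sprintf("  centre of mass  l_com = %.3g * L\n", x$com_fraction))
  cat(sprintf("  gyration radius %.4g * L\n", x$gyration_fraction))
  cat(sprintf("  stiffness       k_elas = %.4g * L N/m\n", x$stiffness_coeff))
  cat(sprintf("  damping         c = %.4g * L^%.3g N s/m\n",
              x$damping_coeff, x$damping_exp))
  cat(sprintf("  moment arm      r = %.3g * L\n", x$moment_arm_fraction))
  cat(sprintf("  body/limb mass ratio %.4g,  g = %.4g m/s^2\n",
              x$body_mass_ratio, x$g))
  invisible(x)
}

#' Derive the mechanical parameters of a limb of given length
#'
#' Applies the allometric laws at length `L` and converts the linear actuator
#' stiffness and damping to rotational joint coefficients by the principle of
#' virtual work (multiplication by the squared moment arm \eqn{r^2}).
#'
#' @param L Limb length in metres (single positive number).
#' @param laws An [allometric_laws()] object.
#'
#' @return An object of class `limb_params`: a list with fields `L`, `m_L`
#'   (kg), `l_com` (m), `J_swing` (kg m^2, leg about the hip), `J_stance`
#'   (kg m^2, leg about the foot plus the body point mass), `m_B` (kg), `r`
#'   (m), `c_r` (N m s rad^-1), `k_r_elas` (N m rad^-1), `k_r_grav_swing`
#'   (N m rad^-1, stabilising) and `k_r_grav_stance` (N m rad^-1,
#'   destabilising).
#' @export
#' @examples
#' p <- derive_params(1, default_laws())
#' p$k_r_grav_stance / p$k_r_grav_swing   # stance gravity is much stronger
derive_params <- function(L, laws = default_laws()) {
  laws <- validate_laws(laws)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0) {
    stop("limb length L must be a single positive number (got ",
         deparse(substitute(L)), " = ", paste(L, collapse = ","), ")")
  }
  m_L <- laws$mass_coeff * L^3
  l_com <- laws$com_fraction * L
  J_leg <- m_L * (laws$gyration_fraction * L)^2
  m_B <- laws$body_mass_ratio * m_L
  r <- laws$moment_arm_fraction * L
  k_elas <- laws$stiffness_coeff * L
  c_lin <- laws$damping_coeff * L^laws$damping_exp
  structure(list(
    L = L, m_L = m_L, l_com = l_com,
    J_swing = J_leg,
    J_stance = J_leg + m_B * L^2,
    m_B = m_B, r = r,
    c_r = c_lin * r^2,
    k_r_elas = k_elas * r^2,
    k_r_grav_swing = m_L * laws$g * l_com,
    k_r_grav_stance = (m_L * l_com + m_B * L) * laws$g
  ), class = "limb_params")
}

#' @export
print.limb_params <- function(x, ...) {
  cat(sprintf("Limb parameters at L = %.4g m\n", x$L))
  cat(sprintf("  m_L = %.4g kg, m_B = %.4g kg, l_com = %.4g m, r = %.4g m\n",
              x$m_L, x$m_B, x$l_com, x$r))
  cat(sprintf("  J_swing = %.4g, J_stance = %.4g kg m^2\n",
              x$J_swing, x$J_stance))
  cat(sprintf("  c_r = %.4g N m s/rad, k_r_elas = %.4g N m/rad\n",
              x$c_r, x$k_r_elas))
  cat(sprintf("  k_r_grav: swing %.4g (stabilising), stance %.4g (destabilising) N m/rad\n",
              x$k_r_grav_swing, x$k_r_grav_stance))
  invisible(x)
}

#' Fit a damping-versus-length power law
#'
#' Ordinary least squares of \eqn{\log c} on \eqn{\log L}: fits
#' \eqn{c = a L^b} to joint-damping measurements, the straight-line fit on
#' log-log axes used to establish that joint damping scales proportional to
#' limb length.
#'
#' @param data A data.frame with numeric columns `L` (limb length, m) and
#'   `c_linear` (linear damping, N s m^-1), e.g. from
#'   [generate_damping_fixture()] or a CSV with columns
#'   `length_m,c_linear,label` read via [read_damping_csv()].
#'
#' @return A list with `coeff` (prefactor \eqn{a}), `exponent` (\eqn{b}),
#'   and `r_squared` (goodness of fit on the log-log scale).
#' @export
#' @examples
#' d <- data.frame(L = c(0.01, 0.1, 1), c_linear = 2 * c(0.01, 0.1, 1))
#' fit_power_law(d)   # recovers coeff 2, exponent 1 exactly
fit_power_law <- function(data) {
  if (is.null(data$L) && !is.null(data$length_m)) data$L <- data$length_m
  if (!is.data.frame(data) || is.null(data$L) || is.null(data$c_linear)) {
    stop("data must be a data.frame with columns L (or length_m) and c_linear")
  }
  L <- as.numeric(data$L); cc <- as.numeric(data$c_linear)
  if (any(!is.finite(L)) || any(!is.finite(cc)) || any(L <= 0) || any(cc <= 0)) {
    stop("all lengths and damping values must be positive and finite")
  }
  if (length(unique(L)) < 3L) {
    stop("need at least 3 data points with distinct lengths to fit a power law")
  }
  fit <- stats::lm(log(cc) ~ log(L))
  res <- stats::residuals(fit)
  tot <- log(cc) - mean(log(cc))
  list(coeff = unname(exp(stats::coef(fit)[1L])),
       exponent = unname(stats::coef(fit)[2L]),
       r_squared = 1 - sum(res^2) / sum(tot^2))
}
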