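# shared fixtures built in code

# a small laws object with easy round numbers (not the calibrated defaults)
toy_laws <- function(...) {
  allometric_laws(mass_coeff = 10, com_fraction = 0.5,
                  gyration_fraction = 1 / sqrt(3), stiffness_coeff = 100,
                  damping_coeff = 10, damping_exp = 1,
                  moment_arm_fraction = 0.1, body_mass_ratio = 2, g = 9.81, ...)
}

# independent finite-difference inverse dynamics: builds a moment trace from
# an angle trace without using the package's analytic derivatives
fd_moment <- function(theta, dt, J, c, k) {
  n <- length(theta)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  thd <- (theta[ip] - theta[im]) / (2 * dt)
  thdd <- (theta[ip] - 2 * theta + theta[im]) / dt^2
  J * thdd + c * thd + k * theta
}

# deviation of a trajectory from the prescribed steady-state sinusoid
traj_deviation <- function(traj) {
  ctx <- traj$ctx
  traj$theta - ctx$theta_amplitude * sin(ctx$omega * traj$t)
}
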