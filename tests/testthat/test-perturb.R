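test_that("zero-magnitude perturbation leaves the steady sinusoid untouched", {
  ctx <- phase_context("swing", T_cycle = 1, L = 0.01)
  tr <- simulate_perturbation(ctx, perturbation_spec(0), n_cycles = 12)
  expect_lt(max(abs(traj_deviation(tr))), 1e-6 * ctx$theta_amplitude)
  expect_false(tr$truncated)
})

test_that("pre-perturbation motion matches the target sinusoid within 1%", {
  for (gait in c("swing", "stance")) {
    ctx <- phase_context(gait, T_cycle = 0.5, L = 0.005)
    tr <- simulate_perturbation(ctx, n_cycles = 12)
    pre <- tr$t < tr$onset
    dev <- traj_deviation(tr)[pre]
    expect_lt(max(abs(dev)), 0.01 * ctx$theta_amplitude)
  }
})

test_that("analytic response classes follow zeta and the sign of k_eff", {
  # undamped oscillator: zeta = 0 -> underdamped
  p <- derive_params(0.1, toy_laws())
  p$c_r <- 0
  expect_equal(classify_response(phase_context("swing", params = p, T_cycle = 1)),
               "stable_underdamped")
  # stance with weaker spring than gravity -> unstable
  p2 <- derive_params(1, default_laws())
  expect_lt(p2$k_r_elas, p2$k_r_grav_stance)
  expect_equal(classify_response(phase_context("stance", params = p2, T_cycle = 1)),
               "unstable")
  # small-limb swing at the defaults is overdamped
  small <- phase_context("swing", T_cycle = 1, L = 1e-3)
  expect_gt(damping_ratio(small), 1)
  expect_equal(classify_response(small), "stable_overdamped")
})

test_that("perturbed large-limb stance explodes and is truncated", {
  tr <- simulate_perturbation(phase_context("stance", T_cycle = 1, L = 1),
                              n_cycles = 12)
  expect_true(tr$truncated)
  expect_equal(tr$classification, "unstable")
})

test_that("region-I swing rings for many cycles; damped regimes settle fast", {
  ringing <- simulate_perturbation(phase_context("swing", T_cycle = 0.1, L = 1),
                                   n_cycles = 40)
  dev_r <- abs(ringing$cycle_maxima$max_angle - 0.5) / 0.5
  post_r <- dev_r[ringing$cycle_maxima$cycle >= 6]
  expect_gt(sum(post_r > 0.05), 10)
  damped <- simulate_perturbation(phase_context("swing", T_cycle = 0.1, L = 1e-3),
                                  n_cycles = 15)
  dev_d <- abs(damped$cycle_maxima$max_angle - 0.5) / 0.5
  # settled within two cycles of the perturbation ending
  expect_lt(max(dev_d[damped$cycle_maxima$cycle >= 8]), 0.05)
})

test_that("simulation-based classification agrees with the analytic rule", {
  cases <- expand.grid(L = c(1e-3, 1e-1, 1), Tc = c(0.03, 0.3, 3))
  for (i in seq_len(nrow(cases))) {
    ctx <- phase_context("swing", T_cycle = cases$Tc[i], L = cases$L[i])
    co <- effective_coefficients(ctx)
    T_nat <- 2 * pi / sqrt(co$k_eff / co$J_eff)
    nc <- min(320, max(12, ceiling(6 * T_nat / cases$Tc[i]) + 8))
    tr <- simulate_perturbation(ctx, n_cycles = nc)
    expect_equal(classify_from_trajectory(tr), classify_response(ctx),
                 label = sprintf("L=%g T=%g", cases$L[i], cases$Tc[i]))
  }
  # an unstable stance point, simulated
  ctx_u <- phase_context("stance", T_cycle = 1, L = 0.1)
  expect_equal(classify_from_trajectory(simulate_perturbation(ctx_u, n_cycles = 12)),
               classify_response(ctx_u))
})

test_that("post-perturbation decay follows the analytic envelope within 5%", {
  ctx <- phase_context("swing", T_cycle = 0.3, L = 1)
  tr <- simulate_perturbation(ctx, n_cycles = 60)
  post <- tr$t >= tr$onset + tr$duration
  d <- traj_deviation(tr)[post]
  tt <- tr$t[post]
  co <- effective_coefficients(ctx)
  wn <- sqrt(co$k_eff / co$J_eff)
  zeta <- damping_ratio(ctx)
  peaks <- which(diff(sign(diff(abs(d)))) < 0) + 1L
  sel <- peaks[abs(d[peaks]) > 0.02 * max(abs(d))]
  fit <- stats::lm(log(abs(d[sel])) ~ tt[sel])
  expect_equal(-unname(stats::coef(fit)[2]), zeta * wn, tolerance = 0.05)
})

test_that("perturbation work on the deviation equals extra dissipation within 2%", {
  ctx <- phase_context("swing", T_cycle = 0.5, L = 0.02)
  tr <- simulate_perturbation(ctx, n_cycles = 30, samples_per_cycle = 512)
  dt <- diff(tr$t)[1]
  ddot <- tr$theta_dot - ctx$theta_amplitude * ctx$omega * cos(ctx$omega * tr$t)
  inwin <- tr$t >= tr$onset & tr$t < tr$onset + tr$duration
  W_in <- sum(tr$M_pert * ddot[inwin]) * dt
  W_diss <- effective_coefficients(ctx)$c_eff * sum(ddot^2) * dt
  expect_equal(W_diss, W_in, tolerance = 0.02)
})

test_that("passive stability boundary matches the closed form and ignores T", {
  laws <- toy_laws()
  # k_r_elas = a_k f_r^2 L^3 meets k_r_grav_stance = g a_m (f_com + rho) L^4
  a <- laws$stiffness_coeff * laws$moment_arm_fraction^2
  b <- laws$g * laws$mass_coeff * (laws$com_fraction + laws$body_mass_ratio)
  expect_equal(passive_stability_boundary(laws), a / b, tolerance = 1e-5)
  # no frequency enters: classification flips exactly at the boundary
  Lb <- passive_stability_boundary(laws)
  for (Tc in c(0.01, 1, 100)) {
    expect_equal(classify_response(phase_context("stance", T_cycle = Tc,
                                                 L = Lb * 1.01, laws = laws)),
                 "unstable")
    expect_true(classify_response(phase_context("stance", T_cycle = Tc,
                                                L = Lb * 0.99, laws = laws))
                != "unstable")
  }
  # degenerate laws with no crossing in range are rejected
  no_cross <- allometric_laws(stiffness_coeff = 1e20)
  expect_error(passive_stability_boundary(no_cross, interval = c(1e-5, 1e2)),
               "no passive stability boundary")
})

test_that("nonlinear gravity reduces the restoring torque at large angles", {
  ctx <- phase_context("swing", T_cycle = 1, L = 0.01)
  lin <- simulate_perturbation(ctx, perturbation_spec(0.5), n_cycles = 12)
  nl <- simulate_perturbation(ctx, perturbation_spec(0.5), n_cycles = 12,
                              nonlinear_gravity = TRUE)
  expect_false(isTRUE(all.equal(lin$theta, nl$theta)))
  # both still settle back towards the steady cycle
  expect_false(lin$truncated || nl$truncated)
})

test_that("cycle-maxima envelope interpolates the per-cycle maxima", {
  tr <- simulate_perturbation(phase_context("swing", T_cycle = 0.3, L = 0.5),
                              n_cycles = 20)
  sp <- cycle_maxima_spline(tr)
  expect_true(all(diff(sp$t) > 0))
  cm <- tr$cycle_maxima
  mid <- (cm$cycle[3] + 0.5) * 0.3
  expect_equal(sp$envelope[which.min(abs(sp$t - mid))], cm$max_angle[3],
               tolerance = 1e-2)
})
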