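make_ctx <- function(gait = "swing", L = 0.01, T_cycle = 1, laws = toy_laws(),
                     ...) {
  phase_context(gait, T_cycle = T_cycle, L = L, laws = laws, ...)
}

test_that("effective coefficients apply the gravity sign rule", {
  p <- derive_params(0.05, toy_laws())
  sw <- effective_coefficients(phase_context("swing", params = p, T_cycle = 1))
  st <- effective_coefficients(phase_context("stance", params = p, T_cycle = 1))
  expect_equal(sw$k_eff, p$k_r_elas + p$k_r_grav_swing)
  expect_equal(st$k_eff, p$k_r_elas - p$k_r_grav_stance)
  expect_equal(sw$J_eff, p$J_swing)
  expect_equal(st$J_eff, p$J_stance)
  expect_equal(sw$c_eff, st$c_eff)
})

test_that("pure-spring and pure-inertia limits give 0 and 180 degrees", {
  # kill damping and gravity so only stiffness and inertia remain
  laws <- allometric_laws(mass_coeff = 10, stiffness_coeff = 100,
                          damping_coeff = 1e-300, g = 1e-300,
                          com_fraction = 0.5, gyration_fraction = 1 / sqrt(3),
                          damping_exp = 1, moment_arm_fraction = 0.1,
                          body_mass_ratio = 1)
  ctx_slow <- phase_context("swing", T_cycle = 100, L = 0.1, laws = laws)
  expect_equal(phase_shift(ctx_slow)$phi_deg, 0, tolerance = 1e-6)
  ctx_fast <- phase_context("swing", T_cycle = 1e-3, L = 0.1, laws = laws)
  expect_equal(phase_shift(ctx_fast)$phi_deg, 180, tolerance = 1e-6)
})

test_that("phi is 90 degrees exactly at the undamped resonance condition", {
  laws <- toy_laws()
  p <- derive_params(0.05, laws)
  co <- effective_coefficients(phase_context("swing", params = p, T_cycle = 1))
  T_res <- 2 * pi / sqrt(co$k_eff / co$J_eff)
  r <- phase_shift(phase_context("swing", params = p, T_cycle = T_res))
  expect_equal(r$phi_deg, 90, tolerance = 1e-9)
})

test_that("phi lies in [0, 180]; monotone in frequency when k_eff > 0, above 90 otherwise", {
  for (gait in c("swing", "stance")) {
    for (L in c(1e-3, 0.05, 1)) {
      Ts <- 10^seq(2, -3, length.out = 60)
      phis <- vapply(Ts, function(Tc) {
        phase_shift(make_ctx(gait, L = L, T_cycle = Tc))$phi_deg
      }, numeric(1))
      expect_true(all(phis >= 0 & phis <= 180))
      k_eff <- effective_coefficients(make_ctx(gait, L = L))$k_eff
      if (k_eff > 0) {
        expect_true(all(diff(phis) >= -1e-9),
                    label = sprintf("monotone phi (%s, L=%g)", gait, L))
      } else {
        # destabilised stance: the moment always leads by more than 90 deg
        expect_true(all(phis > 90),
                    label = sprintf("phi > 90 under negative k_eff (%s, L=%g)",
                                    gait, L))
      }
    }
  }
})

test_that("stance phase shift is at least the swing phase shift at matched (L, T)", {
  laws <- default_laws()
  for (L in 10^seq(-4, 0.5, length.out = 8)) {
    for (Tc in 10^seq(-2.5, 2, length.out = 8)) {
      sw <- phase_shift(phase_context("swing", T_cycle = Tc, L = L, laws = laws))
      st <- phase_shift(phase_context("stance", T_cycle = Tc, L = L, laws = laws))
      expect_gte(st$phi_deg, sw$phi_deg - 1e-9)
    }
  }
})

test_that("phi approaches its plateau within 1 degree under 100x dominance", {
  laws <- toy_laws()
  probe <- function(gait, L, Tc) phase_shift(make_ctx(gait, L = L, T_cycle = Tc))
  # scan a wide grid and check the limit property wherever dominance holds
  hits <- c(elastic = 0L, inertial = 0L, viscous = 0L)
  for (L in 10^seq(-4, 1, length.out = 12)) {
    for (Tc in 10^seq(-3, 2, length.out = 12)) {
      r <- probe("swing", L, Tc)
      others <- c(r$A_inertial, r$A_viscous, r$A_elastic, r$A_grav)
      if (r$A_elastic > 100 * max(others[-3])) {
        expect_lt(abs(r$phi_deg - 0), 1); hits["elastic"] <- hits["elastic"] + 1L
      }
      if (r$A_inertial > 100 * max(others[-1])) {
        expect_lt(abs(r$phi_deg - 180), 1); hits["inertial"] <- hits["inertial"] + 1L
      }
      if (r$A_viscous > 100 * max(others[-2])) {
        expect_lt(abs(r$phi_deg - 90), 1); hits["viscous"] <- hits["viscous"] + 1L
      }
    }
  }
  expect_true(all(hits > 0))   # each limit was actually exercised
})

test_that("undamped resonance is reported as degenerate", {
  laws <- allometric_laws(mass_coeff = 10, stiffness_coeff = 100,
                          damping_coeff = 1e-300, g = 1e-300,
                          com_fraction = 0.5, gyration_fraction = 1 / sqrt(3),
                          damping_exp = 1, moment_arm_fraction = 0.1,
                          body_mass_ratio = 1)
  p <- derive_params(0.1, laws)
  co <- effective_coefficients(phase_context("swing", params = p, T_cycle = 1))
  T_res <- 2 * pi / sqrt(co$k_eff / co$J_eff)
  # zero the damping exactly by constructing params by hand
  p$c_r <- 0
  expect_error(phase_shift(phase_context("swing", params = p, T_cycle = T_res)),
               "degenerate|resonance")
})

test_that("dominance labels and regions follow the amplitude argmax", {
  mk <- function(A_i, A_v, A_e, A_g, gait) {
    # craft a params object giving exactly these amplitudes at T = 2*pi
    p <- derive_params(1, toy_laws())
    p$J_swing <- p$J_stance <- A_i
    p$c_r <- A_v
    p$k_r_elas <- A_e
    p$k_r_grav_swing <- p$k_r_grav_stance <- A_g
    phase_shift(phase_context(gait, params = p, T_cycle = 2 * pi,
                              theta_amplitude = 0.5))
  }
  expect_equal(mk(10, 1, 1, 1, "swing")$region, "I_kinetic")
  expect_equal(mk(1, 10, 1, 1, "swing")$region, "III_viscous")
  expect_equal(mk(1, 1, 10, 1, "swing")$region, "II_quasistatic")
  # gravity counts with the quasi-static group in swing, kinetic in stance
  expect_equal(mk(1, 1, 1, 10, "swing")$region, "II_quasistatic")
  expect_equal(mk(1, 1, 1, 10, "stance")$region, "I_kinetic")
  # ties break by the documented priority: inertial > gravitational > elastic
  expect_equal(mk(5, 5, 5, 5, "swing")$dominant, "inertial")
})

test_that("landscape matches pointwise evaluation and is grid-invariant", {
  laws <- toy_laws()
  one <- phase_landscape(0.02, 0.5, "stance", laws)
  expect_equal(nrow(one), 1L)
  direct <- phase_shift(phase_context("stance", T_cycle = 0.5, L = 0.02,
                                      laws = laws))
  expect_equal(one$phi_deg, direct$phi_deg, tolerance = 1e-12)
  coarse <- phase_landscape(c(0.01, 0.1), c(0.1, 1), "swing", laws)
  fine <- phase_landscape(c(0.01, 0.05, 0.1), c(0.1, 0.5, 1), "swing", laws)
  shared_c <- coarse[coarse$length_m == 0.01 & coarse$period_s == 1, "phi_deg"]
  shared_f <- fine[fine$length_m == 0.01 & fine$period_s == 1, "phi_deg"]
  expect_equal(shared_c, shared_f, tolerance = 1e-12)
  expect_error(phase_landscape(numeric(0), 1, "swing"), "non-empty")
  expect_error(phase_landscape(c(2, 1), c(1, 2), "swing"), "increasing")
})

test_that("default swing landscape shows the three phase plateaus", {
  ls <- phase_landscape(10^seq(-4, 1, length.out = 25),
                        10^seq(-3, 2, length.out = 25), "swing")
  expect_true(any(ls$phi_deg < 5))
  expect_true(any(abs(ls$phi_deg - 90) < 5))
  expect_true(any(ls$phi_deg > 175))
  expect_setequal(unique(ls$region),
                  c("I_kinetic", "II_quasistatic", "III_viscous"))
})

test_that("crossover finder matches the closed-form L^3 = L^5 balance", {
  # elastic amplitude a*L^3 vs swing inertial amplitude b*L^5 crosses at
  # sqrt(a/b); both quantities are built from the same laws object
  laws <- toy_laws()
  Tc <- 0.37
  w <- 2 * pi / Tc
  a <- laws$stiffness_coeff * laws$moment_arm_fraction^2
  b <- laws$mass_coeff * laws$gyration_fraction^2 * w^2
  L_star <- find_crossover(Tc, "swing", laws, balance = "elastic_vs_inertial")
  expect_equal(L_star, sqrt(a / b), tolerance = 1e-5)
  # no crossover in a range that excludes the root
  expect_error(
    find_crossover(Tc, "swing", laws, balance = "elastic_vs_inertial",
                   interval = c(1e-4, L_star / 10)),
    "no crossover")
})

test_that("froude and reynolds numbers follow their definitions", {
  expect_equal(froude(1, 1, g = 1), 1)
  expect_equal(reynolds(1, 1, 1, 1), 1)
  expect_equal(froude(2, 1, g = 1) / froude(1, 1, g = 1), 4)
  expect_equal(reynolds(2, 1, 1, 1) / reynolds(1, 1, 1, 1), 2)
  expect_equal(froude(3, 2), 9 / (9.81 * 2))
})

test_that("cross-correlation phase extraction recovers known shifts", {
  n <- 1024
  tau <- seq(0, 1 - 1 / n, length.out = n)
  for (phi in c(5, 45, 90, 135, 175)) {
    est <- phase_from_traces(sin(2 * pi * tau),
                             3 * sin(2 * pi * tau + phi * pi / 180))
    expect_equal(est, phi, tolerance = 0.05)
  }
})
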