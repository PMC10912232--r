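test_that("intra-fraction repair factor g", {
  expect_equal(repair_g(0), 1)
  expect_equal(repair_g(1), 2 * exp(-1))
  expect_equal(repair_g(1000), 2 / 1000, tolerance = 1e-2)
  # series / closed-form continuity at the switch point
  expect_equal(repair_g(1e-4 - 1e-12), repair_g(1e-4 + 1e-12),
               tolerance = 1e-9)
  x <- seq(0, 5, by = 0.1)
  g <- repair_g(x)
  expect_true(all(g > 0 & g <= 1))
  expect_true(all(diff(g) < 0))
})

test_that("inter-fraction incomplete repair factor h_n", {
  phis <- seq(0, 0.95, by = 0.05)
  expect_equal(incomplete_repair_h(1, phis), rep(0, length(phis)))
  expect_equal(incomplete_repair_h(5, 0), 0)
  # algebraic identity h_2(phi) = phi, checked over the grid
  expect_equal(incomplete_repair_h(2, phis), phis, tolerance = 1e-12)
  expect_error(incomplete_repair_h(2, 1), "phi")
  expect_error(incomplete_repair_h(1.5, 0.1), "integer")
})

test_that("combined repair correction M", {
  # instantaneous single fraction: no repair correction at all
  rp <- radio_params(tau_r = 1e-10, delta_tau_r = 1e-9, n_per_day = 1)
  expect_equal(repair_correction_M(rp), 1, tolerance = 1e-6)
  # M >= g for any schedule
  set.seed(11)
  for (i in 1:20) {
    tr <- runif(1, 1e-6, 5e-4)
    rp <- radio_params(tau_r = tr,
                       delta_tau_r = tr + runif(1, 0, 2e-3),
                       n_per_day = sample(1:4, 1))
    expect_gte(repair_correction_M(rp), repair_g(rp$mu * rp$tau_r))
  }
  # default published schedule, frozen regression value
  expect_equal(repair_correction_M(radio_params()), 1.0976053,
               tolerance = 1e-6)
})

test_that("effective radiation is the n-fraction LQ effect", {
  expect_equal(effective_radiation(radio_params(dose = 1e-300)), 0,
               tolerance = 1e-12)
  rp <- radio_params(beta_s = 1e-10, dose = 0.5)
  expect_equal(effective_radiation(rp), rp$alpha_s * 2 * 0.5,
               tolerance = 1e-6)
  doses <- seq(0.01, 2, by = 0.01)
  reff <- sapply(doses,
                 function(d) effective_radiation(radio_params(dose = d)))
  expect_true(all(diff(reff) > 0))
})

test_that("radiation switch respects schedule and gating", {
  rp <- radio_params(gating = "fraction")
  day <- 1 / 365
  expect_equal(radiation_switch(-0.1, rp, t_start = 0), 0)
  expect_equal(radiation_switch(rp$tau_r / 2, rp), 1)       # 1st window
  expect_equal(radiation_switch(rp$tau_r * 2, rp), 0)       # gap
  expect_equal(radiation_switch(rp$delta_tau_r + rp$tau_r / 2, rp), 1)
  expect_equal(radiation_switch(2 * rp$delta_tau_r + rp$tau_r / 2, rp),
               0)                                           # only n = 2
  # irradiated fraction of one treatment day is n tau_r
  tt <- seq(0, day, by = rp$tau_r / 20)
  expect_equal(mean(radiation_switch(tt, rp)) * day,
               rp$n_per_day * rp$tau_r, tolerance = 0.1)
  # day gating: on through treatment days, off on the weekend
  rpd <- radio_params(gating = "day")
  expect_equal(radiation_switch(0.5 * day, rpd), 1)
  expect_equal(radiation_switch(5.5 * day, rpd), 0)
  expect_equal(radiation_switch(7.5 * day, rpd), 1)
  expect_equal(radiation_switch(1, rpd, duration = 0.5), 0)
  expect_error(radio_params(tau_r = 1e-3, delta_tau_r = 1e-4),
               "non-overlapping")
})

test_that("late-tissue BED", {
  expect_equal(bed_late(radio_params(dose = 1e-300)), 0,
               tolerance = 1e-12)
  rp <- radio_params(tau_r = 1e-10, delta_tau_r = 1e-9, n_per_day = 1,
                     theta_late = 3, dose = 3)
  expect_equal(bed_late(rp), 2 * 3 * 1, tolerance = 1e-6)  # M ~ 1
  d <- seq(0.1, 3, by = 0.1)
  b <- sapply(d, function(x) bed_late(radio_params(dose = x)))
  expect_true(all(diff(b) > 0))
  expect_true(all(diff(diff(b)) > 0))  # convex
})

test_that("tumor BED: equivalence of the two forms and clamping", {
  set.seed(23)
  for (i in 1:20) {
    rp <- radio_params(dose = runif(1, 0.1, 3),
                       n_per_day = sample(1:40, 1),
                       theta_late = runif(1, 1, 4),
                       theta_can = runif(1, 5, 12),
                       K = runif(1, 0.05, 0.5))
    T <- rp$f * rp$n_per_day - 1  # schedule relation
    expect_equal(bed_cancer(rp, T = T, form = "direct"),
                 bed_cancer(rp, T = T, form = "late-tissue"),
                 tolerance = 1e-10)
  }
  # K = 0 mirrors the late form with the tumor ratio
  rp <- radio_params(K = 1e-300, dose = 1.4)
  expect_equal(bed_cancer(rp),
               rp$n_per_day * 1.4 * (1 + 1.4 / rp$theta_can) *
                 repair_correction_M(rp), tolerance = 1e-10)
  # repopulation does not apply before it starts
  rp <- radio_params(dose = 1, T = 30, T_d = 40)
  expect_equal(bed_cancer(rp), bed_cancer(radio_params(dose = 1, T = 40)))
})

test_that("log cell kill is alpha_s times the tumor BED", {
  set.seed(5)
  for (i in 1:10) {
    rp <- radio_params(dose = runif(1, 0.1, 3), T = runif(1, 20, 60))
    expect_equal(log_cell_kill_E(rp), rp$alpha_s * bed_cancer(rp),
                 tolerance = 1e-12)
  }
  # LQ core: instantaneous fractions, full inter-fraction repair,
  # no repopulation
  rp <- radio_params(tau_r = 1e-10, delta_tau_r = 0.01, K = 1e-300,
                     dose = 2)
  expect_equal(log_cell_kill_E(rp),
               rp$alpha_s * rp$n_per_day * 2 + rp$beta_s *
                 rp$n_per_day * 4, tolerance = 1e-6)
})

test_that("optimum dose zeroes the quadratic and maximises tumor BED", {
  rp <- radio_params()
  D <- optimum_dose(rp)
  a <- 1 - rp$theta_late / rp$theta_can
  M <- repair_correction_M(rp)
  expect_lt(abs(a * M * D^2 - 2 * rp$K * rp$f * D -
                  rp$K * rp$f * rp$theta_late), 1e-10)
  # K -> 0 drives the optimum to 0
  expect_lt(optimum_dose(radio_params(K = 1e-12)), 1e-5)
  # brute-force check: D maximises BED_can over doses at fixed BED_late
  # (repopulation active, the regime the quadratic is derived in)
  BL <- bed_late(rp, n = 1, dose = D)
  dgrid <- seq(0.05, 10, by = 0.005)
  bed_at <- function(d) {
    n <- BL / (d * (1 + d / rp$theta_late) * M)  # fixed late effect
    T <- rp$f * n - 1
    n * d * (1 + d / rp$theta_can) * M - rp$K * (T - rp$T_d)
  }
  expect_equal(dgrid[which.max(sapply(dgrid, bed_at))], D,
               tolerance = 0.01)
  expect_error(optimum_dose(radio_params(theta_late = 8)),
               "no finite optimum")
  # the published closed form differs (repair factor missing in the root)
  expect_gt(abs(optimum_dose(rp, form = "as-printed") - D), 1e-3)
})

test_that("TCP is a proper dose-response probability", {
  rp <- radio_params(dose = 1)
  expect_equal(tcp(rp, density = 0, volume = 80000)$tcp, 1)
  # no dose: pure Poisson with the initial clonogen number
  rp0 <- radio_params(dose = 1e-300, K = 1e-300)
  tc <- tcp(rp0, density = 0.000805, volume = 80000)
  expect_equal(tc$N, 64.4)
  expect_equal(tc$tcp, exp(-64.4 * exp(0)), tolerance = 1e-6)
  # monotone in dose, ordered in volume
  cur <- tcp_curve(radio_params(), doses = seq(0, 2, by = 0.05))
  small <- cur[cur$volume == 80000, ]
  big <- cur[cur$volume == 250000, ]
  expect_true(all(diff(small$tcp) >= 0))
  expect_true(all(big$tcp <= small$tcp))
  expect_true(all(cur$tcp > 0 & cur$tcp <= 1))
})

test_that("sensitivity scan spans schedule conventions", {
  sc <- bed_sensitivity_scan()
  expect_s3_class(sc, "data.frame")
  expect_true(all(c("tau_r", "delta_tau_r", "n", "form", "M", "D_opt",
                    "bed_can") %in% names(sc)))
  expect_gt(nrow(sc), 20)
  expect_true(all(is.finite(sc$D_opt)))
})
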