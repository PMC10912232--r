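test_that("jacobian at E2 carries the printed entry structure", {
  p <- prostate()
  ksq <- 2
  J <- jacobian_at_E2(p, m2 = 0.08, ksq = ksq)
  S2 <- -p$S0 * log(p$alpha * 0.08 / p$gamma)
  D2 <- S2 / p$d
  w <- (2 * p$d * D2 / p$sigma) * (1 - p$d / p$q0)
  # row 3 couples only to itself
  expect_equal(J$A[3, ], c(0, 0, -p$alpha - p$Da * ksq, 0))
  expect_equal(J$A[4, 1], -(p$alpha / p$S0) * 0.08)
  expect_equal(J$B[1, 2], p$d)
  expect_equal(J$B[1, 4], w)
  expect_true(all(J$B[-1, ] == 0) && J$B[1, 1] == 0 && J$B[1, 3] == 0)
  # stability at tau = 0, k = 0 (d < q0 and m2 < gamma/alpha)
  J0 <- jacobian_at_E2(p, m2 = 0.08, ksq = 0)
  expect_true(all(Re(eigen(J0$A + J0$B)$values) < 0))
  expect_error(jacobian_at_E2(p, m2 = 4), "invalid E2")
})

test_that("characteristic coefficients match the numeric determinant", {
  set.seed(42)
  tau <- 0.37
  for (mk in list(prostate, lung, breast)) {
    p <- mk()
    for (i in 1:20) {
      ksq <- runif(1, 0, 5)
      l <- complex(real = runif(1, -2, 2), imaginary = runif(1, -3, 3))
      J <- jacobian_at_E2(p, m2 = 0.08, ksq = ksq)
      cf <- char_from_matrices(J$A, J$B, ksq = ksq)
      M <- J$A + J$B * exp(-l * tau) - l * diag(4)
      expect_equal(char_poly(cf, l, tau), cdet(M),
                   tolerance = 1e-8)
    }
  }
})

test_that("the quartic factors through lambda + alpha + Da k^2", {
  for (mk in list(prostate, lung, breast)) {
    p <- mk()
    for (ksq in c(0, 0.5, 3)) {
      cf <- char_coefficients(p, m2 = 0.08, ksq = ksq)
      root <- p$alpha + p$Da * ksq
      expect_lt(abs(lin_div_remainder(cf$C_poly, root)), 1e-10)
      expect_lt(abs(lin_div_remainder(cf$E_poly, root)), 1e-10)
    }
  }
})

test_that("zero delayed part yields zero E coefficients", {
  J <- jacobian_at_E2(prostate(), m2 = 0.08)
  B0 <- J$B * 0
  cf <- char_from_matrices(J$A, B0)
  expect_equal(c(cf$E11, cf$E22, cf$E33), c(0, 0, 0))
  # and delayed entries outside row 1 are rejected
  Bbad <- J$B * 0
  Bbad[2, 2] <- 1
  expect_error(char_from_matrices(J$A, Bbad), "row 1")
})

test_that("omega roots solve the z-quartic; absence is reported", {
  cf <- char_coefficients(breast(), m2 = 0.08)
  oms <- omega_roots(cf)
  expect_gt(length(oms), 0)
  zc <- c(cf$C44^2 - cf$E33^2,
          cf$C33^2 + 2 * cf$E11 * cf$E33 - 2 * cf$C22 * cf$C44 -
            cf$E22^2,
          cf$C22^2 + 2 * cf$C44 - 2 * cf$C11 * cf$C33 - cf$E11^2,
          cf$C11^2 - 2 * cf$C22, 1)
  for (om in oms) {
    z <- om^2
    val <- sum(zc * z^(0:4))
    expect_lt(abs(val), 1e-6 * max(abs(zc * z^(0:4))))
  }
  # the prostate set admits no purely imaginary crossing at any mode
  expect_length(omega_roots(char_coefficients(prostate(), m2 = 0.08)), 0)
})

test_that("delay branches satisfy the crossing trigonometry", {
  cf <- char_coefficients(lung(), m2 = 0.5)
  om <- omega_roots(cf)[1]
  taus <- critical_delays(cf, om, j_max = 3)
  # independent solve of the 2x2 linear system for (cos, sin)
  A <- cf$E33 - cf$E11 * om^2
  B <- cf$E22 * om
  R1 <- cf$C22 * om^2 - cf$C44 - om^4
  R2 <- cf$C11 * om^3 - cf$C33 * om
  cs <- solve(matrix(c(A, B, B, -A), 2, 2, byrow = TRUE), c(R1, R2))
  den <- A^2 + B^2
  Z22 <- cs[1] * den
  Z11 <- cs[2] * den
  for (tau in taus) {
    expect_equal(cos(om * tau), Z22 / den, tolerance = 1e-8)
    expect_equal(sin(om * tau), Z11 / den, tolerance = 1e-8)
    # a branch delay is a genuine root of the characteristic equation
    expect_lt(Mod(char_poly(cf, complex(imaginary = om), tau)),
              1e-6 * max(1, abs(cf$C44)))
  }
  expect_equal(diff(taus), rep(2 * pi / om, 3))
  # first-quadrant case reduces to the plain arctangent
  if (Z11 > 0 && Z22 > 0)
    expect_equal(taus[1], atan(Z11 / Z22) / om)
})

test_that("transversality sign agrees with root continuation", {
  cfs <- list(char_coefficients(lung(), m2 = 0.5),
              char_coefficients(breast(), m2 = 0.08),
              char_coefficients(csc_params(q0 = 80, d = 40), m2 = 0.05))
  checked <- 0
  for (cf in cfs) {
    for (om in omega_roots(cf)) {
      tau0 <- critical_delays(cf, om)[1]
      sg <- transversality(cf, om, tau0)
      # finite-difference oracle: continue the root across the crossing
      d <- 1e-3 * max(1, tau0)
      lm <- char_root_near(cf, tau0 - d, complex(imaginary = om))
      lp <- char_root_near(cf, tau0 + d, complex(imaginary = om))
      expect_equal(sign(Re(lp) - Re(lm)), sg)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 2)
  # first crossing reached from the stable zero-delay regime
  # destabilises: positive transversality
  cf <- char_coefficients(breast(), m2 = 0.08)
  om <- omega_roots(cf)[1]
  expect_equal(transversality(cf, om, critical_delays(cf, om)[1]), 1)
  # sign is scale-invariant in the coefficients of the derivative forms:
  # doubling all E and C coefficients leaves the sign unchanged
  cf2 <- cf
  for (nm in c("C11", "C22", "C33", "C44", "E11", "E22", "E33"))
    cf2[[nm]] <- 2 * cf[[nm]]
  expect_equal(transversality(cf2, om, critical_delays(cf, om)[1]),
               transversality(cf, om, critical_delays(cf, om)[1]))
})

test_that("critical delay minimises admissible crossings over modes", {
  p <- lung()
  h <- critical_delay(p, m2 = 0.5)
  expect_s3_class(h, "hopf_result")
  expect_true(is.finite(h$tau_c))
  expect_true(all(h$crossings$sign %in% c(-1, 1)))
  # independent check at the minimising mode: modulus-condition search
  cf <- char_coefficients(p, m2 = 0.5, ksq = h$ksq_at_min)
  expect_equal(h$tau_c, modulus_tau0(cf), tolerance = 1e-6)
  # tau_c is not lowered by scanning higher branches
  h3 <- critical_delay(p, m2 = 0.5, j_max = 3)
  expect_equal(h3$tau_c, h$tau_c)
  # the prostate set reports delay-independent stability
  h0 <- critical_delay(prostate(), m2 = 0.08)
  expect_true(is.na(h0$tau_c))
  expect_match(h0$message, "no Hopf bifurcation")
  expect_error(critical_delay(csc_params(q0 = 80, d = 87.2), m2 = 0.08),
               "not stable at tau = 0")
})

test_that("rightmost root crosses the axis at the critical delay", {
  cf <- char_coefficients(lung(), m2 = 0.5, ksq = 0)
  om <- omega_roots(cf)[1]
  tau_c <- critical_delays(cf, om)[1]
  lm <- char_root_near(cf, 0.95 * tau_c, complex(imaginary = om))
  lp <- char_root_near(cf, 1.05 * tau_c, complex(imaginary = om))
  expect_lt(Re(lm), 0)
  expect_gt(Re(lp), 0)
})
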