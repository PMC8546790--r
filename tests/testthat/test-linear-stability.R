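test_that("eigenvalues at E0 and E1 are delay-independent and match the closed forms", {
  p <- p_free()
  expect_equal(jacobian_point_eigs(p, "E0"),
               c(lambda_x = -1, lambda_y = -0.6, lambda_z = 0.7))
  expect_equal(jacobian_point_eigs(p, "E1"),
               c(lambda_x = -1, lambda_y = -0.6,
                 lambda_z = -(0.5 - 0.42) / 0.6))
  # in the coexistence regime E1 is unstable through the z-direction
  expect_equal(unname(jacobian_point_eigs(p_osc(), "E1")[3]), (6 - 4) / 0.6,
               tolerance = 1e-12)

  # the closed forms agree with the numeric spectrum of J0 + J1 (the delay
  # factors multiply zero entries at these points, so e^{-lambda delta} -> 1
  # is exact)
  for (pt in c("E0", "E1")) {
    jb <- tidelay:::jacobian_blocks(p, at = pt)
    ev <- sort(Re(eigen(jb$J0 + jb$J1, only.values = TRUE)$values))
    expect_equal(ev, sort(unname(jacobian_point_eigs(p, pt))),
                 tolerance = 1e-12)
  }
})

test_that("characteristic coefficients match direct substitution", {
  cc <- char_coeffs(p_sw())
  expect_equal(cc[c("A", "B", "C", "D", "E", "F")],
               list(A = -5.4, B = 7, C = -10.6, D = 11.1, E = -4.2, F = 4.9),
               tolerance = 1e-12)
  cc2 <- char_coeffs(p_osc())
  expect_equal(cc2$B, 10)
  expect_equal(cc2$E, -6)
  expect_equal(cc2$F, 6 + 0.3 * 10 * (2 / 3), tolerance = 1e-12)
  expect_error(char_coeffs(p_esc()), "E2 does not exist")
})

test_that("F + E > 0, p2 < 0, and G = (a2a4 - a3)^2/(a1a4) whenever E2 exists", {
  set.seed(404)
  for (p in draw_params(300, require_e2 = TRUE)) {
    cc <- char_coeffs(p)
    expect_gt(cc$F + cc$E, 0)
    expect_gt(cc$F, abs(cc$E))
    expect_equal(cc$G, (p$a2 * p$a4 - p$a3)^2 / (p$a1 * p$a4),
                 tolerance = 1e-9)
  }
})

test_that("Routh-Hurwitz margins reproduce the reduced-form arithmetic", {
  rh <- routh_hurwitz(p_sw())
  expect_equal(rh$margin, 1.6 * 0.5 - 0.7, tolerance = 1e-12)
  expect_true(rh$stable)
  rh2 <- routh_hurwitz(p_osc())
  expect_equal(rh2$cond1 * (char_coeffs(p_osc())$C + char_coeffs(p_osc())$D),
               1.6 * 0.4, tolerance = 1e-12)
  expect_false(rh2$stable)
  # conditions 1 and 2 hold automatically whenever E2 exists
  set.seed(505)
  for (p in draw_params(200, require_e2 = TRUE)) {
    rh <- routh_hurwitz(p)
    expect_gt(rh$cond1, 0)
    expect_gt(rh$cond2, 0)
  }
})

test_that("crossing frequencies solve the auxiliary cubic, verified against a companion matrix", {
  cf <- crossing_frequencies(p_sw())
  expect_equal(c(cf$p0, cf$p1, cf$p2), c(1.36, 12.39, -6.37),
               tolerance = 1e-12)
  # independent root oracle: eigenvalues of the companion matrix of
  # u^3 + p0 u^2 + p1 u + p2
  comp <- matrix(c(0, 0, -cf$p2,
                   1, 0, -cf$p1,
                   0, 1, -cf$p0), 3, 3)
  ev <- eigen(comp, only.values = TRUE)$values
  u_ref <- Re(ev[abs(Im(ev)) < 1e-9 & Re(ev) > 0])
  expect_equal(sort(cf$u_roots), sort(u_ref), tolerance = 1e-9)
  expect_equal(cf$m0, 0.6927633, tolerance = 1e-6)
  # cubic residual at the returned frequencies
  expect_lt(max(abs(cf$m0^6 + cf$p0 * cf$m0^4 + cf$p1 * cf$m0^2 + cf$p2)), 1e-9)

  cf2 <- crossing_frequencies(p_osc())
  expect_equal(cf2$p2, 36 - 64, tolerance = 1e-12)
})

test_that("critical delays satisfy the crossing system exactly", {
  cr <- critical_delays(p_sw(), k_max = 3)
  expect_equal(cr$delta0, 0.0127526, tolerance = 1e-5)
  expect_equal(cr$omega0, 0.6927633, tolerance = 1e-6)
  # trigonometric identity from the exact 2x2 solve
  expect_lt(max(abs(cr$cos_theta^2 + cr$sin_theta^2 - 1)), 1e-9)
  # every tabulated (m0, k, delta) is a root of the reduced quasi-polynomial
  expect_lt(max(cr$delta_table$residual), 1e-8)
  # branch spacing 2 pi / m0
  d <- cr$delta_table
  for (m in unique(d$m0))
    expect_equal(diff(d$delta[d$m0 == m]), rep(2 * pi / m, 3),
                 tolerance = 1e-9)
  expect_equal(2 * pi / cr$omega0, 9.069743, tolerance = 1e-6)

  # both real and imaginary crossing equations hold at (m0, delta0)
  cc <- char_coeffs(p_sw())
  m0 <- cr$omega0
  K1 <- cc$F - cc$B * m0^2; K2 <- cc$D * m0
  cth <- cos(m0 * cr$delta0); sth <- sin(m0 * cr$delta0)
  expect_equal(cc$A * m0^2 - cc$E, K1 * cth + K2 * sth, tolerance = 1e-8)
  expect_equal(m0^3 - cc$C * m0, K2 * cth - K1 * sth, tolerance = 1e-8)
})

test_that("the refined crossing solves the full characteristic equation", {
  cr <- critical_delays(p_sw())
  expect_true(cr$refined)
  cc <- char_coeffs(p_sw())
  expect_lt(abs(char_function(cc, 1i * cr$omega_star, cr$delta_star,
                              char = "full")), 1e-10)
  # the second-harmonic term moves the threshold upward here
  expect_gt(cr$delta_star, cr$delta0)
})

test_that("transversality is +1 at the crossing and matches root tracking", {
  cr <- critical_delays(p_sw())
  expect_identical(transversality(p_sw(), cr$omega0), 1L)
  expect_error(transversality(p_sw(), 0), "positive")
  # finite-difference sign of the tracked root across delta0
  lo <- rightmost_roots(p_sw(), cr$delta0 - 1e-3)
  hi <- rightmost_roots(p_sw(), cr$delta0 + 1e-3)
  expect_identical(sign(hi$re[1] - lo$re[1]), 1)
  # p2 < 0 forces F^2 > E^2, so p0 >= 0 gives Pi = +1 without further work
  set.seed(606)
  for (p in draw_params(100, require_e2 = TRUE)) {
    cf <- crossing_frequencies(p)
    if (cf$p0 >= 0)
      for (m in cf$m0) expect_identical(transversality(p, m), 1L)
  }
})

test_that("rightmost roots honor their residual contract and known limits", {
  p <- p_sw()
  # delta = 0: the reduced quasi-polynomial degenerates to its cubic
  rr0 <- rightmost_roots(p, 0)
  cc <- char_coeffs(p)
  ref <- polyroot(c(cc$E + cc$F, cc$C + cc$D, cc$A + cc$B, 1))
  ref <- ref[Im(ref) > -1e-9]
  got <- complex(real = rr0$re, imaginary = rr0$im)
  expect_equal(sort(Re(got)), sort(Re(ref)), tolerance = 1e-9)
  expect_lt(max(rr0$residual), 1e-8)

  # at the critical delay a root sits on the imaginary axis at m0
  cr <- critical_delays(p)
  rr <- rightmost_roots(p, cr$delta0)
  expect_lt(abs(rr$re[1]), 1e-6)
  expect_equal(rr$im[1], cr$omega0, tolerance = 1e-6)

  # the full variant at delta = 0 reproduces the exact Jacobian spectrum
  jb <- tidelay:::jacobian_blocks(p, at = "E2")
  ev <- eigen(jb$J0 + jb$J1, only.values = TRUE)$values
  ev <- ev[Im(ev) > -1e-9]
  rrf <- rightmost_roots(p, 0, char = "full")
  expect_equal(sort(rrf$re), sort(Re(ev)), tolerance = 1e-8)
  expect_equal(sort(rrf$im), sort(Im(ev)), tolerance = 1e-8)

  # the reduced and full constant terms differ by exactly G
  expect_equal(abs(char_function(cc, 0, 0) - char_function(cc, 0, 0, "full")),
               cc$G, tolerance = 1e-12)
})

test_that("the closed-form root derivative agrees with implicit differentiation", {
  p <- p_sw()
  cr <- critical_delays(p)
  lp_closed <- lambda_prime_closed_form(p, cr$omega0, cr$delta0)
  lp_impl <- lambda_prime_crossing(p, cr$omega0, cr$delta0, char = "reduced")
  expect_equal(lp_closed, lp_impl, tolerance = 1e-8)
  # finite difference of the tracked reduced-form root
  h <- 1e-5
  lo <- rightmost_roots(p, cr$delta0 - h)
  hi <- rightmost_roots(p, cr$delta0 + h)
  fd <- complex(real = (hi$re[1] - lo$re[1]) / (2 * h),
                imaginary = (hi$im[1] - lo$im[1]) / (2 * h))
  expect_equal(Re(fd), Re(lp_closed), tolerance = 0.01)
  expect_equal(Im(fd), Im(lp_closed), tolerance = 0.01)
})
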