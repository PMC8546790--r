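nf <- suppressWarnings(hopf_normal_form(p_sw()))

test_that("eigenvectors satisfy their defining systems and the bilinear identities", {
  expect_lt(nf$residuals$right, 1e-10)
  expect_lt(nf$residuals$left, 1e-10)
  expect_lt(nf$residuals$ip_vv, 1e-9)     # <v*, v> = 1
  expect_lt(nf$residuals$ip_vvbar, 1e-9)  # <v*, vbar> = 0
  expect_lt(nf$residuals$E1, 1e-10)
  expect_lt(nf$residuals$E2, 1e-10)
  # v1 closed form is exact (it is the row-2 solve)
  p <- p_sw()
  expect_equal(nf$v1, p$a1 / (p$a2 + 1i * nf$omega0), tolerance = 1e-12)
})

test_that("the printed v2 and v2* forms are flagged as inconsistent with the solve", {
  expect_warning(hopf_normal_form(p_sw(), warn = TRUE), "printed closed form")
  # the recorded deviations are material, not roundoff
  expect_gt(nf$printed_checks$v2, 1e-8)
  expect_gt(nf$printed_checks$v2s, 1e-8)
})

test_that("classification numbers are real and mutually consistent", {
  expect_equal(nf$beta2, 2 * Re(nf$c1), tolerance = 1e-15)
  expect_true(all(is.finite(c(nf$mu2, nf$beta2, nf$T2))))
  # Pi = +1 here, so mu2 > 0 forces Re c1 < 0 and hence a stable cycle
  expect_gt(Re(nf$lambda_prime), 0)
  expect_gt(nf$mu2, 0)
  expect_lt(nf$beta2, 0)
  expect_identical(nf$classification$direction, "supercritical")
  expect_identical(nf$classification$cycle, "stable")
  expect_identical(nf$classification$period_trend,
                   if (nf$T2 > 0) "increasing" else "decreasing")
  expect_identical(classify_hopf(nf), nf$classification)
})

test_that("the crossing pair is refined onto the full characteristic function", {
  expect_equal(nf$omega0_printed, 0.6927633, tolerance = 1e-6)
  expect_equal(nf$delta_k_printed, 0.0127526, tolerance = 1e-5)
  cc <- char_coeffs(p_sw())
  expect_lt(abs(char_function(cc, 1i * nf$omega0, nf$delta_k, char = "full")),
            1e-10)
  # unrefined computation keeps the printed pair but carries an O(G)
  # eigen-residual from the dropped second-harmonic term
  nf0 <- suppressWarnings(hopf_normal_form(p_sw(), refine = FALSE))
  expect_equal(nf0$delta_k, nf0$delta_k_printed)
  expect_gt(nf0$residuals$right, 1e-6)
})

test_that("lambda'(Delta_k) matches a finite difference of the tracked root", {
  h <- 1e-5
  lo <- rightmost_roots(p_sw(), nf$delta_k - h, char = "full")
  hi <- rightmost_roots(p_sw(), nf$delta_k + h, char = "full")
  fd_re <- (hi$re[1] - lo$re[1]) / (2 * h)
  fd_im <- (hi$im[1] - lo$im[1]) / (2 * h)
  expect_equal(fd_re, Re(nf$lambda_prime), tolerance = 0.01)
  expect_equal(fd_im, Im(nf$lambda_prime), tolerance = 0.01)
})

test_that("second-order center-manifold values use the corrected constant vectors", {
  # W20(-1) and W11(-1) are assembled from E1vec/E2vec plus the resonant
  # eigenvector parts; re-derive them independently here
  w <- nf$omega0; dk <- nf$delta_k; th <- w * dk
  v <- c(1, nf$v1, nf$v2)
  W20 <- (1i * nf$g20 / (w * dk)) * v * exp(-1i * th) +
    (1i * Conj(nf$g02) / (3 * w * dk)) * Conj(v) * exp(1i * th) +
    nf$E1vec * exp(-2i * th)
  W11 <- (-1i * nf$g11 / (w * dk)) * v * exp(-1i * th) +
    (1i * Conj(nf$g11) / (w * dk)) * Conj(v) * exp(1i * th) + nf$E2vec
  expect_equal(W20, nf$W20m1, tolerance = 1e-12)
  expect_equal(W11, nf$W11m1, tolerance = 1e-12)
  # E2vec is real (it solves a real system with a real right-hand side)
  expect_true(is.numeric(nf$E2vec))
})
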