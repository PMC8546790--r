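#' Center-manifold normal form of the delay-induced Hopf bifurcation
#'
#' At a critical delay the characteristic equation has a simple pair of
#' purely imaginary roots and the flow on the two-dimensional center
#' manifold reduces, after a Hassard-style computation, to the normal form
#' whose first Lyapunov quantity is
#' \deqn{c_1(0) = \frac{i}{2\Delta_k\omega_0}\left(g_{11}g_{20}
#'   - 2|g_{11}|^2 - \frac{|g_{02}|^2}{3}\right) + \frac{g_{21}}{2}.}
#' The classification numbers are `mu2 = -Re c1(0) / Re lambda'(Delta_k)`
#' (bifurcation direction: supercritical iff `mu2 > 0`),
#' `beta2 = 2 Re c1(0)` (cycle stability: stable iff `beta2 < 0`), and
#' `T2 = -(Im c1(0) + mu2 * Im lambda'(Delta_k)) / (Delta_k * omega0)`
#' (period trend: increasing iff `T2 > 0`).
#'
#' The computation needs an *exact* crossing pair: with `refine = TRUE`
#' (default) the reduced-form estimate `(m0, Delta_k)` from
#' [critical_delays()] is Newton-refined to the nearby exact crossing of
#' the full characteristic function, after which the eigenvector systems
#' are consistent to machine precision. With `refine = FALSE` the printed
#' pair and the reduced characteristic function are used as-is; the
#' eigenvector residuals then reflect the dropped second-harmonic term.
#'
#' Eigenvectors `v(theta) = (1, v1, v2)^T exp(i*omega0*Delta_k*theta)` and
#' the adjoint `v*` are obtained by direct linear solves on the
#' characteristic matrix and its transpose (first component normalized to
#' 1); the printed closed forms are evaluated as cross-checks and any
#' disagreement beyond `1e-8` is recorded in `printed_checks` (and warned
#' about when `warn = TRUE`), with the direct solve taking precedence. The
#' quadratic and cubic coefficients of the nonlinearity are Taylor
#' coefficients of the actual right-hand side at E2:
#' `u2*u3/(1+zh)^2 - yh*u3^2/(1+zh)^3` plus cubic terms for the first
#' component, and exactly `-u2*u3` for the third. The constant vectors of
#' the second-order terms solve
#' `(2i*omega0*I - J0 - J1*exp(-2i*omega0*Delta_k)) E1vec = F20` and
#' `(J0 + J1) E2vec = -F11`, where `F20`, `F11` are the `z^2` and `z*zbar`
#' coefficient vectors of the nonlinearity; the bilinear pairing is
#' evaluated through its single delayed-point correction term (the
#' spectral measure is concentrated at `theta = 0` and `theta = -1`), with
#' no quadrature.
#'
#' @param p a [ti_params()] object with `E2` existing.
#' @param k branch index of the critical delay (default 0, the first
#'   crossing).
#' @param refine refine the crossing pair on the full characteristic
#'   function (default `TRUE`).
#' @param warn warn when a printed closed form disagrees with the direct
#'   solve (default `TRUE`).
#' @return An object of class `ti_hopf`: list with the crossing pair
#'   (`omega0`, `delta_k`, plus the unrefined `omega0_printed`,
#'   `delta_k_printed`), eigenvector components `v1`, `v2`, `v1s`, `v2s`,
#'   normalization `Dbar`, coefficients `g20`, `g11`, `g02`, `g21`,
#'   constant vectors `E1vec`, `E2vec`, center-manifold values `W20m1`,
#'   `W11m1` (at `theta = -1`), `c1`, `lambda_prime`, the real
#'   classification numbers `mu2`, `beta2`, `T2`, the `classification`
#'   list (`direction`, `cycle`, `period_trend`), residual diagnostics,
#'   and `printed_checks`.
#' @examples
#' \donttest{
#' nf <- hopf_normal_form(ti_params(0.4, 0.6, 3.5, 7.0))
#' nf$classification
#' }
#' @export
hopf_normal_form <- function(p, k = 0, refine = TRUE, warn = TRUE) {
  cc <- if (inherits(p, "ti_charcoeffs")) p else char_coeffs(p)
  p <- cc$params
  cr <- critical_delays(cc, k_max = max(3, k))
  m0 <- cr$omega0
  dk_printed <- cr$delta_table$delta[cr$delta_table$m0 == m0 &
                                       cr$delta_table$k == k]
  if (!length(dk_printed))
    stop("no critical delay tabulated for branch index k = ", k, call. = FALSE)
  if (refine) {
    ref <- refine_crossing(cc, m0, dk_printed)
    if (!ref$converged)
      stop("refinement of the crossing pair did not converge", call. = FALSE)
    w <- ref$omega; dk <- ref$delta
    char_used <- "full"
  } else {
    w <- m0; dk <- dk_printed
    char_used <- "reduced"
  }
  yh <- cc$point[["y"]]; zh <- cc$point[["z"]]
  jb <- jacobian_blocks(p, at = cc$point)
  J0 <- jb$J0; J1 <- jb$J1
  th <- w * dk
  eE <- exp(-1i * th)
  M <- J0 + J1 * eE - 1i * w * diag(3)

  # right eigenvector (1, v1, v2): rows 2 and 3 determine the components,
  # row 1 is the characteristic condition and must vanish at an exact crossing
  v1 <- p$a1 / (p$a2 + 1i * w)
  v2 <- zh * eE * v1 / (p$a4 - 1i * w - yh * eE)
  v <- c(1, v1, v2)
  res_right <- max(abs(M %*% v))
  # adjoint (left) eigenvector: (1, conj(v1s), conj(v2s)) is a left null
  # vector of M
  w1b <- (1 + 1i * w) / p$a1                       # = conj(v1*)
  w2b <- -(yh / (1 + zh)^2) * eE / (p$a4 - 1i * w - yh * eE)  # = conj(v2*)
  u <- c(1, w1b, w2b)
  res_left <- max(abs(t(u) %*% M))
  if (refine && max(res_right, res_left) > 1e-6)
    stop(sprintf("eigenvector residual %.3g exceeds 1e-6 at the refined crossing",
                 max(res_right, res_left)), call. = FALSE)

  # printed closed forms as cross-checks
  v2_printed <- -p$a1 * zh * eE / ((p$a2 + 1i * w) * (1i * w + yh * eE))
  v2s_printed <- -yh / ((1 + yh)^2 * (1i * w - yh * exp(-1i * th)) * exp(-1i * th))
  printed_checks <- list(
    v1 = 0,                                        # row-2 solve is the printed form
    v2 = abs(v2 - v2_printed),
    v2s = abs(Conj(w2b) - v2s_printed))
  if (warn) {
    bad <- names(printed_checks)[vapply(printed_checks, function(d) d > 1e-8, TRUE)]
    if (length(bad))
      warning("printed closed form(s) ", paste(bad, collapse = ", "),
              " disagree with the direct eigenvector solve; ",
              "the direct solve is used", call. = FALSE)
  }

  Z <- zh / (1 + zh); Y <- yh / (1 + zh)^2
  Dbar <- 1 / ((1 + w1b * v1 + w2b * v2) +
                 dk * eE * (Z * v1 + Y * v2 - zh * w2b * v1 - yh * w2b * v2))
  # bilinear-form identities
  ip_vv <- Dbar * ((1 + w1b * v1 + w2b * v2) +
                     dk * eE * (Z * v1 + Y * v2 - zh * w2b * v1 - yh * w2b * v2))
  ip_vvbar <- Dbar * (sum(u * Conj(v)) -
                        (1 / (2i * w)) *
                        drop(t(u) %*% ((J0 + J1 * eE) -
                                         (J0 + J1 * exp(1i * th))) %*% Conj(v)))

  # Taylor coefficients of the nonlinearity at E2 (first component from
  # y z/(1+z), third component exactly -u2*u3)
  al <- 1 / (1 + zh)^2
  be <- yh / (1 + zh)^3
  ga <- 1 / (1 + zh)^3
  de <- yh / (1 + zh)^4
  a_ <- v1 * eE; b_ <- v2 * eE
  g20 <- 2 * dk * Dbar * ((al - w2b) * a_ * b_ - be * b_^2)
  g11 <- dk * Dbar * ((al - w2b) * (a_ * Conj(b_) + Conj(a_) * b_) -
                        2 * be * Mod(b_)^2)
  g02 <- 2 * dk * Dbar * ((al - w2b) * Conj(a_) * Conj(b_) - be * Conj(b_)^2)

  F20 <- c(2 * (al * a_ * b_ - be * b_^2), 0, -2 * a_ * b_)
  F11 <- c(al * (a_ * Conj(b_) + Conj(a_) * b_) - 2 * be * Mod(b_)^2, 0,
           -(a_ * Conj(b_) + Conj(a_) * b_))
  M1 <- 2i * w * diag(3) - J0 - J1 * exp(-2i * th)
  M2 <- J0 + J1
  if (rcond_cplx(M1) < 1e-12 || rcond(M2) < 1e-12)
    stop(sprintf(
      "resonant second-order system (reciprocal condition numbers %.3g, %.3g)",
      rcond_cplx(M1), rcond(M2)), call. = FALSE)
  E1vec <- solve(M1, F20)
  E2vec <- Re(solve(M2, -F11))
  res_E1 <- max(abs(M1 %*% E1vec - F20))
  res_E2 <- max(abs(M2 %*% E2vec + F11))

  W20m1 <- (1i * g20 / (w * dk)) * v * eE +
    (1i * Conj(g02) / (3 * w * dk)) * Conj(v) / eE +
    E1vec * exp(-2i * th)
  W11m1 <- (-1i * g11 / (w * dk)) * v * eE +
    (1i * Conj(g11) / (w * dk)) * Conj(v) / eE + E2vec

  g21 <- 2 * dk * Dbar *
    ((al - w2b) * (a_ * W11m1[3] + Conj(a_) * W20m1[3] / 2 +
                     b_ * W11m1[2] + Conj(b_) * W20m1[2] / 2) -
       be * (2 * b_ * W11m1[3] + Conj(b_) * W20m1[3]) -
       ga * (2 * a_ * Mod(b_)^2 + Conj(a_) * b_^2) +
       3 * de * Mod(b_)^2 * b_)

  c1 <- (1i / (2 * dk * w)) * (g11 * g20 - 2 * Mod(g11)^2 - Mod(g02)^2 / 3) +
    g21 / 2
  lp <- lambda_prime_crossing(cc, w, dk, char = char_used)
  if (abs(Re(lp)) < 1e-12)
    stop("degenerate Hopf point: Re lambda'(Delta_k) = 0", call. = FALSE)
  mu2 <- -Re(c1) / Re(lp)
  beta2 <- 2 * Re(c1)
  T2 <- -(Im(c1) + mu2 * Im(lp)) / (dk * w)

  structure(list(
    omega0 = w, delta_k = dk, k = k,
    omega0_printed = m0, delta_k_printed = dk_printed,
    refined = refine,
    v1 = v1, v2 = v2, v1s = Conj(w1b), v2s = Conj(w2b), Dbar = Dbar,
    g20 = g20, g11 = g11, g02 = g02, g21 = g21,
    E1vec = E1vec, E2vec = E2vec, W20m1 = W20m1, W11m1 = W11m1,
    c1 = c1, lambda_prime = lp,
    lambda_prime_printed = lambda_prime_closed_form(cc, m0, dk_printed),
    mu2 = mu2, beta2 = beta2, T2 = T2,
    classification = list(
      direction = if (mu2 > 0) "supercritical" else "subcritical",
      cycle = if (beta2 < 0) "stable" else "unstable",
      period_trend = if (T2 > 0) "increasing" else "decreasing"),
    residuals = list(right = res_right, left = res_left,
                     E1 = res_E1, E2 = res_E2,
                     ip_vv = abs(ip_vv - 1), ip_vvbar = abs(ip_vvbar)),
    printed_checks = printed_checks,
    coeffs = cc), class = "ti_hopf")
}

rcond_cplx <- function(M) {
  s <- svd(M, nu = 0, nv = 0)$d
  min(s) / max(s)
}

#' @export
print.ti_hopf <- function(x, ...) {
  cat(sprintf("Hopf bifurcation at delta_k = %.6g (omega0 = %.6g, branch k = %d)\n",
              x$delta_k, x$omega0, x$k))
  if (isTRUE(x$refined))
    cat(sprintf("  (reduced-form estimate: delta = %.6g, omega = %.6g)\n",
                x$delta_k_printed, x$omega0_printed))
  cat(sprintf("  c1(0) = %.6g %+.6gi,  lambda'(Delta_k) = %.6g %+.6gi\n",
              Re(x$c1), Im(x$c1), Re(x$lambda_prime), Im(x$lambda_prime)))
  cat(sprintf("  mu2 = %.6g (%s), beta2 = %.6g (cycle %s), T2 = %.6g (period %s)\n",
              x$mu2, x$classification$direction,
              x$beta2, x$classification$cycle,
              x$T2, x$classification$period_trend))
  invisible(x)
}

#' Theorem-style classification of a computed normal form
#'
#' @param nf a `ti_hopf` object from [hopf_normal_form()].
#' @return List with `direction` (`"supercritical"` iff `mu2 > 0`),
#'   `cycle` (`"stable"` iff `beta2 < 0`), and `period_trend`
#'   (`"increasing"` iff `T2 > 0`).
#' @export
classify_hopf <- function(nf) {
  stopifnot(inherits(nf, "ti_hopf"))
  nf$classification
}
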