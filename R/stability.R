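#' Jacobian blocks of the linearization
#'
#' Splits the Jacobian of the model at a point into the block `J0` acting on
#' the current state and the block `J1` acting on the delayed state, so that
#' the linearization reads `u'(t) = J0 u(t) + J1 u(t - delta)` and the
#' characteristic matrix is `J0 + J1 exp(-lambda*delta) - lambda*I`.
#'
#' @param p a [ti_params()] object.
#' @param at point to linearize about: an equilibrium label or a numeric
#'   `(x, y, z)`.
#' @return List with 3x3 matrices `J0` and `J1`.
#' @keywords internal
jacobian_blocks <- function(p, at = "E2") {
  p <- as_ti_params(p)
  pt <- if (is.character(at)) {
    if (at == "E0") c(0, 0, 0)
    else if (at == "E1") c(0, p$a3 / p$a2, 0)
    else {
      e2 <- equilibrium_point(p, "E2")
      if (is.null(e2)) stop("E2 does not exist for these parameters", call. = FALSE)
      e2
    }
  } else at
  y <- pt[2]; z <- pt[3]
  J0 <- matrix(c(-1, p$a1, 0,
                 0, -p$a2, 0,
                 0, 0, p$a4), 3, 3)
  J1 <- matrix(c(0, 0, 0,
                 z / (1 + z), 0, -z,
                 y / (1 + z)^2, 0, -y), 3, 3)
  list(J0 = J0, J1 = J1, point = pt)
}

#' Eigenvalues at the delay-transparent equilibria E0 and E1
#'
#' At the origin and at the tumor-free equilibrium the delayed Jacobian
#' entries multiply zero state components, so the eigenvalues are
#' delay-independent and real: `(-1, -a2, a4)` at `E0` and
#' `(-1, -a2, -(a3 - a2*a4)/a2)` at `E1`. The `-1` eigenvalue is the one
#' attached to the x-direction (its left eigenvector is the x-axis).
#'
#' @param p a [ti_params()] object.
#' @param which `"E0"` or `"E1"`.
#' @return Named numeric vector of the three eigenvalues
#'   (`lambda_x`, `lambda_y`, `lambda_z`).
#' @examples
#' jacobian_point_eigs(ti_params(0.3, 0.6, 0.5, 0.7), "E1")
#' @export
jacobian_point_eigs <- function(p, which = c("E0", "E1")) {
  p <- as_ti_params(p)
  which <- match.arg(which)
  if (which == "E0")
    c(lambda_x = -1, lambda_y = -p$a2, lambda_z = p$a4)
  else
    c(lambda_x = -1, lambda_y = -p$a2, lambda_z = -(p$a3 - p$a2 * p$a4) / p$a2)
}

#' Coefficients of the characteristic quasi-polynomial at E2
#'
#' Linearizing about the co-axial equilibrium `(xh, yh, zh)` gives the
#' transcendental characteristic equation
#' \deqn{\lambda^3 + (A + B e^{-\lambda\Delta})\lambda^2
#'       + (C + D e^{-\lambda\Delta})\lambda + (E + F e^{-\lambda\Delta})
#'       - G e^{-2\lambda\Delta} = 0,}
#' with `A = 1 + a2 - a4`, `B = yh`, `C = a2 - a4 - a2*a4`,
#' `D = a2*yh + yh - a1*zh/(1+zh)`, `E = -a2*a4`,
#' `F = a1*a4*zh/(1+zh) + a2*yh`, and the second-harmonic coefficient
#' `G = a1*yh*zh^2/(1+zh)^2 = (a2*a4 - a3)^2/(a1*a4)`, which is the 2x2
#' minor of the two delayed Jacobian columns. The six-coefficient truncation
#' (`G` dropped) is the *reduced* characteristic function on which the
#' closed-form crossing analysis ([crossing_frequencies()],
#' [critical_delays()], [transversality()], [delay_length_bound()]) is
#' built; the *full* form including `G` reproduces the exact Jacobian
#' spectrum (at `delta = 0` the two constant terms differ by `G`) and is
#' used wherever agreement with the actual dynamics matters
#' (see [hopf_normal_form()] and the `char` argument of
#' [rightmost_roots()]).
#'
#' When `E2` exists, `F = a2*a4 + a1*a4*zh/(1+zh) > |E|`, hence the
#' auxiliary-cubic constant `p2 = E^2 - F^2` is always negative.
#'
#' @param p a [ti_params()] object with `E2` existing.
#' @return An object of class `ti_charcoeffs`: list with `A`--`G`, the
#'   equilibrium `point`, and `params`.
#' @examples
#' char_coeffs(ti_params(0.4, 0.6, 3.5, 7.0))
#' @export
char_coeffs <- function(p) {
  p <- as_ti_params(p)
  e2 <- equilibrium_point(p, "E2")
  if (is.null(e2))
    stop("E2 does not exist for these parameters (regime ",
         existence_regime(p), ")", call. = FALSE)
  yh <- e2[["y"]]; zh <- e2[["z"]]
  w <- p$a1 * zh / (1 + zh)
  structure(list(
    A = 1 + p$a2 - p$a4,
    B = yh,
    C = p$a2 - p$a4 - p$a2 * p$a4,
    D = p$a2 * yh + yh - w,
    E = -p$a2 * p$a4,
    F = p$a1 * p$a4 * zh / (1 + zh) + p$a2 * yh,
    G = p$a1 * yh * zh^2 / (1 + zh)^2,
    point = e2, params = p), class = "ti_charcoeffs")
}

#' @export
print.ti_charcoeffs <- function(x, ...) {
  cat(sprintf("Characteristic coefficients at E2 = (%.4g, %.4g, %.4g)\n",
              x$point[1], x$point[2], x$point[3]))
  cat(sprintf("  A = %.6g  B = %.6g  C = %.6g\n  D = %.6g  E = %.6g  F = %.6g\n",
              x$A, x$B, x$C, x$D, x$E, x$F))
  cat(sprintf("  second-harmonic coefficient G = %.6g (dropped in the reduced form)\n",
              x$G))
  invisible(x)
}

#' Evaluate the characteristic function
#'
#' @param cc a [char_coeffs()] object (or a [ti_params()] to be converted).
#' @param lambda complex argument (vectorized).
#' @param delta delay at which to evaluate.
#' @param char `"reduced"` for the six-coefficient quasi-polynomial,
#'   `"full"` to include the second-harmonic term `-G exp(-2*lambda*delta)`.
#' @return Complex vector of characteristic-function values.
#' @export
char_function <- function(cc, lambda, delta, char = c("reduced", "full")) {
  if (inherits(cc, "ti_params")) cc <- char_coeffs(cc)
  char <- match.arg(char)
  e <- exp(-lambda * delta)
  v <- lambda^3 + (cc$A + cc$B * e) * lambda^2 + (cc$C + cc$D * e) * lambda +
    cc$E + cc$F * e
  if (char == "full") v <- v - cc$G * e^2
  v
}

# derivative of the characteristic function in lambda
char_function_dlambda <- function(cc, lambda, delta, char = "reduced") {
  e <- exp(-lambda * delta)
  v <- 3 * lambda^2 + 2 * (cc$A + cc$B * e) * lambda + cc$C + cc$D * e -
    delta * e * (cc$B * lambda^2 + cc$D * lambda + cc$F)
  if (char == "full") v <- v + 2 * delta * cc$G * e^2
  v
}

# derivative of the characteristic function in delta
char_function_ddelta <- function(cc, lambda, delta, char = "reduced") {
  e <- exp(-lambda * delta)
  v <- -lambda * e * (cc$B * lambda^2 + cc$D * lambda + cc$F)
  if (char == "full") v <- v + 2 * lambda * cc$G * e^2
  v
}

#' Routh-Hurwitz verdict for E2 without delay
#'
#' For `delta = 0` the reduced characteristic equation is the cubic
#' `lambda^3 + (A+B) lambda^2 + (C+D) lambda + (E+F) = 0`, and E2 is
#' asymptotically stable iff `A+B > 0`, `E+F > 0`, and
#' `(A+B)(C+D) > E+F`. The first two conditions reduce to `1 + a2 > 0` and
#' `a1*a4 > 0` and hold automatically; the binding condition is the third,
#' whose margin `(A+B)(C+D) - (E+F)` is also the coefficient `chi3` of the
#' delay-length bound ([delay_length_bound()]).
#'
#' The exact (untruncated) constant term is `E + F - G`; the corresponding
#' exact margin and verdict are reported alongside so that callers can see
#' when the reduced criterion and the true Jacobian spectrum disagree.
#'
#' @param p a [ti_params()] object with `E2` existing.
#' @return List with `cond1 = A+B`, `cond2 = E+F`,
#'   `margin = (A+B)(C+D) - (E+F)`, the verdict `stable`, and the exact
#'   counterparts `cond2_exact`, `margin_exact`, `stable_exact`.
#' @examples
#' routh_hurwitz(ti_params(0.4, 0.6, 3.5, 7.0))  # stable, margin 0.1
#' @export
routh_hurwitz <- function(p) {
  cc <- if (inherits(p, "ti_charcoeffs")) p else char_coeffs(p)
  cond1 <- cc$A + cc$B
  cond2 <- cc$E + cc$F
  margin <- cond1 * (cc$C + cc$D) - cond2
  cond2_exact <- cond2 - cc$G
  margin_exact <- margin + cc$G
  list(cond1 = cond1, cond2 = cond2, margin = margin,
       stable = cond1 > 0 && cond2 > 0 && margin > 0,
       cond2_exact = cond2_exact, margin_exact = margin_exact,
       stable_exact = cond1 > 0 && cond2_exact > 0 && margin_exact > 0)
}

#' Crossing frequencies of the delayed characteristic equation
#'
#' Substituting `lambda = i*m` (`m > 0`) into the reduced characteristic
#' equation and eliminating the trigonometric terms yields
#' `m^6 + p0*m^4 + p1*m^2 + p2 = 0` with
#' `p0 = A^2 - 2C - B^2`, `p1 = C^2 - 2AE + 2BF - D^2`, `p2 = E^2 - F^2`.
#' Because `F > |E|` whenever E2 exists, `p2 < 0` and the cubic in
#' `u = m^2` always has at least one positive root, so a crossing frequency
#' always exists. Roots are found with the polynomial solver and polished by
#' Newton iteration on the cubic.
#'
#' @param p a [ti_params()] or [char_coeffs()] object.
#' @return List with `p0`, `p1`, `p2`, `u_roots` (real positive roots of
#'   the cubic in `m^2`), and `m0` (their square roots, increasing).
#' @examples
#' crossing_frequencies(ti_params(0.4, 0.6, 3.5, 7.0))  # single m0 ~ 0.693
#' @export
crossing_frequencies <- function(p) {
  cc <- if (inherits(p, "ti_charcoeffs")) p else char_coeffs(p)
  p0 <- cc$A^2 - 2 * cc$C - cc$B^2
  p1 <- cc$C^2 - 2 * cc$A * cc$E + 2 * cc$B * cc$F - cc$D^2
  p2 <- cc$E^2 - cc$F^2
  u <- polyroot(c(p2, p1, p0, 1))
  u <- Re(u[abs(Im(u)) < 1e-8 * (1 + Mod(u))])
  u <- u[u > 0]
  # Newton polish on the cubic
  if (length(u)) {
    for (i in 1:8)
      u <- u - (u^3 + p0 * u^2 + p1 * u + p2) / (3 * u^2 + 2 * p0 * u + p1)
    u <- sort(u)
  }
  list(p0 = p0, p1 = p1, p2 = p2, u_roots = u, m0 = sqrt(u))
}

#' Critical delays and transversality at E2
#'
#' For each crossing frequency `m0`, the real and imaginary parts of the
#' reduced characteristic equation at `lambda = i*m0` form a 2x2 linear
#' system in `cos(m0*delta)` and `sin(m0*delta)`, which is solved exactly;
#' `cos^2 + sin^2 = 1` then holds identically (it is equivalent to the
#' auxiliary cubic) and is checked numerically. The crossing angle is taken
#' with a two-argument arctangent wrapped to `[0, 2*pi)`, avoiding the
#' quadrant ambiguity of the scalar-arctan closed form, and the critical
#' delays are `Delta_k = (angle + 2*pi*k)/m0`, `k = 0..k_max`. `delta0` is
#' the global minimum over all frequencies; by the transversality of the
#' crossing (Pi = +1 whenever E2 exists, see [transversality()]) the
#' equilibrium is asymptotically stable for `delta` in `[0, delta0)` when it
#' is Routh-Hurwitz stable at `delta = 0`, and unstable beyond.
#'
#' Because the reduced characteristic function drops the second-harmonic
#' term, `delta0` is an estimate of the true threshold; the exact crossing
#' `(omega_star, delta_star)` of the full characteristic function is
#' obtained by a two-dimensional Newton refinement seeded at
#' `(m0, delta0)` and reported alongside. Simulated stability switches
#' agree with `delta_star` (see the package vignette).
#'
#' @param p a [ti_params()] or [char_coeffs()] object.
#' @param k_max largest branch index `k` tabulated (default 3).
#' @return An object of class `ti_crossing`: list with the auxiliary-cubic
#'   coefficients, `m0` vector, the `delta_table` data frame
#'   (`m0`, `k`, `delta`, `residual`), `delta0`, `omega0` (frequency
#'   achieving `delta0`), `cos_theta`/`sin_theta`, transversality signs
#'   `pi_sign` per frequency, and the refined pair
#'   `omega_star`, `delta_star` with `refined` flag.
#' @examples
#' critical_delays(ti_params(0.4, 0.6, 3.5, 7.0))  # delta0 ~ 0.01275
#' @export
critical_delays <- function(p, k_max = 3) {
  cc <- if (inherits(p, "ti_charcoeffs")) p else char_coeffs(p)
  cf <- crossing_frequencies(cc)
  if (!length(cf$m0))
    stop("no crossing frequency (cannot happen when E2 exists)", call. = FALSE)
  rows <- list()
  cth <- sth <- numeric(length(cf$m0))
  pis <- integer(length(cf$m0))
  for (i in seq_along(cf$m0)) {
    m0 <- cf$m0[i]
    K1 <- cc$F - cc$B * m0^2
    K2 <- cc$D * m0
    L1 <- cc$A * m0^2 - cc$E
    L2 <- m0^3 - cc$C * m0
    den <- K1^2 + K2^2
    cth[i] <- (K1 * L1 + K2 * L2) / den
    sth[i] <- (K2 * L1 - K1 * L2) / den
    if (abs(cth[i]^2 + sth[i]^2 - 1) > 1e-6)
      stop(sprintf(
        "inconsistent crossing system at m0 = %g: cos^2 + sin^2 - 1 = %g",
        m0, cth[i]^2 + sth[i]^2 - 1), call. = FALSE)
    ang <- atan2(sth[i], cth[i]) %% (2 * pi)
    dk <- (ang + 2 * pi * (0:k_max)) / m0
    rows[[i]] <- data.frame(m0 = m0, k = 0:k_max, delta = dk,
                            residual = abs(char_function(cc, 1i * m0, dk)))
    pis[i] <- transversality(cc, m0)
  }
  tab <- do.call(rbind, rows)
  i0 <- which.min(tab$delta[tab$k == 0])
  delta0 <- tab$delta[tab$k == 0][i0]
  omega0 <- tab$m0[tab$k == 0][i0]
  ref <- refine_crossing(cc, omega0, delta0)
  structure(list(p0 = cf$p0, p1 = cf$p1, p2 = cf$p2, m0 = cf$m0,
                 cos_theta = cth, sin_theta = sth,
                 delta_table = tab, delta0 = delta0, omega0 = omega0,
                 pi_sign = pis,
                 omega_star = ref$omega, delta_star = ref$delta,
                 refined = ref$converged,
                 coeffs = cc), class = "ti_crossing")
}

#' @export
print.ti_crossing <- function(x, ...) {
  cat(sprintf("Crossing frequencies m0: %s\n",
              paste(format(x$m0, digits = 6), collapse = ", ")))
  cat(sprintf("Smallest critical delay delta0 = %.6g at omega0 = %.6g (Pi = %+d)\n",
              x$delta0, x$omega0, x$pi_sign[match(x$omega0, x$m0)]))
  if (isTRUE(x$refined))
    cat(sprintf("Exact crossing of the full characteristic function: omega* = %.6g, delta* = %.6g\n",
                x$omega_star, x$delta_star))
  invisible(x)
}

# Newton refinement of a crossing (omega, delta) of the full characteristic
# function, seeded from the reduced-form estimate.
refine_crossing <- function(cc, omega, delta) {
  conv <- FALSE
  for (it in 1:60) {
    fv <- char_function(cc, 1i * omega, delta, char = "full")
    dl <- char_function_dlambda(cc, 1i * omega, delta, char = "full") * 1i
    dd <- char_function_ddelta(cc, 1i * omega, delta, char = "full")
    Jm <- matrix(c(Re(dl), Im(dl), Re(dd), Im(dd)), 2, 2)
    step <- tryCatch(solve(Jm, c(Re(fv), Im(fv))), error = function(e) NULL)
    if (is.null(step)) break
    omega <- omega - step[1]
    delta <- delta - step[2]
    if (max(abs(step)) < 1e-13) { conv <- TRUE; break }
  }
  if (!conv || omega <= 0 || delta < 0 ||
      abs(char_function(cc, 1i * omega, delta, char = "full")) > 1e-9)
    return(list(omega = NA_real_, delta = NA_real_, converged = FALSE))
  list(omega = omega, delta = delta, converged = TRUE)
}

#' Transversality sign at a crossing frequency
#'
#' Sign of `Re (dlambda/ddelta)^{-1}` at `lambda = i*m0`, which reduces to
#' the sign of `2*m0^6 + p0*m0^4 + (F^2 - E^2)` (the denominator of the
#' closed form is positive). Since `F^2 > E^2` always holds when E2 exists,
#' the sign is `+1` whenever `p0 >= 0`, and in particular every root
#' crossing moves rightward: delay destabilizes.
#'
#' @param p a [ti_params()] or [char_coeffs()] object.
#' @param m0 a positive crossing frequency from [crossing_frequencies()].
#' @return `+1`, `-1`, or `0`.
#' @export
transversality <- function(p, m0) {
  cc <- if (inherits(p, "ti_charcoeffs")) p else char_coeffs(p)
  if (!is.numeric(m0) || m0 <= 0)
    stop("m0 must be a positive crossing frequency", call. = FALSE)
  p0 <- cc$A^2 - 2 * cc$C - cc$B^2
  as.integer(sign(2 * m0^6 + p0 * m0^4 + (cc$F^2 - cc$E^2)))
}

#' Derivative of the crossing root with respect to the delay
#'
#' `lambda_prime_crossing()` evaluates `dlambda/ddelta` by implicit
#' differentiation of the characteristic function at `lambda = i*omega`;
#' `lambda_prime_closed_form()` evaluates the printed closed form of the
#' inverse derivative for the reduced quasi-polynomial (the two agree for
#' `char = "reduced"`).
#'
#' @param p a [ti_params()] or [char_coeffs()] object.
#' @param omega crossing frequency.
#' @param delta critical delay.
#' @param char which characteristic function to differentiate.
#' @return A complex scalar `dlambda/ddelta`.
#' @export
lambda_prime_crossing <- function(p, omega, delta, char = c("full", "reduced")) {
  cc <- if (inherits(p, "ti_charcoeffs")) p else char_coeffs(p)
  char <- match.arg(char)
  lam <- 1i * omega
  -char_function_ddelta(cc, lam, delta, char) /
    char_function_dlambda(cc, lam, delta, char)
}

#' @rdname lambda_prime_crossing
#' @export
lambda_prime_closed_form <- function(p, omega, delta) {
  cc <- if (inherits(p, "ti_charcoeffs")) p else char_coeffs(p)
  lam <- 1i * omega
  inv <- (2 * lam^3 + cc$A * lam^2 - cc$E) /
    (-lam^2 * (lam^3 + cc$A * lam^2 + cc$C * lam + cc$E)) +
    (cc$B * lam^2 - cc$F) / (lam^2 * (cc$B * lam^2 + cc$D * lam + cc$F)) -
    delta / lam
  1 / inv
}

#' Rightmost characteristic roots
#'
#' Locates roots of the characteristic function by damped Newton iteration
#' from a rectangular grid of seeds over a search window (default real part
#' in `[-5, 2]`, imaginary part in `[0, 4*max(m0, 1)]`; complex-conjugate
#' roots are implied and only the closed upper half plane is searched).
#' Converged roots are deduplicated to `1e-6` and returned sorted by
#' descending real part; every reported root has residual below `1e-8`.
#'
#' At `delta = 0` the reduced quasi-polynomial degenerates to the cubic
#' whose roots the Newton search recovers; the full variant reproduces the
#' exact Jacobian spectrum.
#'
#' @param p a [ti_params()] or [char_coeffs()] object.
#' @param delta delay at which to evaluate.
#' @param char `"reduced"` (default) or `"full"` characteristic function.
#' @param re_window numeric length-2 real-part window.
#' @param im_max upper bound of the imaginary window; default
#'   `4 * max(m0, 1)`.
#' @param grid number of seeds per axis (default `c(41, 41)`).
#' @param tol Newton tolerance on the step (default 1e-12).
#' @param maxit maximum Newton iterations per seed.
#' @return A data frame with columns `re`, `im`, `residual`, sorted by
#'   descending `re`; zero rows (with a warning) if no seed converged.
#' @export
rightmost_roots <- function(p, delta, char = c("reduced", "full"),
                            re_window = c(-5, 2), im_max = NULL,
                            grid = c(41, 41), tol = 1e-12, maxit = 100) {
  cc <- if (inherits(p, "ti_charcoeffs")) p else char_coeffs(p)
  char <- match.arg(char)
  if (is.null(im_max)) {
    m0 <- crossing_frequencies(cc)$m0
    im_max <- 4 * max(m0, 1)
  }
  seeds <- as.vector(outer(seq(re_window[1], re_window[2], length.out = grid[1]),
                           1i * seq(0, im_max, length.out = grid[2]), `+`))
  lam <- seeds
  active <- rep(TRUE, length(lam))
  for (it in seq_len(maxit)) {
    if (!any(active)) break
    fv <- char_function(cc, lam[active], delta, char)
    fp <- char_function_dlambda(cc, lam[active], delta, char)
    step <- fv / fp
    step[!is.finite(step)] <- 1e6           # kill degenerate seeds
    lam[active] <- lam[active] - step
    done <- abs(step) < tol
    idx <- which(active)
    active[idx[done]] <- FALSE
  }
  res <- abs(char_function(cc, lam, delta, char))
  ok <- !active & is.finite(lam) & is.finite(res) & res < 1e-8
  ok[is.na(ok)] <- FALSE
  lam <- lam[ok]
  if (!length(lam)) {
    warning("no characteristic root converged in the search window")
    return(data.frame(re = numeric(0), im = numeric(0), residual = numeric(0)))
  }
  lam[abs(Im(lam)) < 1e-9] <- complex(real = Re(lam[abs(Im(lam)) < 1e-9]), imaginary = 0)
  lam <- lam[Im(lam) >= 0]
  keep <- !duplicated(round(lam / 1e-6) * 1e-6)
  lam <- lam[keep]
  lam <- lam[order(-Re(lam))]
  data.frame(re = Re(lam), im = Im(lam),
             residual = abs(char_function(cc, lam, delta, char)))
}
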