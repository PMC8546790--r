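#' Equilibria of the delayed tumor-immune model
#'
#' The model has up to three fixed points. The tumor-free equilibrium
#' `E1 = (0, a3/a2, 0)` always exists. The co-axial (coexistence)
#' equilibrium
#' `E2 = ((a2*a4 - a3)/a1, a4, (a2*a4 - a3)/(a3 + a1*a4 - a2*a4))`
#' exists when both its numerator `a2*a4 - a3` and denominator
#' `a3 + a1*a4 - a2*a4` are strictly positive; the denominator condition is
#' algebraically identical to `(a2 - a1)*a4 < a3`, so the operative
#' condition is `(a2 - a1)*a4 < a3 < a2*a4`. The origin `E0 = (0, 0, 0)` is
#' a genuine fixed point only when `a3 = 0` (otherwise `dy/dt = a3 > 0`
#' there); it is reported as existing only in that degenerate limit, while
#' its Jacobian eigenvalues remain available via [jacobian_point_eigs()].
#'
#' On boundary equalities (`a3 = a2*a4` or `a3 = (a2 - a1)*a4`) equilibria
#' merge; `E2` is flagged nonexistent there rather than duplicated, because
#' the downstream stability formulas divide by quantities that vanish at
#' the boundary.
#'
#' @param p a [ti_params()] object (or coercible).
#' @return A data frame with one row per equilibrium and columns `label`,
#'   `x`, `y`, `z`, `exists`, `note`, with the [existence_regime()] string
#'   attached as attribute `"regime"`.
#' @examples
#' compute_equilibria(ti_params(0.3, 0.6, 4.0, 10.0))
#' @export
compute_equilibria <- function(p) {
  p <- as_ti_params(p)
  N <- p$a2 * p$a4 - p$a3           # E2 numerator
  Dn <- p$a3 + p$a1 * p$a4 - p$a2 * p$a4  # E2 denominator, = a3 - (a2-a1)*a4
  if (Dn == 0 && N > 0)
    stop("degenerate co-axial equilibrium: a3 + a1*a4 - a2*a4 = 0 while a3 < a2*a4",
         call. = FALSE)
  e2_exists <- (N > 0 && Dn > 0)
  e2 <- if (e2_exists) c(N / p$a1, p$a4, N / Dn) else c(NA_real_, NA_real_, NA_real_)
  regime <- existence_regime(p)
  out <- data.frame(
    label = c("E0", "E1", "E2"),
    x = c(0, 0, e2[1]),
    y = c(0, p$a3 / p$a2, e2[2]),
    z = c(0, 0, e2[3]),
    exists = c(p$a3 == 0, TRUE, e2_exists),
    note = c(
      if (p$a3 == 0) "origin; fixed point only because a3 = 0"
      else "origin; not a fixed point (dy/dt = a3 > 0), eigenvalues still defined",
      "tumor-free equilibrium",
      if (e2_exists)
        sprintf("co-axial equilibrium; (a2-a1)a4 = %g < a3 = %g < a2a4 = %g",
                (p$a2 - p$a1) * p$a4, p$a3, p$a2 * p$a4)
      else sprintf("co-axial equilibrium absent (regime %s)", regime)),
    stringsAsFactors = FALSE)
  attr(out, "regime") <- regime
  attr(out, "params") <- p
  out
}

#' Extract one equilibrium point as a state vector
#'
#' @param p a [ti_params()] object.
#' @param label `"E0"`, `"E1"`, or `"E2"`.
#' @return Numeric `(x, y, z)`, or `NULL` if the equilibrium does not exist.
#' @export
equilibrium_point <- function(p, label = "E2") {
  eq <- compute_equilibria(p)
  row <- eq[eq$label == match.arg(label, c("E0", "E1", "E2")), ]
  if (!row$exists) return(NULL)
  c(x = row$x, y = row$y, z = row$z)
}

#' Existence regime classification
#'
#' Classifies the parameter set into one of five regimes: only `E1` with a
#' high production rate (`a3 > a2*a4`, tumor-free equilibrium stable), only
#' `E1` with a low production rate (`a2 > a1` and `0 < a3 < (a2 - a1)*a4`,
#' immune-escape regime), coexistence of `E1` and `E2` with `a2 < a1`, the
#' same with `a2 > a1`, or `BOUNDARY` when any of the defining inequalities
#' holds with equality.
#'
#' @inheritParams compute_equilibria
#' @return A single string: one of `"E1_ONLY_HIGH_A3"`, `"E1_ONLY_LOW_A3"`,
#'   `"E1_AND_E2_A2_LT_A1"`, `"E1_AND_E2_A2_GT_A1"`, `"BOUNDARY"`.
#' @export
existence_regime <- function(p) {
  p <- as_ti_params(p)
  N <- p$a2 * p$a4 - p$a3
  Dn <- p$a3 + p$a1 * p$a4 - p$a2 * p$a4
  if (N == 0 || Dn == 0) return("BOUNDARY")
  if (N < 0) return("E1_ONLY_HIGH_A3")
  if (Dn < 0) return("E1_ONLY_LOW_A3")
  if (p$a2 == p$a1) return("BOUNDARY")
  if (p$a2 < p$a1) "E1_AND_E2_A2_LT_A1" else "E1_AND_E2_A2_GT_A1"
}
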