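#' Nyquist-based bound on the stability-preserving delay length
#'
#' Starting from the linearization about a Routh-Hurwitz-stable E2, a
#' Nyquist-type argument bounds the frequency of any marginal mode by
#' \deqn{\zeta_+ = \frac{|D| + \sqrt{D^2 + 4(|A|-|B|)(|E|+|F|)}}{2(|A|-|B|)}}
#' in the notation of [char_coeffs()], and then bounds the delay for which
#' E2 remains stable (with at most a period-1 limit cycle) by the positive
#' root of the quadratic `chi1*Delta^2 + chi2*Delta <= chi3`:
#' \deqn{\Delta_+ = \frac{-\chi_2 + \sqrt{\chi_2^2 + 4\chi_1\chi_3}}{2\chi_1}.}
#' Here `chi3 = (A+B)(C+D) - (E+F)` is exactly the third Routh-Hurwitz
#' margin (computed once in [routh_hurwitz()] terms), so `chi3 = 0` gives
#' `Delta_+ = 0`, and
#' `chi1 = zeta_+^2/2 * |B*zeta_+^2 + A*D - F|` (the bound `zeta_+` is
#' substituted for the unknown marginal frequency).
#'
#' The printed expression for `chi2` contains a typographical ambiguity: a
#' missing operator between the term `a1*zh/(1+zh)` and the factor
#' `(1 + a2 - a4)*yh` inside its first brace. The default reading
#' (`grouping = "product"`) takes the literal token sequence as a product,
#' i.e. `|a2*yh + yh - (a1*zh/(1+zh))*(1+a2-a4)*yh|*zeta_+^2 + |A|*|F|`;
#' the alternative (`grouping = "difference"`) reads the missing operator
#' as a minus sign, giving `|D - A*B|*zeta_+^2 + |A|*|F|`, which is the
#' combination produced by re-deriving the inequality. Both values are
#' reported; `grouping` selects the one used for `delta_plus`.
#'
#' The bound requires `|A| > |B|`; otherwise the quadratic inequality
#' underlying `zeta_+` reverses and no finite frequency bound follows, in
#' which case the function either signals a classed error or (with
#' `partial = TRUE`) returns `chi3` with the remaining fields `NA`.
#'
#' @param p a [ti_params()] or [char_coeffs()] object with `E2` existing.
#' @param grouping `"product"` (default) or `"difference"`, see Details.
#' @param partial if `TRUE`, return a partial result instead of erroring
#'   when `|A| <= |B|`.
#' @return An object of class `ti_delaybound`: list with `zeta_plus`,
#'   `chi1`, `chi2`, `chi2_alt`, `chi3`, `delta_plus`, `delta_plus_alt`,
#'   `grouping`, `defined`.
#' @export
delay_length_bound <- function(p, grouping = c("product", "difference"),
                               partial = FALSE) {
  cc <- if (inherits(p, "ti_charcoeffs")) p else char_coeffs(p)
  grouping <- match.arg(grouping)
  rh <- routh_hurwitz(cc)
  if (!rh$stable)
    warning("E2 is not Routh-Hurwitz stable at delta = 0; ",
            "the delay-length bound presumes undelayed stability")
  chi3 <- rh$margin
  gap <- abs(cc$A) - abs(cc$B)
  if (gap <= 0) {
    msg <- sprintf(paste0(
      "delay-length bound undefined: |A| = %.4g <= |B| = %.4g, so the ",
      "frequency bound zeta_+ has a nonpositive denominator"),
      abs(cc$A), abs(cc$B))
    if (!partial) {
      cond <- simpleError(msg)
      class(cond) <- c("tidelay_bound_undefined", class(cond))
      stop(cond)
    }
    out <- list(zeta_plus = NA_real_, chi1 = NA_real_, chi2 = NA_real_,
                chi2_alt = NA_real_, chi3 = chi3, delta_plus = NA_real_,
                delta_plus_alt = NA_real_, grouping = grouping,
                defined = FALSE, message = msg)
    return(structure(out, class = "ti_delaybound"))
  }
  zp <- (abs(cc$D) + sqrt(cc$D^2 + 4 * gap * (abs(cc$E) + abs(cc$F)))) / (2 * gap)
  chi1 <- 0.5 * zp^2 * abs(cc$B * zp^2 + cc$A * cc$D - cc$F)
  # chi2 under the two readings of the printed brace
  yh <- cc$point[["y"]]; zh <- cc$point[["z"]]
  a <- cc$params
  chi2_prod <- abs(a$a2 * yh + yh -
                     (a$a1 * zh / (1 + zh)) * (1 + a$a2 - a$a4) * yh) * zp^2 +
    abs(cc$A) * abs(cc$F)
  chi2_diff <- abs(cc$D - cc$A * cc$B) * zp^2 + abs(cc$A) * abs(cc$F)
  chi2 <- if (grouping == "product") chi2_prod else chi2_diff
  dplus <- function(c2) {
    disc <- c2^2 + 4 * chi1 * chi3
    if (disc < 0) return(NA_real_)
    max(0, (-c2 + sqrt(disc)) / (2 * chi1))
  }
  structure(list(zeta_plus = zp, chi1 = chi1,
                 chi2 = chi2,
                 chi2_alt = if (grouping == "product") chi2_diff else chi2_prod,
                 chi3 = chi3,
                 delta_plus = dplus(chi2),
                 delta_plus_alt = dplus(if (grouping == "product") chi2_diff else chi2_prod),
                 grouping = grouping, defined = TRUE),
            class = "ti_delaybound")
}

#' @export
print.ti_delaybound <- function(x, ...) {
  if (!isTRUE(x$defined)) {
    cat("Delay-length bound undefined:\n  ", x$message, "\n", sep = "")
    cat(sprintf("  chi3 (Routh-Hurwitz margin) = %.6g\n", x$chi3))
    return(invisible(x))
  }
  cat(sprintf("Frequency bound zeta_+ = %.6g\n", x$zeta_plus))
  cat(sprintf("chi1 = %.6g, chi2 = %.6g (%s reading; alternative %.6g), chi3 = %.6g\n",
              x$chi1, x$chi2, x$grouping, x$chi2_alt, x$chi3))
  cat(sprintf("Stability-preserving delay length Delta_+ = %.6g (alternative %.6g)\n",
              x$delta_plus, x$delta_plus_alt))
  invisible(x)
}
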