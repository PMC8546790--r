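#' Analytic regime classification of a parameter set
#'
#' Classifies the long-run regime predicted by the local analysis:
#' `"steady"` when a stable equilibrium exists (E2 stable at the given
#' delay, or E2 absent with the tumor-free equilibrium stable,
#' `a3 > a2*a4`), `"oscillatory"` when E2 exists but is unstable (at
#' `delta = 0`, judged by the exact Jacobian cubic; at positive delay, by
#' the sign of the rightmost root of the full characteristic function at
#' that delay), and `"no-E2"` when E2 is absent and E1 is unstable
#' (unbounded tumor growth, the immune-escape regime).
#'
#' The rightmost-root test is used instead of comparing the delay with the
#' reduced-form critical delay `delta0` because the latter can miss the
#' first crossing badly when the second-harmonic coefficient `G` of
#' [char_coeffs()] is large relative to `F`.
#'
#' @param p a [ti_params()] object.
#' @return List with `class` and `detail` (threshold and margins used).
#' @export
analytic_class <- function(p) {
  p <- as_ti_params(p)
  N <- p$a2 * p$a4 - p$a3
  Dn <- p$a3 + p$a1 * p$a4 - p$a2 * p$a4
  if (!(N > 0 && Dn > 0)) {
    cls <- if (p$a3 > p$a2 * p$a4) "steady" else "no-E2"
    return(list(class = cls, detail = list(e2 = FALSE)))
  }
  cc <- char_coeffs(p)
  rh <- routh_hurwitz(cc)
  if (!rh$stable_exact)
    return(list(class = "oscillatory",
                detail = list(e2 = TRUE, margin_exact = rh$margin_exact)))
  if (p$delta == 0)
    return(list(class = "steady",
                detail = list(e2 = TRUE, margin_exact = rh$margin_exact)))
  # stable without delay: decide at the configured delay from the rightmost
  # root of the full characteristic function (the reduced-form delta0 can
  # miss the first crossing badly when the second-harmonic term is large)
  rr <- rightmost_roots(cc, p$delta, char = "full", grid = c(25, 25))
  max_re <- if (nrow(rr)) rr$re[1] else -Inf
  list(class = if (max_re < 0) "steady" else "oscillatory",
       detail = list(e2 = TRUE, margin_exact = rh$margin_exact,
                     max_re = max_re))
}

#' One-parameter equilibrium branch sweep
#'
#' Follows the co-axial equilibrium branch while one parameter varies,
#' recording the branch coordinates, the analytic stability verdict at the
#' configured delay, and (for oscillatory points, when `simulate = TRUE`)
#' the per-component extrema of the simulated attractor.
#'
#' @param base a [ti_params()] object giving the non-varied parameters and
#'   the delay.
#' @param vary one of `"a1"`, `"a2"`, `"a3"`, `"a4"`, `"delta"`.
#' @param range numeric length-2 range for the varied parameter.
#' @param n number of grid points (default 41).
#' @param simulate record simulated cycle extrema for unstable points
#'   (default `TRUE`).
#' @param t_end,transient_fraction simulation horizon and analysis window
#'   for the cycle extrema.
#' @return A data frame of class `ti_branch` with columns `value` (the
#'   varied parameter), `x`, `y`, `z` (E2 branch, `NA` when absent),
#'   `class`, and `cycle_min_*`/`cycle_max_*` per component.
#' @export
branch_sweep <- function(base, vary, range, n = 41, simulate = TRUE,
                         t_end = 400, transient_fraction = 0.5) {
  base <- as_ti_params(base)
  vary <- match.arg(vary, c("a1", "a2", "a3", "a4", "delta"))
  stopifnot(length(range) == 2, all(range > 0) || vary == "delta")
  grid <- seq(range[1], range[2], length.out = n)
  rows <- vector("list", n)
  any_e2 <- FALSE
  for (i in seq_len(n)) {
    p <- base
    p[[vary]] <- grid[i]
    p <- ti_params(p$a1, p$a2, p$a3, p$a4, p$delta)
    e2 <- equilibrium_point(p, "E2")
    ac <- analytic_class(p)
    row <- data.frame(value = grid[i],
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      class = ac$class,
                      cycle_min_x = NA_real_, cycle_max_x = NA_real_,
                      cycle_min_y = NA_real_, cycle_max_y = NA_real_,
                      cycle_min_z = NA_real_, cycle_max_z = NA_real_)
    if (!is.null(e2)) {
      any_e2 <- TRUE
      row[c("x", "y", "z")] <- as.list(unname(e2))
      if (ac$class == "steady") {
        # a stable branch point is its own attractor
        row[c("cycle_min_x", "cycle_min_y", "cycle_min_z")] <- as.list(unname(e2))
        row[c("cycle_max_x", "cycle_max_y", "cycle_max_z")] <- as.list(unname(e2))
      } else if (simulate && ac$class == "oscillatory") {
        traj <- dde_solve(p, t_end = t_end, max_step = 0.0125)
        if (!traj$diverged) {
          w <- traj$states[traj$times >= max(traj$times) * transient_fraction, ,
                           drop = FALSE]
          row[c("cycle_min_x", "cycle_min_y", "cycle_min_z")] <-
            as.list(apply(w, 2, min))
          row[c("cycle_max_x", "cycle_max_y", "cycle_max_z")] <-
            as.list(apply(w, 2, max))
        }
      }
    }
    rows[[i]] <- row
  }
  if (!any_e2)
    warning("E2 exists nowhere on the requested range: empty branch")
  out <- do.call(rbind, rows)
  attr(out, "base") <- base
  attr(out, "vary") <- vary
  class(out) <- c("ti_branch", class(out))
  out
}

#' Two-parameter oscillation region map
#'
#' Classifies each cell of a rectangular grid over two parameters with the
#' analytic regime classification ([analytic_class()]); optionally verifies
#' a random sample of cells by direct simulation. Boundary cells (cells
#' adjacent to a cell of a different class) trace the Hopf locus and the
#' existence boundaries.
#'
#' @param base a [ti_params()] object.
#' @param xname,yname names of the two varied parameters (one may be
#'   `"delta"`).
#' @param xrange,yrange numeric length-2 ranges.
#' @param n cells per axis, scalar or length-2 (default 25, minimum 2).
#' @param audit number of randomly chosen cells to verify by simulation
#'   (default 0).
#' @param audit_t_end simulation horizon for audited cells (default 1500;
#'   near-boundary cells decay or grow slowly and need a long window).
#' @param seed optional seed for the audit sample.
#' @return An object of class `ti_regionmap`: list with `cells` (data
#'   frame `xval`, `yval`, `class`, `boundary`), the axis descriptors, and
#'   (when audited) `audit` (data frame with `expected`, `simulated`,
#'   `agree`) and the agreement rate.
#' @export
region_map_2d <- function(base, xname, xrange, yname, yrange, n = 25,
                          audit = 0, audit_t_end = 1500, seed = NULL) {
  base <- as_ti_params(base)
  nm <- c("a1", "a2", "a3", "a4", "delta")
  xname <- match.arg(xname, nm); yname <- match.arg(yname, nm)
  if (identical(xname, yname)) stop("the two parameters must differ", call. = FALSE)
  n <- rep(as.integer(n), length.out = 2)
  if (any(n < 2)) stop("resolution must be at least 2 per axis", call. = FALSE)
  xs <- seq(xrange[1], xrange[2], length.out = n[1])
  ys <- seq(yrange[1], yrange[2], length.out = n[2])
  cells <- expand.grid(xval = xs, yval = ys, KEEP.OUT.ATTRS = FALSE)
  cls <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- base
    p[[xname]] <- cells$xval[i]
    p[[yname]] <- cells$yval[i]
    p <- ti_params(p$a1, p$a2, p$a3, p$a4, p$delta)
    cls[i] <- analytic_class(p)$class
  }
  cells$class <- cls
  cmat <- matrix(cls, n[1], n[2])
  bnd <- matrix(FALSE, n[1], n[2])
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) {
    nb <- c(if (i > 1) cmat[i - 1, j], if (i < n[1]) cmat[i + 1, j],
            if (j > 1) cmat[i, j - 1], if (j < n[2]) cmat[i, j + 1])
    bnd[i, j] <- any(nb != cmat[i, j])
  }
  cells$boundary <- as.vector(bnd)
  out <- list(cells = cells, xname = xname, yname = yname,
              xs = xs, ys = ys, base = base)
  if (audit > 0) {
    if (!is.null(seed)) set.seed(seed)
    idx <- sample(nrow(cells), min(audit, nrow(cells)))
    sim_cls <- character(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      p <- base
      p[[xname]] <- cells$xval[i]
      p[[yname]] <- cells$yval[i]
      p <- ti_params(p$a1, p$a2, p$a3, p$a4, p$delta)
      traj <- dde_solve(p, t_end = audit_t_end, max_step = 0.0125,
                        out_dt = 0.2)
      sim_cls[k] <- summarize_trajectory(traj,
                                         transient_fraction = 0.7)$classification
    }
    expected <- c(steady = "steady", oscillatory = "oscillatory",
                  `no-E2` = "divergent")[cells$class[idx]]
    out$audit <- data.frame(xval = cells$xval[idx], yval = cells$yval[idx],
                            class = cells$class[idx],
                            expected = unname(expected),
                            simulated = sim_cls,
                            agree = unname(expected) == sim_cls)
    out$agreement <- mean(out$audit$agree)
    if (any(!out$audit$agree))
      message(sprintf("audit: %d/%d cells disagree (near-boundary cells may differ)",
                      sum(!out$audit$agree), length(idx)))
  }
  structure(out, class = "ti_regionmap")
}

#' @export
print.ti_regionmap <- function(x, ...) {
  tab <- table(x$cells$class)
  cat(sprintf("Region map over %s x %s (%d x %d cells):\n",
              x$xname, x$yname, length(x$xs), length(x$ys)))
  print(tab)
  if (!is.null(x$agreement))
    cat(sprintf("Simulation audit agreement: %.1f%%\n", 100 * x$agreement))
  invisible(x)
}

#' Boundary-cell midpoints separating steady and oscillatory cells
#'
#' @param map a `ti_regionmap`.
#' @return Data frame of cell centers on the steady/oscillatory boundary.
#' @export
hopf_locus <- function(map) {
  stopifnot(inherits(map, "ti_regionmap"))
  cells <- map$cells
  cells[cells$boundary & cells$class %in% c("steady", "oscillatory"),
        c("xval", "yval", "class")]
}
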