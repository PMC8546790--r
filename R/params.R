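#' Nondimensional model parameters
#'
#' Container for the four dimensionless rates of the tumor-immune model and
#' the discrete delay. `a1` is the scaled maximum recruitment rate of
#' immature lymphocytes by the tumor, `a2` the scaled inactivation rate of
#' mature lymphocytes, `a3` the scaled constant production rate of immature
#' lymphocytes, `a4` the scaled tumor growth rate, and `delta` the
#' dimensionless interaction/stimulation lag.
#'
#' @param a1,a2,a3,a4 strictly positive dimensionless rates (`a3 = 0` is
#'   accepted as a degenerate limit, in which the origin becomes a genuine
#'   fixed point coinciding with the tumor-free equilibrium).
#' @param delta nonnegative dimensionless delay (default 0).
#' @return An object of class `ti_params`.
#' @seealso [nondimensionalize()] to build one from dimensional rates.
#' @examples
#' ti_params(0.4, 0.6, 3.5, 7.0, delta = 0.01)
#' @export
ti_params <- function(a1, a2, a3, a4, delta = 0) {
  vals <- c(a1 = a1, a2 = a2, a3 = a3, a4 = a4)
  if (any(!is.finite(vals)) || any(vals[c(1, 2, 4)] <= 0) || a3 < 0)
    stop("a1, a2, a4 must be finite and strictly positive, a3 nonnegative",
         call. = FALSE)
  if (!is.finite(delta) || delta < 0)
    stop("delta must be finite and nonnegative", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, delta = delta),
            class = "ti_params")
}

#' @export
print.ti_params <- function(x, ...) {
  cat(sprintf(
    "Tumor-immune model parameters: a1 = %g, a2 = %g, a3 = %g, a4 = %g, delay = %g\n",
    x$a1, x$a2, x$a3, x$a4, x$delta))
  invisible(x)
}

as_ti_params <- function(p) {
  if (inherits(p, "ti_params")) return(p)
  if (is.numeric(p) && length(p) %in% c(4L, 5L)) {
    p <- as.list(unname(p))
    return(ti_params(p[[1]], p[[2]], p[[3]], p[[4]],
                     if (length(p) == 5L) p[[5]] else 0))
  }
  if (is.list(p))
    return(ti_params(p$a1, p$a2, p$a3, p$a4, if (is.null(p$delta)) 0 else p$delta))
  stop("cannot interpret 'p' as model parameters", call. = FALSE)
}

#' Dimensional model parameters
#'
#' The dimensional form of the model tracks immature T lymphocytes L1,
#' mature T lymphocytes L2, and tumor cells T. Its rates are: `mu`, the
#' constant production of immature lymphocytes (cells/time), equal to the
#' product `lambda0 * L0` of a per-capita production rate and a reference
#' cell level; `lambda1`, the maturation rate (1/time); `lambda2`, the tumor
#' growth rate (1/time); `alpha1`, the maximum recruitment rate (1/time);
#' `alpha2`, the kill rate of tumor cells by mature lymphocytes
#' (1/(cells*time)); `alpha3`, the inactivation rate of mature lymphocytes
#' (1/time); and `eta`, the half-saturation tumor level of the recruitment
#' term (cells).
#'
#' Only the product `lambda0 * L0` enters the nondimensional rates, so `mu`
#' may be given directly or through the pair (`lambda0`, `L0`).
#'
#' @param lambda1,lambda2,alpha1,alpha2,alpha3,eta strictly positive rates
#'   as described above.
#' @param mu production rate of immature lymphocytes; either `mu` or both
#'   `lambda0` and `L0` must be supplied.
#' @param lambda0,L0 per-capita production rate and reference level whose
#'   product is `mu`.
#' @return An object of class `ti_dimparams`.
#' @export
dimensional_params <- function(lambda1, lambda2, alpha1, alpha2, alpha3, eta,
                               mu = NULL, lambda0 = NULL, L0 = NULL) {
  if (is.null(mu)) {
    if (is.null(lambda0) || is.null(L0))
      stop("supply either 'mu' or both 'lambda0' and 'L0'", call. = FALSE)
    mu <- lambda0 * L0
  }
  vals <- c(mu = mu, lambda1 = lambda1, lambda2 = lambda2, alpha1 = alpha1,
            alpha2 = alpha2, alpha3 = alpha3, eta = eta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all dimensional parameters must be finite and strictly positive",
         call. = FALSE)
  structure(as.list(vals), class = "ti_dimparams")
}

#' Convert dimensional rates to the nondimensional parameter set
#'
#' Applies the scaling `a1 = alpha1/lambda1`, `a2 = alpha3/lambda1`,
#' `a3 = alpha2 * mu / lambda1^2`, `a4 = lambda2/lambda1`, and rescales time
#' by `t = lambda1 * tau`, so that a dimensional delay `delay` becomes
#' `lambda1 * delay`.
#'
#' @param dp a [dimensional_params()] object.
#' @param delay nonnegative delay on the dimensional time scale.
#' @return A [ti_params()] object.
#' @examples
#' dp <- dimensional_params(lambda1 = 2, lambda2 = 20, alpha1 = 0.6,
#'                          alpha2 = 1, alpha3 = 1.2, eta = 1, mu = 16)
#' nondimensionalize(dp, delay = 0.005)   # a = (0.3, 0.6, 4, 10), delta 0.01
#' @export
nondimensionalize <- function(dp, delay = 0) {
  stopifnot(inherits(dp, "ti_dimparams"))
  if (!is.finite(delay) || delay < 0)
    stop("delay must be finite and nonnegative", call. = FALSE)
  ti_params(a1 = dp$alpha1 / dp$lambda1,
            a2 = dp$alpha3 / dp$lambda1,
            a3 = dp$alpha2 * dp$mu / dp$lambda1^2,
            a4 = dp$lambda2 / dp$lambda1,
            delta = dp$lambda1 * delay)
}

#' Map dimensional states to nondimensional ones and back
#'
#' The nondimensional state is
#' `x = (alpha2/alpha1) * (L1 - mu/lambda1)`, `y = (alpha2/lambda1) * L2`,
#' `z = T/eta`. Note that `x` is a scaled *deviation* from the
#' tumor-free resting level of immature lymphocytes and may be negative.
#'
#' @param dp a [dimensional_params()] object.
#' @param L1,L2,T dimensional cell levels (vectors allowed).
#' @param x,y,z nondimensional state components.
#' @return `state_transform()` returns a list with `x`, `y`, `z`;
#'   `inverse_state_transform()` returns a list with `L1`, `L2`, `T`.
#' @export
state_transform <- function(dp, L1, L2, T) {
  stopifnot(inherits(dp, "ti_dimparams"))
  list(x = (dp$alpha2 / dp$alpha1) * (L1 - dp$mu / dp$lambda1),
       y = (dp$alpha2 / dp$lambda1) * L2,
       z = T / dp$eta)
}

#' @rdname state_transform
#' @export
inverse_state_transform <- function(dp, x, y, z) {
  stopifnot(inherits(dp, "ti_dimparams"))
  list(L1 = dp$mu / dp$lambda1 + (dp$alpha1 / dp$alpha2) * x,
       L2 = (dp$lambda1 / dp$alpha2) * y,
       T = dp$eta * z)
}

#' Right-hand side of the delayed model
#'
#' Evaluates the rates of change given the current state and the state one
#' delay in the past. The delayed components enter the recruitment term
#' `y_d * z_d / (1 + z_d)` and the kill term `y_d * z_d`.
#'
#' @param current numeric length-3 state `(x, y, z)` at time `t`.
#' @param delayed numeric length-3 state at time `t - delta`; defaults to
#'   `current` (appropriate for `delta = 0` or equilibrium checks).
#' @param p a [ti_params()] object (or coercible).
#' @return Numeric length-3 vector of derivatives.
#' @export
ti_rhs <- function(current, delayed = current, p) {
  p <- as_ti_params(p)
  stopifnot(length(current) == 3L, length(delayed) == 3L)
  if (delayed[3] <= -1)
    stop("delayed z must exceed -1 (saturating term singular)", call. = FALSE)
  c(-current[1] + delayed[2] * delayed[3] / (1 + delayed[3]),
    p$a1 * current[1] - p$a2 * current[2] + p$a3,
    p$a4 * current[3] - delayed[2] * delayed[3])
}

#' Initial history functions
#'
#' A history is a function mapping `theta` in `[-delta, 0]` to a state
#' triple. `const_history()` builds the constant-in-theta history used by
#' all packaged scenarios; `as_history()` accepts a length-3 numeric
#' (constant history), a data frame with columns `theta`, `x`, `y`, `z`
#' (interpolated by natural cubic splines), or an arbitrary function of
#' `theta` returning a length-3 numeric.
#'
#' @param x0,y0,z0 state held constant over the history interval.
#' @param h history specification as described above.
#' @return A function of `theta` with attribute `"kind"` set to one of
#'   `"constant"`, `"interpolated"`, `"user"`.
#' @export
const_history <- function(x0, y0, z0) {
  v <- c(x = x0, y = y0, z = z0)
  if (any(!is.finite(v))) stop("history values must be finite", call. = FALSE)
  f <- function(theta) v
  attr(f, "kind") <- "constant"
  attr(f, "value") <- v
  f
}

#' @rdname const_history
#' @export
as_history <- function(h) {
  if (is.function(h)) {
    if (is.null(attr(h, "kind"))) attr(h, "kind") <- "user"
    return(h)
  }
  if (is.numeric(h) && length(h) == 3L)
    return(const_history(h[1], h[2], h[3]))
  if (is.data.frame(h)) {
    stopifnot(all(c("theta", "x", "y", "z") %in% names(h)))
    fx <- stats::splinefun(h$theta, h$x, method = "natural")
    fy <- stats::splinefun(h$theta, h$y, method = "natural")
    fz <- stats::splinefun(h$theta, h$z, method = "natural")
    f <- function(theta) c(x = fx(theta), y = fy(theta), z = fz(theta))
    attr(f, "kind") <- "interpolated"
    return(f)
  }
  stop("cannot interpret history specification", call. = FALSE)
}

#' Read a simulation configuration file
#'
#' Configuration files are YAML or JSON with keys `a1`, `a2`, `a3`, `a4`,
#' `delta`, `history: {x0, y0, z0}`, `t_end`, `max_step`, `rtol`, `atol`.
#' Alternatively a `dimensional:` block with the [dimensional_params()]
#' fields plus `delay` triggers [nondimensionalize()].
#'
#' @param path file path ending in `.yaml`, `.yml`, or `.json`.
#' @return A list with elements `params` ([ti_params()]), `history`
#'   (history function or `NULL`), `t_end`, `max_step`, `rtol`, `atol`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("config must be .yaml/.yml or .json", call. = FALSE))
  if (!is.null(cfg$dimensional)) {
    d <- cfg$dimensional
    dp <- dimensional_params(lambda1 = d$lambda1, lambda2 = d$lambda2,
                             alpha1 = d$alpha1, alpha2 = d$alpha2,
                             alpha3 = d$alpha3, eta = d$eta,
                             mu = d$mu, lambda0 = d$lambda0, L0 = d$L0)
    params <- nondimensionalize(dp, delay = if (is.null(d$delay)) 0 else d$delay)
  } else {
    params <- ti_params(cfg$a1, cfg$a2, cfg$a3, cfg$a4,
                        delta = if (is.null(cfg$delta)) 0 else cfg$delta)
  }
  history <- NULL
  if (!is.null(cfg$history))
    history <- const_history(cfg$history$x0, cfg$history$y0, cfg$history$z0)
  list(params = params,
       history = history,
       t_end = if (is.null(cfg$t_end)) 100 else cfg$t_end,
       max_step = if (is.null(cfg$max_step)) 0.01 else cfg$max_step,
       rtol = if (is.null(cfg$rtol)) 1e-8 else cfg$rtol,
       atol = if (is.null(cfg$atol)) 1e-10 else cfg$atol)
}
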