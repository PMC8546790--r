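# Parameter sets used across the suite (the four packaged rate sets, by the
# regime they demonstrate)
p_osc  <- function(delta = 0.05) ti_params(0.3, 0.6, 4.0, 10.0, delta)   # always oscillatory
p_sw   <- function(delta = 0)    ti_params(0.4, 0.6, 3.5, 7.0, delta)    # delay-induced switch
p_esc  <- function(delta = 0.01) ti_params(0.3, 0.6, 1.0, 5.0, delta)    # immune escape
p_free <- function(delta = 0.01) ti_params(0.3, 0.6, 0.5, 0.7, delta)    # tumor regression

# log-uniform parameter draws, optionally restricted to sets where the
# co-axial equilibrium exists; the caller controls the RNG state
draw_params <- function(n, lo = 1e-2, hi = 1e2, require_e2 = FALSE) {
  out <- vector("list", n)
  i <- 0
  while (i < n) {
    a <- exp(runif(4, log(lo), log(hi)))
    if (require_e2) {
      N <- a[2] * a[4] - a[3]
      Dn <- a[3] + a[1] * a[4] - a[2] * a[4]
      if (!(N > 0 && Dn > 0)) next
    }
    i <- i + 1
    out[[i]] <- ti_params(a[1], a[2], a[3], a[4])
  }
  out
}

# study conditions for trajectory-level nonnegativity checks: the packaged
# rate sets with delays in the simulated range and random constant
# nonnegative histories
draw_study_case <- function() {
  sets <- list(c(0.3, 0.6, 4, 10), c(0.4, 0.6, 3.5, 7),
               c(0.3, 0.6, 1, 5), c(0.3, 0.6, 0.5, 0.7))
  a <- sets[[sample(4, 1)]]
  list(params = ti_params(a[1], a[2], a[3], a[4], runif(1, 0.005, 0.05)),
       history = runif(3, 0, 2))
}
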