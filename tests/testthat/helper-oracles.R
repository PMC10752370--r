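# Independent oracles, kept free of the package's own integrators.

# closed-form logistic solution
logistic_closed_form <- function(mu, K, x0, t) {
  K * x0 * exp(mu * t) / (K + x0 * (exp(mu * t) - 1))
}

# deSolve-based gLV trajectory (reference integrator)
glv_desolve <- function(mu, A, x0, times) {
  rhs <- function(t, x, p) list((p$mu + as.vector(p$A %*% x)) * x)
  out <- deSolve::lsoda(x0, times, rhs, list(mu = mu, A = A),
                        rtol = 1e-10, atol = 1e-12)
  unname(out[, -1, drop = FALSE])
}

# small stable two-species competition fixture with a coexistence fixed point
lv2_fixture <- function() {
  mu <- c(0.8, 0.6)
  A <- matrix(c(-1.0, -0.3,
                -0.4, -0.9), 2, 2, byrow = TRUE)
  xstar <- solve(A, -mu) # interior equilibrium of (mu + A x) = 0
  list(mu = mu, A = A, xstar = xstar)
}
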