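# Shared fixtures and independent oracles used across test files.

# Reference demographies (the published study settings)
fig1_logistic <- function(gamma = 0.003) logistic_growth(Nk = 1e4, gamma = gamma,
                                                         onset = 5000)
table2_exponential <- function() exponential_growth(N0 = 1e5, gamma = 0.003)
table2_gompertz <- function() gompertz_growth(N0 = 1, gamma = 0.01,
                                              alpha = 0.001, onset = 5000)

# Closed-form expected coalescence times for exponential growth,
# t_m = (1/gamma) * log(2 N0 gamma (1/m - 1/n) + 1), written out directly so
# it does not route through the package's inversion code.
exp_growth_times_closed_form <- function(N0, gamma, n) {
  m <- seq_len(n - 1)
  log(2 * N0 * gamma * (1 / m - 1 / n) + 1) / gamma
}

# Front-factor rearrangement of the spectrum sum,
#   E[S_j] = (n-j-1)! (j-1)! / (n-1)! * mu * sum_k k(k-1) C(n-k, j-1) E[W_k],
# exact in double precision for n <= 12 (all factorials < 12! are integers
# representable exactly).  This is the overflow-prone form the package must
# never use internally; here it serves as the small-n brute-force oracle.
front_factor_spectrum <- function(EW, n, mu) {
  k <- 2:n
  vapply(seq_len(n - 1), function(j) {
    pref <- factorial(n - j - 1) * factorial(j - 1) / factorial(n - 1)
    pref * mu * sum(k * (k - 1) * choose(n - k, j - 1) * EW)
  }, numeric(1))
}

# Brute-force scaled-time variance: sum of squared epoch means of the
# standard coalescent, accumulated in an explicit loop.
brute_sigma2 <- function(n) {
  vapply(seq_len(n - 1), function(m) {
    tot <- 0
    for (k in (m + 1):n) tot <- tot + (2 / (k * (k - 1)))^2
    tot
  }, numeric(1))
}

# Adaptive-quadrature g(t), independent of the package's evaluators.
quad_g <- function(model, t) {
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    stats::integrate(function(u) 1 / population_size(model, u), 0, ti,
                     rel.tol = 1e-12, abs.tol = 0, subdivisions = 2000L)$value
  }, numeric(1))
}
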