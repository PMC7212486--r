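#' Expected scaled coalescence times of the standard n-coalescent
#'
#' In a constant-size population with time in units of the haploid size, the
#' time at which `m + 1` lineages merge into `m` has expectation
#' `mu_m = 2 (1/m - 1/n)` for `m = 1, ..., n-1`.
#'
#' @param n sample size (number of haplotypes), integer `>= 2`.
#' @return vector of length `n - 1`, strictly decreasing in `m`.
#' @export
kingman_expected_scaled <- function(n) {
  n <- check_sample_size(n)
  m <- seq_len(n - 1L)
  2 * (1 / m - 1 / n)
}

#' Variances of the scaled coalescence times
#'
#' The scaled time at level `m` is the sum of the independent exponential
#' epoch lengths for `k = m + 1, ..., n` lineages (rates `k(k-1)/2`), so its
#' variance is `sigma_m^2 = sum_k 4 / (k^2 (k-1)^2)`.
#'
#' @inheritParams kingman_expected_scaled
#' @return vector of length `n - 1`, strictly decreasing in `m`.
#' @export
kingman_variance_scaled <- function(n) {
  n <- check_sample_size(n)
  k <- 2:n
  a <- 4 / (k^2 * (k - 1)^2)      # epoch variance, k = 2..n
  rev(cumsum(rev(a)))             # sigma_m^2 = sum over k = m+1..n
}

check_sample_size <- function(n) {
  if (length(n) != 1L || !is.numeric(n) || !is.finite(n) || n < 2 ||
      n != round(n))
    stop_validation("'n' must be a single integer >= 2")
  as.integer(n)
}

#' Expected coalescence times under a variable-size demography
#'
#' First-order approximation `E[T_m] = g^{-1}(mu_m)`: each standard-coalescent
#' expected scaled time is mapped back to generations through the inverse of
#' the time-scaling function, by the chosen scheme.
#'
#' @param model a `demography_model`.
#' @param n sample size `>= 2`.
#' @param method `"finite_sum"` (generation-stepping scan), `"root"`
#'   (bracketed root-finding on `g`), or `"analytic"` (closed forms, only for
#'   constant/exponential/logistic).
#' @param cfg a [finite_sum_config()]; its `max_time` also caps root brackets.
#' @param tol relative tolerance for the root method.
#' @return vector `E[T_m]`, `m = 1, ..., n-1` (generations), strictly
#'   decreasing in `m`.
#' @examples
#' expected_times(constant_size(1000), 4, "analytic")     # 1500 500 166.7
#' @export
expected_times <- function(model, n, method = c("finite_sum", "root", "analytic"),
                           cfg = finite_sum_config(), tol = 1e-10) {
  method <- match.arg(method)
  n <- check_sample_size(n)
  cfg <- as_fs_config(cfg)
  mu <- kingman_expected_scaled(n)
  et <- switch(method,
    finite_sum = {
      res <- invert_scale_finite_sum(model, rev(mu), cfg)   # ascending mu
      structure(rev(as.numeric(res)),
                n_evaluations = attr(res, "n_evaluations"))
    },
    root = invert_scale_root(model, mu, tol = tol, max_time = cfg$max_time),
    analytic = invert_scale_analytic(model, mu))
  et
}

#' First-order variances of coalescence times
#'
#' `Var[T_m] = sigma_m^2 / g'(g^{-1}(mu_m))^2` with `g'(t) = 1/N(t)`, i.e.
#' `sigma_m^2 * N(E[T_m])^2`.  Exact for a constant-size history, where it
#' reduces to the variance of the exponential epoch sums.
#'
#' @inheritParams expected_times
#' @return vector `Var[T_m]` in squared generations.
#' @export
variance_times <- function(model, n, method = c("finite_sum", "root", "analytic"),
                           cfg = finite_sum_config(), tol = 1e-10) {
  et <- expected_times(model, n, method, cfg, tol)
  s2 <- kingman_variance_scaled(n)
  s2 * population_size(model, et)^2
}

#' Expected intercoalescence times E[W_k]
#'
#' `W_k` is the duration during which exactly `k` lineages exist:
#' `W_k = T_{k-1} - T_k` with the boundary `T_n = 0`, so `E[W_n] = E[T_{n-1}]`
#' and the total tree depth identity `sum_k E[W_k] = E[T_1]` holds by
#' telescoping.
#'
#' @param ET vector `E[T_m]`, `m = 1, ..., n-1`, strictly decreasing.
#' @param n sample size consistent with `length(ET) = n - 1`.
#' @return vector `E[W_k]`, `k = 2, ..., n` (names give `k`).
#' @export
intercoalescence_times <- function(ET, n) {
  n <- check_sample_size(n)
  if (length(ET) != n - 1L)
    stop_validation("'ET' must have length n - 1")
  # ties are tolerated (the generation-stepping scan can land adjacent levels
  # on the same grid point, giving E[W_k] = 0); an increase is a broken inversion
  if (n > 2L && any(diff(ET) > 0))
    stop_validation("'ET' must be non-increasing in m; the upstream inversion is broken")
  ew <- c(if (n > 2L) ET[seq_len(n - 2L)] - ET[2:(n - 1L)], ET[n - 1L])
  names(ew) <- as.character(2:n)
  ew
}

#' Full schedule of expected coalescence quantities
#'
#' Bundles the scaled moments, expected coalescence times, first-order
#' variances and intercoalescence times for a sample of `n` under a
#' demography.
#'
#' @inheritParams expected_times
#' @return an object of class `coalescent_schedule` with fields `n`,
#'   `mu_scaled`, `sigma2_scaled`, `ET`, `VarT`, `EW`, `method`.
#' @export
coalescent_schedule <- function(model, n,
                                method = c("finite_sum", "root", "analytic"),
                                cfg = finite_sum_config(), tol = 1e-10) {
  method <- match.arg(method)
  n <- check_sample_size(n)
  ET <- expected_times(model, n, method, cfg, tol)
  s2 <- kingman_variance_scaled(n)
  out <- list(
    n = n,
    mu_scaled = kingman_expected_scaled(n),
    sigma2_scaled = s2,
    ET = as.numeric(ET),
    VarT = s2 * population_size(model, as.numeric(ET))^2,
    EW = intercoalescence_times(as.numeric(ET), n),
    method = method)
  class(out) <- "coalescent_schedule"
  out
}

#' @export
print.coalescent_schedule <- function(x, ...) {
  cat(sprintf("<coalescent_schedule: n = %d, method = %s>\n", x$n, x$method))
  cat(sprintf("  E[T1] (tree depth) = %.6g generations\n", x$ET[1L]))
  cat(sprintf("  E[T%d] (first merger) = %.6g generations\n",
              x$n - 1L, x$ET[x$n - 1L]))
  invisible(x)
}
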