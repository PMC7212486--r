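# log binomial coefficient via lgamma, with structural zeros short-circuited
# to -Inf before any exponentiation; never touches raw factorials.
lchoose_lg <- function(a, b) {
  out <- rep_len(-Inf, max(length(a), length(b)))
  a <- rep_len(a, length(out)); b <- rep_len(b, length(out))
  ok <- b >= 0 & a >= b
  out[ok] <- lgamma(a[ok] + 1) - lgamma(b[ok] + 1) - lgamma(a[ok] - b[ok] + 1)
  out
}

#' Probability that a size-k branch mutation reaches derived count j
#'
#' While `k` ancestral lineages exist, a mutation on any one of them is
#' inherited by `j` of the `n` sampled haplotypes with probability
#' `C(n-j-1, k-2) / C(n-1, k-1)` (a polytomy-free lineage-splitting argument).
#' Computed through log-gamma differences so it stays finite for thousands of
#' haplotypes; structurally impossible combinations (`n - j - 1 < k - 2`)
#' return exactly 0.
#'
#' @param n sample size `>= 2`.
#' @param k number of ancestral lineages, `2 <= k <= n` (vectorised).
#' @param j derived allele count, `1 <= j <= n - 1` (vectorised).
#' @return probabilities; for fixed `k`, summing over
#'   `j = 1, ..., n - k + 1` gives 1.
#' @export
lineage_frequency_prob <- function(n, k, j) {
  n <- check_sample_size(n)
  if (any(k < 2 | k > n)) stop_validation("'k' must satisfy 2 <= k <= n")
  if (any(j < 1 | j > n - 1)) stop_validation("'j' must satisfy 1 <= j <= n - 1")
  lp <- lchoose_lg(n - j - 1, k - 2) - lchoose_lg(n - 1, k - 1)
  ifelse(is.finite(lp), exp(lp), 0)
}

#' Expected allele frequency spectrum from intercoalescence times
#'
#' Under the infinitely-many-sites model, mutations on any of the `k` branches
#' spanning `W_k` occur as a Poisson process with mean `mu * k * E[W_k]`, and
#' each reaches derived count `j` with [lineage_frequency_prob()].  Summing
#' over branch sizes,
#' `E[S_j] = sum_{k=2}^{n} C(n-j-1, k-2)/C(n-1, k-1) * mu * k * E[W_k]`.
#'
#' Each `(j, k)` term is assembled as a log-space probability times a linear
#' time term.  The algebraically equivalent "front-factor" rearrangement that
#' pulls `(n-j-1)! (j-1)! / (n-1)!` out of the sum overflows double precision
#' already for moderate `n` and is never used here (it serves only as a
#' small-`n` oracle in the tests).
#'
#' @param EW vector `E[W_k]`, `k = 2, ..., n` (generations), all `>= 0`.
#' @param n sample size, `length(EW) == n - 1`.
#' @param mutation_rate per-generation, per-locus mutation rate `mu >= 0`.
#'   Note the unit: this is a whole-locus rate; users with a per-site rate
#'   should multiply by the locus length.
#' @return an object of class `frequency_spectrum` with fields `n`,
#'   `mutation_rate`, `counts` (expected segregating sites `E[S_j]`,
#'   `j = 1, ..., n-1`) and `proportions` (counts normalised to sum 1, `NA`
#'   when all counts are zero).
#' @examples
#' n <- 4; N <- 1000
#' EW <- 2 * N / ((2:n) * (1:(n - 1)))       # constant-size epoch means
#' expected_spectrum(EW, n, 1e-3)$counts     # theta/j with theta = 2 N mu
#' @export
expected_spectrum <- function(EW, n, mutation_rate) {
  n <- check_sample_size(n)
  mutation_rate <- check_scalar_number(mutation_rate, "mutation_rate", 0)
  if (length(EW) != n - 1L)
    stop_validation("'EW' must have length n - 1 (k = 2..n)")
  if (any(!is.finite(EW)) || any(EW < 0))
    stop_validation("'EW' must be finite and >= 0")
  k <- 2:n
  j <- seq_len(n - 1L)
  # log P[j, k] matrix; structural zeros stay 0 after exp
  lp <- outer(j, k, function(jj, kk)
    lchoose_lg(n - jj - 1, kk - 2) - lchoose_lg(n - 1, kk - 1))
  P <- exp(lp)
  P[!is.finite(lp)] <- 0
  counts <- as.numeric(P %*% (mutation_rate * k * EW))
  new_frequency_spectrum(n, mutation_rate, counts)
}

new_frequency_spectrum <- function(n, mutation_rate, counts) {
  s <- sum(counts)
  structure(list(n = n, mutation_rate = mutation_rate, counts = counts,
                 proportions = if (s > 0) counts / s else rep(NA_real_, n - 1L)),
            class = "frequency_spectrum")
}

#' Normalise a frequency spectrum to proportions
#'
#' Populates `proportions = counts / sum(counts)`, a mutation-rate-free
#' summary suitable for comparing spectra across methods or rates.
#'
#' @param spec a `frequency_spectrum`.
#' @return the spectrum with `proportions` populated; `counts` unchanged.
#' @export
normalize_spectrum <- function(spec) {
  stopifnot(inherits(spec, "frequency_spectrum"))
  s <- sum(spec$counts)
  if (s <= 0)
    stop_numeric("cannot normalise an all-zero spectrum",
                 class = "coalafs_degenerate_spectrum_error")
  spec$proportions <- spec$counts / s
  spec
}

#' Expected AFS of a demography in one call
#'
#' Convenience pipeline: expected coalescence times by the chosen inversion
#' scheme, intercoalescence times, then the spectrum assembly.
#'
#' @inheritParams expected_times
#' @param mutation_rate per-generation per-locus mutation rate.
#' @return a `frequency_spectrum`.
#' @examples
#' fs <- expected_afs(logistic_growth(1e4, 0.003, 5000), n = 51,
#'                    mutation_rate = 1e-3, method = "analytic")
#' head(fs$counts)
#' @export
expected_afs <- function(model, n, mutation_rate,
                         method = c("finite_sum", "root", "analytic"),
                         cfg = finite_sum_config(), tol = 1e-10) {
  method <- match.arg(method)
  ET <- as.numeric(expected_times(model, n, method, cfg, tol))
  EW <- intercoalescence_times(ET, n)
  expected_spectrum(EW, n, mutation_rate)
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat(sprintf("<frequency_spectrum: n = %d, mu = %g>\n", x$n, x$mutation_rate))
  cat(sprintf("  E[S] total = %.6g; singleton share = %.4f\n",
              sum(x$counts),
              if (all(is.na(x$proportions))) NA_real_ else x$proportions[1L]))
  invisible(x)
}
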