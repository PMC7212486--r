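#' Sample coalescence times of one genealogy under a demography
#'
#' Draws the standard-coalescent scaled epoch lengths (independent
#' exponentials with rate `k(k-1)/2` while `k` lineages remain), accumulates
#' them into scaled coalescence times `tau_m`, and maps each back to
#' generations through the numerical inverse of the time-scaling function
#' (closed forms where available, otherwise cached high-order quadrature with
#' Newton refinement to 1e-8 relative).
#'
#' Uses the current R random number generator state; seed it with
#' [set.seed()] (or use [estimate_afs_mc()], which seeds explicitly).
#'
#' @param model a `demography_model`.
#' @param n sample size `>= 2`.
#' @param inverter optional vectorised inverse of `g`, as produced internally;
#'   pass it when sampling many genealogies to reuse the cached grid.
#' @return vector of sampled `T_m`, `m = 1, ..., n-1` (generations), strictly
#'   decreasing in `m`.
#' @export
sample_genealogy_times <- function(model, n, inverter = NULL) {
  n <- check_sample_size(n)
  if (is.null(inverter)) inverter <- make_scale_inverter(model, tol = 1e-8)
  k <- n:2
  w <- stats::rexp(n - 1L, rate = k * (k - 1) / 2)   # epochs, k = n..2
  tau <- rev(cumsum(w))                              # tau_m, m = 1..n-1
  inverter(tau)
}

#' Monte-Carlo estimate of coalescence times and the expected AFS
#'
#' Simulates `reps` independent genealogies under the demography, inverts
#' every scaled coalescence time to generations, and summarises (i) the
#' per-level coalescence times and (ii) the spectrum entries obtained by
#' evaluating the branch-size mixture with each replicate's intercoalescence
#' times.  Mutation placement is integrated out analytically
#' (Rao-Blackwellised), so the standard errors reflect genealogical noise
#' only.
#'
#' @param model a `demography_model`.
#' @param n sample size `>= 2`.
#' @param mutation_rate per-generation per-locus rate `>= 0`.
#' @param reps number of replicate genealogies, `>= 1`.
#' @param seed integer seed; identical seed and parameters reproduce the
#'   estimate bit-for-bit.
#' @return an object of class `mc_estimate` with fields `n`, `reps`, `seed`,
#'   `mean_T`, `se_T` (generations, indexed `m = 1..n-1`), `mean_counts`,
#'   `se_counts` (spectrum entries, indexed `j = 1..n-1`).  Standard errors
#'   are `NA` when `reps == 1`.
#' @examples
#' est <- estimate_afs_mc(constant_size(1000), n = 10, mutation_rate = 1e-3,
#'                        reps = 200, seed = 1)
#' est$mean_T[1]    # close to 2 * 1000 * (1 - 1/10)
#' @export
estimate_afs_mc <- function(model, n, mutation_rate, reps, seed) {
  n <- check_sample_size(n)
  mutation_rate <- check_scalar_number(mutation_rate, "mutation_rate", 0)
  if (length(reps) != 1L || !is.numeric(reps) || reps < 1 || reps != round(reps))
    stop_validation("'reps' must be a single integer >= 1")
  reps <- as.integer(reps)
  if (length(seed) != 1L || !is.numeric(seed) || seed != round(seed))
    stop_validation("'seed' must be a single integer")
  seed <- as.integer(seed)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")

  inverter <- make_scale_inverter(model, tol = 1e-8)
  k <- n:2
  rates <- k * (k - 1) / 2
  # scaled epochs; columns are replicates, rows k = n..2
  W <- matrix(stats::rexp((n - 1L) * reps, rate = rates), nrow = n - 1L)
  # scaled coalescence times: row r is tau_{n-r} (ascending down the column)
  TAU <- apply(W, 2L, cumsum)
  if (n == 2L) TAU <- matrix(TAU, nrow = 1L)
  Tgen <- matrix(inverter(as.vector(TAU)), nrow = n - 1L)

  # intercoalescence times in generations, rows k = n..2
  Wgen <- Tgen - rbind(0, Tgen[-(n - 1L), , drop = FALSE])

  # spectrum mixture: counts_j = sum_k P[j,k] * mu * k * W_k; rows of Wgen are
  # k = n..2, so flip to k = 2..n
  jj <- seq_len(n - 1L)
  lp <- outer(jj, 2:n, function(j, kk)
    lchoose_lg(n - j - 1, kk - 2) - lchoose_lg(n - 1, kk - 1))
  P <- exp(lp); P[!is.finite(lp)] <- 0
  K <- P * rep(mutation_rate * (2:n), each = n - 1L)
  Cnt <- K %*% Wgen[rev(seq_len(n - 1L)), , drop = FALSE]

  # per-level times in m = 1..n-1 order (row r of Tgen is m = n-r)
  Tm <- Tgen[rev(seq_len(n - 1L)), , drop = FALSE]

  sd_or_na <- function(M) {
    if (reps == 1L) rep(NA_real_, nrow(M))
    else apply(M, 1L, stats::sd) / sqrt(reps)
  }
  structure(list(
    n = n, reps = reps, seed = seed,
    mean_T = rowMeans(Tm), se_T = sd_or_na(Tm),
    mean_counts = as.numeric(rowMeans(Cnt)), se_counts = sd_or_na(Cnt)),
    class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("<mc_estimate: n = %d, reps = %d, seed = %d>\n",
              x$n, x$reps, x$seed))
  cat(sprintf("  mean T1 = %.6g (se %.3g) generations\n",
              x$mean_T[1L], x$se_T[1L]))
  invisible(x)
}
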