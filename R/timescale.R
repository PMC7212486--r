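#' Discretisation controls for the finite-sum time-scale scan
#'
#' The finite-sum scheme replaces the integral `g(t) = integral_0^t 1/N(u) du`
#' with a left-endpoint Riemann sum on a regular grid of generation steps and
#' scans it once from the present into the past.
#'
#' @param step generation increment of the scan (default 1 generation, the
#'   natural unit of the discrete-generation derivation).  Use a
#'   sub-generation step when the history passes through very small sizes,
#'   where the per-step mass `step/N` becomes coarse.
#' @param max_time guard on the total number of generations scanned; exceeding
#'   it raises a non-coalescing-history error.
#' @param overshoot_rule how to resolve the grid point once the accumulated sum
#'   first reaches a target: `"table1"` returns the current step `t` whenever
#'   the overshoot `G - mu` is smaller than the last increment (and `t - step`
#'   otherwise -- unreachable with exact arithmetic, retained as rounding
#'   protection); `"nearest"` returns whichever of `t - step`, `t` has
#'   accumulated sum closest to the target.
#' @return a list of class `finite_sum_config`.
#' @export
finite_sum_config <- function(step = 1, max_time = 1e8,
                              overshoot_rule = c("table1", "nearest")) {
  structure(list(
    step = check_scalar_number(step, "step", 0, strict = TRUE),
    max_time = check_scalar_number(max_time, "max_time", 0, strict = TRUE),
    overshoot_rule = match.arg(overshoot_rule)),
    class = "finite_sum_config")
}

as_fs_config <- function(cfg) {
  if (is.null(cfg)) finite_sum_config()
  else if (inherits(cfg, "finite_sum_config")) cfg
  else do.call(finite_sum_config, cfg)
}

#' Time-scaling function by finite summation
#'
#' Left-endpoint Riemann approximation of `g(t)`: the sum of `step/N(u)` over
#' `u = 0, step, 2*step, ... <= t`.  With `step = 1` this is exactly the
#' accumulator driven by the generation-stepping scan (the sum starts at
#' `step/N(0)`, so `scale_time_numeric(model, 0)` equals `step/N(0)`, not 0).
#'
#' @param model a `demography_model`.
#' @param t vector of backward times (generations), `>= 0`.
#' @param cfg a [finite_sum_config()] (or list of its fields).
#' @return scaled times (dimensionless), non-decreasing in `t`.
#' @export
scale_time_numeric <- function(model, t, cfg = finite_sum_config()) {
  stopifnot(inherits(model, "demography_model"))
  cfg <- as_fs_config(cfg)
  if (any(t < 0)) stop_validation("'t' must be >= 0")
  sizef <- size_closure(model)
  vapply(t, function(ti) {
    u <- seq(0, ti, by = cfg$step)
    n <- sizef(u)
    if (!all(is.finite(n)) || any(n <= 0))
      stop_numeric(sprintf("non-finite population size at u = %g",
                           u[which(!is.finite(n) | n <= 0)[1L]]))
    sum(cfg$step / n)
  }, numeric(1))
}

#' Closed-form time-scaling function g(t)
#'
#' Analytic `g(t) = integral_0^t 1/N(u) du` for the families where it exists:
#' constant (`t/N0`), exponential (`(e^(gamma t) - 1)/(N0 gamma)`), and
#' logistic.  The logistic form was obtained by integrating the reciprocal of
#' the backward logistic size directly:
#' `g(t) = ((Nk - 1) e^(-gamma*onset) (e^(gamma t) - 1) + gamma t) / (Nk gamma)`,
#' and is validated against adaptive quadrature in the test suite.
#'
#' @inheritParams scale_time_numeric
#' @return scaled times (dimensionless).
#' @export
scale_time_analytic <- function(model, t) {
  stopifnot(inherits(model, "demography_model"))
  if (any(t < 0)) stop_validation("'t' must be >= 0")
  if (!is.null(model$size_floor))
    stop_unsupported_family(paste0(model$family, " (with size_floor)"),
                            "scale_time_analytic")
  p <- model$params
  switch(model$family,
    constant = t / p$N0,
    exponential = expm1(p$gamma * t) / (p$N0 * p$gamma),
    logistic = {
      # (Nk-1) e^{-gT} (e^{gt}-1) computed as (Nk-1)(e^{g(t-T)} - e^{-gT})
      # to avoid overflow of e^{gt} at large onset*gamma
      a <- (p$Nk - 1) * (exp(p$gamma * (t - p$onset)) - exp(-p$gamma * p$onset))
      (a + p$gamma * t) / (p$Nk * p$gamma)
    },
    stop_unsupported_family(model$family, "scale_time_analytic"))
}

# Internal: cached composite quadrature of g(t) = int_0^t 1/N for families
# without a closed form.  Cumulative 5-point Gauss-Legendre per unit
# generation (effectively exact for the smooth reciprocals arising here),
# extended lazily into the past.  Reciprocal sizes that overflow (N underflown
# to ~0 deep in the past of a collapsing history) are clamped to 1e12 per
# generation; any realistic scaled-time target (mu < ~2 log n) is reached long
# before the clamp can bias a result.
make_quad_g <- function(model) {
  sizef <- size_closure(model)
  gl_x <- c(0.0469100770306680, 0.2307653449471585, 0.5,
            0.7692346550528415, 0.9530899229693320)
  gl_w <- c(0.1184634425280945, 0.2393143352496832, 0.2844444444444444,
            0.2393143352496832, 0.1184634425280945)
  grid_G <- 0                 # cumulative g at integer grid 0..M
  recip <- function(u) {
    f <- 1 / sizef(u)
    f[!is.finite(f)] <- 1e12
    f
  }
  ensure <- function(upto) {
    m0 <- length(grid_G) - 1L
    upto <- as.integer(ceiling(upto))
    if (upto <= m0) return(invisible())
    new_t <- (m0 + 1L):upto
    nodes <- rep(new_t - 1, each = 5L) + rep(gl_x, times = length(new_t))
    seg <- colSums(matrix(recip(nodes) * rep(gl_w, times = length(new_t)),
                          nrow = 5L))
    grid_G <<- c(grid_G, grid_G[m0 + 1L] + cumsum(seg))
    invisible()
  }
  g <- function(t) {
    if (any(t < 0)) stop_validation("'t' must be >= 0")
    if (length(t) == 0L) return(numeric(0))
    ensure(max(t))
    i <- floor(t)
    h <- t - i
    nodes <- rep(i, each = 5L) + rep(gl_x, times = length(t)) * rep(h, each = 5L)
    part <- colSums(matrix(recip(nodes) * rep(gl_w, times = length(t)),
                           nrow = 5L)) * h
    grid_G[i + 1L] + part
  }
  list(g = g, ensure = ensure,
       grid_max = function() grid_G[length(grid_G)],
       grid = function() grid_G)
}

# Internal: best available evaluator of g for a model -- exact closed forms
# for constant/exponential/logistic, exact epoch sums for piecewise, cached
# composite quadrature otherwise (gompertz, size_floor).
g_evaluator <- function(model) {
  p <- model$params
  if (is.null(model$size_floor) &&
      model$family %in% c("constant", "exponential", "logistic"))
    return(function(t) scale_time_analytic(model, t))
  if (is.null(model$size_floor) && model$family == "piecewise") {
    G <- c(0, cumsum(diff(p$time) / p$size[-length(p$size)]))
    return(function(t) {
      i <- findInterval(t, p$time)
      G[i] + (t - p$time[i]) / p$size[i]
    })
  }
  make_quad_g(model)$g
}

#' Invert the time scale by the single-pass finite-sum scan
#'
#' Implements the generation-stepping procedure: initialise `t = 0`,
#' `G = step/N(0)`; for each target scaled time `mu` (consumed in ascending
#' order, i.e. the level `n-1` target first), advance `t` by `step` and
#' accumulate `G <- G + step/N(t)` while `G < mu`, then settle the boundary
#' according to `cfg$overshoot_rule`.  The scan never rewinds between targets,
#' so the total number of `N(t)` evaluations is governed by the largest target
#' alone; the count is returned in the `"n_evaluations"` attribute.
#'
#' The classic `Else` branch (return `t - step`) is unreachable when the loop
#' guard is `G < mu`, because the final increment is exactly `step/N(t)` and
#' hence `G - mu < step/N(t)` always holds; it is retained under
#' `overshoot_rule = "table1"` purely as floating-point rounding protection.
#'
#' A warning suggesting a sub-generation step is emitted when the scan meets
#' sizes below 100 with `step >= 1`, where the per-step mass `1/N` is coarse.
#'
#' @param model a `demography_model`.
#' @param targets strictly positive scaled times sorted increasingly (the
#'   consumption order of the scan).
#' @param cfg a [finite_sum_config()].
#' @return generation times in consumption order (non-decreasing), with
#'   attribute `n_evaluations` counting `N(t)` evaluations consumed.
#' @export
invert_scale_finite_sum <- function(model, targets, cfg = finite_sum_config()) {
  stopifnot(inherits(model, "demography_model"))
  cfg <- as_fs_config(cfg)
  if (length(targets) < 1L || any(!is.finite(targets)) || any(targets <= 0))
    stop_validation("'targets' must be finite and > 0")
  if (is.unsorted(targets))
    stop_validation("'targets' must be sorted ascending (smallest scaled time first)")
  sizef <- size_closure(model)
  step <- cfg$step

  n0 <- sizef(0)
  t <- 0
  inc <- step / n0
  G <- inc
  nev <- 1L
  small_seen <- n0 < 100 && step >= 1
  out <- numeric(length(targets))

  for (i in seq_along(targets)) {
    mu <- targets[i]
    while (G < mu) {
      t <- t + step
      if (t > cfg$max_time)
        stop_numeric(sprintf(
          "history did not accumulate scaled time %g within max_time = %g generations",
          mu, cfg$max_time), class = "coalafs_non_coalescing_error")
      nt <- sizef(t)
      nev <- nev + 1L
      if (!is.finite(nt) || nt <= 0)
        stop_numeric(sprintf("non-finite population size at t = %g", t))
      if (nt < 100 && step >= 1) small_seen <- TRUE
      inc <- step / nt
      G <- G + inc
    }
    out[i] <- if (cfg$overshoot_rule == "table1") {
      if (G - mu < inc) t else t - step
    } else {
      if (abs(G - mu) <= abs((G - inc) - mu)) t else t - step
    }
  }
  if (small_seen)
    warning("population sizes below 100 encountered; a sub-generation step ",
            "(e.g. step = 0.01) is recommended for the finite-sum scan",
            call. = FALSE)
  structure(out, n_evaluations = nev)
}

#' Invert the time scale by bracketed root-finding
#'
#' Solves `g(t) = mu` with `g` taken from the closed form when the family has
#' one and adaptive quadrature otherwise.  The root is bracketed by geometric
#' expansion (doubling from the initial guess `N(0) * mu`) and located with a
#' bracketed hybrid solver (bisection plus inverse interpolation), then
#' polished with Newton steps (`g'(t) = 1/N(t)`) until
#' `|g(t) - mu| <= tol * max(1, mu)`.
#'
#' @param model a `demography_model`.
#' @param target scaled time `mu > 0` (vectorised).
#' @param tol relative tolerance on `g` (default 1e-10).
#' @param max_time bracket expansion cap in generations.
#' @return generation times `t*`.
#' @export
invert_scale_root <- function(model, target, tol = 1e-10, max_time = 1e8) {
  stopifnot(inherits(model, "demography_model"))
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0)
    stop_validation("'tol' must be a single positive number")
  if (any(!is.finite(target)) || any(target <= 0))
    stop_validation("'target' must be finite and > 0")
  g <- g_evaluator(model)
  sizef <- size_closure(model)
  vapply(target, function(mu) {
    hi <- min(max(sizef(0) * mu, 1), max_time)
    while (g(hi) < mu) {
      if (hi >= max_time)
        stop_numeric(sprintf(
          "no bracket for scaled time %g within max_time = %g generations",
          mu, max_time), class = "coalafs_non_coalescing_error")
      hi <- min(hi * 2, max_time)
    }
    # residual clamped above (sign-preserving) so the hybrid solver's
    # interpolation never overflows on violently exploding g
    t <- stats::uniroot(function(x) pmin(g(x) - mu, 1e8), lower = 0, upper = hi,
                        tol = max(1e-12, tol) * max(1, hi))$root
    # Newton polish on the residual in g
    for (it in 1:50) {
      r <- g(t) - mu
      if (abs(r) <= tol * max(1, mu)) break
      t <- max(t - r * sizef(t), 0)
    }
    t
  }, numeric(1))
}

#' Invert the time scale in closed form
#'
#' Constant: `t = N0 * mu`.  Exponential: `t = log(N0 gamma mu + 1) / gamma`
#' (`log1p` keeps the small-rate limit `t -> N0 mu` accurate).  Logistic: the
#' principal-branch Lambert-W inverse of the verified logistic `g`, derived by
#' solving `gamma t + A e^(gamma t) = B` with `A = (Nk-1) e^(-gamma*onset)` and
#' `B = A + Nk gamma mu`, giving `t = (B - W(A e^B)) / gamma`; the W argument
#' is handled on the log scale so that large `B` does not overflow.
#'
#' @param model a `demography_model` of family constant, exponential or
#'   logistic (no `size_floor`).
#' @param target scaled time(s) `mu > 0` (vectorised).
#' @return generation times.
#' @export
invert_scale_analytic <- function(model, target) {
  stopifnot(inherits(model, "demography_model"))
  if (any(!is.finite(target)) || any(target <= 0))
    stop_validation("'target' must be finite and > 0")
  if (!is.null(model$size_floor))
    stop_unsupported_family(paste0(model$family, " (with size_floor)"),
                            "invert_scale_analytic")
  p <- model$params
  switch(model$family,
    constant = p$N0 * target,
    exponential = log1p(p$N0 * p$gamma * target) / p$gamma,
    logistic = {
      A <- (p$Nk - 1) * exp(-p$gamma * p$onset)
      B <- A + p$Nk * p$gamma * target
      if (A == 0) return(p$Nk * target)      # degenerate Nk = 1: g = t/Nk
      w <- lambert_w_exp(log(A) + B)
      t <- (B - w) / p$gamma
      if (any(!is.finite(t)) || any(t < 0))
        stop_numeric(sprintf(
          "Lambert-W inversion failed (Nk = %g, gamma = %g, onset = %g, mu = %g)",
          p$Nk, p$gamma, p$onset, target[which(!is.finite(t) | t < 0)[1L]]))
      pmax(t, 0)
    },
    stop_unsupported_family(model$family, "invert_scale_analytic"))
}

# Internal: vectorised inverse of g for any family, used by the Monte-Carlo
# sampler.  Closed forms where available; exact epoch inversion for piecewise;
# otherwise a cached cumulative Gauss-Legendre grid (5-point per generation,
# effectively exact for smooth 1/N) refined by Newton to |g - tau| <=
# tol * max(1, tau).
make_scale_inverter <- function(model, tol = 1e-8, max_time = 1e8) {
  p <- model$params
  if (is.null(model$size_floor) &&
      model$family %in% c("constant", "exponential", "logistic"))
    return(function(tau) invert_scale_analytic(model, tau))
  if (is.null(model$size_floor) && model$family == "piecewise") {
    G <- c(0, cumsum(diff(p$time) / p$size[-length(p$size)]))
    return(function(tau) {
      i <- findInterval(tau, G)
      p$time[i] + (tau - G[i]) * p$size[i]
    })
  }
  sizef <- size_closure(model)
  quad <- make_quad_g(model)
  function(tau) {
    if (any(!is.finite(tau)) || any(tau < 0))
      stop_validation("'tau' must be finite and >= 0")
    tmax <- 64
    repeat {
      quad$ensure(tmax)
      if (quad$grid_max() >= max(tau)) break
      tmax <- tmax * 2
      if (tmax > max_time)
        stop_numeric("history does not accumulate the requested scaled time",
                     class = "coalafs_non_coalescing_error")
    }
    G <- quad$grid()
    i <- findInterval(tau, G)             # t in [i-1, i]
    lo <- i - 1
    t <- lo + (tau - G[i]) / pmax(G[i + 1L] - G[i], 1e-300)
    t <- pmin(pmax(t, lo), i)
    for (it in 1:60) {
      r <- quad$g(t) - tau
      if (max(abs(r) / pmax(1, tau)) <= tol) break
      dN <- sizef(t)
      dN[!is.finite(dN) | dN <= 0] <- 1e-12
      t <- t - r * dN
      t <- pmin(pmax(t, lo), i)
    }
    t
  }
}
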