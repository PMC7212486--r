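#' Demographic models of haploid population size in backward time
#'
#' A `demography_model` describes the haploid population size `N(t)` as a
#' function of backward time `t` in generations, with `t = 0` the present.
#' Sizes are counted in sequences (haploid size); diploid census sizes must be
#' doubled by the caller (the CLI does this with `--diploid`).
#'
#' Five families are supported:
#' \describe{
#'   \item{constant}{`N(t) = N0`.}
#'   \item{exponential}{`N(t) = N0 * exp(-gamma * t)`: a population growing
#'     exponentially forward in time at rate `gamma`, so it shrinks backward.}
#'   \item{logistic}{Logistic growth from a founding size of one sequence at
#'     backward time `onset` (generations since growth began) towards carrying
#'     capacity `Nk` with intrinsic rate `gamma`.  In backward time
#'     `N(t) = Nk * exp(gamma*onset) / (exp(gamma*onset) + (Nk-1)*exp(gamma*t))`,
#'     evaluated for all `t >= 0`; beyond `onset` the size continues to decay
#'     below one, which guarantees coalescence and matches the analytic form.}
#'   \item{gompertz}{Growth from founding size `N0` at backward time `onset`
#'     whose per-capita rate starts at `gamma` and decays exponentially at
#'     rate `alpha`.  The backward form is obtained by substituting forward
#'     time `onset - t` into the forward solution:
#'     `N(t) = N0 * exp((gamma/alpha) * (1 - exp(-alpha*(onset - t))))`.}
#'   \item{piecewise}{A right-continuous step function given by breakpoints
#'     `(t_i, N_i)` with `t_1 = 0`; the last size extends to infinity.}
#' }
#'
#' `size_floor`, when given, clamps `N(t)` from below.  The default (no floor)
#' follows the analytic treatment of the growth models verbatim; a floor is a
#' deliberate departure useful to emulate a constant ancestral size.
#'
#' @param family one of `"constant"`, `"exponential"`, `"logistic"`,
#'   `"gompertz"`, `"piecewise"`.
#' @param params named list of family parameters: `N0`, `gamma`, `Nk`,
#'   `alpha`, `onset`, or for piecewise `time` and `size` vectors.
#' @param size_floor optional positive lower bound applied to every evaluated
#'   size.
#' @return an object of class `demography_model`.
#' @examples
#' m <- build_demography("logistic", list(Nk = 1e4, gamma = 0.003, onset = 5000))
#' population_size(m, c(0, 5000))
#' @export
build_demography <- function(family, params, size_floor = NULL) {
  family <- match.arg(family,
                      c("constant", "exponential", "logistic", "gompertz",
                        "piecewise"))
  if (!is.null(size_floor))
    size_floor <- check_scalar_number(size_floor, "size_floor", 0, strict = TRUE)
  p <- switch(family,
    constant = list(N0 = check_scalar_number(params$N0, "N0", 0, strict = TRUE)),
    exponential = list(
      N0    = check_scalar_number(params$N0, "N0", 0, strict = TRUE),
      gamma = check_scalar_number(params$gamma, "gamma", 0, strict = TRUE)),
    logistic = list(
      Nk    = check_scalar_number(params$Nk, "Nk", 0, strict = TRUE),
      gamma = check_scalar_number(params$gamma, "gamma", 0, strict = TRUE),
      onset = check_scalar_number(params$onset, "onset", 0, strict = TRUE)),
    gompertz = list(
      N0    = check_scalar_number(params$N0, "N0", 0, strict = TRUE),
      gamma = check_scalar_number(params$gamma, "gamma", 0, strict = TRUE),
      alpha = check_scalar_number(params$alpha, "alpha", 0, strict = TRUE),
      onset = check_scalar_number(params$onset, "onset", 0, strict = TRUE)),
    piecewise = validate_piecewise(params))
  structure(list(family = family, params = p, size_floor = size_floor),
            class = "demography_model")
}

validate_piecewise <- function(params) {
  time <- params$time
  size <- params$size
  if (is.null(time) || is.null(size))
    stop_validation("piecewise models need 'time' and 'size' vectors")
  if (length(time) != length(size) || length(time) < 1L)
    stop_validation("'time' and 'size' must have equal positive length")
  time <- as.numeric(time); size <- as.numeric(size)
  if (!all(is.finite(time)) || !all(is.finite(size)))
    stop_validation("piecewise 'time'/'size' must be finite")
  if (time[1L] != 0)
    stop_validation("piecewise breakpoints must start at time 0 (field 'time')")
  if (is.unsorted(time, strictly = TRUE))
    stop_validation("piecewise breakpoints must be strictly increasing (field 'time')")
  if (any(size <= 0))
    stop_validation("piecewise sizes must all be > 0 (field 'size')")
  list(time = time, size = size)
}

#' Convenience constructors for the demographic families
#'
#' Thin wrappers around [build_demography()].  `onset` is the number of
#' generations since growth began (the growth duration, often written `T`);
#' `gamma` is a per-generation rate.
#'
#' @param N0,Nk,gamma,alpha,onset family parameters, see [build_demography()].
#' @param time,size piecewise breakpoints (backward generations, first must be
#'   0) and haploid sizes.
#' @param size_floor optional lower clamp on `N(t)`.
#' @name demography-constructors
NULL

#' @rdname demography-constructors
#' @export
constant_size <- function(N0, size_floor = NULL)
  build_demography("constant", list(N0 = N0), size_floor)

#' @rdname demography-constructors
#' @export
exponential_growth <- function(N0, gamma, size_floor = NULL)
  build_demography("exponential", list(N0 = N0, gamma = gamma), size_floor)

#' @rdname demography-constructors
#' @export
logistic_growth <- function(Nk, gamma, onset, size_floor = NULL)
  build_demography("logistic", list(Nk = Nk, gamma = gamma, onset = onset),
                   size_floor)

#' @rdname demography-constructors
#' @export
gompertz_growth <- function(N0, gamma, alpha, onset, size_floor = NULL)
  build_demography("gompertz",
                   list(N0 = N0, gamma = gamma, alpha = alpha, onset = onset),
                   size_floor)

#' @rdname demography-constructors
#' @export
piecewise_history <- function(time, size, size_floor = NULL)
  build_demography("piecewise", list(time = time, size = size), size_floor)

# Fast evaluation closure: skips argument checking in inner loops.  All
# returned closures are vectorised over t.
size_closure <- function(model) {
  p <- model$params
  f <- switch(model$family,
    constant    = function(t) rep_len(p$N0, length(t)),
    exponential = function(t) p$N0 * exp(-p$gamma * t),
    # numerically stable backward logistic:
    # Nk e^{gT} / (e^{gT} + (Nk-1) e^{gt}) == Nk / (1 + (Nk-1) e^{g(t-T)})
    logistic    = function(t) p$Nk / (1 + (p$Nk - 1) * exp(p$gamma * (t - p$onset))),
    gompertz    = function(t)
      p$N0 * exp((p$gamma / p$alpha) * (1 - exp(-p$alpha * (p$onset - t)))),
    piecewise   = function(t) p$size[findInterval(t, p$time)])
  if (is.null(model$size_floor)) f
  else {
    floor_ <- model$size_floor
    function(t) pmax(f(t), floor_)
  }
}

#' Evaluate the haploid population size N(t)
#'
#' @param model a `demography_model`.
#' @param t vector of backward times in generations, all `>= 0`.
#' @return vector of haploid sizes, all `> 0`.
#' @examples
#' population_size(logistic_growth(1e4, 0.003, 5000), c(0, 5000))
#' @export
population_size <- function(model, t) {
  stopifnot(inherits(model, "demography_model"))
  if (!is.numeric(t) || anyNA(t))
    stop_validation("'t' must be numeric and non-missing")
  if (any(t < 0))
    stop_validation(sprintf("backward time must be >= 0 (got %g)", min(t)))
  n <- size_closure(model)(t)
  bad <- !is.finite(n) | n <= 0
  if (any(bad))
    stop_numeric(sprintf(
      "population size evaluated to a non-positive or non-finite value at t = %g",
      t[which(bad)[1L]]))
  n
}

#' Relative size function lambda(t) = N(t) / N(0)
#'
#' @inheritParams population_size
#' @return dimensionless vector; `relative_size(model, 0)` is exactly 1.
#' @export
relative_size <- function(model, t) {
  population_size(model, t) / population_size(model, 0)
}

#' Read a piecewise size history from a headered TSV
#'
#' The file must have columns `time_generations` (real, `>= 0`, strictly
#' increasing, first row 0) and `haploid_size` (real, `> 0`).
#'
#' @param path path to a tab-separated file.
#' @param size_floor optional lower clamp on `N(t)`.
#' @return a piecewise `demography_model`.
#' @examples
#' path <- system.file("extdata", "example_history.tsv", package = "coalafs")
#' m <- read_piecewise_history(path)
#' population_size(m, c(0, 1000, 5000))
#' @export
read_piecewise_history <- function(path, size_floor = NULL) {
  if (!file.exists(path))
    stop_validation(sprintf("piecewise history file not found: %s", path))
  d <- utils::read.delim(path, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("time_generations", "haploid_size")
  if (!all(need %in% names(d)))
    stop_validation(sprintf("piecewise history must have columns %s",
                            paste(need, collapse = ", ")))
  piecewise_history(d$time_generations, d$haploid_size, size_floor)
}

#' @export
print.demography_model <- function(x, ...) {
  cat(sprintf("<demography_model: %s>\n", x$family))
  if (x$family == "piecewise") {
    cat(sprintf("  %d epochs; N(0) = %g, ancestral N = %g\n",
                length(x$params$time), x$params$size[1L],
                x$params$size[length(x$params$size)]))
  } else {
    cat("  ", paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
                    collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$size_floor))
    cat(sprintf("  size floor: %g\n", x$size_floor))
  invisible(x)
}
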