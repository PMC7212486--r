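# Principal-branch Lambert W evaluated on a log-scale argument.
#
# lambert_w_exp(z) returns W0(exp(z)) for real z, vectorised.  Working from
# log(x) rather than x matters here: inverting the logistic time scale needs
# W(A * exp(B)) where B = A + Nk*gamma*tau can exceed 700, so exp(B) itself
# overflows double precision long before the answer does.
#
# For exp(z) > 0 the principal branch solves w + log(w) = z with w > 0, a
# strictly increasing concave equation solved by safeguarded Newton steps.
lambert_w_exp <- function(z) {
  if (!is.numeric(z)) stop_validation("'z' must be numeric")
  w <- ifelse(z > 1, z - log(pmax(z, 1.1)), exp(z) / (1 + exp(z)))
  w <- pmax(w, .Machine$double.xmin)
  for (iter in 1:100) {
    f <- w + log(w) - z
    step <- w * f / (w + 1)          # Newton on f, scaled form keeps w > 0
    wn <- w - step
    wn <- pmax(wn, w * 1e-3)         # safeguard: never collapse to <= 0
    done <- abs(f) <= 1e-14 * pmax(1, abs(z))
    if (all(done)) break
    w <- ifelse(done, w, wn)
  }
  w
}

# W0(x) for plain arguments, used where x is known to be moderate.
lambert_w0 <- function(x) {
  if (any(x < 0)) stop_numeric("Lambert W argument below 0 not supported here")
  ifelse(x == 0, 0, lambert_w_exp(log(x)))
}
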