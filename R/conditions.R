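# Condition helpers shared by all modules.  Two top-level classes are used so
# the CLI can map failures to distinct exit codes:
#   coalafs_validation_error - bad user input (parameters, preconditions, config)
#   coalafs_numeric_error    - failures arising during numerical evaluation
# Unsupported model/method pairings get their own subclass of the validation
# class so callers can fall back to a numeric scheme programmatically.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(msg, class = character(), call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "coalafs_validation_error"),
                      call = call))
}

stop_numeric <- function(msg, class = character(), call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "coalafs_numeric_error"),
                      call = call))
}

stop_unsupported_family <- function(family, what) {
  stop_validation(
    sprintf("family '%s' is not supported by %s", family, what),
    class = "coalafs_unsupported_family_error", call = sys.call(-1))
}

check_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (is.null(x) || length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop_validation(sprintf("'%s' must be a single finite number", name))
  if ((strict && x <= lower) || (!strict && x < lower))
    stop_validation(sprintf("'%s' must be %s %s (got %g)", name,
                            if (strict) ">" else ">=", format(lower), x))
  as.numeric(x)
}
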