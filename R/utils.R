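#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop() with a caller-friendly message.
abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a vector of action symbols
#'
#' Actions are encoded as the two-letter alphabet `"C"` (cooperate, the
#' standard price in the shop cover story) and `"D"` (defect, the sale
#' price). This helper checks encoding and returns the vector unchanged.
#'
#' @param actions character vector of `"C"`/`"D"` symbols.
#' @param what label used in error messages.
#' @return The validated character vector.
#' @export
as_actions <- function(actions, what = "actions") {
  actions <- as.character(actions)
  bad <- !(actions %in% c("C", "D"))
  abort_if(any(bad), sprintf(
    "%s must be 'C' or 'D'; found: %s", what,
    paste(unique(actions[bad]), collapse = ", ")
  ))
  actions
}

# Truncated-normal draws by inverse-CDF; degenerate at the mean when sd = 0.
# When the truncation interval lies in the parent's upper tail the CDF is
# evaluated as an upper-tail probability, which keeps full precision where
# pnorm would round to 1 (and symmetrically for the lower tail).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  abort_if(sd < 0, "sd must be non-negative")
  abort_if(lower >= upper, "lower truncation bound must be below upper")
  if (sd == 0) {
    abort_if(mean < lower || mean > upper,
             "degenerate distribution: mean outside truncation bounds")
    return(rep(mean, n))
  }
  qtruncnorm(stats::runif(n), mean, sd, lower, upper)
}

# Significance stars used throughout the rendered tables.
p_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("")
    if (x < 0.001) "***" else if (x < 0.01) "**" else if (x < 0.05) "*"
    else if (x < 0.1) "." else ""
  }, character(1))
}
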