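# Internal numeric helpers. Integration is trapezoidal everywhere (uniform
# grids assumed); angles are unwrapped before range statistics.

#' @importFrom pracma trapz cumtrapz
trapz_window <- function(t, y, i1, i2) {
  pracma::trapz(t[i1:i2], y[i1:i2])
}

# nearest-sample snap of a time to an index of t (uniform grid)
snap_index <- function(t, time) {
  i <- which.min(abs(t - time))
  i[[1L]]
}

stop_named <- function(stage, msg) {
  stop(sprintf("%s: %s", stage, msg), call. = FALSE)
}

# argument check returning the offending field name in the message
check_positive <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0) {
    stop(sprintf("invalid configuration: '%s' must be a positive finite number", field),
         call. = FALSE)
  }
  invisible(value)
}

check_nonneg <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value < 0) {
    stop(sprintf("invalid configuration: '%s' must be a non-negative finite number", field),
         call. = FALSE)
  }
  invisible(value)
}
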