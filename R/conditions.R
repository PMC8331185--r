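# Classed conditions used across the package.
#
# Hard contract violations abort with a classed error so callers can
# distinguish invalid configuration from invalid data. "Undefined" results
# (zero-variance correlation, CV with zero mean) are *signals*, not errors:
# they return NA_real_ and emit a classed warning.

abort_ecdysim <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ecdysim_error")))
}

signal_undefined <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "ecdysim_undefined")))
  NA_real_
}

#' @keywords internal
stopifnot_config <- function(ok, msg) {
  if (!ok) abort_ecdysim(msg, "ecdysim_invalid_config")
  invisible(TRUE)
}

stopifnot_data <- function(ok, msg) {
  if (!ok) abort_ecdysim(msg, "ecdysim_invalid_data")
  invisible(TRUE)
}

# Natural collation for muscle labels: M2 sorts before M12.
natural_key <- function(labels) {
  num <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", labels)))
  alpha <- sub("[0-9]+$", "", labels)
  order(alpha, num, labels)
}

natural_sort <- function(labels) labels[natural_key(labels)]
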