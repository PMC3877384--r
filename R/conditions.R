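# Classed conditions so callers (and the CLI) can map failures to exit codes.

iso_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "iso_error", "error", "condition")))
}

iso_format_error      <- function(msg) iso_error(msg, "iso_format_error")
iso_validation_error  <- function(msg) iso_error(msg, "iso_validation_error")
iso_convergence_error <- function(msg) iso_error(msg, "iso_convergence_error")
iso_coverage_error    <- function(msg) iso_error(msg, "iso_coverage_error")
iso_no_response_error <- function(msg) iso_error(msg, c("iso_no_response_error", "iso_validation_error"))
iso_no_intersection_error <- function(msg) iso_error(msg, c("iso_no_intersection_error", "iso_validation_error"))
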