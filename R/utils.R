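# Internal helpers shared across modules.

#' @importFrom rlang .data
NULL

# Classed errors so callers (and the CLI) can distinguish input problems
# from computation problems.
stop_pqi <- function(subclass, message, ...) {
  stop(structure(
    class = c(subclass, "pqi_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

abort_input   <- function(message, ...) stop_pqi("pqi_input_error", message, ...)
abort_routing <- function(message, ...) stop_pqi("pqi_routing_error", message, ...)
abort_config  <- function(message, ...) stop_pqi("pqi_config_error", message, ...)
abort_contract <- function(message, ...) stop_pqi("pqi_contract_error", message, ...)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# The four substitutable provider classes, in a fixed display order.
HCP_CLASSES <- c("private clinic", "public clinic",
                 "private hospital", "public hospital")

euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)
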