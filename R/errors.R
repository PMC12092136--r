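# Classed conditions so callers can distinguish failure modes programmatically.
# All errors inherit "nashnets_error"; the subclass names the failure mode.

nn_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "nashnets_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

nn_domain_error <- function(msg, ...) nn_abort(msg, "nashnets_domain_error", ...)
nn_input_error <- function(msg, ...) nn_abort(msg, "nashnets_input_error", ...)
nn_parse_error <- function(msg, ...) nn_abort(msg, "nashnets_parse_error", ...)
nn_resource_error <- function(msg, ...) nn_abort(msg, "nashnets_resource_error", ...)
nn_usage_error <- function(msg, ...) nn_abort(msg, "nashnets_usage_error", ...)
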