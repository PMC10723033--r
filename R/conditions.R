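# Classed conditions so callers (and the CLI) can map failures to exit codes.

stop_spotlayer <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "spotlayer_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

stop_validation <- function(msg) stop_spotlayer(msg, "spotlayer_validation_error")
stop_name       <- function(msg) stop_spotlayer(msg, "spotlayer_name_error")
stop_kind       <- function(msg) stop_spotlayer(msg, "spotlayer_kind_error")
stop_format     <- function(msg) stop_spotlayer(msg, "spotlayer_format_error")
stop_io         <- function(msg) stop_spotlayer(msg, "spotlayer_io_error")
stop_param      <- function(msg) stop_spotlayer(msg, "spotlayer_param_error")
stop_duplicate  <- function(msg) stop_spotlayer(msg, "spotlayer_duplicate_error")
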