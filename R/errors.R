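# Classed conditions so callers (and tests) can catch specific failures.

sponge_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(paste0("spongescan_", class), class,
                                     "spongescan_error"), ...))
}

#' @noRd
sponge_warn <- function(msg) warning(msg, call. = FALSE)

# Lightweight run log: messages at INFO level, suppressible via option.
sponge_log <- function(...) {
  if (isTRUE(getOption("spongescan.quiet", FALSE))) return(invisible(NULL))
  message("[spongescan] ", sprintf(...))
}
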