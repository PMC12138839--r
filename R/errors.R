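# Classed conditions so the command-line wrapper can map error families to
# distinct exit codes: config (bad settings/schema), data (bad input values),
# computation (a stage failed on valid input).

abort_config <- function(message) {
  rlang::abort(message, class = "warpnet_config_error")
}

abort_data <- function(message) {
  rlang::abort(message, class = "warpnet_data_error")
}

abort_compute <- function(message) {
  rlang::abort(message, class = "warpnet_compute_error")
}
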