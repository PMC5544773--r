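# Error taxonomy: argument errors (bad inputs, caught before computation)
# versus computation errors (valid inputs that lead to a degenerate result).
# The CLI maps these to distinct exit codes.

stop_argument <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("atr_argument_error", "atr_error")))
}

stop_computation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("atr_computation_error", "atr_error")))
}
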