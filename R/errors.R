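# Classed conditions so the CLI can map failures to exit codes
# (input error -> 2, numerical/solver error -> 3).

mg_stop_input <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("multigrank_input_error", "error")))
}

mg_stop_solver <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("multigrank_solver_error", "error")))
}

mg_stop_internal <- function(..., call. = FALSE) {
  stop(errorCondition(paste0("internal invariant breach: ", ...),
                      class = c("multigrank_internal_error", "error")))
}
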