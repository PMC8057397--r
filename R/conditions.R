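# Structured error conditions. Every anticipated failure carries a class so
# callers (and the CLI exit-code mapping) can dispatch without parsing text.

wb_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "wearbio_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

wb_io_error         <- function(msg) wb_stop(msg, "wearbio_io_error")
wb_contract_error   <- function(msg) wb_stop(msg, "wearbio_contract_error")
wb_empty_input      <- function(msg) wb_stop(msg, "wearbio_empty_input")
wb_untrainable      <- function(msg) wb_stop(msg, "wearbio_untrainable_labels")
wb_insufficient     <- function(msg) wb_stop(msg, "wearbio_insufficient_data")
wb_no_features      <- function(msg) wb_stop(msg, "wearbio_no_features")
wb_no_resting_data  <- function(msg) wb_stop(msg, "wearbio_no_resting_data")
wb_degenerate       <- function(msg) wb_stop(msg, "wearbio_degenerate_smoothing")

# Re-raise any wearbio error with the pipeline stage prepended, preserving
# the condition class so exit-code mapping still works.
with_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, wearbio_error = function(e) {
      e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
      stop(e)
    }),
    warning = function(w) {
      warning(sprintf("[stage %s] %s", stage, conditionMessage(w)), call. = FALSE)
      invokeRestart("muffleWarning")
    }
  )
}
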