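# classed error conditions so callers can distinguish failure modes
sc_stop <- function(class, msg, ..., data = NULL) {
  cond <- errorCondition(sprintf(msg, ...),
                         class = c(paste0("spinecobb_", class), "spinecobb_error"))
  if (!is.null(data)) cond$data <- data
  stop(cond)
}
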