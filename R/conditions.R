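# Classed conditions so callers can distinguish failure modes programmatically.
# Every error raised by the package carries class c("graintomo_<what>", "graintomo_error").

gt_error <- function(class, message, ...) {
  stop(structure(
    class = c(paste0("graintomo_", class), "graintomo_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

gt_assert <- function(cond, class, message, ...) {
  if (!isTRUE(cond)) gt_error(class, message, ...)
  invisible(TRUE)
}
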