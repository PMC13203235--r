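#' @keywords internal
tv_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

tv_assert <- function(ok, class, msg) {
  if (!isTRUE(ok)) tv_error(class, msg)
  invisible(TRUE)
}
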