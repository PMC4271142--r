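# Condition system shared by all engine components. Every user-facing error
# is a classed condition under "ps_error" so callers (and the CLI) can map
# error families to exit codes without string matching.

ps_condition <- function(subclass, message, pos = NULL, data = list()) {
  if (!is.null(pos)) {
    message <- sprintf("%s [%s:%d:%d]", message, pos$file, pos$line, pos$col)
  }
  structure(
    class = c(subclass, "ps_error", "error", "condition"),
    list(message = message, call = NULL, pos = pos, data = data)
  )
}

ps_stop <- function(subclass, message, pos = NULL, data = list()) {
  stop(ps_condition(subclass, message, pos = pos, data = data))
}

# Source position attached to tokens, nodes and diagnostics. line/col are
# 1-based and always point into the original (pre-include) file.
source_pos <- function(file, line, col) {
  stopifnot(line >= 1L, col >= 1L)
  list(file = file, line = as.integer(line), col = as.integer(col))
}

fmt_pos <- function(pos) {
  if (is.null(pos)) return("<unknown>")
  sprintf("%s:%d:%d", pos$file, pos$line, pos$col)
}
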