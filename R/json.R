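# Canonical JSON encoder used for checkpoint files.
#
# Checkpoints must satisfy load-then-save byte identity, so the writer is
# deterministic: object keys are emitted sorted, numbers use a fixed
# shortest-round-trip format, and no whitespace depends on input order.
# Reading goes through jsonlite (simplifyVector = FALSE) so the decoded
# structure feeds straight back into this writer.

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  # remaining control characters, rare but must not corrupt the container
  if (grepl("[\x01-\x1f]", s)) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(chars <= "\x1f" & chars != "")
    for (i in bad) chars[i] <- sprintf("\\u%04x", utf8ToInt(chars[i]))
    s <- paste(chars, collapse = "")
  }
  s
}

json_num <- function(x) {
  if (!is.finite(x)) ps_stop("ps_io_error", "non-finite number in serialization")
  if (x == trunc(x) && abs(x) < 2^53) {
    sprintf("%.0f", x)
  } else {
    # shortest representation that round-trips a double
    for (d in 1:17) {
      s <- sprintf("%.*g", d, x)
      if (as.numeric(s) == x) return(s)
    }
    s
  }
}

json_encode <- function(x) {
  if (is.null(x)) return("null")
  if (inherits(x, "json_verbatim")) return(unclass(x))
  if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) {
      return(paste0("[", paste(vapply(x, json_encode, ""), collapse = ","), "]"))
    }
    if (any(nms == "")) ps_stop("ps_io_error", "partially named list in serialization")
    ord <- order(nms, method = "radix")
    parts <- vapply(ord, function(i) {
      paste0("\"", json_escape(nms[i]), "\":", json_encode(x[[i]]))
    }, "")
    return(paste0("{", paste(parts, collapse = ","), "}"))
  }
  if (length(x) != 1L) {
    # atomic vectors of length != 1 are written as arrays
    return(paste0("[", paste(vapply(seq_along(x),
      function(i) json_encode(x[[i]]), ""), collapse = ","), "]"))
  }
  if (is.na(x)) return("null")
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(json_num(as.numeric(x)))
  if (is.character(x)) return(paste0("\"", json_escape(x), "\""))
  ps_stop("ps_io_error", sprintf("unserializable value of class %s", class(x)[1]))
}

json_read_file <- function(path) {
  jsonlite::fromJSON(readChar(path, file.size(path), useBytes = TRUE),
                     simplifyVector = FALSE)
}

# md5 of a text blob (via a temp file; tools::md5sum is file-based)
text_digest <- function(text) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(charToRaw(enc2utf8(text)), tf)
  unname(tools::md5sum(tf))
}
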