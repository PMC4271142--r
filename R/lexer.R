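# Lexer for pipeline scripts.
#
# Mostly a conventional hand-written scanner, with two modal twists that the
# language's shell heritage forces on it:
#   * after the `sys` keyword the remainder of the line is one RAW token
#     (a verbatim shell command);
#   * after `task`/`dep`, once the optional parenthesised header closes, a
#     `{ ... }` body is consumed as RAW command lines rather than tokens.
# Newlines are significant (they terminate statements) except inside
# parentheses and brackets, where the lexer suppresses them.

PS_KEYWORDS <- c(
  "if", "else", "while", "for", "break", "continue", "return",
  "true", "false", "print", "println", "exit", "include", "sys",
  "task", "dep", "goal", "wait", "par", "checkpoint",
  "int", "real", "bool", "string", "void"
)

ps_token <- function(kind, text, file, line, col) {
  list(kind = kind, text = text, pos = source_pos(file, line, col))
}

#' Tokenize pipeline script source
#'
#' Splits script source text into a token stream. Token kinds are `IDENT`,
#' `KW` (keyword), `INT`, `REAL`, `STRING`, `OP`, `RAW` (verbatim shell
#' command text from `sys` lines and `task`/`dep` bodies), `LBRACE`/`RBRACE`,
#' `NL` (statement-terminating newline) and a final `EOF`. Every token
#' carries the 1-based line/column of its first character in `origin`.
#'
#' @param source Script text (a single string; may contain newlines).
#' @param origin File name used in source positions and error messages.
#' @return A list of tokens; each token is a list with `kind`, `text`, `pos`.
#' @examples
#' toks <- tokenize('in := "input.file"')
#' vapply(toks, `[[`, "", "kind")
#' @export
tokenize <- function(source, origin = "<script>") {
  lines <- strsplit(source, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) lines <- ""
  toks <- vector("list", 64L)
  ntok <- 0L
  push <- function(kind, text, line, col) {
    ntok <<- ntok + 1L
    if (ntok > length(toks)) length(toks) <<- 2L * ntok
    toks[[ntok]] <<- ps_token(kind, text, origin, line, col)
  }

  paren_depth <- 0L    # () and [] depth: suppresses NL tokens
  await_task <- FALSE  # saw task/dep, watching for its { body
  task_depth <- 0L     # header-paren depth while await_task
  raw_body <- FALSE    # inside a multi-line task body

  two_char <- c(":=", "<-", "==", "!=", "<=", ">=", "&&", "||")
  singles <- c("+", "-", "*", "/", "%", "<", ">", "=", "!", "(", ")",
               "[", "]", ",", ";", ":")

  for (li in seq_along(lines)) {
    text <- lines[[li]]
    if (raw_body) {
      trimmed <- trimws(text)
      if (trimmed == "}") {
        push("RBRACE", "}", li, max(1L, regexpr("}", text, fixed = TRUE)[1]))
        raw_body <- FALSE
        if (paren_depth == 0L) push("NL", "\n", li, nchar(text) + 1L)
      } else if (nzchar(trimmed)) {
        col <- regexpr("[^ \t]", text)[1]
        push("RAW", trimmed, li, col)
      }
      next
    }
    n <- nchar(text)
    i <- 1L
    while (i <= n) {
      ch <- substr(text, i, i)
      if (ch == " " || ch == "\t" || ch == "\r") { i <- i + 1L; next }
      if (ch == "#") break  # comment to end of line

      # identifier / keyword
      if (grepl("^[A-Za-z_]$", ch)) {
        m <- regmatches(substr(text, i, n),
                        regexpr("^[A-Za-z_][A-Za-z0-9_]*", substr(text, i, n)))
        word <- m[1]
        if (word %in% PS_KEYWORDS) {
          push("KW", word, li, i)
          i <- i + nchar(word)
          if (word == "sys") {
            rest <- trimws(substr(text, i, n))
            # strip a trailing comment only if the raw line starts with one
            if (nzchar(rest)) push("RAW", rest, li, i)
            break  # rest of line consumed; NL below
          }
          if (word %in% c("task", "dep")) {
            await_task <- TRUE
            task_depth <- 0L
          }
          next
        }
        push("IDENT", word, li, i)
        if (await_task && task_depth == 0L) await_task <- FALSE
        i <- i + nchar(word)
        next
      }

      # number
      if (grepl("^[0-9]$", ch)) {
        rest <- substr(text, i, n)
        m <- regmatches(rest, regexpr("^[0-9]+\\.[0-9]+([eE][+-]?[0-9]+)?", rest))
        if (length(m) == 1L) {
          push("REAL", m, li, i)
          i <- i + nchar(m)
        } else {
          m <- regmatches(rest, regexpr("^[0-9]+", rest))
          push("INT", m, li, i)
          i <- i + nchar(m)
        }
        if (await_task && task_depth == 0L) await_task <- FALSE
        next
      }

      # string literal
      if (ch == "\"") {
        j <- i + 1L
        out <- character(0)
        closed <- FALSE
        while (j <= n) {
          cj <- substr(text, j, j)
          if (cj == "\\") {
            if (j + 1L > n) break
            esc <- substr(text, j + 1L, j + 1L)
            out <- c(out, switch(esc,
              n = "\n", t = "\t", "\"" = "\"", "\\" = "\\", "$" = "$",
              ps_stop("ps_lex_error",
                      sprintf("unknown string escape '\\%s'", esc),
                      pos = source_pos(origin, li, j))))
            j <- j + 2L
          } else if (cj == "\"") {
            closed <- TRUE
            break
          } else {
            out <- c(out, cj)
            j <- j + 1L
          }
        }
        if (!closed) {
          ps_stop("ps_lex_error", "unterminated string literal",
                  pos = source_pos(origin, li, i))
        }
        push("STRING", paste(out, collapse = ""), li, i)
        if (await_task && task_depth == 0L) await_task <- FALSE
        i <- j + 1L
        next
      }

      # braces (task bodies are modal)
      if (ch == "{") {
        if (await_task && task_depth == 0L) {
          push("LBRACE", "{", li, i)
          rest <- substr(text, i + 1L, n)
          close_rel <- tail_brace(rest)
          if (close_rel > 0L) {
            body <- trimws(substr(rest, 1L, close_rel - 1L))
            if (nzchar(body)) push("RAW", body, li, i + 1L)
            push("RBRACE", "}", li, i + close_rel)
            await_task <- FALSE
            i <- i + 1L + close_rel
            next
          }
          first <- trimws(rest)
          if (nzchar(first)) push("RAW", first, li, i + 1L)
          raw_body <- TRUE
          await_task <- FALSE
          break
        }
        push("LBRACE", "{", li, i)
        i <- i + 1L
        next
      }
      if (ch == "}") {
        push("RBRACE", "}", li, i)
        i <- i + 1L
        next
      }

      # operators
      pair <- substr(text, i, i + 1L)
      if (pair %in% two_char) {
        push("OP", pair, li, i)
        if (await_task && task_depth == 0L && !pair %in% c(":=", "<-")) {
          # shouldn't occur before the header opens; be safe
        }
        i <- i + 2L
        next
      }
      if (ch %in% singles) {
        push("OP", ch, li, i)
        if (ch == "(" || ch == "[") {
          paren_depth <- paren_depth + 1L
          if (await_task && ch == "(") task_depth <- task_depth + 1L
        } else if (ch == ")" || ch == "]") {
          paren_depth <- max(0L, paren_depth - 1L)
          if (await_task && ch == ")") task_depth <- max(0L, task_depth - 1L)
        } else if (await_task && task_depth == 0L && ch != ",") {
          await_task <- FALSE
        }
        i <- i + 1L
        next
      }

      ps_stop("ps_lex_error", sprintf("unexpected character '%s'", ch),
              pos = source_pos(origin, li, i))
    }
    if (!raw_body && paren_depth == 0L) push("NL", "\n", li, max(1L, n + 1L))
  }
  if (raw_body) {
    ps_stop("ps_lex_error", "unterminated task body (missing '}')",
            pos = source_pos(origin, length(lines), 1L))
  }
  push("EOF", "", length(lines), nchar(lines[[length(lines)]]) + 1L)
  toks[seq_len(ntok)]
}

# position of the last '}' in a string, 0 if none
tail_brace <- function(s) {
  hits <- gregexpr("}", s, fixed = TRUE)[[1]]
  if (hits[1] == -1L) 0L else hits[length(hits)]
}
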