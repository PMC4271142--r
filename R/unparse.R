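# Pretty-printer over the syntax tree. Re-parsing its output yields a
# structurally identical tree (ignoring positions/ids), which tests use as
# a structural round-trip check.

#' Render a syntax tree back to script source
#'
#' @param x A `ps_tree` from [parse_script()] or a single node.
#' @return A single string of script source.
#' @export
unparse <- function(x) {
  if (inherits(x, "ps_tree")) x <- x$root
  paste(unparse_stmts(x$stmts, 0L), collapse = "\n")
}

ind <- function(depth) strrep("  ", depth)

unparse_stmts <- function(stmts, depth) {
  unlist(lapply(stmts, unparse_stmt, depth = depth))
}

unparse_stmt <- function(s, depth) {
  pre <- ind(depth)
  out <- switch(s$kind,
    decl = if (isTRUE(s$infer)) {
      sprintf("%s := %s", s$name, unparse_expr(s$init))
    } else if (is.null(s$init)) {
      sprintf("%s %s", s$type, s$name)
    } else {
      sprintf("%s %s = %s", s$type, s$name, unparse_expr(s$init))
    },
    assign = sprintf("%s = %s", s$name, unparse_expr(s$value)),
    "if" = {
      lines <- c(sprintf("if( %s ) {", unparse_expr(s$cond)),
                 unparse_stmts(s$then$stmts, depth + 1L),
                 paste0(pre, "}"))
      if (!is.null(s$elseb)) {
        lines <- c(lines[-length(lines)],
                   paste0(pre, "} else {"),
                   unparse_stmts(s$elseb$stmts, depth + 1L),
                   paste0(pre, "}"))
      }
      return(c(paste0(pre, lines[1]), lines[-1]))
    },
    "while" = {
      return(c(sprintf("%swhile( %s ) {", pre, unparse_expr(s$cond)),
               unparse_stmts(s$body$stmts, depth + 1L),
               paste0(pre, "}")))
    },
    "for" = {
      init <- sub("^\\s+", "", unparse_stmt(s$init, 0L))
      return(c(sprintf("%sfor( %s ; %s ; %s ) {", pre, init,
                       unparse_expr(s$cond),
                       sub("^\\s+", "", unparse_stmt(s$update, 0L))),
               unparse_stmts(s$body$stmts, depth + 1L),
               paste0(pre, "}")))
    },
    forin = {
      head <- if (is.null(s$vartype)) s$var else paste(s$vartype, s$var)
      return(c(sprintf("%sfor( %s : %s ) {", pre, head, unparse_expr(s$seq)),
               unparse_stmts(s$body$stmts, depth + 1L),
               paste0(pre, "}")))
    },
    "break" = "break",
    "continue" = "continue",
    "return" = if (is.null(s$value)) "return"
               else sprintf("return %s", unparse_expr(s$value)),
    funcdef = {
      params <- paste(vapply(s$params, function(pp) paste(pp$type, pp$name), ""),
                      collapse = ", ")
      return(c(sprintf("%s%s %s(%s) {", pre, s$rettype, s$name, params),
               unparse_stmts(s$body$stmts, depth + 1L),
               paste0(pre, "}")))
    },
    print = sprintf("%s%s", if (s$newline) "println" else "print",
                    if (is.null(s$value)) "" else paste0(" ", unparse_expr(s$value))),
    exit = if (is.null(s$value)) "exit"
           else sprintf("exit %s", unparse_expr(s$value)),
    sys = sprintf("sys %s", unparse_segments(s$segments)),
    wait = if (is.null(s$ids)) "wait"
           else sprintf("wait %s", unparse_expr(s$ids)),
    checkpoint = if (is.null(s$name)) "checkpoint"
                 else sprintf("checkpoint %s", unparse_expr(s$name)),
    exprstmt = {
      e <- s$expr
      if (e$kind == "task") return(unparse_task(e, depth))
      unparse_expr(e)
    },
    ps_stop("ps_runtime_error", sprintf("unparse: unknown statement %s", s$kind))
  )
  paste0(pre, out)
}

unparse_task <- function(e, depth) {
  pre <- ind(depth)
  header <- character(0)
  if (!is.null(e$depclause)) header <- unparse_expr(e$depclause)
  for (nm in names(e$options)) {
    header <- c(header, sprintf("%s := %s", nm, unparse_expr(e$options[[nm]])))
  }
  head <- if (length(header) > 0L) {
    sprintf("%s( %s ) {", e$task_kind, paste(header, collapse = ", "))
  } else {
    sprintf("%s {", e$task_kind)
  }
  c(paste0(pre, head),
    vapply(e$lines, function(l) paste0(ind(depth + 1L), unparse_segments(l)), ""),
    paste0(pre, "}"))
}

unparse_segments <- function(segs) {
  paste(vapply(segs, function(sg) {
    if (sg$kind == "text") {
      gsub("$", "\\$", sg$text, fixed = TRUE)
    } else if (sg$expr$kind == "ident") {
      paste0("$", sg$expr$name)
    } else {
      paste0("${", unparse_expr(sg$expr), "}")
    }
  }, ""), collapse = "")
}

unparse_expr <- function(e) {
  switch(e$kind,
    literal = switch(e$type,
      int = sprintf("%.0f", e$value),
      real = {
        s <- format(e$value, digits = 15, scientific = FALSE)
        if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
        s
      },
      bool = if (e$value) "true" else "false",
      string = paste0("\"", escape_string(e$value), "\"")
    ),
    ident = e$name,
    binary = sprintf("(%s %s %s)", unparse_expr(e$lhs), e$op, unparse_expr(e$rhs)),
    depop = sprintf("%s <- %s", unparse_expr(e$outs), unparse_expr(e$ins)),
    unary = sprintf("%s(%s)", e$op, unparse_expr(e$operand)),
    call = sprintf("%s(%s)", e$name,
                   paste(vapply(e$args, unparse_expr, ""), collapse = ", ")),
    index = sprintf("%s[%s]", unparse_expr(e$obj), unparse_expr(e$idx)),
    listlit = sprintf("[%s]",
                      paste(vapply(e$items, unparse_expr, ""), collapse = ", ")),
    goal = sprintf("goal %s", unparse_expr(e$targets)),
    par = if (e$par_kind == "call") {
      sprintf("par %s", unparse_expr(e$call))
    } else {
      # single-line rendering is not possible for blocks; rare as expression
      paste(c("par {", unparse_stmts(e$body$stmts, 1L), "}"), collapse = "\n")
    },
    task = paste(unparse_task(e, 0L), collapse = "\n"),
    ps_stop("ps_runtime_error", sprintf("unparse: unknown expression %s", e$kind))
  )
}

escape_string <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  gsub("\t", "\\t", s, fixed = TRUE)
}
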