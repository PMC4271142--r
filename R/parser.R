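# Recursive-descent parser producing the syntax tree.
#
# Statements: typed declaration, inferred declaration (:=), assignment,
# if/else, while, C-style for, for-in-list, break/continue/return, function
# definition, print/println, exit, include (resolved at parse time), sys,
# task/dep (also expressions), goal, wait, par, checkpoint, expression
# statement. Expressions use conventional precedence with the dependency
# operator `<-` binding loosest.
#
# After parsing, every node receives a dense pre-order integer id; a node's
# subtree occupies the contiguous id range [id, id_max], which the
# checkpoint recovery traversal uses to pick branches.

ps_node <- function(kind, pos, ...) {
  structure(list(kind = kind, pos = pos, ...), class = "ps_node")
}

is_node <- function(x) inherits(x, "ps_node")

# fields that are never children
.ps_node_scalar_fields <- c("kind", "pos", "id", "id_max")

# Apply f to every node in pre-order, rebuilding the (immutable) tree.
walk_nodes <- function(x, f) {
  if (is_node(x)) {
    x <- f(x)
    for (nm in setdiff(names(x), .ps_node_scalar_fields)) {
      v <- x[[nm]]
      if (is_node(v) || is.list(v)) x[[nm]] <- walk_nodes(v, f)
    }
    return(x)
  }
  if (is.list(x)) {
    for (i in seq_along(x)) {
      v <- x[[i]]
      if (is_node(v) || is.list(v)) x[[i]] <- walk_nodes(v, f)
    }
  }
  x
}

new_parser <- function(tokens) {
  p <- new.env(parent = emptyenv())
  p$toks <- tokens
  p$i <- 1L
  p
}

p_cur <- function(p) p$toks[[p$i]]
p_peek <- function(p, k = 1L) {
  j <- min(p$i + k, length(p$toks))
  p$toks[[j]]
}
p_at <- function(p, kind, text = NULL) {
  t <- p_cur(p)
  t$kind == kind && (is.null(text) || t$text == text)
}
p_advance <- function(p) {
  t <- p_cur(p)
  if (t$kind != "EOF") p$i <- p$i + 1L
  t
}
p_expect <- function(p, kind, text = NULL, what = NULL) {
  t <- p_cur(p)
  if (t$kind == kind && (is.null(text) || t$text == text)) return(p_advance(p))
  want <- if (!is.null(what)) what else if (!is.null(text)) sprintf("'%s'", text) else kind
  ps_stop("ps_parse_error",
          sprintf("expected %s but found '%s'", want,
                  if (t$kind == "EOF") "end of input" else t$text),
          pos = t$pos)
}
p_skip_nl <- function(p) {
  while (p_at(p, "NL") || (p_at(p, "OP", ";"))) p_advance(p)
}
p_end_stmt <- function(p) {
  t <- p_cur(p)
  if (t$kind %in% c("NL", "EOF", "RBRACE") ||
      (t$kind == "OP" && t$text == ";")) {
    if (t$kind == "NL" || (t$kind == "OP" && t$text == ";")) p_advance(p)
    return(invisible(NULL))
  }
  ps_stop("ps_parse_error",
          sprintf("expected end of statement but found '%s'", t$text),
          pos = t$pos)
}

is_type_kw <- function(t) t$kind == "KW" && t$text %in% c("int", "real", "bool", "string")

p_parse_type <- function(p) {
  t <- p_advance(p)
  base <- t$text
  if (p_at(p, "OP", "[")) {
    p_advance(p)
    p_expect(p, "OP", "]")
    return(paste0(base, "[]"))
  }
  base
}

#' Parse pipeline script source into a syntax tree
#'
#' Tokenizes and parses script text, resolving `include` directives
#' relative to the including file (then along `include_path`). The result
#' carries deterministic dense node ids: identical source always produces a
#' structurally identical tree with identical ids, which is what makes
#' checkpoint program counters portable.
#'
#' @param source Script text.
#' @param origin File name for positions (and the base for relative includes
#'   when `source` came from a file).
#' @param include_path Extra directories searched for `include` targets.
#' @param sources Internal: a named list of preloaded file contents; when an
#'   include target matches a name here it is read from memory (used by
#'   checkpoint resume, which must not depend on the original files).
#' @return An object of class `ps_tree` with fields `root` (the program
#'   node), `index` (node id to node), `sources` (named character of every
#'   file text consumed, post-include), and `source_hash`.
#' @export
parse_script <- function(source, origin = "<script>", include_path = character(),
                         sources = NULL) {
  src_env <- new.env(parent = emptyenv())
  src_env$sources <- list()
  src_env$by_target <- list()   # include target string -> text (for resume)
  src_env$preloaded <- sources
  stmts <- parse_file_stmts(source, origin, include_path,
                            active = character(0), src_env = src_env)
  root <- ps_node("program", source_pos(origin, 1L, 1L), stmts = stmts)

  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  index <- new.env(parent = emptyenv())
  root <- assign_ids(root, counter, index)
  idx <- vector("list", counter$n)
  for (nm in ls(index)) idx[[as.integer(nm)]] <- index[[nm]]

  srcs <- src_env$sources
  if (!origin %in% names(srcs)) srcs[[origin]] <- source
  bt <- src_env$by_target
  bt_txt <- if (length(bt) > 0L) unlist(bt[order(names(bt))]) else character(0)
  concat <- paste(c(source, bt_txt), collapse = "\n\x01\n")
  structure(
    list(root = root, index = idx, n_nodes = counter$n,
         origin = origin, main_source = source, sources = srcs,
         includes = bt, source_hash = text_digest(concat)),
    class = "ps_tree"
  )
}

#' Parse a pipeline script file
#'
#' @param path Path to the script file.
#' @param include_path Extra directories searched for includes.
#' @return A `ps_tree`; see [parse_script()].
#' @export
parse_script_file <- function(path, include_path = character()) {
  if (!file.exists(path)) {
    ps_stop("ps_usage_error", sprintf("script not found: %s", path))
  }
  src <- read_text_file(path)
  parse_script(src, origin = path, include_path = include_path)
}

read_text_file <- function(path) {
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

parse_file_stmts <- function(source, origin, include_path, active, src_env) {
  src_env$sources[[origin]] <- source
  toks <- tokenize(source, origin)
  p <- new_parser(toks)
  stmts <- list()
  p_skip_nl(p)
  while (!p_at(p, "EOF")) {
    if (p_at(p, "KW", "include")) {
      inc_tok <- p_advance(p)
      target <- p_expect(p, "STRING", what = "include file name")
      p_end_stmt(p)
      inc_stmts <- resolve_include(target$text, origin, include_path,
                                   active, src_env, inc_tok$pos)
      stmts <- c(stmts, inc_stmts)
    } else {
      stmts <- c(stmts, list(parse_statement(p, toplevel = TRUE)))
    }
    p_skip_nl(p)
  }
  stmts
}

resolve_include <- function(target, origin, include_path, active, src_env, pos) {
  cands <- character(0)
  if (!is.null(src_env$preloaded) && target %in% names(src_env$preloaded)) {
    key <- target
    text <- src_env$preloaded[[target]]
  } else {
    base <- dirname(origin)
    cands <- c(file.path(base, target), file.path(include_path, target), target)
    hit <- cands[file.exists(cands)]
    if (length(hit) == 0L) {
      ps_stop("ps_include_not_found_error",
              sprintf("include file not found: \"%s\"", target), pos = pos)
    }
    key <- normalizePath(hit[[1]])
    text <- read_text_file(hit[[1]])
  }
  if (key %in% active) {
    ps_stop("ps_include_cycle_error",
            sprintf("include cycle through \"%s\"", target), pos = pos)
  }
  src_env$by_target[[target]] <- text
  parse_file_stmts(text, key, include_path, c(active, key), src_env)
}

assign_ids <- function(node, counter, index) {
  counter$n <- counter$n + 1L
  node$id <- counter$n
  for (nm in setdiff(names(node), .ps_node_scalar_fields)) {
    v <- node[[nm]]
    if (is_node(v) || is.list(v)) node[[nm]] <- assign_ids_any(v, counter, index)
  }
  node$id_max <- counter$n
  index[[as.character(node$id)]] <- node
  node
}

assign_ids_any <- function(x, counter, index) {
  if (is_node(x)) return(assign_ids(x, counter, index))
  if (is.list(x)) {
    for (i in seq_along(x)) {
      v <- x[[i]]
      if (is_node(v) || is.list(v)) x[[i]] <- assign_ids_any(v, counter, index)
    }
  }
  x
}

# ---------------------------------------------------------------- statements

parse_statement <- function(p, toplevel = FALSE) {
  t <- p_cur(p)
  if (t$kind == "KW") {
    switch(t$text,
      "if" = return(parse_if(p)),
      "while" = return(parse_while(p)),
      "for" = return(parse_for(p)),
      "break" = { p_advance(p); p_end_stmt(p)
                  return(ps_node("break", t$pos)) },
      "continue" = { p_advance(p); p_end_stmt(p)
                     return(ps_node("continue", t$pos)) },
      "return" = return(parse_return(p)),
      "print" = ,
      "println" = return(parse_print(p)),
      "exit" = return(parse_exit(p)),
      "sys" = return(parse_sys(p)),
      "wait" = return(parse_wait(p)),
      "checkpoint" = return(parse_checkpoint(p)),
      "include" = ps_stop("ps_parse_error",
                          "include is only allowed at the top level",
                          pos = t$pos),
      "int" = , "real" = , "bool" = , "string" = , "void" =
        return(parse_decl_or_func(p, toplevel)),
      NULL
    )
  }
  if (t$kind == "IDENT") {
    nxt <- p_peek(p)
    if (nxt$kind == "OP" && nxt$text == ":=") {
      name <- p_advance(p)
      p_advance(p)
      init <- parse_expr(p)
      p_end_stmt(p)
      return(ps_node("decl", name$pos, name = name$text, type = NULL,
                     init = init, infer = TRUE))
    }
    if (nxt$kind == "OP" && nxt$text == "=") {
      name <- p_advance(p)
      p_advance(p)
      value <- parse_expr(p)
      p_end_stmt(p)
      return(ps_node("assign", name$pos, name = name$text, value = value))
    }
  }
  expr <- parse_expr(p)
  p_end_stmt(p)
  ps_node("exprstmt", expr$pos, expr = expr)
}

parse_decl_or_func <- function(p, toplevel) {
  t0 <- p_cur(p)
  if (t0$text == "void") {
    p_advance(p)
    type <- "void"
  } else {
    type <- p_parse_type(p)
  }
  name <- p_expect(p, "IDENT", what = "a name")
  if (p_at(p, "OP", "(")) {
    if (!toplevel) {
      ps_stop("ps_parse_error", "functions may only be defined at the top level",
              pos = t0$pos)
    }
    return(parse_funcdef(p, type, name, t0$pos))
  }
  if (type == "void") {
    ps_stop("ps_parse_error", "'void' is only valid as a function return type",
            pos = t0$pos)
  }
  init <- NULL
  if (p_at(p, "OP", "=")) {
    p_advance(p)
    init <- parse_expr(p)
  }
  p_end_stmt(p)
  ps_node("decl", t0$pos, name = name$text, type = type, init = init,
          infer = FALSE)
}

parse_funcdef <- function(p, rettype, name, pos) {
  p_expect(p, "OP", "(")
  params <- list()
  if (!p_at(p, "OP", ")")) {
    repeat {
      if (!is_type_kw(p_cur(p))) {
        ps_stop("ps_parse_error", "expected a parameter type", pos = p_cur(p)$pos)
      }
      ptype <- p_parse_type(p)
      pname <- p_expect(p, "IDENT", what = "a parameter name")
      params <- c(params, list(list(name = pname$text, type = ptype)))
      if (p_at(p, "OP", ",")) { p_advance(p); next }
      break
    }
  }
  p_expect(p, "OP", ")")
  body <- parse_block(p)
  ps_node("funcdef", pos, name = name$text, rettype = rettype,
          params = params, body = body)
}

parse_block <- function(p) {
  p_skip_nl(p)
  open <- p_expect(p, "LBRACE", what = "'{'")
  stmts <- list()
  p_skip_nl(p)
  while (!p_at(p, "RBRACE")) {
    if (p_at(p, "EOF")) {
      ps_stop("ps_parse_error", "unterminated block (missing '}')", pos = open$pos)
    }
    stmts <- c(stmts, list(parse_statement(p)))
    p_skip_nl(p)
  }
  p_advance(p)
  ps_node("block", open$pos, stmts = stmts)
}

parse_if <- function(p) {
  t <- p_advance(p)
  p_expect(p, "OP", "(")
  cond <- parse_expr(p)
  p_expect(p, "OP", ")")
  then <- parse_block(p)
  elseb <- NULL
  save <- p$i
  p_skip_nl(p)
  if (p_at(p, "KW", "else")) {
    p_advance(p)
    p_skip_nl(p)
    if (p_at(p, "KW", "if")) {
      elseb <- ps_node("block", p_cur(p)$pos, stmts = list(parse_if(p)))
    } else {
      elseb <- parse_block(p)
    }
  } else {
    p$i <- save
  }
  ps_node("if", t$pos, cond = cond, then = then, elseb = elseb)
}

parse_while <- function(p) {
  t <- p_advance(p)
  p_expect(p, "OP", "(")
  cond <- parse_expr(p)
  p_expect(p, "OP", ")")
  body <- parse_block(p)
  ps_node("while", t$pos, cond = cond, body = body)
}

parse_for <- function(p) {
  t <- p_advance(p)
  p_expect(p, "OP", "(")
  # disambiguate for-in from C-style
  if (is_type_kw(p_cur(p))) {
    type <- p_parse_type(p)
    name <- p_expect(p, "IDENT", what = "a name")
    if (p_at(p, "OP", ":")) {
      p_advance(p)
      seq <- parse_expr(p)
      p_expect(p, "OP", ")")
      body <- parse_block(p)
      return(ps_node("forin", t$pos, var = name$text, vartype = type,
                     seq = seq, body = body))
    }
    p_expect(p, "OP", "=")
    init_expr <- parse_expr(p)
    init <- ps_node("decl", name$pos, name = name$text, type = type,
                    init = init_expr, infer = FALSE)
  } else {
    name <- p_expect(p, "IDENT", what = "a loop variable")
    if (p_at(p, "OP", ":")) {
      p_advance(p)
      seq <- parse_expr(p)
      p_expect(p, "OP", ")")
      body <- parse_block(p)
      return(ps_node("forin", t$pos, var = name$text, vartype = NULL,
                     seq = seq, body = body))
    }
    op <- p_cur(p)
    if (p_at(p, "OP", ":=")) {
      p_advance(p)
      init_expr <- parse_expr(p)
      init <- ps_node("decl", name$pos, name = name$text, type = NULL,
                      init = init_expr, infer = TRUE)
    } else if (p_at(p, "OP", "=")) {
      p_advance(p)
      init_expr <- parse_expr(p)
      init <- ps_node("assign", name$pos, name = name$text, value = init_expr)
    } else {
      ps_stop("ps_parse_error", "expected ':', ':=' or '=' in for header",
              pos = op$pos)
    }
  }
  p_expect(p, "OP", ";")
  cond <- parse_expr(p)
  p_expect(p, "OP", ";")
  upd_name <- p_expect(p, "IDENT", what = "an update assignment")
  p_expect(p, "OP", "=")
  upd_expr <- parse_expr(p)
  update <- ps_node("assign", upd_name$pos, name = upd_name$text,
                    value = upd_expr)
  p_expect(p, "OP", ")")
  body <- parse_block(p)
  ps_node("for", t$pos, init = init, cond = cond, update = update, body = body)
}

parse_return <- function(p) {
  t <- p_advance(p)
  value <- NULL
  if (!stmt_ends_here(p)) value <- parse_expr(p)
  p_end_stmt(p)
  ps_node("return", t$pos, value = value)
}

parse_print <- function(p) {
  t <- p_advance(p)
  value <- NULL
  if (!stmt_ends_here(p)) value <- parse_expr(p)
  if (t$text == "print" && is.null(value)) {
    ps_stop("ps_parse_error", "print requires an expression", pos = t$pos)
  }
  p_end_stmt(p)
  ps_node("print", t$pos, value = value, newline = t$text == "println")
}

parse_exit <- function(p) {
  t <- p_advance(p)
  value <- NULL
  if (!stmt_ends_here(p)) value <- parse_expr(p)
  p_end_stmt(p)
  ps_node("exit", t$pos, value = value)
}

parse_sys <- function(p) {
  t <- p_advance(p)
  if (!p_at(p, "RAW")) {
    ps_stop("ps_parse_error", "sys requires a command on the same line",
            pos = t$pos)
  }
  raw <- p_advance(p)
  p_end_stmt(p)
  ps_node("sys", t$pos,
          segments = parse_command_segments(raw$text, raw$pos))
}

parse_wait <- function(p) {
  t <- p_advance(p)
  ids <- NULL
  if (!stmt_ends_here(p)) ids <- parse_expr(p)
  p_end_stmt(p)
  ps_node("wait", t$pos, ids = ids)
}

parse_checkpoint <- function(p) {
  t <- p_advance(p)
  name <- NULL
  if (!stmt_ends_here(p)) name <- parse_expr(p)
  p_end_stmt(p)
  ps_node("checkpoint", t$pos, name = name)
}

stmt_ends_here <- function(p) {
  t <- p_cur(p)
  t$kind %in% c("NL", "EOF", "RBRACE") || (t$kind == "OP" && t$text == ";")
}

# --------------------------------------------------------------- expressions

parse_expr <- function(p) parse_depop(p)

parse_depop <- function(p) {
  lhs <- parse_or(p)
  if (p_at(p, "OP", "<-")) {
    op <- p_advance(p)
    rhs <- parse_or(p)
    return(ps_node("depop", op$pos, outs = lhs, ins = rhs))
  }
  lhs
}

parse_binary_level <- function(p, ops, next_fn) {
  lhs <- next_fn(p)
  repeat {
    t <- p_cur(p)
    if (t$kind == "OP" && t$text %in% ops) {
      p_advance(p)
      rhs <- next_fn(p)
      lhs <- ps_node("binary", t$pos, op = t$text, lhs = lhs, rhs = rhs)
    } else break
  }
  lhs
}

parse_or <- function(p) parse_binary_level(p, "||", parse_and)
parse_and <- function(p) parse_binary_level(p, "&&", parse_eq)
parse_eq <- function(p) parse_binary_level(p, c("==", "!="), parse_rel)
parse_rel <- function(p) parse_binary_level(p, c("<", "<=", ">", ">="), parse_add)
parse_add <- function(p) parse_binary_level(p, c("+", "-"), parse_mul)
parse_mul <- function(p) parse_binary_level(p, c("*", "/", "%"), parse_unary)

parse_unary <- function(p) {
  t <- p_cur(p)
  if (t$kind == "OP" && t$text %in% c("!", "-")) {
    p_advance(p)
    operand <- parse_unary(p)
    return(ps_node("unary", t$pos, op = t$text, operand = operand))
  }
  parse_postfix(p)
}

parse_postfix <- function(p) {
  e <- parse_primary(p)
  repeat {
    if (p_at(p, "OP", "[")) {
      t <- p_advance(p)
      idx <- parse_expr(p)
      p_expect(p, "OP", "]")
      e <- ps_node("index", t$pos, obj = e, idx = idx)
    } else break
  }
  e
}

parse_primary <- function(p) {
  t <- p_cur(p)
  if (t$kind == "INT") {
    p_advance(p)
    return(ps_node("literal", t$pos, type = "int", value = as.numeric(t$text)))
  }
  if (t$kind == "REAL") {
    p_advance(p)
    return(ps_node("literal", t$pos, type = "real", value = as.numeric(t$text)))
  }
  if (t$kind == "STRING") {
    p_advance(p)
    return(ps_node("literal", t$pos, type = "string", value = t$text))
  }
  if (t$kind == "KW") {
    if (t$text %in% c("true", "false")) {
      p_advance(p)
      return(ps_node("literal", t$pos, type = "bool", value = t$text == "true"))
    }
    if (t$text %in% c("task", "dep")) return(parse_task_expr(p))
    if (t$text == "goal") {
      p_advance(p)
      targets <- parse_expr(p)
      return(ps_node("goal", t$pos, targets = targets))
    }
    if (t$text == "par") return(parse_par_expr(p))
  }
  if (t$kind == "IDENT") {
    nxt <- p_peek(p)
    if (nxt$kind == "OP" && nxt$text == "(") {
      name <- p_advance(p)
      p_advance(p)
      args <- list()
      if (!p_at(p, "OP", ")")) {
        repeat {
          args <- c(args, list(parse_expr(p)))
          if (p_at(p, "OP", ",")) { p_advance(p); next }
          break
        }
      }
      p_expect(p, "OP", ")")
      return(ps_node("call", name$pos, name = name$text, args = args))
    }
    p_advance(p)
    return(ps_node("ident", t$pos, name = t$text))
  }
  if (t$kind == "OP" && t$text == "(") {
    p_advance(p)
    e <- parse_expr(p)
    p_expect(p, "OP", ")")
    return(e)
  }
  if (t$kind == "OP" && t$text == "[") {
    p_advance(p)
    items <- list()
    if (!p_at(p, "OP", "]")) {
      repeat {
        items <- c(items, list(parse_expr(p)))
        if (p_at(p, "OP", ",")) { p_advance(p); next }
        break
      }
    }
    p_expect(p, "OP", "]")
    return(ps_node("listlit", t$pos, items = items))
  }
  ps_stop("ps_parse_error",
          sprintf("unexpected token '%s' in expression",
                  if (t$kind == "EOF") "end of input" else t$text),
          pos = t$pos)
}

# ------------------------------------------------------------- task headers

PS_TASK_OPTIONS <- c("cpus", "mem", "timeout", "retry", "taskName")

#' @rdname parse_script
#' @details `task`/`dep` headers accept an optional dependency clause
#'   `outs <- ins` plus the named resource options `cpus`, `mem`, `timeout`,
#'   `retry` and `taskName` (all bound with `:=`). The body between braces is
#'   kept verbatim as shell command lines with `$name` / `${expr}`
#'   interpolation markers parsed into expression nodes.
#' @keywords internal
parse_task_expr <- function(p) {
  t <- p_advance(p)  # task | dep
  depclause <- NULL
  options <- list()
  if (p_at(p, "OP", "(")) {
    p_advance(p)
    repeat {
      if (p_at(p, "OP", ")")) break
      el <- p_cur(p)
      nxt <- p_peek(p)
      if (el$kind == "IDENT" && nxt$kind == "OP" && nxt$text == ":=") {
        if (!el$text %in% PS_TASK_OPTIONS) {
          ps_stop("ps_parse_error",
                  sprintf("unknown task option '%s'", el$text), pos = el$pos)
        }
        if (el$text %in% names(options)) {
          ps_stop("ps_parse_error",
                  sprintf("duplicate task option '%s'", el$text), pos = el$pos)
        }
        p_advance(p); p_advance(p)
        options[[el$text]] <- parse_expr(p)
      } else {
        e <- parse_expr(p)
        if (e$kind != "depop") {
          ps_stop("ps_parse_error",
                  "expected a dependency clause 'outs <- ins' or a named option",
                  pos = el$pos)
        }
        if (!is.null(depclause)) {
          ps_stop("ps_parse_error", "multiple dependency clauses in task header",
                  pos = el$pos)
        }
        depclause <- e
      }
      if (p_at(p, "OP", ",")) { p_advance(p); next }
      break
    }
    p_expect(p, "OP", ")")
  }
  if (t$text == "dep" && is.null(depclause)) {
    ps_stop("ps_parse_error", "dep requires a dependency clause 'outs <- ins'",
            pos = t$pos)
  }
  p_skip_nl(p)
  p_expect(p, "LBRACE", what = "task body '{'")
  lines <- list()
  while (p_at(p, "RAW")) {
    raw <- p_advance(p)
    lines <- c(lines, list(parse_command_segments(raw$text, raw$pos)))
  }
  p_expect(p, "RBRACE", what = "'}' closing the task body")
  if (length(lines) == 0L) {
    ps_stop("ps_parse_error", "task body is empty", pos = t$pos)
  }
  ps_node("task", t$pos, task_kind = t$text, depclause = depclause,
          options = options, lines = lines)
}

parse_par_expr <- function(p) {
  t <- p_advance(p)
  p_skip_nl_before_brace(p)
  if (p_at(p, "LBRACE")) {
    body <- parse_block(p)
    return(ps_node("par", t$pos, par_kind = "block", body = body, call = NULL))
  }
  e <- parse_expr(p)
  if (e$kind != "call") {
    ps_stop("ps_parse_error", "par expects a block or a function call",
            pos = t$pos)
  }
  ps_node("par", t$pos, par_kind = "call", body = NULL, call = e)
}

p_skip_nl_before_brace <- function(p) {
  save <- p$i
  p_skip_nl(p)
  if (!p_at(p, "LBRACE")) p$i <- save
}

# Split raw command text into literal/interpolation segments.
# `$name` interpolates a variable, `${expr}` a full expression, `\$`
# escapes a literal dollar sign.
parse_command_segments <- function(text, pos) {
  segs <- list()
  buf <- character(0)
  flush_buf <- function() {
    if (length(buf) > 0L) {
      segs[[length(segs) + 1L]] <<- list(kind = "text",
                                         text = paste(buf, collapse = ""))
      buf <<- character(0)
    }
  }
  n <- nchar(text)
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\\" && i < n && substr(text, i + 1L, i + 1L) == "$") {
      buf <- c(buf, "$")
      i <- i + 2L
      next
    }
    if (ch == "$" && i < n) {
      nxt <- substr(text, i + 1L, i + 1L)
      if (nxt == "{") {
        close <- regexpr("}", substr(text, i + 2L, n), fixed = TRUE)[1]
        if (close < 0L) {
          ps_stop("ps_parse_error", "unterminated ${...} interpolation",
                  pos = pos)
        }
        inner <- substr(text, i + 2L, i + close)
        flush_buf()
        segs[[length(segs) + 1L]] <- list(
          kind = "expr",
          expr = parse_interp_expr(inner, pos)
        )
        i <- i + close + 2L
        next
      }
      if (grepl("^[A-Za-z_]$", nxt)) {
        m <- regmatches(substr(text, i + 1L, n),
                        regexpr("^[A-Za-z_][A-Za-z0-9_]*",
                                substr(text, i + 1L, n)))
        flush_buf()
        segs[[length(segs) + 1L]] <- list(
          kind = "expr",
          expr = ps_node("ident", pos, name = m[1])
        )
        i <- i + 1L + nchar(m[1])
        next
      }
    }
    buf <- c(buf, ch)
    i <- i + 1L
  }
  flush_buf()
  segs
}

parse_interp_expr <- function(text, pos) {
  toks <- tokenize(text, origin = pos$file)
  p <- new_parser(toks)
  e <- parse_expr(p)
  p_skip_nl(p)
  if (!p_at(p, "EOF")) {
    ps_stop("ps_parse_error", "trailing input in ${...} interpolation",
            pos = pos)
  }
  # positions inside the interpolation refer to the synthetic snippet;
  # rewrite them to the command line's own position
  walk_nodes(e, function(nd) { nd$pos <- pos; nd })
}
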