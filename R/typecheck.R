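# Static typechecker with local type inference.
#
# The language is strongly typed: every expression gets a type before any
# execution ("pseudo-compilation"), so conversion errors surface immediately
# instead of hours into a run. Types are `bool`, `int`, `real`, `string` and
# homogeneous lists `T[]`. The only implicit conversion is the widening
# int -> real; everything else goes through the cast builtins toInt, toReal,
# toStr. All type errors in a program are collected and reported together.

PS_SCALARS <- c("bool", "int", "real", "string")

is_list_type <- function(t) !is.null(t) && endsWith(t, "[]")
elem_type <- function(t) substr(t, 1L, nchar(t) - 2L)
is_numeric_type <- function(t) t %in% c("int", "real")
is_scalar_type <- function(t) t %in% PS_SCALARS

# predefined duration constants (seconds scale), so `timeout := 6*hour`
# reads naturally in task headers
PS_CONSTANTS <- c(second = 1, minute = 60, hour = 3600, day = 86400)

PS_BUILTINS <- list(
  toInt = list(params = "scalar", ret = "int"),
  toReal = list(params = "scalar", ret = "real"),
  toStr = list(params = "scalar", ret = "string"),
  len = list(params = "list", ret = "int")
)

new_symtab <- function(parent = NULL) {
  e <- new.env(parent = if (is.null(parent)) emptyenv() else parent)
  e
}

symtab_lookup <- function(scope, name) {
  if (exists(name, envir = scope, inherits = TRUE)) {
    get(name, envir = scope, inherits = TRUE)
  } else {
    NULL
  }
}

# The result of binary `lt op rt`, or NULL when the operands don't combine.
binop_type <- function(op, lt, rt) {
  if (identical(lt, "error") || identical(rt, "error")) return("error")
  if (op == "+") {
    if (is_numeric_type(lt) && is_numeric_type(rt)) {
      return(if (lt == "int" && rt == "int") "int" else "real")
    }
    if (lt == "string" && is_scalar_type(rt)) return("string")
    if (rt == "string" && is_scalar_type(lt)) return("string")
    if (is_list_type(lt) && identical(lt, rt)) return(lt)
    if (is_list_type(lt) && identical(elem_type(lt), rt)) return(lt)
    return(NULL)
  }
  if (op %in% c("-", "*", "/")) {
    if (is_numeric_type(lt) && is_numeric_type(rt)) {
      return(if (lt == "int" && rt == "int") "int" else "real")
    }
    return(NULL)
  }
  if (op == "%") {
    if (lt == "int" && rt == "int") return("int")
    return(NULL)
  }
  if (op %in% c("==", "!=")) {
    if (is_numeric_type(lt) && is_numeric_type(rt)) return("bool")
    if (is_scalar_type(lt) && identical(lt, rt)) return("bool")
    return(NULL)
  }
  if (op %in% c("<", "<=", ">", ">=")) {
    if (is_numeric_type(lt) && is_numeric_type(rt)) return("bool")
    if (lt == "string" && rt == "string") return("bool")
    return(NULL)
  }
  if (op %in% c("&&", "||")) {
    if (lt == "bool" && rt == "bool") return("bool")
    return(NULL)
  }
  NULL
}

assignable_to <- function(from, to) {
  if (identical(from, "error") || identical(to, "error")) return(TRUE)
  identical(from, to) || (to == "real" && from == "int")
}

new_check_ctx <- function(tree) {
  ctx <- new.env(parent = emptyenv())
  ctx$tree <- tree
  ctx$errors <- list()
  ctx$types <- new.env(parent = emptyenv())   # node id -> type
  ctx$funcs <- list()                          # name -> signature
  ctx$globals <- list()                        # name -> list(type, overridable)
  ctx
}

ctx_error <- function(ctx, msg, pos) {
  ctx$errors[[length(ctx$errors) + 1L]] <- list(message = msg, pos = pos)
  invisible("error")
}

set_type <- function(ctx, node, type) {
  assign(as.character(node$id), type, envir = ctx$types)
  type
}

#' Typecheck a parsed program
#'
#' Verifies declarations, assignments, operators, function calls, task
#' resource options (which must be `int`), dependency-clause sides (which
#' must be `string` or `string[]`) and command-line interpolations, before
#' anything runs. All errors are collected; on failure the condition of
#' class `ps_type_error` carries the full diagnostic list in
#' `data$errors`.
#'
#' @param tree A `ps_tree` from [parse_script()].
#' @return An object of class `ps_typed`: the tree plus a node-id-to-type
#'   map, the function table and the table of top-level (command-line
#'   overridable) globals.
#' @seealso [program_diagnostics()] for the non-throwing variant.
#' @export
check_program <- function(tree) {
  ctx <- new_check_ctx(tree)
  gscope <- new_symtab()
  for (nm in names(PS_CONSTANTS)) assign(nm, "int", envir = gscope)

  # hoist top-level function signatures so call order doesn't matter
  for (s in tree$root$stmts) {
    if (s$kind == "funcdef") {
      if (s$name %in% names(ctx$funcs)) {
        ctx_error(ctx, sprintf("function '%s' is already defined (no overloading)",
                               s$name), s$pos)
      } else if (s$name %in% names(PS_BUILTINS)) {
        ctx_error(ctx, sprintf("'%s' is a builtin and cannot be redefined",
                               s$name), s$pos)
      } else {
        ctx$funcs[[s$name]] <- list(
          name = s$name, rettype = s$rettype,
          param_types = vapply(s$params, `[[`, "", "type"),
          param_names = vapply(s$params, `[[`, "", "name"),
          node_id = s$id
        )
      }
    }
  }

  barrier_seen <- FALSE
  for (s in tree$root$stmts) {
    check_stmt(ctx, s, gscope, fn = NULL, in_loop = FALSE)
    if (s$kind == "decl" && !barrier_seen) {
      ty <- symtab_lookup(gscope, s$name)
      ctx$globals[[s$name]] <- list(type = ty, overridable = TRUE)
    }
    if (s$kind %in% c("sys", "wait", "exprstmt", "checkpoint")) barrier_seen <- TRUE
  }

  if (length(ctx$errors) > 0L) {
    msgs <- vapply(ctx$errors, function(e) {
      sprintf("type error: %s [%s]", e$message, fmt_pos(e$pos))
    }, "")
    stop(ps_condition("ps_type_error",
                      paste(msgs, collapse = "\n"),
                      data = list(errors = ctx$errors)))
  }

  types <- as.list(ctx$types)
  structure(
    list(tree = tree, types = types, funcs = ctx$funcs, globals = ctx$globals),
    class = "ps_typed"
  )
}

#' Collect type diagnostics without throwing
#'
#' @param tree A `ps_tree`.
#' @return A character vector of diagnostics, empty when the program checks.
#' @export
program_diagnostics <- function(tree) {
  res <- tryCatch(check_program(tree), ps_type_error = function(c) c)
  if (inherits(res, "ps_typed")) return(character(0))
  vapply(res$data$errors, function(e) {
    sprintf("type error: %s [%s]", e$message, fmt_pos(e$pos))
  }, "")
}

check_stmt <- function(ctx, s, scope, fn, in_loop) {
  switch(s$kind,
    decl = {
      declared <- s$type
      ity <- if (!is.null(s$init)) type_of(ctx, s$init, scope) else NULL
      if (isTRUE(s$infer)) {
        if (is.null(ity) || identical(ity, "void")) {
          ctx_error(ctx, sprintf("cannot infer a type for '%s'", s$name), s$pos)
          ity <- "error"
        }
        declared <- ity
      } else if (!is.null(ity) && !assignable_to(ity, declared)) {
        ctx_error(ctx, sprintf("cannot initialize %s '%s' with %s",
                               declared, s$name, ity), s$pos)
      }
      if (exists(s$name, envir = scope, inherits = FALSE)) {
        ctx_error(ctx, sprintf("'%s' is already declared in this scope", s$name),
                  s$pos)
      }
      assign(s$name, declared, envir = scope)
    },
    assign = {
      vt <- symtab_lookup(scope, s$name)
      et <- type_of(ctx, s$value, scope)
      if (is.null(vt)) {
        ctx_error(ctx, sprintf("assignment to undeclared variable '%s'", s$name),
                  s$pos)
      } else if (!assignable_to(et, vt)) {
        ctx_error(ctx, sprintf("cannot assign %s to %s '%s'", et, vt, s$name),
                  s$pos)
      }
    },
    "if" = {
      ct <- type_of(ctx, s$cond, scope)
      if (!ct %in% c("bool", "error")) {
        ctx_error(ctx, sprintf("if condition must be bool, got %s", ct), s$pos)
      }
      check_block(ctx, s$then, scope, fn, in_loop)
      if (!is.null(s$elseb)) check_block(ctx, s$elseb, scope, fn, in_loop)
    },
    "while" = {
      ct <- type_of(ctx, s$cond, scope)
      if (!ct %in% c("bool", "error")) {
        ctx_error(ctx, sprintf("while condition must be bool, got %s", ct), s$pos)
      }
      check_block(ctx, s$body, scope, fn, in_loop = TRUE)
    },
    "for" = {
      fscope <- new_symtab(scope)
      check_stmt(ctx, s$init, fscope, fn, in_loop)
      ct <- type_of(ctx, s$cond, fscope)
      if (!ct %in% c("bool", "error")) {
        ctx_error(ctx, sprintf("for condition must be bool, got %s", ct), s$pos)
      }
      check_stmt(ctx, s$update, fscope, fn, in_loop)
      check_block(ctx, s$body, fscope, fn, in_loop = TRUE)
    },
    forin = {
      st <- type_of(ctx, s$seq, scope)
      et <- if (is_list_type(st)) elem_type(st) else {
        if (!identical(st, "error")) {
          ctx_error(ctx, sprintf("for-in needs a list, got %s", st), s$pos)
        }
        "error"
      }
      if (!is.null(s$vartype) && !identical(s$vartype, et) &&
          !identical(et, "error")) {
        ctx_error(ctx, sprintf("loop variable '%s' declared %s over %s list",
                               s$var, s$vartype, et), s$pos)
      }
      fscope <- new_symtab(scope)
      assign(s$var, if (is.null(s$vartype)) et else s$vartype, envir = fscope)
      check_block(ctx, s$body, fscope, fn, in_loop = TRUE)
    },
    "break" = ,
    "continue" = {
      if (!in_loop) {
        ctx_error(ctx, sprintf("%s outside of a loop", s$kind), s$pos)
      }
    },
    "return" = {
      if (is.null(fn)) {
        ctx_error(ctx, "return outside of a function", s$pos)
      } else {
        rt <- if (is.null(s$value)) "void" else type_of(ctx, s$value, scope)
        if (fn$rettype == "void" && rt != "void") {
          ctx_error(ctx, "void function cannot return a value", s$pos)
        } else if (fn$rettype != "void" && !assignable_to(rt, fn$rettype)) {
          ctx_error(ctx, sprintf("function '%s' must return %s, got %s",
                                 fn$name, fn$rettype, rt), s$pos)
        }
      }
    },
    funcdef = {
      sig <- ctx$funcs[[s$name]]
      if (is.null(sig)) return(invisible(NULL))  # duplicate, already reported
      fscope <- new_symtab(NULL)
      for (nm in names(PS_CONSTANTS)) assign(nm, "int", envir = fscope)
      for (pp in s$params) assign(pp$name, pp$type, envir = fscope)
      check_block(ctx, s$body, fscope, fn = sig, in_loop = FALSE)
    },
    print = {
      if (!is.null(s$value)) type_of(ctx, s$value, scope)
    },
    exit = {
      if (!is.null(s$value)) {
        et <- type_of(ctx, s$value, scope)
        if (!et %in% c("int", "error")) {
          ctx_error(ctx, sprintf("exit code must be int, got %s", et), s$pos)
        }
      }
    },
    sys = check_segments(ctx, s$segments, scope, s$pos),
    wait = {
      if (!is.null(s$ids)) {
        it <- type_of(ctx, s$ids, scope)
        if (!it %in% c("string", "string[]", "error")) {
          ctx_error(ctx, sprintf("wait expects task ids (string or string[]), got %s",
                                 it), s$pos)
        }
      }
    },
    checkpoint = {
      if (!is.null(s$name)) {
        nt <- type_of(ctx, s$name, scope)
        if (!nt %in% c("string", "error")) {
          ctx_error(ctx, sprintf("checkpoint name must be string, got %s", nt),
                    s$pos)
        }
      }
    },
    exprstmt = {
      type_of(ctx, s$expr, scope)
    },
    ctx_error(ctx, sprintf("unknown statement kind '%s'", s$kind), s$pos)
  )
  invisible(NULL)
}

check_block <- function(ctx, block, scope, fn, in_loop) {
  bscope <- new_symtab(scope)
  for (s in block$stmts) check_stmt(ctx, s, bscope, fn, in_loop)
}

check_segments <- function(ctx, segments, scope, pos) {
  for (sg in segments) {
    if (sg$kind == "expr") {
      st <- type_of(ctx, sg$expr, scope)
      ok <- is_scalar_type(st) ||
        (is_list_type(st) && is_scalar_type(elem_type(st))) ||
        identical(st, "error")
      if (!ok) {
        ctx_error(ctx, sprintf("cannot interpolate a value of type %s", st),
                  sg$expr$pos)
      }
    }
  }
}

type_of <- function(ctx, e, scope) {
  t <- switch(e$kind,
    literal = e$type,
    ident = {
      ty <- symtab_lookup(scope, e$name)
      if (is.null(ty)) {
        ctx_error(ctx, sprintf("undeclared variable '%s'", e$name), e$pos)
        "error"
      } else ty
    },
    binary = {
      lt <- type_of(ctx, e$lhs, scope)
      rt <- type_of(ctx, e$rhs, scope)
      bt <- binop_type(e$op, lt, rt)
      if (is.null(bt)) {
        ctx_error(ctx, sprintf("operator '%s' cannot combine %s and %s",
                               e$op, lt, rt), e$pos)
        "error"
      } else bt
    },
    unary = {
      ot <- type_of(ctx, e$operand, scope)
      if (e$op == "!") {
        if (!ot %in% c("bool", "error")) {
          ctx_error(ctx, sprintf("'!' needs bool, got %s", ot), e$pos)
          "error"
        } else "bool"
      } else {
        if (!ot %in% c("int", "real", "error")) {
          ctx_error(ctx, sprintf("unary '-' needs a number, got %s", ot), e$pos)
          "error"
        } else ot
      }
    },
    depop = {
      for (side in list(e$outs, e$ins)) {
        st <- type_of(ctx, side, scope)
        if (!st %in% c("string", "string[]", "error")) {
          ctx_error(ctx,
                    sprintf("dependency clause sides must be string or string[], got %s",
                            st), side$pos)
        }
      }
      "bool"
    },
    call = type_of_call(ctx, e, scope),
    index = {
      ot <- type_of(ctx, e$obj, scope)
      it <- type_of(ctx, e$idx, scope)
      if (!it %in% c("int", "error")) {
        ctx_error(ctx, sprintf("list index must be int, got %s", it), e$pos)
      }
      if (is_list_type(ot)) elem_type(ot)
      else {
        if (!identical(ot, "error")) {
          ctx_error(ctx, sprintf("cannot index a %s", ot), e$pos)
        }
        "error"
      }
    },
    listlit = {
      if (length(e$items) == 0L) "string[]"  # empty literal defaults to string[]
      else {
        ets <- vapply(e$items, function(it) type_of(ctx, it, scope), "")
        u <- unique(ets[ets != "error"])
        if (length(u) == 2L && setequal(u, c("int", "real"))) u <- "real"
        if (length(u) > 1L) {
          ctx_error(ctx, sprintf("list elements have mixed types: %s",
                                 paste(u, collapse = ", ")), e$pos)
          "error"
        } else if (length(u) == 0L) "error"
        else paste0(u, "[]")
      }
    },
    task = {
      check_task_expr(ctx, e, scope)
      "string"
    },
    par = {
      if (e$par_kind == "call") {
        type_of_call(ctx, e$call, scope)
      } else {
        check_block(ctx, e$body, scope, fn = NULL, in_loop = FALSE)
      }
      "string"
    },
    goal = {
      tt <- type_of(ctx, e$targets, scope)
      if (!tt %in% c("string", "string[]", "error")) {
        ctx_error(ctx, sprintf("goal targets must be string or string[], got %s",
                               tt), e$pos)
      }
      "string[]"
    },
    {
      ctx_error(ctx, sprintf("unknown expression kind '%s'", e$kind), e$pos)
      "error"
    }
  )
  set_type(ctx, e, t)
}

type_of_call <- function(ctx, e, scope) {
  b <- PS_BUILTINS[[e$name]]
  if (!is.null(b)) {
    if (length(e$args) != 1L) {
      ctx_error(ctx, sprintf("%s takes exactly one argument", e$name), e$pos)
      return("error")
    }
    at <- type_of(ctx, e$args[[1]], scope)
    if (identical(at, "error")) return(b$ret)
    ok <- if (b$params == "scalar") is_scalar_type(at) else is_list_type(at)
    if (!ok) {
      ctx_error(ctx, sprintf("%s cannot take a %s", e$name, at), e$pos)
      return("error")
    }
    return(b$ret)
  }
  sig <- ctx$funcs[[e$name]]
  if (is.null(sig)) {
    ctx_error(ctx, sprintf("call to undefined function '%s'", e$name), e$pos)
    for (a in e$args) type_of(ctx, a, scope)
    return("error")
  }
  if (length(e$args) != length(sig$param_types)) {
    ctx_error(ctx, sprintf("'%s' expects %d argument(s), got %d",
                           e$name, length(sig$param_types), length(e$args)),
              e$pos)
  }
  for (i in seq_along(e$args)) {
    at <- type_of(ctx, e$args[[i]], scope)
    if (i <= length(sig$param_types) && !assignable_to(at, sig$param_types[[i]])) {
      ctx_error(ctx, sprintf("argument %d of '%s' must be %s, got %s",
                             i, e$name, sig$param_types[[i]], at), e$pos)
    }
  }
  sig$rettype
}

check_task_expr <- function(ctx, e, scope) {
  if (!is.null(e$depclause)) type_of(ctx, e$depclause, scope)
  for (nm in names(e$options)) {
    ot <- type_of(ctx, e$options[[nm]], scope)
    want <- if (nm == "taskName") "string" else "int"
    if (!ot %in% c(want, "error")) {
      ctx_error(ctx, sprintf("task option '%s' must be %s, got %s", nm, want, ot),
                e$options[[nm]]$pos)
    }
  }
  for (line in e$lines) check_segments(ctx, line, scope, e$pos)
}

#' Infer the type of an expression node
#'
#' Standard rules: `int op int -> int`, mixed `int`/`real` arithmetic
#' widens to `real`, `string + scalar -> string`, comparisons yield `bool`,
#' list literal elements must unify.
#'
#' @param expr An expression node (e.g. from [parse_expression()]).
#' @param symbols A named character vector or list mapping variable names to
#'   their types, e.g. `c(x = "int", files = "string[]")`.
#' @return The type as a string, e.g. `"real"` or `"string[]"`.
#' @examples
#' infer_type(parse_expression("1 + 2.0"))
#' infer_type(parse_expression("xs[0]"), c(xs = "string[]"))
#' @export
infer_type <- function(expr, symbols = character(0)) {
  ctx <- new_check_ctx(NULL)
  scope <- new_symtab()
  for (nm in names(PS_CONSTANTS)) assign(nm, "int", envir = scope)
  for (nm in names(symbols)) assign(nm, as.character(symbols[[nm]]), envir = scope)
  if (is.null(expr[["id"]])) {
    expr <- assign_ids(expr, local({e <- new.env(); e$n <- 0L; e}),
                       new.env(parent = emptyenv()))
  }
  t <- type_of(ctx, expr, scope)
  if (length(ctx$errors) > 0L) {
    msgs <- vapply(ctx$errors, function(e) e$message, "")
    stop(ps_condition("ps_type_error", paste(msgs, collapse = "\n"),
                      data = list(errors = ctx$errors)))
  }
  t
}

#' Parse a single expression
#'
#' Convenience for tests and interactive exploration: parses expression
#' source like `"1 + 2 * x"` into an expression node.
#'
#' @param text Expression source text.
#' @return An expression node.
#' @export
parse_expression <- function(text) {
  toks <- tokenize(text, origin = "<expr>")
  p <- new_parser(toks)
  e <- parse_expr(p)
  p_skip_nl(p)
  if (!p_at(p, "EOF")) {
    ps_stop("ps_parse_error", "trailing input after expression",
            pos = p_cur(p)$pos)
  }
  e
}
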