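# Runtime value representation.
#
# Scalars are length-1 R vectors (numbers are doubles with int semantics
# enforced by the operators: truncating division, integer modulo). Lists are
# R lists of scalars. Scopes are environments whose parent chain implements
# lexical nesting; each binding stores the value with its static type in the
# "pstype" attribute so checkpoints can serialize scopes faithfully.

typed_value <- function(value, type) {
  attr(value, "pstype") <- type
  value
}

value_type <- function(v) attr(v, "pstype")

strip_type <- function(v) {
  attr(v, "pstype") <- NULL
  v
}

default_value <- function(type) {
  if (is_list_type(type)) return(typed_value(list(), type))
  switch(type,
    int = typed_value(0, "int"),
    real = typed_value(0, "real"),
    bool = typed_value(FALSE, "bool"),
    string = typed_value("", "string"),
    ps_stop("ps_runtime_error", sprintf("no default for type %s", type))
  )
}

new_scope <- function(parent = NULL) {
  new.env(parent = if (is.null(parent)) emptyenv() else parent)
}

scope_declare <- function(scope, name, value) {
  assign(name, value, envir = scope)
}

scope_get <- function(scope, name, pos = NULL) {
  if (!exists(name, envir = scope, inherits = TRUE)) {
    ps_stop("ps_runtime_error", sprintf("undefined variable '%s'", name),
            pos = pos)
  }
  get(name, envir = scope, inherits = TRUE)
}

# assignment targets the scope in which the variable was declared
scope_set <- function(scope, name, value, pos = NULL) {
  e <- scope
  while (!identical(e, emptyenv())) {
    if (exists(name, envir = e, inherits = FALSE)) {
      assign(name, value, envir = e)
      return(invisible(NULL))
    }
    e <- parent.env(e)
  }
  ps_stop("ps_runtime_error", sprintf("assignment to undeclared variable '%s'",
                                      name), pos = pos)
}

# textual form used by print, string concatenation and $interpolation
value_text <- function(v) {
  type <- value_type(v)
  if (is_list_type(type)) {
    return(paste(vapply(v, value_text, ""), collapse = " "))
  }
  switch(type,
    int = sprintf("%.0f", v),
    real = {
      s <- format(unclass(strip_type(v)), digits = 15, scientific = FALSE,
                  trim = TRUE)
      s
    },
    bool = if (isTRUE(strip_type(v))) "true" else "false",
    string = strip_type(v),
    as.character(strip_type(v))
  )
}

value_as_paths <- function(v) {
  type <- value_type(v)
  if (is_list_type(type)) {
    vapply(v, function(x) as.character(strip_type(x)), "")
  } else {
    as.character(strip_type(v))
  }
}
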