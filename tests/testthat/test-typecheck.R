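# Static typing: inference rules (checked against an independent rule
# table), error collection before execution, and purity of the checker.

test_that("type inference matches the rule table over scalar operand pairs", {
  # independent statement of the rules, written from the numeric tower:
  # int op int -> int; int/real arithmetic widens; string + scalar -> string;
  # comparisons -> bool; logic needs bool
  oracle <- function(op, lt, rt) {
    num <- c("int", "real")
    if (op %in% c("+", "-", "*", "/")) {
      if (op == "+" && (lt == "string" || rt == "string") &&
          lt %in% c("string", num, "bool") && rt %in% c("string", num, "bool")) {
        return("string")
      }
      if (lt %in% num && rt %in% num) {
        return(if (lt == "int" && rt == "int") "int" else "real")
      }
      return(NA_character_)
    }
    if (op == "%") return(if (lt == "int" && rt == "int") "int" else NA_character_)
    if (op %in% c("==", "!=")) {
      if (lt %in% num && rt %in% num) return("bool")
      return(if (lt == rt) "bool" else NA_character_)
    }
    if (op %in% c("<", "<=", ">", ">=")) {
      if (lt %in% num && rt %in% num) return("bool")
      if (lt == "string" && rt == "string") return("bool")
      return(NA_character_)
    }
    if (op %in% c("&&", "||")) {
      return(if (lt == "bool" && rt == "bool") "bool" else NA_character_)
    }
    NA_character_
  }
  lits <- c(int = "1", real = "2.5", string = "\"s\"", bool = "true")
  ops <- c("+", "-", "*", "/", "%", "==", "!=", "<", "<=", ">", ">=", "&&", "||")
  for (op in ops) {
    for (lt in names(lits)) {
      for (rt in names(lits)) {
        src <- sprintf("%s %s %s", lits[[lt]], op, lits[[rt]])
        want <- oracle(op, lt, rt)
        got <- tryCatch(infer_type(parse_expression(src)),
                        ps_type_error = function(c) NA_character_)
        expect_identical(got, want, label = sprintf("type of `%s`", src))
      }
    }
  }
})

test_that("mixed arithmetic widens and lists infer element types", {
  expect_identical(infer_type(parse_expression("1 + 2")), "int")
  expect_identical(infer_type(parse_expression("1 + 2.0")), "real")
  expect_identical(infer_type(parse_expression('["a.txt", "b.txt"]')), "string[]")
  expect_identical(infer_type(parse_expression("[1, 2.5]")), "real[]")
  expect_identical(infer_type(parse_expression("xs[0]"), c(xs = "string[]")),
                   "string")
  expect_identical(infer_type(parse_expression("6*hour")), "int")
  expect_error(infer_type(parse_expression('[1, "a"]')), class = "ps_type_error")
})

test_that(":= binds the inferred type and conversions fail at check time", {
  typed <- check_program(parse_script('in := "input.file"'))
  expect_identical(typed$globals[["in"]]$type, "string")
  expect_error(check_program(parse_script('int x = "a"')),
               class = "ps_type_error")
  expect_error(check_program(parse_script('task( "o" <- "i", cpus := "two" ) { x }')),
               class = "ps_type_error")
})

test_that("all type errors are collected, not just the first", {
  d <- program_diagnostics(parse_script(paste(
    'int x = "a"',
    "y := x + true",
    "z := nowhere",
    sep = "\n")))
  expect_gte(length(d), 3L)
})

test_that("checking is repeatable and side-effect free", {
  tree <- parse_script("n := 1\nprintln n + 1")
  t1 <- check_program(tree)
  t2 <- check_program(tree)
  expect_identical(t1$types, t2$types)
  expect_identical(unparse(tree), unparse(t1$tree))
})

test_that("interpolated variables must be declared and interpolable", {
  expect_error(check_program(parse_script("sys echo $missing")),
               class = "ps_type_error")
  ok <- check_program(parse_script('xs := ["a","b"]\nsys echo $xs'))
  expect_s3_class(ok, "ps_typed")
})

test_that("function signatures are enforced and overloading is rejected", {
  expect_error(check_program(parse_script(paste(
    "int f(int x) {", "  return x", "}",
    "int f(string s) {", "  return 0", "}", sep = "\n"))),
    class = "ps_type_error")
  expect_error(check_program(parse_script(paste(
    "int f(int x) {", "  return x", "}",
    'y := f("a")', sep = "\n"))),
    class = "ps_type_error")
  expect_error(check_program(parse_script(paste(
    "int f(int x) {", "  return \"s\"", "}", sep = "\n"))),
    class = "ps_type_error")
})

test_that("well-typed generated programs execute without type faults", {
  set.seed(42)
  gen_expr <- function(type, depth) {
    if (depth <= 0) {
      return(switch(type,
        int = as.character(sample(0:9, 1)),
        real = sprintf("%d.%d", sample(0:9, 1), sample(1:9, 1)),
        string = sprintf("\"s%d\"", sample(0:9, 1)),
        bool = sample(c("true", "false"), 1)))
    }
    pick <- sample(1:3, 1)
    if (type == "int" && pick == 1) {
      sprintf("(%s %s %s)", gen_expr("int", depth - 1),
              sample(c("+", "-", "*"), 1), gen_expr("int", depth - 1))
    } else if (type == "real" && pick == 1) {
      sprintf("(%s + %s)", gen_expr(sample(c("int", "real"), 1), depth - 1),
              gen_expr("real", depth - 1))
    } else if (type == "string" && pick == 1) {
      sprintf("(%s + %s)",
              gen_expr("string", depth - 1),
              gen_expr(sample(c("string", "int", "bool"), 1), depth - 1))
    } else if (type == "bool" && pick == 1) {
      sprintf("(%s %s %s)", gen_expr("int", depth - 1),
              sample(c("<", "<=", "==", "!="), 1), gen_expr("int", depth - 1))
    } else if (type == "bool" && pick == 2) {
      sprintf("(%s && %s)", gen_expr("bool", depth - 1),
              gen_expr("bool", depth - 1))
    } else {
      gen_expr(type, 0)
    }
  }
  d <- ps_tmpdir()
  for (i in 1:15) {
    type <- sample(c("int", "real", "string", "bool"), 1)
    src <- sprintf("x := %s\nprintln toStr(x)", gen_expr(type, 3))
    path <- write_script(d, src, sprintf("fuzz%d.bds", i))
    capture.output(run <- suppressMessages(run_script(path, config = quick_cfg(d))))
    expect_equal(run$status$code, 0L, label = src)
  }
})
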