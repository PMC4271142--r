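# Language semantics and engine behavior: expressions, control flow,
# functions, sys, lazy tasks, wait barriers, par threads, overrides.

run_lines <- function(lines, ..., args = character(), cpus = 4) {
  d <- ps_tmpdir()
  script <- write_script(d, lines)
  out <- capture.output(
    run <- run_script(script, args = args, config = quick_cfg(d, cpus = cpus, ...)))
  list(run = run, out = out, dir = d)
}

test_that("arithmetic follows int semantics with widening", {
  fx <- run_lines(c(
    "println 7 / 2",        # truncating int division
    "println 7.0 / 2",      # real division
    "println 7 % 3",
    "println 0 - 7 / 2",
    "println 1 + 2.5",
    'println "n=" + 42',
    "println toInt(\"12\") + 1",
    "println [1,2,3]"
  ))
  expect_equal(fx$run$status$code, 0L)
  expect_equal(fx$out, c("3", "3.5", "1", "-3", "3.5", "n=42", "13", "1 2 3"))
})

test_that("control flow, for-in and functions compute as expected", {
  fx <- run_lines(c(
    "int fib(int n) {",
    "  if( n <= 1 ) {",
    "    return n",
    "  }",
    "  return fib(n - 1) + fib(n - 2)",
    "}",
    "total := 0",
    "for( int i = 0 ; i < 10 ; i = i + 1 ) {",
    "  if( i % 2 == 0 ) {",
    "    continue",
    "  }",
    "  total = total + i",
    "}",
    "println total",
    "println fib(10)",
    "words := [\"a\", \"b\", \"c\"]",
    "acc := \"\"",
    "for( w : words ) {",
    "  acc = acc + w",
    "}",
    "println acc",
    "n := 0",
    "while( true ) {",
    "  n = n + 1",
    "  if( n == 4 ) {",
    "    break",
    "  }",
    "}",
    "println n",
    "println len(words)"
  ))
  expect_equal(fx$out, c("25", "55", "abc", "4", "3"))
})

test_that("sys runs synchronously, returns stdout, and aborts on failure", {
  fx <- run_lines(c('msg := "hello"', "sys echo $msg"))
  expect_equal(fx$run$status$code, 0L)
  expect_true("hello" %in% fx$out)

  fx2 <- run_lines(c("sys true", "sys false", 'println "unreached"'))
  expect_equal(fx2$run$status$code, 1L)
  expect_false("unreached" %in% fx2$out)
  expect_true(file.exists(fx2$run$checkpoint))
})

test_that("tasks with satisfied dependencies are SKIPPED without spawning", {
  d <- ps_tmpdir()
  make_file_tree(list(
    "in.txt" = list(size = 3, mtime_offset = 0),
    "out.txt" = list(size = 3, mtime_offset = 50)
  ), base = d)
  script <- write_script(d, c(
    'task( "out.txt" <- "in.txt" ) {',
    "  cp in.txt out.txt",
    "}"
  ))
  run <- run_script(script, config = quick_cfg(d))
  expect_equal(run$tasks$state, "SKIPPED")
  expect_false(any(run$events$to == "RUNNING"))
  expect_equal(run$tasks$attempts, 0L)
})

test_that("a task with no dependency clause always runs", {
  fx <- run_lines(c("task { echo hi > always.txt }"))
  expect_equal(fx$run$tasks$state, "DONE")
  expect_true(file.exists(file.path(fx$dir, "always.txt")))
})

test_that("the engine blocks at exit until spawned tasks finish (implicit wait)", {
  d <- ps_tmpdir()
  script <- write_script(d, c(
    "task {",
    "  sleep 0.4",
    "  echo done > slow.txt",
    "}"
  ))
  run <- run_script(script, config = quick_cfg(d))
  expect_equal(run$status$code, 0L)
  expect_true(file.exists(file.path(d, "slow.txt")))
  # implicit-wait totality: every unit terminal at exit
  expect_true(all(run$tasks$state %in%
                    c("DONE", "FAILED", "KILLED", "TIMEOUT", "SKIPPED")))
})

test_that("wait on specific ids does not join unrelated tasks", {
  d <- ps_tmpdir()
  script <- write_script(d, c(
    "slow := task {",
    "  sleep 1.2",
    "  echo slow > slow.txt",
    "}",
    "fast := task {",
    "  echo fast > fast.txt",
    "}",
    "wait [fast]",
    "sys test -f fast.txt",
    "sys test ! -f slow.txt",
    "wait"
  ))
  run <- run_script(script, config = quick_cfg(d))
  expect_equal(run$status$code, 0L)
  expect_true(file.exists(file.path(d, "slow.txt")))
})

test_that("waiting on an unknown id is an error", {
  fx <- run_lines(c('wait ["task.999"]'))
  expect_equal(fx$run$status$reason, "runtime-error")
  expect_match(paste(fx$run$failures, collapse = " "), "unknown task")
})

test_that("a failing task stops the program at the wait, after the others finish", {
  d <- ps_tmpdir()
  script <- write_script(d, c(
    "task( taskName := \"bad\" ) {",
    "  exit 3",
    "}",
    "task( taskName := \"slow1\" ) {",
    "  sleep 0.5",
    "  echo one > one.txt",
    "}",
    "task( taskName := \"slow2\" ) {",
    "  sleep 0.5",
    "  echo two > two.txt",
    "}",
    "wait",
    "sys echo never > after.txt"
  ))
  run <- run_script(script, config = quick_cfg(d, cpus = 8))
  expect_equal(run$status$code, 1L)
  expect_equal(run$status$reason, "task-failed")
  # the engine waited for the remaining tasks before stopping
  expect_true(file.exists(file.path(d, "one.txt")))
  expect_true(file.exists(file.path(d, "two.txt")))
  expect_false(file.exists(file.path(d, "after.txt")))
  expect_true(file.exists(run$checkpoint))
  expect_match(paste(run$failures, collapse = " "), "task.1")
})

test_that("par threads snapshot their scope and join through wait", {
  d <- ps_tmpdir()
  script <- write_script(d, c(
    "x := 1",
    "pid := par {",
    "  x = 99",
    "  task {",
    "    sleep 0.2",
    "    echo a > a.txt",
    "  }",
    "}",
    "pid2 := par {",
    "  task {",
    "    sleep 0.2",
    "    echo b > b.txt",
    "  }",
    "}",
    "wait [pid, pid2]",
    "println \"x=\" + x"
  ))
  out <- capture.output(run <- run_script(script, config = quick_cfg(d, cpus = 8)))
  expect_equal(run$status$code, 0L)
  expect_true("x=1" %in% out)  # writes inside par do not leak out
  expect_true(file.exists(file.path(d, "a.txt")))
  expect_true(file.exists(file.path(d, "b.txt")))
  # the two par-spawned tasks overlapped
  fan <- run$tasks$id
  expect_equal(peak_concurrency(run, ids = fan), 2L)
})

test_that("par failures surface at the implicit wait with nonzero exit", {
  fx <- run_lines(c(
    "p := par {",
    "  xs := [1]",
    "  println xs[5]",
    "}",
    'println "main continues"'
  ))
  expect_true("main continues" %in% fx$out)
  expect_equal(fx$run$status$code, 1L)
  expect_match(paste(fx$run$failures, collapse = " "), "par.1")
})

test_that("par can run a function call with arguments", {
  fx <- run_lines(c(
    "void emit(string tag) {",
    "  sys echo $tag > par_out.txt",
    "}",
    "pid := par emit(\"from-par\")",
    "wait [pid]"
  ))
  expect_equal(fx$run$status$code, 0L)
  expect_identical(readLines(file.path(fx$dir, "par_out.txt")), "from-par")
})

test_that("command-line overrides replace initializers with type conversion", {
  d <- ps_tmpdir()
  script <- write_script(d, c(
    'in := "input.file"',
    "n := 0",
    "flag := false",
    'println in + ":" + n + ":" + flag'
  ))
  out <- capture.output(
    run <- run_script(script, args = c("-in", "another.file", "-n", "5",
                                       "-flag", "true"),
                      config = quick_cfg(d)))
  expect_equal(out, "another.file:5:true")
  # override round-trip: same result as editing the initializer
  script2 <- write_script(d, c(
    'in := "another.file"', "n := 5", "flag := true",
    'println in + ":" + n + ":" + flag'), "edited.bds")
  out2 <- capture.output(run2 <- run_script(script2, config = quick_cfg(d)))
  expect_identical(out, out2)
})

test_that("scheduled command sequence is deterministic across runs", {
  seq_of <- function() {
    d <- ps_tmpdir()
    script <- write_script(d, gen_fanout_pipeline(
      n_tasks = 5, cpus_per_task = 1, task_duration = 0), "fan.bds")
    gen_fanout_inputs(d, 5)
    run <- run_script(script, config = quick_cfg(d, cpus = 2))
    scripts <- sort(list.files(run$run_dir, pattern = "^task\\..*\\.sh$"))
    unlist(lapply(scripts, function(f) {
      ln <- readLines(file.path(run$run_dir, f))
      ln[!grepl("^cd ", ln)]  # drop the run-specific working directory
    }))
  }
  expect_identical(seq_of(), seq_of())
})

test_that("dry run reports tasks without executing them", {
  d <- ps_tmpdir()
  script <- write_script(d, c(
    'task( "o.txt" <- "i.txt" ) {',
    "  cp i.txt o.txt",
    "}"
  ))
  writeLines("x", file.path(d, "i.txt"))
  out <- capture.output(
    run <- run_script(script, config = quick_cfg(d, dry_run = TRUE)))
  expect_equal(run$status$code, 0L)
  expect_false(file.exists(file.path(d, "o.txt")))
  expect_match(paste(out, collapse = "\n"), "dry run")
})

test_that("goal statements execute deferred deps lazily end to end", {
  d <- ps_tmpdir()
  lines <- c(
    'src := "src.txt"', 'mid := "mid.txt"', 'fin := "fin.txt"',
    "dep( mid <- src ) {",
    "  cat $src > $mid",
    "}",
    "dep( fin <- mid ) {",
    "  cat $mid $mid > $fin",
    "}",
    "ids := goal fin",
    "wait ids",
    "println len(ids)"
  )
  script <- write_script(d, lines)
  writeLines("payload", file.path(d, "src.txt"))
  out <- capture.output(run <- run_script(script, config = quick_cfg(d)))
  expect_equal(run$status$code, 0L)
  expect_equal(out, "2")
  expect_identical(readLines(file.path(d, "fin.txt")), c("payload", "payload"))
  # rerun: intermediate deleted but final fresh -> no work at all
  unlink(file.path(d, "mid.txt"))
  out2 <- capture.output(run2 <- run_script(script, config = quick_cfg(d)))
  expect_equal(out2, "0")
  expect_equal(nrow(run2$tasks), 0L)
})
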