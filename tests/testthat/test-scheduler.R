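# Resource-pool scheduling: concurrency arithmetic, CPU conservation,
# retry+1 semantics, stale-output cleanup, DAG ordering, and interrupt
# cleanup.

fanout_run <- function(n, cpus_per_task, duration, pool,
                       executor = "local", ...) {
  d <- ps_tmpdir()
  script <- write_script(d, gen_fanout_pipeline(
    n_tasks = n, cpus_per_task = cpus_per_task, task_duration = duration),
    "fan.bds")
  gen_fanout_inputs(d, n)
  run <- run_script(script, config = engine_config(
    executor = executor, cpus = pool, run_dir = file.path(d, "run"),
    work_dir = d, poll_interval = 0.02, ...))
  list(run = run, dir = d)
}

test_that("peak concurrency is min(floor(pool/cpus), n_tasks)", {
  fx <- fanout_run(n = 9, cpus_per_task = 2, duration = 0.4, pool = 8)
  expect_equal(fx$run$status$code, 0L)
  fan <- fx$run$tasks$id[fx$run$tasks$name %in% "myProcess"]
  expect_equal(peak_concurrency(fx$run, ids = fan), 4L)
  # under-subscribed pool: everything runs at once
  fx2 <- fanout_run(n = 3, cpus_per_task = 1, duration = 0.4, pool = 4)
  fan2 <- fx2$run$tasks$id[fx2$run$tasks$name %in% "myProcess"]
  expect_equal(peak_concurrency(fx2$run, ids = fan2), 3L)
})

test_that("running CPU demand never exceeds the pool (conservation)", {
  fx <- fanout_run(n = 8, cpus_per_task = 2, duration = 0.15, pool = 4)
  ev <- fx$run$events
  cpus <- setNames(fx$run$tasks$cpus, fx$run$tasks$id)
  in_use <- 0L
  for (i in seq_len(nrow(ev))) {
    if (ev$to[i] == "RUNNING") in_use <- in_use + cpus[[ev$id[i]]]
    if (ev$from[i] == "RUNNING") in_use <- in_use - cpus[[ev$id[i]]]
    expect_lte(in_use, 4L)
    expect_gte(in_use, 0L)
  }
})

test_that("a task requesting more CPUs than the pool total is rejected before running", {
  fx <- fanout_run(n = 3, cpus_per_task = 2, duration = 0.05, pool = 1)
  expect_equal(fx$run$status$reason, "resource-error")
  expect_gt(fx$run$status$code, 0L)
  expect_equal(sum(fx$run$tasks$state == "DONE"), 0L)
  expect_false(any(fx$run$events$to == "RUNNING"))
  expect_match(paste(fx$run$failures, collapse = " "), "lack of resources")
})

test_that("the mock-cluster executor accepts every submission", {
  fx <- fanout_run(n = 6, cpus_per_task = 2, duration = 0.3, pool = 1,
                   executor = "mock-cluster")
  expect_equal(fx$run$status$code, 0L)
  fan <- fx$run$tasks$id[fx$run$tasks$name %in% "myProcess"]
  sched <- fx$run$events[fx$run$events$to == "SCHEDULED", ]
  expect_equal(sum(sched$id %in% fan), 6L)
  expect_equal(peak_concurrency(fx$run, ids = fan), 6L)
})

test_that("tasks fail only after retry+1 attempts and outputs are cleaned", {
  d <- ps_tmpdir()
  ctr <- file.path(d, "ctr")
  script <- write_script(d, c(
    'task( "out.txt" <- "in.txt", retry := 2 ) {',
    paste0("  ", flaky_command(5, ctr)),
    "  echo payload > out.txt",
    "}"
  ))
  writeLines("x", file.path(d, "in.txt"))
  run <- run_script(script, config = quick_cfg(d))
  expect_equal(run$tasks$state, "FAILED")
  expect_equal(run$tasks$attempts, 3L)          # retry+1
  expect_equal(as.integer(readLines(ctr)), 3L)  # the command really ran 3 times
  expect_false(file.exists(file.path(d, "out.txt")))  # stale output cleaned

  # flaky task that recovers within its retry budget
  d2 <- ps_tmpdir()
  ctr2 <- file.path(d2, "ctr")
  script2 <- write_script(d2, c(
    'task( "out.txt" <- "in.txt", retry := 1 ) {',
    paste0("  ", flaky_command(1, ctr2)),
    "  echo payload > out.txt",
    "}"
  ))
  writeLines("x", file.path(d2, "in.txt"))
  run2 <- run_script(script2, config = quick_cfg(d2))
  expect_equal(run2$tasks$state, "DONE")
  expect_equal(run2$tasks$attempts, 2L)
  expect_equal(as.integer(readLines(ctr2)), 2L)
  expect_true(file.exists(file.path(d2, "out.txt")))
})

test_that("terminal attempt counts stay within [1, retry+1]", {
  d <- ps_tmpdir()
  lines <- c("retryBudget := 2")
  for (k in 0:3) {
    ctr <- file.path(d, sprintf("ctr%d", k))
    lines <- c(lines,
               sprintf('task( taskName := "flaky%d", retry := retryBudget ) {', k),
               paste0("  ", flaky_command(k, ctr)),
               "}")
  }
  run <- run_script(write_script(d, lines), config = quick_cfg(d))
  for (i in seq_len(nrow(run$tasks))) {
    tk <- run$tasks[i, ]
    expect_gte(tk$attempts, 1L)
    expect_lte(tk$attempts, 3L)
    if (tk$state == "FAILED") expect_equal(tk$attempts, 3L)
  }
  expect_equal(sort(run$tasks$state), sort(c("DONE", "DONE", "DONE", "FAILED")))
})

test_that("a DAG successor never starts before its producers are DONE", {
  d <- ps_tmpdir()
  script <- write_script(d, c(
    'a := "a.txt"', 'b := "b.txt"', 'c := "c.txt"',
    "task( a <- \"src.txt\" ) {",
    "  sleep 0.3",
    "  echo a > $a",
    "}",
    "task( b <- \"src.txt\" ) {",
    "  sleep 0.3",
    "  echo b > $b",
    "}",
    "task( c <- [a, b] ) {",
    "  cat $a $b > $c",
    "}"
  ))
  writeLines("s", file.path(d, "src.txt"))
  run <- run_script(script, config = quick_cfg(d, cpus = 8))
  expect_equal(run$status$code, 0L)
  ev <- run$events
  done_a <- ev$time[ev$id == "task.1" & ev$to == "DONE"]
  done_b <- ev$time[ev$id == "task.2" & ev$to == "DONE"]
  start_c <- ev$time[ev$id == "task.3" & ev$to == "RUNNING"]
  expect_gte(start_c, max(done_a, done_b))
  expect_identical(readLines(file.path(d, "c.txt")), c("a", "b"))
})

test_that("interrupting a run terminates every scheduled and running task", {
  skip_if_not(nzchar(Sys.which("pkill")), "pkill unavailable")
  d <- ps_tmpdir()
  marker <- sprintf("sleep 93.1%d", sample(10:99, 1))
  lines <- c("for( int i = 0 ; i < 6 ; i = i + 1 ) {",
             "  task( cpus := 1 ) {",
             paste0("    ", marker),
             "  }",
             "}")
  script <- write_script(d, lines)
  driver <- file.path(d, "driver.R")
  libs <- paste(sprintf("'%s'", .libPaths()), collapse = ", ")
  writeLines(c(
    sprintf(".libPaths(c(%s))", libs),
    "library(pipescript)",
    sprintf("run <- run_script('%s', config = engine_config(cpus = 4,", script),
    sprintf("  run_dir = '%s', work_dir = '%s', poll_interval = 0.02))",
            file.path(d, "run"), d),
    "quit(save = 'no', status = run$status$code)"
  ), driver)
  pid_file <- file.path(d, "driver.pid")
  system(sprintf("Rscript '%s' & echo $! > '%s'", driver, pid_file))
  # wait until tasks are running
  evlog <- file.path(d, "run", "events.log")
  t0 <- Sys.time()
  repeat {
    if (file.exists(evlog) &&
        any(read_event_log(evlog)$to == "RUNNING")) break
    if (as.numeric(Sys.time() - t0, units = "secs") > 20) {
      stop("driver never started tasks")
    }
    Sys.sleep(0.1)
  }
  Sys.sleep(0.3)
  rpid <- as.integer(readLines(pid_file))
  system2("kill", c("-s", "INT", as.character(rpid)))
  t0 <- Sys.time()
  while (file.exists(file.path("/proc", rpid)) &&
         as.numeric(Sys.time() - t0, units = "secs") < 15) {
    Sys.sleep(0.1)
  }
  Sys.sleep(0.3)
  pattern <- sub(".", "[.]", marker, fixed = TRUE)
  survivors <- suppressWarnings(
    system2("pgrep", c("-f", shQuote(pattern)), stdout = TRUE, stderr = FALSE))
  expect_length(survivors[nzchar(survivors)], 0L)
  ev <- read_event_log(evlog)
  expect_false(any(ev$to == "DONE"))
  expect_true(any(ev$to == "KILLED"))
  # interrupt checkpoint was written
  expect_true(file.exists(file.path(d, "run",
                                    "pipeline.bds.interrupt.chp")))
})
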