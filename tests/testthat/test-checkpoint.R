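# Absolute serialization: round-trips, canonical encoding, resume
# equivalence against uninterrupted reference runs, and inspection.

test_that("scope bindings round-trip through a checkpoint with their types", {
  d <- ps_tmpdir()
  script <- write_script(d, c(
    "n := 5",
    'files := ["a.txt", "b.txt"]',
    "r := 2.5",
    "ok := true",
    'checkpoint "c.chp"',
    'println "n=" + n + " files=" + files[0] + "," + files[1] + " r=" + r + " ok=" + ok'
  ))
  out1 <- capture.output(run1 <- run_script(script, config = quick_cfg(d)))
  expect_equal(run1$status$code, 0L)
  out2 <- capture.output(run2 <- resume_checkpoint(file.path(d, "c.chp")))
  expect_equal(run2$status$code, 0L)
  expect_identical(out2, out1[length(out1)])  # identical bindings and types
})

test_that("loading and re-saving a checkpoint is byte-identical", {
  d <- ps_tmpdir()
  script <- write_script(d, c(
    "xs := [1, 2, 3]",
    "pi := 3.14159265358979",
    "task { echo t > t.txt }",
    "wait",
    'checkpoint "c.chp"'
  ))
  run <- run_script(script, config = quick_cfg(d))
  path <- file.path(d, "c.chp")
  before <- readBin(path, "raw", file.size(path))
  chp <- pipescript:::load_checkpoint(path)
  path2 <- file.path(d, "resaved.chp")
  pipescript:::save_checkpoint_data(chp, path2)
  after <- readBin(path2, "raw", file.size(path2))
  expect_identical(after, before)
})

test_that("explicit checkpoint in a loop resumes at its successor statement", {
  d <- ps_tmpdir()
  script <- write_script(d, c(
    "total := 0",
    "for( int i = 0 ; i < 8 ; i = i + 1 ) {",
    "  total = total + i",
    "  if( i == 5 ) {",
    "    checkpoint \"c.chp\"",
    "  }",
    "  sys echo iter $i >> trace.txt",
    "}",
    "println \"total=\" + total"
  ))
  out1 <- capture.output(run1 <- run_script(script, config = quick_cfg(d)))
  expect_equal(length(readLines(file.path(d, "trace.txt"))), 8L)
  expect_true("total=28" %in% out1)
  # wipe the trace: the resumed run must only replay iterations 5..7
  unlink(file.path(d, "trace.txt"))
  out2 <- capture.output(run2 <- resume_checkpoint(file.path(d, "c.chp")))
  expect_equal(run2$status$code, 0L)
  expect_identical(readLines(file.path(d, "trace.txt")),
                   sprintf("iter %d", 5:7))
  expect_true("total=28" %in% out2)  # loop state and totals fully restored
})

test_that("resume after a task failure re-runs only the failed task", {
  d <- ps_tmpdir()
  ctr1 <- file.path(d, "c1")
  ctr2 <- file.path(d, "c2")
  script <- write_script(d, c(
    'task( "o1.txt" <- "src.txt" ) {',
    paste0("  ", flaky_command(0, ctr1)),
    "  cat src.txt > o1.txt",
    "}",
    "wait",
    'task( "o2.txt" <- "o1.txt" ) {',
    paste0("  ", flaky_command(1, ctr2)),
    "  tr a-z A-Z < o1.txt > o2.txt",
    "}",
    "wait",
    'task( "o3.txt" <- "o2.txt" ) {',
    "  cat o2.txt o2.txt > o3.txt",
    "}"
  ))
  writeLines("abc", file.path(d, "src.txt"))
  run1 <- run_script(script, config = quick_cfg(d))
  expect_equal(run1$status$code, 1L)
  states <- setNames(run1$tasks$state, run1$tasks$id)
  expect_equal(unname(states["task.1"]), "DONE")
  expect_equal(unname(states["task.2"]), "FAILED")
  expect_false(file.exists(file.path(d, "o3.txt")))

  run2 <- resume_checkpoint(run1$checkpoint)
  expect_equal(run2$status$code, 0L)
  expect_equal(as.integer(readLines(ctr1)), 1L)  # task 1 was NOT re-run
  expect_equal(as.integer(readLines(ctr2)), 2L)  # task 2 re-ran once
  expect_identical(readLines(file.path(d, "o3.txt")), c("ABC", "ABC"))
})

test_that("interrupted+resumed runs reproduce the uninterrupted outputs exactly", {
  # reference run, no induced failures
  ref <- ps_tmpdir()
  run_ref <- run_script(six_task_pipeline(ref), config = quick_cfg(ref))
  expect_equal(run_ref$status$code, 0L)
  ref_out <- six_outputs(ref)
  expect_false(anyNA(ref_out))

  # five interruption points: induced failures at tasks 2, 3 and 5
  # (auto-checkpoint at the failed wait), plus resumes from the two explicit
  # checkpoint statements after an induced failure downstream of them
  scenarios <- list(
    list(stop = 2, resume_from = "auto"),
    list(stop = 3, resume_from = "auto"),
    list(stop = 5, resume_from = "auto"),
    list(stop = 2, resume_from = "cp_a.chp"),
    list(stop = 4, resume_from = "cp_b.chp")
  )
  for (sc in scenarios) {
    d <- ps_tmpdir()
    script <- six_task_pipeline(d)
    file.create(file.path(d, sprintf("stop_%d", sc$stop)))
    run1 <- run_script(script, config = quick_cfg(d))
    expect_equal(run1$status$code, 1L,
                 label = sprintf("stop_%d first run fails", sc$stop))
    counts_before <- six_counts(d)
    chp <- if (identical(sc$resume_from, "auto")) run1$checkpoint
           else file.path(d, sc$resume_from)
    expect_true(file.exists(chp))
    run2 <- resume_checkpoint(chp)
    expect_equal(run2$status$code, 0L,
                 label = sprintf("stop_%d resume (%s)", sc$stop, sc$resume_from))
    expect_identical(six_outputs(d), ref_out,
                     label = sprintf("stop_%d outputs equal reference", sc$stop))
    # tasks DONE before the checkpoint were not executed again
    done_before <- which(counts_before == 1L & seq_len(6) < sc$stop)
    expect_identical(six_counts(d)[done_before], counts_before[done_before])
  }
})

test_that("resuming an already-completed run schedules zero tasks", {
  d <- ps_tmpdir()
  script <- write_script(d, c(
    'task( "o.txt" <- "i.txt" ) {',
    "  cat i.txt > o.txt",
    "}",
    "wait",
    'checkpoint "done.chp"'
  ))
  writeLines("x", file.path(d, "i.txt"))
  run1 <- run_script(script, config = quick_cfg(d))
  expect_equal(run1$status$code, 0L)
  run2 <- resume_checkpoint(file.path(d, "done.chp"))
  expect_equal(run2$status$code, 0L)
  expect_false(any(run2$events$to == "RUNNING"))
  run3 <- resume_checkpoint(file.path(d, "done.chp"))
  expect_false(any(run3$events$to == "RUNNING"))
})

test_that("resume validates the script against the embedded source", {
  d <- ps_tmpdir()
  script <- write_script(d, c("x := 1", 'checkpoint "c.chp"', "println x"))
  capture.output(run_script(script, config = quick_cfg(d)))
  # unchanged script passes
  out <- capture.output(run <- resume_checkpoint(file.path(d, "c.chp"),
                                                 script = script))
  expect_equal(run$status$code, 0L)
  # edited script is stale
  writeLines(c("x := 2", 'checkpoint "c.chp"', "println x"), script)
  expect_error(resume_checkpoint(file.path(d, "c.chp"), script = script),
               class = "ps_stale_source_error")
})

test_that("unsupported checkpoint versions are rejected", {
  d <- ps_tmpdir()
  script <- write_script(d, c('checkpoint "c.chp"'))
  run_script(script, config = quick_cfg(d))
  chp <- pipescript:::load_checkpoint(file.path(d, "c.chp"))
  chp$format_version <- 999
  pipescript:::save_checkpoint_data(chp, file.path(d, "v999.chp"))
  expect_error(resume_checkpoint(file.path(d, "v999.chp")),
               class = "ps_version_mismatch_error")
})

test_that("inspect prints variables and the failed task table, read-only", {
  d <- ps_tmpdir()
  script <- write_script(d, c(
    'label := "experiment-7"',
    "task( taskName := \"willfail\" ) {",
    "  exit 9",
    "}",
    "wait"
  ))
  run <- run_script(script, config = quick_cfg(d))
  expect_equal(run$status$code, 1L)
  before <- unname(tools::md5sum(run$checkpoint))
  out <- capture.output(inspect_checkpoint(run$checkpoint))
  txt <- paste(out, collapse = "\n")
  expect_match(txt, "label: string = experiment-7")
  expect_match(txt, "task.1 \\[FAILED\\]")
  expect_match(txt, "exit code 9")
  expect_identical(unname(tools::md5sum(run$checkpoint)), before)
})

test_that("serialization stays fast for large task tables", {
  d <- ps_tmpdir()
  lines <- c(
    "for( int i = 0 ; i < 1000 ; i = i + 1 ) {",
    '  dep( "o" + i + ".txt" <- "i" + i + ".txt" ) {',
    "    touch o$i.txt",
    "  }",
    "}",
    'checkpoint "big.chp"'
  )
  script <- write_script(d, lines)
  run <- run_script(script, config = quick_cfg(d))
  expect_equal(run$status$code, 0L)
  t0 <- Sys.time()
  chp <- pipescript:::load_checkpoint(file.path(d, "big.chp"))
  pipescript:::save_checkpoint_data(chp, file.path(d, "big2.chp"))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  expect_equal(length(chp$graph), 1000L)
})
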