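# Task lifecycle management against a resource-budgeted executor.
#
# Two executors share one contract (submit / poll / kill):
#   * local: a CPU/memory pool; strict FIFO dispatch with head-of-line
#     blocking, so a saturated pool runs tasks one wave at a time and a
#     2-CPU task on a 1-CPU pool is rejected outright;
#   * mock-cluster: accepts every submission immediately (the "cluster
#     management system" decides), with optional queue latency and a seeded
#     induced-failure rate for robustness scenarios.
# Task states: CREATED -> SCHEDULED -> RUNNING -> {DONE, FAILED, KILLED,
# TIMEOUT}; SKIPPED tasks never reach the scheduler. A failing task is
# retried until it has failed retry+1 times; each failure deletes the task's
# declared outputs so reruns never consume half-written files.

PS_TERMINAL_STATES <- c("DONE", "FAILED", "KILLED", "TIMEOUT", "SKIPPED")

new_task_record <- function(id, command, ins, outs, cpus = 1L, mem = 0,
                            timeout = 0, retry = 0L, name = NULL,
                            after = character(0), owner = "main",
                            kind = "task") {
  rec <- new.env(parent = emptyenv())
  rec$id <- id
  rec$name <- name
  rec$kind <- kind
  rec$command <- command
  rec$ins <- as.character(ins)
  rec$outs <- as.character(outs)
  rec$cpus <- as.integer(cpus)
  rec$mem <- as.numeric(mem)
  rec$timeout <- as.numeric(timeout)
  rec$retry <- as.integer(retry)
  rec$after <- as.character(after)
  rec$owner <- owner
  rec$state <- "CREATED"
  rec$attempts <- 0L
  rec$pid <- NA_integer_
  rec$exit_code <- NA_integer_
  rec$failure <- NA_character_
  rec$t_sched <- NA_real_
  rec$t_start <- NA_real_
  rec$t_end <- NA_real_
  rec$handle <- NULL
  rec$killing_since <- NA_real_
  rec$synthetic_fail <- FALSE
  rec
}

make_executor <- function(config) {
  ex <- new.env(parent = emptyenv())
  ex$kind <- config$executor
  ex$total_cpus <- as.integer(config$cpus)
  ex$total_mem <- as.numeric(config$mem)
  ex$used_cpus <- 0L
  ex$used_mem <- 0
  ex$queue <- character(0)
  ex$queue_delay <- as.numeric(config$queue_delay)
  ex$fail_rate <- as.numeric(config$fail_rate)
  ex
}

log_event <- function(engine, id, from, to) {
  t <- as.numeric(Sys.time())
  line <- sprintf("%.6f\t%s\t%s\t%s", t, id, from, to)
  if (!is.null(engine$event_con)) {
    writeLines(line, engine$event_con)
    flush(engine$event_con)
  }
  engine$events[[length(engine$events) + 1L]] <-
    list(time = t, id = id, from = from, to = to)
  invisible(NULL)
}

set_task_state <- function(engine, rec, state) {
  old <- rec$state
  rec$state <- state
  log_event(engine, rec$id, old, state)
}

#' Submit a task spec to the engine's executor
#'
#' On the local executor a task whose CPU or memory request exceeds the
#' pool's *total* is rejected immediately with a `ps_resource_error` —
#' the program cannot ever run it, so execution fails owing to lack of
#' resources. The mock-cluster executor accepts every submission.
#'
#' @param engine An engine (internal).
#' @param rec A task record.
#' @keywords internal
submit_task <- function(engine, rec) {
  ex <- engine$executor
  if (ex$kind == "local") {
    if (rec$cpus > ex$total_cpus) {
      ps_stop("ps_resource_error",
              sprintf("task %s requires %d cpus but the executor has %d (lack of resources)",
                      rec$id, rec$cpus, ex$total_cpus))
    }
    if (is.finite(ex$total_mem) && rec$mem > ex$total_mem) {
      ps_stop("ps_resource_error",
              sprintf("task %s requires %.0f bytes but the executor has %.0f (lack of resources)",
                      rec$id, rec$mem, ex$total_mem))
    }
  }
  rec$t_sched <- as.numeric(Sys.time())
  rec$ready_at <- rec$t_sched + if (ex$kind == "mock-cluster") ex$queue_delay else 0
  set_task_state(engine, rec, "SCHEDULED")
  ex$queue <- c(ex$queue, rec$id)
  dispatch_tasks(engine)
  invisible(rec$id)
}

deps_satisfied <- function(engine, rec) {
  if (length(rec$after) == 0L) return(TRUE)
  all(vapply(rec$after, function(id) {
    dep <- engine$tasks[[id]]
    is.null(dep) || dep$state %in% c("DONE", "SKIPPED")
  }, TRUE))
}

# Start queued tasks that fit. Local: strict FIFO, the head blocks the line.
dispatch_tasks <- function(engine) {
  ex <- engine$executor
  if (ex$kind == "local") {
    while (length(ex$queue) > 0L) {
      rec <- engine$tasks[[ex$queue[[1]]]]
      if (!deps_satisfied(engine, rec)) break
      free_cpus <- ex$total_cpus - ex$used_cpus
      free_mem <- ex$total_mem - ex$used_mem
      if (rec$cpus > free_cpus || (is.finite(free_mem) && rec$mem > free_mem)) break
      ex$queue <- ex$queue[-1]
      ex$used_cpus <- ex$used_cpus + rec$cpus
      ex$used_mem <- ex$used_mem + rec$mem
      start_task(engine, rec)
    }
  } else {
    now <- as.numeric(Sys.time())
    keep <- character(0)
    for (id in ex$queue) {
      rec <- engine$tasks[[id]]
      if (rec$ready_at <= now && deps_satisfied(engine, rec)) {
        start_task(engine, rec)
      } else {
        keep <- c(keep, id)
      }
    }
    ex$queue <- keep
  }
  invisible(NULL)
}

start_task <- function(engine, rec) {
  rec$attempts <- rec$attempts + 1L
  rec$t_start <- as.numeric(Sys.time())
  rec$killing_since <- NA_real_
  ex <- engine$executor
  if (ex$kind == "mock-cluster" && ex$fail_rate > 0) {
    if (next_unif(engine) < ex$fail_rate) {
      # induced hardware-style failure: the job never produces a result
      rec$synthetic_fail <- TRUE
      rec$handle <- NULL
      set_task_state(engine, rec, "RUNNING")
      return(invisible(NULL))
    }
  }
  rec$synthetic_fail <- FALSE
  script <- write_task_script(rec$id, rec$command, engine$run_dir,
                              work_dir = engine$work_dir)
  rec$handle <- launch_task(rec$id, script, engine$run_dir,
                            timeout = rec$timeout)
  poller_register(engine$poller, rec$handle$stdout_path, rec$id)
  poller_register(engine$poller, rec$handle$stderr_path, rec$id)
  set_task_state(engine, rec, "RUNNING")
  invisible(NULL)
}

# One scheduler pass: reap finished tasks, enforce timeouts, dispatch, and
# relay freshly appended log output to the console.
scheduler_poll <- function(engine) {
  for (id in engine$task_order) {
    rec <- engine$tasks[[id]]
    if (rec$state != "RUNNING") next
    if (rec$synthetic_fail) {
      finish_task(engine, rec, list(kind = "exit", code = 1L))
      next
    }
    h <- rec$handle
    if (is.na(rec$pid)) rec$pid <- run_handle_pid(h)
    st <- read_exit_status(h$exit_path)
    now <- as.numeric(Sys.time())
    if (!is.na(rec$killing_since)) {
      if (!is.null(st) || !pid_alive(run_handle_pid(h))) {
        write_timeout_sentinel(h$exit_path)
        finish_task(engine, rec, list(kind = "timeout", code = NA_integer_))
      } else if (now - rec$killing_since > engine$config$timeout_grace) {
        kill_group(run_handle_pid(h), "KILL")
      }
      next
    }
    if (!is.null(st)) {
      if (identical(st, PS_TIMEOUT_SENTINEL)) {
        finish_task(engine, rec, list(kind = "timeout", code = NA_integer_))
      } else {
        finish_task(engine, rec, list(kind = "exit", code = st))
      }
      next
    }
    if (!is.na(h$deadline) && now > h$deadline) {
      kill_group(run_handle_pid(h), "TERM")
      rec$killing_since <- now
    }
  }
  dispatch_tasks(engine)
  relay_logs(engine)
  invisible(NULL)
}

relay_logs <- function(engine) {
  ems <- poller_tick(engine$poller)
  if (!engine$config$echo) return(invisible(NULL))
  for (em in ems) {
    lines <- strsplit(em$text, "\n", fixed = TRUE)[[1]]
    for (ln in lines) {
      if (nzchar(ln)) cat(sprintf("[%s] %s\n", em$tag, ln))
    }
  }
  invisible(NULL)
}

credit_pool <- function(engine, rec) {
  ex <- engine$executor
  if (ex$kind == "local") {
    ex$used_cpus <- max(0L, ex$used_cpus - rec$cpus)
    ex$used_mem <- max(0, ex$used_mem - rec$mem)
  }
}

# Terminal transition and the retry+1 rule: a task is only FAILED after
# failing retry+1 times; earlier failures clean the declared outputs and
# re-enter the queue.
finish_task <- function(engine, rec, outcome) {
  rec$t_end <- as.numeric(Sys.time())
  credit_pool(engine, rec)
  if (outcome$kind == "exit" && identical(outcome$code, 0L)) {
    rec$exit_code <- 0L
    set_task_state(engine, rec, "DONE")
    return(invisible(NULL))
  }
  clean_outputs(rec)
  failure_desc <- if (outcome$kind == "timeout") {
    "timed out"
  } else {
    sprintf("exit code %s", outcome$code)
  }
  if (rec$attempts < rec$retry + 1L) {
    set_task_state(engine, rec, "SCHEDULED")
    rec$ready_at <- as.numeric(Sys.time()) +
      if (engine$executor$kind == "mock-cluster") engine$executor$queue_delay else 0
    engine$executor$queue <- c(engine$executor$queue, rec$id)
    return(invisible(NULL))
  }
  rec$exit_code <- if (outcome$kind == "exit") as.integer(outcome$code) else NA_integer_
  rec$failure <- sprintf("%s after %d attempt(s)", failure_desc, rec$attempts)
  set_task_state(engine, rec, if (outcome$kind == "timeout") "TIMEOUT" else "FAILED")
  invisible(NULL)
}

clean_outputs <- function(rec) {
  for (p in rec$outs) {
    if (file.exists(p)) unlink(p, recursive = TRUE)
  }
}

# Terminate everything: dequeue SCHEDULED tasks, signal every RUNNING task's
# process group (TERM, short wait, KILL), confirm no group member survives,
# and clean the outputs of non-DONE tasks.
kill_all_tasks <- function(engine) {
  ex <- engine$executor
  for (id in ex$queue) {
    rec <- engine$tasks[[id]]
    if (rec$state == "SCHEDULED") {
      rec$t_end <- as.numeric(Sys.time())
      set_task_state(engine, rec, "KILLED")
      clean_outputs(rec)
    }
  }
  ex$queue <- character(0)
  running <- list()
  for (id in engine$task_order) {
    rec <- engine$tasks[[id]]
    if (rec$state != "RUNNING") next
    if (rec$synthetic_fail) {
      rec$t_end <- as.numeric(Sys.time())
      set_task_state(engine, rec, "KILLED")
      next
    }
    pid <- wait_handle_pid(rec$handle)
    kill_group(pid, "TERM")
    running[[length(running) + 1L]] <- rec
  }
  if (length(running) > 0L) {
    deadline <- as.numeric(Sys.time()) + 1.0
    repeat {
      alive <- vapply(running, function(rec) {
        length(group_pids(run_handle_pid(rec$handle))) > 0L
      }, TRUE)
      if (!any(alive) || as.numeric(Sys.time()) > deadline) break
      Sys.sleep(0.05)
    }
    for (rec in running[alive]) kill_group(run_handle_pid(rec$handle), "KILL")
    for (rec in running) {
      t0 <- as.numeric(Sys.time())
      while (length(group_pids(run_handle_pid(rec$handle))) > 0L &&
             as.numeric(Sys.time()) - t0 < 2) {
        Sys.sleep(0.02)
      }
      credit_pool(engine, rec)
      rec$t_end <- as.numeric(Sys.time())
      set_task_state(engine, rec, "KILLED")
      clean_outputs(rec)
    }
  }
  invisible(NULL)
}

# Deterministic uniform draws for the mock cluster, isolated from the
# session RNG.
next_unif <- function(engine) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  if (is.null(engine$rng_state)) {
    set.seed(engine$config$seed %||% 0L)
  } else {
    assign(".Random.seed", engine$rng_state, envir = globalenv())
  }
  x <- stats::runif(1)
  engine$rng_state <- get(".Random.seed", envir = globalenv())
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
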