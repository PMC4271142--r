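# The execution engine: evaluates the typed tree, spawns tasks and par
# threads, enforces wait barriers, and cooperates with checkpointing through
# a run/recover traversal mode.
#
# Recovery mode: after loading a checkpoint the tree is traversed without
# executing statements, descending only into the nodes recorded on the saved
# statement stack (pre-order ids make branch membership a range check).
# When the recorded statement is reached the engine flips to run mode and
# either re-executes that statement ("at", used for failed waits) or
# continues after it ("after", used for explicit checkpoint statements).
#
# par blocks run synchronously on a snapshot of the enclosing scope: the
# engine itself is single-threaded, and task-level parallelism comes from
# tasks being asynchronous OS processes; a par failure is recorded in the
# par table and surfaces at the next (or the implicit final) wait.

#' Engine configuration
#'
#' @param executor `"local"` (CPU/memory pool, FIFO dispatch) or
#'   `"mock-cluster"` (accepts everything; optional latency/failures).
#' @param cpus Total CPUs in the local pool (default: machine cores).
#' @param mem Total memory budget in bytes (default unlimited). Memory is
#'   accounting only, not enforcement.
#' @param retry Default per-task retry count (a task fails only after
#'   `retry + 1` failed attempts).
#' @param run_dir Directory for per-task scripts/logs, the event log,
#'   checkpoints and reports; created if needed (default: a fresh temporary
#'   directory).
#' @param work_dir Working directory task commands and relative paths
#'   resolve against.
#' @param poll_interval Scheduler poll interval, seconds.
#' @param timeout_grace Seconds between TERM and KILL when a timeout fires.
#' @param queue_delay Mock-cluster queue latency, seconds.
#' @param fail_rate Mock-cluster induced failure probability per attempt.
#' @param seed Seed for the mock cluster's failure draws.
#' @param mtime_slack Modification-time slack for the out-of-date rule.
#' @param echo Relay task stdout/stderr to the console.
#' @param dry_run Print what would run instead of executing tasks.
#' @param include_path Directories searched by `include`.
#' @return A list of class `ps_config`.
#' @export
engine_config <- function(executor = c("local", "mock-cluster"),
                          cpus = parallel::detectCores(),
                          mem = Inf,
                          retry = 0L,
                          run_dir = NULL,
                          work_dir = getwd(),
                          poll_interval = 0.05,
                          timeout_grace = 5,
                          queue_delay = 0,
                          fail_rate = 0,
                          seed = NULL,
                          mtime_slack = 0,
                          echo = FALSE,
                          dry_run = FALSE,
                          include_path = character()) {
  executor <- match.arg(executor)
  structure(list(
    executor = executor, cpus = as.integer(cpus), mem = mem,
    retry = as.integer(retry), run_dir = run_dir, work_dir = work_dir,
    poll_interval = poll_interval, timeout_grace = timeout_grace,
    queue_delay = queue_delay, fail_rate = fail_rate, seed = seed,
    mtime_slack = mtime_slack, echo = echo, dry_run = dry_run,
    include_path = include_path
  ), class = "ps_config")
}

make_engine <- function(typed, config, overrides = list()) {
  engine <- new.env(parent = emptyenv())
  engine$typed <- typed
  engine$tree <- typed$tree
  engine$config <- config
  engine$overrides <- overrides
  engine$run_dir <- config$run_dir %||% tempfile("psrun-")
  dir.create(engine$run_dir, recursive = TRUE, showWarnings = FALSE)
  engine$work_dir <- normalizePath(config$work_dir)
  engine$tasks <- new.env(parent = emptyenv())
  engine$task_order <- character(0)
  engine$pars <- list()
  engine$graph <- dep_graph()
  engine$executor <- make_executor(config)
  engine$poller <- log_poller()
  engine$events <- list()
  engine$event_con <- file(file.path(engine$run_dir, "events.log"), open = "a")
  engine$counters <- new.env(parent = emptyenv())
  engine$counters$task <- 0L
  engine$counters$par <- 0L
  engine$gscope <- new_scope()
  for (nm in names(PS_CONSTANTS)) {
    scope_declare(engine$gscope, nm, typed_value(unname(PS_CONSTANTS[[nm]]), "int"))
  }
  engine$stack <- list()       # list of list(id, depth, scope)
  engine$call_depth <- 0L
  engine$thread <- "main"
  engine$mode <- "run"
  engine$rpath <- integer(0)
  engine$rpos <- 1L
  engine$rscopes <- list()
  engine$rscope_pos <- 1L
  engine$resume_mode <- NULL
  engine$loop_state <- list()
  engine$rng_state <- NULL
  engine$checkpoint_path <- NA_character_
  engine$failures <- character(0)
  engine
}

engine_close <- function(engine) {
  if (!is.null(engine$event_con)) {
    try(close(engine$event_con), silent = TRUE)
    engine$event_con <- NULL
  }
}

# -------------------------------------------------------------- entry points

#' Run a pipeline script
#'
#' Parses, typechecks and executes a script file. Execution does not return
#' until every spawned task and par thread is terminal (an implicit `wait`
#' closes the main thread). On task failure the engine waits for the
#' remaining tasks, writes a checkpoint, reports the failure reasons and
#' returns a nonzero status.
#'
#' @param script Path to the script file.
#' @param args Character vector of command-line style variable overrides,
#'   e.g. `c("-in", "another.file")`; names must match top-level globals.
#' @param config An [engine_config()].
#' @return An object of class `ps_run`: list with `status` (`code`,
#'   `reason`), `tasks` (data frame of task records), `events`, `run_dir`,
#'   `checkpoint` (path or `NA`) and `failures`.
#' @examples
#' \dontrun{
#' run <- run_script("pipeline.bds", config = engine_config(cpus = 4))
#' run$status
#' }
#' @export
run_script <- function(script, args = character(), config = engine_config()) {
  tree <- parse_script_file(script, include_path = config$include_path)
  typed <- check_program(tree)
  overrides <- convert_overrides(split_variable_args(args), typed)
  run_program(typed, overrides = overrides, config = config)
}

#' Execute a typechecked program
#'
#' @param typed A `ps_typed` from [check_program()].
#' @param overrides Named list of typed override values for top-level
#'   globals (see [parse_cli()]).
#' @param config An [engine_config()].
#' @return A `ps_run`; see [run_script()].
#' @export
run_program <- function(typed, overrides = list(), config = engine_config()) {
  engine <- make_engine(typed, config, overrides)
  on.exit(engine_close(engine))
  status <- execute_engine(engine)
  finish_run(engine, status)
}

execute_engine <- function(engine, resume_plan = NULL) {
  tryCatch(
    {
      withCallingHandlers(
        {
          if (!is.null(resume_plan)) apply_resume_plan(engine, resume_plan)
          if (!isTRUE(engine$skip_program)) {
            exec_stmt_list(engine, engine$tree$root$stmts, engine$gscope)
          }
          final_wait(engine)
          list(code = 0L, reason = "ok")
        },
        interrupt = function(c) {
          handle_interrupt(engine)
        }
      )
    },
    ps_abort = function(c) c$data$status,
    ps_error = function(c) {
      engine$failures <- c(engine$failures, conditionMessage(c))
      kill_all_tasks(engine)
      list(code = 1L, reason = "runtime-error", message = conditionMessage(c))
    }
  )
}

handle_interrupt <- function(engine) {
  kill_all_tasks(engine)
  path <- try(write_checkpoint(engine, reason = "interrupt",
                               resume_mode = "at"), silent = TRUE)
  engine$failures <- c(engine$failures, "interrupted")
  abort_engine(engine, code = 130L, reason = "interrupted")
}

abort_engine <- function(engine, code, reason) {
  stop(ps_condition("ps_abort", sprintf("execution stopped: %s", reason),
                    data = list(status = list(code = code, reason = reason))))
}

finish_run <- function(engine, status) {
  res <- structure(list(
    status = status,
    tasks = task_table_df(engine),
    events = events_df(engine),
    run_dir = engine$run_dir,
    checkpoint = engine$checkpoint_path,
    failures = engine$failures,
    pars = engine$pars
  ), class = "ps_run")
  write_report(res, engine$run_dir)
  res
}

#' @export
print.ps_run <- function(x, ...) {
  cat(sprintf("pipeline run: %s (%s)\n",
              if (x$status$code == 0L) "ok" else sprintf("failed [%d]", x$status$code),
              x$status$reason))
  if (nrow(x$tasks) > 0L) {
    tab <- table(x$tasks$state)
    cat(sprintf("tasks: %s\n",
                paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                      collapse = " ")))
  } else {
    cat("tasks: none\n")
  }
  if (length(x$failures) > 0L) {
    cat("failures:\n")
    for (f in x$failures) cat(sprintf("  - %s\n", f))
  }
  if (!is.na(x$checkpoint)) cat(sprintf("checkpoint: %s\n", x$checkpoint))
  cat(sprintf("run dir: %s\n", x$run_dir))
  invisible(x)
}

task_table_df <- function(engine) {
  ids <- engine$task_order
  df <- data.frame(
    id = character(0), name = character(0), state = character(0),
    cpus = integer(0), attempts = integer(0), exit_code = integer(0),
    t_sched = numeric(0), t_start = numeric(0), t_end = numeric(0),
    stdout = character(0), stderr = character(0),
    stringsAsFactors = FALSE
  )
  if (length(ids) == 0L) return(df)
  rows <- lapply(ids, function(id) {
    rec <- engine$tasks[[id]]
    data.frame(
      id = rec$id,
      name = rec$name %||% NA_character_,
      state = rec$state,
      cpus = rec$cpus,
      attempts = rec$attempts,
      exit_code = rec$exit_code,
      t_sched = rec$t_sched, t_start = rec$t_start, t_end = rec$t_end,
      stdout = if (!is.null(rec$handle)) rec$handle$stdout_path else NA_character_,
      stderr = if (!is.null(rec$handle)) rec$handle$stderr_path else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

events_df <- function(engine) {
  if (length(engine$events) == 0L) {
    return(data.frame(time = numeric(0), id = character(0),
                      from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    time = vapply(engine$events, `[[`, 0, "time"),
    id = vapply(engine$events, `[[`, "", "id"),
    from = vapply(engine$events, `[[`, "", "from"),
    to = vapply(engine$events, `[[`, "", "to"),
    stringsAsFactors = FALSE
  )
}

# ------------------------------------------------------- statement execution

node_type <- function(engine, node) engine$typed$types[[as.character(node$id)]]

exec_stmt_list <- function(engine, stmts, scope) {
  for (s in stmts) {
    if (engine$mode == "recover") {
      target <- engine$rpath[[engine$rpos]]
      if (s$id != target) next
      engine$rpos <- engine$rpos + 1L
      if (engine$rpos > length(engine$rpath)) {
        engine$mode <- "run"
        if (identical(engine$resume_mode, "after")) next
        # "at": fall through and re-execute this statement
      }
    }
    exec_stmt(engine, s, scope)
  }
  invisible(NULL)
}

exec_stmt <- function(engine, s, scope) {
  if (engine$thread == "main") {
    engine$stack[[length(engine$stack) + 1L]] <-
      list(id = s$id, depth = engine$call_depth, scope = scope)
    on.exit(engine$stack[[length(engine$stack)]] <- NULL)
  }
  switch(s$kind,
    decl = exec_decl(engine, s, scope),
    assign = scope_set(scope, s$name, coerce_assign(eval_expr(engine, s$value, scope),
                                                    scope_binding_type(scope, s$name)),
                       pos = s$pos),
    "if" = exec_if(engine, s, scope),
    "while" = exec_while(engine, s, scope),
    "for" = exec_for(engine, s, scope),
    forin = exec_forin(engine, s, scope),
    "break" = stop(ps_condition("ps_break", "break")),
    "continue" = stop(ps_condition("ps_continue", "continue")),
    "return" = {
      v <- if (is.null(s$value)) NULL else eval_expr(engine, s$value, scope)
      stop(ps_condition("ps_return", "return", data = list(value = v)))
    },
    funcdef = invisible(NULL),  # hoisted at typecheck
    print = {
      txt <- if (is.null(s$value)) "" else value_text(eval_expr(engine, s$value, scope))
      cat(txt, if (s$newline) "\n" else "", sep = "")
    },
    exit = {
      code <- if (is.null(s$value)) 0L
              else as.integer(strip_type(eval_expr(engine, s$value, scope)))
      final_wait(engine, allow_abort = code == 0L)
      abort_engine(engine, code = code,
                   reason = if (code == 0L) "ok" else "runtime-error")
    },
    sys = exec_sys(engine, s, scope),
    wait = exec_wait_stmt(engine, s, scope),
    checkpoint = exec_checkpoint(engine, s, scope),
    exprstmt = invisible(eval_expr(engine, s$expr, scope)),
    ps_stop("ps_runtime_error", sprintf("cannot execute %s", s$kind), pos = s$pos)
  )
  invisible(NULL)
}

scope_binding_type <- function(scope, name) {
  v <- get(name, envir = scope, inherits = TRUE)
  value_type(v)
}

coerce_assign <- function(v, target_type) {
  if (identical(value_type(v), "int") && identical(target_type, "real")) {
    return(typed_value(strip_type(v), "real"))
  }
  typed_value(strip_type(v), target_type %||% value_type(v))
}

exec_decl <- function(engine, s, scope) {
  # command-line overrides replace top-level initializers
  ov <- engine$overrides[[s$name]]
  if (!is.null(ov) && identical(scope, engine$gscope)) {
    scope_declare(scope, s$name, ov)
    return(invisible(NULL))
  }
  declared <- node_type_decl(engine, s, scope)
  v <- if (is.null(s$init)) default_value(declared)
       else coerce_assign(eval_expr(engine, s$init, scope), declared)
  scope_declare(scope, s$name, v)
}

node_type_decl <- function(engine, s, scope) {
  if (!isTRUE(s$infer)) return(s$type)
  node_type(engine, s$init) %||% "string"
}

exec_if <- function(engine, s, scope) {
  if (engine$mode == "recover") {
    target <- engine$rpath[[engine$rpos]]
    branch <- if (!is.null(s$then) && target >= s$then$id &&
                  target <= s$then$id_max) s$then else s$elseb
    bscope <- restore_scope(engine, scope)
    run_loop_block(engine, branch, bscope)
    return(invisible(NULL))
  }
  cond <- isTRUE(strip_type(eval_expr(engine, s$cond, scope)))
  branch <- if (cond) s$then else s$elseb
  if (!is.null(branch)) {
    exec_stmt_list(engine, branch$stmts, new_scope(scope))
  }
  invisible(NULL)
}

# run a block's statements, translating break/continue into flow signals
run_loop_block <- function(engine, block, bscope) {
  tryCatch(
    {
      exec_stmt_list(engine, block$stmts, bscope)
      "normal"
    },
    ps_break = function(c) "break",
    ps_continue = function(c) "continue"
  )
}

exec_while <- function(engine, s, scope) {
  if (engine$mode == "recover") {
    bscope <- restore_scope(engine, scope)
    flow <- run_loop_block(engine, s$body, bscope)
    if (flow == "break") return(invisible(NULL))
  }
  repeat {
    if (!isTRUE(strip_type(eval_expr(engine, s$cond, scope)))) break
    flow <- run_loop_block(engine, s$body, new_scope(scope))
    if (flow == "break") break
  }
  invisible(NULL)
}

exec_for <- function(engine, s, scope) {
  if (engine$mode == "recover") {
    fscope <- restore_scope(engine, scope)
    bscope <- restore_scope(engine, fscope)
    flow <- run_loop_block(engine, s$body, bscope)
    if (flow == "break") return(invisible(NULL))
    exec_stmt(engine, s$update, fscope)
  } else {
    fscope <- new_scope(scope)
    exec_stmt(engine, s$init, fscope)
  }
  repeat {
    if (!isTRUE(strip_type(eval_expr(engine, s$cond, fscope)))) break
    flow <- run_loop_block(engine, s$body, new_scope(fscope))
    if (flow == "break") break
    exec_stmt(engine, s$update, fscope)
  }
  invisible(NULL)
}

exec_forin <- function(engine, s, scope) {
  key <- as.character(s$id)
  if (engine$mode == "recover") {
    st <- engine$loop_state[[key]]
    vscope <- restore_scope(engine, scope)
    flow <- run_loop_block(engine, s$body, vscope)
    if (flow == "break") {
      engine$loop_state[[key]] <- NULL
      return(invisible(NULL))
    }
    i <- st$idx + 1L
    values <- st$values
  } else {
    seqv <- eval_expr(engine, s$seq, scope)
    values <- lapply(seqv, function(x) x)
    etype <- s$vartype %||% {
      t <- node_type(engine, s$seq)
      if (is_list_type(t)) elem_type(t) else "string"
    }
    values <- lapply(values, function(x) typed_value(strip_type(x), etype))
    i <- 1L
  }
  while (i <= length(values)) {
    engine$loop_state[[key]] <- list(idx = i, values = values)
    vscope <- new_scope(scope)
    scope_declare(vscope, s$var, values[[i]])
    flow <- run_loop_block(engine, s$body, vscope)
    if (flow == "break") break
    i <- i + 1L
  }
  engine$loop_state[[key]] <- NULL
  invisible(NULL)
}

# ------------------------------------------------------------- sys and tasks

exec_sys <- function(engine, s, scope) {
  line <- interpolate_segments(engine, s$segments, scope)
  if (engine$config$dry_run) {
    cat(sprintf("sys (dry run): %s\n", line))
    return(invisible(""))
  }
  out <- suppressWarnings(
    system2("/bin/sh", c("-c", shQuote(sprintf("cd '%s' && { %s\n}",
                                               engine$work_dir, line))),
            stdout = TRUE, stderr = "")
  )
  status <- attr(out, "status") %||% 0L
  text <- paste(out, collapse = "\n")
  if (nzchar(text)) cat(text, "\n", sep = "")
  if (!identical(as.integer(status), 0L)) {
    engine$failures <- c(engine$failures,
                         sprintf("sys command failed (exit %d): %s", status, line))
    kill_all_tasks(engine)
    write_checkpoint(engine, reason = "runtime-error", resume_mode = "at")
    abort_engine(engine, code = 1L, reason = "task-failed")
  }
  invisible(text)
}

interpolate_segments <- function(engine, segments, scope) {
  paste(vapply(segments, function(sg) {
    if (sg$kind == "text") sg$text
    else value_text(eval_expr(engine, sg$expr, scope))
  }, ""), collapse = "")
}

resolve_path <- function(engine, p) {
  if (startsWith(p, "/")) p else file.path(engine$work_dir, p)
}

eval_task_expr <- function(engine, e, scope) {
  opt <- function(nm, default) {
    if (is.null(e$options[[nm]])) return(default)
    v <- strip_type(eval_expr(engine, e$options[[nm]], scope))
    if (nm == "taskName") return(as.character(v))
    v <- as.numeric(v)
    if (v < 0) {
      ps_stop("ps_runtime_error",
              sprintf("task option '%s' must be non-negative", nm), pos = e$pos)
    }
    v
  }
  cpus <- opt("cpus", 1)
  if (cpus < 1) {
    ps_stop("ps_runtime_error", "task option 'cpus' must be >= 1", pos = e$pos)
  }
  outs <- character(0)
  ins <- character(0)
  if (!is.null(e$depclause)) {
    outs <- vapply(value_as_paths(eval_expr(engine, e$depclause$outs, scope)),
                   function(p) resolve_path(engine, p), "")
    ins <- vapply(value_as_paths(eval_expr(engine, e$depclause$ins, scope)),
                  function(p) resolve_path(engine, p), "")
  }
  command <- vapply(e$lines, function(l) interpolate_segments(engine, l, scope), "")

  engine$counters$task <- engine$counters$task + 1L
  id <- sprintf("task.%d", engine$counters$task)

  if (e$task_kind == "dep") {
    dep_register(engine$graph, id, outs = outs, ins = ins, kind = "dep",
                 spec = list(command = command, cpus = cpus,
                             mem = opt("mem", 0), timeout = opt("timeout", 0),
                             retry = opt("retry", engine$config$retry),
                             name = opt("taskName", NULL), owner = engine$thread))
    log_event(engine, id, "CREATED", "DEFERRED")
    return(typed_value(id, "string"))
  }

  rec <- new_task_record(
    id = id, command = command, ins = ins, outs = outs, cpus = cpus,
    mem = opt("mem", 0), timeout = opt("timeout", 0),
    retry = opt("retry", engine$config$retry),
    name = opt("taskName", NULL), owner = engine$thread, kind = "task"
  )
  register_task(engine, rec)
  if (length(outs) > 0L) {
    tryCatch(dep_register(engine$graph, id, outs = outs, ins = ins,
                          kind = "task"),
             ps_duplicate_producer_error = function(c) engine_fatal(engine, c))
  }
  if (!is.null(e$depclause) &&
      !needs_update(outs, ins, slack = engine$config$mtime_slack)) {
    set_task_state(engine, rec, "SKIPPED")
    return(typed_value(id, "string"))
  }
  if (engine$config$dry_run) {
    cat(sprintf("task (dry run) %s: %s\n", id, paste(rec$command, collapse = " && ")))
    set_task_state(engine, rec, "SKIPPED")
    return(typed_value(id, "string"))
  }
  # implicit DAG: wait for live producers of our inputs
  rec$after <- live_producers(engine, ins)
  tryCatch(submit_task(engine, rec),
           ps_resource_error = function(c) engine_fatal(engine, c))
  typed_value(id, "string")
}

live_producers <- function(engine, ins) {
  ids <- character(0)
  for (p in ins) {
    prod <- dg_producer_of(engine$graph, p)
    if (is.null(prod)) next
    rec <- engine$tasks[[prod]]
    if (!is.null(rec) && !rec$state %in% PS_TERMINAL_STATES) ids <- c(ids, prod)
  }
  unique(ids)
}

register_task <- function(engine, rec) {
  engine$tasks[[rec$id]] <- rec
  engine$task_order <- c(engine$task_order, rec$id)
  log_event(engine, rec$id, "NONE", "CREATED")
}

engine_fatal <- function(engine, cond) {
  engine$failures <- c(engine$failures, conditionMessage(cond))
  kill_all_tasks(engine)
  try(write_checkpoint(engine, reason = "runtime-error", resume_mode = "at"),
      silent = TRUE)
  abort_engine(engine, code = 1L,
               reason = if (inherits(cond, "ps_resource_error")) "resource-error"
                        else "runtime-error")
}

eval_goal <- function(engine, e, scope) {
  targets <- vapply(value_as_paths(eval_expr(engine, e$targets, scope)),
                    function(p) resolve_path(engine, p), "")
  plan <- tryCatch(
    resolve_goal(engine$graph, targets,
                 stamp_fn = function(p) file_stamp(p)),
    ps_unproducible_target_error = function(c) engine_fatal(engine, c)
  )
  ids <- character(0)
  for (nid in plan) {
    node <- engine$graph$nodes[[nid]]
    if (node$kind == "task") next  # ordinary tasks already managed
    existing <- engine$tasks[[nid]]
    if (!is.null(existing)) next   # planned by an earlier goal
    spec <- node$spec
    if (engine$config$dry_run) {
      cat(sprintf("goal (dry run) %s: %s\n", nid,
                  paste(spec$command, collapse = " && ")))
      next
    }
    rec <- new_task_record(
      id = nid, command = spec$command, ins = node$ins, outs = node$outs,
      cpus = spec$cpus, mem = spec$mem, timeout = spec$timeout,
      retry = spec$retry, name = spec$name, owner = engine$thread, kind = "dep"
    )
    rec$after <- intersect(unlist(lapply(node$ins, function(p) {
      dg_producer_of(engine$graph, p)
    })), plan)
    register_task(engine, rec)
    node$state <- "planned"
    engine$graph$nodes[[nid]] <- node
    tryCatch(submit_task(engine, rec),
             ps_resource_error = function(c) engine_fatal(engine, c))
    ids <- c(ids, nid)
  }
  typed_value(lapply(ids, function(x) typed_value(x, "string")), "string[]")
}

# ------------------------------------------------------------------- waiting

unit_terminal <- function(engine, id) {
  rec <- engine$tasks[[id]]
  if (!is.null(rec)) return(rec$state %in% PS_TERMINAL_STATES)
  if (id %in% names(engine$pars)) return(TRUE)  # par runs synchronously
  if (!is.null(engine$graph$nodes[[id]])) return(TRUE)  # unplanned dep
  ps_stop("ps_unknown_id_error", sprintf("unknown task or par id '%s'", id))
}

unit_failed <- function(engine, id) {
  rec <- engine$tasks[[id]]
  if (!is.null(rec)) {
    return(rec$state %in% c("FAILED", "KILLED", "TIMEOUT"))
  }
  p <- engine$pars[[id]]
  !is.null(p) && identical(p$state, "failed")
}

wait_for_units <- function(engine, ids) {
  repeat {
    scheduler_poll(engine)
    done <- vapply(ids, function(id) unit_terminal(engine, id), TRUE)
    if (all(done)) break
    Sys.sleep(engine$config$poll_interval)
  }
  !any(vapply(ids, function(id) unit_failed(engine, id), TRUE))
}

thread_unit_ids <- function(engine, thread = NULL, all_threads = FALSE) {
  ids <- character(0)
  for (id in engine$task_order) {
    rec <- engine$tasks[[id]]
    if (all_threads || identical(rec$owner, thread)) ids <- c(ids, id)
  }
  c(ids, names(engine$pars))
}

exec_wait_stmt <- function(engine, s, scope) {
  ids <- if (is.null(s$ids)) {
    thread_unit_ids(engine, thread = engine$thread)
  } else {
    value_as_paths(eval_expr(engine, s$ids, scope))
  }
  ok <- wait_for_units(engine, ids)
  if (!ok) {
    record_failures(engine, ids)
    write_checkpoint(engine, reason = "wait-failure", resume_mode = "at")
    abort_engine(engine, code = 1L, reason = "task-failed")
  }
  invisible(TRUE)
}

final_wait <- function(engine, allow_abort = TRUE) {
  ids <- thread_unit_ids(engine, all_threads = TRUE)
  if (length(ids) == 0L) return(invisible(TRUE))
  ok <- wait_for_units(engine, ids)
  if (!ok && allow_abort) {
    record_failures(engine, ids)
    write_checkpoint(engine, reason = "wait-failure", resume_mode = "end")
    abort_engine(engine, code = 1L, reason = "task-failed")
  }
  invisible(ok)
}

record_failures <- function(engine, ids) {
  for (id in ids) {
    if (!unit_failed(engine, id)) next
    rec <- engine$tasks[[id]]
    if (!is.null(rec)) {
      engine$failures <- c(
        engine$failures,
        sprintf("task %s%s %s: %s (stderr: %s)",
                rec$id,
                if (!is.null(rec$name)) sprintf(" (%s)", rec$name) else "",
                tolower(rec$state),
                rec$failure %||% "failed",
                if (!is.null(rec$handle)) rec$handle$stderr_path else "<none>")
      )
    } else {
      p <- engine$pars[[id]]
      engine$failures <- c(engine$failures,
                           sprintf("par %s failed: %s", id,
                                   p$message %||% "error"))
    }
  }
}

# ----------------------------------------------------------------- par / fun

eval_par <- function(engine, e, scope) {
  engine$counters$par <- engine$counters$par + 1L
  id <- sprintf("par.%d", engine$counters$par)
  snapshot <- snapshot_scope(scope)
  prev_thread <- engine$thread
  engine$thread <- id
  log_event(engine, id, "NONE", "RUNNING")
  res <- tryCatch(
    {
      if (e$par_kind == "block") {
        exec_stmt_list(engine, e$body$stmts, new_scope(snapshot))
      } else {
        eval_expr(engine, e$call, snapshot)
      }
      list(state = "done", message = NULL)
    },
    ps_abort = function(c) stop(c),  # engine-level aborts pass through
    ps_error = function(c) list(state = "failed", message = conditionMessage(c)),
    error = function(c) list(state = "failed", message = conditionMessage(c))
  )
  engine$thread <- prev_thread
  engine$pars[[id]] <- res
  log_event(engine, id, "RUNNING", if (res$state == "done") "DONE" else "FAILED")
  typed_value(id, "string")
}

# flatten the visible chain into one frozen scope
snapshot_scope <- function(scope) {
  snap <- new_scope()
  seen <- character(0)
  e <- scope
  while (!identical(e, emptyenv())) {
    for (nm in ls(e)) {
      if (!nm %in% seen) {
        assign(nm, get(nm, envir = e), envir = snap)
        seen <- c(seen, nm)
      }
    }
    e <- parent.env(e)
  }
  snap
}

call_function <- function(engine, e, scope) {
  sig <- engine$typed$funcs[[e$name]]
  args <- lapply(e$args, function(a) eval_expr(engine, a, scope))
  fscope <- new_scope(engine$gscope)
  for (i in seq_along(sig$param_names)) {
    scope_declare(fscope, sig$param_names[[i]],
                  coerce_assign(args[[i]], sig$param_types[[i]]))
  }
  fnode <- engine$tree$index[[sig$node_id]]
  engine$call_depth <- engine$call_depth + 1L
  on.exit(engine$call_depth <- engine$call_depth - 1L)
  res <- tryCatch(
    {
      exec_stmt_list(engine, fnode$body$stmts, fscope)
      NULL
    },
    ps_return = function(c) c$data$value
  )
  if (is.null(res) && sig$rettype != "void") {
    res <- default_value(sig$rettype)
  }
  if (!is.null(res) && sig$rettype != "void") {
    res <- coerce_assign(res, sig$rettype)
  }
  res
}

# ------------------------------------------------------------------ builtins

call_builtin <- function(engine, e, scope) {
  v <- eval_expr(engine, e$args[[1]], scope)
  t <- value_type(v)
  switch(e$name,
    toInt = {
      x <- strip_type(v)
      n <- switch(t,
        int = x, real = trunc(x), bool = as.numeric(x),
        string = {
          y <- suppressWarnings(as.numeric(x))
          if (is.na(y)) {
            ps_stop("ps_runtime_error",
                    sprintf("toInt: cannot convert \"%s\"", x), pos = e$pos)
          }
          trunc(y)
        })
      typed_value(n, "int")
    },
    toReal = {
      x <- strip_type(v)
      n <- switch(t,
        int = , real = as.numeric(x), bool = as.numeric(x),
        string = {
          y <- suppressWarnings(as.numeric(x))
          if (is.na(y)) {
            ps_stop("ps_runtime_error",
                    sprintf("toReal: cannot convert \"%s\"", x), pos = e$pos)
          }
          y
        })
      typed_value(n, "real")
    },
    toStr = typed_value(value_text(v), "string"),
    len = typed_value(length(v), "int"),
    ps_stop("ps_runtime_error", sprintf("unknown builtin %s", e$name), pos = e$pos)
  )
}

# ---------------------------------------------------------------- expression

eval_expr <- function(engine, e, scope) {
  switch(e$kind,
    literal = typed_value(e$value, e$type),
    ident = scope_get(scope, e$name, pos = e$pos),
    binary = eval_binary(engine, e, scope),
    unary = {
      v <- eval_expr(engine, e$operand, scope)
      if (e$op == "!") typed_value(!isTRUE(strip_type(v)), "bool")
      else typed_value(-strip_type(v), value_type(v))
    },
    depop = {
      outs <- vapply(value_as_paths(eval_expr(engine, e$outs, scope)),
                     function(p) resolve_path(engine, p), "")
      ins <- vapply(value_as_paths(eval_expr(engine, e$ins, scope)),
                    function(p) resolve_path(engine, p), "")
      typed_value(needs_update(outs, ins, slack = engine$config$mtime_slack),
                  "bool")
    },
    call = {
      if (e$name %in% names(PS_BUILTINS)) call_builtin(engine, e, scope)
      else call_function(engine, e, scope)
    },
    index = {
      obj <- eval_expr(engine, e$obj, scope)
      i <- as.integer(strip_type(eval_expr(engine, e$idx, scope)))
      if (i < 0L || i >= length(obj)) {
        ps_stop("ps_runtime_error",
                sprintf("list index %d out of range [0, %d)", i, length(obj)),
                pos = e$pos)
      }
      obj[[i + 1L]]
    },
    listlit = {
      t <- node_type(engine, e) %||% "string[]"
      et <- elem_type(t)
      items <- lapply(e$items, function(it) {
        coerce_assign(eval_expr(engine, it, scope), et)
      })
      typed_value(items, t)
    },
    task = eval_task_expr(engine, e, scope),
    par = eval_par(engine, e, scope),
    goal = eval_goal(engine, e, scope),
    ps_stop("ps_runtime_error", sprintf("cannot evaluate %s", e$kind),
            pos = e$pos)
  )
}

eval_binary <- function(engine, e, scope) {
  op <- e$op
  # short-circuit logic
  if (op == "&&") {
    l <- strip_type(eval_expr(engine, e$lhs, scope))
    if (!isTRUE(l)) return(typed_value(FALSE, "bool"))
    return(typed_value(isTRUE(strip_type(eval_expr(engine, e$rhs, scope))), "bool"))
  }
  if (op == "||") {
    l <- strip_type(eval_expr(engine, e$lhs, scope))
    if (isTRUE(l)) return(typed_value(TRUE, "bool"))
    return(typed_value(isTRUE(strip_type(eval_expr(engine, e$rhs, scope))), "bool"))
  }
  lv <- eval_expr(engine, e$lhs, scope)
  rv <- eval_expr(engine, e$rhs, scope)
  lt <- value_type(lv)
  rt <- value_type(rv)
  rtype <- node_type(engine, e) %||% binop_type(op, lt, rt)

  if (op %in% c("+", "-", "*", "/", "%")) {
    if (identical(rtype, "string")) {
      return(typed_value(paste0(value_text(lv), value_text(rv)), "string"))
    }
    if (is_list_type(lt)) {
      items <- if (identical(lt, rt)) c(lv, rv)
               else c(lv, list(coerce_assign(rv, elem_type(lt))))
      return(typed_value(lapply(items, function(x) x), lt))
    }
    a <- strip_type(lv)
    b <- strip_type(rv)
    val <- switch(op,
      "+" = a + b,
      "-" = a - b,
      "*" = a * b,
      "/" = {
        if (b == 0) ps_stop("ps_runtime_error", "division by zero", pos = e$pos)
        if (identical(rtype, "int")) trunc(a / b) else a / b
      },
      "%" = {
        if (b == 0) ps_stop("ps_runtime_error", "modulo by zero", pos = e$pos)
        a - trunc(a / b) * b
      })
    return(typed_value(val, rtype))
  }
  if (op %in% c("==", "!=", "<", "<=", ">", ">=")) {
    a <- strip_type(lv)
    b <- strip_type(rv)
    val <- switch(op,
      "==" = isTRUE(all.equal(a, b)) || identical(a, b),
      "!=" = !(isTRUE(all.equal(a, b)) || identical(a, b)),
      "<" = a < b, "<=" = a <= b, ">" = a > b, ">=" = a >= b)
    return(typed_value(isTRUE(val), "bool"))
  }
  ps_stop("ps_runtime_error", sprintf("unknown operator %s", op), pos = e$pos)
}

# -------------------------------------------------------------- checkpoints

exec_checkpoint <- function(engine, s, scope) {
  if (engine$thread != "main") {
    ps_stop("ps_runtime_error",
            "checkpoint statements are not supported inside par threads",
            pos = s$pos)
  }
  path <- if (!is.null(s$name)) {
    p <- as.character(strip_type(eval_expr(engine, s$name, scope)))
    resolve_path(engine, p)
  } else NULL
  write_checkpoint(engine, reason = "explicit-statement", resume_mode = "after",
                   path = path)
}

restore_scope <- function(engine, parent) {
  if (engine$rscope_pos <= length(engine$rscopes)) {
    bindings <- engine$rscopes[[engine$rscope_pos]]
    engine$rscope_pos <- engine$rscope_pos + 1L
    scope <- new_scope(parent)
    install_bindings(scope, bindings)
    scope
  } else {
    new_scope(parent)
  }
}
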