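# Absolute serialization: persist the full interpreter state — embedded
# source, statement stack (program counters), scope bindings with types,
# loop iteration state, the task table, the dependency graph and the par
# table — into a self-contained checkpoint file. Resuming reconstructs the
# engine, traverses the tree in recovery mode to the recorded statement, and
# re-submits every task that had not completed; completed tasks are never
# re-run.
#
# The format is a versioned canonical JSON container: object keys are
# written sorted and numbers in a fixed round-trip format, so loading a
# checkpoint and saving it again is byte-identical, and files are portable
# across machines (nothing references the original script file).

PS_CHECKPOINT_VERSION <- 1L

encode_value <- function(v) {
  type <- value_type(v)
  if (is_list_type(type)) {
    list(type = type,
         value = lapply(v, function(x) strip_value_scalar(x)))
  } else {
    list(type = type, value = strip_value_scalar(v))
  }
}

strip_value_scalar <- function(v) {
  x <- strip_type(v)
  x
}

decode_value <- function(enc) {
  type <- enc$type
  if (is_list_type(type)) {
    et <- elem_type(type)
    typed_value(lapply(enc$value, function(x) typed_value(decode_scalar(x, et), et)),
                type)
  } else {
    typed_value(decode_scalar(enc$value, type), type)
  }
}

decode_scalar <- function(x, type) {
  switch(type,
    int = , real = as.numeric(x),
    bool = isTRUE(x),
    string = as.character(x),
    x
  )
}

encode_scope <- function(scope) {
  nms <- sort(ls(scope))
  lapply(nms, function(nm) {
    c(list(name = nm), encode_value(get(nm, envir = scope)))
  })
}

install_bindings <- function(scope, bindings) {
  for (b in bindings) {
    assign(b$name, decode_value(b), envir = scope)
  }
  scope
}

encode_task <- function(rec) {
  list(
    id = rec$id,
    name = rec$name,
    kind = rec$kind,
    command = as.list(rec$command),
    ins = as.list(rec$ins),
    outs = as.list(rec$outs),
    cpus = rec$cpus,
    mem = rec$mem,
    timeout = rec$timeout,
    retry = rec$retry,
    after = as.list(rec$after),
    owner = rec$owner,
    state = rec$state,
    attempts = rec$attempts,
    exit_code = rec$exit_code,
    failure = rec$failure,
    t_sched = rec$t_sched,
    t_start = rec$t_start,
    t_end = rec$t_end
  )
}

encode_graph <- function(graph) {
  ids <- names(graph$nodes)
  if (length(ids) == 0L) return(list())
  lapply(ids[order(ids, method = "radix")], function(id) {
    n <- graph$nodes[[id]]
    list(id = n$id, kind = n$kind, ins = as.list(n$ins),
         outs = as.list(n$outs), state = n$state,
         spec = if (is.null(n$spec)) NULL else list(
           command = as.list(n$spec$command), cpus = n$spec$cpus,
           mem = n$spec$mem, timeout = n$spec$timeout, retry = n$spec$retry,
           name = n$spec$name, owner = n$spec$owner
         ))
  })
}

# Serialize the engine state. Only the main-thread statement stack at call
# depth zero is recorded: a checkpoint inside a function call resumes AT the
# enclosing top-level statement (documented design choice).
write_checkpoint <- function(engine, reason, resume_mode, path = NULL) {
  stack <- engine$stack
  depths <- vapply(stack, `[[`, 0L, "depth")
  top_level <- which(depths == 0L)
  truncated <- length(stack) > 0L && length(top_level) < length(stack)
  if (truncated && identical(resume_mode, "after")) resume_mode <- "at"
  path_ids <- vapply(stack[top_level], function(fr) as.integer(fr$id), 0L)

  if (length(top_level) > 0L) {
    inner_scope <- stack[[top_level[length(top_level)]]]$scope
  } else {
    inner_scope <- engine$gscope
  }
  chain <- list()
  e <- inner_scope
  while (!identical(e, emptyenv())) {
    chain <- c(chain, list(e))
    e <- parent.env(e)
  }
  chain <- rev(chain)  # global first

  loop_state <- lapply(sort(names(engine$loop_state)), function(k) {
    st <- engine$loop_state[[k]]
    list(node = as.integer(k), idx = st$idx,
         values = lapply(st$values, encode_value))
  })

  chp <- list(
    format_version = PS_CHECKPOINT_VERSION,
    reason = reason,
    resume_mode = resume_mode,
    script = engine$tree$origin,
    main_source = engine$tree$main_source,
    includes = lapply(sort(names(engine$tree$includes)), function(nm) {
      list(name = nm, text = engine$tree$includes[[nm]])
    }),
    source_hash = engine$tree$source_hash,
    stack = as.list(path_ids),
    scopes = lapply(chain, encode_scope),
    loop_state = loop_state,
    tasks = lapply(engine$task_order, function(id) encode_task(engine$tasks[[id]])),
    graph = encode_graph(engine$graph),
    pars = lapply(sort(names(engine$pars)), function(id) {
      p <- engine$pars[[id]]
      list(id = id, state = p$state, message = p$message)
    }),
    counters = list(task = engine$counters$task, par = engine$counters$par),
    work_dir = engine$work_dir,
    run_dir = engine$run_dir,
    failures = as.list(engine$failures)
  )

  if (is.null(path)) {
    path <- file.path(engine$run_dir,
                      sprintf("%s.%s.chp", basename(engine$tree$origin), reason))
  }
  save_checkpoint_data(chp, path)
  engine$checkpoint_path <- path
  invisible(path)
}

save_checkpoint_data <- function(chp, path) {
  tmp <- paste0(path, ".part")
  ok <- tryCatch({
    writeLines(json_encode(chp), tmp, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.rename(tmp, path)) {
    unlink(tmp)
    ps_stop("ps_io_error", sprintf("cannot write checkpoint to %s", path))
  }
  invisible(path)
}

load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    ps_stop("ps_io_error", sprintf("checkpoint not found: %s", path))
  }
  chp <- tryCatch(json_read_file(path), error = function(e) {
    ps_stop("ps_io_error", sprintf("corrupt checkpoint %s: %s", path,
                                   conditionMessage(e)))
  })
  if (is.null(chp$format_version) ||
      chp$format_version != PS_CHECKPOINT_VERSION) {
    ps_stop("ps_version_mismatch_error",
            sprintf("checkpoint format version %s is not supported",
                    chp$format_version %||% "<missing>"))
  }
  chp
}

#' Resume execution from a checkpoint file
#'
#' Reconstructs the interpreter state (program, scopes, program counters,
#' task table) from the checkpoint and continues execution from the exact
#' point where it stopped. Tasks recorded as DONE or SKIPPED are not re-run;
#' tasks that were failed, queued or running when the checkpoint was taken
#' are re-submitted. The embedded source is used, so the original script
#' file is not required; passing `script` re-validates against the current
#' file and raises `ps_stale_source_error` if the source changed.
#'
#' @param path Checkpoint file path.
#' @param config An [engine_config()]; `run_dir`/`work_dir` default to the
#'   values recorded in the checkpoint.
#' @param script Optional script path to validate against the embedded
#'   source.
#' @return A `ps_run`; see [run_script()].
#' @export
resume_checkpoint <- function(path, config = engine_config(), script = NULL) {
  chp <- load_checkpoint(path)
  if (!is.null(script)) {
    current <- read_text_file(script)
    if (!identical(current, chp$main_source)) {
      ps_stop("ps_stale_source_error",
              sprintf("checkpoint %s is no longer valid with respect to the new source code in %s",
                      path, script))
    }
  }
  includes <- list()
  for (inc in chp$includes) includes[[inc$name]] <- inc$text
  tree <- parse_script(chp$main_source, origin = chp$script,
                       sources = includes)
  if (!identical(tree$source_hash, chp$source_hash)) {
    ps_stop("ps_stale_source_error",
            "embedded source does not reproduce the checkpointed program")
  }
  typed <- check_program(tree)
  if (is.null(config$run_dir)) config$run_dir <- chp$run_dir
  config$work_dir <- chp$work_dir
  engine <- make_engine(typed, config)
  on.exit(engine_close(engine))
  status <- execute_engine(engine, resume_plan = chp)
  finish_run(engine, status)
}

apply_resume_plan <- function(engine, chp) {
  engine$counters$task <- as.integer(chp$counters$task)
  engine$counters$par <- as.integer(chp$counters$par)
  engine$failures <- character(0)

  # global scope
  scopes <- chp$scopes
  if (length(scopes) >= 1L) install_bindings(engine$gscope, scopes[[1]])
  engine$rscopes <- if (length(scopes) > 1L) scopes[-1] else list()
  engine$rscope_pos <- 1L

  # loop iteration state
  for (ls_ in chp$loop_state) {
    engine$loop_state[[as.character(ls_$node)]] <- list(
      idx = as.integer(ls_$idx),
      values = lapply(ls_$values, decode_value)
    )
  }

  # dependency graph (producers must exist before tasks re-register)
  for (gn in chp$graph) {
    spec <- NULL
    if (!is.null(gn$spec)) {
      spec <- list(command = as.character(unlist(gn$spec$command)),
                   cpus = gn$spec$cpus, mem = gn$spec$mem,
                   timeout = gn$spec$timeout, retry = gn$spec$retry,
                   name = gn$spec$name, owner = gn$spec$owner)
    }
    dep_register(engine$graph, gn$id,
                 outs = as.character(unlist(gn$outs)),
                 ins = as.character(unlist(gn$ins)),
                 kind = gn$kind, spec = spec)
    node <- engine$graph$nodes[[gn$id]]
    node$state <- gn$state
    engine$graph$nodes[[gn$id]] <- node
  }

  # par table (par threads completed synchronously before the checkpoint)
  for (pp in chp$pars) {
    engine$pars[[pp$id]] <- list(state = pp$state, message = pp$message)
  }

  # task table: keep completed tasks, re-submit everything else
  pending <- list()
  for (tk in chp$tasks) {
    rec <- new_task_record(
      id = tk$id, command = as.character(unlist(tk$command)),
      ins = as.character(unlist(tk$ins)), outs = as.character(unlist(tk$outs)),
      cpus = tk$cpus, mem = tk$mem, timeout = tk$timeout, retry = tk$retry,
      name = tk$name, after = as.character(unlist(tk$after)),
      owner = tk$owner, kind = tk$kind
    )
    engine$tasks[[rec$id]] <- rec
    engine$task_order <- c(engine$task_order, rec$id)
    if (tk$state %in% c("DONE", "SKIPPED")) {
      rec$state <- tk$state
      rec$attempts <- as.integer(tk$attempts)
      rec$exit_code <- if (is.null(tk$exit_code)) NA_integer_
                       else as.integer(tk$exit_code)
      rec$t_sched <- tk$t_sched %||% NA_real_
      rec$t_start <- tk$t_start %||% NA_real_
      rec$t_end <- tk$t_end %||% NA_real_
      log_event(engine, rec$id, "RESTORED", rec$state)
    } else {
      log_event(engine, rec$id, "RESTORED", "CREATED")
      pending[[length(pending) + 1L]] <- rec
    }
  }
  for (rec in pending) submit_task(engine, rec)

  # program counters
  rpath <- as.integer(unlist(chp$stack))
  engine$resume_mode <- chp$resume_mode
  if (length(rpath) == 0L || identical(chp$resume_mode, "end")) {
    engine$skip_program <- TRUE
    engine$mode <- "run"
  } else {
    engine$rpath <- rpath
    engine$rpos <- 1L
    engine$mode <- "recover"
  }
  invisible(engine)
}

#' Inspect a checkpoint file
#'
#' Prints the variables of every serialized scope (name, type, value), the
#' recorded statement stack with source positions, and the task table with
#' states and failure reasons. Never modifies the file.
#'
#' @param path Checkpoint file path.
#' @return Invisibly, the decoded checkpoint structure.
#' @export
inspect_checkpoint <- function(path) {
  chp <- load_checkpoint(path)
  cat(sprintf("checkpoint: %s\n", path))
  cat(sprintf("  script: %s\n", chp$script))
  cat(sprintf("  reason: %s (resume %s)\n", chp$reason, chp$resume_mode))
  cat(sprintf("  source hash: %s\n", chp$source_hash))

  includes <- list()
  for (inc in chp$includes) includes[[inc$name]] <- inc$text
  tree <- tryCatch(parse_script(chp$main_source, origin = chp$script,
                                sources = includes),
                   error = function(e) NULL)
  cat("  stack:\n")
  stack <- as.integer(unlist(chp$stack))
  if (length(stack) == 0L) {
    cat("    <at end of program>\n")
  } else {
    for (id in stack) {
      node <- if (!is.null(tree)) tree$index[[id]] else NULL
      if (!is.null(node)) {
        cat(sprintf("    node %d: %s at %s\n", id, node$kind, fmt_pos(node$pos)))
      } else {
        cat(sprintf("    node %d\n", id))
      }
    }
  }
  cat("  scopes:\n")
  for (i in seq_along(chp$scopes)) {
    cat(sprintf("    scope %d%s:\n", i, if (i == 1L) " (global)" else ""))
    for (b in chp$scopes[[i]]) {
      v <- decode_value(b)
      cat(sprintf("      %s: %s = %s\n", b$name, b$type, value_text(v)))
    }
  }
  cat("  tasks:\n")
  if (length(chp$tasks) == 0L) cat("    <none>\n")
  for (tk in chp$tasks) {
    cat(sprintf("    %s [%s] attempts=%d%s%s\n", tk$id, tk$state,
                as.integer(tk$attempts),
                if (!is.null(tk$failure)) paste0(" failure: ", tk$failure) else "",
                if (!is.null(tk$name)) sprintf(" name=%s", tk$name) else ""))
  }
  if (length(chp$failures) > 0L) {
    cat("  recorded failure reasons:\n")
    for (f in chp$failures) cat(sprintf("    - %s\n", f))
  }
  invisible(chp)
}
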