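# Per-task process supervision.
#
# Each task becomes a shell script plus a tiny shell supervisor launched as
# the leader of a fresh session (setsid), so the supervisor's PID doubles as
# the process-group id covering every descendant the task spawns. The
# supervisor records its PID, redirects the task's stdout/stderr to two log
# files and writes the numeric exit status atomically to an exit-status
# file. The engine's poll loop reads exit files, enforces timeouts by
# signalling the whole group (TERM, grace period, then KILL) and writes the
# distinguished sentinel `timeout` into the exit file, so downstream code
# can tell a timeout from an ordinary failure. Per-task artifacts in the run
# directory are `<id>.sh`, `<id>.stdout`, `<id>.stderr`, `<id>.exitCode`
# (and `<id>.pid`).

PS_TIMEOUT_SENTINEL <- "timeout"

supervisor_source <- function() {
  paste(
    "#!/bin/sh",
    "# pipescript task supervisor: session leader; args:",
    "#   1 task script  2 stdout  3 stderr  4 exit-status file  5 pid file",
    "echo $$ > \"$5\"",
    "/bin/sh \"$1\" > \"$2\" 2> \"$3\"",
    "ec=$?",
    "printf '%s\\n' \"$ec\" > \"$4.part\"",
    "mv \"$4.part\" \"$4\"",
    sep = "\n"
  )
}

ensure_supervisor <- function(run_dir) {
  path <- file.path(run_dir, "supervise.sh")
  if (!file.exists(path)) {
    writeLines(supervisor_source(), path)
    Sys.chmod(path, "0755")
  }
  path
}

#' Write the shell script for a task
#'
#' Produces an executable script with a strict-mode prologue (`set -eu`,
#' `cd` into the working directory) followed by the task's command lines in
#' declared order. Content is deterministic for identical specs.
#'
#' @param id Task id (names the script `<id>.sh`).
#' @param command Character vector of shell command lines.
#' @param dir Directory for the script (the run directory).
#' @param work_dir Working directory the commands run in.
#' @return The script path.
#' @export
write_task_script <- function(id, command, dir, work_dir = getwd()) {
  path <- file.path(dir, paste0(id, ".sh"))
  lines <- c("#!/bin/sh",
             sprintf("# task %s", id),
             "set -eu",
             sprintf("cd '%s'", work_dir),
             command)
  tryCatch(writeLines(lines, path),
           error = function(e) ps_stop("ps_io_error", conditionMessage(e)))
  Sys.chmod(path, "0755")
  path
}

#' Launch a task script under supervision
#'
#' Spawns the supervisor as the leader of a new session/process group with
#' stdout/stderr redirected to the log files, and returns immediately. The
#' supervisor's PID (= the group id) is written to `<id>.pid` and read
#' lazily by [run_handle_pid()].
#'
#' @param id Task id.
#' @param script_path Path of the task script (see [write_task_script()]).
#' @param run_dir Run directory receiving the per-task artifacts.
#' @param timeout Seconds before the whole group is killed (0 = none).
#' @return A run handle: list with the artifact paths and the deadline.
#' @export
launch_task <- function(id, script_path, run_dir, timeout = 0) {
  if (!file.exists(script_path)) {
    ps_stop("ps_spawn_error", sprintf("task script not found: %s", script_path))
  }
  sup <- ensure_supervisor(run_dir)
  h <- list(
    id = id,
    script_path = script_path,
    stdout_path = file.path(run_dir, paste0(id, ".stdout")),
    stderr_path = file.path(run_dir, paste0(id, ".stderr")),
    exit_path = file.path(run_dir, paste0(id, ".exitCode")),
    pid_path = file.path(run_dir, paste0(id, ".pid")),
    launched_at = as.numeric(Sys.time()),
    deadline = if (timeout > 0) as.numeric(Sys.time()) + timeout else NA_real_,
    pid = NA_integer_
  )
  # stale artifacts from a previous attempt must not be mistaken for results
  unlink(c(h$exit_path, h$pid_path))
  rc <- system2("setsid", c("/bin/sh", shQuote(sup), shQuote(script_path),
                            shQuote(h$stdout_path), shQuote(h$stderr_path),
                            shQuote(h$exit_path), shQuote(h$pid_path)),
                wait = FALSE, stdout = FALSE, stderr = FALSE)
  if (!identical(rc, 0L)) {
    ps_stop("ps_spawn_error", sprintf("could not spawn supervisor for %s", id))
  }
  h
}

#' @rdname launch_task
#' @param handle A run handle.
#' @return `run_handle_pid`: the supervisor PID (process-group id), or NA if
#'   not yet available.
#' @export
run_handle_pid <- function(handle) {
  if (!is.na(handle$pid)) return(handle$pid)
  if (file.exists(handle$pid_path)) {
    pid <- suppressWarnings(as.integer(readLines(handle$pid_path, n = 1L,
                                                 warn = FALSE)[1]))
    if (!is.na(pid)) return(pid)
  }
  NA_integer_
}

# the supervisor writes its pid as its first action; wait briefly for it
# when a kill races a fresh launch
wait_handle_pid <- function(handle, timeout = 2) {
  t0 <- as.numeric(Sys.time())
  repeat {
    pid <- run_handle_pid(handle)
    if (!is.na(pid)) return(pid)
    if (as.numeric(Sys.time()) - t0 > timeout) return(NA_integer_)
    Sys.sleep(0.01)
  }
}

pid_alive <- function(pid) {
  !is.na(pid) && file.exists(file.path("/proc", pid))
}

group_pids <- function(pgid) {
  if (is.na(pgid)) return(integer(0))
  out <- suppressWarnings(system2("pgrep", c("-g", as.character(pgid)),
                                  stdout = TRUE, stderr = FALSE))
  as.integer(out[nzchar(out)])
}

kill_group <- function(pgid, signal = "TERM") {
  if (is.na(pgid)) return(invisible(FALSE))
  suppressWarnings(system2("kill", c("-s", signal, "--", paste0("-", pgid)),
                           stdout = FALSE, stderr = FALSE))
  invisible(TRUE)
}

read_exit_status <- function(exit_path) {
  if (!file.exists(exit_path)) return(NULL)
  line <- tryCatch(readLines(exit_path, n = 1L, warn = FALSE)[1],
                   error = function(e) NA_character_)
  if (is.na(line)) return(NULL)
  if (identical(line, PS_TIMEOUT_SENTINEL)) return(PS_TIMEOUT_SENTINEL)
  code <- suppressWarnings(as.integer(line))
  if (is.na(code)) NULL else code
}

#' Supervise a launched task to completion (blocking)
#'
#' Waits for the task to terminate, polling the exit-status file. On
#' deadline breach the entire process group receives TERM, then (after the
#' grace period) KILL, and the exit file is overwritten with the `timeout`
#' sentinel. Used directly by tests and by the synchronous paths of the
#' engine; the scheduler performs the same steps incrementally.
#'
#' @param handle A run handle from [launch_task()].
#' @param grace Seconds between TERM and KILL on timeout.
#' @param poll Poll interval in seconds.
#' @return A list `outcome` with `kind` (`"exit"`, `"timeout"`) and `code`
#'   (the exit status for `"exit"`).
#' @export
supervise_task <- function(handle, grace = 5, poll = 0.05) {
  killing_since <- NA_real_
  repeat {
    st <- read_exit_status(handle$exit_path)
    now <- as.numeric(Sys.time())
    if (!is.null(st)) {
      pid <- run_handle_pid(handle)
      if (!is.na(killing_since)) {
        wait_group_dead(pid, grace)
        write_timeout_sentinel(handle$exit_path)
        return(list(kind = "timeout", code = NA_integer_))
      }
      return(list(kind = "exit", code = st))
    }
    if (!is.na(killing_since)) {
      pid <- run_handle_pid(handle)
      if (now - killing_since > grace) kill_group(pid, "KILL")
      if (!pid_alive(pid)) {
        write_timeout_sentinel(handle$exit_path)
        return(list(kind = "timeout", code = NA_integer_))
      }
    } else if (!is.na(handle$deadline) && now > handle$deadline) {
      kill_group(run_handle_pid(handle), "TERM")
      killing_since <- now
    }
    Sys.sleep(poll)
  }
}

wait_group_dead <- function(pgid, grace) {
  t0 <- as.numeric(Sys.time())
  while (length(group_pids(pgid)) > 0L) {
    if (as.numeric(Sys.time()) - t0 > grace) {
      kill_group(pgid, "KILL")
    }
    Sys.sleep(0.02)
  }
}

write_timeout_sentinel <- function(exit_path) {
  tmp <- paste0(exit_path, ".part")
  writeLines(PS_TIMEOUT_SENTINEL, tmp)
  file.rename(tmp, exit_path)
}

# ------------------------------------------------------------- log polling

#' Multiplex many task log files without exhausting file descriptors
#'
#' A log poller tracks a byte offset per registered file. Each
#' [poller_tick()] stats every file and opens *only* those whose size
#' changed, reading the appended region; files are opened one at a time and
#' closed immediately, so the number of simultaneously open log files never
#' exceeds one regardless of how many are registered. `opens_last_tick`
#' records how many files were opened on the most recent tick.
#'
#' @return `log_poller()`: an object of class `ps_log_poller`.
#' @export
log_poller <- function() {
  p <- new.env(parent = emptyenv())
  p$offsets <- numeric(0)   # named by path
  p$tags <- character(0)    # named by path
  p$opens_last_tick <- 0L
  p$opens_total <- 0L
  structure(p, class = "ps_log_poller")
}

#' @rdname log_poller
#' @param poller A `ps_log_poller`.
#' @param path Log file path to watch (need not exist yet).
#' @param tag Label attached to emitted chunks (typically the task id).
#' @export
poller_register <- function(poller, path, tag) {
  poller$offsets[path] <- 0
  poller$tags[path] <- tag
  invisible(poller)
}

#' @rdname log_poller
#' @return `poller_tick()`: a list of emissions, each a list with `tag`,
#'   `path` and `text` (the newly appended bytes, as a string).
#' @export
poller_tick <- function(poller) {
  emissions <- list()
  opened <- 0L
  paths <- names(poller$offsets)
  if (length(paths) == 0L) {
    poller$opens_last_tick <- 0L
    return(emissions)
  }
  sizes <- suppressWarnings(file.size(paths))
  for (i in seq_along(paths)) {
    sz <- sizes[[i]]
    off <- poller$offsets[[i]]
    if (is.na(sz) || sz <= off) next
    path <- paths[[i]]
    con <- file(path, open = "rb")
    opened <- opened + 1L
    if (off > 0) seek(con, where = off, origin = "start")
    chunk <- readBin(con, what = "raw", n = sz - off)
    close(con)
    poller$offsets[[i]] <- off + length(chunk)
    emissions[[length(emissions) + 1L]] <- list(
      tag = unname(poller$tags[[i]]), path = path,
      text = rawToChar(chunk)
    )
  }
  poller$opens_last_tick <- opened
  poller$opens_total <- poller$opens_total + opened
  emissions
}
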