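# Execution report and event-log utilities.
#
# Every task lifecycle transition is appended to <run_dir>/events.log
# (timestamp, id, old state, new state). After a run — successful or not —
# the engine writes a machine-readable report.json and a self-contained
# report.html with a task execution timeline.

#' Read an engine event log
#'
#' @param path Path to an `events.log` file, or a `ps_run` object.
#' @return A data frame with columns `time`, `id`, `from`, `to`.
#' @export
read_event_log <- function(path) {
  if (inherits(path, "ps_run")) return(path$events)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(time = numeric(0), id = character(0),
                      from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    time = as.numeric(vapply(parts, `[[`, "", 1L)),
    id = vapply(parts, `[[`, "", 2L),
    from = vapply(parts, `[[`, "", 3L),
    to = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

#' Peak number of tasks simultaneously in a state
#'
#' Replays the event log and returns the maximum number of tasks that were
#' in `state` at the same time — e.g. the peak `RUNNING` concurrency, which
#' on an n-CPU pool of uniform c-CPU tasks should be `min(floor(n/c),
#' n_tasks)`.
#'
#' @param events Event data frame (see [read_event_log()]) or a `ps_run`.
#' @param state Task state to count (default `"RUNNING"`).
#' @param ids Optional ids to restrict to. By default par-thread entries are
#'   excluded, so the result counts task processes.
#' @return Integer maximum.
#' @export
peak_concurrency <- function(events, state = "RUNNING", ids = NULL) {
  if (inherits(events, "ps_run")) events <- events$events
  if (is.null(ids)) {
    events <- events[!startsWith(events$id, "par."), , drop = FALSE]
  } else {
    events <- events[events$id %in% ids, , drop = FALSE]
  }
  if (nrow(events) == 0L) return(0L)
  delta <- integer(nrow(events))
  delta[events$to == state] <- 1L
  delta[events$from == state] <- delta[events$from == state] - 1L
  if (all(delta == 0L)) return(0L)
  max(cumsum(delta))
}

#' Write the execution report
#'
#' Emits `report.json` (one record per task ever created: state, resources,
#' attempts, timestamps, exit code, log paths) and `report.html` (a
#' self-contained timeline page). Written even for failed runs.
#'
#' @param run A `ps_run` object.
#' @param dir Output directory (defaults to the run directory).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(run, dir = run$run_dir) {
  paths <- c(json = file.path(dir, "report.json"),
             html = file.path(dir, "report.html"))
  ok <- tryCatch({
    jsonlite::write_json(report_data(run), paths[["json"]],
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
    writeLines(report_html(run), paths[["html"]])
    TRUE
  }, error = function(e) {
    warning(sprintf("could not write report: %s", conditionMessage(e)),
            call. = FALSE)
    FALSE
  })
  invisible(if (ok) paths else character(0))
}

report_data <- function(run) {
  tasks <- run$tasks
  list(
    status = run$status,
    n_tasks = nrow(tasks),
    wall_start = if (nrow(tasks) > 0L) suppressWarnings(min(tasks$t_sched, na.rm = TRUE)) else NULL,
    wall_end = if (nrow(tasks) > 0L) suppressWarnings(max(tasks$t_end, na.rm = TRUE)) else NULL,
    failures = as.list(run$failures),
    checkpoint = if (is.na(run$checkpoint)) NULL else run$checkpoint,
    tasks = lapply(seq_len(nrow(tasks)), function(i) as.list(tasks[i, ]))
  )
}

report_html <- function(run) {
  tasks <- run$tasks
  rows <- character(0)
  bars <- character(0)
  if (nrow(tasks) > 0L) {
    t0 <- suppressWarnings(min(tasks$t_start, na.rm = TRUE))
    t1 <- suppressWarnings(max(tasks$t_end, na.rm = TRUE))
    span <- max(t1 - t0, 1e-6)
    for (i in seq_len(nrow(tasks))) {
      tk <- tasks[i, ]
      rows <- c(rows, sprintf(
        "<tr><td>%s</td><td>%s</td><td class='st-%s'>%s</td><td>%d</td><td>%d</td><td>%s</td></tr>",
        tk$id, if (is.na(tk$name)) "" else tk$name, tk$state, tk$state,
        tk$cpus, tk$attempts,
        if (is.na(tk$exit_code)) "" else as.character(tk$exit_code)))
      if (!is.na(tk$t_start) && !is.na(tk$t_end)) {
        left <- 100 * (tk$t_start - t0) / span
        width <- max(0.5, 100 * (tk$t_end - tk$t_start) / span)
        bars <- c(bars, sprintf(
          "<div class='lane'><span class='lbl'>%s</span><div class='bar st-%s' style='margin-left:%.2f%%;width:%.2f%%'></div></div>",
          tk$id, tk$state, left, width))
      }
    }
  }
  c("<!DOCTYPE html><html><head><meta charset='utf-8'><title>pipeline report</title>",
    "<style>",
    "body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td,th{border:1px solid #ccc;padding:2px 8px;font-size:13px}",
    ".lane{height:14px;margin:1px 0;position:relative}",
    ".lane .lbl{position:absolute;left:0;font-size:10px;color:#666}",
    ".bar{height:12px;margin-left:90px;background:#4a90d9;position:relative;left:90px}",
    ".bar.st-DONE{background:#3a9d4a}.bar.st-FAILED,.bar.st-TIMEOUT,.bar.st-KILLED{background:#c0392b}",
    "td.st-DONE{color:#3a9d4a}td.st-FAILED,td.st-TIMEOUT,td.st-KILLED{color:#c0392b}",
    "</style></head><body>",
    sprintf("<h1>pipeline run: %s</h1>",
            if (run$status$code == 0L) "ok" else "failed"),
    sprintf("<p>status: %s (exit %d); %d task(s); run dir <code>%s</code></p>",
            run$status$reason, run$status$code, nrow(tasks), run$run_dir),
    if (length(run$failures) > 0L) {
      c("<h2>Failures</h2><ul>",
        sprintf("<li>%s</li>", run$failures), "</ul>")
    } else character(0),
    "<h2>Task timeline</h2>", bars,
    "<h2>Tasks</h2>",
    "<table><tr><th>id</th><th>name</th><th>state</th><th>cpus</th><th>attempts</th><th>exit</th></tr>",
    rows,
    "</table></body></html>")
}
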