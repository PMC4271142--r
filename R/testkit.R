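# Fixture generator: synthetic pipelines, file trees with controlled
# mtimes, and fake commands (sleepers, flaky failers), so the whole engine
# is testable without external data. All commands are plain POSIX shell
# one-liners.

#' Generate a fan-out/fan-in pipeline script
#'
#' Emits a two-step pipeline: `n_tasks` parallel tasks, each declaring
#' `cpus_per_task` CPUs, sleeping `task_duration` seconds and producing
#' `out_<i>.txt` from `in_<i>.txt`; then a `wait` barrier; then one fan-in
#' task consuming all the outputs (`mainOut <- outs`). The defaults (100
#' tasks, 2 CPUs each) reproduce the canonical scheduling arithmetic: 32
#' concurrent instances on a 64-CPU pool, one at a time on a dual-core, 100
#' scheduled at once on a cluster, and outright failure on a single-core
#' machine.
#'
#' @param n_tasks Number of fan-out tasks.
#' @param cpus_per_task CPUs each fan-out task declares.
#' @param task_duration Sleep duration (seconds) of each fan-out task.
#' @param task_name `taskName` given to the fan-out tasks.
#' @param main_name `taskName` given to the fan-in task.
#' @return The script text (a single string).
#' @examples
#' cat(gen_fanout_pipeline(n_tasks = 2, cpus_per_task = 1, task_duration = 0))
#' @export
gen_fanout_pipeline <- function(n_tasks = 100L, cpus_per_task = 2L,
                                task_duration = 1,
                                task_name = "myProcess",
                                main_name = "myProcessAll") {
  stopifnot(n_tasks >= 1L)
  dur <- format(task_duration, scientific = FALSE, trim = TRUE)
  paste(c(
    sprintf("int n = %d", n_tasks),
    sprintf("int cpusPerTask = %d", cpus_per_task),
    "string[] outs",
    "for( int i = 0 ; i < n ; i = i + 1 ) {",
    "  in := \"in_\" + i + \".txt\"",
    "  out := \"out_\" + i + \".txt\"",
    "  outs = outs + out",
    sprintf("  task( out <- in, cpus := cpusPerTask, taskName := \"%s\" ) {",
            task_name),
    sprintf("    sleep %s", dur),
    "    cat $in > $out",
    "  }",
    "}",
    "wait",
    "mainOut := \"main.out\"",
    sprintf("task( mainOut <- outs, taskName := \"%s\" ) {", main_name),
    "  cat $outs > $mainOut",
    "}"
  ), collapse = "\n")
}

#' @rdname gen_fanout_pipeline
#' @param dir Directory to create `in_<i>.txt` input files in.
#' @param n Number of input files.
#' @return `gen_fanout_inputs`: invisibly, the created paths.
#' @export
gen_fanout_inputs <- function(dir, n) {
  paths <- file.path(dir, sprintf("in_%d.txt", seq_len(n) - 1L))
  for (i in seq_along(paths)) writeLines(sprintf("input %d", i - 1L), paths[[i]])
  invisible(paths)
}

#' A shell command that fails its first `fail_times` invocations
#'
#' Returns a one-line POSIX shell command that increments a counter file and
#' exits nonzero while the counter is at most `fail_times`, and exits zero
#' afterwards. Reading the counter afterwards gives the number of attempts,
#' which tests use to verify the retry+1 rule and resume semantics.
#'
#' @param fail_times Number of initial failing invocations.
#' @param counter_path Path of the counter file (created on first call).
#' @return A single shell command line. Shell `$` references are emitted as
#'   `\$` so the line can be pasted verbatim into a task body without being
#'   captured by script-variable interpolation.
#' @export
flaky_command <- function(fail_times, counter_path) {
  stopifnot(fail_times >= 0)
  sprintf(
    "n=$(cat '%s' 2>/dev/null || echo 0); n=$((n+1)); echo \\$n > '%s'; [ \\$n -gt %d ]",
    counter_path, counter_path, as.integer(fail_times)
  )
}

#' Materialize a file tree with exact sizes and modification times
#'
#' Creates files and directories (including zero-length files and empty
#' directories) with controlled relative modification times, for exercising
#' the out-of-date rule. Each spec entry is keyed by a relative path and
#' gives `size` (bytes; 0 creates an empty file; `NA` or a trailing `/` in
#' the path creates a directory) and `mtime_offset` (seconds relative to
#' `base_time`).
#'
#' @param spec Named list: `path = list(size =, mtime_offset =)`.
#' @param base Directory to create the tree under.
#' @param base_time Numeric epoch the offsets are relative to (default: one
#'   hour ago, so positive offsets stay in the past).
#' @return Invisibly, the created paths.
#' @examples
#' tree <- make_file_tree(list(
#'   "in.txt" = list(size = 5, mtime_offset = 0),
#'   "out.txt" = list(size = 5, mtime_offset = -10)  # older than its input
#' ), base = tempfile())
#' @export
make_file_tree <- function(spec, base, base_time = as.numeric(Sys.time()) - 3600) {
  dir.create(base, recursive = TRUE, showWarnings = FALSE)
  created <- character(0)
  for (rel in names(spec)) {
    entry <- spec[[rel]]
    path <- file.path(base, sub("/+$", "", rel))
    is_dir <- endsWith(rel, "/") || is.null(entry$size) || is.na(entry$size)
    if (is_dir) {
      dir.create(path, recursive = TRUE, showWarnings = FALSE)
    } else {
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      size <- as.integer(entry$size)
      if (size == 0L) {
        file.create(path)
      } else {
        writeBin(charToRaw(strrep("x", size)), path)
      }
    }
    off <- entry$mtime_offset %||% 0
    Sys.setFileTime(path, as.POSIXct(base_time + off, origin = "1970-01-01"))
    created <- c(created, path)
  }
  invisible(created)
}
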