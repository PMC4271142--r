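---
title: "The pipescript execution model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pipescript execution model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pipescript is a small, strongly typed imperative scripting language for
data-processing pipelines, together with the engine that executes it. A
pipeline script declares shell *tasks* with input/output files and resource
requests; the engine decides what actually needs to run (make-style
laziness), where and when it runs (a resource-budgeted executor), how it is
supervised (POSIX process groups, per-task logs and exit-status files), and
how a stopped run continues (checkpoint files holding the complete
interpreter state). This vignette explains each of those mechanisms, the
parameters that tune them, and the design decisions taken where more than
one behavior was defensible.

## The language

The language covers the constructs ordinary pipelines use and nothing more:
`bool`, `int`, `real`, `string` and homogeneous lists `T[]`; `if`/`else`,
`while`, C-style `for`, `for`-in-list, `break`/`continue`/`return`;
top-level functions with typed parameters; `print`/`println`, `exit`,
`include`; and the pipeline statements `sys`, `task`, `dep`, `goal`,
`wait`, `par` and `checkpoint`. There are no objects, maps or generics.

Typing is static: every expression receives a type before anything
executes, so a unit mismatch in a resource option or a typo in an
interpolated variable is reported immediately rather than hours into a run.
`x := e` infers the declared type from the initializer. The only implicit
conversion is the widening `int -> real`; the cast builtins `toInt`,
`toReal` and `toStr` cover the rest. Integer division truncates toward
zero (`7 / 2 == 3`) — the language does not define a full numeric tower,
and truncation matches what shell arithmetic and most compiled languages
do. The duration constants `second`, `minute`, `hour`, `day` are predefined
`int`s on the seconds scale so that `timeout := 6*hour` reads naturally.

Task bodies and `sys` lines are verbatim shell text; `$name` and `${expr}`
interpolate script values (lists interpolate space-separated), `\$` escapes
a literal dollar. The dependency operator `<-` always lexes as one token
and binds loosest in expressions, so `out <- in` is usable both in task
headers and as a bare boolean; the price is that `a < -1` must be written
`a < (0 - 1)`. A task body closed on the same line uses the *last* `}` on
that line; multi-line bodies end at a line containing only `}` — a literal
lone-`}` line inside a command must therefore be avoided.

## Tasks, barriers and the dependency DAG

`task( outs <- ins, cpus := c, mem := m, timeout := t, retry := r )`
evaluates its dependency clause at declaration time: if the outputs are
current, the task is recorded as `SKIPPED` and no process is spawned.
Otherwise the fully interpolated command is submitted asynchronously and
the statement returns a task id. A file's producer is remembered; a second
task declaring the same output is an error, and a later task consuming a
not-yet-finished task's output is automatically ordered after it (the
inferred DAG). `wait` blocks until the named ids — or, with no ids, all
units spawned by the current thread — are terminal; an implicit global
`wait` closes the main thread, so a program never exits with live tasks.
If any joined task failed, the engine still waits for the others, then
writes a checkpoint, reports every failure reason (exit code, attempt
count, stderr path) and stops with a nonzero status.

An output file is *out of date* when it does not exist, has zero length, is
an empty directory, or is older than the newest input. A missing input
triggers a warning and re-execution, since an upstream step may regenerate
it — treating it as an error instead would make partially cleaned work
directories unrunnable. Directories are first-class dependencies: a
directory's effective modification time is the maximum over itself and its
depth-1 entries. Timestamp comparison is strict `<` with a configurable
slack (`mtime_slack`, default 0 s) for coarse filesystems.

## Deferred tasks and goals

`dep` declares a task whose condition is *not* evaluated immediately;
`goal targets` then resolves the minimal set of deferred tasks needed to
bring the target files up to date and submits it in topological order,
returning the ids. Planning is static per `goal` invocation (timestamps are
not re-read between plan steps).

Two rules define minimality. First, a missing intermediate is bridged: a
target is compared against the nearest *existing* upstream files, so
deleting an intermediate does not force work while the final targets remain
current. Second, staleness is content-recursive: an existing intermediate
that is older than its own (bridged) inputs poisons everything downstream,
because its *content* is outdated even where local timestamps happen to be
monotone; and a plan that regenerates a file invalidates every existing
intermediate between it and another plan node, whose producers therefore
join the plan. The test suite checks the resulting plans against a
brute-force oracle that enumerates all subsets of nodes on small instances
and simulates their execution; the closure rule above was added precisely
because the oracle exposed a case (regenerated upstream, fresh-looking
existing intermediate) where naive nearest-existing planning under-builds.

## Scheduling and executors

Two executors share one submit/poll/kill contract.

The **local** executor owns a CPU/memory pool (defaults: all machine cores,
unlimited memory). Dispatch is strict FIFO with head-of-line blocking — no
backfilling — which makes runs deterministic and reproduces the canonical
arithmetic: 100 two-CPU tasks on a 64-CPU pool run 32 at a time; on a
dual-core machine they serialize; on a single core the first submission
fails outright ("lack of resources") because the request exceeds the pool
total, not merely the free share. Real cluster schedulers backfill; the
deterministic choice is deliberate and documented as a divergence. Memory
is accounting only (requests are debited against the budget and submissions
exceeding the total are rejected) — no ulimit/cgroup enforcement.

The **mock-cluster** executor accepts every submission immediately,
modelling a queue whose management system decides placement. It supports a
queue latency (`queue_delay`) and a seeded induced-failure rate
(`fail_rate`): with probability `fail_rate` an attempt is marked failed
without ever producing a successful exit status, which is how hardware node
failures look from the submit host. Induced failures are synthetic (no
process is spawned for the doomed attempt), keeping the robustness scenario
deterministic under a fixed seed and cheap to run. Combined with retries,
a pipeline on a mock cluster with 10% induced failures completes with zero
human intervention.

A failing task is retried until it has failed `retry + 1` times; every
failure (including the final one) deletes the task's declared outputs so a
rerun can never consume a half-written file. Timeouts count as failures for
retry purposes.

## Process supervision

Each task attempt becomes a shell script (`<id>.sh`: `set -eu`, `cd` to the
working directory, then the command lines) launched under a small shell
supervisor that `setsid` makes the leader of a fresh session. The
supervisor's PID is therefore the process-group id covering every
descendant the task spawns; it is recorded in `<id>.pid`, stdout/stderr are
redirected to `<id>.stdout` / `<id>.stderr`, and the numeric exit status is
written atomically (write-then-rename) to `<id>.exitCode`. Exit-status
files make completion detection uniform across executors and double as a
log.

Timeout enforcement lives in the engine's poll loop rather than in the
supervisor: past the deadline the whole group receives `TERM`, then after a
grace period (`timeout_grace`, default 5 s) `KILL`, and the exit file is
overwritten with the sentinel token `timeout` — a distinguished value
rather than a fake exit code, so downstream code can always tell the two
apart. On interrupt (Ctrl-C) every scheduled task is dequeued and every
running task's group is signalled the same way; a process-tree scan in the
tests verifies that no descendant survives, grandchildren included.

Console logging polls file sizes and opens only the log files that grew
since the last tick, one at a time — with thousands of tasks, holding every
log open would exhaust file-descriptor limits. The poll interval is 50 ms
by default (`poll_interval`).

## Checkpoints and resume

A checkpoint is the complete interpreter state: the embedded program source
(including every `include`d file, so the original files are not needed),
the main thread's statement stack as node ids, every scope's bindings with
their types, loop iteration state, the task table, the dependency graph,
the par table and the id counters. Node ids are assigned densely in
pre-order by the parser and are deterministic for identical source, which
is what makes the recorded program counters portable across machines.

Checkpoints are written at the explicit `checkpoint` statement, at a wait
that observed failures, on `sys` failure and other fatal engine errors (a
uniform failure path), and on interrupt. Serialization happens only at
statement boundaries; a crash in mid-statement loses that statement's
partial work, which is the accepted limitation of the approach.

Resume re-parses the embedded source, restores scopes and the task table,
re-submits every task that was not `DONE`/`SKIPPED` (running processes
cannot be serialized, so `RUNNING` is treated as to-be-re-executed), and
traverses the tree in *recovery mode*: no statement executes; the traversal
descends only into the recorded node-id path — branch membership is a
subtree range check thanks to pre-order ids — while scope-creating
constructs along the path re-install their serialized bindings instead of
fresh scopes. At the recorded statement the engine flips to run mode and
either re-executes it (failed waits: the wait re-blocks on the resubmitted
tasks) or continues after it (explicit checkpoints). Completed tasks are
trusted from the recorded state and never re-run; the alternative —
re-validating their outputs' timestamps on resume — was rejected as it
would conflate resume with a fresh lazy rerun, which the user can always
request instead.

Two deliberate restrictions keep the program-counter model simple in a
single-threaded interpreter. A checkpoint taken while inside a function
call records the enclosing top-level statement and resumes *at* it,
re-executing the whole call; the lazy dependency checks make the re-run
cheap. And `par` blocks execute synchronously at spawn on a snapshot of the
enclosing scope (writes inside do not propagate out): task-level
parallelism — the observable kind — comes from tasks being asynchronous OS
processes, while interpreter-level green threads would have made
checkpoints and data races substantially harder for no measurable benefit
in shell-bound pipelines. A `checkpoint` statement inside a `par` thread is
a runtime error. `wait` accepts ids created in other threads (ids are
global).

The file format is canonical JSON — versioned, sorted keys, fixed
shortest-round-trip number encoding — so loading and re-saving a checkpoint
is byte-identical, files diff cleanly in tests, and nothing in them is
machine-specific. It is a format of this package, not compatible with any
other engine's checkpoint files. `inspect_checkpoint()` prints scopes,
stack and task table without modifying the file.

## Command line and reports

`run_script()` (and the `inst/cli/pipescript` wrapper) accepts engine flags
with a double dash (`--cpus 64`, `--executor mock-cluster`, `--dry-run`,
`--check-only`) and script-variable overrides with a single dash: for a
script `pipeline.bds` declaring `in := "input.file"`, running
`pipeline.bds -in another.file` replaces the value of `in`, converted to
the variable's declared type; list variables consume successive values.
Overrides target top-level declarations made before the first action
statement — later declarations may depend on side effects, so rebinding
them from the command line would be ill-defined. Booleans take an explicit
`true`/`false` value to avoid swallowing a following variable name.

Every lifecycle transition is appended to `events.log` (timestamp, id, old
state, new state); after any run — success or failure — the engine writes
`report.json` (one record per task: state, resources, attempts,
timestamps, exit code, log paths) and a self-contained `report.html`
timeline. Exit codes: 0 ok, 1 task failure (checkpoint written), 2
parse/type error, 3 usage error, 130 interrupted.

## The fixture generator

`gen_fanout_pipeline()` emits the canonical two-step shape: n fan-out tasks
(each `cpus := c`, sleeping a fixed duration, producing `out_i.txt` from
`in_i.txt`), a `wait`, and one fan-in task consuming all outputs. Its
defaults — 100 tasks, 2 CPUs each, a 1 s sleeper — are the study
conditions for the scheduling arithmetic above. `flaky_command()` returns
a POSIX one-liner that fails its first k invocations while counting
attempts in a file, exercising retry and resume; `make_file_tree()`
materializes files and directories with exact sizes and relative
modification times for the out-of-date clauses. All fixture commands are
plain POSIX shell, so generated pipelines run anywhere the engine does.

What the fixtures emulate is the *coordination* load of a pipeline —
dependency shapes, failure patterns, resource contention — not the
computational load: the sleepers stand in for hours-long genomics jobs.
Passing tests therefore demonstrate correct task management, laziness,
recovery and supervision; they say nothing about I/O throughput, scheduler
fairness under heterogeneous requests, or real cluster transports
(GridEngine/Torque/ssh farms are out of scope; the mock cluster models
only queue admission, latency and failure).

Problem sizes used in the test suite were chosen to keep the full run
around a minute while preserving each claim's structure: the 64-CPU
concurrency check runs the full 100-task, 1 s-sleeper fixture (peak = 32
is duration-independent but needs enough overlap to be unambiguous); the
dual-core serialization check keeps the 100-task, 2-CPU shape with a 50 ms
sleeper, since peak concurrency = 1 does not depend on the sleep length;
goal-minimality is brute-forced on DAGs of at most six nodes, the largest
size where subset enumeration stays trivial.

## Known limitations

* One engine process: par threads interleave at statement granularity, so
  a long-blocking `wait` inside one par thread delays the others (their
  tasks, being OS processes, continue regardless).
* Timestamp-only laziness: content hashing is out of scope, so touching a
  file without changing it re-runs its consumers.
* Checkpoints taken inside function bodies resume at the enclosing
  top-level statement (see above); mid-task crashes lose the running
  attempt.
* POSIX only: process groups, `setsid`, `/proc` and `pgrep` are assumed.
* `include` targets are keyed by their literal include string inside
  checkpoints; two different files included under the same relative name
  from different directories would collide on resume.
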