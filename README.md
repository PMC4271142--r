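# pipescript

A strongly typed scripting language for data-processing pipelines, with its
execution engine, implemented as an R package.

Bioinformatics pipelines chain CPU- and I/O-heavy external tools that run
for hours; writing that glue in a general-purpose language means hand-coding
process synchronization, cluster-specific submission, retry logic and
restart bookkeeping, and the result rarely moves between a laptop and a
cluster without surgery. pipescript addresses this at the language level:
scripts declare *tasks* — shell command blocks with input/output files and
resource requests — and the engine supplies everything around them:

* **Lazy (make-style) processing.** `task( out <- in ) { ... }` runs only
  when `out` does not exist, has zero length, is an empty directory, or is
  older than `in`. Re-running a finished pipeline does no work.
* **Deferred goals.** `dep` declares tasks without evaluating them; `goal
  final.txt` executes the minimal subgraph needed to bring the target up to
  date — judged against the nearest *existing* upstream files, so deleted
  intermediates don't force recomputation while the target is current.
* **Resource-aware scheduling.** A task declares `cpus`, `mem`, `timeout`,
  `retry`; the local executor runs as many tasks as fit a CPU pool (strict
  FIFO), and a mock-cluster executor accepts everything at once. The same
  100-task fan-out of 2-CPU jobs runs 32-wide on 64 cores, one at a time on
  a dual-core box, and is rejected up front on a single core.
* **Robust supervision.** Every task runs in its own POSIX process group
  under a shell supervisor: stdout/stderr captured per task, exit status
  written to a file, timeouts kill the whole group (grandchildren
  included), Ctrl-C tears everything down cleanly. Failing tasks retry up
  to `retry + 1` attempts, with stale outputs deleted on every failure.
* **Checkpoint / resume.** The engine serializes its complete state —
  program, scopes, program counters, task table — to a checkpoint file at
  explicit `checkpoint` statements and automatically when a `wait` observes
  failures. `resume_checkpoint()` continues exactly where execution
  stopped, on any machine, re-running only the tasks that had not finished.

## A worked example

`variants.bds` — filter three per-sample VCFs in parallel, then merge:

```
samples := ["s1", "s2", "s3"]
string[] outs
for( string s : samples ) {
    in := s + ".vcf"
    out := s + ".filtered.vcf"
    outs = outs + out
    task( out <- in, cpus := 1, taskName := "filterSample" ) {
        grep -v LOWQUAL $in > $out
    }
}
wait
merged := "all.filtered.vcf"
task( merged <- outs, taskName := "mergeAll" ) {
    cat $outs > $merged
}
```

```r
library(pipescript)
run <- run_script("variants.bds", config = engine_config(cpus = 4))
print(run)
#> pipeline run: ok (ok)
#> tasks: DONE=4
#> run dir: run
```

All four tasks ran: the three filters concurrently (each declared 1 CPU on
a 4-CPU pool), the merge after the `wait` barrier. Running it again:

```r
print(run_script("variants.bds", config = engine_config(cpus = 4)))
#> pipeline run: ok (ok)
#> tasks: SKIPPED=4
#> run dir: run2
```

`SKIPPED=4`: every output is newer than its inputs, so nothing executes —
the lazy no-op rerun. Touching one sample's `.vcf` would re-run exactly
that filter and the merge. The run directory holds per-task artifacts
(`task.1.sh`, `task.1.stdout`, `task.1.stderr`, `task.1.exitCode`), the
lifecycle event log `events.log`, and `report.json` / `report.html` with
the task timeline.

The same script runs from a shell via the bundled entry point, including
automatic command-line overrides of script variables:

```sh
inst/cli/pipescript run variants.bds --cpus 4 -samples a b c
```

Useful entry points: `run_script()`, `resume_checkpoint()`,
`inspect_checkpoint()`, `needs_update()`, `resolve_goal()`,
`peak_concurrency()`, and the fixture generators `gen_fanout_pipeline()`,
`flaky_command()`, `make_file_tree()`. The execution model — laziness
rules, goal minimality, scheduling discipline, supervision protocol,
checkpoint format — is documented in
`vignettes/pipescript-methods.Rmd`.

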