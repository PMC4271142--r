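Package: pipescript
Title: A Strongly Typed Scripting Language and Execution Engine for Data
    Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a small, strongly typed imperative scripting
    language for data-processing pipelines together with its execution
    engine. Pipeline scripts declare shell tasks with input/output file
    dependencies and resource requests (CPUs, memory, timeout, retries);
    the engine provides make-style lazy re-execution, an inferred
    dependency graph with deferred goal resolution, resource-aware FIFO
    scheduling on a local CPU pool or a mock cluster queue, robust
    process supervision through POSIX process groups (per-task logs and
    exit-status files, timeout kills, signal propagation), and
    checkpoint/resume by serializing the full interpreter state so an
    interrupted or failed run continues exactly where it stopped.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
OS_type: unix
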