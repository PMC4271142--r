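# Shared fixtures: scratch dirs, engine configs, synthetic stamp tables for
# the out-of-date rule, a brute-force minimal-plan oracle, and the six-task
# resumable pipeline used by the checkpoint tests.

ps_tmpdir <- function() {
  d <- tempfile("pstest-")
  dir.create(d, recursive = TRUE)
  d
}

quick_cfg <- function(work_dir, cpus = 4, ...) {
  engine_config(cpus = cpus, run_dir = tempfile("psrun-"), work_dir = work_dir,
                poll_interval = 0.02, ...)
}

write_script <- function(dir, lines, name = "pipeline.bds") {
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

# ---- synthetic stamps for needs_update / resolve_goal ----------------------

# stamps: named list path -> list(exists, size, mtime, is_dir, dir_empty)
synth_stamp_fn <- function(stamps) {
  function(path) {
    st <- stamps[[path]]
    if (is.null(st) || !isTRUE(st$exists)) {
      return(list(path = path, exists = FALSE, size = NA_real_,
                  mtime = NA_real_, is_dir = FALSE, dir_empty = NA))
    }
    list(path = path, exists = TRUE, size = st$size %||% 1,
         mtime = st$mtime %||% 0,
         is_dir = isTRUE(st$is_dir),
         dir_empty = if (isTRUE(st$is_dir)) isTRUE(st$dir_empty) else NA)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# literal re-statement of the four-clause rule, kept independent of the
# implementation under test
reference_needs_update <- function(outs, ins, stamp_fn) {
  if (length(outs) == 0) return(FALSE)
  for (o in outs) {
    st <- stamp_fn(o)
    if (!st$exists) return(TRUE)                               # does not exist
    if (!st$is_dir && st$size == 0) return(TRUE)               # zero length
    if (st$is_dir && isTRUE(st$dir_empty)) return(TRUE)        # empty directory
  }
  if (length(ins) == 0) return(FALSE)
  in_st <- lapply(ins, stamp_fn)
  if (any(!vapply(in_st, `[[`, TRUE, "exists"))) return(TRUE)  # unknowable age
  out_mtimes <- vapply(lapply(outs, stamp_fn), `[[`, 0, "mtime")
  in_mtimes <- vapply(in_st, `[[`, 0, "mtime")
  min(out_mtimes) < max(in_mtimes)                             # modified before
}

# ---- brute-force minimal plan oracle ---------------------------------------

# nodes: list of list(id, outs, ins); stamps as above; targets: paths.
# Tries all subsets in increasing size; a subset is valid when it can run in
# topological order with all inputs present and leaves every target fresh
# w.r.t. the nearest existing upstream files.
oracle_min_plans <- function(nodes, stamps, targets) {
  ids <- vapply(nodes, `[[`, "", "id")
  producer <- list()
  for (n in nodes) for (p in n$outs) producer[[p]] <- n$id
  by_id <- setNames(nodes, ids)

  run_subset <- function(subset) {
    sim <- stamps
    clock <- max(c(0, vapply(sim, function(s) s$mtime %||% 0, 0))) + 1
    remaining <- subset
    progress <- TRUE
    while (length(remaining) > 0 && progress) {
      progress <- FALSE
      for (id in remaining) {
        n <- by_id[[id]]
        ins_ok <- all(vapply(n$ins, function(p) isTRUE(sim[[p]]$exists), TRUE))
        preds <- unique(unlist(lapply(n$ins, function(p) producer[[p]])))
        preds_pending <- intersect(preds, remaining)
        if (ins_ok && length(preds_pending) == 0) {
          for (p in n$outs) sim[[p]] <- list(exists = TRUE, size = 1, mtime = clock)
          clock <- clock + 1
          remaining <- setdiff(remaining, id)
          progress <- TRUE
        }
      }
    }
    if (length(remaining) > 0) return(NULL)  # could not execute: invalid
    sim
  }

  eff_mtime <- function(sim, path, visiting = character(0)) {
    st <- sim[[path]]
    if (isTRUE(st$exists)) return(st$mtime %||% 0)
    prod <- producer[[path]]
    if (is.null(prod) || path %in% visiting) return(NA_real_)
    ins <- by_id[[prod]]$ins
    if (length(ins) == 0) return(NA_real_)
    ms <- vapply(ins, function(p) eff_mtime(sim, p, c(visiting, path)), 0)
    if (any(is.na(ms))) NA_real_ else max(ms)
  }

  # recursive content freshness: an existing produced file is fresh when it
  # is nonzero, at least as new as its (bridged) inputs, and those inputs are
  # themselves fresh; a missing produced file merely forwards its inputs'
  # freshness (consumers compare against the nearest existing upstream)
  content_fresh <- function(sim, p, visiting = character(0)) {
    prod <- producer[[p]]
    st <- sim[[p]]
    if (is.null(prod) || p %in% visiting) return(isTRUE(st$exists))
    ins <- by_id[[prod]]$ins
    ins_fresh <- all(vapply(ins, function(q) {
      content_fresh(sim, q, c(visiting, p))
    }, TRUE))
    if (!isTRUE(st$exists)) return(ins_fresh)
    if ((st$size %||% 1) == 0) return(FALSE)
    if (length(ins) > 0) {
      ms <- vapply(ins, function(q) eff_mtime(sim, q), 0)
      if (any(is.na(ms))) return(FALSE)
      if ((st$mtime %||% 0) < max(ms)) return(FALSE)
    }
    ins_fresh
  }

  target_fresh <- function(sim, tg) {
    isTRUE(sim[[tg]]$exists) && content_fresh(sim, tg)
  }

  valid <- function(subset) {
    sim <- run_subset(subset)
    if (is.null(sim)) return(FALSE)
    all(vapply(targets, function(tg) target_fresh(sim, tg), TRUE))
  }

  for (k in 0:length(ids)) {
    combos <- utils::combn(ids, k, simplify = FALSE)
    hits <- Filter(valid, combos)
    if (length(hits) > 0) return(hits)
  }
  list()
}

# build a ps_depgraph from oracle-style nodes
graph_from_nodes <- function(nodes) {
  g <- dep_graph()
  for (n in nodes) {
    dep_register(g, n$id, outs = n$outs, ins = n$ins, kind = "dep",
                 spec = list(command = "true", cpus = 1, mem = 0, timeout = 0,
                             retry = 0, name = NULL, owner = "main"))
  }
  g
}

# random chain/DAG instances (<= 6 nodes incl. files) with mixed missing,
# stale and fresh intermediates, for comparing plans against the oracle
random_dag_case <- function(seed) {
  set.seed(seed)
  k <- sample(2:4, 1)  # producers
  nodes <- list()
  files <- "src"
  for (i in seq_len(k)) {
    n_in <- sample(1:min(2, length(files)), 1)
    ins <- sample(files, n_in)
    out <- sprintf("f%d", i)
    nodes[[i]] <- list(id = sprintf("n%d", i), outs = out, ins = ins)
    files <- c(files, out)
  }
  stamps <- list(src = list(exists = TRUE, mtime = 1))
  clock <- 2
  for (i in seq_len(k)) {
    r <- stats::runif(1)
    if (r < 0.35) {
      # missing
    } else if (r < 0.55) {
      stamps[[sprintf("f%d", i)]] <- list(exists = TRUE, mtime = 0)  # stale
    } else {
      stamps[[sprintf("f%d", i)]] <- list(exists = TRUE, mtime = clock)
      clock <- clock + 1
    }
  }
  list(nodes = nodes, stamps = stamps, target = sprintf("f%d", k))
}

# ---- six-task resumable pipeline -------------------------------------------

# A deterministic 6-task pipeline (chain, then a parallel pair, then a
# fan-in). Task k fails once if a marker file stop_k exists (consuming it),
# and counts its executions in count_k, so tests can prove which tasks
# re-ran after a resume.
six_task_pipeline <- function(dir) {
  body <- function(k, cmd) {
    c(sprintf("task( o%d <- %s ) {", k,
              switch(as.character(k),
                     "1" = "src", "2" = "o1", "3" = "o2",
                     "4" = "o3", "5" = "o3", "6" = "[o4, o5]")),
      sprintf("  if [ -f stop_%d ]; then rm -f stop_%d; exit 1; fi", k, k),
      sprintf("  c=$(cat count_%d 2>/dev/null || echo 0); echo $((c+1)) > count_%d",
              k, k),
      paste0("  ", cmd),
      "}")
  }
  lines <- c(
    "src := \"src.txt\"",
    sprintf("o%d := \"o%d.txt\"", 1:6, 1:6),
    body(1, "cat $src > $o1"),
    "wait",
    "checkpoint \"cp_a.chp\"",
    body(2, "tr a-z A-Z < $o1 > $o2"),
    "wait",
    body(3, "cat $o2 $o2 > $o3"),
    "wait",
    "checkpoint \"cp_b.chp\"",
    body(4, "sed s/E/4/g $o3 > $o4"),
    body(5, "sed s/E/5/g $o3 > $o5"),
    "wait",
    body(6, "cat $o4 $o5 > $o6")
  )
  writeLines("seed text here", file.path(dir, "src.txt"))
  write_script(dir, lines, "six.bds")
}

six_outputs <- function(dir) {
  vapply(sprintf("o%d.txt", 1:6), function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) paste(readLines(p), collapse = "\n") else NA_character_
  }, "")
}

six_counts <- function(dir) {
  vapply(sprintf("count_%d", 1:6), function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) as.integer(readLines(p)[1]) else 0L
  }, 0L)
}
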