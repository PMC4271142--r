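# Make-style laziness and the inferred dependency DAG.
#
# The dependency operator `outs <- ins` is true (the task must run) iff any
# output does not exist, has zero length, is an empty directory, or was
# modified before the newest input. `dep` declares deferred task nodes;
# `goal` resolves the minimal subgraph needed to bring target files up to
# date, comparing against the nearest *existing* upstream files so that
# deleted intermediates do not force re-execution when the final targets are
# already current.

#' Snapshot filesystem metadata for a path
#'
#' Never raises for missing paths; `size`/`mtime` are only meaningful when
#' the path exists. For directories, `dir_empty` reports whether the
#' directory has any entries, and `mtime` is the maximum over the directory
#' and its depth-1 entries (a directory used as a dependency is considered
#' as fresh as its newest member).
#'
#' @param path File or directory path.
#' @return A list with `path`, `exists`, `size`, `mtime`, `is_dir`,
#'   `dir_empty`.
#' @export
file_stamp <- function(path) {
  info <- file.info(path, extra_cols = FALSE)
  if (is.na(info$size)) {
    return(list(path = path, exists = FALSE, size = NA_real_,
                mtime = NA_real_, is_dir = FALSE, dir_empty = NA))
  }
  is_dir <- isTRUE(info$isdir)
  mtime <- as.numeric(info$mtime)
  dir_empty <- NA
  if (is_dir) {
    entries <- list.files(path, all.files = TRUE, no.. = TRUE, full.names = TRUE)
    dir_empty <- length(entries) == 0L
    if (!dir_empty) {
      emt <- suppressWarnings(as.numeric(file.info(entries, extra_cols = FALSE)$mtime))
      mtime <- max(mtime, emt, na.rm = TRUE)
    }
  }
  list(path = path, exists = TRUE, size = as.numeric(info$size),
       mtime = mtime, is_dir = is_dir, dir_empty = dir_empty)
}

stamp_out_of_date <- function(st) {
  !st$exists || (!st$is_dir && st$size == 0) || (st$is_dir && isTRUE(st$dir_empty))
}

#' Decide whether outputs must be (re)generated from inputs
#'
#' The four-clause out-of-date rule: an output triggers re-execution when it
#' does not exist, has zero length, is an empty directory, or is older than
#' the newest input. A missing input (with no way to know its age) also
#' triggers, with a warning, since an upstream step may regenerate it. With
#' no inputs, only the first three clauses apply.
#'
#' @param outs,ins Character vectors of paths.
#' @param stamp_fn Stamp function, `path -> stamp`; injectable for tests and
#'   for goal planning over simulated filesystems. Defaults to
#'   [file_stamp()].
#' @param slack Seconds of modification-time slack for coarse filesystem
#'   timestamps: an output counts as older only if
#'   `out_mtime + slack < in_mtime`.
#' @return `TRUE` iff the task owning `outs` must run.
#' @examples
#' d <- tempfile(); dir.create(d)
#' writeLines("x", file.path(d, "in.txt"))
#' needs_update(file.path(d, "out.txt"), file.path(d, "in.txt"))  # TRUE
#' @export
needs_update <- function(outs, ins, stamp_fn = file_stamp, slack = 0) {
  if (length(outs) == 0L) return(FALSE)
  out_stamps <- lapply(outs, stamp_fn)
  if (any(vapply(out_stamps, stamp_out_of_date, TRUE))) return(TRUE)
  if (length(ins) == 0L) return(FALSE)
  in_stamps <- lapply(ins, stamp_fn)
  missing_in <- !vapply(in_stamps, `[[`, TRUE, "exists")
  if (any(missing_in)) {
    warning(sprintf("missing input file(s): %s (treating outputs as stale)",
                    paste(unlist(ins)[missing_in], collapse = ", ")),
            call. = FALSE)
    return(TRUE)
  }
  min_out <- min(vapply(out_stamps, `[[`, 0, "mtime"))
  max_in <- max(vapply(in_stamps, `[[`, 0, "mtime"))
  min_out + slack < max_in
}

#' Create an empty dependency graph
#'
#' Nodes are tasks (or deferred `dep` declarations); edges are inferred from
#' shared file paths: the producer of a path precedes every consumer of it.
#' Each path has at most one producer and the graph stays acyclic.
#'
#' @return An object of class `ps_depgraph`.
#' @export
dep_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()       # id -> node
  g$producer <- list()    # path -> node id
  structure(g, class = "ps_depgraph")
}

#' Register a task node in a dependency graph
#'
#' @param graph A `ps_depgraph`.
#' @param id Node id (the task id).
#' @param outs,ins Character vectors of produced / consumed paths.
#' @param kind `"task"` (conditions evaluated at declaration) or `"dep"`
#'   (deferred until a `goal`).
#' @param spec Arbitrary payload (the task spec) carried to goal planning.
#' @return The node id, invisibly.
#' @export
dep_register <- function(graph, id, outs, ins, kind = "task", spec = NULL) {
  outs <- as.character(outs)
  ins <- as.character(ins)
  for (p in outs) {
    if (!is.null(graph$producer[[p]])) {
      ps_stop("ps_duplicate_producer_error",
              sprintf("file '%s' already produced by %s", p, graph$producer[[p]]))
    }
  }
  node <- list(id = id, kind = kind, outs = outs, ins = ins, spec = spec,
               state = if (kind == "dep") "deferred" else "declared")
  graph$nodes[[id]] <- node
  for (p in outs) graph$producer[[p]] <- id
  # cycle check: walk upstream from this node's inputs; finding one of our
  # own outputs closes a cycle
  seen <- character(0)
  frontier <- ins
  while (length(frontier) > 0L) {
    path <- frontier[[1]]
    frontier <- frontier[-1]
    if (path %in% outs) {
      for (p in outs) graph$producer[[p]] <- NULL
      graph$nodes[[id]] <- NULL
      ps_stop("ps_cycle_error",
              sprintf("dependency cycle through '%s' at %s", path, id))
    }
    prod <- graph$producer[[path]]
    if (!is.null(prod) && !prod %in% seen) {
      seen <- c(seen, prod)
      frontier <- c(frontier, graph$nodes[[prod]]$ins)
    }
  }
  invisible(id)
}

dg_producer_of <- function(graph, path) graph$producer[[path]]

# Effective stamp: bridge over missing produced files to the nearest
# existing upstream files, so targets can be judged against transitive
# sources even when intermediates were deleted.
dg_eff_stamp <- function(graph, path, stamp_fn, visiting = character(0)) {
  st <- stamp_fn(path)
  if (st$exists) return(st)
  prod <- dg_producer_of(graph, path)
  if (is.null(prod) || path %in% visiting) return(st)  # truly missing
  node <- graph$nodes[[prod]]
  if (length(node$ins) == 0L) return(st)
  ups <- lapply(node$ins, dg_eff_stamp, graph = graph, stamp_fn = stamp_fn,
                visiting = c(visiting, path))
  if (!all(vapply(ups, `[[`, TRUE, "exists"))) return(st)
  list(path = path, exists = TRUE, size = 1,
       mtime = max(vapply(ups, `[[`, 0, "mtime")),
       is_dir = FALSE, dir_empty = NA)
}

# Content staleness of a produced path, recursively. An existing file is
# stale when it is older than the (bridged) modification time of its
# producer's inputs, fails the zero-length/empty-directory clauses, or any
# of those inputs is itself stale — a stale existing intermediate poisons
# everything downstream, even when local timestamps are monotone. A missing
# produced file is not stale by itself (its consumers are judged against the
# nearest existing upstream files); it merely propagates upstream staleness.
dg_path_stale <- function(graph, path, stamp_fn, visiting = character(0)) {
  prod <- dg_producer_of(graph, path)
  if (is.null(prod) || path %in% visiting) return(FALSE)  # source file
  node <- graph$nodes[[prod]]
  ins_stale <- any(vapply(node$ins, function(q) {
    dg_path_stale(graph, q, stamp_fn, c(visiting, path))
  }, TRUE))
  st <- stamp_fn(path)
  if (!st$exists) return(ins_stale)
  if (stamp_out_of_date(st)) return(TRUE)
  if (length(node$ins) > 0L) {
    ups <- lapply(node$ins, dg_eff_stamp, graph = graph, stamp_fn = stamp_fn)
    missing <- !vapply(ups, `[[`, TRUE, "exists")
    if (any(missing)) return(TRUE)  # unknowable input age
    if (st$mtime < max(vapply(ups, `[[`, 0, "mtime"))) return(TRUE)
  }
  ins_stale
}

#' Resolve the minimal execution plan for goal targets
#'
#' Walks the producer chain from the targets toward source files and returns
#' a topologically ordered minimal plan. A node enters the plan iff its
#' outputs are out of date with respect to the nearest existing upstream
#' files, or a consumer already in the plan needs its missing outputs
#' regenerated. If the targets are current with respect to the transitive
#' source inputs, the plan is empty even when intermediate files have been
#' deleted.
#'
#' @param graph A `ps_depgraph`.
#' @param targets Character vector of target paths.
#' @param stamp_fn Stamp function (injectable; see [needs_update()]).
#' @return Character vector of node ids in execution order (possibly empty).
#' @export
resolve_goal <- function(graph, targets, stamp_fn = file_stamp) {
  plan <- character(0)
  include <- function(id) {
    if (id %in% plan) return(invisible(NULL))
    plan <<- c(plan, id)
    node <- graph$nodes[[id]]
    for (p in node$ins) {
      prod <- dg_producer_of(graph, p)
      st <- stamp_fn(p)
      needs_regen <- !st$exists || dg_path_stale(graph, p, stamp_fn)
      if (!needs_regen) next
      if (!is.null(prod)) {
        include(prod)
      } else if (!st$exists) {
        warning(sprintf("goal: input '%s' of %s is missing and has no producer",
                        p, id), call. = FALSE)
      }
    }
  }
  for (tg in as.character(targets)) {
    prod <- dg_producer_of(graph, tg)
    st <- stamp_fn(tg)
    if (is.null(prod)) {
      if (!st$exists) {
        ps_stop("ps_unproducible_target_error",
                sprintf("goal target '%s' does not exist and no task produces it",
                        tg))
      }
      next
    }
    if (!st$exists || stamp_out_of_date(st) ||
        dg_path_stale(graph, tg, stamp_fn)) {
      include(prod)
    }
  }
  # closure: a regenerated upstream file invalidates every existing
  # intermediate between it and a plan node, so the producers of such
  # now-tainted inputs must join the plan too
  repeat {
    dirty <- unique(unlist(lapply(plan, function(id) graph$nodes[[id]]$outs)))
    tainted <- function(q, visiting = character(0)) {
      if (q %in% dirty) return(TRUE)
      if (q %in% visiting) return(FALSE)
      pr <- dg_producer_of(graph, q)
      if (is.null(pr)) return(FALSE)
      any(vapply(graph$nodes[[pr]]$ins, tainted, TRUE,
                 visiting = c(visiting, q)))
    }
    added <- FALSE
    for (id in plan) {
      for (q in graph$nodes[[id]]$ins) {
        pr <- dg_producer_of(graph, q)
        if (is.null(pr) || pr %in% plan) next
        if (tainted(q)) {
          include(pr)
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  dg_topo_order(graph, plan)
}

dg_topo_order <- function(graph, ids) {
  if (length(ids) <= 1L) return(ids)
  remaining <- ids
  ordered <- character(0)
  # producers of a node's inputs that are themselves in the plan must come
  # first; Kahn's algorithm over the plan-induced subgraph
  preds <- lapply(ids, function(id) {
    node <- graph$nodes[[id]]
    ps <- unlist(lapply(node$ins, function(p) dg_producer_of(graph, p)))
    intersect(ps, ids)
  })
  names(preds) <- ids
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(id) {
      all(preds[[id]] %in% ordered)
    }, TRUE)]
    if (length(ready) == 0L) {
      ps_stop("ps_cycle_error", "cycle detected while ordering a goal plan")
    }
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}
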