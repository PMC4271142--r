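# The out-of-date rule, graph registration, and minimal goal planning
# (checked against a brute-force subset oracle).

test_that("file_stamp captures existence, size, directories and emptiness", {
  d <- ps_tmpdir()
  make_file_tree(list(
    "ten.txt" = list(size = 10, mtime_offset = 0),
    "empty.txt" = list(size = 0, mtime_offset = 0),
    "emptydir/" = list(mtime_offset = 0)
  ), base = d)
  st <- file_stamp(file.path(d, "ten.txt"))
  expect_true(st$exists)
  expect_equal(st$size, 10)
  expect_false(file_stamp(file.path(d, "missing"))$exists)
  dd <- file_stamp(file.path(d, "emptydir"))
  expect_true(dd$is_dir)
  expect_true(dd$dir_empty)
})

test_that("the four out-of-date clauses trigger on real files", {
  d <- ps_tmpdir()
  make_file_tree(list(
    "in.txt" = list(size = 4, mtime_offset = 0),
    "fresh.txt" = list(size = 4, mtime_offset = 100),
    "stale.txt" = list(size = 4, mtime_offset = -100),
    "zero.txt" = list(size = 0, mtime_offset = 100),
    "hollow/" = list(mtime_offset = 100)
  ), base = d)
  p <- function(f) file.path(d, f)
  expect_true(needs_update(p("absent.txt"), p("in.txt")))     # does not exist
  expect_true(needs_update(p("zero.txt"), p("in.txt")))       # zero length
  expect_true(needs_update(p("hollow"), p("in.txt")))         # empty directory
  expect_true(needs_update(p("stale.txt"), p("in.txt")))      # modified before
  expect_false(needs_update(p("fresh.txt"), p("in.txt")))     # up to date
  expect_warning(
    expect_true(needs_update(p("fresh.txt"), p("gone.txt"))), # missing input
    "missing input")
})

test_that("needs_update equals the literal four-clause reference on random stamps", {
  set.seed(7)
  for (i in 1:300) {
    n_out <- sample(1:2, 1)
    n_in <- sample(0:2, 1)
    paths <- sprintf("f%d", seq_len(n_out + n_in))
    stamps <- setNames(lapply(paths, function(p) {
      if (stats::runif(1) < 0.2) return(list(exists = FALSE))
      if (stats::runif(1) < 0.15) {
        return(list(exists = TRUE, is_dir = TRUE,
                    dir_empty = stats::runif(1) < 0.5,
                    mtime = sample(1:5, 1)))
      }
      list(exists = TRUE, size = sample(c(0, 1, 10), 1), mtime = sample(1:5, 1))
    }), paths)
    sf <- synth_stamp_fn(stamps)
    outs <- paths[seq_len(n_out)]
    ins <- if (n_in > 0) paths[n_out + seq_len(n_in)] else character(0)
    expect_identical(
      suppressWarnings(needs_update(outs, ins, stamp_fn = sf)),
      suppressWarnings(reference_needs_update(outs, ins, sf)),
      label = sprintf("case %d", i))
  }
})

test_that("registration rejects duplicate producers and cycles; fan-in wiring works", {
  g <- dep_graph()
  for (i in 1:100) dep_register(g, sprintf("t%d", i), outs = sprintf("out_%d", i),
                                ins = "src")
  dep_register(g, "fanin", outs = "main", ins = sprintf("out_%d", 1:100))
  preds <- unique(unlist(lapply(g$nodes[["fanin"]]$ins,
                                function(p) g$producer[[p]])))
  expect_length(preds, 100L)
  expect_error(dep_register(g, "dup", outs = "out_1", ins = character(0)),
               class = "ps_duplicate_producer_error")
  g2 <- dep_graph()
  dep_register(g2, "ab", outs = "b", ins = "a")
  expect_error(dep_register(g2, "ba", outs = "a", ins = "b"),
               class = "ps_cycle_error")
})

test_that("goal planning tolerates deleted intermediates and regenerates minimally", {
  nodes <- list(
    list(id = "mk_mid", outs = "mid", ins = "src"),
    list(id = "mk_fin", outs = "fin", ins = "mid")
  )
  g <- graph_from_nodes(nodes)
  # mid deleted, fin newer than src -> nothing to do
  stamps <- list(src = list(exists = TRUE, mtime = 1),
                 fin = list(exists = TRUE, mtime = 3))
  expect_identical(resolve_goal(g, "fin", synth_stamp_fn(stamps)), character(0))
  # fin deleted -> mid producer included only because fin's producer needs it
  stamps2 <- list(src = list(exists = TRUE, mtime = 1))
  expect_identical(resolve_goal(g, "fin", synth_stamp_fn(stamps2)),
                   c("mk_mid", "mk_fin"))
  # target with no producer but present on disk -> empty plan
  stamps3 <- list(alone = list(exists = TRUE, mtime = 1))
  expect_identical(resolve_goal(graph_from_nodes(list()), "alone",
                                synth_stamp_fn(stamps3)), character(0))
  # unproducible target
  expect_error(resolve_goal(g, "nowhere", synth_stamp_fn(stamps)),
               class = "ps_unproducible_target_error")
})

test_that("goal plans match the brute-force minimal subset oracle on small DAGs", {
  for (seed in 1:40) {
    case <- random_dag_case(seed)
    g <- graph_from_nodes(case$nodes)
    sf <- synth_stamp_fn(case$stamps)
    plan <- tryCatch(
      suppressWarnings(resolve_goal(g, case$target, sf)),
      ps_unproducible_target_error = function(c) NULL)
    if (is.null(plan)) next
    minimal <- oracle_min_plans(case$nodes, case$stamps, case$target)
    expect_true(length(minimal) > 0, label = sprintf("seed %d solvable", seed))
    sizes <- vapply(minimal, length, 0L)
    expect_equal(length(plan), sizes[[1]],
                 label = sprintf("seed %d plan size", seed))
    expect_true(any(vapply(minimal, function(m) setequal(m, plan), TRUE)),
                label = sprintf("seed %d plan is a minimal valid subset", seed))
  }
})

test_that("plans are idempotent and monotone", {
  nodes <- list(
    list(id = "a", outs = "x", ins = "src"),
    list(id = "b", outs = "y", ins = "x"),
    list(id = "c", outs = "z", ins = "y")
  )
  g <- graph_from_nodes(nodes)
  # everything stale: full plan
  stamps <- list(src = list(exists = TRUE, mtime = 10))
  sf <- synth_stamp_fn(stamps)
  plan <- suppressWarnings(resolve_goal(g, "z", sf))
  expect_identical(plan, c("a", "b", "c"))
  # simulate execution, then replanning yields the empty plan
  t <- 11
  for (id in plan) {
    for (o in g$nodes[[id]]$outs) stamps[[o]] <- list(exists = TRUE, mtime = t)
    t <- t + 1
  }
  expect_identical(resolve_goal(g, "z", synth_stamp_fn(stamps)), character(0))
  # deleting the final target never shrinks the plan
  stamps_del <- stamps
  stamps_del[["z"]] <- NULL
  expect_gte(length(resolve_goal(g, "z", synth_stamp_fn(stamps_del))), 1L)
  # touching the source forces the full downstream plan
  stamps_touch <- stamps
  stamps_touch[["src"]] <- list(exists = TRUE, mtime = 99)
  expect_identical(resolve_goal(g, "z", synth_stamp_fn(stamps_touch)),
                   c("a", "b", "c"))
})
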