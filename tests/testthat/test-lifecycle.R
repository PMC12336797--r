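test_that("a task writing its declared output completes with a manifest", {
  svc <- make_service()
  id <- svc$submit(list(
    executors = list(list(image = "alpine",
                          command = c("sh", "-c", "echo ok > out.txt"))),
    outputs = list(list(url = paste0("file://", tempfile()),
                        path = "/out.txt"))
  ))
  expect_identical(svc$worker_run(id), "COMPLETE")
  doc <- svc$store$get(id)
  expect_identical(doc$logs[[1]]$outputs[[1]]$size_bytes, 3)  # "ok\n"
  expect_true(nzchar(doc$logs[[1]]$start_time))
  expect_true(nzchar(doc$logs[[1]]$end_time))
  # workspace destroyed after the terminal state
  expect_false(dir.exists(file.path(svc$config$work_root, id)))
})

test_that("an unsupported input protocol yields SYSTEM_ERROR before any executor runs", {
  svc <- make_service()
  id <- svc$submit(list(
    inputs = list(list(url = "gs://bucket/x", path = "/in")),
    executors = list(list(image = "alpine", command = "true"))
  ))
  expect_identical(svc$worker_run(id), "SYSTEM_ERROR")
  doc <- svc$store$get(id)
  expect_length(doc$logs[[1]]$logs, 0L)
  expect_true(any(grepl("staging failed", doc$logs[[1]]$system_logs)))
  expect_identical(svc$sequence_starts(id), 0L)
})

test_that("a nonzero non-ignored exit yields EXECUTOR_ERROR with one log", {
  svc <- make_service()
  id <- svc$submit(tes_fixture_task("fail", exit_code = 7L))
  expect_identical(svc$worker_run(id), "EXECUTOR_ERROR")
  logs <- svc$store$get(id)$logs[[1]]$logs
  expect_length(logs, 1L)
  expect_identical(logs[[1]]$exit_code, 7L)
})

test_that("a declared output the job never produced yields EXECUTOR_ERROR", {
  svc <- make_service()
  id <- svc$submit(list(
    executors = list(list(image = "alpine", command = "true")),
    outputs = list(list(url = "file:///tmp/never", path = "/ghost"))
  ))
  expect_identical(svc$worker_run(id), "EXECUTOR_ERROR")
})

test_that("an export destination fault yields SYSTEM_ERROR", {
  reg <- tes_protocol_registry()
  tes_register_protocol(reg, "brokenstore",
                        fetch = function(...) NULL,
                        store = function(...) stop("vault sealed"))
  svc <- make_service(registry = reg)
  id <- svc$submit(list(
    executors = list(list(image = "alpine",
                          command = c("sh", "-c", "touch out.txt"))),
    outputs = list(list(url = "brokenstore://x/y", path = "/out.txt"))
  ))
  expect_identical(svc$worker_run(id), "SYSTEM_ERROR")
})

test_that("canceling a queued task takes effect immediately and runs nothing", {
  svc <- make_service()
  id <- svc$submit(tes_fixture_task("noop"))
  expect_identical(svc$cancel(id), "CANCELED")
  svc$run_until_idle()
  doc <- svc$store$get(id)
  expect_identical(doc$state, "CANCELED")
  expect_length(doc$logs[[1]]$logs %||% list(), 0L)
  expect_identical(svc$sequence_starts(id), 0L)
  expect_identical(svc$store$trace(id), c("QUEUED", "CANCELED"))
})

test_that("canceling a running task terminates it, retaining the partial log", {
  svc <- make_service(grace_period = 0.2)
  id <- svc$submit(list(executors = list(
    list(image = "alpine", command = c("sleep", "30")),
    list(image = "alpine", command = "true"),
    list(image = "alpine", command = "true")
  )))
  # advance until the sleeper holds a slot and is RUNNING
  for (i in 1:200) {
    svc$poll()
    if (svc$store$get(id)$state == "RUNNING") break
    Sys.sleep(0.01)
  }
  expect_identical(svc$store$get(id)$state, "RUNNING")
  expect_identical(svc$cancel(id), "CANCELING")
  svc$run_until_idle(timeout = 30)
  doc <- svc$store$get(id)
  expect_identical(doc$state, "CANCELED")
  expect_length(doc$logs[[1]]$logs, 1L)  # partial log; executors 2-3 never ran
  expect_identical(svc$store$trace(id),
                   c("QUEUED", "INITIALIZING", "RUNNING", "CANCELING",
                     "CANCELED"))
})

test_that("cancel is idempotent and terminal states absorb it", {
  svc <- make_service()
  id <- svc$submit(tes_fixture_task("noop"))
  expect_identical(svc$worker_run(id), "COMPLETE")
  expect_identical(svc$cancel(id), "COMPLETE")
  expect_identical(svc$cancel(id), "COMPLETE")
  expect_identical(svc$store$get(id)$state, "COMPLETE")
})

legal_trace <- function(trace) {
  if (trace[[1]] != "QUEUED") return(FALSE)
  for (i in seq_len(length(trace) - 1L)) {
    if (!tes_transition_allowed(trace[[i]], trace[[i + 1L]])) return(FALSE)
  }
  sum(trace %in% TES_TERMINAL_STATES) == 1L &&
    trace[[length(trace)]] %in% TES_TERMINAL_STATES
}

test_that("exhaustive fault injection yields only legal single-terminal state traces", {
  # every fault point the pipeline has: staging failure, each executor
  # failing (with and without ignore_error), spawn fault at each position,
  # export failure, missing output, cancel while queued
  scenarios <- list(
    list(doc = minimal_task_doc(), exits = 0L, expect = "COMPLETE"),
    list(doc = list(inputs = list(list(url = "gs://b/x", path = "/in")),
                    executors = minimal_task_doc()$executors),
         exits = integer(0), expect = "SYSTEM_ERROR"),
    list(doc = minimal_task_doc(command = "x3"), exits = c(1L),
         expect = "EXECUTOR_ERROR"),
    list(doc = list(executors = rep(minimal_task_doc()$executors, 3)),
         exits = c(0L, 1L), expect = "EXECUTOR_ERROR"),
    list(doc = list(executors = rep(minimal_task_doc()$executors, 3)),
         exits = c(0L, 0L, 1L), expect = "EXECUTOR_ERROR"),
    list(doc = list(executors = list(
           list(image = "a", command = "x"),
           list(image = "a", command = "x", ignore_error = TRUE),
           list(image = "a", command = "x"))),
         exits = c(0L, 1L, 0L), expect = "COMPLETE"),
    list(doc = minimal_task_doc(), exits = NA_integer_,
         expect = "SYSTEM_ERROR"),
    list(doc = list(executors = rep(minimal_task_doc()$executors, 2)),
         exits = c(0L, NA_integer_), expect = "SYSTEM_ERROR"),
    list(doc = c(minimal_task_doc(),
                 list(outputs = list(list(url = "file:///tmp/nope",
                                          path = "/ghost")))),
         exits = 0L, expect = "EXECUTOR_ERROR"),
    list(doc = minimal_task_doc(), exits = 0L, cancel_queued = TRUE,
         expect = "CANCELED")
  )
  for (k in seq_along(scenarios)) {
    sc <- scenarios[[k]]
    svc <- make_service(runner = tes_script_runner(sc$exits))
    id <- svc$submit(sc$doc)
    if (isTRUE(sc$cancel_queued)) svc$cancel(id)
    svc$run_until_idle(timeout = 30)
    doc <- svc$store$get(id)
    expect_identical(doc$state, sc$expect,
                     label = sprintf("scenario %d terminal state", k))
    expect_true(legal_trace(svc$store$trace(id)),
                label = sprintf("scenario %d trace %s", k,
                                paste(svc$store$trace(id), collapse = ">")))
    expect_false(dir.exists(file.path(svc$config$work_root, id)),
                 label = sprintf("scenario %d workspace removed", k))
  }
})

test_that("a concurrent pool executes every task at most once", {
  svc <- make_service(runner = tes_script_runner(rep(0L, 40)), pool_size = 4L)
  ids <- vapply(1:40, function(i) svc$submit(minimal_task_doc()),
                character(1))
  svc$run_until_idle(timeout = 60)
  starts <- vapply(ids, svc$sequence_starts, integer(1))
  expect_true(all(starts == 1L))
  states <- vapply(ids, function(id) svc$store$get(id)$state, character(1))
  expect_true(all(states == "COMPLETE"))
})

test_that("random fault-injected task mixes always reach exactly one terminal state", {
  set.seed(99)
  n <- 120
  exits_pool <- integer(0)
  docs <- list()
  for (i in seq_len(n)) {
    kind <- sample(c("ok", "fail", "badurl", "ghost-output", "multi"), 1)
    d <- switch(kind,
      ok = minimal_task_doc(),
      fail = minimal_task_doc(),
      badurl = list(inputs = list(list(url = "gs://b/x", path = "/in")),
                    executors = minimal_task_doc()$executors),
      "ghost-output" = c(minimal_task_doc(),
                         list(outputs = list(list(url = "file:///tmp/x",
                                                  path = "/nope")))),
      multi = list(executors = rep(minimal_task_doc()$executors, 3))
    )
    n_exec <- length(d$executors)
    ex <- if (kind == "badurl") integer(0) else
      sample(c(0L, 0L, 0L, 1L), n_exec, replace = TRUE)
    if (kind == "fail") ex[1] <- 1L
    exits_pool <- c(exits_pool, ex)
    docs[[i]] <- d
  }
  svc <- make_service(runner = tes_script_runner(exits_pool), pool_size = 6L)
  ids <- vapply(docs, svc$submit, character(1))
  svc$run_until_idle(timeout = 120)
  for (id in ids) {
    expect_true(legal_trace(svc$store$trace(id)))
  }
})
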