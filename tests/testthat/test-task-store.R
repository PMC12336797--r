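noop_spec <- function(name = NULL, tags = NULL) {
  tes_validate_task(minimal_task_doc(name = name, tags = tags))
}

test_that("create assigns fresh unique retrievable ids, state QUEUED", {
  store <- TaskStore$new()
  ids <- vapply(1:1000, function(i) store$create(noop_spec()), character(1))
  expect_identical(anyDuplicated(ids), 0L)
  expect_true(all(grepl("^[A-Za-z0-9_-]{26}$", ids)))
  expect_identical(store$size(), 1000L)
  for (id in sample(ids, 25)) {
    doc <- store$get(id)
    expect_identical(doc$id, id)
    expect_identical(doc$state, "QUEUED")
    expect_true(nzchar(doc$creation_time))
  }
})

test_that("unknown ids raise not-found", {
  store <- TaskStore$new()
  expect_error(store$get("zzz"), class = "tes_not_found")
  expect_error(store$update_state("zzz", "CANCELED"), class = "tes_not_found")
})

test_that("state updates follow the transition table; terminal states absorb", {
  store <- TaskStore$new()
  id <- store$create(noop_spec())
  store$update_state(id, "INITIALIZING")
  store$update_state(id, "RUNNING")
  store$update_state(id, "COMPLETE")
  for (to in TES_STATES) {
    expect_error(store$update_state(id, to), class = "tes_illegal_transition")
  }
  expect_identical(store$get(id)$state, "COMPLETE")
  expect_identical(store$trace(id),
                   c("QUEUED", "INITIALIZING", "RUNNING", "COMPLETE"))
  id2 <- store$create(noop_spec())
  expect_error(store$update_state(id2, "COMPLETE"),
               class = "tes_illegal_transition")
  expect_identical(store$get(id2)$state, "QUEUED")  # no partial effect
})

test_that("interleaved log appends from multiple writers all land", {
  store <- TaskStore$new()
  id <- store$create(noop_spec())
  store$modify(id, function(d) {
    d$logs <- list(list(logs = list(), system_logs = character(0)))
    d
  })
  append_line <- function(worker, k) {
    store$modify(id, function(d) {
      d$logs[[1]]$system_logs <- c(d$logs[[1]]$system_logs,
                                   sprintf("w%d-%d", worker, k))
      d
    })
  }
  for (k in 1:50) {  # two workers interleaving
    append_line(1L, k)
    append_line(2L, k)
  }
  expect_length(store$get(id)$logs[[1]]$system_logs, 100L)
})

test_that("modify cannot clobber id, state, or creation_time", {
  store <- TaskStore$new()
  id <- store$create(noop_spec())
  before <- store$get(id)
  store$modify(id, function(d) {
    d$id <- "hacked"; d$state <- "COMPLETE"; d$creation_time <- "1970"
    d
  })
  after <- store$get(id)
  expect_identical(after$id, before$id)
  expect_identical(after$state, "QUEUED")
  expect_identical(after$creation_time, before$creation_time)
})

make_varied_store <- function(n = 40, seed = 42) {
  store <- TaskStore$new()
  set.seed(seed)
  names_pool <- c("align", "align-x", "call", "merge", NA)
  for (i in seq_len(n)) {
    nm <- sample(names_pool, 1)
    tags <- if (runif(1) < 0.5) {
      list(project = sample(c("a", "b"), 1))
    }
    spec <- noop_spec(
      name = if (!is.na(nm)) paste0(nm, "-", i),
      tags = tags
    )
    id <- store$create(spec)
    # walk a random legal path to diversify states
    path <- sample(list(
      character(0),
      "CANCELED",
      c("INITIALIZING", "RUNNING", "COMPLETE"),
      c("INITIALIZING", "RUNNING", "EXECUTOR_ERROR"),
      c("INITIALIZING", "SYSTEM_ERROR"),
      c("INITIALIZING", "RUNNING")
    ), 1)[[1]]
    for (s in path) store$update_state(id, s)
  }
  store
}

test_that("pagination is complete and duplicate-free for every filter and page size", {
  store <- make_varied_store()
  filters <- list(
    list(),
    list(state = "COMPLETE"),
    list(name_prefix = "align"),
    list(tags = list(project = "a")),
    list(state = "COMPLETE", name_prefix = "align"),
    list(state = "RUNNING", tags = list(project = "b"))
  )
  for (f in filters) {
    expected <- brute_force_ids(store, state = f$state,
                                name_prefix = f$name_prefix, tags = f$tags)
    for (ps in c(1, 2, 3, 7)) {
      got <- paged_ids(store, do.call(tes_task_filter, f), ps)
      expect_identical(got, expected,
                       label = sprintf("filter %s page_size %d",
                                       paste(names(f), collapse = "+"), ps))
    }
  }
})

test_that("name_prefix is a prefix match, not a substring match", {
  store <- TaskStore$new()
  store$create(noop_spec(name = "align-1"))
  store$create(noop_spec(name = "realign-1"))
  page <- store$list_page(tes_task_filter(name_prefix = "align"),
                          view = "BASIC")
  expect_length(page$tasks, 1L)
  expect_identical(page$tasks[[1]]$name, "align-1")
})

test_that("listing order is creation time descending with id tie-break", {
  store <- TaskStore$new()
  ids <- vapply(1:5, function(i) store$create(noop_spec()), character(1))
  page <- store$list_page(tes_task_filter(), page_size = 10)
  got <- vapply(page$tasks, function(t) t$id, character(1))
  expect_identical(got, brute_force_ids(store))
})

test_that("page tokens are rejected when malformed or issued for another query", {
  store <- TaskStore$new()
  for (i in 1:4) store$create(noop_spec(name = paste0("align-", i)))
  f1 <- tes_task_filter(name_prefix = "align")
  page <- store$list_page(f1, page_size = 1)
  expect_false(is.null(page$next_page_token))
  expect_error(
    store$list_page(tes_task_filter(state = "COMPLETE"), page_size = 1,
                    page_token = page$next_page_token),
    class = "tes_invalid_page_token"
  )
  expect_error(
    store$list_page(f1, page_size = 1, page_token = "!!not-a-token!!"),
    class = "tes_invalid_page_token"
  )
})

test_that("with retention disabled every created task remains listable", {
  store <- make_varied_store(n = 30)
  expect_identical(length(paged_ids(store, tes_task_filter(), 7)), 30L)
})

test_that("the journal-backed store replays records and traces across reopen", {
  path <- withr::local_tempfile(fileext = ".ndjson")
  store <- FileTaskStore$new(path)
  id1 <- store$create(noop_spec(name = "persist-me", tags = list(k = "v")))
  id2 <- store$create(noop_spec())
  store$update_state(id1, "INITIALIZING")
  store$update_state(id1, "RUNNING")
  store$update_state(id1, "COMPLETE")
  store$modify(id1, function(d) {
    d$logs <- list(list(logs = list(), system_logs = "line-1"))
    d
  })

  reopened <- FileTaskStore$new(path)
  expect_identical(reopened$size(), 2L)
  doc <- reopened$get(id1)
  expect_identical(doc$state, "COMPLETE")
  expect_identical(doc$name, "persist-me")
  expect_identical(doc$tags$k, "v")
  expect_identical(doc$logs[[1]]$system_logs, "line-1")
  expect_identical(reopened$trace(id1),
                   c("QUEUED", "INITIALIZING", "RUNNING", "COMPLETE"))
  expect_identical(reopened$get(id2)$state, "QUEUED")
  # transition discipline survives the reopen
  expect_error(reopened$update_state(id1, "RUNNING"),
               class = "tes_illegal_transition")
  # and the reopened store lists identically to the original
  expect_identical(paged_ids(reopened, tes_task_filter(), 1),
                   brute_force_ids(reopened))
})
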