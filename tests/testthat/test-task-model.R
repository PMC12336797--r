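test_that("a minimal task validates with defaults filled", {
  spec <- tes_validate_task(
    list(executors = list(list(image = "alpine", command = c("echo", "hi"))))
  )
  expect_s3_class(spec, "tes_task")
  e <- spec$executors[[1]]
  expect_identical(e$image, "alpine")
  expect_identical(e$command, c("echo", "hi"))
  expect_false(e$ignore_error)
  expect_identical(spec$inputs, list())
  expect_identical(spec$outputs, list())
  expect_identical(spec$volumes, character(0))
  expect_identical(names(spec$tags), character(0))
})

test_that("validation is all-or-nothing and reports every violation with a path", {
  err <- tryCatch(
    tes_validate_task(list(
      executors = list(),
      inputs = list(list(url = "file:///a", content = "x", path = "/in")),
      volumes = list("relative/path"),
      outputs = list(list(url = "https://host/up", path = "/out"))
    )),
    tes_validation_error = function(e) e
  )
  expect_s3_class(err, "tes_validation_error")
  expect_true(any(grepl("^executors:", err$errors)))
  expect_true(any(grepl("^inputs\\[0\\]:", err$errors)))
  expect_true(any(grepl("^volumes\\[0\\]", err$errors)))
  expect_true(any(grepl("^outputs\\[0\\]\\.url", err$errors)))  # no http upload
})

test_that("paths that escape the workspace are rejected at validation time", {
  bad <- list(executors = list(list(image = "a", command = "true")),
              inputs = list(list(content = "x", path = "/in/../../etc/pw")))
  expect_error(tes_validate_task(bad), class = "tes_validation_error")
  ok <- tes_validate_task(
    list(executors = list(list(image = "a", command = "true")),
         inputs = list(list(content = "x", path = "/in/sub/../a.txt")))
  )
  expect_identical(ok$inputs[[1]]$path, "/in/a.txt")  # normalized, still inside
})

test_that("inputs need exactly one of url and content; outputs need a url", {
  base <- list(executors = list(list(image = "a", command = "true")))
  expect_error(
    tes_validate_task(c(base, list(inputs = list(list(path = "/in"))))),
    class = "tes_validation_error"
  )
  expect_error(
    tes_validate_task(c(base, list(outputs = list(list(path = "/out"))))),
    class = "tes_validation_error"
  )
  ok <- tes_validate_task(c(base, list(
    inputs = list(list(content = "abc", path = "/in")),
    outputs = list(list(url = "file:///dst", path = "/out"))
  )))
  expect_identical(ok$inputs[[1]]$type, "FILE")
})

test_that("resource requests must be positive (gpu count may be zero)", {
  base <- list(executors = list(list(image = "a", command = "true")))
  expect_error(
    tes_validate_task(c(base, list(resources = list(cpu_cores = 0)))),
    class = "tes_validation_error"
  )
  expect_error(
    tes_validate_task(c(base, list(resources = list(ram_gb = -1)))),
    class = "tes_validation_error"
  )
  ok <- tes_validate_task(c(base, list(
    resources = list(cpu_cores = 2, ram_gb = 0.5, gpu_count = 0,
                     preemptible = TRUE)
  )))
  expect_identical(ok$resources$gpu_count, 0L)
})

test_that("strict parsing rejects unknown fields; lenient mode preserves them", {
  json <- '{"executors":[{"image":"a","command":["true"]}],"frob":1}'
  expect_error(tes_parse_task(json), class = "tes_validation_error")
  spec <- tes_parse_task(json, lenient = TRUE)
  expect_identical(spec$frob, 1L)
  expect_error(tes_parse_task("{not json"), class = "tes_parse_error")
})

test_that("serialize/parse is the structural identity on random valid tasks", {
  for (seed in 1:25) {
    spec <- tes_random_task(seed)
    back <- tes_parse_task(tes_serialize_task(spec))
    expect_identical(unclass(back), unclass(spec),
                     label = sprintf("round-trip seed %d", seed))
  }
})

test_that("validation is idempotent on normalized specs", {
  for (seed in c(2, 9, 17)) {
    spec <- tes_random_task(seed)
    expect_identical(unclass(tes_validate_task(unclass(spec))),
                     unclass(spec))
  }
})

seeded_record <- function() {
  # a stored-task document exercising every bulky payload the BASIC view strips
  list(
    id = "t1", state = "COMPLETE", name = "proj-example",
    inputs = list(list(content = "inline-bytes", path = "/in/a", type = "FILE")),
    outputs = list(list(url = "file:///dst", path = "/out", type = "FILE")),
    executors = list(list(image = "alpine", command = c("echo", "hi"),
                          env = list(), ignore_error = FALSE)),
    volumes = character(0), tags = list(run = "1"),
    logs = list(list(
      logs = list(list(start_time = "2024-01-01T00:00:00Z",
                       end_time = "2024-01-01T00:00:01Z",
                       stdout = "hello", stderr = "", exit_code = 0L)),
      start_time = "2024-01-01T00:00:00Z",
      end_time = "2024-01-01T00:00:01Z",
      outputs = list(list(url = "file:///dst", path = "/out",
                          size_bytes = 5)),
      system_logs = c("2024-01-01T00:00:01Z task settled: COMPLETE")
    )),
    creation_time = "2024-01-01T00:00:00Z"
  )
}

test_that("FULL projection is the identity and projection never mutates", {
  rec <- seeded_record()
  expect_identical(tes_project_view(rec, "FULL"), rec)
  basic <- tes_project_view(rec, "BASIC")
  expect_null(basic$inputs[[1]]$content)
  expect_identical(rec$inputs[[1]]$content, "inline-bytes")  # untouched
})

test_that("MINIMAL is exactly id+state and BASIC strips stdio tails, system logs, inline content", {
  rec <- seeded_record()
  minimal <- tes_project_view(rec, "MINIMAL")
  expect_identical(minimal, list(id = "t1", state = "COMPLETE"))
  basic <- tes_project_view(rec, "BASIC")
  expect_null(basic$logs[[1]]$logs[[1]]$stdout)
  expect_null(basic$logs[[1]]$logs[[1]]$stderr)
  expect_null(basic$logs[[1]]$system_logs)
  expect_null(basic$inputs[[1]]$content)
  # everything non-bulky survives
  expect_identical(basic$logs[[1]]$logs[[1]]$exit_code, 0L)
  expect_identical(basic$name, "proj-example")
  expect_identical(basic$logs[[1]]$outputs, rec$logs[[1]]$outputs)
})

test_that("view field sets are strictly nested: MINIMAL < BASIC < FULL", {
  rec <- seeded_record()
  fp <- function(level) sort(tesr:::field_paths(tes_project_view(rec, level)))
  m <- fp("MINIMAL"); b <- fp("BASIC"); f <- fp("FULL")
  expect_true(all(m %in% b) && length(m) < length(b))
  expect_true(all(b %in% f) && length(b) < length(f))
})

test_that("canonical serialization keeps length-1 arrays as arrays", {
  spec <- tes_validate_task(list(
    executors = list(list(image = "a", command = "true")),
    volumes = list("/vol")
  ))
  j <- tes_serialize_task(spec)
  expect_match(j, '"command":\\["true"\\]')
  expect_match(j, '"volumes":\\["/vol"\\]')
})
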