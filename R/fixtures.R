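#' @title Fixture-task generator
#' @description
#' Deterministic synthetic tasks so every layer of the service is testable
#' with no network and no external data. Generators are pure functions of
#' `(profile, seed)`; disk side effects (the `io` profile's source trees)
#' are confined to a caller-supplied scratch directory.
#' @name fixtures
NULL

with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

rand_name <- function(n = 8) {
  paste(sample(c(letters, 0:9), n, replace = TRUE), collapse = "")
}

#' Generate a random file tree
#'
#' Builds a seeded tree of nested directories and small text files under
#' `dir` — the source material for directory-staging fidelity checks.
#'
#' @param dir target directory (created).
#' @param depth maximum nesting depth.
#' @param files number of files to scatter over the tree.
#' @param seed RNG seed.
#' @return `dir`, invisibly.
#' @export
tes_random_tree <- function(dir, depth = 2L, files = 5L, seed = 1L) {
  with_seed(seed, {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dirs <- dir
    for (d in seq_len(depth)) {
      parent <- sample(dirs, 1)
      nd <- file.path(parent, paste0("d", d, "-", rand_name(4)))
      dir.create(nd, showWarnings = FALSE)
      dirs <- c(dirs, nd)
    }
    for (i in seq_len(files)) {
      f <- file.path(sample(dirs, 1), paste0("f", i, "-", rand_name(4), ".txt"))
      writeLines(replicate(sample(1:5, 1), rand_name(20)), f)
    }
  })
  invisible(dir)
}

#' Generate a deterministic fixture task
#'
#' Profiles:
#' * `noop` — one executor running `true`; completes immediately.
#' * `fail` — one executor exiting with `exit_code`.
#' * `sleep` — one executor sleeping `seconds` (cancellation tests).
#' * `multi_exec` — one `sh -c "exit k"` executor per entry of `exits`,
#'   with per-executor `ignore_error` flags (early-termination tests).
#' * `io` — materializes a seeded source tree under `scratch_dir`,
#'   declares it as a DIRECTORY input, copies it to the output location in
#'   the executor, and declares a DIRECTORY output back into
#'   `scratch_dir`; the source and export host paths are attached as
#'   attributes `io_source` and `io_export`.
#'
#' Same `(profile, seed, ...)` always yields the identical spec, and every
#' generated spec passes [tes_validate_task()].
#'
#' @param profile one of `"noop"`, `"fail"`, `"sleep"`, `"io"`,
#'   `"multi_exec"`.
#' @param seed RNG seed fixing all randomness.
#' @param exit_code for `fail`.
#' @param seconds for `sleep`.
#' @param depth,files for `io`'s source tree.
#' @param scratch_dir for `io`: host directory for source/export trees.
#' @param exits,ignores for `multi_exec`.
#' @return a validated `tes_task`.
#' @export
tes_fixture_task <- function(profile = c("noop", "fail", "sleep", "io",
                                         "multi_exec"),
                             seed = 1L, exit_code = 1L, seconds = 1,
                             depth = 2L, files = 5L, scratch_dir = NULL,
                             exits = c(0L, 0L), ignores = NULL) {
  profile <- match.arg(profile)
  doc <- with_seed(seed, {
    base <- list(
      name = paste0(profile, "-", seed, "-", rand_name(6)),
      tags = list(fixture_profile = profile, fixture_seed = as.character(seed))
    )
    switch(profile,
      noop = c(base, list(
        executors = list(list(image = "alpine", command = list("true")))
      )),
      fail = c(base, list(
        executors = list(list(
          image = "alpine",
          command = list("sh", "-c", sprintf("exit %d", exit_code))
        ))
      )),
      sleep = c(base, list(
        executors = list(list(
          image = "alpine",
          command = list("sleep", as.character(seconds))
        ))
      )),
      multi_exec = {
        ignores <- ignores %||% rep(FALSE, length(exits))
        stopifnot(length(ignores) == length(exits))
        c(base, list(
          executors = lapply(seq_along(exits), function(i) {
            list(image = "alpine",
                 command = list("sh", "-c", sprintf("exit %d", exits[[i]])),
                 ignore_error = isTRUE(ignores[[i]]))
          })
        ))
      },
      io = {
        scratch_dir <- scratch_dir %||% tempfile("tes-fixture-")
        src <- file.path(scratch_dir, sprintf("src-%d", seed))
        exp <- file.path(scratch_dir, sprintf("export-%d", seed))
        tes_random_tree(src, depth = depth, files = files, seed = seed)
        c(base, list(
          inputs = list(list(url = paste0("file://", src),
                             path = "/data/in", type = "DIRECTORY")),
          outputs = list(list(url = paste0("file://", exp),
                              path = "/results", type = "DIRECTORY")),
          executors = list(list(
            image = "alpine",
            command = list("sh", "-c",
                           "mkdir -p results && cp -r data/in/. results/")
          ))
        ))
      }
    )
  })
  spec <- tes_validate_task(doc)
  if (profile == "io") {
    attr(spec, "io_source") <- file.path(scratch_dir %||% "",
                                         sprintf("src-%d", seed))
    attr(spec, "io_export") <- file.path(scratch_dir %||% "",
                                         sprintf("export-%d", seed))
  }
  spec
}

#' Generate a random valid task spec
#'
#' Draws a task uniformly-ish over the message type's invariants — random
#' name, tags, resources, inline-content and file-URL inputs, outputs,
#' and a random executor list with env maps and stdio mappings. Used for
#' round-trip and projection property tests.
#'
#' @param seed RNG seed.
#' @return a validated `tes_task`.
#' @export
tes_random_task <- function(seed = 1L) {
  doc <- with_seed(seed, {
    n_exec <- sample(1:3, 1)
    executors <- lapply(seq_len(n_exec), function(i) {
      e <- list(image = paste0("img/", rand_name(5), ":latest"),
                command = as.list(c("sh", "-c", rand_name(12))))
      if (stats::runif(1) < 0.5) {
        k <- sample(1:3, 1)
        e$env <- stats::setNames(as.list(replicate(k, rand_name(6))),
                                 replicate(k, rand_name(4)))
        e$env <- e$env[!duplicated(names(e$env))]
      }
      if (stats::runif(1) < 0.3) e$workdir <- paste0("/", rand_name(4))
      if (stats::runif(1) < 0.3) e$stdout <- paste0("/out/", rand_name(4), ".log")
      if (stats::runif(1) < 0.5) e$ignore_error <- stats::runif(1) < 0.5
      e
    })
    inputs <- lapply(seq_len(sample(0:3, 1)), function(i) {
      io <- list(path = paste0("/in/", rand_name(5)))
      if (stats::runif(1) < 0.5) io$content <- rand_name(20)
      else {
        io$url <- paste0("file:///srv/", rand_name(5))
        if (stats::runif(1) < 0.3) io$type <- "DIRECTORY"
      }
      io
    })
    outputs <- lapply(seq_len(sample(0:2, 1)), function(i) {
      list(url = paste0("file:///dst/", rand_name(5)),
           path = paste0("/out/", rand_name(5)))
    })
    doc <- list(executors = executors)
    if (length(inputs) > 0) doc$inputs <- inputs
    if (length(outputs) > 0) doc$outputs <- outputs
    if (stats::runif(1) < 0.8) doc$name <- rand_name(10)
    if (stats::runif(1) < 0.5) doc$description <- rand_name(30)
    if (stats::runif(1) < 0.5) {
      tg <- stats::setNames(as.list(replicate(2, rand_name(6))),
                            c(rand_name(3), rand_name(5)))
      doc$tags <- tg[!duplicated(names(tg))]
    }
    if (stats::runif(1) < 0.5) {
      doc$resources <- list(cpu_cores = sample(1:8, 1),
                            ram_gb = round(stats::runif(1, 0.5, 16), 2),
                            preemptible = stats::runif(1) < 0.5)
    }
    if (stats::runif(1) < 0.3) doc$volumes <- list(paste0("/vol/", rand_name(4)))
    doc
  })
  tes_validate_task(doc)
}
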