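#' @title Executor engine
#' @description
#' A task carries an ordered list of executors — one command-line
#' invocation each, with its own container image, working directory,
#' stdio mapping, and environment variables. Executors run sequentially,
#' one at a time, sharing the staged inputs, outputs, and volumes. A
#' nonzero exit code from an executor whose `ignore_error` flag is unset
#' (the default) ends the sequence early and fails the task; with
#' `ignore_error = TRUE` the exit code is recorded but the sequence
#' continues.
#'
#' Execution backends implement the *runner* contract: `start(image,
#' command, wd, env, stdin, stdout_file, stderr_file)` returning a process
#' handle with `poll()` (exit code or `NULL` while alive), `signal_stop()`
#' (polite termination), and `kill()` (hard kill). The default backend is a
#' sandboxed host subprocess that records the image without enforcing it,
#' so the whole service runs with no container daemon; a container backend
#' (`docker`-compatible CLI) is selected by configuration.
#' @name executor-engine
NULL

#' Default stdio tail bound (bytes per stream)
#'
#' Executor logs carry only the last `TES_TAIL_BYTES` of each stream so
#' FULL task documents stay bounded; full streams are available in mapped
#' stdout/stderr files.
#'
#' @export
TES_TAIL_BYTES <- 65536L

#' Subprocess runner
#'
#' Runs executor commands as host subprocesses inside the workspace. The
#' container image reference is recorded in the task document but not
#' enforced. The base environment is hermetic: only `PATH`, `HOME`
#' (pointing into the workspace), and `TES_WORKSPACE` are set before the
#' executor's own `env` map is overlaid.
#'
#' @return a `tes_runner`.
#' @export
tes_subprocess_runner <- function() {
  start <- function(image, command, wd, env, stdin, stdout_file, stderr_file) {
    p <- processx::process$new(
      command = command[[1]], args = command[-1], wd = wd,
      env = env, stdin = stdin, stdout = stdout_file, stderr = stderr_file,
      cleanup = TRUE
    )
    list(
      poll = function() if (p$is_alive()) NULL else p$get_exit_status(),
      signal_stop = function() tryCatch(p$signal(15L), error = function(e) NULL),
      kill = function() tryCatch(p$kill(), error = function(e) NULL)
    )
  }
  structure(list(start = start, kind = "subprocess"), class = "tes_runner")
}

#' Container runner
#'
#' Runs each executor through a `docker`-compatible CLI with the workspace
#' bind-mounted at its own host path, so container-absolute workspace
#' paths resolve identically inside and outside the container. Selected by
#' service configuration (`runner = "container"`); requires a container
#' daemon on the host.
#'
#' @param engine CLI binary name (`"docker"`, `"podman"`, ...).
#' @return a `tes_runner`.
#' @export
tes_container_runner <- function(engine = "docker") {
  start <- function(image, command, wd, env, stdin, stdout_file, stderr_file) {
    args <- c("run", "--rm", "-v", paste0(wd, ":", wd), "-w", wd)
    for (k in names(env)) args <- c(args, "-e", paste0(k, "=", env[[k]]))
    args <- c(args, image, command)
    p <- processx::process$new(
      command = engine, args = args,
      stdin = stdin, stdout = stdout_file, stderr = stderr_file,
      cleanup = TRUE
    )
    list(
      poll = function() if (p$is_alive()) NULL else p$get_exit_status(),
      signal_stop = function() tryCatch(p$signal(15L), error = function(e) NULL),
      kill = function() tryCatch(p$kill(), error = function(e) NULL)
    )
  }
  structure(list(start = start, kind = "container"), class = "tes_runner")
}

#' Scripted runner (test backend)
#'
#' A runner whose "processes" finish instantly with a scripted exit-code
#' sequence and never touch the host. Useful for exercising sequence
#' semantics, the lifecycle state machine, and fault injection without
#' spawning real subprocesses: an exit code of `NA` makes `start` itself
#' fail, modelling a spawn/image-pull fault (a system error, distinct from
#' a nonzero exit).
#'
#' @param exits integer vector consumed one per started executor (recycled
#'   never; running past the end fails the call). `NA` entries raise a
#'   spawn fault.
#' @param stdout_text optional text each fake process writes to its stdout
#'   mapping.
#' @return a `tes_runner`; `$state$spawned` counts started processes.
#' @export
tes_script_runner <- function(exits, stdout_text = NULL) {
  state <- new.env(parent = emptyenv())
  state$i <- 0L
  state$spawned <- 0L
  start <- function(image, command, wd, env, stdin, stdout_file, stderr_file) {
    state$i <- state$i + 1L
    if (state$i > length(exits)) stop("script runner exhausted")
    code <- exits[[state$i]]
    if (is.na(code)) stop("scripted spawn fault")
    state$spawned <- state$spawned + 1L
    if (!is.null(stdout_text) && !is.null(stdout_file)) {
      cat(stdout_text, file = stdout_file)
    }
    list(
      poll = function() as.integer(code),
      signal_stop = function() NULL,
      kill = function() NULL
    )
  }
  structure(list(start = start, kind = "script", state = state),
            class = "tes_runner")
}

# Resolve executor stdio/workdir against the workspace and start the
# process. Returns the in-flight execution record used by both the
# blocking API below and the service's asynchronous scheduler.
exec_start <- function(e, ws, runner, index = 1L) {
  wd <- if (!is.null(e$workdir)) ws$map(e$workdir) else ws$root
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)
  log_dir <- paste0(ws$root, ".logs")
  dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
  stdin_host <- if (!is.null(e$stdin)) ws$map(e$stdin) else NULL
  stdout_host <- if (!is.null(e$stdout)) ws$map(e$stdout) else
    file.path(log_dir, sprintf("exec-%d.out", index))
  stderr_host <- if (!is.null(e$stderr)) ws$map(e$stderr) else
    file.path(log_dir, sprintf("exec-%d.err", index))
  dir.create(dirname(stdout_host), recursive = TRUE, showWarnings = FALSE)
  dir.create(dirname(stderr_host), recursive = TRUE, showWarnings = FALSE)

  base_env <- c(PATH = Sys.getenv("PATH"), HOME = ws$root,
                TES_WORKSPACE = ws$root)
  env <- utils::modifyList(as.list(base_env), as.list(e$env %||% list()))
  env <- unlist(env)

  handle <- tryCatch(
    runner$start(e$image, e$command, wd, env, stdin_host, stdout_host,
                 stderr_host),
    error = function(err) {
      tes_abort(
        paste0("failed to start executor: ", conditionMessage(err)),
        "tes_runner_fault", cause = err
      )
    }
  )
  list(
    handle = handle, executor = e, index = index,
    stdout_file = stdout_host, stderr_file = stderr_host,
    start_time = tes_timestamp()
  )
}

# Finalize an execution record into an ExecutorLog once poll() is non-NULL.
exec_finish <- function(ex, exit_code, tail_bytes = TES_TAIL_BYTES) {
  list(
    start_time = ex$start_time,
    end_time = tes_timestamp(),
    stdout = read_tail(ex$stdout_file, tail_bytes),
    stderr = read_tail(ex$stderr_file, tail_bytes),
    exit_code = as.integer(exit_code)
  )
}

#' Run a single executor to completion
#'
#' Blocking convenience over the runner contract: the command runs with
#' its working directory defaulting to the workspace root, the executor's
#' `env` overlaid on a minimal hermetic base, stdin read from its mapping
#' if set, and stdout/stderr written to their mappings if set *and*
#' tail-captured into the log. The exit code is recorded verbatim — a
#' nonzero exit is data, not an error; only spawn failures raise
#' `tes_runner_fault`.
#'
#' @param e a validated executor.
#' @param ws a [tes_workspace()].
#' @param runner a `tes_runner`.
#' @param index position of the executor in its sequence (names unmapped
#'   stdio capture files).
#' @param tail_bytes stdio tail bound.
#' @return an executor log: `list(start_time, end_time, stdout, stderr,
#'   exit_code)`.
#' @export
tes_run_executor <- function(e, ws, runner, index = 1L,
                             tail_bytes = TES_TAIL_BYTES) {
  ex <- exec_start(e, ws, runner, index)
  repeat {
    code <- ex$handle$poll()
    if (!is.null(code)) break
    Sys.sleep(0.002)
  }
  exec_finish(ex, code, tail_bytes)
}

#' Run an ordered executor sequence
#'
#' Executors run strictly one at a time, in order. A nonzero exit from an
#' executor with `ignore_error = FALSE` stops the sequence (`outcome =
#' "FAILED"`, `failed_index` set, later executors never spawned); with
#' `ignore_error = TRUE` the sequence continues past the failure. The
#' outcome is `"OK"` iff every non-ignored executor exited zero. A spawn
#' fault (`tes_runner_fault`) propagates immediately.
#'
#' @param executors non-empty list of validated executors.
#' @param ws a [tes_workspace()].
#' @param runner a `tes_runner`.
#' @param tail_bytes stdio tail bound.
#' @return `list(executor_logs =, outcome = "OK"|"FAILED", failed_index =
#'   <1-based index of the fatal executor, or NULL>)`. When the sequence
#'   fails without `ignore_error`, `length(executor_logs) == failed_index`.
#' @export
tes_run_sequence <- function(executors, ws, runner,
                             tail_bytes = TES_TAIL_BYTES) {
  stopifnot(length(executors) >= 1L)
  logs <- vector("list", 0L)
  outcome <- "OK"
  failed_index <- NULL
  for (i in seq_along(executors)) {
    e <- executors[[i]]
    log <- tes_run_executor(e, ws, runner, index = i,
                            tail_bytes = tail_bytes)
    logs[[length(logs) + 1L]] <- log
    if (log$exit_code != 0L && !isTRUE(e$ignore_error)) {
      outcome <- "FAILED"
      failed_index <- i
      break
    }
  }
  list(executor_logs = logs, outcome = outcome, failed_index = failed_index)
}
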