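#' @title The TES service: lifecycle and worker scheduling
#' @description
#' `TesService` ties the store, the staging layer, and the executor engine
#' into the task lifecycle: a submitted task is persisted `QUEUED`, claimed
#' by a worker slot (`INITIALIZING`: workspace creation, input staging),
#' runs its executor sequence (`RUNNING`), has its declared outputs
#' exported, and ends in exactly one terminal state. Every fault is mapped
#' to a terminal state plus a system-log line — nothing escapes the worker
#' loop. The workspace is always destroyed on the way out.
#'
#' Scheduling is a cooperative event loop inside one R process: the worker
#' pool is `pool_size` concurrent task slots whose executor processes run
#' asynchronously and are advanced by [`poll()`][TesService]. Claiming is a
#' compare-and-set on `QUEUED -> INITIALIZING` through the store's
#' transition check, so a task is executed at most once. Staging proceeds
#' one input per poll, which lets a cancellation interrupt staging between
#' inputs rather than mid-transfer.
#' @name lifecycle
NULL

#' TES service instance
#'
#' @examples
#' svc <- TesService$new(runner = tes_script_runner(0L))
#' id <- svc$submit(list(executors = list(list(image = "alpine",
#'                                             command = "true"))))
#' svc$run_until_idle()
#' svc$store$get(id)$state  # "COMPLETE"
#' @export
TesService <- R6::R6Class(
  "TesService",
  public = list(
    #' @field store the task store (single source of truth for state).
    store = NULL,
    #' @field registry the protocol-handler registry.
    registry = NULL,
    #' @field runner the execution backend.
    runner = NULL,
    #' @field config service configuration list.
    config = NULL,

    #' @description Assemble a service.
    #' @param store a [TaskStore] (default: fresh in-memory store).
    #' @param registry a [tes_protocol_registry()].
    #' @param runner a `tes_runner` (default: subprocess backend).
    #' @param work_root host directory for task workspaces.
    #' @param pool_size worker slots (concurrent tasks), default 4.
    #' @param tail_bytes stdio tail bound, default 64 KiB.
    #' @param grace_period seconds between polite stop and hard kill on
    #'   cancellation, default 10.
    #' @param staging_retries,staging_retry_delay per-input retry policy.
    #' @param name,organization service identity for `/service-info`.
    initialize = function(store = NULL, registry = NULL, runner = NULL,
                          work_root = NULL, pool_size = 4L,
                          tail_bytes = TES_TAIL_BYTES, grace_period = 10,
                          staging_retries = 2L, staging_retry_delay = 0.5,
                          name = "tesr", organization = "tesr authors") {
      self$store <- store %||% TaskStore$new()
      self$registry <- registry %||% tes_protocol_registry()
      self$runner <- runner %||% tes_subprocess_runner()
      self$config <- list(
        work_root = work_root %||% tempfile("tes-work-"),
        pool_size = as.integer(pool_size),
        tail_bytes = as.integer(tail_bytes),
        grace_period = grace_period,
        staging_retries = staging_retries,
        staging_retry_delay = staging_retry_delay,
        name = name, organization = organization
      )
      dir.create(self$config$work_root, recursive = TRUE,
                 showWarnings = FALSE)
      private$queue <- character(0)
      private$active <- list()
      private$seq_starts <- new.env(parent = emptyenv())
    },

    #' @description Validate, persist, and enqueue a task. Asynchronous:
    #'   returns the id immediately; the worker loop drives execution.
    #' @param task a raw task document or a validated `tes_task`.
    #' @return the assigned task id.
    submit = function(task) {
      spec <- if (inherits(task, "tes_task")) task else tes_validate_task(task)
      id <- self$store$create(spec)
      private$queue <- c(private$queue, id)
      id
    },

    #' @description Request cancellation. A `QUEUED` task is canceled
    #'   immediately (never picked up); a live task moves to `CANCELING`
    #'   and the worker tears the attempt down (polite stop, hard kill
    #'   after the grace period). Canceling a terminal task is an
    #'   idempotent no-op.
    #' @param id task id.
    #' @return the task's state after acknowledgment.
    cancel = function(id) {
      doc <- self$store$get(id)
      state <- doc$state
      if (tes_is_terminal(state)) return(state)
      if (state == "QUEUED") {
        private$queue <- setdiff(private$queue, id)
        self$store$update_state(id, "CANCELED")
        private$syslog(id, "canceled while queued")
        return("CANCELED")
      }
      if (state %in% c("INITIALIZING", "RUNNING")) {
        self$store$update_state(id, "CANCELING")
        private$syslog(id, "cancellation requested")
        return("CANCELING")
      }
      state  # CANCELING: already on its way out
    },

    #' @description One scheduler tick: claim queued tasks into free worker
    #'   slots and advance every active attempt (stage one input, poll the
    #'   running executor, start the next executor, export outputs, settle
    #'   terminal states).
    #' @return number of attempts still active.
    poll = function() {
      while (length(private$active) < self$config$pool_size &&
             length(private$queue) > 0L) {
        id <- private$queue[[1]]
        private$queue <- private$queue[-1]
        if (!self$store$exists(id)) next
        if (self$store$get(id)$state != "QUEUED") next  # canceled while queued
        private$claim(id)
      }
      for (id in names(private$active)) private$advance(id)
      length(private$active)
    },

    #' @description Drive the scheduler until the queue is empty and no
    #'   attempt is active.
    #' @param timeout seconds before giving up (a `tes_timeout` error).
    run_until_idle = function(timeout = 600) {
      deadline <- now_num() + timeout
      while (length(private$queue) > 0L || length(private$active) > 0L) {
        n <- self$poll()
        if (now_num() > deadline) {
          tes_abort("run_until_idle timed out", "tes_timeout")
        }
        if (n > 0L) Sys.sleep(0.001)
      }
      invisible(NULL)
    },

    #' @description Synchronously execute one queued task to its terminal
    #'   state (claims it ahead of the queue).
    #' @param id a `QUEUED` task id.
    #' @param timeout seconds.
    #' @return the terminal state.
    worker_run = function(id, timeout = 600) {
      if (id %in% private$queue) {
        private$queue <- c(id, setdiff(private$queue, id))
      }
      deadline <- now_num() + timeout
      repeat {
        self$poll()
        s <- self$store$get(id)$state
        if (tes_is_terminal(s)) return(s)
        if (now_num() > deadline) {
          tes_abort("worker_run timed out", "tes_timeout")
        }
        Sys.sleep(0.001)
      }
    },

    #' @description The `/service-info` document.
    service_info = function() {
      list(
        id = "org.tesr.server",
        name = self$config$name,
        type = list(group = "org.ga4gh", artifact = "tes",
                    version = "1.1.0"),
        description = "Task Execution Service implemented in R",
        organization = list(name = self$config$organization,
                            url = "https://example.org"),
        version = as.character(utils::packageVersion("tesr")),
        storage = I(tes_supported_protocols(self$registry))
      )
    },

    #' @description How many times an executor sequence was started for a
    #'   task (diagnostic; the at-most-once property says this never
    #'   exceeds 1).
    #' @param id task id.
    sequence_starts = function(id) {
      private$seq_starts[[id]] %||% 0L
    },

    #' @description Ids currently queued (FIFO order).
    queued_ids = function() private$queue,

    #' @description Ids of attempts currently holding a worker slot.
    active_ids = function() names(private$active)
  ),

  private = list(
    queue = NULL,
    active = NULL,
    seq_starts = NULL,

    syslog = function(id, msg) {
      line <- paste0(tes_timestamp(), " ", msg)
      self$store$modify(id, function(doc) {
        if (length(doc$logs) == 0L) {
          doc$logs <- list(list(logs = list(), system_logs = character(0)))
        }
        k <- length(doc$logs)
        doc$logs[[k]]$system_logs <- c(doc$logs[[k]]$system_logs %||%
                                         character(0), line)
        doc
      })
      invisible(NULL)
    },

    claim = function(id) {
      claimed <- tryCatch({
        self$store$update_state(id, "INITIALIZING")  # CAS: single ownership
        TRUE
      }, tes_illegal_transition = function(e) FALSE)
      if (!claimed) return(invisible(NULL))
      doc <- self$store$get(id)
      spec <- doc[intersect(TASK_FIELDS, names(doc))]
      ws <- tes_workspace(self$config$work_root, id, 1L)
      self$store$modify(id, function(d) {
        d$logs <- c(d$logs, list(list(
          logs = list(), start_time = tes_timestamp(),
          system_logs = character(0)
        )))
        d
      })
      att <- new.env(parent = emptyenv())
      att$id <- id
      att$spec <- spec
      att$ws <- ws
      att$phase <- "staging"
      att$staged_i <- 0L
      att$volumes_done <- FALSE
      att$exec_i <- 0L
      att$ex <- NULL
      att$cancel_deadline <- NULL
      private$active[[id]] <- att
      invisible(NULL)
    },

    advance = function(id) {
      att <- private$active[[id]]
      if (is.null(att)) return(invisible(NULL))
      state <- self$store$get(id)$state
      if (att$phase == "staging") private$advance_staging(att, state)
      else private$advance_running(att, state)
      invisible(NULL)
    },

    advance_staging = function(att, state) {
      if (state == "CANCELING") {
        private$syslog(att$id, "staging interrupted by cancellation")
        private$settle(att, "CANCELED")
        return(invisible(NULL))
      }
      if (!att$volumes_done) {
        res <- tryCatch({
          for (v in att$spec$volumes) {
            dir.create(att$ws$map(v), recursive = TRUE, showWarnings = FALSE)
          }
          # parent directories of declared outputs exist before user code
          # runs (the output itself must still be produced by the job)
          for (o in att$spec$outputs) {
            dir.create(dirname(att$ws$map(o$path)), recursive = TRUE,
                       showWarnings = FALSE)
          }
          TRUE
        }, tes_error = function(e) e)
        if (!isTRUE(res)) {
          private$syslog(att$id, paste0("staging failed: ",
                                        conditionMessage(res)))
          private$settle(att, "SYSTEM_ERROR")
          return(invisible(NULL))
        }
        att$volumes_done <- TRUE
      }
      if (att$staged_i < length(att$spec$inputs)) {
        i <- att$staged_i + 1L
        res <- tryCatch({
          stage_one_input(att$spec$inputs[[i]], i, att$ws, self$registry,
                          self$config$staging_retries,
                          self$config$staging_retry_delay)
          TRUE
        }, tes_error = function(e) e)
        if (!isTRUE(res)) {
          private$syslog(att$id, paste0("staging failed: ",
                                        conditionMessage(res)))
          private$settle(att, "SYSTEM_ERROR")
          return(invisible(NULL))
        }
        att$staged_i <- i
        if (att$staged_i < length(att$spec$inputs)) return(invisible(NULL))
      }
      # all inputs in place: move to RUNNING and start the first executor
      self$store$update_state(att$id, "RUNNING")
      att$phase <- "running"
      private$seq_starts[[att$id]] <-
        (private$seq_starts[[att$id]] %||% 0L) + 1L
      private$start_executor(att, 1L)
    },

    start_executor = function(att, i) {
      att$exec_i <- i
      res <- tryCatch(
        exec_start(att$spec$executors[[i]], att$ws, self$runner, index = i),
        tes_runner_fault = function(e) e
      )
      if (inherits(res, "tes_runner_fault")) {
        private$syslog(att$id, paste0("executor ", i - 1L, " spawn fault: ",
                                      conditionMessage(res)))
        private$settle(att, "SYSTEM_ERROR")
        return(invisible(NULL))
      }
      att$ex <- res
      invisible(NULL)
    },

    advance_running = function(att, state) {
      if (is.null(att$ex)) return(invisible(NULL))
      if (state == "CANCELING" && is.null(att$cancel_deadline)) {
        att$ex$handle$signal_stop()
        att$cancel_deadline <- now_num() + self$config$grace_period
      }
      if (!is.null(att$cancel_deadline) &&
          now_num() > att$cancel_deadline) {
        att$ex$handle$kill()
      }
      code <- att$ex$handle$poll()
      if (is.null(code)) return(invisible(NULL))

      log <- exec_finish(att$ex, code, self$config$tail_bytes)
      att$ex <- NULL
      self$store$modify(att$id, function(d) {
        k <- length(d$logs)
        d$logs[[k]]$logs <- c(d$logs[[k]]$logs, list(log))
        d
      })

      if (state == "CANCELING") {
        private$syslog(att$id,
                       paste0("executor ", att$exec_i - 1L,
                              " terminated by cancellation"))
        private$settle(att, "CANCELED")
        return(invisible(NULL))
      }
      e <- att$spec$executors[[att$exec_i]]
      if (log$exit_code != 0L && !isTRUE(e$ignore_error)) {
        private$syslog(att$id, paste0("executor ", att$exec_i - 1L,
                                      " exited ", log$exit_code))
        private$settle(att, "EXECUTOR_ERROR")
        return(invisible(NULL))
      }
      if (att$exec_i < length(att$spec$executors)) {
        private$start_executor(att, att$exec_i + 1L)
        return(invisible(NULL))
      }
      private$finish_outputs(att)
    },

    finish_outputs = function(att) {
      res <- tryCatch(
        tes_collect_outputs(att$spec, att$ws, self$registry),
        tes_missing_output = function(e) e,
        tes_export_error = function(e) e
      )
      if (inherits(res, "tes_missing_output")) {
        private$syslog(att$id, conditionMessage(res))
        private$settle(att, "EXECUTOR_ERROR")
      } else if (inherits(res, "tes_export_error")) {
        private$syslog(att$id, conditionMessage(res))
        private$settle(att, "SYSTEM_ERROR")
      } else {
        self$store$modify(att$id, function(d) {
          k <- length(d$logs)
          d$logs[[k]]$outputs <- res
          d
        })
        private$settle(att, "COMPLETE")
      }
      invisible(NULL)
    },

    # Map the attempt into its terminal state (via CANCELING when needed),
    # stamp the attempt end time, destroy the workspace, free the slot.
    settle = function(att, terminal) {
      cur <- self$store$get(att$id)$state
      if (terminal == "CANCELED") {
        if (cur != "CANCELING") self$store$update_state(att$id, "CANCELING")
        self$store$update_state(att$id, "CANCELED")
      } else {
        self$store$update_state(att$id, terminal)
      }
      self$store$modify(att$id, function(d) {
        k <- length(d$logs)
        d$logs[[k]]$end_time <- tes_timestamp()
        d
      })
      private$syslog(att$id, paste0("task settled: ", terminal))
      destroy_workspace(att$ws)
      private$active[[att$id]] <- NULL
      invisible(NULL)
    }
  )
)
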