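#' @title Programmatic TES client
#' @description
#' `TesClient` speaks the TES HTTP contract against any base URL (over
#' curl), or directly against an in-process [TesService] through the same
#' request dispatcher the HTTP server mounts. Transport failures
#' (`tes_connection_error`) are distinguished from API errors
#' (`tes_api_error`, carrying the status code and server message).
#' @name client
NULL

#' In-process transport
#'
#' Routes client requests straight into a service's request dispatcher.
#' Each request first gives the service's worker scheduler one poll, so
#' task execution progresses as an in-process client interacts with it —
#' the same interleaving the HTTP serve loop provides.
#'
#' @param service a [TesService].
#' @param prefix mount prefix.
#' @return a transport function.
#' @export
tes_local_transport <- function(service, prefix = TES_URL_PREFIX) {
  function(method, path, query = list(), body = NULL) {
    service$poll()
    res <- tes_handle(service, method, path, query, body, prefix = prefix)
    list(status = res$status, text = tes_response_json(res$body))
  }
}

#' HTTP transport over curl
#'
#' @param base_url e.g. `"http://127.0.0.1:8170"` (no trailing slash, no
#'   prefix — the client appends the mount prefix).
#' @return a transport function.
#' @export
tes_http_transport <- function(base_url) {
  base_url <- sub("/+$", "", base_url)
  function(method, path, query = list(), body = NULL) {
    url <- paste0(base_url, path, build_query(query))
    h <- curl::new_handle()
    if (method == "POST") {
      curl::handle_setopt(h, post = TRUE,
                          postfields = body %||% "",
                          copypostfields = body %||% "")
      curl::handle_setheaders(h, "Content-Type" = "application/json")
    }
    res <- tryCatch(
      curl::curl_fetch_memory(url, handle = h),
      error = function(e) {
        tes_abort(paste0("cannot reach TES server: ", conditionMessage(e)),
                  "tes_connection_error", cause = e)
      }
    )
    list(status = res$status_code, text = rawToChar(res$content))
  }
}

# Per-index template substitution for array submission: "-<i>" name
# suffix, a tes_array_index tag, and "{index}" replacement in executor
# command arguments and env values.
array_member_spec <- function(template, i) {
  spec <- unclass(template)
  spec$name <- paste0(spec$name %||% "task", "-", i)
  spec$tags$tes_array_index <- as.character(i)
  spec$executors <- lapply(spec$executors, function(e) {
    e$command <- gsub("{index}", as.character(i), e$command, fixed = TRUE)
    if (length(e$env) > 0L) {
      e$env <- lapply(e$env, function(v) {
        gsub("{index}", as.character(i), v, fixed = TRUE)
      })
    }
    e
  })
  structure(spec, class = "tes_task")
}

#' TES API client
#'
#' @examples
#' svc <- TesService$new(runner = tes_script_runner(c(0L, 0L)))
#' cl <- TesClient$new(service = svc)
#' id <- cl$create(list(executors = list(list(image = "alpine",
#'                                            command = "true"))))
#' cl$wait(id, poll_interval = 0)  # "COMPLETE"
#' @export
TesClient <- R6::R6Class(
  "TesClient",
  public = list(
    #' @description Connect to a server URL or wrap an in-process service.
    #' @param url base URL of a TES server (mutually exclusive with
    #'   `service`).
    #' @param service a [TesService] for in-process use.
    #' @param prefix mount prefix, default [TES_URL_PREFIX].
    initialize = function(url = NULL, service = NULL,
                          prefix = TES_URL_PREFIX) {
      if (is.null(url) == is.null(service)) {
        stop("provide exactly one of url, service")
      }
      private$prefix <- prefix
      private$transport <- if (!is.null(url)) tes_http_transport(url)
        else tes_local_transport(service, prefix)
    },

    #' @description Submit a task.
    #' @param task a task document (list, `tes_task`, or JSON string).
    #' @return the assigned task id.
    create = function(task) {
      body <- if (is_string(task)) task else
        tes_serialize_task(if (inherits(task, "tes_task")) task else
                             tes_validate_task(task))
      private$request("POST", "/tasks", body = body)$id
    },

    #' @description Retrieve a task document.
    #' @param id task id.
    #' @param view a [TES_VIEW_LEVELS] member.
    get = function(id, view = "MINIMAL") {
      private$request("GET", paste0("/tasks/", id), query = list(view = view))
    },

    #' @description One page of the task listing.
    #' @param state,name_prefix,tags filter (see [tes_task_filter()]).
    #' @param view projection level.
    #' @param page_size,page_token pagination controls.
    #' @return `list(tasks =, next_page_token = <or NULL>)`.
    list = function(state = NULL, name_prefix = NULL, tags = NULL,
                    view = "MINIMAL", page_size = NULL, page_token = NULL) {
      query <- list(view = view)
      if (!is.null(state)) query$state <- state
      if (!is.null(name_prefix)) query$name_prefix <- name_prefix
      if (!is.null(page_size)) query$page_size <- page_size
      if (!is.null(page_token)) query$page_token <- page_token
      for (k in names(tags)) {
        query <- c(query, list(tag_key = k), list(tag_value = tags[[k]]))
      }
      private$request("GET", "/tasks", query = query)
    },

    #' @description All pages of a filtered listing, concatenated.
    #' @param ... passed to `$list()`.
    list_all = function(...) {
      out <- list()
      token <- NULL
      repeat {
        page <- self$list(..., page_token = token)
        out <- c(out, page$tasks)
        token <- page$next_page_token
        if (is.null(token)) break
      }
      out
    },

    #' @description Request cancellation (idempotent).
    #' @param id task id.
    cancel = function(id) {
      private$request("POST", paste0("/tasks/", id, ":cancel"))
      invisible(id)
    },

    #' @description The server's `/service-info` document.
    service_info = function() {
      private$request("GET", "/service-info")
    },

    #' @description Poll a task (MINIMAL view) until it reaches a terminal
    #'   state.
    #' @param id task id.
    #' @param poll_interval seconds between polls (default 0.5, with
    #'   jitter; use 0 for an in-process service).
    #' @param timeout seconds before a `tes_timeout` error.
    #' @return the terminal state.
    wait = function(id, poll_interval = 0.5, timeout = 60) {
      deadline <- now_num() + timeout
      repeat {
        doc <- self$get(id, view = "MINIMAL")
        if (tes_is_terminal(doc$state)) return(doc$state)
        if (now_num() >= deadline) {
          tes_abort(paste0("timed out waiting for task ", id),
                    "tes_timeout", id = id, last_state = doc$state)
        }
        if (poll_interval > 0) {
          Sys.sleep(poll_interval * stats::runif(1, 0.8, 1.2))
        }
      }
    },

    #' @description Fan a task template out into an array of `n` tasks
    #'   (per-index name suffix `-0 ... -(n-1)`, a `tes_array_index` tag,
    #'   and `{index}` substitution in commands and env). Submissions are
    #'   sequential; a failed submission is recorded per index and does not
    #'   abort the rest.
    #' @param template a task document.
    #' @param n array size (>= 1).
    #' @return `list(ids = <character, NA where failed>, errors = <named
    #'   list index -> condition>)`.
    submit_array = function(template, n) {
      stopifnot(is_count(n), n >= 1)
      template <- if (inherits(template, "tes_task")) template else
        tes_validate_task(template)
      ids <- rep(NA_character_, n)
      errors <- list()
      for (i in seq_len(n)) {
        res <- tryCatch(
          self$create(array_member_spec(template, i - 1L)),
          tes_error = function(e) e
        )
        if (inherits(res, "condition")) {
          errors[[as.character(i - 1L)]] <- res
        } else {
          ids[[i]] <- res
        }
      }
      list(ids = ids, errors = errors)
    }
  ),
  private = list(
    transport = NULL,
    prefix = NULL,
    request = function(method, path, query = list(), body = NULL) {
      res <- private$transport(method, paste0(private$prefix, path),
                               query, body)
      parsed <- tryCatch(
        jsonlite::fromJSON(res$text, simplifyVector = FALSE),
        error = function(e) NULL
      )
      if (res$status >= 400L) {
        tes_abort(
          paste0("API error ", res$status, ": ",
                 parsed$message %||% res$text),
          "tes_api_error", status = res$status
        )
      }
      parsed
    }
  )
)
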