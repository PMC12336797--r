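#' @title The TES HTTP endpoints
#' @description
#' The public surface is exactly five routes, mounted under the standard
#' prefix `/ga4gh/tes/v1`:
#'
#' * `POST /tasks` — create a task, returns `{"id": ...}`
#' * `GET /tasks` — paginated, filtered, view-projected listing
#' * `GET /tasks/{id}` — retrieve one task at a view level
#' * `POST /tasks/{id}:cancel` — request cancellation (idempotent)
#' * `GET /service-info` — service identity and supported storage protocols
#'
#' Every response, success or error, is JSON; error bodies are uniform
#' `{"message": ..., "status_code": ...}` objects. Any other path is a 404.
#' @name http-api
NULL

#' Default URL mount prefix
#' @export
TES_URL_PREFIX <- "/ga4gh/tes/v1"

http_error <- function(status, message) {
  list(status = as.integer(status),
       body = list(message = message, status_code = as.integer(status)))
}

# Map a classed package condition to an HTTP error response.
condition_to_http <- function(e) {
  status <-
    if (inherits(e, c("tes_validation_error", "tes_parse_error",
                      "tes_invalid_page_token"))) 400L
    else if (inherits(e, "tes_not_found")) 404L
    else 500L
  http_error(status, conditionMessage(e))
}

# Positionally paired repeated tag_key/tag_value parameters -> tag map.
tags_from_query <- function(query) {
  keys <- unname(unlist(query[names(query) == "tag_key"]))
  vals <- unname(unlist(query[names(query) == "tag_value"]))
  if (length(keys) == 0L) return(NULL)
  if (length(vals) != length(keys)) {
    tes_abort("tag_key/tag_value parameters must be paired",
              "tes_validation_error", errors = "tag_value: unpaired")
  }
  stats::setNames(as.list(vals), keys)
}

query_scalar <- function(query, name) {
  v <- query[names(query) == name]
  if (length(v) == 0L) NULL else v[[length(v)]]
}

parse_view <- function(query) {
  view <- query_scalar(query, "view") %||% "MINIMAL"
  if (!(view %in% TES_VIEW_LEVELS)) {
    tes_abort(paste0("unknown view value: ", view), "tes_validation_error",
              errors = "view: unknown value")
  }
  view
}

#' Dispatch one API request against a service
#'
#' The transport-independent request handler: the httpuv app, the
#' in-process client transport, and the tests all go through this one
#' dispatcher, so HTTP semantics are identical on every path into the
#' service.
#'
#' @param service a [TesService].
#' @param method `"GET"` or `"POST"`.
#' @param path request path (including the mount prefix).
#' @param query named list of decoded query parameters (repeats preserved).
#' @param body request body as a string (for POST).
#' @param prefix mount prefix, default [TES_URL_PREFIX].
#' @return `list(status = <int>, body = <list>)`; the body serializes to
#'   the wire JSON via [tes_response_json()].
#' @export
tes_handle <- function(service, method, path, query = list(), body = NULL,
                       prefix = TES_URL_PREFIX) {
  if (!startsWith(path, paste0(prefix, "/"))) {
    return(http_error(404L, paste0("no such route: ", path)))
  }
  route <- substring(path, nchar(prefix) + 1L)

  tryCatch({
    if (method == "POST" && route == "/tasks") {
      spec <- tes_parse_task(body %||% "")
      id <- service$submit(spec)
      return(list(status = 200L, body = list(id = id)))
    }
    if (method == "GET" && route == "/tasks") {
      view <- parse_view(query)
      page_size <- query_scalar(query, "page_size")
      if (!is.null(page_size)) {
        ps <- suppressWarnings(as.numeric(page_size))
        if (is.na(ps)) {
          tes_abort("page_size must be a positive integer",
                    "tes_validation_error", errors = "page_size: not a number")
        }
        page_size <- ps
      }
      filter <- tes_task_filter(
        state = query_scalar(query, "state"),
        name_prefix = query_scalar(query, "name_prefix"),
        tags = tags_from_query(query)
      )
      page <- service$store$list_page(
        filter, page_size = page_size,
        page_token = query_scalar(query, "page_token"), view = view
      )
      resp <- list(tasks = lapply(page$tasks, canonical_task))
      if (!is.null(page$next_page_token)) {
        resp$next_page_token <- page$next_page_token
      }
      return(list(status = 200L, body = resp))
    }
    m <- regmatches(route, regexec("^/tasks/([A-Za-z0-9_-]+):cancel$", route))[[1]]
    if (method == "POST" && length(m) == 2L) {
      if (!service$store$exists(m[[2]])) {
        tes_abort(paste0("task not found: ", m[[2]]), "tes_not_found")
      }
      service$cancel(m[[2]])
      return(list(status = 200L,
                  body = stats::setNames(list(), character(0))))
    }
    m <- regmatches(route, regexec("^/tasks/([A-Za-z0-9_-]+)$", route))[[1]]
    if (method == "GET" && length(m) == 2L) {
      view <- parse_view(query)
      doc <- service$store$get(m[[2]])
      return(list(status = 200L,
                  body = canonical_task(tes_project_view(doc, view))))
    }
    if (method == "GET" && route == "/service-info") {
      return(list(status = 200L, body = service$service_info()))
    }
    http_error(404L, paste0("no such route: ", method, " ", path))
  }, tes_error = condition_to_http)
}

#' Serialize a dispatcher response body to JSON
#'
#' @param body the `body` element returned by [tes_handle()].
#' @return a JSON string.
#' @export
tes_response_json <- function(body) {
  as.character(json_out(body))
}

#' Build the httpuv application for a service
#'
#' @param service a [TesService].
#' @param prefix mount prefix.
#' @return an httpuv app list.
#' @export
tes_app <- function(service, prefix = TES_URL_PREFIX) {
  list(call = function(req) {
    body <- NULL
    if (!is.null(req$rook.input)) {
      raw <- req$rook.input$read()
      if (length(raw) > 0L) body <- rawToChar(raw)
    }
    res <- tes_handle(
      service,
      method = req$REQUEST_METHOD,
      path = req$PATH_INFO,
      query = parse_query(req$QUERY_STRING %||% ""),
      body = body,
      prefix = prefix
    )
    list(
      status = res$status,
      headers = list("Content-Type" = "application/json"),
      body = tes_response_json(res$body)
    )
  })
}

#' Serve the TES API over HTTP
#'
#' Starts an httpuv server and runs the combined event loop: socket
#' servicing interleaved with worker-scheduler polls, so task execution
#' progresses while requests are served. Blocks until `stop_when()` (if
#' given) returns `TRUE` or the process is interrupted.
#'
#' @param service a [TesService].
#' @param host,port listen address.
#' @param prefix mount prefix.
#' @param stop_when optional `function()` checked every loop iteration.
#' @param quiet suppress the startup message.
#' @export
tes_serve <- function(service, host = "127.0.0.1", port = 8170L,
                      prefix = TES_URL_PREFIX, stop_when = NULL,
                      quiet = FALSE) {
  srv <- httpuv::startServer(host, port, tes_app(service, prefix))
  on.exit(httpuv::stopServer(srv), add = TRUE)
  if (!quiet) {
    message(sprintf("tesr serving on http://%s:%d%s", host, port, prefix))
  }
  repeat {
    httpuv::service(10)
    service$poll()
    if (!is.null(stop_when) && isTRUE(stop_when())) break
  }
  invisible(NULL)
}
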