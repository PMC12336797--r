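# Shared test fixtures and oracles.

make_service <- function(...) {
  TesService$new(work_root = withr::local_tempdir(.local_envir = parent.frame()),
                 ...)
}

# Independent brute-force listing oracle: a linear scan over every stored
# record with its own predicate and ordering logic (creation_time
# descending, id ascending), kept deliberately separate from the store's
# implementation.
brute_force_ids <- function(store, state = NULL, name_prefix = NULL,
                            tags = NULL) {
  ids <- store$ids()
  docs <- lapply(ids, store$get)
  keep <- vapply(docs, function(d) {
    if (!is.null(state) && !identical(d$state, state)) return(FALSE)
    if (!is.null(name_prefix)) {
      nm <- if (is.null(d$name)) "" else d$name
      if (substr(nm, 1, nchar(name_prefix)) != name_prefix) return(FALSE)
    }
    for (k in names(tags)) {
      if (!identical(d$tags[[k]], tags[[k]])) return(FALSE)
    }
    TRUE
  }, logical(1))
  docs <- docs[keep]
  if (length(docs) == 0L) return(character(0))
  ct <- vapply(docs, function(d) d$creation_time, character(1))
  id <- vapply(docs, function(d) d$id, character(1))
  # RFC 3339 UTC strings sort chronologically as strings
  ord <- order(ct, id, decreasing = c(TRUE, FALSE), method = "radix")
  id[ord]
}

# Walk every page of a store listing, returning the projected ids in order.
paged_ids <- function(store, filter, page_size, view = "MINIMAL") {
  out <- character(0)
  token <- NULL
  repeat {
    page <- store$list_page(filter, page_size = page_size,
                            page_token = token, view = view)
    out <- c(out, vapply(page$tasks, function(t) t$id, character(1)))
    token <- page$next_page_token
    if (is.null(token)) break
  }
  out
}

# Content fingerprint of a directory tree: relative paths + md5 of bytes.
tree_hash <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, all.files = TRUE,
                           no.. = TRUE))
  files <- files[!dir.exists(file.path(dir, files))]
  paste(files,
        vapply(file.path(dir, files),
               function(f) as.character(tools::md5sum(f)), character(1)),
        collapse = "|")
}

# Reference interpreter for the executor early-termination rule: given
# exit codes and ignore flags, how many executors run and does the
# sequence succeed?
stop_rule_oracle <- function(exits, ignores) {
  n_run <- 0L
  ok <- TRUE
  for (i in seq_along(exits)) {
    n_run <- n_run + 1L
    if (exits[[i]] != 0L && !ignores[[i]]) {
      ok <- FALSE
      break
    }
  }
  list(n_run = n_run, outcome = if (ok) "OK" else "FAILED")
}

# Background HTTP server running the installed package; returns the
# process handle and base URL once the server answers.
start_bg_server <- function(port = NULL) {
  port <- port %||% sample(21000:29000, 1)
  bg <- callr::r_bg(function(port) {
    library(tesr)
    svc <- TesService$new(pool_size = 4L)
    tes_serve(svc, port = port, quiet = TRUE)
  }, args = list(port = port))
  base <- sprintf("http://127.0.0.1:%d", port)
  ready <- FALSE
  for (i in 1:150) {
    ready <- tryCatch(
      curl::curl_fetch_memory(
        paste0(base, TES_URL_PREFIX, "/service-info")
      )$status_code == 200,
      error = function(e) FALSE
    )
    if (ready) break
    if (!bg$is_alive()) break
    Sys.sleep(0.2)
  }
  if (!ready) {
    err <- tryCatch(paste(bg$read_all_error_lines(), collapse = "\n"),
                    error = function(e) "")
    bg$kill()
    stop("test server failed to start: ", err)
  }
  list(process = bg, base_url = base)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

minimal_task_doc <- function(name = NULL, tags = NULL, command = "true") {
  doc <- list(executors = list(list(image = "alpine",
                                    command = as.list(command))))
  if (!is.null(name)) doc$name <- name
  if (!is.null(tags)) doc$tags <- tags
  doc
}
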