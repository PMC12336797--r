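#' @title Input/output staging
#' @description
#' Task inputs and outputs are arbitrary strings that the service tries to
#' interpret as URLs according to the conventions of its supported
#' protocols. A protocol-handler registry maps a lowercase scheme to a
#' `fetch` capability (URL -> workspace bytes/tree, used for inputs) and an
#' optional `store` capability (workspace -> URL, used for outputs). The
#' set of registered schemes is what `/service-info` advertises in its
#' `storage` property.
#' @name staging
NULL

#' Create a protocol-handler registry
#'
#' @param defaults if `TRUE` (default), register the built-in handlers:
#'   `file` (copy, both directions), `http`/`https` (fetch-only), and `ftp`
#'   (fetch and store). Object-store schemes (e.g. `s3`) are plug-in
#'   extension points via [tes_register_protocol()], not built-ins.
#' @return a `tes_registry`.
#' @export
tes_protocol_registry <- function(defaults = TRUE) {
  reg <- structure(new.env(parent = emptyenv()), class = "tes_registry")
  if (defaults) {
    tes_register_protocol(reg, "file",
                          fetch = file_fetch, store = file_store)
    tes_register_protocol(reg, "http", fetch = http_fetch)
    tes_register_protocol(reg, "https", fetch = http_fetch)
    tes_register_protocol(reg, "ftp", fetch = http_fetch, store = ftp_store)
  }
  reg
}

#' Register a protocol handler
#'
#' @param registry a [tes_protocol_registry()].
#' @param scheme lowercase scheme name; each scheme registers at most once
#'   per registry.
#' @param fetch `function(remainder, dest, type)` materializing the located
#'   FILE or DIRECTORY at host path `dest`.
#' @param store `function(src, remainder, type)` exporting host path `src`
#'   to the location, or `NULL` for fetch-only schemes.
#' @export
tes_register_protocol <- function(registry, scheme, fetch, store = NULL) {
  stopifnot(inherits(registry, "tes_registry"), is_string(scheme))
  if (!is.null(registry[[scheme]])) {
    tes_abort(paste0("protocol already registered: ", scheme),
              "tes_validation_error", errors = "scheme: duplicate")
  }
  registry[[scheme]] <- list(fetch = fetch, store = store)
  invisible(registry)
}

#' Registered protocol schemes, sorted
#'
#' Feeds the `storage` property of the `/service-info` document: exactly
#' the schemes for which staging can succeed.
#'
#' @param registry a [tes_protocol_registry()].
#' @return character vector of scheme names.
#' @export
tes_supported_protocols <- function(registry) {
  sort(names(registry))
}

#' Interpret a location string as a URL
#'
#' Splits `raw` into a lowercase scheme and the scheme-specific remainder
#' (e.g. `"ftp://host/f.txt"` -> scheme `"ftp"`, remainder
#' `"//host/f.txt"`). A bare absolute path is treated as a `file` URL.
#'
#' @param raw non-empty location string.
#' @param registry optionally, a registry; when given, an unregistered
#'   scheme raises `tes_unsupported_protocol`.
#' @return `list(scheme =, remainder =)`.
#' @export
tes_parse_location <- function(raw, registry = NULL) {
  if (!is_string(raw) || !nzchar(raw)) {
    tes_abort("location must be a non-empty string", "tes_validation_error",
              errors = "url: empty")
  }
  m <- regmatches(raw, regexec("^([A-Za-z][A-Za-z0-9+.-]*):(.*)$", raw))[[1]]
  if (length(m) == 3L) {
    scheme <- tolower(m[[2]])
    remainder <- m[[3]]
  } else if (startsWith(raw, "/")) {
    scheme <- "file"
    remainder <- raw
  } else {
    tes_abort(paste0("cannot interpret location as a URL: ", raw),
              "tes_unsupported_protocol", location = raw)
  }
  if (!is.null(registry) && is.null(registry[[scheme]])) {
    tes_abort(paste0("unsupported protocol: ", scheme),
              "tes_unsupported_protocol", scheme = scheme, location = raw)
  }
  list(scheme = scheme, remainder = remainder)
}

# host filesystem path of a file:// remainder ("///tmp/x" or a bare path)
file_url_path <- function(remainder) {
  if (startsWith(remainder, "//")) {
    p <- substring(remainder, 3)
    if (!startsWith(p, "/")) {
      # non-empty authority, e.g. file://host/x — only localhost supported
      slash <- regexpr("/", p, fixed = TRUE)
      if (slash < 0) tes_abort("file URL has no path", "tes_staging_error")
      p <- substring(p, slash)
    }
    p
  } else {
    remainder
  }
}

copy_tree <- function(src, dst) {
  dir.create(dst, recursive = TRUE, showWarnings = FALSE)
  for (d in list.dirs(src, recursive = TRUE, full.names = FALSE)) {
    if (nzchar(d)) dir.create(file.path(dst, d), recursive = TRUE,
                              showWarnings = FALSE)
  }
  files <- list.files(src, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  for (f in files) {
    if (!file.copy(file.path(src, f), file.path(dst, f), overwrite = TRUE)) {
      stop("copy failed: ", f)
    }
  }
  invisible(NULL)
}

file_fetch <- function(remainder, dest, type) {
  src <- file_url_path(remainder)
  if (type == "DIRECTORY") {
    if (!dir.exists(src)) stop("source directory does not exist: ", src)
    copy_tree(src, dest)
  } else {
    if (!file.exists(src) || dir.exists(src)) {
      stop("source file does not exist: ", src)
    }
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    if (!file.copy(src, dest, overwrite = TRUE)) stop("copy failed: ", src)
  }
  invisible(NULL)
}

file_store <- function(src, remainder, type) {
  dst <- file_url_path(remainder)
  if (type == "DIRECTORY") {
    copy_tree(src, dst)
  } else {
    dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
    if (!file.copy(src, dst, overwrite = TRUE)) stop("copy failed: ", src)
  }
  invisible(NULL)
}

http_fetch <- function(remainder, dest, type) {
  if (type == "DIRECTORY") {
    stop("DIRECTORY staging is not supported over http/ftp")
  }
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  # scheme is re-attached by the caller via the closure below
  stop("http_fetch must be called through the registry wrapper")
}

ftp_store <- function(src, remainder, type) {
  stop("ftp_store must be called through the registry wrapper")
}

#' Create a task workspace
#'
#' One host directory per task attempt
#' (`<work_root>/<task_id>/<attempt>/`). Container-absolute workspace paths
#' (`/data/in.txt`) are mapped under the root; paths that escape the root
#' after normalization are rejected.
#'
#' @param work_root parent directory for all workspaces.
#' @param task_id task identifier.
#' @param attempt attempt number (1-based).
#' @return a `tes_workspace` list with `$root` and `$map(path)`.
#' @export
tes_workspace <- function(work_root, task_id, attempt = 1L) {
  root <- file.path(work_root, task_id, attempt)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  map <- function(path) {
    np <- normalize_ws_path(path)
    if (is.null(np)) {
      tes_abort(paste0("path escapes the task workspace: ", path),
                "tes_staging_error", path = path)
    }
    if (np == "/") root else file.path(root, substring(np, 2))
  }
  structure(list(root = root, map = map), class = "tes_workspace")
}

destroy_workspace <- function(ws) {
  # remove the whole task directory (root is <work_root>/<id>/<attempt>)
  unlink(dirname(ws$root), recursive = TRUE, force = TRUE)
  invisible(NULL)
}

#' Materialize task inputs into the workspace
#'
#' Writes inline `content` inputs verbatim, fetches URL inputs through the
#' protocol registry (FILE: exact bytes; DIRECTORY: full recursive tree),
#' and creates every declared volume as an empty writable directory.
#' Transfers are sequential, with 2 retries and exponential backoff per
#' input before a `tes_staging_error` is raised (the per-input cause is
#' attached). A `check_cancel` callback is polled between inputs so a
#' cancellation interrupts staging cooperatively.
#'
#' @param spec a validated `tes_task`.
#' @param ws a [tes_workspace()].
#' @param registry a [tes_protocol_registry()].
#' @param check_cancel `function()` returning `TRUE` to abort (raises a
#'   `tes_canceled` condition), or `NULL`.
#' @param retries,retry_delay retry policy per input.
#' @return the workspace, invisibly.
#' @export
tes_stage_inputs <- function(spec, ws, registry, check_cancel = NULL,
                             retries = 2L, retry_delay = 0.5) {
  for (v in spec$volumes) {
    dir.create(ws$map(v), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_along(spec$inputs)) {
    if (!is.null(check_cancel) && isTRUE(check_cancel())) {
      tes_abort("task canceled during staging", "tes_canceled")
    }
    stage_one_input(spec$inputs[[i]], i, ws, registry, retries, retry_delay)
  }
  invisible(ws)
}

# Stage a single input (inline content or URL fetch with retry/backoff).
stage_one_input <- function(input, i, ws, registry, retries, retry_delay) {
  dest <- ws$map(input$path)
  if (!is.null(input$content)) {
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    writeBin(charToRaw(input$content), dest)
    return(invisible(NULL))
  }
  loc <- tryCatch(
    tes_parse_location(input$url, registry),
    tes_error = function(e) {
      tes_abort(
        sprintf("cannot stage input %d (%s): %s", i - 1L, input$url,
                conditionMessage(e)),
        "tes_staging_error", input_index = i - 1L, cause = e
      )
    }
  )
  fetch <- registry[[loc$scheme]]$fetch
  last_err <- NULL
  for (try_i in 0:retries) {
    if (try_i > 0L) Sys.sleep(retry_delay * 2^(try_i - 1L))
    last_err <- tryCatch({
      run_fetch(loc$scheme, fetch, loc$remainder, dest, input$type)
      NULL
    }, error = function(e) e)
    if (is.null(last_err)) return(invisible(NULL))
  }
  tes_abort(
    sprintf("cannot stage input %d (%s): %s", i - 1L, input$url,
            conditionMessage(last_err)),
    "tes_staging_error", input_index = i - 1L, cause = last_err
  )
}

# http/https/ftp fetches go through curl; file fetches are plain copies.
run_fetch <- function(scheme, fetch, remainder, dest, type) {
  if (identical(fetch, http_fetch)) {
    if (type == "DIRECTORY") {
      stop("DIRECTORY staging is not supported over ", scheme)
    }
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    curl::curl_download(paste0(scheme, ":", remainder), dest, quiet = TRUE)
  } else {
    fetch(remainder, dest, type)
  }
  invisible(NULL)
}

run_store <- function(scheme, store, src, remainder, type) {
  if (identical(store, ftp_store)) {
    if (type == "DIRECTORY") {
      stop("DIRECTORY export is not supported over ", scheme)
    }
    curl::curl_upload(src, paste0(scheme, ":", remainder), verbose = FALSE)
  } else {
    store(src, remainder, type)
  }
  invisible(NULL)
}

tree_size_bytes <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, recursive = TRUE, all.files = TRUE, no.. = TRUE,
                        full.names = TRUE)
    files <- files[!dir.exists(files)]
    sum(vapply(files, function(f) as.numeric(file.info(f)$size), numeric(1)))
  } else {
    as.numeric(file.info(path)$size)
  }
}

#' Export declared outputs from the workspace
#'
#' Every declared output present in the workspace is exported to its URL
#' through the registry; manifest entries (url, path, measured size in
#' bytes) are returned in declaration order. A declared output missing from
#' the workspace raises `tes_missing_output` (the user's job failed to
#' produce it — an executor error, mirroring exit-code semantics);
#' destination faults raise `tes_export_error` (a system error).
#'
#' @param spec a validated `tes_task`.
#' @param ws a [tes_workspace()].
#' @param registry a [tes_protocol_registry()].
#' @return list of `list(url =, path =, size_bytes =)`.
#' @export
tes_collect_outputs <- function(spec, ws, registry) {
  lapply(spec$outputs, function(output) {
    src <- ws$map(output$path)
    exists <- if (output$type == "DIRECTORY") dir.exists(src) else
      (file.exists(src) && !dir.exists(src))
    if (!exists) {
      tes_abort(paste0("declared output was not produced: ", output$path),
                "tes_missing_output", path = output$path)
    }
    loc <- tryCatch(
      tes_parse_location(output$url, registry),
      tes_error = function(e) {
        tes_abort(conditionMessage(e), "tes_export_error", cause = e)
      }
    )
    store <- registry[[loc$scheme]]$store
    if (is.null(store)) {
      tes_abort(paste0("protocol cannot store outputs: ", loc$scheme),
                "tes_export_error", scheme = loc$scheme)
    }
    res <- tryCatch({
      run_store(loc$scheme, store, src, loc$remainder, output$type)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(res)) {
      tes_abort(
        paste0("failed to export output ", output$path, ": ",
               conditionMessage(res)),
        "tes_export_error", cause = res
      )
    }
    list(url = output$url, path = output$path,
         size_bytes = tree_size_bytes(src))
  })
}
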