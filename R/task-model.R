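#' @title The TES task message model
#' @description
#' A task is the atomic unit of the Task Execution Service API: one JSON
#' message carrying everything a server needs to run a set of command lines
#' on a machine it has never prepared — the container image(s), the command
#' vectors, resource minimums, input files to stage in, output files to
#' export, environment variables, and client metadata tags.
#'
#' Field names follow the upstream TES v1.1 OpenAPI schema
#' (MINIMAL/BASIC/FULL views, `executors`, `ignore_error`, `ram_gb`, ...).
#' @name task-model
NULL

#' The three view levels for task listing and retrieval
#'
#' `MINIMAL` returns only `id` and `state`; `BASIC` returns the record minus
#' bulky payloads (executor stdout/stderr tails, system logs, inline input
#' content); `FULL` returns everything.
#'
#' @export
TES_VIEW_LEVELS <- c("MINIMAL", "BASIC", "FULL")

TASK_FIELDS <- c("name", "description", "inputs", "outputs", "resources",
                 "executors", "volumes", "tags")
INPUT_FIELDS <- c("name", "description", "url", "path", "type", "content",
                  "streamable")
OUTPUT_FIELDS <- c("name", "description", "url", "path", "type",
                   "path_prefix")
RESOURCE_FIELDS <- c("cpu_cores", "preemptible", "ram_gb", "disk_gb",
                     "gpu_count", "zones", "backend_parameters",
                     "backend_parameters_strict")
EXECUTOR_FIELDS <- c("image", "command", "workdir", "stdin", "stdout",
                     "stderr", "env", "ignore_error")

# Coerce a parsed-JSON value (list of strings or character vector) to a
# character vector; NULL if it is not a homogeneous string array.
as_str_vec <- function(x) {
  if (is.null(x)) return(character(0))
  if (is.list(x)) {
    if (!all(vapply(x, is_string, logical(1)))) return(NULL)
    return(vapply(x, identity, character(1)))
  }
  if (is.character(x) && !anyNA(x)) return(x)
  NULL
}

# Coerce to a string->string map (named list); NULL on malformed input.
as_str_map <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(stats::setNames(list(), character(0)))
  }
  if (!is.list(x) && !is.character(x)) return(NULL)
  nm <- names(x)
  if (is.null(nm) || any(!nzchar(nm))) return(NULL)
  vals <- as.list(x)
  if (!all(vapply(vals, is_string, logical(1)))) return(NULL)
  if (anyDuplicated(nm)) return(NULL)
  stats::setNames(vals, nm)
}

#' Validate and normalize a raw task document
#'
#' Checks every invariant of the task message — non-empty executor list,
#' non-empty image and command per executor, absolute workspace paths that
#' do not escape the workspace root, exactly one of `url`/`content` per
#' input, `url` required per output, positive resource requests — and
#' returns a normalized `tes_task` with defaults filled (`ignore_error =
#' FALSE`, `type = "FILE"`, empty lists and maps). Validation is
#' all-or-nothing: on any violation a `tes_validation_error` condition is
#' signalled whose `errors` field lists *every* violated invariant with a
#' JSON field path (0-based array indices).
#'
#' @param doc a parsed JSON-like list (e.g. from [tes_parse_task()]).
#' @param lenient if `TRUE`, unknown fields are preserved in place instead
#'   of rejected (interoperability mode).
#' @return a normalized list of class `tes_task`.
#' @examples
#' spec <- tes_validate_task(list(
#'   executors = list(list(image = "alpine", command = c("echo", "hi")))
#' ))
#' spec$executors[[1]]$ignore_error  # FALSE, filled by normalization
#' @export
tes_validate_task <- function(doc, lenient = FALSE) {
  errs <- character(0)
  bad <- function(path, msg) errs[[length(errs) + 1L]] <<- paste0(path, ": ", msg)

  if (!is.list(doc) || (length(doc) > 0L && is.null(names(doc)) && !is.null(doc))) {
    tes_abort("task document must be a JSON object", "tes_validation_error",
              errors = "$: not an object")
  }
  out <- list()

  unknown <- setdiff(names(doc), TASK_FIELDS)
  if (length(unknown) > 0L && !lenient) {
    for (u in unknown) bad(u, "unknown field")
  }

  for (f in c("name", "description")) {
    if (!is.null(doc[[f]])) {
      if (!is_string(doc[[f]])) bad(f, "must be a string")
      else out[[f]] <- doc[[f]]
    }
  }

  # --- executors -----------------------------------------------------------
  ex_in <- doc$executors
  if (is.null(ex_in) || !is.list(ex_in) || length(ex_in) == 0L ||
      !is.null(names(ex_in))) {
    bad("executors", "non-empty array required")
    ex_in <- list()
  }
  out$executors <- lapply(seq_along(ex_in), function(i) {
    e <- ex_in[[i]]
    p <- sprintf("executors[%d]", i - 1L)
    if (!is.list(e)) {
      bad(p, "must be an object")
      return(list())
    }
    if (!lenient) {
      for (u in setdiff(names(e), EXECUTOR_FIELDS)) {
        bad(paste0(p, ".", u), "unknown field")
      }
    }
    ne <- list()
    if (!is_string(e$image) || !nzchar(e$image)) {
      bad(paste0(p, ".image"), "non-empty string required")
    } else ne$image <- e$image
    cmd <- as_str_vec(e$command)
    if (is.null(cmd) || length(cmd) == 0L) {
      bad(paste0(p, ".command"), "non-empty argument array required")
    } else ne$command <- cmd
    for (f in c("workdir", "stdin", "stdout", "stderr")) {
      if (!is.null(e[[f]])) {
        np <- normalize_ws_path(e[[f]])
        if (is.null(np)) {
          bad(paste0(p, ".", f),
              "must be an absolute path inside the task workspace")
        } else ne[[f]] <- np
      }
    }
    env <- as_str_map(e$env)
    if (is.null(env)) bad(paste0(p, ".env"), "must be a string-to-string map")
    else ne$env <- env
    if (is.null(e$ignore_error)) ne$ignore_error <- FALSE
    else if (!is_flag(e$ignore_error)) {
      bad(paste0(p, ".ignore_error"), "must be a boolean")
    } else ne$ignore_error <- e$ignore_error
    if (lenient) for (u in setdiff(names(e), EXECUTOR_FIELDS)) ne[[u]] <- e[[u]]
    ne
  })

  # --- inputs --------------------------------------------------------------
  validate_io <- function(io, p, role) {
    allowed <- if (role == "input") INPUT_FIELDS else OUTPUT_FIELDS
    ni <- list()
    if (!is.list(io)) {
      bad(p, "must be an object")
      return(ni)
    }
    if (!lenient) {
      for (u in setdiff(names(io), allowed)) bad(paste0(p, ".", u), "unknown field")
    }
    for (f in c("name", "description")) {
      if (!is.null(io[[f]])) {
        if (!is_string(io[[f]])) bad(paste0(p, ".", f), "must be a string")
        else ni[[f]] <- io[[f]]
      }
    }
    if (!is.null(io$url)) {
      if (!is_string(io$url) || !nzchar(io$url)) {
        bad(paste0(p, ".url"), "must be a non-empty string")
      } else ni$url <- io$url
    }
    np <- normalize_ws_path(io$path)
    if (is.null(np)) {
      bad(paste0(p, ".path"),
          "must be an absolute path inside the task workspace")
    } else ni$path <- np
    ty <- io$type %||% "FILE"
    if (!is_string(ty) || !(ty %in% c("FILE", "DIRECTORY"))) {
      bad(paste0(p, ".type"), "must be FILE or DIRECTORY")
    } else ni$type <- ty
    if (role == "input") {
      if (!is.null(io$content) && !is_string(io$content)) {
        bad(paste0(p, ".content"), "must be a string")
      } else ni$content <- io$content
      has_url <- !is.null(io$url)
      has_content <- !is.null(io$content)
      if (has_url == has_content) {
        bad(p, "exactly one of url, content must be set")
      }
      if (has_content && identical(ni$type, "DIRECTORY")) {
        bad(paste0(p, ".content"), "inline content requires type FILE")
      }
      if (!is.null(io$streamable)) {
        if (!is_flag(io$streamable)) {
          bad(paste0(p, ".streamable"), "must be a boolean")
        } else ni$streamable <- io$streamable
      }
    } else {
      if (is.null(io$url)) bad(paste0(p, ".url"), "required for outputs")
      scheme <- tryCatch(tes_parse_location(io$url %||% "x")$scheme,
                         error = function(e) NA_character_)
      if (!is.na(scheme) && scheme %in% c("http", "https")) {
        bad(paste0(p, ".url"),
            "http(s) destinations are not supported for outputs")
      }
      if (!is.null(io$path_prefix)) {
        if (!is_string(io$path_prefix)) {
          bad(paste0(p, ".path_prefix"), "must be a string")
        } else ni$path_prefix <- io$path_prefix
      }
    }
    if (is.null(ni$content)) ni$content <- NULL
    if (lenient) for (u in setdiff(names(io), allowed)) ni[[u]] <- io[[u]]
    ni
  }

  ins <- doc$inputs %||% list()
  if (!is.list(ins) || !is.null(names(ins))) {
    bad("inputs", "must be an array")
    ins <- list()
  }
  out$inputs <- lapply(seq_along(ins), function(i) {
    validate_io(ins[[i]], sprintf("inputs[%d]", i - 1L), "input")
  })

  outs <- doc$outputs %||% list()
  if (!is.list(outs) || !is.null(names(outs))) {
    bad("outputs", "must be an array")
    outs <- list()
  }
  out$outputs <- lapply(seq_along(outs), function(i) {
    validate_io(outs[[i]], sprintf("outputs[%d]", i - 1L), "output")
  })

  # --- resources -----------------------------------------------------------
  if (!is.null(doc$resources)) {
    r <- doc$resources
    if (!is.list(r)) {
      bad("resources", "must be an object")
    } else {
      if (!lenient) {
        for (u in setdiff(names(r), RESOURCE_FIELDS)) {
          bad(paste0("resources.", u), "unknown field")
        }
      }
      nr <- list()
      for (f in c("cpu_cores", "ram_gb", "disk_gb")) {
        if (!is.null(r[[f]])) {
          ok <- is.numeric(r[[f]]) && length(r[[f]]) == 1L && r[[f]] > 0
          if (f == "cpu_cores") ok <- ok && is_count(r[[f]])
          if (!ok) bad(paste0("resources.", f), "must be strictly positive")
          else nr[[f]] <- if (f == "cpu_cores") as.integer(r[[f]]) else r[[f]]
        }
      }
      if (!is.null(r$gpu_count)) {
        if (!is_count(r$gpu_count) || r$gpu_count < 0) {
          bad("resources.gpu_count", "must be a non-negative integer")
        } else nr$gpu_count <- as.integer(r$gpu_count)
      }
      if (!is.null(r$preemptible)) {
        if (!is_flag(r$preemptible)) bad("resources.preemptible", "must be a boolean")
        else nr$preemptible <- r$preemptible
      }
      if (!is.null(r$zones)) {
        z <- as_str_vec(r$zones)
        if (is.null(z)) bad("resources.zones", "must be a string array")
        else nr$zones <- z
      }
      # backend extensions are stored and echoed, never interpreted
      if (!is.null(r$backend_parameters)) {
        bp <- as_str_map(r$backend_parameters)
        if (is.null(bp)) bad("resources.backend_parameters", "must be a string map")
        else nr$backend_parameters <- bp
      }
      if (!is.null(r$backend_parameters_strict)) {
        if (!is_flag(r$backend_parameters_strict)) {
          bad("resources.backend_parameters_strict", "must be a boolean")
        } else nr$backend_parameters_strict <- r$backend_parameters_strict
      }
      if (lenient) for (u in setdiff(names(r), RESOURCE_FIELDS)) nr[[u]] <- r[[u]]
      if (length(nr) > 0L) out$resources <- nr
    }
  }

  # --- volumes and tags ----------------------------------------------------
  vols <- as_str_vec(doc$volumes)
  if (is.null(vols)) {
    bad("volumes", "must be a string array")
    vols <- character(0)
  }
  out$volumes <- vapply(seq_along(vols), function(i) {
    np <- normalize_ws_path(vols[[i]])
    if (is.null(np)) {
      bad(sprintf("volumes[%d]", i - 1L), "must be an absolute path")
      return(vols[[i]])
    }
    np
  }, character(1))

  tags <- as_str_map(doc$tags)
  if (is.null(tags)) {
    bad("tags", "must be a string-to-string map with unique keys")
    tags <- stats::setNames(list(), character(0))
  }
  out$tags <- tags

  if (lenient) for (u in unknown) out[[u]] <- doc[[u]]

  if (length(errs) > 0L) {
    tes_abort(
      paste0("invalid task document: ", paste(errs, collapse = "; ")),
      "tes_validation_error", errors = errs
    )
  }
  structure(out, class = "tes_task")
}

#' Parse a wire-format JSON task document
#'
#' @param json a JSON string.
#' @param lenient passed to [tes_validate_task()]; when `FALSE` (default)
#'   unknown fields are rejected.
#' @return a validated `tes_task`.
#' @export
tes_parse_task <- function(json, lenient = FALSE) {
  doc <- tryCatch(
    jsonlite::fromJSON(json, simplifyVector = FALSE),
    error = function(e) {
      tes_abort(paste0("malformed JSON: ", conditionMessage(e)),
                "tes_parse_error")
    }
  )
  tes_validate_task(doc, lenient = lenient)
}

# Canonical key order for task documents; unknown (lenient-mode) keys are
# appended alphabetically so serialization is deterministic.
ORDER_TASK <- c("id", "state", "name", "description", "inputs", "outputs",
                "resources", "executors", "volumes", "tags", "logs",
                "creation_time")
ORDER_INPUT <- c("name", "description", "url", "path", "type", "content",
                 "streamable")
ORDER_OUTPUT <- c("name", "description", "url", "path", "path_prefix", "type")
ORDER_EXECUTOR <- c("image", "command", "workdir", "stdin", "stdout",
                    "stderr", "env", "ignore_error")

order_keys <- function(x, order) {
  known <- intersect(order, names(x))
  extra <- sort(setdiff(names(x), order))
  x[c(known, extra)]
}

# Prepare a task document for jsonlite: canonical key order and explicit
# array marking so length-1 arrays (command, volumes, ...) stay arrays.
canonical_task <- function(doc) {
  doc <- order_keys(doc, ORDER_TASK)
  arr <- function(v) if (is.null(v)) NULL else I(v)
  if (!is.null(doc$executors)) {
    doc$executors <- lapply(doc$executors, function(e) {
      e <- order_keys(e, ORDER_EXECUTOR)
      e$command <- arr(e$command)
      e
    })
  }
  if (!is.null(doc$inputs)) {
    doc$inputs <- lapply(doc$inputs, function(x) order_keys(x, ORDER_INPUT))
  }
  if (!is.null(doc$outputs)) {
    doc$outputs <- lapply(doc$outputs, function(x) order_keys(x, ORDER_OUTPUT))
  }
  if (!is.null(doc$resources)) {
    doc$resources <- order_keys(doc$resources, RESOURCE_FIELDS)
    doc$resources$zones <- arr(doc$resources$zones)
  }
  doc$volumes <- arr(doc$volumes)
  if (!is.null(doc$logs)) {
    doc$logs <- lapply(doc$logs, function(attempt) {
      attempt <- order_keys(attempt, c("logs", "metadata", "start_time",
                                       "end_time", "outputs", "system_logs"))
      if (!is.null(attempt$system_logs)) {
        attempt$system_logs <- arr(attempt$system_logs)
      }
      attempt
    })
  }
  doc
}

#' Serialize a task (or stored task record) to wire JSON
#'
#' Serialization is canonical: fixed key order, arrays kept as arrays even
#' at length one, so `tes_parse_task(tes_serialize_task(x))` is the
#' structural identity on valid tasks and golden files can be compared
#' byte-for-byte.
#'
#' @param task a `tes_task` or a projected task record (list).
#' @return a length-1 JSON character string.
#' @export
tes_serialize_task <- function(task) {
  as.character(json_out(canonical_task(unclass(task))))
}

#' Project a stored task record to a view level
#'
#' @param record a task record list (as returned by the store).
#' @param level one of `"MINIMAL"`, `"BASIC"`, `"FULL"`.
#' @return a new list; the stored record is never mutated.
#' @export
tes_project_view <- function(record, level = c("MINIMAL", "BASIC", "FULL")) {
  level <- match.arg(level)
  if (level == "FULL") return(record)
  if (level == "MINIMAL") return(list(id = record$id, state = record$state))
  # BASIC: strip bulky payloads, keep structure
  rec <- record
  if (!is.null(rec$inputs)) {
    rec$inputs <- lapply(rec$inputs, function(io) {
      io$content <- NULL
      io
    })
  }
  if (!is.null(rec$logs)) {
    rec$logs <- lapply(rec$logs, function(attempt) {
      attempt$system_logs <- NULL
      if (!is.null(attempt$logs)) {
        attempt$logs <- lapply(attempt$logs, function(el) {
          el$stdout <- NULL
          el$stderr <- NULL
          el
        })
      }
      attempt
    })
  }
  rec
}

# Flat field-path set of a (possibly nested) document; used by tests and the
# view-cardinality acceptance check to assert MINIMAL < BASIC < FULL.
field_paths <- function(x, prefix = "") {
  if (!is.list(x)) return(prefix)
  nm <- names(x)
  if (is.null(nm)) {
    return(unlist(lapply(seq_along(x), function(i) {
      field_paths(x[[i]], paste0(prefix, "[]"))
    })))
  }
  unlist(lapply(nm, function(n) {
    field_paths(x[[n]], if (nzchar(prefix)) paste0(prefix, ".", n) else n)
  }))
}
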