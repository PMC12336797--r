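#' Construct a task listing filter
#'
#' An empty filter matches every task. `state` filters by exact lifecycle
#' state; `name_prefix` matches tasks whose name starts with the prefix
#' (prefix match, not substring); `tags` is a key/value map of which every
#' pair must match exactly (conjunction).
#'
#' @param state a state string from [TES_STATES], or `NULL`.
#' @param name_prefix a string, or `NULL`.
#' @param tags a named character vector / named list of tag equalities.
#' @return a `tes_filter` list.
#' @export
tes_task_filter <- function(state = NULL, name_prefix = NULL, tags = NULL) {
  if (!is.null(state) && !(is_string(state) && state %in% TES_STATES)) {
    tes_abort(paste0("unknown task state: ", state), "tes_validation_error",
              errors = "state: unknown value")
  }
  if (!is.null(name_prefix) && !is_string(name_prefix)) {
    tes_abort("name_prefix must be a string", "tes_validation_error",
              errors = "name_prefix: must be a string")
  }
  tags <- as_str_map(tags)
  if (is.null(tags)) {
    tes_abort("tags must be a string map", "tes_validation_error",
              errors = "tags: must be a string map")
  }
  structure(list(state = state, name_prefix = name_prefix, tags = tags),
            class = "tes_filter")
}

filter_matches <- function(filter, doc) {
  if (!is.null(filter$state) && !identical(doc$state, filter$state)) {
    return(FALSE)
  }
  if (!is.null(filter$name_prefix) &&
      !startsWith(doc$name %||% "", filter$name_prefix)) {
    return(FALSE)
  }
  for (k in names(filter$tags)) {
    if (!identical(doc$tags[[k]], filter$tags[[k]])) return(FALSE)
  }
  TRUE
}

filter_fingerprint <- function(filter) {
  as.character(json_out(list(
    s = filter$state, p = filter$name_prefix,
    t = filter$tags[order(names(filter$tags))]
  )))
}

encode_page_token <- function(filter, created_num, id) {
  payload <- json_out(list(
    f = filter_fingerprint(filter),
    t = formatC(created_num, digits = 17, format = "g"),
    i = id
  ))
  jsonlite::base64_enc(charToRaw(as.character(payload)))
}

decode_page_token <- function(token, filter) {
  tok <- tryCatch(
    jsonlite::fromJSON(rawToChar(jsonlite::base64_dec(token)),
                       simplifyVector = FALSE),
    error = function(e) NULL
  )
  if (is.null(tok) || !is_string(tok$f %||% NA) || !is_string(tok$i %||% NA) ||
      !is_string(tok$t %||% NA)) {
    tes_abort("malformed page token", "tes_invalid_page_token")
  }
  if (!identical(tok$f, filter_fingerprint(filter))) {
    tes_abort("page token was issued for a different query",
              "tes_invalid_page_token")
  }
  list(t = as.numeric(tok$t), i = tok$i)
}

DEFAULT_PAGE_SIZE <- 256L
MAX_PAGE_SIZE <- 2048L

#' In-memory task store
#'
#' Assigns server-side identifiers, persists task records, enforces legal
#' lifecycle transitions, and serves filtered, paginated, view-projected
#' listings in a stable total order (creation time descending, id ascending
#' as tie-break). The store is the single source of truth for task state.
#'
#' Identifiers are 26-character URL-safe random tokens, unique per service
#' instance. Task retention is not prescribed: with the default
#' configuration every created task remains listable for the life of the
#' store.
#'
#' @export
TaskStore <- R6::R6Class(
  "TaskStore",
  public = list(
    #' @description Create an empty store.
    initialize = function() {
      private$records <- new.env(parent = emptyenv())
    },

    #' @description Persist a validated task spec as a new `QUEUED` record.
    #' @param spec a `tes_task` from [tes_validate_task()].
    #' @return the fresh unique task id.
    create = function(spec) {
      id <- new_task_id()
      while (!is.null(private$records[[id]])) id <- new_task_id()
      tnum <- now_num()
      doc <- c(
        list(id = id, state = "QUEUED"),
        unclass(spec),
        list(logs = list(), creation_time = tes_timestamp(as.POSIXct(
          tnum, origin = "1970-01-01", tz = "UTC"
        )))
      )
      rec <- new.env(parent = emptyenv())
      rec$doc <- doc
      rec$created_num <- tnum
      rec$trace <- "QUEUED"
      private$records[[id]] <- rec
      private$persist(rec)
      id
    },

    #' @description Retrieve a task record by id (a copy; mutating the
    #'   return value never affects the store).
    #' @param id task id.
    get = function(id) {
      private$rec(id)$doc
    },

    #' @description Does a record exist?
    #' @param id task id.
    exists = function(id) {
      is_string(id) && !is.null(private$records[[id]])
    },

    #' @description All ids, in no particular order.
    ids = function() names(private$records),

    #' @description Number of stored records.
    size = function() length(private$records),

    #' @description Change a task's lifecycle state. The transition must be
    #'   an edge of the state machine; terminal states are absorbing.
    #' @param id task id.
    #' @param to target state.
    #' @return the updated record.
    update_state = function(id, to) {
      rec <- private$rec(id)
      from <- rec$doc$state
      if (!tes_transition_allowed(from, to)) {
        tes_abort(
          sprintf("illegal transition %s -> %s for task %s", from, to, id),
          "tes_illegal_transition", from = from, to = to
        )
      }
      rec$doc$state <- to
      rec$trace <- c(rec$trace, to)
      private$persist(rec)
      rec$doc
    },

    #' @description Apply a mutation function to a record (log appends,
    #'   attempt bookkeeping). The function receives and returns the record
    #'   document; it must not touch `id`, `state`, or `creation_time` —
    #'   those are owned by `create`/`update_state`.
    #' @param id task id.
    #' @param fn `function(doc) doc`.
    modify = function(id, fn) {
      rec <- private$rec(id)
      doc <- fn(rec$doc)
      doc$id <- rec$doc$id
      doc$state <- rec$doc$state
      doc$creation_time <- rec$doc$creation_time
      rec$doc <- doc
      private$persist(rec)
      rec$doc
    },

    #' @description The observed state trace of a task (every state it has
    #'   ever been in, in order). Diagnostic; not part of the wire format.
    #' @param id task id.
    trace = function(id) private$rec(id)$trace,

    #' @description Filtered, paginated, view-projected listing.
    #' @param filter a [tes_task_filter()].
    #' @param page_size max tasks per page (default 256, cap 2048).
    #' @param page_token token from a previous page, or `NULL`.
    #' @param view a [TES_VIEW_LEVELS] member.
    #' @return `list(tasks = <projected docs>, next_page_token = <string|NULL>)`.
    list_page = function(filter = tes_task_filter(), page_size = NULL,
                         page_token = NULL, view = "MINIMAL") {
      if (!inherits(filter, "tes_filter")) {
        filter <- do.call(tes_task_filter, as.list(filter))
      }
      page_size <- page_size %||% DEFAULT_PAGE_SIZE
      if (!is_count(page_size) || page_size < 1L) {
        tes_abort("page_size must be a positive integer",
                  "tes_validation_error", errors = "page_size: positive required")
      }
      page_size <- min(as.integer(page_size), MAX_PAGE_SIZE)
      if (!(view %in% TES_VIEW_LEVELS)) {
        tes_abort(paste0("unknown view level: ", view),
                  "tes_validation_error", errors = "view: unknown value")
      }

      recs <- mget(names(private$records), envir = private$records)
      keep <- Filter(function(r) filter_matches(filter, r$doc), recs)
      if (length(keep) > 0L) {
        tnum <- vapply(keep, function(r) r$created_num, numeric(1))
        ids <- vapply(keep, function(r) r$doc$id, character(1))
        ord <- order(-tnum, ids)
        keep <- keep[ord]
        tnum <- tnum[ord]
        ids <- ids[ord]
        if (!is.null(page_token)) {
          pos <- decode_page_token(page_token, filter)
          after <- (tnum < pos$t) | (tnum == pos$t & ids > pos$i)
          keep <- keep[after]
        }
      } else if (!is.null(page_token)) {
        decode_page_token(page_token, filter)  # still reject foreign tokens
      }

      n <- length(keep)
      take <- utils::head(keep, page_size)
      tasks <- lapply(take, function(r) tes_project_view(r$doc, view))
      names(tasks) <- NULL
      token <- NULL
      if (n > page_size) {
        last <- take[[length(take)]]
        token <- encode_page_token(filter, last$created_num, last$doc$id)
      }
      list(tasks = tasks, next_page_token = token)
    }
  ),
  private = list(
    records = NULL,
    rec = function(id) {
      r <- if (is_string(id)) private$records[[id]] else NULL
      if (is.null(r)) {
        tes_abort(paste0("task not found: ", id), "tes_not_found")
      }
      r
    },
    persist = function(rec) invisible(NULL)
  )
)

#' Single-file persistent task store
#'
#' The same storage contract as [TaskStore], backed by an append-only
#' journal: every record mutation appends one JSON line to a single file,
#' and opening the store replays the journal (last write per id wins). This
#' keeps deployment state in one portable file with crash-safe appends; the
#' in-memory store remains the default for tests and embedded use.
#'
#' @export
FileTaskStore <- R6::R6Class(
  "FileTaskStore",
  inherit = TaskStore,
  public = list(
    #' @description Open (and replay) or create the journal file.
    #' @param path journal file path.
    initialize = function(path) {
      super$initialize()
      private$path <- path
      if (file.exists(path)) {
        lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) {
          tes_abort(paste0("cannot read task journal: ", conditionMessage(e)),
                    "tes_storage_error")
        })
        for (ln in lines[nzchar(lines)]) {
          entry <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
          rec <- new.env(parent = emptyenv())
          rec$doc <- normalize_replayed_doc(entry$doc)
          rec$created_num <- as.numeric(entry$created_num)
          rec$trace <- as_str_vec(entry$trace)
          assign(rec$doc$id, rec, envir = private$records)
        }
      }
    }
  ),
  private = list(
    path = NULL,
    persist = function(rec) {
      line <- json_out(list(
        doc = canonical_task(rec$doc),
        created_num = formatC(rec$created_num, digits = 17, format = "g"),
        trace = I(rec$trace)
      ))
      ok <- tryCatch({
        cat(as.character(line), "\n", sep = "", file = private$path,
            append = TRUE)
        TRUE
      }, error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) {
        tes_abort("failed to append to task journal", "tes_storage_error")
      }
      invisible(NULL)
    }
  )
)

# Journal replay round-trips through JSON, which turns string arrays into
# lists and loses empty-map names; restore the in-memory representation.
normalize_replayed_doc <- function(doc) {
  if (!is.null(doc$executors)) {
    doc$executors <- lapply(doc$executors, function(e) {
      e$command <- as_str_vec(e$command)
      e$env <- as_str_map(e$env)
      e
    })
  }
  doc$volumes <- as_str_vec(doc$volumes)
  doc$tags <- as_str_map(doc$tags)
  if (!is.null(doc$logs)) {
    doc$logs <- lapply(doc$logs, function(a) {
      if (!is.null(a$system_logs)) a$system_logs <- as_str_vec(a$system_logs)
      a
    })
  }
  doc
}
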