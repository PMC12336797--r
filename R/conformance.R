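#' @title YAML-driven conformance suite
#' @description
#' Conformance cases are written in YAML and interpreted by a dedicated
#' runner that can exercise *any* TES endpoint — the runner holds no
#' knowledge of a server beyond its base URL (or transport function). The
#' suite is modular: cases carry component tags (`model`, `endpoints`,
#' `lifecycle`, `filtering`, `views`, `service-info`) so specific API
#' components can be tested in isolation, or the entire API in one go.
#'
#' A case is an id, a description, tags, and an ordered list of steps.
#' Each step issues one request (`method`, `path`, `params`, `body`),
#' optionally polls it until a JSON-path value enters a set (bounded by a
#' per-case polling cap), captures JSON-path values into variables usable
#' in later steps via `${var}`, and evaluates assertions: `status`, and
#' per-path `equals` / `in` / `regex` / `exists`.
#' @name conformance
NULL

POLL_CAP_SECONDS <- 60

# Minimal JSON-path: dotted fields with 0-based [i] indexing,
# e.g. "tasks[0].id", "logs[0].logs[0].exit_code".
json_path_get <- function(doc, path) {
  tokens <- regmatches(path,
                       gregexpr("\\[[0-9]+\\]|[^.\\[\\]]+", path,
                                perl = TRUE))[[1]]
  cur <- doc
  for (tok in tokens) {
    if (is.null(cur)) return(NULL)
    if (grepl("^\\[", tok)) {
      idx <- as.integer(substr(tok, 2, nchar(tok) - 1)) + 1L
      if (!is.list(cur) || idx > length(cur)) return(NULL)
      cur <- cur[[idx]]
    } else {
      if (!is.list(cur)) return(NULL)
      cur <- cur[[tok]]
    }
  }
  cur
}

subst_vars <- function(x, vars) {
  if (is.character(x) && length(x) == 1L) {
    for (v in names(vars)) {
      x <- gsub(paste0("${", v, "}"), vars[[v]], x, fixed = TRUE)
    }
    return(x)
  }
  if (is.list(x)) return(lapply(x, subst_vars, vars = vars))
  x
}

#' Load conformance cases from YAML files
#'
#' Each file holds a `cases:` list. Cases are validated against the case
#' schema (unique non-empty ids, non-empty step lists, each step carrying a
#' request with method and path); violations raise
#' `tes_suite_schema_error` naming the file.
#'
#' @param paths YAML file paths, or a single directory (all `*.yaml` files
#'   in it, sorted).
#' @return list of case lists, in stable (file, position) order.
#' @export
tes_load_suite <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.ya?ml$",
                             full.names = TRUE))
  }
  schema_err <- function(file, msg) {
    tes_abort(paste0(file, ": ", msg), "tes_suite_schema_error", file = file)
  }
  cases <- list()
  seen <- character(0)
  for (f in paths) {
    doc <- tryCatch(yaml::read_yaml(f), error = function(e) {
      schema_err(f, paste0("YAML parse failure: ", conditionMessage(e)))
    })
    if (!is.list(doc) || is.null(doc$cases) || !is.list(doc$cases)) {
      schema_err(f, "file must contain a 'cases' list")
    }
    for (case in doc$cases) {
      if (!is_string(case$id %||% NA) || !nzchar(case$id %||% "")) {
        schema_err(f, "case missing id")
      }
      if (case$id %in% seen) {
        schema_err(f, paste0("duplicate case id: ", case$id))
      }
      seen <- c(seen, case$id)
      if (is.null(case$steps) || !is.list(case$steps) ||
          length(case$steps) == 0L) {
        schema_err(f, paste0("case ", case$id, ": steps list required"))
      }
      for (s in case$steps) {
        req <- s$request
        if (is.null(req) || !is_string(req$method %||% NA) ||
            !is_string(req$path %||% NA)) {
          schema_err(f, paste0("case ", case$id,
                               ": every step needs request.method and request.path"))
        }
      }
      case$tags <- as.character(unlist(case$tags %||% list()))
      cases[[length(cases) + 1L]] <- case
    }
  }
  cases
}

#' The suite shipped with the package
#'
#' One file per API component: task creation, retrieval, list filtering,
#' cancellation, view projection, service-info, and poll-to-terminal
#' lifecycle cases built on tiny no-op tasks.
#'
#' @return list of cases (see [tes_load_suite()]).
#' @export
tes_shipped_suite <- function() {
  tes_load_suite(system.file("conformance", package = "tesr"))
}

check_assertion <- function(a, status, doc) {
  if (!is.null(a$status)) {
    if (!identical(as.integer(status), as.integer(a$status))) {
      return(sprintf("expected status %s, got %s", a$status, status))
    }
    return(NULL)
  }
  if (is.null(a$path)) return("assertion has neither 'status' nor 'path'")
  val <- json_path_get(doc, a$path)
  if (!is.null(a$exists)) {
    if (isTRUE(a$exists) && is.null(val)) {
      return(sprintf("path %s: expected present, was absent", a$path))
    }
    if (isFALSE(a$exists) && !is.null(val)) {
      return(sprintf("path %s: expected absent, was present", a$path))
    }
    return(NULL)
  }
  if (is.null(val)) {
    return(sprintf("path %s: absent in response", a$path))
  }
  shown <- scalar_preview(val)
  if (!is.null(a$equals)) {
    ok <- !is.list(val) && length(val) == 1L &&
      ((is.numeric(a$equals) && is.numeric(val) && a$equals == val) ||
         identical(as.character(val), as.character(a$equals)))
    if (!ok) {
      return(sprintf("path %s: expected %s, got %s", a$path,
                     a$equals, shown))
    }
  }
  if (!is.null(a[["in"]])) {
    ok <- !is.list(val) && length(val) == 1L &&
      as.character(val) %in% as.character(unlist(a[["in"]]))
    if (!ok) {
      return(sprintf("path %s: value %s not in {%s}", a$path, shown,
                     paste(unlist(a[["in"]]), collapse = ", ")))
    }
  }
  if (!is.null(a$regex)) {
    ok <- !is.list(val) && length(val) == 1L &&
      grepl(a$regex, as.character(val))
    if (!ok) {
      return(sprintf("path %s: value %s does not match /%s/", a$path,
                     shown, a$regex))
    }
  }
  NULL
}

scalar_preview <- function(val) {
  if (is.list(val)) return("<object>")
  if (length(val) != 1L) return("<array>")
  as.character(val)
}

run_case <- function(case, transport, prefix) {
  vars <- list()
  for (si in seq_along(case$steps)) {
    # captured variables substitute anywhere in the step: request paths,
    # params, bodies, and assertion expectations
    step <- subst_vars(case$steps[[si]], vars)
    fail <- function(msg) sprintf("step %d: %s", si, msg)

    do_request <- function() {
      req <- step$request
      path <- paste0(prefix, req$path)
      query <- lapply(req$params %||% list(), as.character)
      body <- NULL
      if (!is.null(req$body)) {
        body <- as.character(json_out(req$body))
      }
      res <- transport(toupper(req$method), path, query, body)
      doc <- tryCatch(
        jsonlite::fromJSON(res$text, simplifyVector = FALSE),
        error = function(e) NULL
      )
      list(status = res$status, doc = doc)
    }

    res <- tryCatch(do_request(), error = function(e) e)
    if (inherits(res, "condition")) {
      return(fail(paste0("transport failure: ", conditionMessage(res))))
    }

    if (!is.null(step$poll)) {
      p <- step$poll
      timeout <- min(as.numeric(p$timeout %||% POLL_CAP_SECONDS),
                     POLL_CAP_SECONDS)
      interval <- as.numeric(p$interval %||% 0.2)
      targets <- as.character(unlist(p$until_in))
      deadline <- now_num() + timeout
      repeat {
        val <- json_path_get(res$doc, p$path)
        if (!is.null(val) && !is.list(val) && length(val) == 1L &&
            as.character(val) %in% targets) break
        if (now_num() > deadline) {
          return(fail(sprintf("poll timed out; %s last was %s", p$path,
                              val %||% "<absent>")))
        }
        Sys.sleep(interval)
        res <- tryCatch(do_request(), error = function(e) e)
        if (inherits(res, "condition")) {
          return(fail(paste0("transport failure: ",
                             conditionMessage(res))))
        }
      }
    }

    for (a in step$assert %||% list()) {
      msg <- check_assertion(a, res$status, res$doc)
      if (!is.null(msg)) return(fail(msg))
    }
    for (v in names(step$capture %||% list())) {
      val <- json_path_get(res$doc, step$capture[[v]])
      if (is.null(val)) {
        return(fail(sprintf("capture %s: path %s absent", v,
                            step$capture[[v]])))
      }
      vars[[v]] <- as.character(val)
    }
  }
  NULL
}

#' Run conformance cases against a TES endpoint
#'
#' Cases run sequentially; a case passes iff every assertion in every step
#' holds. Transport failures mark the case failed — they never crash the
#' runner.
#'
#' @param cases from [tes_load_suite()] / [tes_shipped_suite()].
#' @param base_url a TES server base URL, or
#' @param transport a transport function (e.g. [tes_local_transport()]).
#' @param tag_filter run only cases carrying at least one of these tags.
#' @param prefix mount prefix.
#' @return a `tes_conformance_report`: per-case pass/fail with the first
#'   failed assertion; `$passed` is the overall verdict.
#' @export
tes_run_suite <- function(cases, base_url = NULL, transport = NULL,
                          tag_filter = NULL, prefix = TES_URL_PREFIX) {
  if (is.null(transport)) {
    if (is.null(base_url)) stop("provide base_url or transport")
    transport <- tes_http_transport(base_url)
  }
  if (!is.null(tag_filter)) {
    cases <- Filter(function(c) any(c$tags %in% tag_filter), cases)
  }
  results <- lapply(cases, function(case) {
    failure <- run_case(case, transport, prefix)
    list(id = case$id, description = case$description %||% "",
         tags = case$tags, passed = is.null(failure), failure = failure)
  })
  structure(
    list(cases = results,
         passed = all(vapply(results, function(r) r$passed, logical(1)))),
    class = "tes_conformance_report"
  )
}

#' @export
print.tes_conformance_report <- function(x, ...) {
  for (r in x$cases) {
    status <- if (r$passed) "PASS" else "FAIL"
    cat(sprintf("[%s] %s", status, r$id))
    if (!r$passed) cat(" — ", r$failure, sep = "")
    cat("\n")
  }
  n <- length(x$cases)
  np <- sum(vapply(x$cases, function(r) r$passed, logical(1)))
  cat(sprintf("%d/%d cases passed\n", np, n))
  invisible(x)
}

#' Write a conformance report as JUnit-style XML
#'
#' @param report a `tes_conformance_report`.
#' @param path output file.
#' @export
tes_report_junit <- function(report, path) {
  n <- length(report$cases)
  failures <- sum(vapply(report$cases, function(r) !r$passed, logical(1)))
  doc <- xml2::xml_new_root("testsuite", name = "tes-conformance",
                            tests = as.character(n),
                            failures = as.character(failures))
  for (r in report$cases) {
    tc <- xml2::xml_add_child(doc, "testcase", name = r$id,
                              classname = paste(r$tags, collapse = ","))
    if (!r$passed) {
      f <- xml2::xml_add_child(tc, "failure", message = r$failure)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
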