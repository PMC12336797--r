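`%||%` <- function(x, y) if (is.null(x)) y else x

# All package errors are classed conditions rooted at "tes_error" so callers
# (and the HTTP layer) can map them to status codes without string matching.
tes_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "tes_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == trunc(x)
}

#' Current time as an RFC 3339 UTC timestamp
#'
#' All timestamps on the wire are RFC 3339 UTC strings with microsecond
#' precision, e.g. `"2024-06-19T12:00:00.123456Z"`.
#'
#' @param t a `POSIXct`; defaults to now.
#' @return length-1 character.
#' @export
tes_timestamp <- function(t = Sys.time()) {
  format(t, "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC")
}

# Monotonic-ish numeric clock used only for sort keys; never serialized.
now_num <- function() as.numeric(Sys.time())

# 26-character URL-safe random task identifier.
ID_ALPHABET <- c(LETTERS, letters, 0:9, "_", "-")

new_task_id <- function() {
  paste(sample(ID_ALPHABET, 26, replace = TRUE), collapse = "")
}

# Normalize an absolute workspace path: resolve "." and "..", collapse
# duplicate slashes. Returns NULL if the path escapes the root ("/").
normalize_ws_path <- function(path) {
  if (!is_string(path) || !startsWith(path, "/")) return(NULL)
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  out <- character(0)
  for (p in parts) {
    if (p == "" || p == ".") next
    if (p == "..") {
      if (length(out) == 0L) return(NULL)  # escapes the workspace root
      out <- out[-length(out)]
    } else {
      out <- c(out, p)
    }
  }
  paste0("/", paste(out, collapse = "/"))
}

# Read the final `n` bytes of a file as text (stdio tail capture).
read_tail <- function(path, n) {
  if (!file.exists(path)) return("")
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (size > n) seek(con, size - n)
  raw <- readBin(con, "raw", n = min(size, n))
  rawToChar(raw)
}

# Parse an application/x-www-form-urlencoded query string, preserving
# repeated keys in order (needed for positional tag_key/tag_value pairs).
parse_query <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  qs <- sub("^\\?", "", qs)
  pairs <- strsplit(qs, "&", fixed = TRUE)[[1]]
  pairs <- pairs[nzchar(pairs)]
  keys <- character(length(pairs))
  vals <- character(length(pairs))
  for (i in seq_along(pairs)) {
    kv <- strsplit(pairs[[i]], "=", fixed = TRUE)[[1]]
    keys[[i]] <- httpuv::decodeURIComponent(kv[[1]])
    vals[[i]] <- if (length(kv) > 1L) {
      httpuv::decodeURIComponent(paste(kv[-1], collapse = "="))
    } else ""
  }
  stats::setNames(as.list(vals), keys)
}

build_query <- function(params) {
  if (length(params) == 0L) return("")
  enc <- vapply(seq_along(params), function(i) {
    paste0(
      httpuv::encodeURIComponent(names(params)[[i]]), "=",
      httpuv::encodeURIComponent(as.character(params[[i]]))
    )
  }, character(1))
  paste0("?", paste(enc, collapse = "&"))
}

json_out <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
}
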