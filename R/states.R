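#' Task lifecycle states
#'
#' The vocabulary of the task state machine. A task is created `QUEUED`,
#' is claimed by a worker (`INITIALIZING`: workspace creation and input
#' staging), runs its executor sequence (`RUNNING`), and ends in exactly one
#' terminal state: `COMPLETE` (all non-ignored executors exited zero and all
#' declared outputs were exported), `EXECUTOR_ERROR` (user code failed:
#' non-ignored nonzero exit, or a declared output was not produced),
#' `SYSTEM_ERROR` (the service failed: staging, spawn, or export fault), or
#' `CANCELED`. A cancellation request on a live task passes through
#' `CANCELING` while the worker tears the attempt down.
#'
#' @export
TES_STATES <- c("QUEUED", "INITIALIZING", "RUNNING", "COMPLETE",
                "EXECUTOR_ERROR", "SYSTEM_ERROR", "CANCELING", "CANCELED")

#' Terminal (absorbing) task states
#' @export
TES_TERMINAL_STATES <- c("COMPLETE", "EXECUTOR_ERROR", "SYSTEM_ERROR",
                         "CANCELED")

# The closed edge set of the state machine. Any transition not listed here
# is illegal; terminal states have no outgoing edges.
TES_TRANSITIONS <- list(
  QUEUED       = c("INITIALIZING", "CANCELED"),
  INITIALIZING = c("RUNNING", "SYSTEM_ERROR", "CANCELING"),
  RUNNING      = c("COMPLETE", "EXECUTOR_ERROR", "SYSTEM_ERROR", "CANCELING"),
  CANCELING    = c("CANCELED")
)

#' Is a lifecycle state terminal?
#' @param state a state string.
#' @export
tes_is_terminal <- function(state) state %in% TES_TERMINAL_STATES

#' Is `from` -> `to` a legal lifecycle transition?
#'
#' The edge set is closed: `QUEUED -> {INITIALIZING, CANCELED}`,
#' `INITIALIZING -> {RUNNING, SYSTEM_ERROR, CANCELING}`, `RUNNING ->
#' {COMPLETE, EXECUTOR_ERROR, SYSTEM_ERROR, CANCELING}`, `CANCELING ->
#' CANCELED`; everything else is illegal.
#'
#' @param from,to state strings.
#' @export
tes_transition_allowed <- function(from, to) {
  to %in% (TES_TRANSITIONS[[from]] %||% character(0))
}
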