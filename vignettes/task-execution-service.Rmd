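---
title: "The tesr task execution service: model, semantics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tesr task execution service: model, semantics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bioinformatics analyses chain command-line tools with incompatible software
stacks across compute environments that guarantee nothing about each other:
an HPC node shares a POSIX filesystem and a configured environment with the
submission host, while a freshly allocated cloud VM has neither. The Task
Execution Service (TES) API addresses this by making the *task* an atomic,
self-contained message: it names the container image(s), command vectors,
resource minimums, the inputs to transfer into place before user code runs,
the outputs to export afterward, environment variables, and free-form
client tags. Because the message carries everything, it can be passed
between clients, servers, queues, and databases, and executed on whatever
backend a server fronts.

`tesr` implements the full service side of this contract in R — model,
store, staging, executor engine, lifecycle, HTTP endpoints — plus a client
with array fan-out and a YAML conformance runner. This vignette is the
package's account of the semantics it implements and the design decisions
that were genuinely open.

## The task message

A task document must carry at least one executor with a non-empty image
and command. Validation (`tes_validate_task()`) is all-or-nothing and
collects *every* violation with a JSON field path, so a client fixing a
rejected task sees the complete list at once. Normalization fills defaults
(`ignore_error = FALSE`, `type = "FILE"`, empty collections) and is
idempotent, which makes the normalized form a fixed point: serialize →
parse → validate returns the identical structure.

Two rules deserve justification because the API leaves them open:

* **Inputs carry exactly one of `url` or `content`.** An input with both
  would have two competing staging sources; mutual exclusion keeps the
  staging source unambiguous. Outputs must carry a `url` and never
  `content`.
* **Strict parsing by default.** Unknown fields are rejected rather than
  ignored so that conformance failures (typoed field names, schema drift)
  are loud at submission time; a `lenient` flag preserves unknown fields
  in place for interoperability testing.

Workspace paths (`path`, `workdir`, stdio mappings, `volumes`) must be
absolute and are normalized at validation time; a path whose normal form
escapes the workspace root (`/in/../../etc`) is rejected *before* the task
is ever stored, so no staging code needs to defend against traversal.

Field spellings follow the upstream TES v1.1 OpenAPI schema wherever this
package had no reason to deviate, so documents interoperate with other TES
tooling. One addition: `resources.gpu_count` is accepted and validated
(GPUs are part of the resource vocabulary even though the upstream message
omits a dedicated field). Resource requests are matched and recorded, not
enforced — enforcement is a property of real cluster backends, not of the
API contract.

## Views

Listing and retrieval accept exactly three detail levels:

| level   | contents                                                        |
|---------|-----------------------------------------------------------------|
| MINIMAL | `id`, `state`                                                   |
| BASIC   | everything except executor stdout/stderr tails, system logs, inline input content |
| FULL    | the complete record                                             |

The API names the levels but not their exact contents; the table above
implements the evident intent — BASIC removes the payloads whose size is
unbounded (stdio tails, logs, inline bytes) while keeping the record's
structure, giving the strict nesting MINIMAL ⊂ BASIC ⊂ FULL that the test
suite asserts on seeded records. Projection never mutates the stored
record.

## Identifiers, listing, and pagination

Task ids are 26-character URL-safe random tokens, unique per service
instance — the API requires uniqueness and nothing else, and random tokens
avoid leaking creation order. Listings are served in a stable total order
(creation time descending, id ascending as tie-break). Page tokens encode
the issuing query's fingerprint and the last-seen sort key, so a token
replayed against a different filter is rejected with a 400 rather than
silently returning the wrong slice. Default page size is 256, capped at
2048. Tag filters match exactly on key and value and conjoin; name
filtering is prefix match, not substring. Task retention is deliberately a
configuration concern, not schema: the default stores keep everything.

Two storage backends sit behind one contract: the in-memory store, and a
single-file append-only JSON journal (`FileTaskStore`) that replays on
open (last write per id wins) — crash-safe appends in one portable file,
with the same transition discipline after reopen.

## Staging

Input and output locations are arbitrary strings interpreted as URLs
through a protocol-handler registry; the sorted set of registered schemes
is exactly what `/service-info` advertises as `storage`. Built-ins are
`file` (copy, both directions), `http`/`https` (fetch-only), and `ftp`;
object stores like `s3` are plug-in extension points. A bare absolute path
is treated as a `file` URL, matching common client behavior. `http(s)`
output destinations are rejected at validation time because no generic
upload semantics exist for them.

Each input is transferred with 2 retries and exponential backoff before
the task fails; transfers are sequential per task, and a cancellation
interrupts staging *between* inputs (checked cooperatively), never
mid-transfer. Bulk file transfer is intentionally outside the service —
inputs are expected to live on storage both submitter and worker can
reach.

A fault taxonomy choice the API leaves open: a **declared output missing**
after the executor sequence finishes is classified an *executor* error
(the user's job failed to produce what it promised, mirroring exit-code
semantics), while staging faults, spawn failures, and export destination
faults are *system* errors.

## Executors

Executors run strictly sequentially, sharing staged inputs, outputs, and
volumes. A nonzero exit from an executor whose `ignore_error` flag is
unset ends the sequence early; with the flag set, the exit code is
recorded and the sequence continues. The sequence outcome is successful
iff every *non-ignored* executor exited zero. Exit codes are data — only
spawn failures raise errors, and they are classified as system faults,
distinct from user-code failure.

Stdio tails are bounded at 64 KiB per stream so FULL task documents stay
bounded; complete streams are available by mapping stdout/stderr to
workspace files. The executor environment is hermetic by default: only
`PATH`, `HOME` (pointing into the workspace), and `TES_WORKSPACE` are set
before the executor's own `env` map is overlaid, so tasks cannot silently
depend on the server's environment.

Execution backends implement a small runner contract. The default is a
**sandboxed host subprocess** that records the container image without
enforcing it, so the entire service, test suite, and conformance run need
no container daemon; a `docker`-compatible container runner is selected by
configuration, and scripted runners support fault-injection testing.
Because the subprocess backend materializes container-absolute workspace
paths (`/data/x`) under a host directory, commands address staged files
workspace-relatively (the working directory defaults to the workspace
root) or via `$TES_WORKSPACE`; under the container runner the workspace is
bind-mounted and absolute paths resolve as written. Image-format
translation for engines like Singularity is an extension seam on the
runner contract, not implemented here.

## Lifecycle

```
QUEUED ──► INITIALIZING ──► RUNNING ──► COMPLETE
   │             │             ├──────► EXECUTOR_ERROR
   │             ├──────► SYSTEM_ERROR ◄┤
   │             └──► CANCELING ◄───────┘(cancel)
   └────────► CANCELED ◄──┘
```

The edge set is closed and the four terminal states are absorbing; the
store enforces this on every write, so an illegal transition is impossible
to record, and observed state traces are checkable paths. Every fault maps
to a terminal state plus a timestamped system-log line — nothing escapes
the worker loop — and the workspace is always destroyed on the way out.

Scheduling is a cooperative event loop in one R process. The "worker pool"
is `pool_size` concurrent task slots (default 4): claiming a task is a
compare-and-set on QUEUED → INITIALIZING through the store's transition
check, which guarantees at-most-once execution; executor processes run
asynchronously and each `poll()` advances every active attempt. R's
single-threaded runtime makes in-process slots the natural pool design —
an in-memory store cannot be shared by OS-level worker processes — and the
HTTP serve loop interleaves socket servicing with scheduler polls so
execution progresses while requests are answered. Tasks are single-attempt
by design: retries are a client concern, keeping the logs structure 1:1
with attempts (the wire format still carries a *list* of attempt logs for
forward compatibility).

Cancellation semantics: a QUEUED task is canceled immediately and never
picked up; a live task moves to CANCELING, its current process receives a
polite termination signal, then a hard kill after a grace period (default
10 s, configurable); the partial log of the interrupted executor is
retained and later executors never start. Cancelling a terminal task is an
idempotent acknowledgment.

## HTTP surface

Five routes under `/ga4gh/tes/v1` (the upstream convention; configurable):
`POST /tasks`, `GET /tasks`, `GET /tasks/{id}`, `POST /tasks/{id}:cancel`,
`GET /service-info`. Everything — success or error — is JSON; errors use a
uniform `{message, status_code}` body. Validation failures map to 400 with
field paths in the message, unknown ids to 404, storage faults to 500. Tag
filters use repeated positionally-paired `tag_key`/`tag_value` parameters.
One dispatcher (`tes_handle()`) backs the httpuv app, the in-process
client transport, and the tests, so HTTP semantics cannot drift between
transports.

## The conformance suite

Cases are YAML documents a neutral runner interprets against any base URL:
each step issues a request, optionally polls a JSON-path value until it
enters a target set (capped at 60 s per case so the suite stays at desk
scale), captures values into `${var}` substitutions for later steps, and
asserts on status and JSON paths. The shipped suite is one file per API
component — creation, retrieval, list filtering, cancellation, views,
service-info, lifecycle — and the bundled server passing it is the
keystone test of the repository. The runner's neutrality is itself tested
by pointing it at a minimal stub that shares no code with the server. The
YAML dialect is this package's own design fulfilling the role of a
machine-readable conformance format; it makes no compatibility claim with
other TES test harnesses. Cases create uniquely-prefixed tasks but assume
a reasonably fresh server instance; running the suite twice against one
long-lived server can trip the counting assertions in the filtering cases.

## The fixture generator

`tes_fixture_task()` produces deterministic tasks per `(profile, seed)`:
`noop` (immediate success), `fail` (chosen exit code), `sleep`
(cancellation targets), `multi_exec` (scripted exit/ignore vectors for the
early-termination rule), and `io` (a seeded random file tree declared as a
DIRECTORY input, copied by the executor, and exported as a DIRECTORY
output — the staging-fidelity oracle). `tes_random_task()` draws valid
task messages across the type's invariants for round-trip properties.

What the generator emulates is the *control plane*: message validity,
state flow, staging mechanics, executor sequencing. What it does not
emulate: real container images (the subprocess runner records but does not
enforce them), remote-protocol transfers (fixtures stage over `file://`;
`http`/`ftp` handlers exist but tests never leave the host), large files,
or contended multi-tenant load. Passing tests therefore demonstrate
protocol and lifecycle correctness, not container isolation or
wide-area transfer behavior.

## Numerical and operational choices

* stdio tail bound: 64 KiB per stream; timestamps RFC 3339 UTC with
  microsecond precision (which also makes them sort lexicographically).
* staging: 2 retries per input, exponential backoff (0.5 s base).
* cancellation grace period: 10 s default; tests shorten it.
* scheduler: one input staged per poll (cooperative cancel); 1 ms sleeps
  between idle polls.
* page sizes: default 256, maximum 2048.
* ids: 26 characters over `[A-Za-z0-9_-]`, rejection-sampled to
  uniqueness within the store.

Problem sizes in the test suite were chosen to exercise each property well
inside a desk-scale run: the pagination oracle uses 200 tasks against
every filter × page sizes {1, 2, 3, 7}; the stop-rule oracle draws 1,000
random exit/ignore vectors against a reference interpreter; the
state-machine check enumerates every fault-injection point the pipeline
has; the default suite drives a 1,000-task no-op array to COMPLETE, and
`scripts/acceptance.R` runs the full 10,000-task array.

## Known limitations

* One R process: the pool is concurrent task slots, not OS-level workers;
  throughput is bounded by process-spawn latency (~5 ms per executor).
* No authentication, TLS, or rate limiting — deploy behind a reverse
  proxy if exposed.
* The journal store rewrites nothing and so grows monotonically; compaction
  is a maintenance operation left to deployment.
* `ftp` upload and `http(s)` fetch handlers exist but are untested against
  live remote endpoints in the default suite.
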