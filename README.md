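# tesr — a GA4GH Task Execution Service in R

`tesr` implements the GA4GH **Task Execution Service (TES)** API: the
standard HTTP interface for describing and executing batch command-line
tasks across HPC/HTC clusters, cloud platforms, and hybrid environments.
Bioinformatics pipelines chain command-line tools whose software stacks and
data rarely live where the compute does; TES makes the *task* an atomic
message carrying everything a bare worker needs — container image(s),
command vectors, resource minimums (CPU cores, GPUs, RAM, disk), inputs to
stage in, outputs to export, environment variables, and client tags — so
the same task runs anywhere a TES server fronts.

The package bundles:

* **Server** — task-message validation and normalization; an
  identifier-assigning store (in-memory, or a single-file append-only
  journal) with filtered, paginated, view-projected listings
  (MINIMAL/BASIC/FULL); URL-protocol staging through an extensible handler
  registry (`file`, `http`, `https`, `ftp` built in); a sequential
  executor engine honoring per-executor stdio/env mappings and the
  `ignore_error` early-termination rule; the task lifecycle state machine
  (`QUEUED → INITIALIZING → RUNNING → COMPLETE | EXECUTOR_ERROR |
  SYSTEM_ERROR | CANCELED`, with `CANCELING` for live cancellation) driven
  by a cooperative worker pool; and the five standard endpoints
  (`POST /tasks`, `GET /tasks`, `GET /tasks/{id}`,
  `POST /tasks/{id}:cancel`, `GET /service-info`) served over httpuv.
* **Client & CLI** — a typed client over HTTP or directly in-process,
  with polling (`wait`) and task-array fan-out (`submit_array`), plus a
  command-line front end (`inst/cli/tes.R`).
* **Conformance runner** — a YAML-driven test runner that exercises any
  TES base URL, with a shipped modular suite the bundled server passes.
* **Fixture generator** — deterministic synthetic tasks (`noop`, `fail`,
  `sleep`, `io`, `multi_exec`) so everything is testable offline.

Executor semantics in brief: executors run sequentially, one at a time,
sharing staged inputs, outputs, and volumes. A nonzero exit from an
executor whose `ignore_error` flag is unset (the default) ends the
sequence early and fails the task; the sequence succeeds iff every
non-ignored executor exits zero. Exit codes are data; only spawn faults
are system errors.

## Worked example

```r
library(tesr)
svc <- TesService$new(pool_size = 4L)      # in-memory store, subprocess runner
client <- TesClient$new(service = svc)     # same dispatcher the HTTP server mounts

id <- client$create(list(
  name = "demo-wordcount",
  inputs = list(list(content = "one two three\n", path = "/data/in.txt")),
  outputs = list(list(url = "file:///tmp/demo-count.txt", path = "/out/count.txt")),
  executors = list(list(
    image = "alpine",
    command = c("sh", "-c", "wc -w < data/in.txt > out/count.txt")
  ))
))
id
#> [1] "eO4VbD3ACYS6QXNL49JYw5f0o1"

client$wait(id, poll_interval = 0)
#> [1] "COMPLETE"

doc <- client$get(id, view = "FULL")
doc$logs[[1]]$outputs[[1]]$size_bytes      # exported manifest entry: "3\n"
#> [1] 2

readLines("/tmp/demo-count.txt")           # the exported output itself
#> [1] "3"

vapply(client$list(state = "COMPLETE", view = "BASIC")$tasks,
       function(t) t$name, character(1))
#> [1] "demo-wordcount"
```

The inline input was staged to `/data/in.txt` in the task workspace, the
executor counted its words (3), the declared output was exported to the
`file://` destination with its measured size (2 bytes, `"3\n"`) recorded
in the attempt's output manifest, and the finished task is visible through
the filtered listing.

To serve the same service over HTTP and test any server's conformance:

```sh
Rscript inst/cli/tes.R serve --port 8170 &
Rscript inst/cli/tes.R conform run --url http://127.0.0.1:8170
```

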