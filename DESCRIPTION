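Package: tesr
Title: Task Execution Service Server, Client, and Conformance Suite
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reference implementation of the GA4GH Task Execution Service
    (TES) API. Provides the task message model with validation and the three
    view-projection levels, an identifier-assigning task store with filtered
    and paginated listings, URL-protocol input/output staging, a sequential
    executor engine with ignore-error semantics and bounded log capture, the
    task lifecycle state machine with a cooperative worker scheduler, the
    standard HTTP endpoints served over 'httpuv', a programmatic client and
    command-line interface, a YAML-driven conformance test runner, and a
    deterministic fixture-task generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    jsonlite,
    yaml,
    curl,
    httpuv,
    processx,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    callr,
    withr
Config/testthat/edition: 3
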