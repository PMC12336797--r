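# Lifecycle functional cases: poll tiny tasks to their terminal states.
cases:
  - id: noop-task-completes
    description: A trivial task reaches COMPLETE with a zero exit code recorded.
    tags: [lifecycle]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            executors:
              - image: alpine
                command: ["true"]
        capture:
          task_id: id
      - request:
          method: GET
          path: /tasks/${task_id}
          params:
            view: FULL
        poll:
          path: state
          until_in: [COMPLETE, EXECUTOR_ERROR, SYSTEM_ERROR]
          interval: 0.1
          timeout: 30
        assert:
          - path: state
            equals: COMPLETE
          - path: logs[0].logs[0].exit_code
            equals: 0

  - id: failing-executor-is-executor-error
    description: A nonzero exit maps to EXECUTOR_ERROR with the code recorded verbatim.
    tags: [lifecycle]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            executors:
              - image: alpine
                command: ["sh", "-c", "exit 3"]
        capture:
          task_id: id
      - request:
          method: GET
          path: /tasks/${task_id}
          params:
            view: FULL
        poll:
          path: state
          until_in: [COMPLETE, EXECUTOR_ERROR, SYSTEM_ERROR]
          interval: 0.1
          timeout: 30
        assert:
          - path: state
            equals: EXECUTOR_ERROR
          - path: logs[0].logs[0].exit_code
            equals: 3

  - id: unsupported-input-protocol-is-system-error
    description: An input whose URL scheme has no registered handler fails staging; no executor runs.
    tags: [lifecycle]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            inputs:
              - url: "gs://bucket/object"
                path: /data/in
            executors:
              - image: alpine
                command: ["true"]
        capture:
          task_id: id
      - request:
          method: GET
          path: /tasks/${task_id}
          params:
            view: FULL
        poll:
          path: state
          until_in: [COMPLETE, EXECUTOR_ERROR, SYSTEM_ERROR]
          interval: 0.1
          timeout: 30
        assert:
          - path: state
            equals: SYSTEM_ERROR
          - path: logs[0].logs[0]
            exists: false

  - id: nonzero-exit-ends-sequence-early
    description: Without ignore_error, the first nonzero exit stops the sequence; later executors never run.
    tags: [lifecycle]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            executors:
              - {image: alpine, command: ["sh", "-c", "exit 0"]}
              - {image: alpine, command: ["sh", "-c", "exit 1"]}
              - {image: alpine, command: ["sh", "-c", "exit 0"]}
        capture:
          task_id: id
      - request:
          method: GET
          path: /tasks/${task_id}
          params:
            view: FULL
        poll:
          path: state
          until_in: [COMPLETE, EXECUTOR_ERROR, SYSTEM_ERROR]
          interval: 0.1
          timeout: 30
        assert:
          - path: state
            equals: EXECUTOR_ERROR
          - path: logs[0].logs[1].exit_code
            equals: 1
          - path: logs[0].logs[2]
            exists: false

  - id: ignore-error-lets-sequence-continue
    description: With ignore_error on the failing executor, the sequence continues and the task completes.
    tags: [lifecycle]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            executors:
              - {image: alpine, command: ["sh", "-c", "exit 0"]}
              - {image: alpine, command: ["sh", "-c", "exit 1"], ignore_error: true}
              - {image: alpine, command: ["sh", "-c", "exit 0"]}
        capture:
          task_id: id
      - request:
          method: GET
          path: /tasks/${task_id}
          params:
            view: FULL
        poll:
          path: state
          until_in: [COMPLETE, EXECUTOR_ERROR, SYSTEM_ERROR]
          interval: 0.1
          timeout: 30
        assert:
          - path: state
            equals: COMPLETE
          - path: logs[0].logs[1].exit_code
            equals: 1
          - path: logs[0].logs[2].exit_code
            equals: 0
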