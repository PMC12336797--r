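# Task creation: POST /tasks accepts conformant messages and rejects
# non-conformant ones with field-path details.
cases:
  - id: create-minimal-task
    description: A minimal valid task (one executor) is accepted and assigned a non-empty id.
    tags: [model, endpoints]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            name: conform-create-minimal
            executors:
              - image: alpine
                command: ["true"]
        capture:
          task_id: id
        assert:
          - status: 200
          - path: id
            regex: "^[A-Za-z0-9_-]+$"
      - request:
          method: GET
          path: /tasks/${task_id}
        assert:
          - status: 200
          - path: id
            equals: ${task_id}
          - path: state
            in: [QUEUED, INITIALIZING, RUNNING, COMPLETE]

  - id: create-rejects-empty-executors
    description: An empty executor list violates the task invariants and is rejected naming the field.
    tags: [model, endpoints]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            executors: []
        assert:
          - status: 400
          - path: message
            regex: executors
          - path: status_code
            equals: 400

  - id: create-rejects-unknown-field
    description: Strict parsing rejects documents with unknown top-level fields.
    tags: [model, endpoints]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            frobnicate: "yes"
            executors:
              - image: alpine
                command: ["true"]
        assert:
          - status: 400
          - path: message
            regex: frobnicate

  - id: create-rejects-input-with-url-and-content
    description: Inputs must carry exactly one of url and inline content.
    tags: [model]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            inputs:
              - url: "file:///tmp/a"
                content: "x"
                path: /data/a
            executors:
              - image: alpine
                command: ["true"]
        assert:
          - status: 400
          - path: message
            regex: "inputs\\[0\\]"
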