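# Cancellation: POST /tasks/{id}:cancel.
cases:
  - id: cancel-live-task
    description: Canceling a queued or running task drives it to CANCELED.
    tags: [lifecycle, endpoints]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            name: conform-cancel-sleeper
            executors:
              - image: alpine
                command: ["sleep", "30"]
        capture:
          task_id: id
        assert:
          - status: 200
      - request:
          method: POST
          path: /tasks/${task_id}:cancel
        assert:
          - status: 200
      - request:
          method: GET
          path: /tasks/${task_id}
        poll:
          path: state
          until_in: [CANCELED]
          interval: 0.1
          timeout: 30
        assert:
          - path: state
            equals: CANCELED

  - id: cancel-is-idempotent
    description: Canceling a finished task acknowledges without changing its terminal state.
    tags: [lifecycle, endpoints]
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
        poll:
          path: state
          until_in: [COMPLETE]
          interval: 0.1
          timeout: 30
      - request:
          method: POST
          path: /tasks/${task_id}:cancel
        assert:
          - status: 200
      - request:
          method: POST
          path: /tasks/${task_id}:cancel
        assert:
          - status: 200
      - request:
          method: GET
          path: /tasks/${task_id}
        assert:
          - path: state
            equals: COMPLETE

  - id: cancel-unknown-id-404
    description: Canceling an unknown id fails with 404.
    tags: [endpoints]
    steps:
      - request:
          method: POST
          path: /tasks/nonexistent0000000000000000:cancel
        assert:
          - status: 404
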