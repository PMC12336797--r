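# View projection: MINIMAL / BASIC / FULL detail levels.
cases:
  - id: minimal-view-is-id-and-state
    description: MINIMAL returns only the task id and state.
    tags: [views]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            name: conform-view-minimal
            executors:
              - image: alpine
                command: ["true"]
        capture:
          task_id: id
      - request:
          method: GET
          path: /tasks/${task_id}
          params:
            view: MINIMAL
        assert:
          - status: 200
          - path: id
            exists: true
          - path: state
            exists: true
          - path: name
            exists: false
          - path: executors
            exists: false
          - path: logs
            exists: false

  - id: basic-view-strips-bulky-payloads
    description: BASIC omits inline input content and executor stdio tails but keeps structure.
    tags: [views]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            name: conform-view-basic
            inputs:
              - content: "inline-payload"
                path: /data/in.txt
            executors:
              - image: alpine
                command: ["sh", "-c", "cat data/in.txt"]
        capture:
          task_id: id
      - request:
          method: GET
          path: /tasks/${task_id}
          params:
            view: FULL
        poll:
          path: state
          until_in: [COMPLETE]
          interval: 0.1
          timeout: 30
        assert:
          - path: logs[0].logs[0].stdout
            equals: inline-payload
      - request:
          method: GET
          path: /tasks/${task_id}
          params:
            view: BASIC
        assert:
          - status: 200
          - path: inputs[0].path
            exists: true
          - path: inputs[0].content
            exists: false
          - path: logs[0].logs[0].exit_code
            exists: true
          - path: logs[0].logs[0].stdout
            exists: false
          - path: logs[0].system_logs
            exists: false

  - id: full-view-includes-logs-and-tails
    description: FULL carries executor logs with stdio tails and system logs.
    tags: [views]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            executors:
              - image: alpine
                command: ["sh", "-c", "echo full-view-probe"]
        capture:
          task_id: id
      - request:
          method: GET
          path: /tasks/${task_id}
          params:
            view: FULL
        poll:
          path: state
          until_in: [COMPLETE]
          interval: 0.1
          timeout: 30
        assert:
          - path: logs[0].logs[0].exit_code
            equals: 0
          - path: logs[0].logs[0].stdout
            regex: full-view-probe
          - path: logs[0].system_logs
            exists: true
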