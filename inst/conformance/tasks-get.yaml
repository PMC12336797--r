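# Task retrieval: GET /tasks/{id}.
cases:
  - id: get-unknown-id-404
    description: Retrieving an unknown task id yields 404 with a JSON error body.
    tags: [endpoints]
    steps:
      - request:
          method: GET
          path: /tasks/nonexistent0000000000000000
        assert:
          - status: 404
          - path: message
            exists: true
          - path: status_code
            equals: 404

  - id: get-rejects-bogus-view
    description: The view parameter is a closed three-member enum.
    tags: [endpoints, views]
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
        assert:
          - status: 200
      - request:
          method: GET
          path: /tasks/${task_id}
          params:
            view: BOGUS
        assert:
          - status: 400

  - id: get-full-echoes-spec
    description: The FULL view contains the submitted spec verbatim alongside server-added fields.
    tags: [endpoints, model]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            name: conform-get-echo
            tags:
              project: conformance
            executors:
              - image: alpine/custom:1
                command: ["true"]
        capture:
          task_id: id
        assert:
          - status: 200
      - request:
          method: GET
          path: /tasks/${task_id}
          params:
            view: FULL
        assert:
          - status: 200
          - path: name
            equals: conform-get-echo
          - path: executors[0].image
            equals: "alpine/custom:1"
          - path: tags.project
            equals: conformance
          - path: creation_time
            exists: true
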