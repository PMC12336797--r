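# Listing: GET /tasks with state / name-prefix / tag filters and pagination.
cases:
  - id: list-returns-task-array
    description: The listing endpoint always returns a JSON tasks array.
    tags: [endpoints, filtering]
    steps:
      - request:
          method: GET
          path: /tasks
        assert:
          - status: 200
          - path: tasks
            exists: true

  - id: filter-by-name-prefix
    description: name_prefix matches task-name prefixes, not substrings.
    tags: [filtering]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            name: confprefix-alpha
            executors:
              - image: alpine
                command: ["true"]
        capture:
          task_id: id
      - request:
          method: POST
          path: /tasks
          body:
            name: not-confprefix-alpha
            executors:
              - image: alpine
                command: ["true"]
      - request:
          method: GET
          path: /tasks
          params:
            name_prefix: confprefix-
            view: BASIC
        assert:
          - status: 200
          - path: tasks[0].name
            regex: "^confprefix-"
          - path: tasks[1].name
            exists: false

  - id: filter-by-tag-pair
    description: tag_key/tag_value pairs filter on exact key and value match.
    tags: [filtering]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            tags:
              conform_marker: tag-target
            executors:
              - image: alpine
                command: ["true"]
        capture:
          task_id: id
      - request:
          method: GET
          path: /tasks
          params:
            tag_key: conform_marker
            tag_value: tag-target
        assert:
          - status: 200
          - path: tasks[0].id
            equals: ${task_id}
      - request:
          method: GET
          path: /tasks
          params:
            tag_key: conform_marker
            tag_value: no-such-value
        assert:
          - status: 200
          - path: tasks[0].id
            exists: false

  - id: pagination-token-walk
    description: page_size bounds each page; the token continues the same query and disappears on the last page.
    tags: [filtering, endpoints]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            name: confpage-0
            executors: [{image: alpine, command: ["true"]}]
      - request:
          method: POST
          path: /tasks
          body:
            name: confpage-1
            executors: [{image: alpine, command: ["true"]}]
      - request:
          method: POST
          path: /tasks
          body:
            name: confpage-2
            executors: [{image: alpine, command: ["true"]}]
      - request:
          method: GET
          path: /tasks
          params:
            name_prefix: confpage-
            page_size: 2
        capture:
          token: next_page_token
        assert:
          - status: 200
          - path: tasks[1].id
            exists: true
          - path: tasks[2].id
            exists: false
          - path: next_page_token
            exists: true
      - request:
          method: GET
          path: /tasks
          params:
            name_prefix: confpage-
            page_size: 2
            page_token: ${token}
        assert:
          - status: 200
          - path: tasks[0].id
            exists: true
          - path: tasks[1].id
            exists: false
          - path: next_page_token
            exists: false

  - id: foreign-page-token-rejected
    description: A token issued for one query is invalid for another.
    tags: [filtering]
    steps:
      - request:
          method: POST
          path: /tasks
          body:
            name: conftoken-0
            executors: [{image: alpine, command: ["true"]}]
      - request:
          method: POST
          path: /tasks
          body:
            name: conftoken-1
            executors: [{image: alpine, command: ["true"]}]
      - request:
          method: GET
          path: /tasks
          params:
            name_prefix: conftoken-
            page_size: 1
        capture:
          token: next_page_token
        assert:
          - status: 200
      - request:
          method: GET
          path: /tasks
          params:
            name_prefix: somethingelse-
            page_token: ${token}
        assert:
          - status: 400
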