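# Service discovery: GET /service-info.
cases:
  - id: service-info-shape
    description: The discovery document carries identity, type, and the storage protocol list.
    tags: [service-info, endpoints]
    steps:
      - request:
          method: GET
          path: /service-info
        assert:
          - status: 200
          - path: name
            exists: true
          - path: type.artifact
            equals: tes
          - path: storage
            exists: true

  - id: storage-advertises-file-protocol
    description: The storage property lists supported URL schemes (sorted); file is a built-in.
    tags: [service-info]
    steps:
      - request:
          method: GET
          path: /service-info
        assert:
          - status: 200
          - path: storage[0]
            equals: file
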