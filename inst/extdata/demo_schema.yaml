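attributes:
  - name: name
    role: identifier
    kind: categorical
  - name: age
    role: quasi_identifier
    kind: numeric
    domain: [0, 99]
    level_widths: [1, 5, 10, 20, 100]
  - name: sex
    role: quasi_identifier
    kind: categorical
    taxonomy:
      label: "*"
      children:
        - label: M
        - label: F
  - name: zipcode
    role: quasi_identifier
    kind: numeric
    domain: [1, 100000]
    level_widths: [1, 100, 1000, 10000, 100000]
  - name: disease
    role: sensitive
    kind: categorical
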