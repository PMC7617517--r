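device: "melanopiQ Circadian Eye"
manufacturer: "Max Planck Institute for Biological Cybernetics"
delimiter: ","
skip: 0
header: true
decimal_mark: "."
datetime:
  columns: ["Datetime"]
  format: "%Y-%m-%dT%H:%M:%S%z"
  timezone: embedded
id_column: null
channels:
  - column: "MEDI"
    channel: "MEDI"
    unit: "mel-EDI lx"
  - column: "LUX"
    channel: "lux"
    unit: "lx"
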